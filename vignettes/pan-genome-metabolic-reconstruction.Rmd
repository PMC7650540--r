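---
title: "Pan-genome guided metabolic reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-genome guided metabolic reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangemr)
```

`pangemr` is a pipeline for comparing the metabolism of related bacterial
species through their pan-genome: ortholog families are clustered across
proteomes into a presence/absence matrix, the openness of the pan-genome is
estimated by random genome-order sampling, the matrix is pivoted by enzymatic
function, per-species genome-scale metabolic models (GEMs) are consolidated
into a genus-level pan-GEM, draft models are repaired against a universal
reaction database by multi-condition MILP gap-filling, and species are
compared by Jaccard clustergrams of pathway reaction content. This vignette
documents the underlying models, the parameters that matter, and the design
choices that were genuinely open.

## Ortholog clustering

Proteins are clustered by **bidirectional best hit** (BDBH): every pair of
proteomes is aligned all-against-all with Needleman–Wunsch global alignment
(BLOSUM62, gap opening 10, extension 0.5, via `Biostrings`), and two genes are
linked when each is the other's best passing hit. A hit passes when

* coverage — aligned (both-non-gap) positions over the shorter sequence —
  is at least `min_coverage` (default **0.75**), and
* identity — identical positions over the shorter sequence — is at least
  `min_identity` (default **0.40**).

Within-species pairs passing the same thresholds are also linked, so recent
paralogs join their family. Clusters are connected components of this graph;
ties in best-hit selection break toward higher identity, then the
lexicographically smaller gene id, which makes the clustering deterministic
and invariant to input order. A `granularity` field (default 1.5) is recorded
in the configuration for provenance with Markov-clustering tools but plays no
role in BDBH; how a granularity parameter should map onto a non-MCL method is
undefined, so we record it and leave it unused.

Markov clustering itself is deliberately not reimplemented: BDBH is
deterministic and oracle-checkable (the test suite proves equivalence with
brute-force all-pairs connected components on instances up to 200 genes, and
exact recovery of planted families at adjusted Rand index 1 when within-family
identity is 0.9 against a 0.2 background).

A two-stage driver (`cluster_two_stage()`) mirrors the common workflow for
genera with several strains per species: stage 1 clusters within species,
stage 2 clusters representatives of user-chosen representative strains.

## Core/pan classification and accumulation curves

`classify_matrix()` partitions matrix rows into **core** (present in every
species), **strain-specific** (exactly one species), and **shell** (the
remainder), with percentages rounded to integers. A single-species matrix is
degenerate — every row is simultaneously core and strain-specific — and is
reported under core with a degeneracy flag.

`sample_curves()` implements random genome-order sampling: for each of
`n_permutations` (default **100**) orderings of the species, the pan size
(cumulative union) and core size (cumulative intersection) are recorded at
every prefix length. Within a permutation pan is non-decreasing and core
non-increasing by construction; the tests assert this exactly, and assert
equality with exhaustive enumeration over all orderings for small species
counts.

Two standard functional forms are fitted to the medians across permutations
(the cited sampling algorithms are conventionally paired with these forms;
medians are robust to sampling noise):

* **Pan growth** (Heaps-style): the median number of new families contributed
  by the N-th genome is modelled as $\kappa N^{-\gamma}$; the pan-genome is
  called *open* when $\gamma < 1$. The fitted rate evaluated at the last
  genome is reported as `new_families_at_N` — the "new families per
  additional genome" figure.
* **Core decay**: median core size is modelled as
  $(c_0-\Omega)e^{-(N-1)/\tau} + \Omega$ with asymptote $\Omega \ge 0$
  constrained not to exceed the observed core at the largest N.

Both fits use profiled/multi-start least squares (grid over the nonlinear
parameter with linear solves, polished by Levenberg–Marquardt via
`minpack.lm`) to avoid local minima; degenerate inputs (identical genomes)
return a closed verdict with rate 0 and an unidentifiable $\tau$ reported as
`NA` rather than a fit error. Parameter recovery on synthetic open
pan-genomes (core 100, 50 new families per genome, 5 genomes, 100
permutations, 20 seeds) holds the median error of the discovery rate within
15% and of the core asymptote within 10 families.

## Functional pivot

Ortholog clustering splits true functional groups when evolutionary distances
differ across species, hiding core functionality. The pivot merges matrix
rows by an explicit two-step rule (`canonicalize()`):

1. **EC match** — identical (sorted) EC-number sets merge; partial EC strings
   such as `2.8.3.-` merge only with the identical partial string, to avoid
   over-merging whole transferase families.
2. **Synonym match** — otherwise, names are normalized (case, punctuation,
   whitespace) and looked up in a synonym dictionary.
3. **Verbatim** — otherwise the normalized name itself is the key.

Hypothetical/putative/uncharacterized proteins are never merged: such
annotations carry no functional information, so each keeps a private row.
The function row is the elementwise OR of its contributing cluster rows; a
species has a function iff it has at least one contributing cluster.
`hidden_core()` then reports functions that are core at the functional level
while no single contributing cluster is core — the "hidden core" obscured by
differential clustering. The published notion of "similar functional
annotations" is not precise; the EC-then-synonym rule is this package's
explicit, documented stand-in.

## Metabolic models, SBML, and the pan-GEM

`metabolic_model()` is a light stoichiometric container: metabolites carry
bracketed compartment suffixes (`glc[e]`), reactions carry flux bounds, a
gene-association string and a subsystem. SBML Level 3 IO (`write_sbml()` /
`read_sbml()`, built on `xml2`) round-trips ids, stoichiometry, bounds, gene
associations and the biomass objective losslessly; it covers the SBML subset
the package writes (fbc-style bound parameters and flux objective).

Reactions classify by a fixed rule: the designated biomass reaction;
**exchange** = single-metabolite boundary reaction; **transporter** =
non-exchange reaction spanning two or more compartments; else **metabolic**.
Ids without a parseable compartment default to the cytosol, so such reactions
fall through to metabolic.

`build_pangem()` consolidates models into one table keyed by **normalized
reaction id** (compartment suffix stripped, optional alias table), with
per-species presence and gene-association columns — the supra-model layout.
Stoichiometric-equivalence matching is deliberately not attempted: models
built from a common curated database share ids, and equivalence matching
would silently merge distinct biochemistry. `reaction_sets()` provides the
core / group-exclusive / species-exclusive arithmetic; because published
percentages of such counts are ambiguous about their denominator, the package
reports raw counts (for all reactions and for metabolic reactions only) and
leaves percentages to the caller.

## FBA and multi-condition MILP gap-filling

Flux balance analysis maximizes biomass flux subject to steady-state mass
balance $Sv = 0$, flux bounds, and media-limited uptake (an exchange's uptake
bound is the rate its metabolite is granted in the medium; absent metabolites
get zero uptake; secretion is never restricted). LPs are solved by a dense
two-phase simplex written for this package (C++, with Bland's-rule
anti-cycling); there is deliberately a dual route in the tests, where an
independent simplex (`boot::simplex`) re-solves the same instances.

Gap-filling follows the phenotype-array protocol:

1. `add_transporters()` grants exchange + reversible uniport to every
   array-positive compound (idempotent).
2. `screen_conditions()` retains a growth condition only if the model plus
   the *entire* universal database can reach the growth threshold
   $\varepsilon$ on it; the rest are discarded as unexplainable.
3. `essential_candidates()` flags database reactions whose single removal
   (with everything else present) kills some retained condition — they must
   be in any solution.
4. `gapfill_milp()` minimizes the number of added database reactions such
   that **every** retained condition reaches $\varepsilon$ simultaneously:
   binary indicator $y_r$ per candidate, per-condition flux systems, and
   coupling $|v_r^c| \le M y_r$ (one indicator constrains both directions of
   a reversible candidate). The MILP is solved exactly by branch and bound:
   conditions couple only through $y$, so the weighted minimum of each
   condition's single-condition LP relaxation ($y \in [0,1]$) is a valid
   lower bound, and the largest of them plus the committed additions prunes
   the search. Among equal-cardinality optima, gene-supported candidates and
   then lexicographically earlier ids win, via infinitesimal weight
   perturbations (mirroring the curation preference for gene-supported
   candidates); the objective is pure cardinality by default, with optional
   weights.
5. Every result is re-verified by plain FBA per condition before it is
   returned; tests additionally prove minimality against brute-force subset
   enumeration on instances with up to ~30 candidates and 4 conditions, and
   monotonicity (adding a condition never shrinks the minimal addition set).

Defaults: $\varepsilon = 10^{-3}$ flux units, $M = 1000$ (dominating every
bound magnitude), LP feasibility tolerance $10^{-6}$, integrality
$10^{-5}$-scale perturbations kept three orders below cardinality so they can
never change the optimum count.

`minimal_media()` removes pool nutrients greedily (in reverse preference
order) while growth survives, then certifies irreducibility by single-removal
FBA — the standard irreducible-subset notion of a minimal medium beyond a
fixed base of salts and sources of C/N/P/S.

## Pathway clustergrams

Pathway definitions are plain tables (pathway id, member reaction ids),
editable by the user since pathway membership is curation-dependent.
`score_presence()` scores each reaction's per-species presence from the
pan-GEM; `jaccard_matrix()` compares species by the Jaccard similarity of
their present reaction sets, either against the pan-reactome or restricted to
a reference strain's repertoire (the two agree whenever the reference carries
the pathway's full pan-reactome — a tested invariant). Empty-versus-empty
Jaccard is defined as 1: two species both lacking a pathway are
indistinguishable on it. Clustergrams use average linkage (UPGMA) on
$1 - J$; the published analysis names only the metric, not the linkage, and
average linkage is the common default for similarity profiles. Dendrograms
are exported as Newick strings with merge heights plus a leaf-ordered
heat-map table.

## The synthetic-data generator

Every pipeline input can be generated with planted ground truth, so all
stages are testable offline:

* **Proteomes** (`generate_pangenome()`): core families occur once per
  species; shell families are Bernoulli(`p_shell`) per species; each species
  adds Poisson(`cloud_rate`) strain-specific families; optional
  *hidden-core pairs* are complementary shell families jointly covering all
  species. Sequences are random ~80–120 aa proteins; family members mutate
  the family ancestor at per-site rate $(1-w)/2$ so pairwise within-family
  identity targets $w$, while unrelated families sit near the random
  background. There is no codon model, no indel process and no rate
  heterogeneity — clustering only needs controlled identity, and passing
  tests show threshold behaviour, not robustness to realistic evolution.
* **Networks** (`generate_true_network()`): layered uptake → conversion →
  biomass chains with stoichiometric coefficients in {1, 2}; each panel
  compound has its own exchange/transport/conversion route into the central
  chain; a fraction of compounds are planted dead ends (route absent from
  the database — the screening stage must discard them); decoy conversions
  pad the database. Every species model is verified to grow on the base
  medium by FBA at build time. Biomass is a single sink reaction: FBA/MILP
  behaviour is exercised without biological realism, so tests show solver
  correctness, not biochemical plausibility.
* **Drafts** (`degrade_models()`): a recorded fraction of non-protected
  reactions is removed per species; biomass, exchanges and the base-medium
  transport route are never removed.
* **Phenotype arrays** (`simulate_phenotype_array()`): growth calls by FBA
  on the *true* model per sole-carbon-source condition at threshold
  $10^{-3}$.
* **Annotations** (`generate_annotations()`): a controlled fraction of
  multi-family functions are synonym-split (distinct synonymous names, no
  EC); cloud families become hypothetical proteins; the split count is
  recorded for exact comparison with the pivot's collapse.

All randomness flows from one explicit seed through `withr::with_seed`; no
global random state is touched, and a fixed seed reproduces byte-identical
FASTA/SBML/TSV artifacts (a tested invariant, and the basis of the
pipeline-manifest checksum test).

## Problem sizes and scope of the checks

The shipped checks run on deliberately small instances: clustering oracles at
~200 genes, accumulation fits at ~320 families over 100 permutations and 20
seeds, gap-filling at ≤ ~30 candidates and ≤ 4 conditions over 50+ random
instances, clustergrams at 4 species. These sizes make brute-force oracles
(subset enumeration, all-pairs alignment, exhaustive orderings) exact, which
is the point: correctness is proven against independent computation, while
scalability to real genome collections is a matter of the same algorithms on
larger inputs (all-pairs alignment is the only quadratic-cost stage).

## Known limitations

* BDBH with an identity cutoff stands in for Markov clustering; very fast or
  highly divergent families below 40% identity will fragment (exactly the
  failure mode the functional pivot then repairs).
* The SBML reader targets the subset this package writes; exotic SBML
  dialects (kinetic laws, species references by annotation) are out of scope.
* Gap-fill candidate weighting by annotation evidence is available but
  defaults to pure cardinality; likelihood-weighted gap-filling and
  thermodynamic reversibility assignment are out of scope.
* Reaction identity across models is id-based; models not built against a
  shared reaction database need an alias table.
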