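#' Parameters for the synthetic pan-genome generator
#'
#' Describes an open pan-genome in the classic core/shell/cloud partition:
#' `core_size` families occur once in every species, `shell_families` occur
#' in each species independently with probability `p_shell`, and each species
#' additionally carries a Poisson(`cloud_rate`) number of strain-specific
#' (cloud) families. `hidden_core_pairs` plants pairs of complementary shell
#' families that jointly cover all species while neither does alone - the
#' raw material for the hidden-core detector of the functional pivot.
#'
#' @param n_species number of species (>= 1).
#' @param core_size number of core families.
#' @param shell_families number of shell families.
#' @param p_shell per-species presence probability of a shell family, in (0,1).
#' @param cloud_rate expected strain-specific families per species (>= 0).
#' @param within_family_identity target pairwise amino-acid identity inside a
#'   family, in (0,1].
#' @param between_family_identity upper bound on expected identity across
#'   families, in [0,1); must be below `within_family_identity`.
#' @param hidden_core_pairs number of planted split-core family pairs.
#' @param seq_length_range integer range protein lengths are drawn from.
#' @param seed integer seed; the same seed reproduces byte-identical output.
#' @return a `pangenome_params` list.
#' @export
pangenome_params <- function(n_species, core_size, shell_families = 0,
                             p_shell = 0.5, cloud_rate = 0,
                             within_family_identity = 0.9,
                             between_family_identity = 0.2,
                             hidden_core_pairs = 0,
                             seq_length_range = c(80L, 120L), seed = 1L) {
  stopifnot(n_species >= 1, core_size >= 0, shell_families >= 0,
            cloud_rate >= 0, hidden_core_pairs >= 0)
  if (!(p_shell > 0 && p_shell < 1) && shell_families > 0)
    stop("p_shell must lie in (0,1)")
  if (!(within_family_identity > 0 && within_family_identity <= 1))
    stop("within_family_identity must lie in (0,1]")
  if (!(between_family_identity >= 0 && between_family_identity < 1))
    stop("between_family_identity must lie in [0,1)")
  if (within_family_identity <= between_family_identity)
    stop("within_family_identity must exceed between_family_identity")
  structure(list(n_species = as.integer(n_species),
                 core_size = as.integer(core_size),
                 shell_families = as.integer(shell_families),
                 p_shell = p_shell, cloud_rate = cloud_rate,
                 within_family_identity = within_family_identity,
                 between_family_identity = between_family_identity,
                 hidden_core_pairs = as.integer(hidden_core_pairs),
                 seq_length_range = as.integer(seq_length_range),
                 seed = as.integer(seed)),
            class = "pangenome_params")
}

aa_alphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) {
  paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}

# mutate each site independently with probability rate, always to a
# different residue, so two members drawn at rate (1-w)/2 from a common
# ancestor have expected pairwise identity of about w
mutate_protein <- function(seq, rate) {
  s <- strsplit(seq, "")[[1]]
  hit <- runif(length(s)) < rate
  if (any(hit)) {
    aa <- aa_alphabet()
    s[hit] <- vapply(s[hit], function(a) sample(setdiff(aa, a), 1), character(1))
  }
  paste(s, collapse = "")
}

#' Generate a synthetic pan-genome of protein sequences
#'
#' Produces per-species proteomes with a hidden ortholog-family label per
#' gene. Family members are independent mutants of a random family ancestor
#' at a per-site substitution rate of `(1 - within_family_identity)/2`;
#' ancestors of different families are independent random proteins, so
#' cross-family identity stays near the random-alignment background, below
#' `between_family_identity`.
#'
#' @param params a [pangenome_params()].
#' @return list with `proteomes` (named list of [Biostrings::AAStringSet],
#'   one per species `sp1..spN`), `truth` (data.frame gene/species/family/
#'   category/hidden_pair) and `params`.
#' @export
generate_pangenome <- function(params) {
  stopifnot(inherits(params, "pangenome_params"))
  withr::with_seed(params$seed, {
    n <- params$n_species
    species <- sprintf("sp%d", seq_len(n))
    fam <- 0L
    fam_rows <- list()          # per family: presence vector + category
    new_family <- function(presence, category, pair = NA_integer_) {
      fam <<- fam + 1L
      fam_rows[[fam]] <<- list(id = sprintf("fam%04d", fam),
                               presence = presence, category = category,
                               pair = pair)
    }
    for (i in seq_len(params$core_size))
      new_family(rep(TRUE, n), "core")
    for (i in seq_len(params$shell_families)) {
      repeat {
        pres <- runif(n) < params$p_shell
        if (any(pres)) break
      }
      new_family(pres, "shell")
    }
    if (params$hidden_core_pairs > 0 && n < 2)
      stop("hidden_core_pairs requires at least 2 species")
    for (p in seq_len(params$hidden_core_pairs)) {
      k <- sample(seq_len(n - 1L), 1)
      s1 <- sort(sample(n, k))
      pres1 <- seq_len(n) %in% s1
      new_family(pres1, "hidden", p)
      new_family(!pres1, "hidden", p)
    }
    for (i in seq_len(n)) {
      for (k in seq_len(rpois(1, params$cloud_rate))) {
        pres <- rep(FALSE, n); pres[i] <- TRUE
        new_family(pres, "cloud")
      }
    }

    rate <- (1 - params$within_family_identity) / 2
    lr <- params$seq_length_range
    genes <- vector("list", n)
    truth <- list()
    counter <- integer(n)
    for (f in fam_rows) {
      len <- sample(seq(lr[1], lr[2]), 1)
      anc <- random_protein(len)
      for (i in which(f$presence)) {
        counter[i] <- counter[i] + 1L
        gid <- sprintf("%s_g%04d", species[i], counter[i])
        genes[[i]][[gid]] <- mutate_protein(anc, rate)
        truth[[length(truth) + 1L]] <- data.frame(
          gene = gid, species = species[i], family = f$id,
          category = f$category, hidden_pair = f$pair,
          stringsAsFactors = FALSE)
      }
    }
    proteomes <- lapply(genes, function(g)
      Biostrings::AAStringSet(unlist(g)))
    names(proteomes) <- species
    list(proteomes = proteomes,
         truth = do.call(rbind, truth),
         params = params)
  })
}

#' Write per-species proteomes as FASTA
#' @param proteomes named list of [Biostrings::AAStringSet].
#' @param dir output directory (created if needed).
#' @return character vector of file paths, named by species.
#' @export
write_proteomes <- function(proteomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- setNames(file.path(dir, paste0(names(proteomes), ".faa")),
                    names(proteomes))
  for (sp in names(proteomes))
    Biostrings::writeXStringSet(proteomes[[sp]], paths[[sp]])
  paths
}

# --- universal reaction database -------------------------------------------

#' Construct a universal reaction database
#'
#' The candidate pool for gap-filling: a table of reactions with
#' stoichiometry, bounds and a gene-support flag, in the style of a
#' ModelSEED-like database.
#'
#' @param stoich named list of named numeric stoichiometries (as in
#'   [metabolic_model()]).
#' @param lb,ub bounds, recycled.
#' @param gene_supported logical, recycled; whether database evidence ties
#'   the reaction to genes.
#' @return a `reaction_db` object.
#' @export
reaction_db <- function(stoich, lb = -1000, ub = 1000, gene_supported = FALSE) {
  n <- length(stoich)
  stopifnot(n > 0, !is.null(names(stoich)))
  structure(list(stoich = stoich,
                 lb = rep_len(as.numeric(lb), n),
                 ub = rep_len(as.numeric(ub), n),
                 gene_supported = rep_len(as.logical(gene_supported), n),
                 ids = names(stoich)),
            class = "reaction_db")
}

#' @export
print.reaction_db <- function(x, ...) {
  cat("<reaction_db> ", length(x$ids), " reactions, ",
      sum(x$gene_supported), " gene-supported\n", sep = "")
  invisible(x)
}

db_subset <- function(db, ids) {
  keep <- match(ids, db$ids)
  reaction_db(db$stoich[keep], db$lb[keep], db$ub[keep], db$gene_supported[keep])
}

#' Merge database reactions into a model
#'
#' Adds every database reaction not already present in the model (by id).
#' @param model a [metabolic_model()].
#' @param db a [reaction_db()].
#' @param ids optional subset of database ids to add.
#' @return the extended model.
#' @export
model_with_db <- function(model, db, ids = db$ids) {
  ids <- setdiff(ids, model$reactions$id)
  if (length(ids) == 0L) return(model)
  k <- match(ids, db$ids)
  if (anyNA(k)) stop("unknown database reaction(s): ",
                     paste(ids[is.na(k)], collapse = ", "))
  add_reactions(model, db$stoich[k], lb = db$lb[k], ub = db$ub[k],
                gpr = ifelse(db$gene_supported[k], "dbgene", ""))
}

# --- synthetic true metabolic networks -------------------------------------

#' Generate a synthetic true network with a superset universal database
#'
#' Builds layered uptake -> conversion -> biomass toy networks: a base carbon
#' source feeds a short central chain into a biomass sink, and each panel
#' compound has its own exchange, transporter and two-step conversion route
#' into the chain, with stoichiometric coefficients in {1, 2}. A fraction of
#' panel compounds are planted dead ends (their conversion route is missing
#' from the database entirely), and decoy conversions among disconnected
#' metabolites pad the database to `db_size`. Per-species true models take
#' the base route plus shared routes (all species) and accessory routes
#' (species-specific coin flips, recorded); every species model is verified
#' to grow on the base medium by FBA at build time.
#'
#' @param n_species number of species models.
#' @param db_size total universal-database size (>= 12).
#' @param shared_fraction probability a panel route is shared by all species.
#' @param seed integer seed.
#' @param p_accessory inclusion probability of a non-shared route per species.
#' @param dead_fraction fraction of panel compounds planted as dead ends.
#' @param growth_threshold biomass flux a viable model must reach on the
#'   base medium.
#' @return list with `universal_db` ([reaction_db()]), `models` (list of
#'   [metabolic_model()], names `sp1..spN`), `base_medium` (named uptake
#'   vector), `compound_panel` (extracellular metabolite ids),
#'   `dead_end_compounds`, `route_reactions` (list: compound -> reaction ids
#'   of its route), and `accessory` (logical species x compound matrix of
#'   the recorded assignments).
#' @export
generate_true_network <- function(n_species, db_size = 30, shared_fraction = 0.5,
                                  seed = 1L, p_accessory = 0.5,
                                  dead_fraction = 0.15,
                                  growth_threshold = 1e-3) {
  if (db_size < 12) stop("db_size must be at least 12 (minimal viable chain)")
  withr::with_seed(seed, {
    species <- sprintf("sp%d", seq_len(n_species))
    # reaction budget: base route 3 (EX,T,CV) + core chain 2; live compound
    # route 4 (EX,T,CV1,CV2); dead compound 2 (EX,T); decoys fill the rest
    n_cpd <- max(2L, (db_size - 5L) %/% 5L)
    n_dead <- min(n_cpd - 1L, max(1L, round(dead_fraction * n_cpd)))
    dead <- sort(sample(n_cpd, n_dead))

    st <- list(); lbv <- c(); ubv <- c(); gs <- c()
    put <- function(id, s, lb, ub, gene = TRUE) {
      st[[id]] <<- s; lbv[id] <<- lb; ubv[id] <<- ub; gs[id] <<- gene
    }
    put("EX_base", c("base[e]" = -1), -1000, 1000, FALSE)
    put("T_base", c("base[e]" = -1, "base[c]" = 1), -1000, 1000)
    put("CV_base", c("base[c]" = -1, "A[c]" = 1), 0, 1000)
    put("CH_1", c("A[c]" = -1, "B[c]" = sample(1:2, 1)), 0, 1000)
    put("CH_2", c("B[c]" = -1, "P[c]" = 1), 0, 1000)
    route <- list(base = c("EX_base", "T_base", "CV_base"))
    for (j in seq_len(n_cpd)) {
      cpd <- sprintf("cpd%02d", j)
      put(paste0("EX_", cpd), setNames(-1, paste0(cpd, "[e]")), -1000, 1000, FALSE)
      put(paste0("T_", cpd),
          setNames(c(-1, 1), paste0(cpd, c("[e]", "[c]"))), -1000, 1000)
      if (!(j %in% dead)) {
        mid <- paste0("X", j, "[c]")
        put(paste0("CV1_", cpd),
            setNames(c(-1, sample(1:2, 1)), c(paste0(cpd, "[c]"), mid)), 0, 1000)
        put(paste0("CV2_", cpd), setNames(c(-1, 1), c(mid, "A[c]")), 0, 1000)
        route[[cpd]] <- paste0(c("EX_", "T_", "CV1_", "CV2_"), cpd)
      } else {
        route[[cpd]] <- paste0(c("EX_", "T_"), cpd)
      }
    }
    d <- 0L
    while (length(st) < db_size) {
      d <- d + 1L
      put(sprintf("DC_%02d", d),
          setNames(c(-1, 1), sprintf("dead%d[c]", c(d, d + 1L))), 0, 1000,
          gene = runif(1) < 0.5)
    }
    db <- reaction_db(st, lbv, ubv, gs)

    cpds <- sprintf("cpd%02d", seq_len(n_cpd))
    live <- setdiff(seq_len(n_cpd), dead)
    shared <- live[runif(length(live)) < shared_fraction]
    acc_pool <- setdiff(live, shared)
    accessory <- matrix(FALSE, n_species, n_cpd,
                        dimnames = list(species, cpds))
    accessory[, acc_pool] <- runif(n_species * length(acc_pool)) < p_accessory

    base_medium <- c("base[e]" = 10)
    models <- list()
    for (i in seq_len(n_species)) {
      ids <- c(route$base, "CH_1", "CH_2",
               unlist(route[cpds[shared]], use.names = FALSE),
               unlist(route[cpds[accessory[i, ]]], use.names = FALSE))
      m <- metabolic_model(species[i], st[ids], lbv[ids], ubv[ids],
                           gpr = ifelse(gs[ids], paste0(species[i], "_gene"), ""))
      m <- add_reactions(m, list(BIOMASS = c("P[c]" = -1)), lb = 0, ub = 1000)
      m$biomass_id <- "BIOMASS"
      sol <- fba(m, base_medium)
      if (sol$objective <= growth_threshold)
        stop("generated model ", species[i], " fails to grow on base medium")
      models[[species[i]]] <- m
    }
    list(universal_db = db, models = models, base_medium = base_medium,
         compound_panel = paste0(cpds, "[e]"),
         dead_end_compounds = paste0(cpds[dead], "[e]"),
         route_reactions = route, accessory = accessory, seed = seed)
  })
}

#' Remove reactions from true models to create drafts with planted gaps
#'
#' Biomass, exchange reactions and the transport route of the base medium
#' are protected and never removed; among the rest, a fraction
#' `gap_fraction` is deleted per species and recorded.
#'
#' @param models list of true [metabolic_model()]s.
#' @param gap_fraction fraction of removable reactions to delete, in [0,1).
#' @param seed integer seed.
#' @param base_medium named uptake vector whose transport route is protected.
#' @return list with `drafts` (models) and `gaps` (list per species of the
#'   removed reaction ids).
#' @export
degrade_models <- function(models, gap_fraction, seed = 1L,
                           base_medium = c("base[e]" = 10)) {
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop("gap_fraction must lie in [0,1)")
  withr::with_seed(seed, {
    drafts <- list(); gaps <- list()
    for (sp in names(models)) {
      m <- models[[sp]]
      cl <- reaction_classes(m)
      base_mets <- names(base_medium)
      touches_base <- vapply(m$stoich, function(s)
        any(names(s) %in% base_mets), logical(1))
      protected <- cl %in% c("biomass", "exchange") |
        (cl == "transporter" & touches_base)
      removable <- m$reactions$id[!protected]
      k <- floor(gap_fraction * length(removable))
      rem <- if (k > 0) sort(sample(removable, k)) else character(0)
      drafts[[sp]] <- remove_reactions(m, rem)
      gaps[[sp]] <- rem
    }
    list(drafts = drafts, gaps = gaps, gap_fraction = gap_fraction)
  })
}

#' Simulate a phenotype growth array on the true model
#'
#' Calls growth per panel compound as the sole carbon source: the medium
#' opens only that compound's exchange (at the base-medium rate), and the
#' call is `TRUE` iff FBA biomass on the true model reaches
#' `growth_threshold`. Compounds without an exchange reaction anywhere in
#' the database are reported as unmappable and excluded. Duplicated panel
#' entries are deduplicated.
#'
#' @param model the true [metabolic_model()].
#' @param compound_panel extracellular metabolite ids.
#' @param universal_db the [reaction_db()] naming the mappable exchanges.
#' @param growth_threshold minimal biomass flux called as growth.
#' @param uptake_rate uptake bound granted to the tested compound.
#' @return data.frame compound/growth/objective, plus attribute `unmappable`.
#' @export
simulate_phenotype_array <- function(model, compound_panel, universal_db,
                                     growth_threshold = 1e-3,
                                     uptake_rate = 10) {
  panel <- unique(compound_panel)
  db_ex_mets <- unlist(lapply(universal_db$stoich[
    lengths(universal_db$stoich) == 1L], names), use.names = FALSE)
  mappable <- panel %in% db_ex_mets
  res <- data.frame(compound = panel[mappable], growth = FALSE,
                    objective = 0, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    med <- setNames(uptake_rate, res$compound[i])
    sol <- fba(model, med)
    res$objective[i] <- sol$objective
    res$growth[i] <- sol$objective >= growth_threshold
  }
  attr(res, "unmappable") <- panel[!mappable]
  res
}

#' Generate functional annotations with controlled synonym splits
#'
#' Assigns each ortholog family a ground-truth function. A fraction
#' `split_rate` of the multi-family functions are "synonym-split": their
#' families receive distinct but synonymous enzyme names and no EC number,
#' so only the synonym dictionary can merge them. Unsplit functions carry
#' the canonical name, and half of them an EC number. Cloud (strain-specific)
#' families are annotated as hypothetical proteins, which the pivot never
#' merges. Families planted as hidden-core pairs are always split (that is
#' their purpose) and count toward the recorded split total.
#'
#' @param truth the `truth` data.frame of [generate_pangenome()].
#' @param n_functions number of ground-truth functions to spread over the
#'   non-cloud families.
#' @param split_rate fraction of multi-family functions to synonym-split,
#'   in [0,1).
#' @param seed integer seed.
#' @return list with `annotations` (data.frame cluster/name/ec keyed by
#'   family id), `synonyms` (data.frame name/canonical), `function_key`
#'   (data.frame family/function_id/split) and `n_split` (recorded count of
#'   synonym-split functions).
#' @export
generate_annotations <- function(truth, n_functions, split_rate = 0,
                                 seed = 1L) {
  if (split_rate < 0 || split_rate >= 1) stop("split_rate must lie in [0,1)")
  withr::with_seed(seed, {
    fam <- unique(truth[, c("family", "category", "hidden_pair")])
    fam <- fam[order(fam$family), ]
    cloud <- fam$family[fam$category == "cloud"]
    hidden <- fam[fam$category == "hidden", ]
    regular <- fam$family[!fam$category %in% c("cloud", "hidden")]

    fn_of <- character(0); split_of <- logical(0)
    syn_rows <- list(); ann_rows <- list()
    fid <- 0L
    new_fn <- function() { fid <<- fid + 1L; sprintf("F%03d", fid) }

    # hidden-core pairs: one shared function per pair, always synonym-split
    for (p in unique(hidden$hidden_pair)) {
      f <- new_fn()
      members <- hidden$family[hidden$hidden_pair == p]
      canon <- paste0("enzyme ", f)
      for (k in seq_along(members)) {
        nm <- if (k == 1) canon else paste0(canon, " synonym ", k - 1)
        if (k > 1) syn_rows[[length(syn_rows) + 1L]] <-
            data.frame(name = nm, canonical = canon, stringsAsFactors = FALSE)
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          cluster = members[k], name = nm, ec = "", stringsAsFactors = FALSE)
        fn_of[members[k]] <- f; split_of[f] <- TRUE
      }
    }

    # regular families round-robin over the remaining functions
    n_reg_fn <- max(0L, n_functions - length(unique(hidden$hidden_pair)))
    if (length(regular) > 0 && n_reg_fn == 0L)
      stop("n_functions too small for the non-cloud families present")
    if (length(regular) > 0) {
      fns <- vapply(seq_len(min(n_reg_fn, length(regular))),
                    function(i) new_fn(), character(1))
      assign_fn <- rep_len(fns, length(regular))
      multi <- names(which(table(assign_fn) > 1))
      do_split <- sample(multi, floor(split_rate * length(multi)))
      for (f in fns) split_of[f] <- f %in% do_split
      has_ec <- setNames(runif(length(fns)) < 0.5, fns)
      seen <- integer(0)
      for (i in seq_along(regular)) {
        f <- assign_fn[i]
        canon <- paste0("enzyme ", f)
        seen[f] <- if (f %in% names(seen)) seen[f] + 1L else 1L
        if (f %in% do_split) {
          nm <- if (seen[f] == 1) canon else paste0(canon, " synonym ", seen[f] - 1)
          if (seen[f] > 1) syn_rows[[length(syn_rows) + 1L]] <-
              data.frame(name = nm, canonical = canon, stringsAsFactors = FALSE)
          ec <- ""
        } else {
          nm <- canon
          ec <- if (has_ec[[f]]) paste0("1.1.1.", sub("^F0*", "", f)) else ""
        }
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          cluster = regular[i], name = nm, ec = ec, stringsAsFactors = FALSE)
        fn_of[regular[i]] <- f
      }
    }

    for (fm in cloud) {
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        cluster = fm, name = paste("hypothetical protein", fm), ec = "",
        stringsAsFactors = FALSE)
      f <- new_fn(); fn_of[fm] <- f; split_of[f] <- FALSE
    }

    annotations <- do.call(rbind, ann_rows)
    synonyms <- if (length(syn_rows)) do.call(rbind, syn_rows) else
      data.frame(name = character(0), canonical = character(0))
    list(annotations = annotations, synonyms = synonyms,
         function_key = data.frame(family = names(fn_of),
                                   function_id = unname(fn_of),
                                   split = unname(split_of[fn_of]),
                                   stringsAsFactors = FALSE),
         n_split = sum(split_of))
  })
}
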