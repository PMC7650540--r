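#' Ortholog clustering configuration
#'
#' Thresholds for reciprocal-best-hit ortholog detection on global protein
#' alignments: a hit requires alignment coverage of at least `min_coverage`
#' of the shorter sequence and at least `min_identity` identical positions
#' over the shorter sequence. The `granularity` field is recorded for
#' provenance with Markov-clustering-based tools but is not used by the
#' reciprocal-best-hit algorithm.
#'
#' @param min_coverage minimum aligned (non-gap) fraction of the shorter
#'   sequence, default 0.75.
#' @param min_identity minimum identity fraction over the shorter sequence,
#'   default 0.40.
#' @param granularity recorded clustering granularity, default 1.5 (unused).
#' @param gap_opening,gap_extension alignment gap penalties.
#' @param substitution_matrix scoring matrix name, default `"BLOSUM62"`.
#' @return a `clustering_config` list.
#' @export
clustering_config <- function(min_coverage = 0.75, min_identity = 0.40,
                              granularity = 1.5, gap_opening = 10,
                              gap_extension = 0.5,
                              substitution_matrix = "BLOSUM62") {
  stopifnot(min_coverage > 0, min_coverage <= 1,
            min_identity >= 0, min_identity <= 1)
  structure(list(min_coverage = min_coverage, min_identity = min_identity,
                 granularity = granularity, gap_opening = gap_opening,
                 gap_extension = gap_extension,
                 substitution_matrix = substitution_matrix),
            class = "clustering_config")
}

#' Global pairwise identity and coverage between two sequence sets
#'
#' Needleman-Wunsch global alignment of every sequence of `a` against every
#' sequence of `b`. Identity is identical positions over the shorter
#' sequence length; coverage is aligned (substituted, i.e. both-non-gap)
#' positions over the shorter sequence length.
#'
#' @param a,b [Biostrings::AAStringSet] objects.
#' @param config a [clustering_config()].
#' @return list of two matrices (`identity`, `coverage`) with rownames from
#'   `a` and colnames from `b`.
#' @export
alignment_identity <- function(a, b, config = clustering_config()) {
  data(list = config$substitution_matrix, package = "Biostrings",
       envir = environment())
  submat <- get(config$substitution_matrix, envir = environment())
  na <- length(a); nb <- length(b)
  idm <- cov <- matrix(0, na, nb, dimnames = list(names(a), names(b)))
  wa <- Biostrings::width(a)
  for (j in seq_len(nb)) {
    aln <- Biostrings::pairwiseAlignment(a, b[[j]], type = "global",
      substitutionMatrix = submat, gapOpening = config$gap_opening,
      gapExtension = config$gap_extension)
    shorter <- pmin(wa, Biostrings::width(b)[j])
    nm <- Biostrings::nmatch(aln)
    idm[, j] <- nm / shorter
    cov[, j] <- (nm + Biostrings::nmismatch(aln)) / shorter
  }
  list(identity = idm, coverage = cov)
}

#' Cluster proteins into ortholog families by reciprocal best hits
#'
#' Computes global alignments between all proteomes, links genes across
#' species when each is the other's best scoring hit (bidirectional best
#' hit) above the coverage and identity thresholds, links within-species
#' gene pairs (paralogs) above the same thresholds, and reports connected
#' components as ortholog clusters. Best-hit ties are broken toward higher
#' identity, then the lexicographically smaller gene id. The result is a
#' partition of all input genes (unlinked genes form singletons), invariant
#' to the order proteomes are supplied in.
#'
#' @param proteomes named list of [Biostrings::AAStringSet], one per
#'   species; gene names must be unique across species.
#' @param config a [clustering_config()].
#' @return an `ortholog_clusters` object: data.frame with columns
#'   `cluster_id`, `species`, `gene`, plus attribute `representatives`
#'   (named vector cluster_id -> representative gene).
#' @export
cluster_orthologs <- function(proteomes, config = clustering_config()) {
  if (length(proteomes) < 1L) stop("at least one proteome is required")
  if (is.null(names(proteomes)) || any(names(proteomes) == ""))
    stop("proteomes must be a named list (one name per species)")
  for (sp in names(proteomes)) {
    if (length(proteomes[[sp]]) == 0L)
      stop("empty proteome for species '", sp, "'")
    if (any(Biostrings::width(proteomes[[sp]]) == 0L))
      stop("empty sequence in proteome '", sp, "'")
  }
  # canonical order makes the result independent of input order
  proteomes <- proteomes[order(names(proteomes))]
  proteomes <- lapply(proteomes, function(p) p[order(names(p))])
  species <- names(proteomes)
  gene2sp <- unlist(lapply(species, function(sp)
    setNames(rep(sp, length(proteomes[[sp]])), names(proteomes[[sp]]))))
  if (anyDuplicated(names(gene2sp)))
    stop("gene ids must be unique across proteomes")

  edges_from <- character(0); edges_to <- character(0)
  add_edge <- function(g1, g2) {
    edges_from <<- c(edges_from, g1); edges_to <<- c(edges_to, g2)
  }
  pass <- function(al) al$identity >= config$min_identity &
    al$coverage >= config$min_coverage

  for (si in seq_along(species)) {
    # within-species paralog edges
    a <- proteomes[[si]]
    if (length(a) > 1L) {
      al <- alignment_identity(a, a, config)
      ok <- pass(al)
      idx <- which(ok & upper.tri(ok), arr.ind = TRUE)
      if (nrow(idx))
        add_edge(rownames(ok)[idx[, 1]], colnames(ok)[idx[, 2]])
    }
    for (sj in seq_along(species)) {
      if (sj <= si) next
      b <- proteomes[[sj]]
      al <- alignment_identity(a, b, config)
      ok <- pass(al)
      # best passing hit per row; ties toward the smaller gene id
      bh <- function(idm, okm) {
        out <- rep(NA_character_, nrow(idm))
        for (i in seq_len(nrow(idm))) {
          cand <- which(okm[i, ])
          if (length(cand)) {
            top <- cand[idm[i, cand] == max(idm[i, cand])]
            out[i] <- sort(colnames(idm)[top])[1]
          }
        }
        setNames(out, rownames(idm))
      }
      ab <- bh(al$identity, ok)
      ba <- bh(t(al$identity), t(ok))
      for (g in names(ab)) {
        h <- ab[[g]]
        if (!is.na(h) && !is.na(ba[[h]]) && ba[[h]] == g) add_edge(g, h)
      }
    }
  }

  g <- igraph::graph_from_data_frame(
    data.frame(from = edges_from, to = edges_to, stringsAsFactors = FALSE),
    directed = FALSE, vertices = names(gene2sp))
  comp <- igraph::components(g)$membership
  # deterministic ids: clusters ordered by their smallest member gene id
  first <- tapply(names(comp), comp, function(v) sort(v)[1])
  ord <- order(first)
  relabel <- setNames(seq_along(ord), names(first)[ord])
  cid <- sprintf("OC%05d", relabel[as.character(comp)])
  out <- data.frame(cluster_id = cid, species = unname(gene2sp[names(comp)]),
                    gene = names(comp), stringsAsFactors = FALSE)
  out <- out[order(out$cluster_id, out$gene), ]
  rownames(out) <- NULL
  widths <- setNames(unlist(lapply(proteomes, Biostrings::width)),
                     names(gene2sp))
  reps <- vapply(split(out$gene, out$cluster_id), function(gs) {
    gs[order(-widths[gs], gs)][1]
  }, character(1))
  structure(out, representatives = reps, class = c("ortholog_clusters",
                                                   "data.frame"))
}

#' Two-stage ortholog clustering with representative strains
#'
#' Stage 1 clusters each species' proteome against itself (collapsing
#' recent paralogs); stage 2 runs the cross-species reciprocal-best-hit
#' clustering on the representative sequence of every stage-1 cluster,
#' restricted to user-chosen representative strains.
#'
#' @param proteomes named list of [Biostrings::AAStringSet].
#' @param representatives character vector of species to carry into stage
#'   2 (default: all).
#' @param config a [clustering_config()].
#' @return list with `stage1` (per-species `ortholog_clusters`) and
#'   `stage2` (`ortholog_clusters` over representative genes).
#' @export
cluster_two_stage <- function(proteomes, representatives = names(proteomes),
                              config = clustering_config()) {
  stopifnot(all(representatives %in% names(proteomes)))
  stage1 <- lapply(names(proteomes), function(sp)
    cluster_orthologs(proteomes[sp], config))
  names(stage1) <- names(proteomes)
  rep_sets <- lapply(representatives, function(sp) {
    reps <- attr(stage1[[sp]], "representatives")
    proteomes[[sp]][unname(reps)]
  })
  names(rep_sets) <- representatives
  list(stage1 = stage1, stage2 = cluster_orthologs(rep_sets, config))
}

#' Build the pan-genomic matrix from ortholog clusters
#'
#' @param clusters an `ortholog_clusters` data.frame (cluster_id, species,
#'   gene).
#' @param species_list column order of the matrix; every member's species
#'   must appear here.
#' @return a `pan_genome_matrix`: integer matrix of member counts, clusters
#'   by species.
#' @export
build_matrix <- function(clusters, species_list) {
  unknown <- setdiff(unique(clusters$species), species_list)
  if (length(unknown)) stop("unknown species id(s): ",
                            paste(unknown, collapse = ", "))
  tab <- table(factor(clusters$cluster_id),
               factor(clusters$species, levels = species_list))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  structure(m, class = c("pan_genome_matrix", class(m)))
}

#' Binarize a pan-genome (or functional) matrix
#' @param m a matrix of member counts.
#' @return logical presence matrix of the same shape.
#' @export
binarize <- function(m) {
  structure(unclass(m) > 0, dimnames = dimnames(m))
}

#' Classify pan-genome matrix rows into core / shell / strain-specific
#'
#' Core rows are present in every species, strain-specific rows in exactly
#' one; the remainder is shell. Percentages are relative to total rows and
#' rounded to the nearest integer. For a single-species matrix every row is
#' simultaneously core and strain-specific; such rows are reported under
#' core and the result is flagged degenerate.
#'
#' @param m a [build_matrix()] result (or any count/presence matrix).
#' @return list with `counts`, `percent` (named core/shell/
#'   strain_specific), `total`, and `degenerate`.
#' @export
classify_matrix <- function(m) {
  if (length(m) == 0L) stop("empty matrix")
  b <- binarize(m)
  npres <- rowSums(b)
  total <- nrow(b)
  degenerate <- ncol(b) == 1L
  core <- sum(npres == ncol(b))
  strain <- if (degenerate) 0L else sum(npres == 1L)
  shell <- total - core - strain
  counts <- c(core = core, shell = shell, strain_specific = strain)
  list(counts = counts, percent = round(100 * counts / total),
       total = total, degenerate = degenerate)
}
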