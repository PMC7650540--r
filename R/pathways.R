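#' Jaccard similarity between two sets
#'
#' `|a intersect b| / |a union b|`. Two empty sets are defined as maximally
#' similar (1): for pathway profiles, species that both lack a pathway are
#' indistinguishable on it.
#'
#' @param a,b vectors treated as sets.
#' @return similarity in [0, 1].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Score pathway reaction presence per species
#'
#' Resolves each pathway's member reactions against the pan-GEM and records
#' the per-species presence bit of every resolved reaction. Reaction ids
#' absent from the pan-GEM are reported; pathways left empty after
#' resolution are dropped with a warning.
#'
#' @param pangem a [build_pangem()] result.
#' @param pathway_defs data.frame with columns `pathway`, `reaction`.
#' @return a `pathway_profile` object: list with `presence` (long
#'   data.frame species/pathway/reaction/present), `sets` (nested list
#'   species -> pathway -> present reaction ids), `pathways`, `species`,
#'   `unresolved` (dropped reaction ids).
#' @export
score_presence <- function(pangem, pathway_defs) {
  stopifnot(all(c("pathway", "reaction") %in% names(pathway_defs)))
  p <- pangem_presence(pangem)
  resolved <- pathway_defs$reaction %in% rownames(p)
  unresolved <- unique(pathway_defs$reaction[!resolved])
  defs <- pathway_defs[resolved, ]
  empty <- setdiff(unique(pathway_defs$pathway), unique(defs$pathway))
  if (length(empty))
    warning("pathway(s) dropped (no resolvable reactions): ",
            paste(empty, collapse = ", "))
  if (nrow(defs) == 0L) stop("no pathway reactions resolve against the pan-GEM")
  species <- attr(pangem, "species")
  long <- do.call(rbind, lapply(species, function(sp)
    data.frame(species = sp, pathway = defs$pathway, reaction = defs$reaction,
               present = p[defs$reaction, sp], stringsAsFactors = FALSE)))
  rownames(long) <- NULL
  sets <- lapply(species, function(sp) {
    d <- long[long$species == sp & long$present, ]
    split(d$reaction, factor(d$pathway, levels = unique(defs$pathway)))
  })
  names(sets) <- species
  structure(list(presence = long, sets = sets,
                 pathways = unique(defs$pathway), species = species,
                 pathway_reactions = split(defs$reaction, defs$pathway),
                 unresolved = unresolved),
            class = "pathway_profile")
}

#' Species-by-species Jaccard similarity of pathway reaction content
#'
#' In `"pan"` reference mode the compared sets are each species' present
#' pathway reactions out of the full pan-reactome complement; in
#' `"reference"` mode both sets are first intersected with the reaction
#' complement of a reference strain, so distances express differences
#' relative to that strain's repertoire. The two modes agree whenever the
#' reference strain carries the full pan-reactome of the scored pathways.
#'
#' @param profile a [score_presence()] result.
#' @param reference_mode `"pan"` or `"reference"`.
#' @param reference species id (required for `"reference"` mode).
#' @return symmetric similarity matrix with unit diagonal.
#' @export
jaccard_matrix <- function(profile, reference_mode = c("pan", "reference"),
                           reference = NULL) {
  reference_mode <- match.arg(reference_mode)
  sp <- profile$species
  allsets <- lapply(sp, function(s)
    unlist(profile$sets[[s]], use.names = FALSE))
  names(allsets) <- sp
  if (reference_mode == "reference") {
    if (is.null(reference) || !reference %in% sp)
      stop("reference must name one of the profiled species")
    universe <- allsets[[reference]]
    allsets <- lapply(allsets, intersect, y = universe)
  }
  J <- matrix(1, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in seq_along(sp)) for (j in seq_along(sp))
    if (i < j) J[i, j] <- J[j, i] <- jaccard(allsets[[i]], allsets[[j]])
  J
}

#' Cluster species by pathway similarity (clustergram)
#'
#' Agglomerative (average-linkage) clustering on distance `1 - J` over the
#' species' pathway reaction content, with the per-pathway completeness
#' heat-map table emitted in dendrogram leaf order.
#'
#' @param profile a [score_presence()] result (>= 2 species).
#' @inheritParams jaccard_matrix
#' @return list with `similarity` (the Jaccard matrix), `hclust`, `newick`
#'   (tree string with merge heights), `leaf_order`, and `heatmap`
#'   (species x pathway matrix of the fraction of each pathway's
#'   pan-reactome present, rows in leaf order).
#' @export
cluster_profiles <- function(profile, reference_mode = c("pan", "reference"),
                             reference = NULL) {
  if (length(profile$species) < 2L) stop("at least 2 species are required")
  J <- jaccard_matrix(profile, reference_mode, reference)
  hc <- hclust(as.dist(1 - J), method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  paths <- profile$pathways
  hm <- matrix(0, length(profile$species), length(paths),
               dimnames = list(profile$species, paths))
  for (sp in profile$species) for (pw in paths) {
    total <- length(profile$pathway_reactions[[pw]])
    hm[sp, pw] <- length(profile$sets[[sp]][[pw]]) / total
  }
  leaf_order <- hc$labels[hc$order]
  list(similarity = J, hclust = hc, newick = newick,
       leaf_order = leaf_order, heatmap = hm[leaf_order, , drop = FALSE])
}
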