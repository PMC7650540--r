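#' Normalize a reaction id for cross-model comparison
#'
#' Reaction identity across models is the database id after stripping a
#' bracketed or underscore compartment suffix (`"rxn00001[c]"`,
#' `"rxn00001_c"` -> `"rxn00001"`) and applying an optional alias table.
#' Stoichiometric-equivalence matching is deliberately not attempted.
#'
#' @param ids character reaction ids.
#' @param aliases optional named character vector mapping raw ids to
#'   canonical ids (applied after suffix stripping).
#' @param compartment_regex pattern of the strippable suffix.
#' @return normalized ids.
#' @export
normalize_reaction_id <- function(ids,
                                  aliases = NULL,
                                  compartment_regex = "(\\[[a-z]\\]|_[ce])$") {
  out <- sub(compartment_regex, "", ids)
  if (!is.null(aliases)) {
    hit <- out %in% names(aliases)
    out[hit] <- aliases[out[hit]]
  }
  out
}

#' Consolidate per-species models into a genus-level pan-GEM
#'
#' One row per normalized reaction id across all models, with per-species
#' presence flags and gene-association strings, plus the reaction class
#' (metabolic / transporter / exchange / biomass) taken from the first
#' model carrying the reaction. The census by class and the core set
#' (reactions present in every species) are attached.
#'
#' @param models list of [metabolic_model()]s.
#' @param species_ids names for the presence columns (default: model ids);
#'   duplicates are an error.
#' @param aliases optional alias table for [normalize_reaction_id()].
#' @return a `pangem` object: data.frame with columns `reaction`, `class`,
#'   one logical `present.<sp>` and one character `genes.<sp>` per species;
#'   attributes `species`, `core` (core reaction ids) and `census`.
#' @export
build_pangem <- function(models, species_ids = NULL, aliases = NULL) {
  if (length(models) < 1L) stop("at least one model is required")
  if (is.null(species_ids))
    species_ids <- vapply(models, function(m) m$id, character(1))
  if (anyDuplicated(species_ids))
    stop("duplicate species id(s): ",
         paste(unique(species_ids[duplicated(species_ids)]), collapse = ", "))
  names(models) <- species_ids

  norm <- lapply(models, function(m)
    normalize_reaction_id(m$reactions$id, aliases))
  all_rxn <- sort(unique(unlist(norm, use.names = FALSE)))
  pres <- matrix(FALSE, length(all_rxn), length(models),
                 dimnames = list(all_rxn, species_ids))
  gmat <- matrix("", length(all_rxn), length(models),
                 dimnames = list(all_rxn, species_ids))
  cl <- setNames(rep(NA_character_, length(all_rxn)), all_rxn)
  for (sp in species_ids) {
    m <- models[[sp]]
    rc <- reaction_classes(m)
    ids <- norm[[sp]]
    pres[ids, sp] <- TRUE
    gmat[ids, sp] <- m$reactions$gpr
    take <- is.na(cl[ids])
    cl[ids[take]] <- rc[take]
  }
  out <- data.frame(reaction = all_rxn, class = unname(cl),
                    stringsAsFactors = FALSE)
  for (sp in species_ids) {
    out[[paste0("present.", sp)]] <- unname(pres[, sp])
    out[[paste0("genes.", sp)]] <- unname(gmat[, sp])
  }
  core <- all_rxn[rowSums(pres) == length(models)]
  census <- c(table(factor(cl, levels = c("metabolic", "transporter",
                                          "exchange", "biomass"))))
  structure(out, species = species_ids, core = core, census = census,
            class = c("pangem", "data.frame"))
}

#' @export
print.pangem <- function(x, ...) {
  cs <- attr(x, "census")
  cat("<pangem> ", nrow(x), " reactions over ",
      length(attr(x, "species")), " species\n",
      "  metabolic: ", cs[["metabolic"]],
      "  transporters: ", cs[["transporter"]],
      "  core: ", length(attr(x, "core")), "\n", sep = "")
  invisible(x)
}

pangem_presence <- function(pangem) {
  sp <- attr(pangem, "species")
  p <- as.matrix(pangem[, paste0("present.", sp)])
  colnames(p) <- sp
  rownames(p) <- pangem$reaction
  p
}

#' Core / group-exclusive / species-exclusive reaction counts
#'
#' Set arithmetic over the pan-GEM presence flags. A reaction is exclusive
#' to a group when it occurs in at least one group member and in no
#' non-member; exclusive-and-universal when additionally present in every
#' group member. Species-exclusive counts treat each species as a
#' singleton group. Counts are reported for all reactions and for
#' metabolic reactions only (the usual basis of comparison).
#'
#' @param pangem a [build_pangem()] result.
#' @param grouping named character vector species -> group label, covering
#'   all species.
#' @return list with `core` (count), `group_exclusive`,
#'   `group_exclusive_universal` (named by group), `species_exclusive`
#'   (named by species), and the same restricted to metabolic reactions
#'   under `metabolic$...`.
#' @export
reaction_sets <- function(pangem, grouping) {
  sp <- attr(pangem, "species")
  if (!all(sp %in% names(grouping)))
    stop("grouping must cover all species: missing ",
         paste(setdiff(sp, names(grouping)), collapse = ", "))
  p <- pangem_presence(pangem)
  met <- pangem$class == "metabolic"
  count_sets <- function(pm) {
    groups <- unique(grouping[sp])
    gx <- gxu <- setNames(integer(length(groups)), groups)
    for (g in groups) {
      ing <- sp[grouping[sp] == g]
      inside <- rowSums(pm[, ing, drop = FALSE])
      outside <- rowSums(pm[, setdiff(sp, ing), drop = FALSE])
      gx[g] <- sum(inside >= 1 & outside == 0)
      gxu[g] <- sum(inside == length(ing) & outside == 0)
    }
    sx <- setNames(integer(length(sp)), sp)
    for (s in sp)
      sx[s] <- sum(pm[, s] & rowSums(pm[, setdiff(sp, s), drop = FALSE]) == 0)
    list(core = sum(rowSums(pm) == length(sp)),
         group_exclusive = gx, group_exclusive_universal = gxu,
         species_exclusive = sx)
  }
  out <- count_sets(p)
  out$metabolic <- count_sets(p[met, , drop = FALSE])
  out
}

#' Reaction differences between two models
#'
#' Symmetric difference of the two reaction sets by normalized id,
#' partitioned by direction; optionally restricted to metabolic reactions.
#'
#' @param a,b [metabolic_model()]s.
#' @param aliases optional alias table for [normalize_reaction_id()].
#' @param metabolic_only drop transporters/exchanges/biomass first.
#' @return list with `a_only` and `b_only` (character vectors).
#' @export
diff_models <- function(a, b, aliases = NULL, metabolic_only = FALSE) {
  ids <- function(m) {
    keep <- if (metabolic_only)
      reaction_classes(m) == "metabolic" else rep(TRUE, nrow(m$reactions))
    unique(normalize_reaction_id(m$reactions$id[keep], aliases))
  }
  ia <- ids(a); ib <- ids(b)
  list(a_only = sort(setdiff(ia, ib)), b_only = sort(setdiff(ib, ia)))
}

#' Write a pan-GEM as a wide TSV
#' @param pangem a [build_pangem()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pangem <- function(pangem, path) {
  write.table(as.data.frame(pangem), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
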