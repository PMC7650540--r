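#' Canonicalize a functional annotation into a function key
#'
#' Merging rule, in fixed precedence: (1) EC match - annotations sharing the
#' same (sorted) set of EC numbers get the same key; partial EC strings like
#' `"2.8.3.-"` only match identical partial strings. (2) Synonym match - the
#' normalized name is looked up in the synonym dictionary and replaced by
#' its canonical form. (3) Verbatim - the normalized name itself.
#' Name comparison ignores case, punctuation and whitespace runs.
#' Hypothetical/putative/uncharacterized proteins are canonicalized verbatim
#' but flagged non-mergeable; the pivot keeps each such cluster as its own
#' row. Unparseable EC strings fall back to name matching.
#'
#' Canonicalization is idempotent: applying it to a key's own name yields
#' the same key.
#'
#' @param name annotation name string.
#' @param ec character vector of EC numbers (or a single `";"`-separated
#'   string); may be empty.
#' @param synonyms data.frame with columns `name`, `canonical`.
#' @return a `function_key` list: `key`, `rule` (`"ec"`, `"synonym"`,
#'   `"verbatim"`), `mergeable`, `name`, `ec`.
#' @export
canonicalize <- function(name, ec = character(0), synonyms = NULL) {
  if (length(ec) == 1L && grepl(";", ec))
    ec <- strsplit(ec, ";")[[1]]
  ec <- trimws(ec[!is.na(ec) & trimws(ec) != ""])
  valid_ec <- grepl("^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9A-Za-z]+|-)$", ec)
  nname <- normalize_name(name)
  hypothetical <- grepl("hypothetical|putative|uncharacteri[sz]ed", nname)
  if (any(valid_ec) && !hypothetical) {
    key <- paste0("ec:", paste(sort(unique(ec[valid_ec])), collapse = "+"))
    return(structure(list(key = key, rule = "ec", mergeable = TRUE,
                          name = name, ec = ec), class = "function_key"))
  }
  if (hypothetical)
    return(structure(list(key = paste0("name:", nname), rule = "verbatim",
                          mergeable = FALSE, name = name, ec = ec),
                     class = "function_key"))
  if (!is.null(synonyms) && nrow(synonyms)) {
    lut <- setNames(normalize_name(synonyms$canonical),
                    normalize_name(synonyms$name))
    if (nname %in% names(lut))
      return(structure(list(key = paste0("name:", lut[[nname]]),
                            rule = "synonym", mergeable = TRUE,
                            name = name, ec = ec), class = "function_key"))
  }
  structure(list(key = paste0("name:", nname), rule = "verbatim",
                 mergeable = TRUE, name = name, ec = ec),
            class = "function_key")
}

normalize_name <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

#' Pivot the pan-genomic matrix by function
#'
#' Collapses ortholog-cluster rows that canonicalize to the same function
#' key ([canonicalize()]); the row of a function is the elementwise OR of
#' its contributing cluster rows, so a species has a function iff it has at
#' least one contributing cluster. Non-mergeable (hypothetical/putative)
#' clusters each keep a private row.
#'
#' @param m a [build_matrix()] result.
#' @param annotations data.frame with columns `cluster`, `name`, `ec`
#'   (`";"`-separated string, possibly empty); every matrix row needs an
#'   annotation.
#' @param synonyms synonym dictionary (data.frame `name`, `canonical`).
#' @return a `functional_matrix`: logical presence matrix (functions by
#'   species) with attributes `back_map` (named list key -> cluster ids),
#'   `rules` (named character key -> merge rule), `collapse_ratio`
#'   (rows after / rows before) and `n_merged` (rows removed by collapsing).
#' @export
pivot <- function(m, annotations, synonyms = NULL) {
  cl_ids <- rownames(m)
  miss <- setdiff(cl_ids, annotations$cluster)
  if (length(miss))
    stop("annotation missing for cluster(s): ", paste(miss, collapse = ", "))
  ann <- annotations[match(cl_ids, annotations$cluster), ]
  keys <- character(length(cl_ids)); rules <- character(length(cl_ids))
  for (i in seq_along(cl_ids)) {
    fk <- canonicalize(ann$name[i], ann$ec[i], synonyms)
    keys[i] <- if (fk$mergeable) fk$key else
      paste0(fk$key, "#", cl_ids[i])       # private row, never merged
    rules[i] <- fk$rule
  }
  b <- binarize(m)
  groups <- split(seq_along(keys), keys)
  fm <- t(vapply(groups, function(ix)
    colSums(b[ix, , drop = FALSE]) > 0, logical(ncol(b))))
  colnames(fm) <- colnames(m)
  back <- lapply(groups, function(ix) cl_ids[ix])
  structure(fm,
            back_map = back,
            rules = setNames(rules, keys)[!duplicated(keys)],
            collapse_ratio = nrow(fm) / nrow(m),
            n_merged = nrow(m) - nrow(fm),
            class = c("functional_matrix", class(fm)))
}

#' Detect hidden-core functions
#'
#' Functions whose pivoted row is present in every species while none of
#' their contributing ortholog clusters is individually core - core
#' functionality obscured by differential clustering.
#'
#' @param m the [build_matrix()] result the pivot was computed from.
#' @param fm the corresponding [pivot()] result.
#' @return character vector of hidden-core function keys.
#' @export
hidden_core <- function(m, fm) {
  b <- binarize(m)
  back <- attr(fm, "back_map")
  all_present <- rownames(fm)[rowSums(fm) == ncol(fm)]
  out <- character(0)
  for (key in all_present) {
    members <- back[[key]]
    member_core <- rowSums(b[members, , drop = FALSE]) == ncol(b)
    if (!any(member_core)) out <- c(out, key)
  }
  out
}
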