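# shared readers/writers for the TSV formats used across stages

#' Write / read a pan-genome or functional matrix as TSV
#'
#' Header row = species; first column = row (cluster/function) ids.
#' @param m matrix with dimnames.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), unclass(m) * 1, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  structure(m, class = c("pan_genome_matrix", class(m)))
}

#' Format / parse reaction equation strings
#'
#' Human-readable stoichiometry: `"1 a[c] + 2 b[c] -> 1 p[c]"`, with `"<=>"`
#' for reversible reactions. Round-trips through [parse_equation()].
#' @param stoich named numeric stoichiometry (negative = substrate).
#' @param reversible logical.
#' @return equation string (format) or list `stoich`, `reversible` (parse).
#' @export
format_equation <- function(stoich, reversible = TRUE) {
  side <- function(s) {
    if (length(s) == 0L) return("")
    paste(paste(format(abs(unname(s)), trim = TRUE), names(s)), collapse = " + ")
  }
  paste(side(stoich[stoich < 0]), if (reversible) "<=>" else "->",
        side(stoich[stoich > 0]))
}

#' @rdname format_equation
#' @param equation an equation string.
#' @export
parse_equation <- function(equation) {
  rev <- grepl("<=>", equation)
  parts <- strsplit(equation, if (rev) "<=>" else "->", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("malformed equation: ", equation)
  side <- function(txt, sign) {
    txt <- trimws(txt)
    if (txt == "") return(numeric(0))
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    coef <- as.numeric(sub("^([0-9.]+) .*$", "\\1", terms))
    met <- sub("^[0-9.]+ ", "", terms)
    setNames(sign * coef, met)
  }
  list(stoich = c(side(parts[1], -1), side(parts[2], 1)), reversible = rev)
}

#' Write / read a universal reaction database as TSV
#'
#' Columns: id, equation, reversible, gene_supported, lb, ub.
#' @param db a [reaction_db()].
#' @param path file path.
#' @return `path` (write) or a [reaction_db()] (read).
#' @export
write_reaction_db <- function(db, path) {
  df <- data.frame(
    id = db$ids,
    equation = vapply(seq_along(db$ids), function(i)
      format_equation(db$stoich[[i]], db$lb[i] < 0), character(1)),
    reversible = db$lb < 0,
    gene_supported = db$gene_supported,
    lb = db$lb, ub = db$ub, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reaction_db
#' @export
read_reaction_db <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  st <- lapply(df$equation, function(e) parse_equation(e)$stoich)
  names(st) <- df$id
  reaction_db(st, lb = df$lb, ub = df$ub, gene_supported = df$gene_supported)
}

#' Write / read media as TSV (compound, max_uptake)
#' @param media named uptake vector.
#' @param path file path.
#' @export
write_media_tsv <- function(media, path) {
  write.table(data.frame(compound = names(media),
                         max_uptake = unname(media)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_media_tsv
#' @export
read_media_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(df$max_uptake, df$compound)
}

#' Pipeline configuration
#'
#' All tunables of the end-to-end synthetic pipeline in one validated
#' object. Unknown fields are rejected; the object round-trips losslessly
#' through JSON (see [run_pipeline()]'s manifest).
#'
#' @param out_dir output directory.
#' @param seed master seed; all stage seeds derive from it.
#' @param n_species,core_size,shell_families,p_shell,cloud_rate,hidden_core_pairs
#'   pan-genome generator settings ([pangenome_params()]).
#' @param n_functions,split_rate annotation generator settings.
#' @param db_size,shared_fraction,gap_fraction network generator and
#'   degradation settings.
#' @param epsilon,big_M gap-fill settings.
#' @param min_coverage,min_identity clustering thresholds.
#' @param n_permutations accumulation-curve permutations.
#' @param models_dir optional directory of existing SBML models to use in
#'   place of generated ones.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, n_species = 5L, core_size = 40L,
                       shell_families = 20L, p_shell = 0.5, cloud_rate = 10,
                       hidden_core_pairs = 2L, n_functions = 30L,
                       split_rate = 0.2, db_size = 30L,
                       shared_fraction = 0.5, gap_fraction = 0.15,
                       epsilon = 1e-3, big_M = 1000, min_coverage = 0.75,
                       min_identity = 0.40, n_permutations = 100L,
                       models_dir = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Coerce a plain list (e.g. parsed JSON) to a run_config
#'
#' @param x named list of configuration fields; unknown keys are rejected.
#' @return a `run_config`.
#' @export
as_run_config <- function(x) {
  known <- names(formals(run_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(run_config, x)
}

#' Run the full synthetic pipeline
#'
#' Executes generation -> ortholog clustering -> matrix classification ->
#' accumulation-curve fits -> functional pivot -> pan-GEM -> multi-condition
#' gap-fill -> pathway clustergram, writing each stage's outputs under
#' `config$out_dir` and an md5-checksummed run manifest. A stage failure
#' aborts with the stage name; rerunning the same config reproduces the
#' checksums of all deterministic outputs.
#'
#' @param config a [run_config()].
#' @return the manifest (invisibly also written as `manifest.json`): list
#'   with `params`, `files` (named md5 vector), `results` (headline numbers
#'   per stage).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- synth ---------------------------------------------------------------
  pg <- net <- drafts <- ann <- NULL
  stage("synth", {
    pg <- generate_pangenome(pangenome_params(
      n_species = config$n_species, core_size = config$core_size,
      shell_families = config$shell_families, p_shell = config$p_shell,
      cloud_rate = config$cloud_rate,
      hidden_core_pairs = config$hidden_core_pairs, seed = config$seed))
    files <- c(files, write_proteomes(pg$proteomes, file.path(out, "proteomes")))
    write.table(pg$truth, file.path(out, "family_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    net <- generate_true_network(n_species = config$n_species,
                                  db_size = config$db_size,
                                  shared_fraction = config$shared_fraction,
                                  seed = config$seed + 1L)
    ann <- generate_annotations(pg$truth, n_functions = config$n_functions,
                                 split_rate = config$split_rate,
                                 seed = config$seed + 2L)
    write.table(ann$annotations, file.path(out, "annotations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ann$synonyms, file.path(out, "synonyms.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_reaction_db(net$universal_db, file.path(out, "universal_db.tsv"))
    mdir <- file.path(out, "models"); dir.create(mdir, showWarnings = FALSE)
    for (sp in names(net$models))
      write_sbml(net$models[[sp]], file.path(mdir, paste0(sp, ".xml")))
    drafts <- degrade_models(net$models, config$gap_fraction,
                              seed = config$seed + 3L,
                              base_medium = net$base_medium)
    ddir <- file.path(out, "drafts"); dir.create(ddir, showWarnings = FALSE)
    for (sp in names(drafts$drafts))
      write_sbml(drafts$drafts[[sp]], file.path(ddir, paste0(sp, ".xml")))
    pa <- simulate_phenotype_array(net$models[[1]], net$compound_panel,
                                   net$universal_db)
    write.table(pa, file.path(out, "phenotype_array.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$synth <- list(n_genes = nrow(pg$truth),
                           n_db_reactions = length(net$universal_db$ids),
                           n_growth_calls = sum(pa$growth))
  })
  models <- net$models
  if (!is.null(config$models_dir)) {
    stage("load_models", {
      paths <- list.files(config$models_dir, pattern = "\\.xml$",
                          full.names = TRUE)
      if (length(paths) == 0L)
        stop("no SBML models at path: ", config$models_dir)
      models <- lapply(paths, read_sbml)
    })
  }

  # --- pangenome -----------------------------------------------------------
  mat <- NULL
  stage("pangenome", {
    cl <- cluster_orthologs(pg$proteomes, clustering_config(
      min_coverage = config$min_coverage, min_identity = config$min_identity))
    write.table(as.data.frame(cl), file.path(out, "clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    mat <- build_matrix(cl, names(pg$proteomes))
    write_matrix_tsv(mat, file.path(out, "pan_matrix.tsv"))
    results$pangenome <- classify_matrix(mat)[c("counts", "percent")]
  })

  # --- panfit --------------------------------------------------------------
  stage("panfit", {
    curves <- sample_curves(mat, n_permutations = config$n_permutations,
                            seed = config$seed + 4L)
    write.table(curves, file.path(out, "accumulation_curves.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    gf <- fit_pan_growth(curves); cf <- fit_core_decay(curves)
    results$panfit <- list(new_families_at_N = gf$new_families_at_N,
                            verdict = gf$verdict, core_omega = cf$omega)
  })

  # --- funcpivot -----------------------------------------------------------
  stage("funcpivot", {
    # annotate clusters by the (unanimous on clean recovery) family of
    # their member genes
    cl <- read.delim(file.path(out, "clusters.tsv"), stringsAsFactors = FALSE)
    fam_of_gene <- setNames(pg$truth$family, pg$truth$gene)
    cl$family <- fam_of_gene[cl$gene]
    fam_major <- vapply(split(cl$family, cl$cluster_id), function(f)
      names(sort(table(f), decreasing = TRUE))[1], character(1))
    ann_cl <- ann$annotations[match(fam_major, ann$annotations$cluster), ]
    ann_cl$cluster <- names(fam_major)
    fm <- pivot(mat, ann_cl, ann$synonyms)
    write_matrix_tsv(fm, file.path(out, "functional_matrix.tsv"))
    hc <- hidden_core(mat, fm)
    jsonlite::write_json(
      list(collapse_ratio = attr(fm, "collapse_ratio"),
           n_merged = attr(fm, "n_merged"), hidden_core = hc),
      file.path(out, "pivot_report.json"), auto_unbox = TRUE, digits = NA)
    results$funcpivot <- list(collapse_ratio = attr(fm, "collapse_ratio"),
                               n_hidden_core = length(hc))
  })

  # --- pangem --------------------------------------------------------------
  pgem <- NULL
  stage("pangem", {
    pgem <- build_pangem(models)
    write_pangem(pgem, file.path(out, "pangem.tsv"))
    results$pangem <- list(census = attr(pgem, "census"),
                            core = length(attr(pgem, "core")))
  })

  # --- gapfill -------------------------------------------------------------
  stage("gapfill", {
    sp1 <- names(drafts$drafts)[1]
    draft <- drafts$drafts[[sp1]]
    pa <- read.delim(file.path(out, "phenotype_array.tsv"),
                     stringsAsFactors = FALSE)
    pos <- pa$compound[pa$growth]
    draft <- add_transporters(draft, pos)
    conds <- c(list(base = net$base_medium),
               setNames(lapply(pos, function(cpd) setNames(10, cpd)), pos))
    scr <- screen_conditions(draft, net$universal_db, conds, config$epsilon)
    prob <- gapfill_problem(draft, net$universal_db, conds[scr$retained],
                            epsilon = config$epsilon, big_M = config$big_M)
    res <- gapfill_milp(prob)
    jsonlite::write_json(
      list(added = res$added, objective = res$objective,
           verified = res$verified, discarded = scr$discarded,
           planted_gaps = drafts$gaps[[sp1]]),
      file.path(out, "gapfill_result.json"), auto_unbox = TRUE, digits = NA)
    results$gapfill <- list(added = res$added, verified = res$verified,
                             n_discarded = length(scr$discarded))
  })

  # --- pathways ------------------------------------------------------------
  stage("pathways", {
    defs <- do.call(rbind, lapply(names(net$route_reactions), function(cp)
      data.frame(pathway = paste0("catabolism_", cp),
                 reaction = net$route_reactions[[cp]],
                 stringsAsFactors = FALSE)))
    # dead-end routes never made it into any model; drop them up front
    defs <- defs[defs$reaction %in% pgem$reaction, ]
    prof <- score_presence(pgem, defs)
    cg <- cluster_profiles(prof, "pan")
    write.table(cg$similarity, file.path(out, "jaccard_similarity.tsv"),
                sep = "\t", quote = FALSE)
    writeLines(cg$newick, file.path(out, "clustergram.nwk"))
    write.table(cg$heatmap, file.path(out, "pathway_heatmap.tsv"),
                sep = "\t", quote = FALSE)
    results$pathways <- list(leaf_order = cg$leaf_order)
  })

  rel_files <- sort(setdiff(list.files(out, recursive = TRUE),
                            "manifest.json"))
  md5 <- tools::md5sum(file.path(out, rel_files))
  names(md5) <- rel_files                   # manifest is path-relocatable
  manifest <- list(
    package_version = as.character(utils::packageVersion("pangemr")),
    params = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    files = as.list(md5),
    results = results)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
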