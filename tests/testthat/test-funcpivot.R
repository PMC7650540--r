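test_that("canonicalization merges by EC, then synonym, never hypothetical", {
  syn <- data.frame(name = "acetokinase", canonical = "acetate kinase")
  k1 <- canonicalize("acetate kinase", "2.7.2.1", syn)
  k2 <- canonicalize("acetokinase", "2.7.2.1", syn)
  expect_equal(k1$key, k2$key)
  expect_equal(k1$rule, "ec")

  # synonym rule when no EC is available
  k3 <- canonicalize("acetate kinase", character(0), syn)
  k4 <- canonicalize("acetokinase", character(0), syn)
  expect_equal(k3$key, k4$key)
  expect_equal(k4$rule, "synonym")

  # case/whitespace/punctuation-insensitive comparison
  k5 <- canonicalize("Acetate--Kinase ", character(0), syn)
  expect_equal(k5$key, k3$key)

  # hypothetical/putative: verbatim, never mergeable
  h <- canonicalize("hypothetical protein", character(0), syn)
  expect_false(h$mergeable)
  expect_equal(h$rule, "verbatim")

  # partial EC numbers merge only with the identical partial string
  p1 <- canonicalize("transferase A", "2.8.3.-")
  p2 <- canonicalize("transferase B", "2.8.3.-")
  p3 <- canonicalize("transferase C", "2.8.3.1")
  expect_equal(p1$key, p2$key)
  expect_false(p1$key == p3$key)

  # unparseable EC falls back to name matching
  u <- canonicalize("enolase", "EC?broken")
  expect_equal(u$rule, "verbatim")
  expect_equal(u$key, "name:enolase")

  # idempotence: canonicalizing a canonical name again gives the same key
  expect_equal(canonicalize(k3$name, character(0), syn)$key, k3$key)
})

toy_pgm <- function(rows, species = LETTERS[seq_len(ncol(rows))]) {
  dimnames(rows) <- list(paste0("OC", seq_len(nrow(rows))), species)
  structure(rows, class = c("pan_genome_matrix", class(rows)))
}

test_that("pivot with all-distinct functions is the identity", {
  m <- toy_pgm(rbind(c(1, 1, 0), c(0, 1, 1), c(1, 0, 0)))
  ann <- data.frame(cluster = paste0("OC", 1:3),
                    name = paste("enzyme", 1:3), ec = "")
  fm <- pivot(m, ann)
  expect_equal(nrow(fm), 3)
  expect_equal(attr(fm, "collapse_ratio"), 1)
  expect_equal(attr(fm, "n_merged"), 0)
})

test_that("pivot ORs rows sharing an EC and reports the collapse", {
  m <- toy_pgm(rbind(c(1, 1, 0), c(0, 0, 1), c(1, 0, 0)))
  ann <- data.frame(cluster = paste0("OC", 1:3),
                    name = c("carboxylase alpha", "carboxylase beta", "other"),
                    ec = c("2.1.3.1", "2.1.3.1", ""))
  fm <- pivot(m, ann)
  expect_equal(nrow(fm), 2)
  merged <- unclass(fm)["ec:2.1.3.1", ]
  expect_equal(unname(merged), c(TRUE, TRUE, TRUE))
  expect_equal(attr(fm, "back_map")[["ec:2.1.3.1"]], c("OC1", "OC2"))
  # OR semantics: species has the function iff >= 1 contributing cluster
  expect_true(all(unclass(fm)["ec:2.1.3.1", ] ==
                  (colSums(binarize(m)[1:2, ]) > 0)))
})

test_that("pivot requires an annotation for every cluster", {
  m <- toy_pgm(rbind(c(1, 1), c(1, 0)))
  ann <- data.frame(cluster = "OC1", name = "x", ec = "")
  expect_error(pivot(m, ann), "OC2")
})

test_that("pivot is idempotent under the same tables", {
  m <- toy_pgm(rbind(c(1, 1, 0), c(0, 0, 1), c(0, 1, 1)))
  syn <- data.frame(name = "enzyme one synonym 1", canonical = "enzyme one")
  ann <- data.frame(cluster = paste0("OC", 1:3),
                    name = c("enzyme one", "enzyme one synonym 1", "enzyme two"),
                    ec = "")
  fm1 <- pivot(m, ann, syn)
  # re-pivot the pivoted matrix with key-level annotations
  ann2 <- data.frame(cluster = rownames(fm1),
                     name = sub("^name:", "", rownames(fm1)), ec = "")
  fm2 <- pivot(structure(unclass(fm1) * 1L,
                         class = c("pan_genome_matrix", "matrix")),
               ann2, syn)
  expect_equal(nrow(fm2), nrow(fm1))
  expect_equal(unname(unclass(fm2) > 0), unname(unclass(fm1) > 0))
})

test_that("hypothetical proteins never merge even with identical names", {
  m <- toy_pgm(rbind(c(1, 0), c(0, 1)))
  ann <- data.frame(cluster = c("OC1", "OC2"),
                    name = rep("hypothetical protein", 2), ec = "")
  fm <- pivot(m, ann)
  expect_equal(nrow(fm), 2)
})

test_that("synthetic synonym splits collapse by exactly the recorded count", {
  p <- pangenome_params(n_species = 4, core_size = 24, shell_families = 0,
                        cloud_rate = 0, seed = 61)
  g <- generate_pangenome(p)
  a <- generate_annotations(g$truth, n_functions = 8, split_rate = 0.5,
                            seed = 2)
  tab <- table(g$truth$family, g$truth$species)
  m <- structure(matrix(as.integer(tab), nrow(tab), ncol(tab),
                        dimnames = dimnames(tab)),
                 class = c("pan_genome_matrix", "matrix"))
  fm <- pivot(m, a$annotations, a$synonyms)
  # rows collapse from one per family to one per function
  expect_equal(nrow(fm), length(unique(a$function_key$function_id)))
  expect_equal(attr(fm, "n_merged"),
               nrow(m) - length(unique(a$function_key$function_id)))
})

test_that("hidden-core detector returns exactly the planted split functions", {
  p <- pangenome_params(n_species = 5, core_size = 6, shell_families = 0,
                        cloud_rate = 0, hidden_core_pairs = 5, seed = 77)
  g <- generate_pangenome(p)
  a <- generate_annotations(g$truth, n_functions = 11, split_rate = 0,
                            seed = 3)
  tab <- table(g$truth$family, g$truth$species)
  m <- structure(matrix(as.integer(tab), nrow(tab), ncol(tab),
                        dimnames = dimnames(tab)),
                 class = c("pan_genome_matrix", "matrix"))
  fm <- pivot(m, a$annotations, a$synonyms)
  hc <- hidden_core(m, fm)
  expect_length(hc, 5)
  planted <- unique(g$truth$family[g$truth$category == "hidden"])
  flagged <- unlist(attr(fm, "back_map")[hc], use.names = FALSE)
  expect_setequal(flagged, planted)

  # with no splits the detector is empty
  a0 <- generate_annotations(
    g$truth[g$truth$category != "hidden", ], n_functions = 6,
    split_rate = 0, seed = 3)
  m0 <- m[rownames(m) %in% a0$annotations$cluster, ]
  fm0 <- pivot(structure(m0, class = c("pan_genome_matrix", "matrix")),
               a0$annotations, a0$synonyms)
  expect_length(hidden_core(m0, fm0), 0)
})

test_that("pivot preserves core functionality counts", {
  # core-function count >= core-cluster count; row count never grows
  p <- pangenome_params(n_species = 4, core_size = 10, shell_families = 6,
                        cloud_rate = 2, hidden_core_pairs = 1, seed = 19)
  g <- generate_pangenome(p)
  a <- generate_annotations(g$truth, n_functions = 12, split_rate = 0.3,
                            seed = 4)
  tab <- table(g$truth$family, g$truth$species)
  m <- structure(matrix(as.integer(tab), nrow(tab), ncol(tab),
                        dimnames = dimnames(tab)),
                 class = c("pan_genome_matrix", "matrix"))
  fm <- pivot(m, a$annotations, a$synonyms)
  expect_lte(nrow(fm), nrow(m))
  core_clusters <- sum(rowSums(binarize(m)) == ncol(m))
  core_functions <- sum(rowSums(fm) == ncol(fm))
  expect_gte(core_functions, core_clusters)
})
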