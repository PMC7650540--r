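test_that("pan-genome generator is deterministic and byte-identical per seed", {
  p <- pangenome_params(n_species = 3, core_size = 5, shell_families = 3,
                        cloud_rate = 2, seed = 99)
  g1 <- generate_pangenome(p)
  g2 <- generate_pangenome(p)
  expect_identical(g1$truth, g2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_proteomes(g1$proteomes, d1)
  f2 <- write_proteomes(g2$proteomes, d2)
  for (sp in names(f1))
    expect_identical(readBin(f1[[sp]], "raw", file.size(f1[[sp]])),
                     readBin(f2[[sp]], "raw", file.size(f2[[sp]])))
})

test_that("closed pan-genome: no shell/cloud means all families core", {
  p <- pangenome_params(n_species = 4, core_size = 10, shell_families = 0,
                        cloud_rate = 0, seed = 5)
  g <- generate_pangenome(p)
  expect_setequal(unique(g$truth$category), "core")
  # each family appears exactly once per species
  tab <- table(g$truth$family, g$truth$species)
  expect_true(all(tab == 1))
  # pan size constant in species count
  for (n_sub in 2:4) {
    sub <- g$truth[g$truth$species %in% sprintf("sp%d", 1:n_sub), ]
    expect_equal(length(unique(sub$family)), 10)
  }
})

test_that("mean pan size matches the analytic expectation of the model", {
  # core + Poisson cloud per species: E[pan] = core + n * cloud_rate
  core <- 20; rate <- 10; n <- 4; nseed <- 40
  pans <- vapply(seq_len(nseed), function(s) {
    g <- generate_pangenome(pangenome_params(
      n_species = n, core_size = core, cloud_rate = rate, seed = s))
    length(unique(g$truth$family))
  }, numeric(1))
  expected <- core + n * rate
  se <- sqrt(n * rate / nseed)       # Poisson variance of the mean
  expect_lt(abs(mean(pans) - expected), 4 * se)
})

test_that("generator parameter validation rejects impossible settings", {
  expect_error(pangenome_params(3, 5, within_family_identity = 0.3,
                                between_family_identity = 0.5),
               "must exceed")
  expect_error(pangenome_params(3, 5, shell_families = 2, p_shell = 1.2),
               "p_shell")
})

test_that("within-family identity is high and between-family identity low", {
  p <- pangenome_params(n_species = 3, core_size = 4,
                        within_family_identity = 0.9,
                        between_family_identity = 0.2, seed = 7)
  g <- generate_pangenome(p)
  seqs <- do.call(c, unname(g$proteomes))
  fam <- setNames(g$truth$family, g$truth$gene)
  al <- alignment_identity(seqs, seqs)
  idm <- al$identity
  same <- outer(fam[rownames(idm)], fam[colnames(idm)], "==")
  diag(same) <- NA
  within <- idm[which(same)]
  between <- idm[which(!same)]
  expect_gt(min(within), 0.75)
  expect_lt(max(between), 0.35)
})

test_that("true network models all grow on base medium and share recorded accessories", {
  net <- generate_true_network(3, db_size = 30, shared_fraction = 0.5, seed = 7)
  for (m in net$models)
    expect_gt(fba(m, net$base_medium)$objective, 0)
  # species reaction sets differ exactly by recorded accessory routes
  for (i in seq_along(net$models)) for (j in seq_along(net$models)) {
    if (i >= j) next
    d <- diff_models(net$models[[i]], net$models[[j]])
    acc_i <- colnames(net$accessory)[net$accessory[i, ] & !net$accessory[j, ]]
    acc_j <- colnames(net$accessory)[net$accessory[j, ] & !net$accessory[i, ]]
    expect_setequal(d$a_only, as.character(
      unlist(net$route_reactions[acc_i], use.names = FALSE)))
    expect_setequal(d$b_only, as.character(
      unlist(net$route_reactions[acc_j], use.names = FALSE)))
  }
})

test_that("shared_fraction = 1 yields identical species models", {
  net <- generate_true_network(3, db_size = 30, shared_fraction = 1, seed = 3)
  for (j in 2:3) {
    d <- diff_models(net$models[[1]], net$models[[j]])
    expect_length(d$a_only, 0)
    expect_length(d$b_only, 0)
  }
})

test_that("degradation records gaps exactly and protects vital reactions", {
  net <- generate_true_network(3, db_size = 30, shared_fraction = 0.4, seed = 11)
  dg0 <- degrade_models(net$models, 0, seed = 13,
                        base_medium = net$base_medium)
  expect_true(all(lengths(dg0$gaps) == 0))
  expect_identical(dg0$drafts[[1]]$reactions$id, net$models[[1]]$reactions$id)

  dg <- degrade_models(net$models, 0.2, seed = 13,
                       base_medium = net$base_medium)
  for (sp in names(net$models)) {
    truth_ids <- net$models[[sp]]$reactions$id
    draft_ids <- dg$drafts[[sp]]$reactions$id
    # definitional: gap list = truth minus draft
    expect_setequal(dg$gaps[[sp]], setdiff(truth_ids, draft_ids))
    # protection: biomass, exchanges, base-medium transport survive
    expect_true("BIOMASS" %in% draft_ids)
    expect_true(all(c("EX_base", "T_base") %in% draft_ids))
    cl <- reaction_classes(net$models[[sp]])
    expect_true(all(names(cl)[cl == "exchange"] %in% draft_ids))
  }
  expect_error(degrade_models(net$models, 1), "gap_fraction")
})

test_that("phenotype array equals an independent FBA oracle, deduplicated", {
  net <- generate_true_network(2, db_size = 30, shared_fraction = 1, seed = 21)
  m <- net$models[[1]]
  panel <- c(net$compound_panel, net$compound_panel[1])  # duplicate entry
  pa <- simulate_phenotype_array(m, panel, net$universal_db)
  expect_false(anyDuplicated(pa$compound) > 0)
  for (i in seq_len(nrow(pa))) {
    ref <- oracle_fba(m, setNames(10, pa$compound[i]))
    expect_equal(pa$growth[i], ref$objective >= 1e-3,
                 info = pa$compound[i])
  }
  # planted dead ends cannot grow even on the true model
  expect_true(all(!pa$growth[pa$compound %in% net$dead_end_compounds]))
  # unmappable compounds are excluded and reported
  pa2 <- simulate_phenotype_array(m, c("ghost[e]", net$compound_panel),
                                  net$universal_db)
  expect_identical(attr(pa2, "unmappable"), "ghost[e]")
  expect_false("ghost[e]" %in% pa2$compound)
})

test_that("annotation generator records synonym splits exactly", {
  p <- pangenome_params(n_species = 4, core_size = 30, shell_families = 0,
                        cloud_rate = 0, seed = 31)
  g <- generate_pangenome(p)
  a0 <- generate_annotations(g$truth, n_functions = 10, split_rate = 0,
                             seed = 1)
  expect_equal(a0$n_split, 0)
  expect_equal(nrow(a0$synonyms), 0)
  # one name per function
  expect_equal(length(unique(a0$annotations$name)),
               length(unique(a0$function_key$function_id)))

  a <- generate_annotations(g$truth, n_functions = 10, split_rate = 0.4,
                            seed = 1)
  expect_equal(a$n_split, sum(unique(a$function_key[, c("function_id",
                                                        "split")])$split))
  expect_gt(a$n_split, 0)
  # determinism
  b <- generate_annotations(g$truth, n_functions = 10, split_rate = 0.4,
                            seed = 1)
  expect_identical(a, b)
})
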