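# Independent oracles used across the suite. These deliberately avoid the
# package's own solver / clustering code paths.

# FBA by boot::simplex: maximize flux of `objective` s.t. S v = 0 and the
# model's bounds with `media` applied to exchange reactions.
oracle_fba <- function(model, media = numeric(0),
                       objective = model$biomass_id) {
  st <- model$stoich
  rids <- model$reactions$id
  # clamp the huge default bounds: toy-network fluxes never exceed |100|,
  # and boot's tableau simplex is fragile with 1e3-scale coefficients
  lb <- pmax(model$reactions$lb, -100)
  ub <- pmin(model$reactions$ub, 100)
  for (i in seq_along(rids)) {
    s <- st[[i]]
    if (length(s) == 1L) {                       # exchange reaction
      met <- names(s)[1]
      lb[i] <- if (met %in% names(media)) -media[[met]] else 0
      if (ub[i] < lb[i]) ub[i] <- lb[i]
    }
  }
  mets <- sort(unique(unlist(lapply(st, names), use.names = FALSE)))
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  for (i in seq_along(rids)) S[names(st[[i]]), i] <- st[[i]]
  # shift x = v - lb >= 0; upper bound rows x <= ub - lb; boot::simplex
  # needs non-negative right-hand sides, so flip equality rows as required
  obj <- as.numeric(rids == objective)
  n <- length(rids)
  A3 <- S
  b3 <- as.numeric(-S %*% lb)
  neg <- b3 < 0
  A3[neg, ] <- -A3[neg, , drop = FALSE]
  b3[neg] <- -b3[neg]
  res <- boot::simplex(a = obj,
                       A1 = diag(n), b1 = ub - lb,
                       A3 = A3, b3 = b3,
                       maxi = TRUE)
  if (res$solved != 1) return(list(objective = NA_real_, solved = res$solved))
  list(objective = unname(res$value) + sum(obj * lb),
       fluxes = setNames(res$soln + lb, rids), solved = 1)
}

# brute-force clustering oracle: all-pairs global alignment, link every
# pair passing the thresholds, connected components by BFS
oracle_cluster <- function(proteomes, config = clustering_config()) {
  all_seq <- do.call(c, unname(proteomes))
  genes <- names(all_seq)
  n <- length(genes)
  adj <- vector("list", n)
  al <- alignment_identity(all_seq, all_seq, config)
  ok <- al$identity >= config$min_identity &
    al$coverage >= config$min_coverage
  for (i in seq_len(n)) adj[[i]] <- setdiff(which(ok[i, ]), i)
  comp <- integer(n); cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  setNames(comp, genes)
}

# adjusted Rand index between two labellings given as named vectors
ari <- function(a, b) {
  b <- b[names(a)]
  mclust::adjustedRandIndex(as.character(a), as.character(b))
}

# brute-force minimal gap-fill: smallest candidate subset whose addition
# lets the model reach eps in every condition, by subset enumeration
oracle_min_gapfill <- function(model, db, conditions, eps = 1e-3,
                               max_size = length(setdiff(db$ids,
                                                         model$reactions$id))) {
  cand <- setdiff(db$ids, model$reactions$id)
  feasible <- function(ids) {
    filled <- model_with_db(model, db, ids)
    for (med in conditions)
      if (fba(filled, med)$objective < eps - 1e-9) return(FALSE)
    TRUE
  }
  for (k in 0:max_size) {
    subsets <- if (k == 0) list(character(0)) else
      utils::combn(cand, k, simplify = FALSE)
    for (s in subsets) if (feasible(s)) return(list(size = k, set = s))
  }
  NULL
}

# small hand-built branched toy model used by several FBA tests
toy_branched_model <- function() {
  metabolic_model("branched",
    stoich = list(
      EX_a = c("a[e]" = -1),
      EX_b = c("b[e]" = -1),
      T_a = c("a[e]" = -1, "a[c]" = 1),
      T_b = c("b[e]" = -1, "b[c]" = 1),
      R1 = c("a[c]" = -1, "m[c]" = 1),
      R2 = c("b[c]" = -2, "m[c]" = 1),
      BIOMASS = c("m[c]" = -1)),
    lb = c(-1000, -1000, -1000, -1000, 0, 0, 0),
    ub = 1000, biomass = "BIOMASS")
}
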