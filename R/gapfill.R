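#' Flux balance analysis
#'
#' Maximizes the flux of an objective reaction subject to steady-state mass
#' balance (`S v = 0`), the model's flux bounds, and media-limited uptake:
#' for every exchange reaction, uptake (negative flux) is capped at the rate
#' the medium grants its metabolite, and zero for metabolites absent from
#' the medium. Secretion is never restricted by the medium.
#'
#' @param model a [metabolic_model()].
#' @param media named numeric vector: extracellular metabolite id -> maximum
#'   uptake rate (>= 0).
#' @param objective_id reaction to maximize; defaults to the biomass
#'   reaction.
#' @return list with `objective`, `fluxes` (named vector over reactions) and
#'   `status`. An optimum of zero is returned as a regular solution; an
#'   infeasible LP (contradictory bounds) is an error.
#' @export
fba <- function(model, media = numeric(0), objective_id = model$biomass_id) {
  if (is.null(objective_id)) stop("no objective reaction: biomass unset")
  if (!objective_id %in% model$reactions$id)
    stop("objective reaction '", objective_id, "' not in model")
  if (any(media < 0)) stop("media uptake rates must be >= 0")
  m <- apply_media(model, media)
  S <- as.matrix(stoich_matrix(m))
  n <- ncol(S)
  obj <- as.numeric(m$reactions$id == objective_id)
  res <- lp_solve_bounded(obj, S, rep("=", nrow(S)), rep(0, nrow(S)),
                          lb = m$reactions$lb, ub = m$reactions$ub,
                          maximize = TRUE)
  if (res$status != "optimal")
    stop("FBA LP ", res$status, " for model '", model$id, "' (",
         nrow(S), " metabolites, ", n, " reactions)")
  list(objective = res$objective,
       fluxes = setNames(res$x, m$reactions$id),
       status = res$status)
}

#' Constrain a model's exchange reactions to a medium
#'
#' @inheritParams fba
#' @return the model with exchange lower bounds set from the medium.
#' @export
apply_media <- function(model, media) {
  ex <- exchange_metabolites(model)
  for (rid in names(ex)) {
    met <- ex[[rid]]
    i <- match(rid, model$reactions$id)
    rate <- if (met %in% names(media)) media[[met]] else 0
    model$reactions$lb[i] <- -rate
    if (model$reactions$ub[i] < -rate) model$reactions$ub[i] <- -rate
  }
  model
}

#' Add exchange and transport reactions for compounds
#'
#' For each extracellular compound, ensures an exchange reaction and a
#' reversible uniport into the cytosol exist. Already-present reactions are
#' left untouched, so the operation is idempotent.
#'
#' @param model a [metabolic_model()].
#' @param compounds extracellular metabolite ids (`"x[e]"`).
#' @return the extended model.
#' @export
add_transporters <- function(model, compounds) {
  ex_mets <- unname(exchange_metabolites(model))
  for (cpd in unique(compounds)) {
    if (met_compartment(cpd) != "e")
      stop("compound '", cpd, "' is not extracellular")
    base <- sub("\\[e\\]$", "", cpd)
    cyt <- paste0(base, "[c]")
    if (!cpd %in% ex_mets) {
      rid <- paste0("EX_", gsub("[^A-Za-z0-9]", "_", base))
      while (rid %in% model$reactions$id) rid <- paste0(rid, "_")
      model <- add_reactions(model, setNames(list(setNames(-1, cpd)), rid),
                             lb = -1000, ub = 1000)
    }
    has_transport <- any(vapply(model$stoich, function(s)
      length(s) == 2L && setequal(names(s), c(cpd, cyt)), logical(1)))
    if (!has_transport) {
      rid <- paste0("T_", gsub("[^A-Za-z0-9]", "_", base))
      while (rid %in% model$reactions$id) rid <- paste0(rid, "_")
      model <- add_reactions(model,
        setNames(list(setNames(c(-1, 1), c(cpd, cyt))), rid),
        lb = -1000, ub = 1000)
    }
  }
  model
}

#' Screen growth conditions against the full universal database
#'
#' A condition is retained iff the model extended with the entire database
#' reaches the growth threshold on it; conditions that cannot sustain
#' growth even with every database reaction available are discarded.
#'
#' @param model the draft [metabolic_model()].
#' @param universal_db a [reaction_db()].
#' @param conditions named list of media (named uptake vectors).
#' @param epsilon growth threshold.
#' @return list with `retained` and `discarded` condition names.
#' @export
screen_conditions <- function(model, universal_db, conditions,
                              epsilon = 1e-3) {
  full <- model_with_db(model, universal_db)
  ok <- vapply(conditions, function(med)
    fba(full, med)$objective >= epsilon, logical(1))
  list(retained = names(conditions)[ok], discarded = names(conditions)[!ok])
}

#' Identify database reactions essential for any condition
#'
#' A candidate is essential for a condition iff the model plus the database
#' minus that one reaction cannot reach the growth threshold on it. Returns
#' the union over conditions; these reactions must appear in any gap-fill
#' solution covering the conditions.
#'
#' @inheritParams screen_conditions
#' @return character vector of essential candidate reaction ids.
#' @export
essential_candidates <- function(model, universal_db, conditions,
                                 epsilon = 1e-3) {
  cand <- setdiff(universal_db$ids, model$reactions$id)
  full <- model_with_db(model, universal_db)
  ess <- character(0)
  for (r in cand) {
    red <- remove_reactions(full, r)
    for (med in conditions) {
      if (fba(red, med)$objective < epsilon) { ess <- c(ess, r); break }
    }
  }
  ess
}

#' Define a multi-condition gap-fill problem
#'
#' @param model the draft [metabolic_model()] (with transporters for the
#'   tested compounds already added).
#' @param universal_db candidate pool, a [reaction_db()].
#' @param conditions named list of media the filled model must grow on
#'   (screen first with [screen_conditions()]).
#' @param epsilon minimal biomass flux per condition (> 0).
#' @param big_M flux bound coupling candidate fluxes to their indicator;
#'   must dominate every bound magnitude.
#' @param weights optional positive objective weight per candidate
#'   (default 1: pure cardinality).
#' @return a `gapfill_problem` object.
#' @export
gapfill_problem <- function(model, universal_db, conditions, epsilon = 1e-3,
                            big_M = 1000, weights = NULL) {
  stopifnot(epsilon > 0)
  cand <- setdiff(universal_db$ids, model$reactions$id)
  k <- match(cand, universal_db$ids)
  maxb <- max(abs(c(model$reactions$lb, model$reactions$ub,
                    universal_db$lb, universal_db$ub)))
  if (big_M < maxb) stop("big_M must be >= the largest bound magnitude (",
                         maxb, ")")
  if (is.null(weights)) weights <- rep(1, length(cand))
  stopifnot(length(weights) == length(cand), all(weights > 0))
  structure(list(model = model, db = universal_db, candidates = cand,
                 cand_gene = setNames(universal_db$gene_supported[k], cand),
                 conditions = conditions, epsilon = epsilon, big_M = big_M,
                 weights = setNames(weights, cand)),
            class = "gapfill_problem")
}

# LP relaxation for one condition at a branch-and-bound node:
# min sum w_r y_r over free candidates, y in [0,1], subject to
# S v = 0, biomass >= eps, |v_r| <= M y_r (free r), v_out = 0.
# Returns list(bound, y) or NULL when infeasible.
gapfill_relax_condition <- function(full, S, eps, M, media, objective_id,
                                    free, w, out) {
  m <- apply_media(full, media)
  lb <- m$reactions$lb; ub <- m$reactions$ub
  i_out <- match(out, m$reactions$id)
  lb[i_out] <- 0; ub[i_out] <- 0
  nv <- length(lb); nf <- length(free)
  i_free <- match(free, m$reactions$id)
  i_bio <- match(objective_id, m$reactions$id)
  nmet <- nrow(S)
  A <- cbind(S, matrix(0, nmet, nf))
  rel <- rep("=", nmet); b <- rep(0, nmet)
  bio <- c(as.numeric(seq_len(nv) == i_bio), rep(0, nf))
  A <- rbind(A, bio); rel <- c(rel, ">="); b <- c(b, eps)
  if (nf > 0) {
    Cup <- matrix(0, nf, nv + nf)
    Cdn <- matrix(0, nf, nv + nf)
    Cup[cbind(seq_len(nf), i_free)] <- 1
    Cdn[cbind(seq_len(nf), i_free)] <- -1
    Cup[cbind(seq_len(nf), nv + seq_len(nf))] <- -M
    Cdn[cbind(seq_len(nf), nv + seq_len(nf))] <- -M
    A <- rbind(A, Cup, Cdn)
    rel <- c(rel, rep("<=", 2 * nf)); b <- c(b, rep(0, 2 * nf))
  }
  obj <- c(rep(0, nv), w)
  res <- lp_solve_bounded(obj, A, rel, b,
                          lb = c(lb, rep(0, nf)), ub = c(ub, rep(1, nf)))
  if (res$status != "optimal") return(NULL)
  list(bound = res$objective,
       y = if (nf > 0) setNames(res$x[nv + seq_len(nf)], free) else numeric(0))
}

#' Solve the multi-condition minimal-addition gap-fill MILP
#'
#' Minimizes the (weighted) number of database reactions added so that the
#' model reaches the growth threshold in every condition simultaneously:
#' binary indicators `y_r` gate candidate fluxes via `|v_r^c| <= M y_r` in
#' each condition's steady-state system. Solved exactly by branch and bound;
#' the lower bound at each node is the weighted additions already committed
#' plus the largest per-condition LP-relaxation minimum over the free
#' candidates (conditions couple only through `y`, so each condition's
#' relaxed minimum is a valid bound). Among equal-cardinality optima,
#' gene-supported candidates and then lexicographically earlier ids are
#' preferred through infinitesimal weight perturbations. The returned
#' additions are re-verified by plain FBA per condition.
#'
#' @param problem a [gapfill_problem()].
#' @return a `gapfill_result`: list with `added` (reaction ids),
#'   `objective` (count of additions), `witnesses` (per-condition flux
#'   vectors of the verification FBA), `support` (data.frame id/
#'   gene_supported), and `verified` (logical).
#' @export
gapfill_milp <- function(problem) {
  stopifnot(inherits(problem, "gapfill_problem"))
  model <- problem$model; db <- problem$db
  conds <- problem$conditions; eps <- problem$epsilon; M <- problem$big_M
  cand <- problem$candidates

  finish <- function(added) {
    wit <- list(); ok <- TRUE
    filled <- model_with_db(model, db, added)
    for (cn in names(conds)) {
      sol <- fba(filled, conds[[cn]])
      wit[[cn]] <- sol$fluxes
      ok <- ok && sol$objective >= eps - 1e-7
    }
    structure(list(added = added, objective = length(added), witnesses = wit,
                   support = data.frame(id = added,
                     gene_supported = unname(problem$cand_gene[added]),
                     stringsAsFactors = FALSE),
                   verified = ok),
              class = "gapfill_result")
  }
  if (length(conds) == 0L) return(finish(character(0)))

  # preference perturbation: gene-supported, then lexicographic id
  ord <- order(!problem$cand_gene, cand)
  pert <- numeric(length(cand)); pert[ord] <- seq_along(cand)
  w <- problem$weights + 1e-5 * pert / max(1, length(cand))
  names(w) <- cand

  full <- model_with_db(model, db)
  S <- as.matrix(stoich_matrix(full))

  node_bound <- function(inset, outset) {
    free <- setdiff(cand, c(inset, outset))
    best <- 0; ysum <- setNames(numeric(length(free)), free)
    for (cn in names(conds)) {
      r <- gapfill_relax_condition(full, S, eps, M, conds[[cn]],
                                   model$biomass_id, free, w[free], outset)
      if (is.null(r)) return(NULL)              # condition infeasible here
      if (r$bound > best) best <- r$bound
      if (length(free)) ysum[free] <- pmax(ysum[free], r$y)
    }
    list(lb = sum(w[inset]) + best, ysum = ysum)
  }

  feasible_with <- function(inset) {
    filled <- model_with_db(model, db, inset)
    for (cn in names(conds))
      if (fba(filled, conds[[cn]])$objective < eps - 1e-9) return(FALSE)
    TRUE
  }

  incumbent <- NULL; inc_val <- Inf
  consider <- function(inset) {
    v <- sum(w[inset])
    if (v < inc_val - 1e-12 && feasible_with(inset)) {
      incumbent <<- inset; inc_val <<- v
    }
  }

  # initial incumbent: all candidates (root screening guarantees feasibility
  # when the problem is well-posed), greedily reduced in preference order
  if (feasible_with(cand)) {
    cur <- cand
    for (r in cand[rev(order(!problem$cand_gene, cand))]) {
      tryr <- setdiff(cur, r)
      if (feasible_with(tryr)) cur <- tryr
    }
    incumbent <- cur; inc_val <- sum(w[cur])
  }

  stack <- list(list(inset = character(0), outset = character(0)))
  while (length(stack)) {
    nd <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    bd <- node_bound(nd$inset, nd$outset)
    if (is.null(bd)) next                       # infeasible subtree
    if (bd$lb >= inc_val - 1e-9) next
    free <- setdiff(cand, c(nd$inset, nd$outset))
    if (length(free) == 0L || all(bd$ysum < 1e-7)) {
      consider(nd$inset); next
    }
    br <- names(which.max(bd$ysum))
    # explore exclusion later, inclusion first (depth-first via stack order)
    stack[[length(stack) + 1L]] <- list(inset = nd$inset,
                                        outset = c(nd$outset, br))
    stack[[length(stack) + 1L]] <- list(inset = c(nd$inset, br),
                                        outset = nd$outset)
  }
  if (is.null(incumbent))
    stop("gap-fill MILP infeasible: screen conditions before solving")
  finish(sort(incumbent))
}

#' @export
print.gapfill_result <- function(x, ...) {
  cat("<gapfill_result> ", x$objective, " reaction(s) added",
      if (x$verified) " (verified by FBA)" else " (VERIFICATION FAILED)",
      "\n", sep = "")
  if (length(x$added)) cat("  ", paste(x$added, collapse = ", "), "\n")
  invisible(x)
}

#' Predict a minimal medium
#'
#' Finds an irreducible subset of a nutrient pool (beyond a fixed base
#' medium) that sustains biomass at the growth threshold. Nutrients are
#' dropped greedily in reverse preference order whenever growth survives
#' their removal; irreducibility of the result is verified by
#' single-removal FBA.
#'
#' @param model a [metabolic_model()].
#' @param nutrient_pool named uptake vector of optional nutrients.
#' @param epsilon growth threshold.
#' @param base named uptake vector always present (salts, phosphate, ...).
#' @return character vector of required nutrient ids (possibly empty), with
#'   attribute `irreducible` = TRUE.
#' @export
minimal_media <- function(model, nutrient_pool, epsilon = 1e-3,
                          base = numeric(0)) {
  grow <- function(keep) {
    med <- c(base, nutrient_pool[keep])
    fba(model, med)$objective >= epsilon
  }
  all_n <- names(nutrient_pool)
  if (!grow(all_n)) stop("model does not grow on the full nutrient pool")
  keep <- all_n
  for (nut in rev(all_n)) {
    cand <- setdiff(keep, nut)
    if (grow(cand)) keep <- cand
  }
  for (nut in keep)
    if (grow(setdiff(keep, nut)))
      stop("internal error: result not irreducible at ", nut)
  structure(keep, irreducible = TRUE)
}
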