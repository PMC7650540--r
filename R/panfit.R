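#' Sample pan- and core-genome accumulation curves
#'
#' Random genome-order sampling: for each permutation of the species and
#' each prefix length N, records the pan size (union of families present in
#' the first N species) and core size (intersection). Within a permutation
#' the pan curve is non-decreasing and the core curve non-increasing by
#' construction.
#'
#' @param m a [build_matrix()] result (>= 2 species).
#' @param n_permutations number of sampled species orderings (default 100).
#' @param seed integer seed.
#' @param exhaustive enumerate all orderings instead of sampling (allowed up
#'   to 7 species); overrides `n_permutations`.
#' @return an `accumulation_curve` data.frame with columns `perm`, `N`,
#'   `pan`, `core`, and attributes `n_permutations`, `seed`.
#' @export
sample_curves <- function(m, n_permutations = 100, seed = 1L,
                          exhaustive = FALSE) {
  b <- binarize(m)
  ns <- ncol(b)
  if (ns < 2L) stop("at least 2 species are required")
  perms <- if (exhaustive) {
    if (ns > 7L) stop("exhaustive enumeration limited to 7 species")
    all_permutations(ns)
  } else {
    withr::with_seed(seed, replicate(n_permutations, sample(ns),
                                     simplify = FALSE))
  }
  rows <- vector("list", length(perms))
  for (p in seq_along(perms)) {
    ordv <- perms[[p]]
    pan <- core <- integer(ns)
    u <- rep(FALSE, nrow(b)); i <- rep(TRUE, nrow(b))
    for (N in seq_len(ns)) {
      col <- b[, ordv[N]]
      u <- u | col; i <- i & col
      pan[N] <- sum(u); core[N] <- sum(i)
    }
    rows[[p]] <- data.frame(perm = p, N = seq_len(ns), pan = pan, core = core)
  }
  structure(do.call(rbind, rows),
            n_permutations = length(perms), seed = seed,
            class = c("accumulation_curve", "data.frame"))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

# robust multi-start nonlinear least squares over fixed starting points
nls_multistart <- function(formula, data, starts, lower = NULL, upper = NULL) {
  best <- NULL; best_ss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ss <- sum(residuals(fit)^2)
      if (ss < best_ss) { best <- fit; best_ss <- ss }
    }
  }
  best
}

#' Fit the pan-genome growth law
#'
#' Fits the per-genome rate of new family discovery as a power-law decay
#' (Heaps-style): the median number of new families contributed by the N-th
#' genome across permutations is modelled as `kappa * N^(-gamma)`. The pan
#' genome is called open when the decay exponent `gamma` is below 1 (the
#' cumulative pan size then diverges). The rate evaluated at the last
#' sampled genome is reported as `new_families_at_N`.
#'
#' @param curve an [sample_curves()] result.
#' @return a `pan_growth_fit` list: `kappa`, `gamma`, `new_families_at_N`,
#'   `open` (logical), `verdict` (`"open"`/`"closed"`), `median_increments`,
#'   `residual_sd`. Degenerate curves (no new families ever) return the
#'   closed verdict with rate 0 and no fitted parameters.
#' @export
fit_pan_growth <- function(curve) {
  if (length(unique(curve$N)) < 3L) stop("need >= 3 distinct N values")
  inc <- curve[curve$N > 1L, ]
  # increments within each permutation
  inc$new <- inc$pan - curve$pan[match(paste(inc$perm, inc$N - 1L),
                                       paste(curve$perm, curve$N))]
  med <- aggregate(new ~ N, inc, median)
  Nmax <- max(curve$N)
  if (all(med$new == 0)) {
    return(structure(list(kappa = NA_real_, gamma = NA_real_,
                          new_families_at_N = 0, open = FALSE,
                          verdict = "closed", median_increments = med,
                          residual_sd = 0),
                     class = "pan_growth_fit"))
  }
  starts <- list(list(kappa = max(med$new), gamma = 0.1),
                 list(kappa = max(med$new), gamma = 0.5),
                 list(kappa = med$new[1], gamma = 1),
                 list(kappa = mean(med$new), gamma = 0.01),
                 list(kappa = max(med$new) * 2, gamma = 1.5))
  fit <- nls_multistart(new ~ kappa * N^(-gamma), med, starts,
                        lower = c(kappa = 0, gamma = -5),
                        upper = c(kappa = Inf, gamma = 5))
  if (is.null(fit)) stop("pan growth fit failed to converge")
  k <- coef(fit)[["kappa"]]; g <- coef(fit)[["gamma"]]
  structure(list(kappa = k, gamma = g,
                 new_families_at_N = k * Nmax^(-g),
                 open = g < 1, verdict = if (g < 1) "open" else "closed",
                 median_increments = med,
                 residual_sd = sqrt(mean(residuals(fit)^2))),
            class = "pan_growth_fit")
}

#' @export
print.pan_growth_fit <- function(x, ...) {
  cat("<pan_growth_fit> verdict: ", x$verdict, "\n", sep = "")
  if (!is.na(x$kappa))
    cat(sprintf("  new families per genome ~ %.1f * N^(-%.3f); at last N: %.1f\n",
                x$kappa, x$gamma, x$new_families_at_N))
  invisible(x)
}

#' Fit the core-genome decay
#'
#' Fits the median core size across permutations as an exponential decay to
#' an asymptote: `core(N) = (c0 - omega) * exp(-(N-1)/tau) + omega`, with
#' `omega >= 0` the extrapolated core-genome size and `tau` the decay
#' constant in genomes. The asymptote is constrained not to exceed the
#' observed core at the largest N. A flat curve (identical genomes) returns
#' `omega` equal to the genome size with `tau` not applicable.
#'
#' @param curve an [sample_curves()] result.
#' @return a `core_decay_fit` list: `omega`, `tau`, `c0`,
#'   `median_core`, `residual_sd`; `tau` is `NA` when unidentifiable.
#' @export
fit_core_decay <- function(curve) {
  if (length(unique(curve$N)) < 3L) stop("need >= 3 distinct N values")
  med <- aggregate(core ~ N, curve, median)
  if (diff(range(med$core)) == 0) {
    return(structure(list(omega = med$core[1], tau = NA_real_,
                          c0 = med$core[1], median_core = med,
                          residual_sd = 0),
                     class = "core_decay_fit"))
  }
  omax <- min(med$core)
  # profiled least squares: for fixed tau the model is linear in
  # (c0 - omega) and omega; scan tau on a log grid, then polish with
  # constrained Levenberg-Marquardt from the grid optimum
  profile_fit <- function(tau) {
    z <- exp(-(med$N - 1) / tau)
    X <- cbind(z = z, one = 1)
    cf <- tryCatch(qr.coef(qr(X), med$core), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) return(NULL)
    omega <- min(max(cf[["one"]], 0), omax)
    a <- max(cf[["z"]], 0)
    ss <- sum((a * z + omega - med$core)^2)
    list(omega = omega, c0 = a + omega, tau = tau, ss = ss)
  }
  grid <- exp(seq(log(0.05), log(50), length.out = 60))
  cands <- Filter(Negate(is.null), lapply(grid, profile_fit))
  if (length(cands) == 0L) stop("core decay fit failed to converge")
  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "ss"))]]
  polish <- tryCatch(
    minpack.lm::nlsLM(core ~ (c0 - omega) * exp(-(N - 1) / tau) + omega,
                      data = med,
                      start = list(c0 = best$c0, omega = best$omega,
                                   tau = best$tau),
                      lower = c(c0 = 0, omega = 0, tau = 1e-3),
                      upper = c(c0 = Inf, omega = omax, tau = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(polish) && sum(residuals(polish)^2) <= best$ss + 1e-9) {
    co <- coef(polish)
    best <- list(omega = co[["omega"]], c0 = co[["c0"]], tau = co[["tau"]],
                 ss = sum(residuals(polish)^2))
  }
  structure(list(omega = best$omega, tau = best$tau, c0 = best$c0,
                 median_core = med,
                 residual_sd = sqrt(best$ss / nrow(med))),
            class = "core_decay_fit")
}

#' @export
print.core_decay_fit <- function(x, ...) {
  cat("<core_decay_fit> asymptotic core omega = ",
      round(x$omega, 1), ", tau = ",
      if (is.na(x$tau)) "n/a (flat curve)" else round(x$tau, 2), "\n",
      sep = "")
  invisible(x)
}
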