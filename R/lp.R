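#' Solve a small dense linear program
#'
#' Thin solver interface used by all flux-balance and gap-filling routines.
#' Solves `min/max obj'x` subject to `A x (rel) b`, `x >= 0`, with a dense
#' two-phase simplex. Problems in this package are small (at most a few
#' hundred rows), so no sparse machinery is used.
#'
#' @param obj numeric objective coefficients, length `ncol(A)`.
#' @param A dense constraint matrix.
#' @param rel character vector of `"<="`, `"="`, `">="`, one per row.
#' @param b right-hand sides.
#' @param maximize logical; maximize instead of minimize.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective`, and primal solution `x`.
#' @keywords internal
lp_solve <- function(obj, A, rel, b, maximize = FALSE) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  rel_code <- match(rel, c("<=", "=", ">=")) - 2L
  if (anyNA(rel_code)) stop("rel must be one of '<=', '=', '>='")
  .cpp_simplex(as.numeric(obj), A, as.integer(rel_code), as.numeric(b),
               isTRUE(maximize))
}

#' Solve a bounded LP in flux form
#'
#' Variables carry finite lower/upper bounds (flux bounds); internally shifted
#' to the nonnegative orthant for [lp_solve()].
#'
#' @param obj objective over variables.
#' @param A,rel,b linear constraints over the original (unshifted) variables.
#' @param lb,ub finite bounds per variable.
#' @inheritParams lp_solve
#' @return as [lp_solve()], with `x` on the original scale.
#' @keywords internal
lp_solve_bounded <- function(obj, A, rel, b, lb, ub, maximize = FALSE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n, all(is.finite(lb)), all(is.finite(ub)))
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible", objective = NA_real_, x = numeric(0)))
  A <- as.matrix(A)
  # shift x = v - lb >= 0
  b2 <- b - as.numeric(A %*% lb)
  span <- ub - lb
  fixed <- span <= 1e-12
  # upper bounds as rows (only for non-fixed variables)
  ub_rows <- which(!fixed)
  Aub <- matrix(0, length(ub_rows), n)
  if (length(ub_rows)) Aub[cbind(seq_along(ub_rows), ub_rows)] <- 1
  Afull <- rbind(A, Aub, if (any(fixed)) {
    Af <- matrix(0, sum(fixed), n)
    Af[cbind(seq_len(sum(fixed)), which(fixed))] <- 1
    Af
  })
  relfull <- c(rel, rep("<=", length(ub_rows)), rep("=", sum(fixed)))
  bfull <- c(b2, span[ub_rows], rep(0, sum(fixed)))
  res <- lp_solve(obj, Afull, relfull, bfull, maximize = maximize)
  if (res$status == "optimal") {
    res$x <- res$x + lb
    res$objective <- res$objective + sum(obj * lb)
  }
  res
}
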