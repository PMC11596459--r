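# Bounded-variable two-phase simplex.
#
# Solves  max c'v  s.t.  A v = b,  lb <= v <= ub.
# Dense revised simplex with Bland's rule (anti-cycling); the basis system is
# re-factorised at every iteration, which is robust and fast enough for the
# network sizes this package targets (tens to a few thousand reactions).
# All flux bounds in metabolic models here are finite (+-FLUX_MAX), so
# unboundedness can only arise from user-supplied infinite bounds.

#' @keywords internal
lp_pivot_tol <- 1e-9

#' Maximise a linear objective over a bounded polyhedron
#'
#' @param A constraint matrix (m x n), dense or sparse.
#' @param b right-hand side (length m).
#' @param cvec objective coefficients (length n), maximised.
#' @param lb,ub variable bounds (length n); may contain `-Inf`/`Inf`.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `objective` (numeric, `NA` unless optimal) and `x` (length-n solution,
#'   `NA` unless optimal).
#' @keywords internal
lp_maximize <- function(A, b, cvec, lb, ub) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(cvec) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub + lp_pivot_tol)) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  if (m == 0L) {
    # no equality constraints: each variable sits at its best finite bound
    x <- ifelse(cvec >= 0, ub, lb)
    if (any(!is.finite(x) & cvec != 0)) {
      return(list(status = "unbounded", objective = NA_real_, x = rep(NA_real_, n)))
    }
    x[!is.finite(x)] <- 0
    return(list(status = "optimal", objective = sum(cvec * x), x = x))
  }

  # augment with m artificial variables so an initial basis always exists
  n_tot <- n + m
  lb_t <- c(lb, rep(0, m))
  ub_t <- c(ub, rep(Inf, m))

  # nonbasic structurals start at their smaller-magnitude finite bound
  start_val <- function(j) {
    l <- lb[j]; u <- ub[j]
    if (is.finite(l) && is.finite(u)) return(if (abs(l) <= abs(u)) l else u)
    if (is.finite(l)) return(l)
    if (is.finite(u)) return(u)
    0
  }
  x <- numeric(n_tot)
  at_upper <- logical(n_tot)
  for (j in seq_len(n)) {
    x[j] <- start_val(j)
    at_upper[j] <- is.finite(ub[j]) && x[j] == ub[j] && !(is.finite(lb[j]) && lb[j] == ub[j])
  }
  resid <- b - as.vector(A %*% x[seq_len(n)])
  art_sign <- ifelse(resid >= 0, 1, -1)
  A_t <- cbind(A, diag(art_sign, nrow = m, ncol = m))
  x[n + seq_len(m)] <- abs(resid)
  basis <- n + seq_len(m)

  run_simplex <- function(cost, basis, x, at_upper, art_fixed) {
    repeat {
      Bm <- A_t[, basis, drop = FALSE]
      nb <- setdiff(seq_len(n_tot), basis)
      xb <- tryCatch(solve(Bm, b - A_t[, nb, drop = FALSE] %*% x[nb]),
                     error = function(e) NULL)
      if (is.null(xb)) return(list(status = "singular"))
      x[basis] <- as.vector(xb)
      y <- solve(t(Bm), cost[basis])
      d <- cost[nb] - as.vector(crossprod(A_t[, nb, drop = FALSE], y))
      lower_nb <- !at_upper[nb]
      eligible <- (lower_nb & d > lp_pivot_tol) | (!lower_nb & d < -lp_pivot_tol)
      if (art_fixed) eligible[nb > n] <- FALSE   # artificials frozen in phase 2
      if (!any(eligible)) {
        return(list(status = "optimal", basis = basis, x = x, at_upper = at_upper))
      }
      j <- nb[eligible][which.min(nb[eligible])]  # Bland: smallest index
      delta <- if (at_upper[j]) -1 else 1
      dxb <- -delta * as.vector(solve(Bm, A_t[, j]))
      # ratio test: entering may also just flip to its opposite bound
      t_flip <- ub_t[j] - lb_t[j]
      t_best <- t_flip; leave <- 0L
      for (i in seq_len(m)) {
        if (dxb[i] > lp_pivot_tol) {
          ti <- (ub_t[basis[i]] - x[basis[i]]) / dxb[i]
        } else if (dxb[i] < -lp_pivot_tol) {
          ti <- (lb_t[basis[i]] - x[basis[i]]) / dxb[i]
        } else next
        if (ti < t_best - lp_pivot_tol ||
            (ti < t_best + lp_pivot_tol && leave > 0L && basis[i] < basis[leave])) {
          t_best <- ti; leave <- i
        }
      }
      if (!is.finite(t_best)) return(list(status = "unbounded"))
      t_best <- max(t_best, 0)
      x[basis] <- x[basis] + t_best * dxb
      x[j] <- x[j] + delta * t_best
      if (leave == 0L) {
        at_upper[j] <- !at_upper[j]            # bound flip, basis unchanged
      } else {
        out <- basis[leave]
        at_upper[out] <- dxb[leave] > 0        # left at upper if it rose
        x[out] <- if (at_upper[out]) ub_t[out] else lb_t[out]
        basis[leave] <- j
      }
    }
  }

  # phase 1: drive sum of artificials to zero
  cost1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_simplex(cost1, basis, x, at_upper, art_fixed = FALSE)
  if (ph1$status != "optimal") {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  if (sum(ph1$x[n + seq_len(m)]) > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  # freeze artificials at zero for phase 2 (some may linger in the basis,
  # degenerate at value 0)
  ub_t[n + seq_len(m)] <- 0
  cost2 <- c(cvec, rep(0, m))
  ph2 <- run_simplex(cost2, ph1$basis, ph1$x, ph1$at_upper, art_fixed = TRUE)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_, x = rep(NA_real_, n)))
  }
  if (ph2$status != "optimal") {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  xs <- ph2$x[seq_len(n)]
  list(status = "optimal", objective = sum(cvec * xs), x = xs)
}
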