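# Independent oracles used across the suite. Nothing here calls the
# package's LP solver: optima come from exhaustive vertex enumeration (or
# boot::simplex), so agreement is a genuine dual-route check.

# Enumerate candidate basic solutions of  max c'x, A x = b, lb <= x <= ub.
# Handles rank-deficient A by enumerating bases of an independent row subset
# and checking feasibility against the full system.
vertex_enumeration_optimum <- function(A, b, cvec, lb, ub, tol = 1e-7) {
  A <- as.matrix(A)
  n <- ncol(A)
  qrA <- qr(t(A))
  rows <- sort(qrA$pivot[seq_len(qrA$rank)])
  Ar <- A[rows, , drop = FALSE]
  br <- b[rows]
  m <- nrow(Ar)
  best <- -Inf
  feasible <- FALSE
  check <- function(x) {
    if (any(x < lb - tol) || any(x > ub + tol)) return()
    if (max(abs(A %*% x - b)) > tol) return()
    feasible <<- TRUE
    best <<- max(best, sum(cvec * x))
  }
  if (m == 0L) {
    check(ifelse(cvec >= 0, ub, lb))
  } else {
    for (bas in combn(n, m, simplify = FALSE)) {
      Bm <- Ar[, bas, drop = FALSE]
      if (abs(det(Bm)) < 1e-10) next
      nb <- setdiff(seq_len(n), bas)
      k <- length(nb)
      for (mask in seq_len(2^k) - 1L) {
        xn <- numeric(k)
        for (t in seq_len(k)) {
          xn[t] <- if (bitwAnd(mask, bitwShiftL(1L, t - 1L)) > 0) ub[nb[t]] else lb[nb[t]]
        }
        if (any(!is.finite(xn))) next
        rhs <- br - if (k > 0) as.vector(Ar[, nb, drop = FALSE] %*% xn) else 0 * br
        xb <- tryCatch(solve(Bm, rhs), error = function(e) NULL)
        if (is.null(xb)) next
        x <- numeric(n); x[bas] <- xb; x[nb] <- xn
        check(x)
      }
    }
  }
  if (!feasible) return(list(status = "infeasible", objective = NA_real_))
  list(status = "optimal", objective = best)
}

# FBA optimum of a model by vertex enumeration (models with <= ~10 reactions)
fba_vertex_oracle <- function(model, objective = NULL) {
  obj_id <- resolve_objective(model, objective)
  S <- as.matrix(stoichiometric_matrix(model))
  bd <- reaction_bounds(model)
  vertex_enumeration_optimum(S, rep(0, nrow(S)), as.numeric(bd$id == obj_id),
                             bd$lb, bd$ub)
}

# Second LP backend: boot::simplex after shifting x = v - lb >= 0
fba_boot_oracle <- function(model, objective = NULL) {
  obj_id <- resolve_objective(model, objective)
  S <- as.matrix(stoichiometric_matrix(model))
  bd <- reaction_bounds(model)
  n <- nrow(bd)
  b3 <- as.vector(-S %*% bd$lb)
  flip <- b3 < 0  # boot::simplex requires non-negative right-hand sides
  S[flip, ] <- -S[flip, , drop = FALSE]
  b3[flip] <- -b3[flip]
  res <- boot::simplex(a = as.numeric(bd$id == obj_id),
                       A1 = diag(n), b1 = bd$ub - bd$lb,
                       A3 = S, b3 = b3,
                       maxi = TRUE)
  if (res$solved != 1) return(list(status = "not_solved", objective = NA_real_))
  list(status = "optimal",
       objective = res$value + sum((bd$id == obj_id) * bd$lb))
}

# Independent subset enumeration (recursive, no combn) for the screen oracle
all_subsets_upto <- function(n, max_size) {
  out <- list()
  recurse <- function(start, cur) {
    if (length(cur) > 0 && length(cur) <= max_size) out[[length(out) + 1L]] <<- cur
    if (length(cur) == max_size || start > n) return()
    for (i in start:n) recurse(i + 1L, c(cur, i))
  }
  recurse(1L, integer(0))
  out
}

# Brute-force deletion screen: direct bound zeroing, no knock_out()/screen code
brute_force_deletion_reference <- function(model, resolved_ids, max_size,
                                           product_objective) {
  subsets <- all_subsets_upto(length(resolved_ids), max_size)
  rows <- lapply(subsets, function(idx) {
    m <- model
    for (rid in unique(unlist(resolved_ids[idx]))) {
      m$reactions[[rid]]$lb <- 0
      m$reactions[[rid]]$ub <- 0
    }
    sol <- solve_fba(m, product_objective)
    data.frame(labels = paste(names(resolved_ids)[idx], collapse = " + "),
               size = length(idx),
               b12_umol = report_in_micromol(sol$objective_value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
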