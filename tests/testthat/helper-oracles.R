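# Independent oracles used across the suite. These never call the code
# paths they check.

# Brute-force LP oracle: enumerate candidate vertices of
# {v : S v = 0, lb <= v <= ub} by fixing all but rank(S) variables at a
# bound and solving the remaining square-ish system. Exact for bounded
# polytopes with few reactions.
vertex_enumeration_optimum <- function(model, tol = 1e-8) {
  S <- as.matrix(model$S)
  lb <- model$lower_bounds
  ub <- model$upper_bounds
  w <- model$objective_coeffs
  r <- ncol(S)
  k <- qr(S)$rank
  best <- -Inf
  feasible <- FALSE
  for (free in utils::combn(r, k, simplify = FALSE)) {
    SF <- S[, free, drop = FALSE]
    if (qr(SF)$rank < k) next
    fixed <- setdiff(seq_len(r), free)
    nfx <- length(fixed)
    for (mask in 0:(2^nfx - 1)) {
      at_upper <- bitwAnd(mask, 2^(seq_len(nfx) - 1)) > 0
      vfix <- ifelse(at_upper, ub[fixed], lb[fixed])
      vfree <- tryCatch(
        qr.solve(SF, -S[, fixed, drop = FALSE] %*% vfix),
        error = function(e) NULL)
      if (is.null(vfree)) next
      v <- numeric(r)
      v[free] <- vfree
      v[fixed] <- vfix
      if (max(abs(S %*% v)) < tol &&
          all(v >= lb - tol) && all(v <= ub + tol)) {
        feasible <- TRUE
        best <- max(best, sum(w * v))
      }
    }
  }
  if (!feasible) NA_real_ else best
}

# Double-loop Monte-Carlo oracle for Sobol indices of a cheap function of
# independent U[0,1] factors: outer loop conditions on X_i, inner loop
# integrates over the rest. Returns S1 and ST with standard errors.
double_loop_sobol <- function(f, d, n_outer = 400, n_inner = 400,
                              seed = 99) {
  set.seed(seed)
  big <- matrix(runif(20000 * d), ncol = d)
  VY <- var(apply(big, 1, f))
  S1 <- numeric(d); S1_se <- numeric(d)
  ST <- numeric(d); ST_se <- numeric(d)
  for (i in seq_len(d)) {
    cond_mean <- numeric(n_outer)
    cond_var <- numeric(n_outer)
    for (o in seq_len(n_outer)) {
      xi <- runif(1)
      X <- matrix(runif(n_inner * d), ncol = d)
      X[, i] <- xi
      cond_mean[o] <- mean(apply(X, 1, f))
      # for ST: condition on all-but-i instead
      xrest <- runif(d)
      X2 <- matrix(rep(xrest, each = n_inner), ncol = d)
      X2[, i] <- runif(n_inner)
      cond_var[o] <- mean(apply(X2, 1, f))
    }
    S1[i] <- var(cond_mean) / VY
    S1_se[i] <- sd(cond_mean^2) / sqrt(n_outer) / VY
    ST[i] <- 1 - var(cond_var) / VY
    ST_se[i] <- sd(cond_var^2) / sqrt(n_outer) / VY
  }
  list(S1 = S1, S1_se = pmax(S1_se, 0.015),
       ST = ST, ST_se = pmax(ST_se, 0.015))
}

# Fixture with intentionally swapped first-order vs total-effect rankings:
# x1 carries the only main effect, the x2:x3 interaction carries more
# total variance. f = x1 + 6 (x2 - 1/2)(x3 - 1/2).
ranking_swap_function <- function(x) {
  x[1] + 6 * (x[2] - 0.5) * (x[3] - 0.5)
}

# absolute-tolerance comparison for sensitivity indices (the analytic
# tolerances quoted in tests are absolute, not relative)
expect_within <- function(actual, expected, tol) {
  actual <- as.numeric(actual)
  testthat::expect_lte(max(abs(actual - expected)), tol)
}
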