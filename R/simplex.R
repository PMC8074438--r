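# Bounded-variable primal simplex, two phases, Bland's anti-cycling rule.
#
# Solves   max  c'x   s.t.  A x = b,  lo <= x <= hi
# with lo/hi possibly infinite. Dense linear algebra: intended for the small
# and medium LPs of curated metabolic models, not for sparse mega-scale
# problems. Statuses are first-class values, never conditions: "optimal",
# "infeasible", "unbounded".
#
# Phase I appends one artificial variable per row (cost -1, maximized), so
# rank-deficient stoichiometries are handled without preprocessing: redundant
# rows simply leave their artificial basic at zero, pinned by [0,0] bounds in
# phase II.

simplex_solve <- function(A, b, cc, lo, hi, tol = 1e-9, max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  max_iter <- max_iter %||% (200L * (n + m) + 1000L)

  # nonbasic start: each structural variable sits at a finite bound
  # (or at 0 when free)
  x0 <- ifelse(is.finite(lo), lo, ifelse(is.finite(hi), hi, 0))
  vstat <- ifelse(is.finite(lo), "lower",
                  ifelse(is.finite(hi), "upper", "free"))

  resid <- b - as.vector(A %*% x0)
  art_sign <- ifelse(resid >= 0, 1, -1)
  A_full <- cbind(A, diag(art_sign, m, m))
  lo_full <- c(lo, rep(0, m))
  hi_full <- c(hi, rep(Inf, m))
  x <- c(x0, abs(resid))
  vstat <- c(vstat, rep("basic", m))
  basis <- n + seq_len(m)

  # Phase I: drive sum of artificials to zero
  c1 <- c(rep(0, n), rep(-1, m))
  st <- simplex_iterate(A_full, c1, lo_full, hi_full, basis, x, vstat,
                        tol, max_iter)
  if (st$status == "maxiter") {
    abort("Simplex iteration limit reached in phase I.",
          class = "fluxsens_solver_error")
  }
  infeas <- sum(st$x[n + seq_len(m)])
  scale <- max(1, max(abs(b)))
  if (infeas > 1e-7 * scale) {
    return(list(status = "infeasible", objective = NA_real_,
                fluxes = rep(NA_real_, n)))
  }

  # Phase II: pin artificials at zero, optimize the true objective
  hi_full[n + seq_len(m)] <- 0
  st$x[n + seq_len(m)] <- 0
  c2 <- c(cc, rep(0, m))
  st <- simplex_iterate(A_full, c2, lo_full, hi_full, st$basis, st$x,
                        st$vstat, tol, max_iter)
  if (st$status == "maxiter") {
    abort("Simplex iteration limit reached in phase II.",
          class = "fluxsens_solver_error")
  }
  if (st$status == "unbounded") {
    return(list(status = "unbounded", objective = Inf,
                fluxes = rep(NA_real_, n)))
  }
  v <- st$x[seq_len(n)]
  v <- pmin(pmax(v, lo), hi)  # snap roundoff at bounds
  list(status = "optimal", objective = sum(cc * v), fluxes = v)
}

# One simplex run on a fixed problem; mutates (basis, x, vstat) to optimality.
simplex_iterate <- function(A, cc, lo, hi, basis, x, vstat, tol, max_iter) {
  n_all <- ncol(A)
  for (iter in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    y <- solve(t(B), cc[basis])
    nonbasic <- which(vstat != "basic")
    d <- cc[nonbasic] - as.vector(crossprod(A[, nonbasic, drop = FALSE], y))

    improving <- (vstat[nonbasic] == "lower" & d > tol) |
                 (vstat[nonbasic] == "upper" & d < -tol) |
                 (vstat[nonbasic] == "free" & abs(d) > tol)
    if (!any(improving)) {
      return(list(status = "optimal", basis = basis, x = x, vstat = vstat))
    }
    j <- min(nonbasic[improving])          # Bland: smallest index enters
    dj <- d[match(j, nonbasic)]
    s <- if (dj > 0) 1 else -1             # direction of change of x_j

    wdir <- solve(B, A[, j])               # x_B moves by -s*t*wdir
    delta_b <- -s * wdir

    t_max <- Inf
    leave_pos <- 0L                        # 0 = entering flips to its bound
    for (p in seq_along(basis)) {
      if (delta_b[p] > tol) {
        cap <- (hi[basis[p]] - x[basis[p]]) / delta_b[p]
      } else if (delta_b[p] < -tol) {
        cap <- (x[basis[p]] - lo[basis[p]]) / (-delta_b[p])
      } else next
      cap <- max(cap, 0)
      if (cap < t_max - tol ||
          (cap < t_max + tol && leave_pos > 0L &&
           basis[p] < basis[leave_pos])) { # Bland: smallest index leaves
        t_max <- cap
        leave_pos <- p
      }
    }
    # entering variable blocked by its own opposite bound?
    own_cap <- if (s > 0) hi[j] - x[j] else x[j] - lo[j]
    if (own_cap < t_max - tol) {
      t_max <- own_cap
      leave_pos <- 0L
    }

    if (!is.finite(t_max)) {
      return(list(status = "unbounded", basis = basis, x = x, vstat = vstat))
    }

    x[basis] <- x[basis] + t_max * delta_b
    x[j] <- x[j] + s * t_max
    if (leave_pos == 0L) {                 # bound flip, basis unchanged
      vstat[j] <- if (s > 0) "upper" else "lower"
      x[j] <- if (s > 0) hi[j] else lo[j]
    } else {
      l_var <- basis[leave_pos]
      hit_upper <- delta_b[leave_pos] > 0
      vstat[l_var] <- if (hit_upper) "upper" else "lower"
      x[l_var] <- if (hit_upper) hi[l_var] else lo[l_var]
      basis[leave_pos] <- j
      vstat[j] <- "basic"
    }
  }
  list(status = "maxiter", basis = basis, x = x, vstat = vstat)
}
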