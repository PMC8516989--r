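# Independent oracles the estimators are checked against.

# Exhaustive profiled grid search for the magnitude inversion-recovery fit.
# For a candidate T1 the signed model a - c * exp(-t/T1) (c = a*b >= 0) is
# monotone along the sorted TIs, so its sign pattern is one of n+1 index
# splits; for each split the magnitude least-squares problem is linear in
# (a, c) and solved via the 2x2 normal equations. The minimum feasible SSE
# over the grid bounds the SSE any (a, b, T1) fit with T1 in the grid span
# can reach.
oracle_ir_sse <- function(y, t, t1_grid = seq(10, 5000, by = 1),
                          b_bounds = c(0, 2.5)) {
  n <- length(t)
  E <- exp(-outer(t1_grid, t, function(T1, tt) tt / T1))
  se1 <- rowSums(E)
  se2 <- rowSums(E^2)
  sy2 <- sum(y^2)
  best <- sum((y - mean(y))^2)          # b = 0 candidate (constant model)
  w <- 1 - b_bounds[2] * E              # b clamped at the upper bound
  a_up <- drop(abs(w) %*% y) / rowSums(w^2)
  sse_up <- sy2 - a_up^2 * rowSums(w^2)
  sse_up[!(is.finite(sse_up) & a_up > 0)] <- Inf
  best <- min(best, sse_up)
  for (k in 0:n) {
    s <- c(rep(-1, k), rep(1, n - k))
    x1 <- sum(s * y)
    x2 <- -drop(E %*% (s * y))
    det <- n * se2 - se1^2
    a_hat <- (se2 * x1 + se1 * x2) / det
    c_hat <- (n * x2 + se1 * x1) / det
    sse <- sy2 - (a_hat * x1 + c_hat * x2)
    b_hat <- c_hat / a_hat
    ok <- is.finite(sse) & a_hat > 0 &
      b_hat >= b_bounds[1] & b_hat <= b_bounds[2]
    if (any(ok)) best <- min(best, min(sse[ok]))
  }
  best
}

# Monte-Carlo oracle for the mean of a Rician magnitude observation with
# signed underlying signal s and per-channel sigma.
oracle_rician_mean <- function(s, sigma, n_draws = 1e6, seed = 424242) {
  withr::with_seed(seed, {
    n1 <- stats::rnorm(n_draws, 0, sigma)
    n2 <- stats::rnorm(n_draws, 0, sigma)
    mean(sqrt((s + n1)^2 + n2^2))
  })
}

# Ordinary least squares by explicit normal equations (no lm()).
oracle_ols <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Direct-summation log2 fold change: explicit loops, no matrix algebra.
oracle_fold_change <- function(mat_log2, groups) {
  n_genes <- nrow(mat_log2)
  out <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    st <- 0; nt <- 0; sc <- 0; nc <- 0
    for (j in seq_len(ncol(mat_log2))) {
      if (groups[j] == "target_postnatal") {
        st <- st + mat_log2[i, j]; nt <- nt + 1
      } else {
        sc <- sc + mat_log2[i, j]; nc <- nc + 1
      }
    }
    out[i] <- st / nt - sc / nc
  }
  names(out) <- rownames(mat_log2)
  out
}

# A cohort table whose residuals are centred within infant, so the
# between-infant variance component is forced to its zero boundary and the
# mixed-model fixed effects must coincide with OLS.
make_centred_cohort <- function(beta0 = 2.0, beta1 = -0.0015,
                                sigma = 0.03, seed = 4) {
  sim <- simulate_cohort(cohort_simulation_spec(beta0, beta1, tau = 0,
                                                sigma = sigma, seed = seed))
  tab <- sim$table
  fixedpart <- beta0 + beta1 * tab$age_days
  eps <- tab$value - fixedpart
  tab$value <- fixedpart + eps - stats::ave(eps, tab$infant_id)
  tab
}
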