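# Voxelwise estimation of T1 from magnitude inversion-recovery series.
#
# The signed recovery signal is S(t) = a * (1 - b * exp(-t / T1)); magnitude
# images discard the sign, so the fitting model is |S(t)|. The kink at the
# null point is handled by multistart Levenberg-Marquardt minimisation with
# an analytic Jacobian of the signed model, sign applied afterwards.

#' The default 20-point inversion-time schedule
#'
#' An arithmetic TI sequence starting at 50 ms with 150 ms spacing, 20 times
#' in total (50, 200, ..., 2900 ms), matching the slice-shuffled IR-EPI
#' acquisition the fitting model is designed for.
#'
#' @return A [ti_schedule()] of length 20.
#' @examples
#' build_default_schedule()
#' @export
build_default_schedule <- function() {
  ti_schedule(seq(50, by = 150, length.out = 20))
}

#' Predict the magnitude inversion-recovery signal
#'
#' Evaluates `|a * (1 - b * exp(-t / T1))|` at each inversion time. `a`
#' scales with the initial magnetization, `b` is the effective inversion
#' coefficient (2 for a perfect inversion) and `t1_ms` the longitudinal
#' relaxation time.
#'
#' @param a Signal scale, arbitrary scanner units.
#' @param b Inversion coefficient (dimensionless).
#' @param t1_ms Relaxation time in ms; must be positive.
#' @param schedule A [ti_schedule()] (or numeric TI vector, ms).
#' @return Numeric vector of predicted magnitudes, one per TI.
#' @examples
#' predict_ir_signal(1000, 2, 1000, build_default_schedule())
#' @export
predict_ir_signal <- function(a, b, t1_ms, schedule) {
  if (!is.numeric(t1_ms) || t1_ms <= 0) {
    stop("'t1_ms' must be positive", call. = FALSE)
  }
  t <- as.numeric(as_ti_schedule(schedule))
  abs(a * (1 - b * exp(-t / t1_ms)))
}

#' Options controlling the voxelwise T1 fit
#'
#' @param t1_bounds_ms Lower/upper bounds on T1 in ms. The default
#'   `c(50, 10000)` covers infant cortex (roughly 1500-2500 ms) with wide
#'   margins.
#' @param b_bounds Bounds on the inversion coefficient; `c(0, 2.5)` brackets
#'   the perfect-inversion value 2.
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @param sse_rel_tol Relative tolerance on the sum of squared errors used
#'   as the convergence criterion.
#' @param extra_t1_starts_ms Fixed additional T1 initialisations, tried on
#'   top of the null-point heuristic multistarts.
#' @param r_squared_min Optional exclusion threshold on the voxelwise R^2;
#'   `NULL` (the default) applies none.
#' @return A `fit_options` list.
#' @export
fit_options <- function(t1_bounds_ms = c(50, 10000),
                        b_bounds = c(0, 2.5),
                        max_iter = 500L,
                        sse_rel_tol = 1e-10,
                        extra_t1_starts_ms = c(500, 2500),
                        r_squared_min = NULL) {
  stopifnot(length(t1_bounds_ms) == 2L, all(t1_bounds_ms > 0),
            t1_bounds_ms[1] < t1_bounds_ms[2],
            length(b_bounds) == 2L, b_bounds[1] < b_bounds[2],
            b_bounds[1] >= 0)
  structure(
    list(t1_bounds_ms = as.numeric(t1_bounds_ms),
         b_bounds = as.numeric(b_bounds),
         max_iter = as.integer(max_iter),
         sse_rel_tol = sse_rel_tol,
         extra_t1_starts_ms = as.numeric(extra_t1_starts_ms),
         r_squared_min = r_squared_min),
    class = "fit_options"
  )
}

# Residuals and Jacobian for the magnitude model. The Jacobian of |f| is
# sign(f) * J(f); at f == 0 the subgradient convention sign = +1 avoids NaN.
ir_residual <- function(par, t, y) {
  f <- par[1] * (1 - par[2] * exp(-t / par[3]))
  y - abs(f)
}

ir_jacobian <- function(par, t, y) {
  a <- par[1]; b <- par[2]; t1 <- par[3]
  e <- exp(-t / t1)
  f <- a * (1 - b * e)
  s <- ifelse(f < 0, -1, 1)
  # d(residual)/d(par) = -sign(f) * d f / d par
  cbind(-s * (1 - b * e),
        -s * (-a * e),
        -s * (-a * b * e * t / t1^2))
}

# Profiled coarse-grid search over T1 used as one multistart seed. For
# fixed T1 the signed model a - c*exp(-t/T1) (c = a*b >= 0) is monotone in
# t, so its sign pattern along the sorted TIs is -1...-1,+1...+1; for each
# of the n+1 patterns the magnitude least-squares problem is linear in
# (a, c) and solves in closed form. Bound-constrained candidates (b = 0 and
# b = b_max) cover solutions whose unconstrained b leaves the box.
profile_t1_grid <- function(y, t, t1_grid, b_bounds) {
  n <- length(t)
  E <- exp(-outer(t1_grid, t, function(T1, tt) tt / T1))  # grid x n
  se1 <- rowSums(E)
  se2 <- rowSums(E^2)
  sy2 <- sum(y^2)
  best <- list(sse = Inf, a = NA, b = NA, t1 = NA)
  consider <- function(sse, a, b, t1) {
    i <- which.min(sse)
    if (length(i) && is.finite(sse[i]) && sse[i] < best$sse) {
      best <<- list(sse = sse[i], a = a[i], b = b[i], t1 = t1[i])
    }
  }
  # b = 0: constant positive model, independent of T1
  a0 <- mean(y)
  consider(sum((y - a0)^2), a0, 0, t1_grid[1])
  # candidate clamped at the upper b bound: model magnitude is a * |w|
  w <- 1 - b_bounds[2] * E
  a_up <- drop(abs(w) %*% y) / rowSums(w^2)
  sse_up <- sy2 - a_up^2 * rowSums(w^2)
  sse_up[!(is.finite(sse_up) & a_up > 0)] <- Inf
  consider(sse_up, a_up, rep(b_bounds[2], length(t1_grid)), t1_grid)
  for (k in 0:n) {
    s <- c(rep(-1, k), rep(1, n - k))
    xty1 <- sum(s * y)
    xty2 <- -drop(E %*% (s * y))
    det <- n * se2 - se1^2
    a_hat <- (se2 * xty1 + se1 * xty2) / det
    c_hat <- (n * xty2 + se1 * xty1) / det
    sse <- sy2 - (a_hat * xty1 + c_hat * xty2)
    b_hat <- c_hat / a_hat
    ok <- is.finite(sse) & a_hat > 0 &
      b_hat >= b_bounds[1] & b_hat <= b_bounds[2]
    sse[!ok] <- Inf
    consider(sse, a_hat, b_hat, t1_grid)
  }
  best
}

fit_sentinel <- function(n_starts = 0L) {
  structure(
    list(a = NA_real_, b = NA_real_, t1_ms = NA_real_,
         r_squared = NA_real_, sse = NA_real_,
         converged = FALSE, n_starts_tried = as.integer(n_starts)),
    class = "t1_fit"
  )
}

#' Fit the inversion-recovery model to one voxel
#'
#' Minimises the sum of squared differences between the measured magnitudes
#' and `|a(1 - b exp(-t/T1))|` over `(a, b, T1)` by Levenberg-Marquardt,
#' from several starting points, returning the best. T1 starts are
#' `{0.5, 1, 2}` times the null-point heuristic `T1_0 = t_min / ln 2`
#' (where `t_min` is the TI of the series minimum, near the zero crossing
#' when `b` is close to 2) plus the fixed starts in the options; `a` starts
#' at the maximum signal and `b` at 2.
#'
#' @param series Numeric vector of magnitude signals, one per TI;
#'   non-negative, no `NA`.
#' @param schedule A [ti_schedule()] aligned with `series`.
#' @param options A [fit_options()] list.
#' @return A `t1_fit` list: `a`, `b`, `t1_ms`, `r_squared`, `sse`,
#'   `converged`, `n_starts_tried`. A constant (e.g. all-zero) series cannot
#'   identify the model and yields `converged = FALSE` with `NA` parameters.
#' @export
fit_t1_voxel <- function(series, schedule, options = fit_options()) {
  schedule <- as_ti_schedule(schedule)
  t <- as.numeric(schedule)
  y <- as.numeric(series)
  if (length(y) != length(t)) {
    stop("series length (", length(y), ") does not match schedule (",
         length(t), ")", call. = FALSE)
  }
  if (anyNA(y)) stop("series contains NA/NaN", call. = FALSE)
  if (any(y < 0)) stop("magnitude signals must be non-negative", call. = FALSE)

  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(fit_sentinel())   # constant series: unidentifiable

  lo <- c(1e-12, options$b_bounds[1], options$t1_bounds_ms[1])
  hi <- c(10 * max(y), options$b_bounds[2], options$t1_bounds_ms[2])

  t1_null <- t[which.min(y)] / log(2)
  t1_starts <- unique(pmin(pmax(c(0.5, 1, 2) * t1_null,
                                options$t1_bounds_ms[1]),
                           options$t1_bounds_ms[2]))
  t1_starts <- unique(c(t1_starts,
                        pmin(pmax(options$extra_t1_starts_ms,
                                  options$t1_bounds_ms[1]),
                             options$t1_bounds_ms[2])))
  a0 <- max(y)
  b0 <- min(max(2, options$b_bounds[1]), options$b_bounds[2])

  # profiled coarse grid over T1 supplies one more start (and a fallback
  # solution that LM can only improve on)
  grid <- exp(seq(log(options$t1_bounds_ms[1]), log(options$t1_bounds_ms[2]),
                  length.out = 400))
  gbest <- profile_t1_grid(y, t, grid, options$b_bounds)

  starts <- lapply(t1_starts, function(t1_0) c(a0, b0, t1_0))
  if (is.finite(gbest$sse)) {
    starts <- c(starts, list(c(max(gbest$a, lo[1]),
                               min(max(gbest$b, lo[2]), hi[2]),
                               gbest$t1)))
  }

  best <- NULL
  n_tried <- 0L
  ctrl <- minpack.lm::nls.lm.control(maxiter = options$max_iter,
                                     ftol = options$sse_rel_tol)
  for (par0 in starts) {
    n_tried <- n_tried + 1L
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lo, upper = hi,
                         fn = ir_residual, jac = ir_jacobian,
                         t = t, y = y, control = ctrl),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- fit$deviance
    if (is.null(best) || sse < best$deviance) best <- fit
  }
  if (is.null(best)) return(fit_sentinel(n_tried))

  par <- best$par
  sse <- best$deviance
  if (is.finite(gbest$sse) && gbest$sse < sse) {
    # LM left the grid solution's basin; keep the better grid point
    par <- c(gbest$a, gbest$b, gbest$t1)
    sse <- gbest$sse
  }
  structure(
    list(a = par[1], b = par[2], t1_ms = par[3],
         r_squared = 1 - sse / sst, sse = sse,
         converged = TRUE, n_starts_tried = n_tried),
    class = "t1_fit"
  )
}

#' @export
print.t1_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("IR fit: a = %.4g, b = %.4f, T1 = %.2f ms, R^2 = %.5f\n",
                x$a, x$b, x$t1_ms, x$r_squared))
  } else {
    cat("IR fit: not converged (degenerate series)\n")
  }
  invisible(x)
}

#' Fit T1 over a masked 4D inversion-recovery volume
#'
#' Applies [fit_t1_voxel()] to every voxel in the mask and assembles T1
#' (seconds), R1 (1/s, computed as `1000 / T1_ms`), goodness-of-fit R^2 and
#' inversion-coefficient maps. Voxels outside the mask, unconverged voxels,
#' and voxels failing an optional R^2 threshold are `NaN`.
#'
#' @param signals 4D array `(x, y, z, TI)` of magnitudes.
#' @param schedule A [ti_schedule()] matching the 4th dimension.
#' @param options A [fit_options()] list.
#' @param mask Optional 3D logical (or 0/1) array selecting voxels to fit;
#'   `NULL` fits all voxels.
#' @param voxel_size_mm Voxel size recorded in the output maps.
#' @return A list of [quantitative_map()] objects: `t1`, `r1`, `r_squared`,
#'   `b`.
#' @export
fit_t1_volume <- function(signals, schedule, options = fit_options(),
                          mask = NULL, voxel_size_mm = c(2, 2, 2)) {
  schedule <- as_ti_schedule(schedule)
  if (length(dim(signals)) != 4L) {
    stop("'signals' must be a 4D array (x, y, z, TI)", call. = FALSE)
  }
  d <- dim(signals)
  if (d[4] != length(schedule)) {
    stop("4th dimension does not match the TI schedule", call. = FALSE)
  }
  grid <- d[1:3]
  if (is.null(mask)) {
    sel <- rep(TRUE, prod(grid))
  } else {
    if (!identical(as.integer(dim(mask)), as.integer(grid))) {
      stop("mask dimensions do not match the signal grid", call. = FALSE)
    }
    sel <- as.logical(mask)
    sel[is.na(sel)] <- FALSE
  }

  flat <- matrix(signals, nrow = prod(grid), ncol = d[4])
  t1 <- r2 <- bmap <- rep(NaN, prod(grid))
  for (v in which(sel)) {
    fit <- fit_t1_voxel(flat[v, ], schedule, options)
    keep <- fit$converged &&
      (is.null(options$r_squared_min) ||
         fit$r_squared >= options$r_squared_min)
    if (keep) {
      t1[v] <- fit$t1_ms / 1000
      r2[v] <- fit$r_squared
      bmap[v] <- fit$b
    }
  }
  shape <- function(x) array(x, dim = grid)
  list(
    t1 = quantitative_map(shape(t1), "t1_s", voxel_size_mm),
    r1 = quantitative_map(shape(1 / t1), "r1_per_s", voxel_size_mm),
    r_squared = quantitative_map(shape(r2), "r_squared", voxel_size_mm),
    b = quantitative_map(shape(bmap), "b", voxel_size_mm)
  )
}

#' Relaxation-rate map from a T1 map
#'
#' R1 = 1/T1 elementwise; `NaN` (unfit) voxels stay `NaN`. R1 is the
#' preferred scale for growth-rate comparisons because it varies linearly
#' with myelin content, whereas equal myelin changes produce larger T1
#' changes in less myelinated tissue.
#'
#' @param t1_map A [quantitative_map()] with metric `t1_s`.
#' @return A [quantitative_map()] with metric `r1_per_s`.
#' @export
compute_r1_map <- function(t1_map) {
  stopifnot(inherits(t1_map, "quantitative_map"))
  if (t1_map$metric != "t1_s") {
    stop("compute_r1_map() expects a map with metric 't1_s', got '",
         t1_map$metric, "'", call. = FALSE)
  }
  quantitative_map(1 / t1_map$values, "r1_per_s", t1_map$voxel_size_mm)
}
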