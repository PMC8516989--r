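# The T1/R1-myelin relations that motivate analysing growth on the R1
# scale: R1 rises linearly with myelin fraction, so equal myelin increments
# give equal R1 increments, while T1 = 1/R1 is compressive - the same
# myelin change shifts T1 more in lightly myelinated tissue.

#' Linear relaxation-rate model of myelin content
#'
#' `R1(mf) = c0 + c1 * mf`, with `mf` the voxel myelin volume fraction.
#' `c0` is the relaxation rate of myelin-free tissue and `c1` the rate
#' increase per unit myelin fraction. The relation is structural; the
#' constants are user parameters (defaults are plausible for cortex at 3T
#' and used only for illustration and tests).
#'
#' @param c0 Baseline rate at zero myelin, 1/s (>= 0).
#' @param c1 Rate increase per unit myelin fraction, 1/s (> 0).
#' @return A `myelin_linear_model` list.
#' @export
myelin_linear_model <- function(c0 = 0.35, c1 = 1.2) {
  stopifnot(c0 >= 0, c1 > 0)
  structure(list(c0 = c0, c1 = c1), class = "myelin_linear_model")
}

check_mf <- function(mf) {
  if (any(!is.finite(mf)) || any(mf < 0) || any(mf > 1)) {
    stop("myelin fraction must lie in [0, 1]", call. = FALSE)
  }
  mf
}

#' Relaxation rate at a given myelin fraction
#'
#' @param model A [myelin_linear_model()].
#' @param mf Myelin fraction(s) in `[0, 1]`.
#' @return R1 in 1/s.
#' @export
r1_from_myelin <- function(model, mf) {
  stopifnot(inherits(model, "myelin_linear_model"))
  model$c0 + model$c1 * check_mf(mf)
}

#' Relaxation time at a given myelin fraction
#'
#' `T1 = 1 / (c0 + c1 * mf)`, seconds; monotone decreasing in myelin.
#'
#' @inheritParams r1_from_myelin
#' @return T1 in seconds.
#' @export
t1_from_myelin <- function(model, mf) {
  r1 <- r1_from_myelin(model, mf)
  if (any(r1 <= 0)) {
    stop("relaxation rate must be positive to invert to T1", call. = FALSE)
  }
  1 / r1
}

#' T1 change produced by a myelin change
#'
#' `t1(mf + d_mf) - t1(mf)`. For a fixed positive myelin increment the
#' magnitude of the T1 change strictly decreases with the baseline myelin
#' fraction, while the corresponding R1 change (`c1 * d_mf`) is constant -
#' the asymmetry that makes T1 growth rates hard to compare across areas
#' that start at different myelination levels.
#'
#' @inheritParams r1_from_myelin
#' @param d_mf Myelin-fraction increment; `mf + d_mf` must stay in `[0, 1]`.
#' @return Change in T1, seconds (negative for increasing myelin).
#' @export
delta_t1_for_delta_myelin <- function(model, mf, d_mf) {
  t1_from_myelin(model, mf + d_mf) - t1_from_myelin(model, mf)
}
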