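# Longitudinal trajectory modelling of ROI means with linear mixed models.
#
# The per-area growth model is value ~ age_days + (1 | infant): the fixed
# intercept estimates the metric at birth (age is deliberately NOT centred)
# and the fixed slope its rate of change per day, while per-infant random
# intercepts absorb repeated measures. Stream-level models add area and
# hemisphere (or stream) factors with random intercepts and age slopes by
# area. Model comparison is by maximum-likelihood ratio tests.

#' Canonical area orderings
#'
#' Area codes in hierarchy order for the dorsal visual stream (9 areas),
#' ventral visual stream (8 areas) and primary sensory-motor cortices
#' (4 areas). Used as factor level order (the first area of a stream is the
#' treatment-contrast reference).
#' @format Character vectors.
#' @export
DORSAL_STREAM_AREAS <- c("V1d", "V2d", "V3d", "V3A", "V3B",
                         "IPS0", "IPS1", "IPS2", "IPS3")

#' @rdname DORSAL_STREAM_AREAS
#' @export
VENTRAL_STREAM_AREAS <- c("V1v", "V2v", "V3v", "hV4", "VO1", "VO2",
                          "PHC1", "PHC2")

#' @rdname DORSAL_STREAM_AREAS
#' @export
SENSORIMOTOR_AREAS <- c("V1", "A1", "S1", "M1")

CANONICAL_AREA_ORDER <- c(DORSAL_STREAM_AREAS, VENTRAL_STREAM_AREAS,
                          SENSORIMOTOR_AREAS)

area_levels <- function(areas) {
  u <- unique(areas)
  known <- CANONICAL_AREA_ORDER[CANONICAL_AREA_ORDER %in% u]
  c(known, setdiff(u, known))
}

stream_of_area <- function(area) {
  ifelse(area %in% DORSAL_STREAM_AREAS, "dorsal",
         ifelse(area %in% VENTRAL_STREAM_AREAS, "ventral", NA_character_))
}

#' Voxel-value distribution within an ROI
#'
#' Summarises the finite voxel values of a quantitative map inside a label
#' mask; unfit (`NaN`) voxels are excluded.
#'
#' @param map A [quantitative_map()].
#' @param mask A [label_mask()] in the same grid.
#' @param breaks Passed to [graphics::hist()] (computed without plotting).
#' @return A list: `mean`, `sd`, `n`, and `histogram` (`mids`, `counts`,
#'   `breaks`).
#' @export
roi_distribution <- function(map, mask, breaks = 30) {
  stopifnot(inherits(map, "quantitative_map"), inherits(mask, "label_mask"))
  if (!identical(as.integer(dim(map$values)), mask$space_dim)) {
    stop("mask index space does not match the map grid", call. = FALSE)
  }
  vals <- map$values[mask$indices]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) {
    stop("mask '", mask$label, "' contains no finite voxels", call. = FALSE)
  }
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals),
       histogram = list(mids = h$mids, counts = h$counts, breaks = h$breaks))
}

#' Build a tidy ROI table from maps, masks and ages
#'
#' Computes the ROI mean of every map inside every area/hemisphere mask and
#' assembles one row per (infant, timepoint, hemisphere, area, metric).
#'
#' @param maps Nested named list: `maps[[infant_id]][[timepoint]]` is a list
#'   of [quantitative_map()] objects named by metric.
#' @param masks Nested named list: `masks[[area]][[hemisphere]]` is a
#'   [label_mask()].
#' @param ages Data.frame with columns `infant_id`, `timepoint`, `age_days`.
#' @return A validated ROI table.
#' @export
build_roi_table <- function(maps, masks, ages) {
  stopifnot(all(c("infant_id", "timepoint", "age_days") %in% names(ages)))
  rows <- list()
  for (inf in names(maps)) {
    for (tp in names(maps[[inf]])) {
      age <- ages$age_days[ages$infant_id == inf & ages$timepoint == tp]
      if (length(age) != 1L) {
        stop("need exactly one age for ", inf, " at ", tp, call. = FALSE)
      }
      for (metric in names(maps[[inf]][[tp]])) {
        map <- maps[[inf]][[tp]][[metric]]
        for (area in names(masks)) {
          for (hemi in names(masks[[area]])) {
            mask <- masks[[area]][[hemi]]
            if (is.null(mask)) {
              stop("missing mask for area ", area, " (", hemi, ")",
                   call. = FALSE)
            }
            d <- roi_distribution(map, mask)
            rows[[length(rows) + 1L]] <- data.frame(
              infant_id = inf, age_days = age, timepoint = tp,
              hemisphere = hemi, area = area, metric = metric,
              value = d$mean, stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  validate_roi_table(do.call(rbind, rows))
}

#' Specification of a linear mixed model on an ROI table
#'
#' @param metric Response metric, one of [ROI_METRICS].
#' @param fixed Character vector of fixed-effect terms over
#'   `age_days`, `area`, `hemisphere`, `stream`, optionally with `:`
#'   interactions; `age_days` must be included.
#' @param random Named list describing the random-effects structure: names
#'   are grouping factors (`infant_id`, `area`, ...), each entry a character
#'   vector from `c("intercept", "age_days")` saying what varies by group.
#' @param criterion `"reml"` (for reported coefficients) or `"ml"` (for
#'   likelihood-ratio model comparison).
#' @return An `lmm_spec` list.
#' @examples
#' # the per-area growth model: value ~ age_days + (1 | infant)
#' lmm_spec("t1_s")
#' @export
lmm_spec <- function(metric, fixed = "age_days",
                     random = list(infant_id = "intercept"),
                     criterion = c("reml", "ml")) {
  metric <- match.arg(metric, ROI_METRICS)
  criterion <- match.arg(criterion)
  if (!"age_days" %in% fixed) {
    stop("'age_days' must be a fixed effect", call. = FALSE)
  }
  if (!length(random) || is.null(names(random)) || any(names(random) == "")) {
    stop("'random' must be a named list of grouping factors", call. = FALSE)
  }
  for (g in names(random)) {
    bad <- setdiff(random[[g]], c("intercept", "age_days"))
    if (length(bad)) {
      stop("unsupported random term(s) for ", g, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(metric = metric, fixed = fixed, random = random,
                 criterion = criterion),
            class = "lmm_spec")
}

random_term <- function(group, what) {
  if ("age_days" %in% what) paste0("(1 + age_days | ", group, ")")
  else paste0("(1 | ", group, ")")
}

lmm_formula <- function(spec) {
  rhs <- c(spec$fixed,
           vapply(names(spec$random),
                  function(g) random_term(g, spec$random[[g]]), ""))
  stats::as.formula(paste("value ~", paste(rhs, collapse = " + ")))
}

prepare_lmm_data <- function(table, spec) {
  table <- validate_roi_table(table)
  dat <- table[table$metric == spec$metric, , drop = FALSE]
  if (!nrow(dat)) stop("no rows with metric '", spec$metric, "'", call. = FALSE)
  dat$infant_id <- factor(dat$infant_id)
  dat$area_code <- factor(dat$area, levels = area_levels(dat$area))
  dat$hemisphere <- factor(dat$hemisphere, levels = HEMISPHERES)
  needs_stream <- any(grepl("stream", c(spec$fixed, names(spec$random))))
  if (needs_stream) {
    dat$stream <- stream_of_area(dat$area)
    if (anyNA(dat$stream)) {
      stop("cannot assign a stream to area(s): ",
           paste(unique(dat$area[is.na(dat$stream)]), collapse = ", "),
           call. = FALSE)
    }
    dat$stream <- factor(dat$stream, levels = c("dorsal", "ventral"))
    # each area belongs to one stream, so treatment-coded area would alias
    # the stream contrast: across streams, area enters as its hierarchy
    # position within the stream (1 = earliest), a single ordinal term
    dat$area <- ifelse(dat$stream == "dorsal",
                       match(as.character(dat$area_code),
                             DORSAL_STREAM_AREAS),
                       match(as.character(dat$area_code),
                             VENTRAL_STREAM_AREAS))
  } else {
    dat$area <- dat$area_code
  }
  dat
}

check_identifiable <- function(dat, spec) {
  if (length(unique(dat$age_days)) < 2L) {
    stop("need at least 2 distinct ages to estimate a slope", call. = FALSE)
  }
  for (g in names(spec$random)) {
    if (nlevels(droplevels(dat[[g]])) < 2L) {
      stop("grouping factor '", g, "' has fewer than 2 levels; ",
           "the random effect is not identifiable", call. = FALSE)
    }
  }
  fixed_vars <- unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE)))
  for (v in setdiff(fixed_vars, "age_days")) {
    n_lev <- if (is.factor(dat[[v]])) nlevels(droplevels(dat[[v]]))
             else length(unique(dat[[v]]))
    if (n_lev < 2L) {
      stop("fixed factor '", v, "' has fewer than 2 levels", call. = FALSE)
    }
  }
  invisible(dat)
}

new_lmm_fit <- function(coefs, varcomp, loglik, criterion, n_obs, n_params,
                        r_squared, formula, spec, response_sum,
                        degenerate = FALSE) {
  structure(
    list(coefficients = coefs, varcomp = varcomp, loglik = loglik,
         criterion = criterion, n_obs = n_obs, n_params = n_params,
         r_squared = r_squared, formula = formula, spec = spec,
         response_sum = response_sum, degenerate = degenerate),
    class = "lmm_fit"
  )
}

#' Fit a linear mixed model to an ROI table
#'
#' Fits the Gaussian linear mixed model defined by the spec with
#' [lme4::lmer()]. Because age is not centred, the fixed intercept is the
#' estimated metric value at birth (age 0) and the `age_days` coefficient
#' the growth rate in metric units per day. Fixed-effect p-values use the t
#' distribution with residual degrees of freedom (`n_obs - n_fixed`).
#'
#' If the response is an exact deterministic function of the fixed effects
#' (zero residual variance, as in noise-free synthetic data), the mixed
#' model is degenerate; the fit falls back to ordinary least squares with
#' all variance components zero and an undefined log-likelihood.
#'
#' @param table An ROI table (see [validate_roi_table()]).
#' @param spec An [lmm_spec()].
#' @return An `lmm_fit` object: `coefficients` (data.frame with `term`,
#'   `estimate`, `se`, `t`, `df`, `p`), `varcomp` (data.frame of variance
#'   components), `loglik`, `criterion`, `n_obs`, `n_params`, `r_squared`.
#' @export
fit_lmm <- function(table, spec) {
  stopifnot(inherits(spec, "lmm_spec"))
  dat <- prepare_lmm_data(table, spec)
  check_identifiable(dat, spec)
  form <- lmm_formula(spec)
  fixed_form <- stats::as.formula(
    paste("value ~", paste(spec$fixed, collapse = " + ")))

  ols <- stats::lm(fixed_form, data = dat)
  sse <- sum(stats::residuals(ols)^2)
  sst <- sum((dat$value - mean(dat$value))^2)
  if (sse <= 1e-16 * max(sst, .Machine$double.eps)) {
    # deterministic data: the mixed model is degenerate, report OLS
    sm <- suppressWarnings(summary(ols))$coefficients
    coefs <- data.frame(
      term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
      t = sm[, 3], df = stats::df.residual(ols), p = sm[, 4],
      row.names = NULL, stringsAsFactors = FALSE
    )
    varcomp <- data.frame(
      grp = c(names(spec$random), "Residual"),
      term = c(rep("(Intercept)", length(spec$random)), NA),
      variance = 0, sd = 0, stringsAsFactors = FALSE
    )
    return(new_lmm_fit(coefs, varcomp, loglik = NA_real_,
                       criterion = spec$criterion, n_obs = nrow(dat),
                       n_params = length(stats::coef(ols)) + 1L,
                       r_squared = 1, formula = form, spec = spec,
                       response_sum = sum(dat$value), degenerate = TRUE))
  }

  # two optimizers, keep whichever reaches the higher criterion value:
  # guards against either stopping short of the optimum (which would break
  # the nesting inequality logLik_alt >= logLik_null in model comparisons)
  fits <- list()
  errors <- character()
  for (opt in c("nloptwrap", "bobyqa")) {
    ctrl <- lme4::lmerControl(optimizer = opt, calc.derivs = FALSE,
                              check.scaleX = "ignore")
    f <- tryCatch(
      suppressMessages(lme4::lmer(form, data = dat,
                                  REML = spec$criterion == "reml",
                                  control = ctrl)),
      error = function(e) conditionMessage(e)
    )
    if (is.character(f)) errors <- c(errors, f) else fits <- c(fits, list(f))
  }
  if (!length(fits)) {
    stop("mixed-model fit failed for ", deparse(form), ": ",
         paste(unique(errors), collapse = "; "), call. = FALSE)
  }
  lls <- vapply(fits, function(f) as.numeric(stats::logLik(f)), 0)
  fit <- fits[[which.max(lls)]]

  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  df_resid <- nrow(dat) - length(fe)
  tval <- fe / se
  coefs <- data.frame(
    term = names(fe), estimate = unname(fe), se = unname(se),
    t = unname(tval), df = df_resid,
    p = 2 * stats::pt(-abs(unname(tval)), df_resid),
    row.names = NULL, stringsAsFactors = FALSE
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- data.frame(
    grp = vc$grp, term = ifelse(is.na(vc$var1), NA, vc$var1),
    term2 = vc$var2, variance = vc$vcov, sd = vc$sdcor,
    stringsAsFactors = FALSE
  )
  n_params <- length(fe) + length(lme4::getME(fit, "theta")) + 1L
  new_lmm_fit(coefs, varcomp,
              loglik = as.numeric(stats::logLik(fit)),
              criterion = spec$criterion, n_obs = nrow(dat),
              n_params = n_params,
              r_squared = stats::cor(stats::fitted(fit), dat$value)^2,
              formula = form, spec = spec,
              response_sum = sum(dat$value))
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("linear mixed model (%s), %d obs, logLik %s\n",
              toupper(x$criterion), x$n_obs,
              if (is.na(x$loglik)) "NA (degenerate)" else
                sprintf("%.3f", x$loglik)))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Extract a named fixed-effect row from an `lmm_fit`
#'
#' @param fit An `lmm_fit`.
#' @param term Coefficient name, e.g. `"(Intercept)"` or `"age_days"`.
#' @return One-row data.frame with `estimate`, `se`, `t`, `df`, `p`.
#' @export
fixed_effect <- function(fit, term) {
  stopifnot(inherits(fit, "lmm_fit"))
  row <- fit$coefficients[fit$coefficients$term == term, , drop = FALSE]
  if (!nrow(row)) stop("no fixed effect named '", term, "'", call. = FALSE)
  row
}

random_nested <- function(null_random, alt_random) {
  all(vapply(names(null_random), function(g) {
    g %in% names(alt_random) &&
      all(null_random[[g]] %in% alt_random[[g]])
  }, TRUE))
}

#' Likelihood-ratio comparison of two nested mixed models
#'
#' `LR = 2 * (logLik_alt - logLik_null)`, referred to a chi-square with
#' degrees of freedom equal to the parameter-count difference. Both fits
#' must use maximum likelihood (not REML) on identical rows. When the extra
#' parameters are variance components the true null distribution sits
#' partly on the boundary, so the plain chi-square reference is
#' conservative.
#'
#' @param fit_null,fit_alt `lmm_fit` objects from [fit_lmm()] with
#'   `criterion = "ml"`; the null model must be nested in the alternative.
#' @return A `model_comparison` list: `loglik_null`, `loglik_alt`, `lr`,
#'   `df`, `p`.
#' @export
compare_lmm <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "lmm_fit"), inherits(fit_alt, "lmm_fit"))
  if (fit_null$criterion != "ml" || fit_alt$criterion != "ml") {
    stop("likelihood-ratio comparison requires ML fits, not REML",
         call. = FALSE)
  }
  if (fit_null$n_obs != fit_alt$n_obs ||
      abs(fit_null$response_sum - fit_alt$response_sum) >
        1e-8 * max(1, abs(fit_null$response_sum))) {
    stop("models were not fit to identical rows", call. = FALSE)
  }
  if (!all(fit_null$spec$fixed %in% fit_alt$spec$fixed) ||
      !random_nested(fit_null$spec$random, fit_alt$spec$random)) {
    stop("null model is not nested in the alternative", call. = FALSE)
  }
  df <- fit_alt$n_params - fit_null$n_params
  if (df < 0) stop("alternative has fewer parameters than the null",
                   call. = FALSE)
  lr <- 2 * (fit_alt$loglik - fit_null$loglik)
  if (is.na(lr)) stop("log-likelihood unavailable (degenerate fit)",
                      call. = FALSE)
  lr <- max(lr, 0)
  p <- if (df == 0L) 1 else stats::pchisq(lr, df, lower.tail = FALSE)
  structure(list(loglik_null = fit_null$loglik, loglik_alt = fit_alt$loglik,
                 lr = lr, df = df, p = p),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("LR = %.4f on %d df, p = %.4g\n", x$lr, x$df, x$p))
  invisible(x)
}

#' Bonferroni correction factor from pairwise comparison counts
#'
#' For `k` areas the adjusted threshold divides alpha by the number of
#' pairwise comparisons `k * (k - 1) / 2` (4 areas -> 6, 9 -> 36, 8 -> 28).
#'
#' @param k Number of areas (>= 2).
#' @return Integer comparison count.
#' @export
bonferroni_pairwise_count <- function(k) {
  stopifnot(k >= 2, k == round(k))
  as.integer(k * (k - 1) / 2)
}

#' Per-area growth models with Bonferroni-adjusted significance
#'
#' Fits `value ~ age_days + (1 | infant)` separately to each area (REML)
#' and flags areas whose age slope is significant at
#' `alpha / (k * (k-1) / 2)`, the pairwise-comparison Bonferroni threshold
#' for the `k` areas analysed together.
#'
#' @param table An ROI table.
#' @param areas Character vector of area codes to fit; all must be present.
#' @param metric Response metric.
#' @param alpha Family-wise error level before correction.
#' @return A `per_area_fits` object with `summary` (one row per area:
#'   intercept and slope estimates, SEs, slope t/df/p, significance),
#'   `fits` (named list of `lmm_fit`), `alpha`, `n_comparisons`,
#'   `threshold`.
#' @export
fit_per_area <- function(table, areas, metric, alpha = 0.05) {
  table <- validate_roi_table(table)
  present <- unique(table$area[table$metric == metric])
  missing_areas <- setdiff(areas, present)
  if (length(missing_areas)) {
    stop("area(s) absent from table: ",
         paste(missing_areas, collapse = ", "), call. = FALSE)
  }
  k <- length(areas)
  n_comp <- if (k >= 2) bonferroni_pairwise_count(k) else 1L
  threshold <- alpha / n_comp
  spec <- lmm_spec(metric)
  fits <- lapply(areas, function(ar) {
    fit_lmm(table[table$area == ar, , drop = FALSE], spec)
  })
  names(fits) <- areas
  summary <- do.call(rbind, lapply(areas, function(ar) {
    ic <- fixed_effect(fits[[ar]], "(Intercept)")
    sl <- fixed_effect(fits[[ar]], "age_days")
    data.frame(area = ar,
               intercept = ic$estimate, intercept_se = ic$se,
               slope = sl$estimate, slope_se = sl$se,
               t = sl$t, df = sl$df, p = sl$p,
               significant = sl$p < threshold,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(summary = summary, fits = fits, alpha = alpha,
                 n_comparisons = n_comp, threshold = threshold),
            class = "per_area_fits")
}

#' @export
print.per_area_fits <- function(x, ...) {
  cat(sprintf("per-area growth fits (%d areas, Bonferroni threshold %g = %g/%d)\n",
              nrow(x$summary), x$threshold, x$alpha, x$n_comparisons))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Stream-level mixed model across areas
#'
#' Fits one mixed model to all areas of a processing stream (or across
#' streams) with age plus the requested categorical factors as fixed
#' effects. Factors are treatment-coded; the reference levels are the first
#' area in hierarchy order, the left hemisphere and the dorsal stream.
#' When `stream` is included alongside `area`, area membership would alias
#' the stream contrast, so area then enters as its ordinal hierarchy
#' position within its stream. The default random structure lets intercepts
#' and age slopes vary by area (grouping factor `area_code`) and keeps a
#' per-infant random intercept. A single-area table degenerates to the
#' per-area model.
#'
#' @param table An ROI table.
#' @param metric Response metric.
#' @param factors Categorical fixed effects: subset of
#'   `c("area", "hemisphere", "stream")`. A `stream` factor is derived from
#'   the canonical dorsal/ventral area lists.
#' @param random Random-effects structure as in [lmm_spec()]; `NULL` uses
#'   the default (`(1 + age_days | area) + (1 | infant_id)`).
#' @param age_interactions Add `age_days:` interactions with each factor.
#' @param criterion `"reml"` or `"ml"`.
#' @return An `lmm_fit`.
#' @export
fit_stream_lmm <- function(table, metric,
                           factors = c("area", "hemisphere"),
                           random = NULL, age_interactions = FALSE,
                           criterion = "reml") {
  table <- validate_roi_table(table)
  factors <- match.arg(factors, c("area", "hemisphere", "stream"),
                       several.ok = TRUE)
  sub <- table[table$metric == metric, , drop = FALSE]
  n_areas <- length(unique(sub$area))
  if ("area" %in% factors && n_areas < 2L) {
    # degenerate single-area case: the per-area growth model
    return(fit_lmm(table, lmm_spec(metric, criterion = criterion)))
  }
  if (is.null(random)) {
    random <- if (n_areas >= 2L) {
      list(area_code = c("intercept", "age_days"), infant_id = "intercept")
    } else {
      list(infant_id = "intercept")
    }
  }
  fixed <- c("age_days", factors)
  if (age_interactions) fixed <- c(fixed, paste0("age_days:", factors))
  fit_lmm(table, lmm_spec(metric, fixed = fixed, random = random,
                          criterion = criterion))
}
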