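# Synthetic inputs with known ground truth: inversion-recovery voxel
# signals under Rician noise, longitudinal ROI cohorts, expression matrices
# with planted differential expression, and mask pairs with exact overlap.
# Every generator takes an explicit seed and is bitwise reproducible.

#' Specification for simulated inversion-recovery voxels
#'
#' Noise is Rician: each measured magnitude is
#' `sqrt((S(t) + n1)^2 + n2^2)` with `n1, n2 ~ N(0, noise_sigma^2)` drawn
#' independently per TI, i.e. the magnitude of a complex Gaussian channel
#' pair centred on the signed signal. At `noise_sigma = 0` the generator
#' returns exactly `|S(t)|`.
#'
#' @param a True signal scale (> 0).
#' @param t1_ms True relaxation time in ms (> 0).
#' @param b True inversion coefficient, in `[0, 2.5]`; 2 for a perfect
#'   inversion (the default).
#' @param noise_sigma Gaussian sigma of each complex channel (>= 0).
#' @param schedule A [ti_schedule()].
#' @param n_voxels Number of voxels to simulate.
#' @param seed Integer RNG seed.
#' @return An `ir_simulation_spec` list.
#' @export
ir_simulation_spec <- function(a, t1_ms, b = 2, noise_sigma = 0,
                               schedule = build_default_schedule(),
                               n_voxels = 1L, seed = 1L) {
  stopifnot(a > 0, t1_ms > 0, noise_sigma >= 0, n_voxels >= 1)
  if (b < 0 || b > 2.5) stop("'b' must lie in [0, 2.5]", call. = FALSE)
  structure(
    list(a = a, b = b, t1_ms = t1_ms, noise_sigma = noise_sigma,
         schedule = as_ti_schedule(schedule),
         n_voxels = as.integer(n_voxels), seed = as.integer(seed)),
    class = "ir_simulation_spec"
  )
}

#' Simulate magnitude inversion-recovery voxel signals
#'
#' @param spec An [ir_simulation_spec()].
#' @return A list with `signals` (matrix, voxels x TIs), `schedule`, and
#'   `truth` (the generating parameters).
#' @examples
#' sim <- simulate_ir_voxels(ir_simulation_spec(a = 1000, t1_ms = 2000,
#'                                              noise_sigma = 20, seed = 7))
#' dim(sim$signals)
#' @export
simulate_ir_voxels <- function(spec) {
  stopifnot(inherits(spec, "ir_simulation_spec"))
  t <- as.numeric(spec$schedule)
  s_signed <- spec$a * (1 - spec$b * exp(-t / spec$t1_ms))
  n_ti <- length(t)
  signals <- withr::with_seed(spec$seed, {
    if (spec$noise_sigma == 0) {
      matrix(abs(s_signed), nrow = spec$n_voxels, ncol = n_ti, byrow = TRUE)
    } else {
      n1 <- matrix(stats::rnorm(spec$n_voxels * n_ti, 0, spec$noise_sigma),
                   nrow = spec$n_voxels)
      n2 <- matrix(stats::rnorm(spec$n_voxels * n_ti, 0, spec$noise_sigma),
                   nrow = spec$n_voxels)
      real <- matrix(s_signed, nrow = spec$n_voxels, ncol = n_ti,
                     byrow = TRUE) + n1
      sqrt(real^2 + n2^2)
    }
  })
  colnames(signals) <- sprintf("TI%03d", seq_len(n_ti))
  list(signals = signals, schedule = spec$schedule,
       truth = list(a = spec$a, b = spec$b, t1_ms = spec$t1_ms,
                    noise_sigma = spec$noise_sigma))
}

#' Specification for a simulated longitudinal ROI cohort
#'
#' Each measurement follows the random-intercept growth model
#' `value = beta0 + u_i + beta1 * age_days + eps`, with `u_i ~ N(0, tau^2)`
#' per infant and `eps ~ N(0, sigma^2)` per row. Ages are integers drawn
#' uniformly within each timepoint's window; one age per infant-timepoint,
#' shared across hemispheres and areas.
#'
#' @param beta0 Fixed intercept: the metric's value at birth (age 0), in
#'   metric units.
#' @param beta1 Fixed slope, metric units per day.
#' @param tau Between-infant random-intercept SD (>= 0).
#' @param sigma Residual SD (>= 0).
#' @param design A [cohort_design()].
#' @param area Area code for the generated rows.
#' @param metric One of [ROI_METRICS].
#' @param hemispheres Hemispheres to generate rows for.
#' @param seed Integer RNG seed.
#' @return A `cohort_simulation_spec` list.
#' @export
cohort_simulation_spec <- function(beta0, beta1, tau, sigma,
                                   design = default_cohort_design(),
                                   area = "V1", metric = "t1_s",
                                   hemispheres = c("left", "right"),
                                   seed = 1L) {
  stopifnot(inherits(design, "cohort_design"), tau >= 0, sigma >= 0)
  metric <- match.arg(metric, ROI_METRICS)
  hemispheres <- match.arg(hemispheres, HEMISPHERES, several.ok = TRUE)
  structure(
    list(beta0 = beta0, beta1 = beta1, tau = tau, sigma = sigma,
         design = design, area = as.character(area), metric = metric,
         hemispheres = hemispheres, seed = as.integer(seed)),
    class = "cohort_simulation_spec"
  )
}

# Infant-level draws shared by all areas of one simulated dataset: random
# intercepts and one age per participating infant-timepoint.
draw_cohort_effects <- function(design, tau, seed) {
  withr::with_seed(seed, {
    infants <- rownames(design$participation)
    u <- stats::rnorm(length(infants), 0, tau)
    names(u) <- infants
    ages <- list()
    for (inf in infants) {
      for (tp in colnames(design$participation)) {
        if (design$participation[inf, tp]) {
          w <- design$age_windows[[tp]]
          ages[[paste(inf, tp, sep = "|")]] <-
            as.integer(sample(seq(w[1], w[2]), 1))
        }
      }
    }
    list(u = u, ages = ages)
  })
}

cohort_rows <- function(spec, effects, noise_seed) {
  design <- spec$design
  infants <- rownames(design$participation)
  rows <- list()
  for (inf in infants) {
    for (tp in colnames(design$participation)) {
      if (!design$participation[inf, tp]) next
      age <- effects$ages[[paste(inf, tp, sep = "|")]]
      for (hemi in spec$hemispheres) {
        rows[[length(rows) + 1L]] <- data.frame(
          infant_id = inf, age_days = age, timepoint = tp,
          hemisphere = hemi, area = spec$area, metric = spec$metric,
          value = NA_real_, stringsAsFactors = FALSE
        )
      }
    }
  }
  tab <- do.call(rbind, rows)
  eps <- withr::with_seed(noise_seed,
                          stats::rnorm(nrow(tab), 0, spec$sigma))
  tab$value <- spec$beta0 + effects$u[tab$infant_id] +
    spec$beta1 * tab$age_days + eps
  rownames(tab) <- NULL
  tab
}

#' Simulate a longitudinal ROI cohort table
#'
#' @param spec A [cohort_simulation_spec()].
#' @return A list with `table` (a validated ROI table) and `truth`
#'   (generating parameters, per-infant random intercepts `u`, and ages).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_simulation_spec"))
  effects <- draw_cohort_effects(spec$design, spec$tau, spec$seed)
  tab <- cohort_rows(spec, effects, noise_seed = spec$seed + 1L)
  list(
    table = validate_roi_table(tab),
    truth = list(beta0 = spec$beta0, beta1 = spec$beta1, tau = spec$tau,
                 sigma = spec$sigma, u = effects$u, ages = effects$ages)
  )
}

#' Simulate a multi-area cortical hierarchy
#'
#' Generates one combined ROI table for an ordered list of areas (e.g. a
#' visual processing stream with intercepts increasing and slopes changing
#' along the hierarchy). All areas share the same cohort: each infant's
#' random intercept and scan ages are drawn once and reused across areas,
#' as in real data where one infant contributes all areas.
#'
#' @param area_specs List of [cohort_simulation_spec()], one per area, all
#'   with identical designs, hemispheres, `tau` and seed; per-area `beta0`,
#'   `beta1` and `sigma` may differ.
#' @return A list with `table` (combined ROI table) and `truth` (per-area
#'   fixed effects plus the shared random effects).
#' @export
simulate_hierarchy <- function(area_specs) {
  stopifnot(length(area_specs) >= 1L,
            all(vapply(area_specs, inherits, TRUE, "cohort_simulation_spec")))
  base <- area_specs[[1L]]
  for (s in area_specs[-1L]) {
    if (!identical(s$design$participation, base$design$participation) ||
        !identical(s$design$age_windows, base$design$age_windows) ||
        !identical(s$hemispheres, base$hemispheres) ||
        !identical(s$seed, base$seed) || s$tau != base$tau) {
      stop("all area specs must share design, hemispheres, tau and seed",
           call. = FALSE)
    }
  }
  effects <- draw_cohort_effects(base$design, base$tau, base$seed)
  tabs <- lapply(seq_along(area_specs), function(i) {
    cohort_rows(area_specs[[i]], effects, noise_seed = base$seed + i)
  })
  tab <- do.call(rbind, tabs)
  list(
    table = validate_roi_table(tab),
    truth = list(
      areas = data.frame(
        area = vapply(area_specs, `[[`, "", "area"),
        beta0 = vapply(area_specs, `[[`, 0, "beta0"),
        beta1 = vapply(area_specs, `[[`, 0, "beta1"),
        sigma = vapply(area_specs, `[[`, 0, "sigma")
      ),
      tau = base$tau, u = effects$u, ages = effects$ages
    )
  )
}

#' Specification for a simulated expression matrix
#'
#' Gene baselines are drawn on the log2 scale; a planted fraction of genes
#' receives an additive log2 effect in the target (postnatal) group. The
#' matrix is returned on the linear RPKM scale as `2^x`.
#'
#' @param n_genes Number of genes.
#' @param n_target,n_control Samples per group (>= 2 each); defaults mirror
#'   the tissue-donor counts of the screen this emulates (3 postnatal
#'   targets vs 7 prenatal controls).
#' @param baseline_log2_mean,baseline_log2_sd Mean and SD of per-gene
#'   baseline log2 expression.
#' @param de_gene_fraction Fraction of genes planted as differentially
#'   expressed, in `[0, 1]`.
#' @param de_log2_effect Log2 effect (> 0) added to the target group for
#'   planted genes.
#' @param within_sd Within-group log2 SD.
#' @param seed Integer RNG seed.
#' @return An `expression_simulation_spec` list.
#' @export
expression_simulation_spec <- function(n_genes = 1000L, n_target = 3L,
                                       n_control = 7L,
                                       baseline_log2_mean = 2,
                                       baseline_log2_sd = 1,
                                       de_gene_fraction = 0.012,
                                       de_log2_effect = 4,
                                       within_sd = 0.5,
                                       seed = 1L) {
  stopifnot(n_genes >= 1, n_target >= 2, n_control >= 2,
            de_log2_effect >= 0, within_sd >= 0,
            is.finite(baseline_log2_mean), is.finite(baseline_log2_sd))
  if (de_gene_fraction < 0 || de_gene_fraction > 1) {
    stop("'de_gene_fraction' must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes), n_target = as.integer(n_target),
         n_control = as.integer(n_control),
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         de_gene_fraction = de_gene_fraction,
         de_log2_effect = de_log2_effect,
         within_sd = within_sd, seed = as.integer(seed)),
    class = "expression_simulation_spec"
  )
}

#' Simulate an RPKM expression matrix with planted differential expression
#'
#' @param spec An [expression_simulation_spec()].
#' @return A list with `matrix` (linear-scale [expression_matrix()]),
#'   `metadata` (sample data.frame: `sample_id`, `group`, `region`,
#'   `age_label`) and `de_genes` (the planted gene symbols).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_simulation_spec"))
  genes <- sprintf("GENE%05d", seq_len(spec$n_genes))
  samples <- c(sprintf("postnatal_%02d", seq_len(spec$n_target)),
               sprintf("prenatal_%02d", seq_len(spec$n_control)))
  group <- rep(c("target_postnatal", "control_prenatal"),
               c(spec$n_target, spec$n_control))
  n_de <- round(spec$de_gene_fraction * spec$n_genes)
  out <- withr::with_seed(spec$seed, {
    de_idx <- if (n_de > 0) sort(sample.int(spec$n_genes, n_de)) else integer(0)
    baseline <- stats::rnorm(spec$n_genes, spec$baseline_log2_mean,
                             spec$baseline_log2_sd)
    x <- matrix(stats::rnorm(spec$n_genes * length(samples), 0,
                             spec$within_sd),
                nrow = spec$n_genes,
                dimnames = list(genes, samples)) + baseline
    x[de_idx, group == "target_postnatal"] <-
      x[de_idx, group == "target_postnatal"] + spec$de_log2_effect
    list(x = x, de_idx = de_idx)
  })
  metadata <- data.frame(
    sample_id = samples, group = group, region = "V1",
    age_label = ifelse(group == "target_postnatal", "4 mos", "21 pcw"),
    stringsAsFactors = FALSE
  )
  list(matrix = expression_matrix(2^out$x, scale = "linear"),
       metadata = metadata,
       de_genes = genes[out$de_idx])
}

#' Simulate a pair of label masks with exact overlap
#'
#' Constructs two masks in the same grid with `|A| = n_a`, `|B| = n_b` and
#' `|A intersect B| = n_overlap` exactly, for validating overlap statistics.
#'
#' @param n_a,n_b Mask sizes in voxels.
#' @param n_overlap Size of the intersection; at most `min(n_a, n_b)`.
#' @param grid_shape Integer grid dimensions, large enough to hold
#'   `n_a + n_b - n_overlap` voxels.
#' @param seed Integer RNG seed.
#' @return A list of two [label_mask()] objects, `a` and `b`.
#' @export
simulate_mask_pair <- function(n_a, n_b, n_overlap,
                               grid_shape = c(10, 10, 10), seed = 1L) {
  stopifnot(n_a >= 0, n_b >= 0, n_overlap >= 0)
  if (n_overlap > min(n_a, n_b)) {
    stop("'n_overlap' cannot exceed min(n_a, n_b)", call. = FALSE)
  }
  total <- n_a + n_b - n_overlap
  if (total > prod(grid_shape)) {
    stop("masks of the requested size do not fit in the grid", call. = FALSE)
  }
  idx <- withr::with_seed(seed, sample.int(prod(grid_shape), total))
  a_idx <- idx[seq_len(n_a)]
  b_idx <- c(a_idx[seq_len(n_overlap)],
             idx[seq_len(total) > n_a])
  list(a = label_mask(a_idx, "mask_a", grid_shape),
       b = label_mask(b_idx, "mask_b", grid_shape))
}
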