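make_map <- function(vals, metric = "t1_s") {
  quantitative_map(array(vals, dim = c(3, 3, 3)), metric)
}

test_that("ROI distributions summarise finite voxels only", {
  const <- make_map(rep(2, 27))
  mask <- label_mask(1:10, "V1", c(3, 3, 3))
  d <- roi_distribution(const, mask)
  expect_equal(d$mean, 2.0)
  expect_equal(d$sd, 0)
  expect_equal(d$n, 10L)

  vals <- rep(NaN, 27); vals[1:3] <- c(1, 2, 3)
  mixed <- make_map(vals)
  d2 <- roi_distribution(mixed, label_mask(1:5, "V1", c(3, 3, 3)))
  expect_equal(d2$mean, 2.0)
  expect_equal(d2$n, 3L)
  expect_equal(sum(d2$histogram$counts), d2$n)

  allnan <- make_map(rep(NaN, 27))
  expect_error(roi_distribution(allnan, mask), "no finite voxels")
  expect_error(roi_distribution(const, label_mask(1, "V1", c(2, 2, 2))),
               "does not match")
})

test_that("ROI tables assemble one row per cell with the ROI mean", {
  maps <- list(infant01 = list(
    newborn = list(t1_s = make_map(rep(2.0, 27))),
    `3mo`   = list(t1_s = make_map(rep(1.9, 27))),
    `6mo`   = list(t1_s = make_map(rep(1.7, 27)))
  ))
  masks <- list(V1 = list(left = label_mask(1:5, "V1", c(3, 3, 3))))
  ages <- data.frame(infant_id = "infant01",
                     timepoint = c("newborn", "3mo", "6mo"),
                     age_days = c(20L, 90L, 180L))
  tab <- build_roi_table(maps, masks, ages)
  expect_equal(nrow(tab), 3L)
  expect_equal(sort(tab$value), c(1.7, 1.9, 2.0))
  expect_equal(tab$value[tab$timepoint == "newborn"],
               roi_distribution(maps$infant01$newborn$t1_s, masks$V1$left)$mean)
  expect_error(build_roi_table(maps, masks,
                               ages[ages$timepoint != "3mo", ]),
               "exactly one age")
})

test_that("deterministic tables give an exact line with zero variance", {
  sim <- simulate_cohort(cohort_simulation_spec(2.0, -0.0015, 0, 0, seed = 2))
  fit <- fit_lmm(sim$table, lmm_spec("t1_s"))
  expect_equal(fixed_effect(fit, "(Intercept)")$estimate, 2.0,
               tolerance = 1e-10)
  expect_equal(fixed_effect(fit, "age_days")$estimate, -0.0015,
               tolerance = 1e-10)
  expect_true(all(fit$varcomp$variance == 0))
  expect_equal(fit$r_squared, 1)
})

test_that("with a zero between-infant component the fit equals OLS", {
  tab <- make_centred_cohort(seed = 4)
  fit <- fit_lmm(tab, lmm_spec("t1_s"))
  beta <- oracle_ols(cbind(1, tab$age_days), tab$value)
  expect_equal(fit$coefficients$estimate, unname(beta), tolerance = 1e-8)
  # the random-intercept variance sits at its boundary
  expect_equal(fit$varcomp$variance[fit$varcomp$grp == "infant_id"], 0,
               tolerance = 1e-12)
})

test_that("fits are invariant to row order and infant relabeling", {
  sim <- simulate_cohort(cohort_simulation_spec(2.0, -0.0015, 0.05, 0.03,
                                                seed = 12))
  tab <- sim$table
  ref <- fit_lmm(tab, lmm_spec("t1_s"))

  shuffled <- tab[withr::with_seed(1, sample(nrow(tab))), ]
  fit_sh <- fit_lmm(shuffled, lmm_spec("t1_s"))
  expect_equal(fit_sh$coefficients$estimate, ref$coefficients$estimate,
               tolerance = 1e-8)

  relabeled <- tab
  lev <- sort(unique(tab$infant_id))
  new_names <- stats::setNames(paste0("zz_", rev(seq_along(lev))), lev)
  relabeled$infant_id <- unname(new_names[tab$infant_id])
  fit_rl <- fit_lmm(relabeled, lmm_spec("t1_s"))
  expect_equal(fit_rl$coefficients$estimate, ref$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("unidentifiable designs are refused", {
  sim <- simulate_cohort(cohort_simulation_spec(2.0, -0.0015, 0.05, 0.03,
                                                seed = 13))
  one_infant <- sim$table[sim$table$infant_id == "infant01", ]
  expect_error(fit_lmm(one_infant, lmm_spec("t1_s")), "fewer than 2 levels")
  one_age <- sim$table[sim$table$timepoint == "newborn", ]
  one_age$age_days <- 20L
  expect_error(fit_lmm(one_age, lmm_spec("t1_s")), "distinct ages")
})

test_that("likelihood comparisons behave at the identity and reject misuse", {
  sim <- simulate_cohort(cohort_simulation_spec(2.0, -0.0015, 0.05, 0.03,
                                                seed = 14))
  ml0 <- fit_lmm(sim$table, lmm_spec("t1_s", criterion = "ml"))
  ml1 <- fit_lmm(sim$table,
                 lmm_spec("t1_s",
                          random = list(infant_id = c("intercept", "age_days")),
                          criterion = "ml"))
  same <- compare_lmm(ml0, ml0)
  expect_equal(same$lr, 0)
  expect_equal(same$p, 1)

  cmp <- compare_lmm(ml0, ml1)
  expect_gte(ml1$loglik, ml0$loglik - 1e-8)
  expect_equal(cmp$df, 2L)
  expect_gte(cmp$lr, 0)

  reml <- fit_lmm(sim$table, lmm_spec("t1_s"))
  expect_error(compare_lmm(reml, ml1), "REML")
  other <- simulate_cohort(cohort_simulation_spec(2.0, -0.0015, 0.05, 0.03,
                                                  seed = 15))
  expect_error(compare_lmm(fit_lmm(other$table,
                                   lmm_spec("t1_s", criterion = "ml")), ml1),
               "identical rows")
  expect_error(compare_lmm(ml1, ml0), "not nested")
})

test_that("a strong random slope is detected with high power", {
  rejections <- vapply(1:60, function(i) {
    sim <- simulate_cohort(cohort_simulation_spec(2.0, -0.0015, 0.05, 0.03,
                                                  seed = 7000 + i))
    tab <- sim$table
    slopes <- withr::with_seed(300 + i, stats::rnorm(13, 0, 5e-4))
    names(slopes) <- rownames(default_cohort_design()$participation)
    tab$value <- tab$value + slopes[tab$infant_id] * tab$age_days
    f0 <- fit_lmm(tab, lmm_spec("t1_s", criterion = "ml"))
    f1 <- fit_lmm(tab, lmm_spec("t1_s",
                                random = list(infant_id = c("intercept",
                                                            "age_days")),
                                criterion = "ml"))
    compare_lmm(f0, f1)$p < 0.05
  }, TRUE)
  expect_gt(mean(rejections), 0.8)
})

test_that("Bonferroni thresholds use pairwise comparison counts", {
  expect_equal(bonferroni_pairwise_count(4), 6L)
  expect_equal(bonferroni_pairwise_count(9), 36L)
  expect_equal(bonferroni_pairwise_count(8), 28L)

  h <- simulate_hierarchy(lapply(1:4, function(i) {
    cohort_simulation_spec(2.0 + 0.02 * i, -0.0015, 0.05, 0.03,
                           area = SENSORIMOTOR_AREAS[i], seed = 3)
  }))
  pa <- fit_per_area(h$table, SENSORIMOTOR_AREAS, "t1_s")
  expect_equal(pa$n_comparisons, 6L)
  expect_equal(pa$threshold, 0.05 / 6)
  expect_equal(nrow(pa$summary), 4L)
  expect_error(fit_per_area(h$table, c(SENSORIMOTOR_AREAS, "V1d"), "t1_s"),
               "absent")
})

test_that("per-area intercepts track a planted hierarchy gradient", {
  beta0s <- 2.0 + 0.03 * (0:8)
  h <- simulate_hierarchy(lapply(1:9, function(i) {
    cohort_simulation_spec(beta0s[i], -0.0015, 0.05, 0.01,
                           area = DORSAL_STREAM_AREAS[i], seed = 41)
  }))
  pa <- fit_per_area(h$table, DORSAL_STREAM_AREAS, "t1_s")
  # intercepts recovered close to truth; monotone alignment with the
  # planted gradient
  expect_lt(max(abs(pa$summary$intercept - beta0s)), 0.05)
  expect_gt(stats::cor(pa$summary$intercept, beta0s), 0.99)
})

test_that("a single-area stream model reduces to the per-area fit", {
  sim <- simulate_cohort(cohort_simulation_spec(2.0, -0.0015, 0.05, 0.03,
                                                area = "V1d", seed = 16))
  stream <- fit_stream_lmm(sim$table, "t1_s")
  plain <- fit_lmm(sim$table, lmm_spec("t1_s"))
  expect_equal(stream$coefficients$estimate, plain$coefficients$estimate,
               tolerance = 1e-10)
})

test_that("a null hemisphere factor stays non-significant", {
  small <- vapply(1:300, function(i) {
    h <- simulate_hierarchy(lapply(1:3, function(k) {
      cohort_simulation_spec(2.0 + 0.05 * k, -0.0015 - 1e-4 * k, 0.05, 0.03,
                             area = DORSAL_STREAM_AREAS[k], seed = 500 + i)
    }))
    fit <- fit_stream_lmm(h$table, "t1_s")
    abs(fixed_effect(fit, "hemisphereright")$t) < 2
  }, TRUE)
  expect_gte(mean(small), 0.9)
})

test_that("age and area drive cross-stream fits when streams are matched", {
  ok <- vapply(1:20, function(i) {
    specs <- lapply(1:6, function(k) {
      area <- c(DORSAL_STREAM_AREAS[1:3], VENTRAL_STREAM_AREAS[1:3])[k]
      pos <- ((k - 1) %% 3)
      cohort_simulation_spec(2.0 + 0.08 * pos, -0.0015, 0.05, 0.03,
                             area = area, seed = 900 + i)
    })
    h <- simulate_hierarchy(specs)
    fit <- fit_stream_lmm(h$table, "t1_s", factors = c("area", "stream"))
    age_sig <- fixed_effect(fit, "age_days")$p < 0.05
    area_sig <- fixed_effect(fit, "area")$p < 0.05
    stream_ns <- fixed_effect(fit, "streamventral")$p > 0.05
    age_sig && area_sig && stream_ns
  }, TRUE)
  expect_gt(mean(ok), 0.5)
})
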