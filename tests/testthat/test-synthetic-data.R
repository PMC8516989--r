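test_that("noise-free IR signals follow the signed model exactly", {
  # null point: 1 - b*exp(-t/T1) = 0 at t = T1 * ln(b) for b = 2
  sch <- ti_schedule(c(50, 1000 * log(2), 2900))
  sim <- simulate_ir_voxels(ir_simulation_spec(a = 1000, t1_ms = 1000, b = 2,
                                               noise_sigma = 0,
                                               schedule = sch, seed = 1))
  expect_equal(as.numeric(sim$signals[1, 2]), 0, tolerance = 1e-9)

  sim0 <- simulate_ir_voxels(ir_simulation_spec(a = 750, t1_ms = 1500, b = 0,
                                                noise_sigma = 0, seed = 1))
  expect_true(all(sim0$signals == 750))

  # sigma = 0 reduces exactly to |S(t)|
  spec <- ir_simulation_spec(a = 1000, t1_ms = 2000, noise_sigma = 0,
                             n_voxels = 3, seed = 1)
  sim2 <- simulate_ir_voxels(spec)
  expected <- predict_ir_signal(1000, 2, 2000, spec$schedule)
  expect_identical(sim2$signals[2, ], expected,
                   ignore_attr = TRUE)
})

test_that("Rician voxel means match a Monte-Carlo oracle", {
  spec <- ir_simulation_spec(a = 1000, t1_ms = 2000, noise_sigma = 20,
                             n_voxels = 1000, seed = 11)
  sim <- simulate_ir_voxels(spec)
  t <- as.numeric(spec$schedule)
  s_signed <- 1000 * (1 - 2 * exp(-t / 2000))
  se <- 20 / sqrt(1000)  # per-TI standard error of the sample mean
  for (i in seq_along(t)) {
    mc <- oracle_rician_mean(s_signed[i], 20, seed = 424242 + i)
    expect_lt(abs(mean(sim$signals[, i]) - mc), 3 * se)
  }
})

test_that("simulators are bitwise reproducible under a fixed seed", {
  s <- ir_simulation_spec(a = 1000, t1_ms = 2000, noise_sigma = 30,
                          n_voxels = 5, seed = 99)
  expect_identical(simulate_ir_voxels(s)$signals, simulate_ir_voxels(s)$signals)
  cs <- cohort_simulation_spec(2, -0.001, 0.05, 0.03, seed = 99)
  expect_identical(simulate_cohort(cs)$table, simulate_cohort(cs)$table)
  es <- expression_simulation_spec(n_genes = 50, seed = 99)
  expect_identical(simulate_expression(es)$matrix,
                   simulate_expression(es)$matrix)
})

test_that("noise-free cohorts are an exact line; rows follow the design", {
  sim <- simulate_cohort(cohort_simulation_spec(2.0, -0.0015, tau = 0,
                                                sigma = 0, seed = 3))
  expect_equal(sim$table$value, 2.0 - 0.0015 * sim$table$age_days)

  # 10 participating infants per timepoint -> 10 rows per
  # (timepoint, area, hemisphere, metric) cell
  counts <- table(sim$table$timepoint, sim$table$hemisphere)
  expect_true(all(counts == 10L))
  windows <- AGE_WINDOWS
  for (tp in names(windows)) {
    ages <- sim$table$age_days[sim$table$timepoint == tp]
    expect_true(all(ages >= windows[[tp]][1] & ages <= windows[[tp]][2]))
  }
})

test_that("cohort marginal variance matches tau^2 + sigma^2", {
  tau <- 0.05; sigma <- 0.03
  resid <- unlist(lapply(1:200, function(i) {
    sim <- simulate_cohort(cohort_simulation_spec(2.0, -0.0015, tau, sigma,
                                                  hemispheres = "left",
                                                  seed = 2000 + i))
    sim$table$value - (2.0 - 0.0015 * sim$table$age_days)
  }))
  expect_equal(stats::var(resid), tau^2 + sigma^2, tolerance = 0.1)
})

test_that("hierarchies reuse one cohort across areas", {
  base <- cohort_simulation_spec(2.0, -0.0015, 0.05, 0.03, area = "V1d",
                                 seed = 7)
  single <- simulate_hierarchy(list(base))
  expect_identical(single$table, simulate_cohort(base)$table)

  two <- simulate_hierarchy(list(
    base,
    cohort_simulation_spec(2.2, -0.0020, 0.05, 0.03, area = "V2d", seed = 7)
  ))
  expect_identical(two$truth$u, simulate_cohort(base)$truth$u)
  # same infant, same timepoint -> same age in every area
  ages <- tapply(two$table$age_days,
                 paste(two$table$infant_id, two$table$timepoint),
                 function(x) length(unique(x)))
  expect_true(all(ages == 1L))

  other_seed <- cohort_simulation_spec(2.2, -0.002, 0.05, 0.03,
                                       area = "V2d", seed = 8)
  expect_error(simulate_hierarchy(list(base, other_seed)), "must share")
})

test_that("planted expression effects are recovered and nulls stay null", {
  spec <- expression_simulation_spec(n_genes = 300, de_gene_fraction = 0.04,
                                     de_log2_effect = 3, within_sd = 0.01,
                                     seed = 21)
  sim <- simulate_expression(spec)
  lfc <- fold_change(to_log2(sim$matrix, 0), sim$metadata)
  expect_true(all(abs(lfc[sim$de_genes] - 3) < 0.05))

  null_spec <- expression_simulation_spec(n_genes = 500,
                                          de_gene_fraction = 0, seed = 22)
  null_sim <- simulate_expression(null_spec)
  res <- diff_expression(null_sim$matrix, null_sim$metadata)
  expect_equal(nrow(select_genes(res)), 0L)

  expect_error(expression_simulation_spec(de_gene_fraction = 1.5), "\\[0, 1\\]")
})

test_that("mask pairs have the exact requested set sizes", {
  m <- simulate_mask_pair(3, 5, 2, seed = 1)
  expect_equal(length(m$a$indices), 3L)
  expect_equal(length(m$b$indices), 5L)
  expect_equal(length(intersect(m$a$indices, m$b$indices)), 2L)

  ident <- simulate_mask_pair(4, 4, 4, seed = 2)
  expect_identical(ident$a$indices, ident$b$indices)
  disj <- simulate_mask_pair(4, 4, 0, seed = 3)
  expect_length(intersect(disj$a$indices, disj$b$indices), 0)

  expect_error(simulate_mask_pair(3, 3, 4, seed = 1), "n_overlap")
  expect_error(simulate_mask_pair(900, 900, 0, grid_shape = c(10, 10, 10)),
               "do not fit")
})
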