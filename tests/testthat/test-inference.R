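test_that("the estimator pipeline reproduces constructed ratios", {
  tabs <- gen_measurements(noise_cv = 0, seed = 1)

  # identical input at both ages -> zero divisions
  same <- tabs$measurements
  same$age_days <- ifelse(same$age_days == 50, 2, same$age_days)
  both <- dplyr::bind_rows(same, dplyr::mutate(same, age_days = 50))
  dens_same <- dplyr::bind_rows(
    dplyr::mutate(tabs$densities[tabs$densities$age_days == 2, ], age_days = 2),
    dplyr::mutate(tabs$densities[tabs$densities$age_days == 2, ], age_days = 50)
  )
  expect_equal(estimate_division_number(both, dens_same, 2, 50)$n_divisions, 0)

  # calibrated construction at zero noise
  est <- estimate_division_number(tabs$measurements, tabs$densities, 2, 50)
  expect_equal(est$n_divisions, 1.3128, tolerance = 1e-3)
  expect_equal(est$details$dv_t0, 0.18, tolerance = 1e-9)
  expect_equal(est$details$dv_t1, 2.32, tolerance = 1e-9)
  expect_equal(est$cell_ratio, est$volume_ratio * est$density_ratio)

  # missing groups are reported by age
  expect_error(
    estimate_division_number(tabs$measurements[tabs$measurements$age_days == 2, ],
                             tabs$densities, 2, 50),
    "age 50")
  expect_error(
    estimate_division_number(tabs$measurements, tabs$densities, 2, 50,
                             layer = "dermal_papilla"),
    "dermal_papilla")
})

test_that("bootstrap interval is ordered, seeded, and covers the truth", {
  tabs <- gen_measurements(noise_cv = 0.05, seed = 3)
  est <- estimate_division_number(tabs$measurements, tabs$densities, 2, 50,
                                  n_boot = 200, seed = 10)
  expect_lte(est$ci_low, est$ci_high)
  est2 <- estimate_division_number(tabs$measurements, tabs$densities, 2, 50,
                                   n_boot = 200, seed = 10)
  expect_identical(est$ci_low, est2$ci_low)

  # coverage at nominal 95% with n = 3 animals per group; small-n percentile
  # bootstrap under-covers, so the requirement is >= 80%
  hits <- vapply(1:60, function(s) {
    tb <- gen_measurements(noise_cv = 0.05, seed = 1000 + s)
    e <- estimate_division_number(tb$measurements, tb$densities, 2, 50,
                                  n_boot = 120, seed = s)
    e$ci_low <= 1.3128 && 1.3128 <= e$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("closed-loop estimation from simulated tissue recovers the division budget", {
  tabs <- gen_measurements(noise_cv = 0, seed = 0)
  ns <- vapply(1:12, function(s) {
    cfg <- preset_postnatal_expansion(seed = s, domain_um = c(800, 800))
    snaps <- run_expansion(cfg, c(2, 50))
    d <- lapply(snaps, snapshot_density)
    dens <- dplyr::bind_rows(
      dplyr::mutate(d$age_2, age_days = 2, n_regions = 1L),
      dplyr::mutate(d$age_50, age_days = 50, n_regions = 1L)
    )
    estimate_division_number(tabs$measurements, dens, 2, 50)$n_divisions
  }, numeric(1))
  expect_lt(abs(mean(ns) - 1.3), 0.1)
})

test_that("grid-search rate fitting recovers a known rate and degenerates sanely", {
  cfg <- preset_embryonic_labelling(seed = 0, domain_um = c(400, 400))

  # observed summary generated at rate 2.5 on a wider field (many clones)
  cfg_true <- preset_embryonic_labelling(seed = 99, domain_um = c(900, 900))
  snap <- run_expansion(cfg_true, 2)[[1]]
  ct <- call_clones(snap$cells)
  observed <- clone_sizes_by_compartment(ct, snap$cells,
                                         compartments = cfg$layers_um$layer)$summary

  fit <- fit_division_rate(observed, cfg, rate_grid = c(1, 1.75, 2.5, 3),
                           reps = 8, n_boot = 100, seed = 5)
  expect_equal(fit$rate, 2.5)
  expect_true(fit$rate %in% fit$grid$rate)
  expect_lte(fit$ci_low, fit$ci_high)

  # one-point grid returns that point
  flat <- fit_division_rate(observed, cfg, rate_grid = 2, reps = 2,
                            n_boot = 0, seed = 1)
  expect_equal(flat$rate, 2)

  # stability: a different seed at the same settings lands on the same argmin
  fit2 <- fit_division_rate(observed, cfg, rate_grid = c(1, 1.75, 2.5, 3),
                            reps = 8, n_boot = 0, seed = 6)
  expect_equal(fit2$rate, fit$rate)

  expect_error(fit_division_rate(observed[0, ], cfg, 1:2), "non-empty")
  expect_error(fit_division_rate(observed, cfg, numeric(0)), "non-empty")
})
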