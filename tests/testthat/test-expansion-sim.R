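test_that("tissue seeding follows the configured spatial Poisson process", {
  empty <- small_config()
  empty$density_per_mm2[] <- 0
  expect_equal(nrow(init_tissue(empty, seed = 1)$cells), 0)

  cfg <- sim_config(domain_um = c(1000, 1000), start_age_days = 0,
                    end_age_days = 1,
                    layers_um = tibble::tibble(layer = "papillary",
                                               z0_um = 0, z1_um = 50),
                    density_per_mm2 = c(papillary = 1000))
  counts <- vapply(1:100, function(s) nrow(init_tissue(cfg, seed = s)$cells),
                   numeric(1))
  # mean of 100 Poisson(1000) draws: 3 sigma of the mean is 3*sqrt(1000/100)
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000 / 100))

  expect_identical(init_tissue(cfg, seed = 7), init_tissue(cfg, seed = 7))
})

test_that("pure advection conserves cells and scales distances exactly", {
  cfg <- small_config(
    expansion = tibble::tibble(age_days = c(0, 10), sx = c(1, 2),
                               sy = c(1, 2), sz = c(1, 2))
  )
  snap0 <- induce_labels(init_tissue(cfg, seed = 5), seed = 21)
  snap1 <- advance(snap0, 10, seed = 22)

  expect_identical(nrow(snap1$cells), nrow(snap0$cells))
  expect_identical(sort(snap1$cells$clone_id), sort(snap0$cells$clone_id))
  expect_identical(snap1$cells$labelled, snap0$cells$labelled)

  d0 <- dist(cbind(snap0$cells$x_um, snap0$cells$y_um))
  d1 <- dist(cbind(snap1$cells$x_um, snap1$cells$y_um))
  expect_equal(as.numeric(d1), as.numeric(2 * d0), tolerance = 1e-12)
  expect_equal(snap1$domain_um, snap0$domain_um * 2)
})

test_that("mean growth matches the exponential doubling law", {
  cfg <- small_config(division_rate = 1)
  ratios <- vapply(1:200, function(s) {
    cfg$seed <- s
    snaps <- suppressWarnings(run_expansion(cfg, c(0, 10)))
    nrow(snaps$age_10$cells) / nrow(snaps$age_0$cells)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2) / 2, 0.05)
})

test_that("death hazard gives exponential survival of founders", {
  cfg <- small_config(death_rate = 1)
  surv <- vapply(1:120, function(s) {
    cfg$seed <- s
    snaps <- suppressWarnings(run_expansion(cfg, c(0, 10)))
    nrow(snaps$age_10$cells) / nrow(snaps$age_0$cells)
  }, numeric(1))
  # ~110 founders x 120 seeds of Bernoulli(e^-1) survival
  n_tot <- 110 * 120
  p <- exp(-1)
  expect_lt(abs(mean(surv) - p), 3 * sqrt(p * (1 - p) / n_tot) + 0.005)
})

test_that("sparse labelling hits the configured expectation per region", {
  cfg <- sim_config(domain_um = c(2000, 2000), start_age_days = 0,
                    end_age_days = 1,
                    layers_um = tibble::tibble(layer = "papillary",
                                               z0_um = 0, z1_um = 50),
                    density_per_mm2 = c(papillary = 2000),
                    labels_per_region = 1.5, region_pitch_um = 200)
  snap <- init_tissue(cfg, seed = 2)
  lab <- induce_labels(snap, seed = 3)

  expect_equal(sum(induce_labels(snap, labels_per_region = 0,
                                 seed = 3)$cells$labelled), 0)
  # 100 regions x Poisson(1.5): 3 sigma of the total
  n_lab <- sum(lab$cells$labelled)
  expect_lt(abs(n_lab - 150), 3 * sqrt(150))
  founders <- lab$cells[lab$cells$labelled, ]
  expect_identical(founders$clone_id, founders$cell_id)
  expect_error(advance(lab, -5), "precede")
})

test_that("embryonic preset yields mostly 4-8 cell clones spanning the layers", {
  sizes <- unlist(lapply(1:6, function(s) {
    snap <- run_expansion(preset_embryonic_labelling(seed = s), 2)[[1]]
    lab <- snap$cells[snap$cells$labelled, ]
    as.vector(table(lab$clone_id))
  }))
  expect_gt(length(sizes), 30)
  expect_gte(mean(sizes >= 4 & sizes <= 8), 0.6)

  snap <- run_expansion(preset_embryonic_labelling(seed = 1), 2)[[1]]
  lab <- snap$cells[snap$cells$labelled, ]
  expect_gt(length(unique(lab$layer)), 1)  # clones span compartments
})

test_that("runs are reproducible and respect requested output ages", {
  cfg <- preset_embryonic_labelling(seed = 9, domain_um = c(300, 300))
  a <- run_expansion(cfg, c(-7, 0, 2))
  b <- run_expansion(cfg, c(-7, 0, 2))
  expect_identical(a$age_2$cells, b$age_2$cells)
  expect_named(a, c("age_-7", "age_0", "age_2"))

  only_start <- run_expansion(cfg, cfg$start_age_days)
  expect_length(only_start, 1)
  expect_equal(only_start[[1]]$age_days, -7)
  expect_gt(sum(only_start[[1]]$cells$labelled), 0)

  expect_error(run_expansion(cfg, c(2, 0)), "sorted")
  expect_error(run_expansion(cfg, 99), "interval")
})

test_that("postnatal preset keeps labelled-cell growth within the doubling budget", {
  counts <- vapply(1:20, function(s) {
    cfg <- preset_postnatal_expansion(seed = s, domain_um = c(500, 500))
    snaps <- run_expansion(cfg, c(2, 50))
    c(sum(snaps$age_2$cells$labelled), sum(snaps$age_50$cells$labelled))
  }, numeric(2))
  ratio <- mean(counts[2, ]) / mean(counts[1, ])
  # expected fold change is 2^1.3; allow sampling noise above it
  expect_lt(ratio, 2^1.3 * 1.15)
  expect_gt(ratio, 1)  # some growth, but nowhere near the 13-fold volume
})
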