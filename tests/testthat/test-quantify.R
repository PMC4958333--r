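test_that("clone calling implements the distance-cutoff rule", {
  one <- cells_from_xy(matrix(c(10, 10), 1))
  ct <- call_clones(one)
  expect_equal(nrow(ct$assignments), 1)
  expect_equal(ct$assignments$clone_call, 1L)

  two_near <- cells_from_xy(rbind(c(0, 0), c(100, 0)))
  two_far <- cells_from_xy(rbind(c(0, 0), c(300, 0)))
  expect_length(unique(call_clones(two_near)$assignments$clone_call), 1)
  expect_length(unique(call_clones(two_far)$assignments$clone_call), 2)
  # radius reading doubles the effective cutoff
  radius <- clone_calling_params(cutoff_mode = "radius")
  expect_length(unique(call_clones(two_far, radius)$assignments$clone_call), 1)

  expect_equal(nrow(call_clones(one[0, ])$assignments), 0)
  bad <- one; bad$x_um <- NaN
  expect_error(call_clones(bad), "non-finite")

  # xyz projection separates cells stacked in z
  stacked <- cells_from_xy(rbind(c(0, 0), c(0, 0)))
  stacked$z_um <- c(0, 400)
  expect_length(unique(call_clones(stacked)$assignments$clone_call), 1)
  xyz <- clone_calling_params(projection = "xyz")
  expect_length(unique(call_clones(stacked, xyz)$assignments$clone_call), 2)
})

test_that("clone calling matches the exhaustive-partition oracle and ignores input order", {
  withr::with_seed(31, {
    for (i in 1:120) {
      n <- sample(2:8, 1)
      xy <- matrix(runif(n * 2, 0, 700), ncol = 2)
      dm <- as.matrix(dist(xy))
      got <- call_clones(cells_from_xy(xy))$assignments$clone_call
      expect_identical(canon_part(got), canon_part(oracle_partition(dm, 260)))

      perm <- sample(n)
      shuffled <- cells_from_xy(xy[perm, , drop = FALSE], ids = perm)
      got2 <- call_clones(shuffled)$assignments  # returned sorted by cell_id
      expect_identical(canon_part(got2$clone_call), canon_part(got))
    }
  })
})

test_that("clone sizes per compartment match direct tabulation", {
  cells <- tibble::tibble(
    cell_id = 1:4, x_um = c(0, 10, 20, 30), y_um = 0, z_um = 0,
    labelled = TRUE, layer = "papillary"
  )
  ct <- call_clones(cells)
  sz <- clone_sizes_by_compartment(ct, cells,
                                   compartments = c("papillary", "reticular"))
  s <- sz$summary
  expect_equal(s$mean_cells[s$compartment == "papillary"], 4)
  expect_equal(s$mean_cells[s$compartment == "reticular"], 0)
  expect_equal(s$mean_cells[s$compartment == "total"], 4)

  # two clones of 2 and 6 cells
  cells2 <- tibble::tibble(
    cell_id = 1:8,
    x_um = c(0, 10, 5000, 5010, 5020, 5030, 5040, 5050), y_um = 0, z_um = 0,
    labelled = TRUE, layer = rep(c("papillary", "reticular"), c(2, 6))
  )
  sz2 <- clone_sizes_by_compartment(call_clones(cells2), cells2)
  tot <- sz2$per_clone[sz2$per_clone$compartment == "total", ]
  expect_setequal(tot$n_cells, c(2, 6))
  s2 <- sz2$summary[sz2$summary$compartment == "total", ]
  expect_equal(s2$mean_cells, 4)
  expect_equal(s2$sd_cells, sd(c(2, 6)))

  expect_error(clone_sizes_by_compartment(call_clones(cells2), cells2,
                                          compartments = "papillary"),
               "unknown layer")

  # simulated tissue: summary equals an independent groupby
  snap <- run_expansion(preset_embryonic_labelling(seed = 2), 2)[[1]]
  lab <- snap$cells[snap$cells$labelled, ]
  ct3 <- call_clones(lab)
  sz3 <- clone_sizes_by_compartment(ct3, lab)
  merged <- merge(as.data.frame(ct3$assignments), as.data.frame(lab))
  oracle_tot <- tapply(merged$cell_id, merged$clone_call, length)
  s3 <- sz3$summary[sz3$summary$compartment == "total", ]
  expect_equal(s3$mean_cells, mean(oracle_tot))
  expect_equal(s3$n_clones, length(oracle_tot))
})

test_that("region-based density estimation recovers Poisson intensity", {
  regions <- tibble::tibble(region_id = 1, x0_um = 0, x1_um = 500,
                            y0_um = 0, y1_um = 50)
  none <- tibble::tibble(x_um = numeric(0), y_um = numeric(0),
                         layer = character(0))
  expect_equal(density_per_layer(none, regions)$rho_per_mm2, 0)

  # 50 cells in 0.025 mm^2 -> 2000 per mm^2
  fifty <- tibble::tibble(x_um = runif(50, 0, 500), y_um = runif(50, 0, 50),
                          layer = "papillary")
  d <- density_per_layer(fifty, regions)
  expect_equal(d$rho_per_mm2[d$layer == "total"], 2000)

  expect_error(density_per_layer(fifty, regions[0, ]), "no regions")
  bad <- regions; bad$x1_um <- 0
  expect_error(density_per_layer(fifty, bad), "positive")

  # Poisson tissue at known intensity: estimate within 3 sigma; the total
  # equals the sum over layers (conservation)
  cells <- gen_wholemount(domain_um = c(3000, 3000),
                          clones = list(n_clones = 0, size = 0, spread_um = 0),
                          seed = 41)
  grid <- tidyr::expand_grid(i = 0:4, j = 0:4)
  regions <- tibble::tibble(
    region_id = seq_len(nrow(grid)),
    x0_um = grid$i * 600, x1_um = (grid$i + 1) * 600,
    y0_um = grid$j * 600, y1_um = (grid$j + 1) * 600
  )
  d <- density_per_layer(cells, regions)
  lambda <- sum(attr(cells, "truth")$density_per_mm2)   # 1200 per mm^2
  area_tot <- 9  # mm^2 scored
  expect_lt(abs(d$rho_per_mm2[d$layer == "total"] - lambda),
            3 * sqrt(lambda / area_tot))
  expect_equal(d$rho_per_mm2[d$layer == "total"],
               sum(d$rho_per_mm2[d$layer != "total"]))
  expect_true(all(d$rho_per_mm2 >= 0))
})

test_that("marker fractions behave as binomial percentages", {
  cells <- tibble::tibble(ki67 = rep(FALSE, 10))
  expect_equal(fraction_positive(cells, "ki67"), 0)
  cells17 <- tibble::tibble(ki67 = rep(c(TRUE, FALSE), c(17, 83)))
  expect_equal(fraction_positive(cells17, "ki67"), 17)
  expect_warning(p <- fraction_positive(cells[0, , drop = FALSE], "ki67"),
                 "undefined")
  expect_true(is.na(p))
  expect_error(fraction_positive(cells, "nope"), "not found")
  expect_error(fraction_positive(tibble::tibble(ki67 = c(TRUE, NA)), "ki67"),
               "defined")

  cells_p <- gen_wholemount(marker_probs = c(ki67 = 0.2), seed = 42)
  n <- nrow(cells_p)
  est <- fraction_positive(cells_p, "ki67")
  expect_lt(abs(est - 20), 3 * 100 * sqrt(0.2 * 0.8 / n))
  expect_gte(est, 0); expect_lte(est, 100)
})

test_that("background normalisation supports ratio and subtraction modes", {
  expect_equal(normalized_mean_intensity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(normalized_mean_intensity(300, 100), 3)
  expect_equal(normalized_mean_intensity(300, 100, method = "subtract"), 200)
  expect_equal(normalized_mean_intensity(7 * c(10, 20), 7 * c(5, 5)),
               normalized_mean_intensity(c(10, 20), c(5, 5)))
  expect_error(normalized_mean_intensity(1, numeric(0)), "empty")
  expect_error(normalized_mean_intensity(1, c(-2, 0)), "positive")
})

test_that("wound-section summaries match their sampling model", {
  rec <- gen_wound_sections(n_wounds = 1, sections_per_wound = 8,
                            mean_hfs = 0, seed = 1)
  expect_equal(mean_hfs_per_section(rec)$group_mean, 0)

  flat <- tibble::tibble(wound_id = 1, section_id = 1:8, n_new_hfs = 5)
  res <- mean_hfs_per_section(flat)
  expect_equal(res$per_wound$mean_hfs, 5)
  expect_equal(res$per_wound$sd_hfs, 0)

  expect_warning(mean_hfs_per_section(flat[1:3, ]), "fewer than 8")

  big <- gen_wound_sections(n_wounds = 12, sections_per_wound = 8,
                            mean_hfs = 5, seed = 2)
  gm <- mean_hfs_per_section(big)$group_mean
  expect_lt(abs(gm - 5), 3 * sqrt(5 / (12 * 8)))
})

test_that("apparent clone size shrinks as pure expansion separates cells", {
  mean_called_size <- function(scale_end, seed) {
    cfg <- sim_config(
      domain_um = c(600, 600), start_age_days = 0, end_age_days = 5,
      density_per_mm2 = c(papillary = 600, reticular = 400, DWAT = 300),
      division_rate = 0, death_rate = 0,
      expansion = tibble::tibble(age_days = c(0, 5), sx = c(1, scale_end),
                                 sy = c(1, scale_end), sz = c(1, scale_end)),
      labels_per_region = 2, region_pitch_um = 150, seed = seed
    )
    snap <- run_expansion(cfg, 5)[[1]]
    ct <- call_clones(snap$cells)
    nrow(ct$assignments) / length(unique(ct$assignments$clone_call))
  }
  m <- vapply(c(1, 2, 4), function(sc) {
    mean(vapply(1:40, function(s) mean_called_size(sc, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(m) <= 0))
  expect_gt(m[1], m[3])  # strict separation between extremes
})
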