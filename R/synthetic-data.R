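# Synthetic-data generators. These replace the study's imaging-derived
# inputs with tables that have the statistical structure the analysis
# assumes, and always emit the generating truth alongside so downstream
# recovery tests are closed-loop. Every generator is a pure function of
# (parameters, seed).

# Base morphometry for the calibrated preset. Trunk dimensions are
# realistic for neonatal (P2) and young-adult (P50) mice; the dermis depth
# of each group is back-solved so the per-group mean shell volumes equal
# 0.18 cm^3 (P2) and 2.32 cm^3 (P50, sex average), and the density tables
# are scaled so the P50/P2 density ratio equals 2^1.3128 * 0.18/2.32.
# Absolute density magnitudes are order-of-magnitude placeholders; only the
# ratio is pinned.
calibrated_base <- function() {
  m <- tibble::tibble(
    age_days = c(2, 2, 50, 50),
    sex = c("male", "female", "male", "female"),
    length_cm = c(2.5, 2.5, 5.5, 5.0),
    width_cm = c(1.2, 1.2, 2.8, 2.6),
    dv_cm3 = c(0.18, 0.18, 2.42, 2.22)
  )
  m$dermis_depth_cm <- dermis_depth_for_volume(m$width_cm / 2, m$length_cm, m$dv_cm3)
  rho_p2 <- c(papillary = 550, reticular = 400, DWAT = 250, total = 1200)
  ratio <- 2^1.3128 * 0.18 / 2.32     # density fold change P50/P2
  list(measurements = m, rho_p2 = rho_p2, density_ratio = ratio)
}

#' Generate synthetic morphometry and density tables
#'
#' Emulates the raw measurement tables behind the division-number estimate:
#' trunk length, body width and dermis depth for `n_per_group` animals per
#' age and sex, plus replicate fibroblast densities per dermal layer. The
#' `"calibrated"` preset encodes group-mean dermis volumes of 0.18 cm^3
#' at P2 and 2.32 cm^3 at P50 (sex average) and a P50/P2 total-density ratio
#' of `2^1.3128 * 0.18/2.32 ~ 0.1927`, so at zero noise the estimator
#' returns exactly n = 1.3128. Noise is multiplicative Gaussian with the
#' given coefficient of variation, applied per animal and per replicate.
#'
#' @param preset Only `"calibrated"` currently.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 makes all animals in a group identical).
#' @param n_per_group Animals per age x sex group (default 3) and density
#'   replicates per age x layer.
#' @param seed RNG seed.
#' @return List with `measurements` (tibble: `age_days`, `sex`,
#'   `length_cm`, `width_cm`, `dermis_depth_cm`), `densities` (tibble:
#'   `age_days`, `layer`, `rho_per_mm2`, `n_regions`) and `truth`
#'   (generating values: volumes, density ratio, expected `n`).
#' @export
gen_measurements <- function(preset = "calibrated", noise_cv = 0,
                             n_per_group = 3, seed = 0L) {
  preset <- match.arg(preset)
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  base <- calibrated_base()
  withr::with_seed(as.integer(seed), {
    jitter <- function(x) x * pmax(1 + noise_cv * stats::rnorm(length(x)), 0.05)
    meas <- base$measurements[rep(seq_len(nrow(base$measurements)),
                                  each = n_per_group), ]
    meas <- tibble::tibble(
      age_days = meas$age_days,
      sex = meas$sex,
      length_cm = jitter(meas$length_cm),
      width_cm = jitter(meas$width_cm),
      dermis_depth_cm = jitter(meas$dermis_depth_cm)
    )
    layers <- names(base$rho_p2)
    dens <- tidyr::expand_grid(
      age_days = c(2, 50), layer = layers,
      replicate = seq_len(n_per_group)
    )
    rho_base <- base$rho_p2[dens$layer] *
      ifelse(dens$age_days == 50, base$density_ratio, 1)
    dens <- tibble::tibble(
      age_days = dens$age_days,
      layer = dens$layer,
      rho_per_mm2 = jitter(unname(rho_base)),
      n_regions = 30L
    )
    list(
      measurements = meas,
      densities = dens,
      truth = list(
        dv_p2_cm3 = 0.18, dv_p50_cm3 = 2.32,
        density_ratio = base$density_ratio,
        n_divisions = log2((2.32 / 0.18) * base$density_ratio)
      )
    )
  })
}

#' Generate a synthetic whole-mount cell table
#'
#' Emulates the coordinate table extracted from a confocal whole-mount:
#' Poisson background fibroblasts per dermal layer, plus labelled clones
#' placed as a founder with offspring scattered around it (small scatter =
#' young tissue, large scatter = expanded tissue). Founders are kept at
#' least `min_founder_sep_um` apart (rejection sampling), emulating the
#' sparse labelling design of 1-2 founders per inter-HF region. Every cell
#' carries its layer, labelled flag, true clone id and Bernoulli marker
#' states.
#'
#' @param domain_um Length-2 field extent (µm).
#' @param density_per_mm2 Named areal background density per layer.
#' @param clones List with `n_clones`, `size` (scalar or vector, recycled)
#'   and `spread_um` (sd of the isotropic xy scatter of offspring around the
#'   founder).
#' @param layers_um Layer geometry, see [default_layers()].
#' @param marker_probs Named probabilities for the Bernoulli marker states
#'   (`ki67`, `ccasp3`, `topgfp`).
#' @param min_founder_sep_um Minimum pairwise founder separation (µm).
#' @param seed RNG seed.
#' @return Tibble of cells (`cell_id`, `x_um`, `y_um`, `z_um`, `layer`,
#'   `labelled`, `clone_id`, marker columns) with the generating truth in
#'   `attr(, "truth")`.
#' @export
gen_wholemount <- function(domain_um = c(2000, 2000),
                           density_per_mm2 = c(papillary = 550, reticular = 400,
                                               DWAT = 250),
                           clones = list(n_clones = 10, size = 5, spread_um = 30),
                           layers_um = default_layers(),
                           marker_probs = c(ki67 = 0.02, ccasp3 = 0.005,
                                            topgfp = 0.1),
                           min_founder_sep_um = 600,
                           seed = 0L) {
  withr::with_seed(as.integer(seed), {
    area_mm2 <- prod(domain_um) / 1e6
    depth <- max(layers_um$z1_um)
    bg <- lapply(seq_len(nrow(layers_um)), function(i) {
      ly <- layers_um[i, ]
      n <- stats::rpois(1, density_per_mm2[[ly$layer]] * area_mm2)
      tibble::tibble(x_um = stats::runif(n, 0, domain_um[1]),
                     y_um = stats::runif(n, 0, domain_um[2]),
                     z_um = stats::runif(n, ly$z0_um, ly$z1_um),
                     labelled = FALSE, clone_id = NA_integer_)
    })

    k <- clones$n_clones
    sizes <- rep_len(clones$size, k)
    founders <- matrix(NA_real_, k, 2)
    for (i in seq_len(k)) {
      for (try in 1:2000) {
        p <- stats::runif(2) * domain_um
        ok <- i == 1 ||
          all(sqrt(rowSums((founders[seq_len(i - 1), , drop = FALSE] -
                              matrix(p, i - 1, 2, byrow = TRUE))^2)) >=
                min_founder_sep_um)
        if (ok) { founders[i, ] <- p; break }
      }
      if (any(is.na(founders[i, ]))) {
        stop("could not place founders at the requested separation; enlarge the domain",
             call. = FALSE)
      }
    }
    cl <- lapply(seq_len(k), function(i) {
      n <- sizes[i]
      sc <- clones$spread_um
      x <- c(founders[i, 1], founders[i, 1] + stats::rnorm(n - 1, 0, sc))
      y <- c(founders[i, 2], founders[i, 2] + stats::rnorm(n - 1, 0, sc))
      tibble::tibble(
        x_um = pmin(pmax(x, 0), domain_um[1]),
        y_um = pmin(pmax(y, 0), domain_um[2]),
        z_um = stats::runif(n, 0, depth),
        labelled = TRUE, clone_id = i
      )
    })

    cells <- dplyr::bind_rows(c(bg, cl))
    cells$layer <- layer_of(cells$z_um, layers_um)
    cells <- tibble::tibble(cell_id = seq_len(nrow(cells)), cells)
    for (mk in names(marker_probs)) {
      cells[[mk]] <- stats::runif(nrow(cells)) < marker_probs[[mk]]
    }
    attr(cells, "truth") <- list(clone_sizes = sizes,
                                 marker_probs = marker_probs,
                                 density_per_mm2 = density_per_mm2)
    cells
  })
}

#' Generate synthetic wound-section hair-follicle counts
#'
#' Counts of newly formed hair follicles per serial wound-bed section,
#' drawn Poisson with the given mean (five per section echoes the healing
#' neonatal wound scenario).
#'
#' @param n_wounds Number of wounds.
#' @param sections_per_wound Sections per wound (default 8, the scoring
#'   minimum).
#' @param mean_hfs Poisson mean of new follicles per section.
#' @param section_thickness_um Recorded section thickness (µm).
#' @param seed RNG seed.
#' @return Tibble with `wound_id`, `section_id`, `section_thickness_um`,
#'   `n_new_hfs`; the generating mean in `attr(, "truth")`.
#' @export
gen_wound_sections <- function(n_wounds = 4, sections_per_wound = 8,
                               mean_hfs = 5, section_thickness_um = 60,
                               seed = 0L) {
  stopifnot(sections_per_wound >= 1)
  withr::with_seed(as.integer(seed), {
    out <- tidyr::expand_grid(wound_id = seq_len(n_wounds),
                              section_id = seq_len(sections_per_wound))
    out$section_thickness_um <- section_thickness_um
    out$n_new_hfs <- stats::rpois(nrow(out), mean_hfs)
    attr(out, "truth") <- list(mean_hfs = mean_hfs)
    out
  })
}
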