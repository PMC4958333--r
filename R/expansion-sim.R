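# Cells are stored in the start-age ("material") frame as (x0_um, y0_um,
# z0_um); the position at age a is x0 * sx(a) etc. Storing material
# coordinates makes passive advection exact: no per-step rounding
# accumulates, and with zero rates pairwise distances transform by exactly
# the configured affine map.

#' Seed a tissue snapshot with a spatial Poisson process
#'
#' Places cells in each dermal layer by a homogeneous spatial Poisson process
#' at the configured areal density: the count in a layer is
#' `Poisson(density * area)` and positions are uniform in the layer slab.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; `NULL` uses the current RNG stream (as inside
#'   [run_expansion()]), the default uses `config$seed`.
#' @return A `tissue_snapshot` at `config$start_age_days`.
#' @export
init_tissue <- function(config, seed = config$seed) {
  run_seeded(seed, {
    area_mm2 <- prod(config$domain_um) / 1e6
    pieces <- lapply(seq_len(nrow(config$layers_um)), function(i) {
      ly <- config$layers_um[i, ]
      n <- stats::rpois(1, config$density_per_mm2[[ly$layer]] * area_mm2)
      tibble::tibble(
        x0_um = stats::runif(n, 0, config$domain_um[1]),
        y0_um = stats::runif(n, 0, config$domain_um[2]),
        z0_um = stats::runif(n, ly$z0_um, ly$z1_um)
      )
    })
    cells <- dplyr::bind_rows(pieces)
    cells <- tibble::tibble(
      cell_id = seq_len(nrow(cells)),
      parent_id = NA_integer_,
      clone_id = NA_integer_,
      x0_um = cells$x0_um, y0_um = cells$y0_um, z0_um = cells$z0_um,
      labelled = FALSE,
      birth_age_days = config$start_age_days
    )
    new_snapshot(config$start_age_days, cells, config)
  })
}

#' Sparse clonal labelling over inter-HF region tiles
#'
#' Tiles the field into square inter-HF regions of side `region_pitch_um`
#' and labels, independently per region, a Poisson-distributed number of
#' resident cells with mean `labels_per_region` (capped at the region's
#' occupancy, with a warning if any region ran short). Each labelled founder
#' receives `clone_id` equal to its own `cell_id`.
#'
#' @param snapshot A `tissue_snapshot`.
#' @param labels_per_region Expected labelled cells per region.
#' @param region_pitch_um Tile side length (µm) in the current frame.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return The snapshot with `labelled`/`clone_id` updated.
#' @export
induce_labels <- function(snapshot,
                          labels_per_region = snapshot$config$labels_per_region,
                          region_pitch_um = snapshot$config$region_pitch_um,
                          seed = NULL) {
  if (nrow(snapshot$cells) == 0) {
    stop("cannot label an empty snapshot", call. = FALSE)
  }
  run_seeded(seed, {
    cells <- snapshot$cells
    tile <- paste(
      pmin(floor(cells$x_um / region_pitch_um),
           ceiling(snapshot$domain_um[1] / region_pitch_um) - 1),
      pmin(floor(cells$y_um / region_pitch_um),
           ceiling(snapshot$domain_um[2] / region_pitch_um) - 1)
    )
    short <- 0L
    for (tl in unique(tile)) {
      idx <- which(tile == tl)
      k <- stats::rpois(1, labels_per_region)
      if (k > length(idx)) {
        short <- short + 1L
        k <- length(idx)
      }
      if (k > 0) {
        pick <- if (length(idx) == 1) idx else sample(idx, k)
        cells$labelled[pick] <- TRUE
        cells$clone_id[pick] <- cells$cell_id[pick]
      }
    }
    if (short > 0) {
      warning(sprintf("%d region(s) held fewer cells than labels requested; labelled all residents",
                      short), call. = FALSE)
    }
    new_snapshot(snapshot$age_days, strip_frame(cells), snapshot$config)
  })
}

#' Advance a snapshot in time
#'
#' Evolves the tissue from the snapshot's age to `to_age` in steps of at most
#' `config$step_days`. Each step (i) advects all cells passively by the
#' per-axis expansion schedule, (ii) kills each cell with the per-step death
#' hazard, and (iii) divides each survivor with the per-step division
#' probability; daughters inherit `clone_id` and `labelled`, are placed
#' uniformly in a ball of `daughter_radius_um` around the mother, clipped to
#' the domain, and take their layer from their z position.
#'
#' Per-step probabilities are chosen so the exponential laws hold exactly in
#' expectation: division uses `exp(lambda*dt) - 1` (expected fold change over
#' the interval is exactly `2^division_rate`) and death uses
#' `1 - exp(-mu*dt)` (founder survival exactly `exp(-death_rate)`). In
#' `"rounds"` mode divisions instead occur in `n_rounds` synchronous waves at
#' evenly spaced ages, each cell dividing with probability
#' `2^(division_rate/n_rounds) - 1` per wave.
#'
#' @param snapshot A `tissue_snapshot`.
#' @param to_age Target age (days); must be >= the snapshot age.
#' @param config A [sim_config()] (defaults to the snapshot's own).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return A `tissue_snapshot` at `to_age`.
#' @export
advance <- function(snapshot, to_age, config = snapshot$config, seed = NULL) {
  if (to_age < snapshot$age_days) {
    stop("`to_age` must not precede the snapshot age", call. = FALSE)
  }
  run_seeded(seed, {
    cells <- strip_frame(snapshot$cells)
    age <- snapshot$age_days
    total_days <- config$end_age_days - config$start_age_days
    lambda <- if (total_days > 0) config$division_rate * log(2) / total_days else 0
    mu <- if (total_days > 0) config$death_rate / total_days else 0
    round_ages <- if (config$division_mode == "rounds" && config$n_rounds > 0) {
      config$start_age_days +
        seq_len(config$n_rounds) * total_days / config$n_rounds
    } else {
      numeric(0)
    }
    p_round <- 2^(config$division_rate / max(config$n_rounds, 1)) - 1
    if (config$division_mode == "rounds" && p_round > 1) {
      stop("division_rate too high for the configured number of rounds", call. = FALSE)
    }
    next_id <- if (nrow(cells)) max(cells$cell_id) else 0L

    while (age < to_age - 1e-9) {
      dt <- min(config$step_days, to_age - age)
      age_new <- age + dt

      # deaths (memoryless hazard in both modes)
      if (mu > 0 && nrow(cells)) {
        die <- stats::runif(nrow(cells)) < (1 - exp(-mu * dt))
        cells <- cells[!die, ]
      }

      # divisions
      if (nrow(cells)) {
        if (config$division_mode == "hazard") {
          p_div <- min(1, exp(lambda * dt) - 1)
          n_waves <- if (p_div > 0) 1L else 0L
        } else {
          n_waves <- sum(round_ages > age + 1e-9 & round_ages <= age_new + 1e-9)
          p_div <- p_round
        }
        for (w in seq_len(n_waves)) {
          divide <- stats::runif(nrow(cells)) < p_div
          if (any(divide)) {
            d <- place_daughters(cells[divide, ], age_new, config)
            d$cell_id <- next_id + seq_len(nrow(d))
            next_id <- next_id + nrow(d)
            cells <- dplyr::bind_rows(cells, d)
          }
        }
      }
      age <- age_new
    }
    new_snapshot(to_age, cells, config)
  })
}

# daughters of `mothers` at `age`: uniform in a ball around the mother in the
# *current* frame, clipped to the current domain, stored back in material
# coordinates
place_daughters <- function(mothers, age, config) {
  n <- nrow(mothers)
  s <- scale_at(config, age)
  r <- config$daughter_radius_um * stats::runif(n)^(1 / 3)
  z <- stats::runif(n, -1, 1)
  th <- stats::runif(n, 0, 2 * pi)
  rxy <- r * sqrt(1 - z^2)
  dom <- c(config$domain_um * s[1:2], max(config$layers_um$z1_um) * s[3])
  cx <- pmin(pmax(mothers$x0_um * s[1] + rxy * cos(th), 0), dom[1])
  cy <- pmin(pmax(mothers$y0_um * s[2] + rxy * sin(th), 0), dom[2])
  cz <- pmin(pmax(mothers$z0_um * s[3] + r * z, 0), dom[3])
  tibble::tibble(
    cell_id = NA_integer_,
    parent_id = mothers$cell_id,
    clone_id = mothers$clone_id,
    x0_um = cx / s[1], y0_um = cy / s[2], z0_um = cz / s[3],
    labelled = mothers$labelled,
    birth_age_days = age
  )
}

#' Run the expansion simulator
#'
#' Composes [init_tissue()], [induce_labels()] (at `config$label_time_days`)
#' and [advance()], returning snapshots at each requested age. The whole run
#' is a pure function of the configuration: one RNG stream is seeded from
#' `config$seed`, so identical configurations give identical snapshot
#' streams.
#'
#' @param config A [sim_config()].
#' @param output_ages Sorted ages (days) within the simulated interval at
#'   which to record snapshots.
#' @return A named list of `tissue_snapshot`s, one per output age.
#' @export
run_expansion <- function(config, output_ages = config$end_age_days) {
  if (is.unsorted(output_ages)) {
    stop("`output_ages` must be sorted", call. = FALSE)
  }
  if (any(output_ages < config$start_age_days) ||
      any(output_ages > config$end_age_days)) {
    stop("`output_ages` must lie within the simulated interval", call. = FALSE)
  }
  run_seeded(config$seed, {
    snap <- init_tissue(config, seed = NULL)
    out <- list()
    record <- function(s) out[[sprintf("age_%g", s$age_days)]] <<- s
    labelled <- FALSE
    label_now <- function(s) induce_labels(s, seed = NULL)
    if (config$label_time_days <= config$start_age_days) {
      snap <- label_now(snap); labelled <- TRUE
    }
    for (a in output_ages) {
      if (!labelled && config$label_time_days <= a) {
        if (config$label_time_days > snap$age_days) {
          snap <- advance(snap, config$label_time_days, config, seed = NULL)
        }
        snap <- label_now(snap); labelled <- TRUE
      }
      if (a > snap$age_days) snap <- advance(snap, a, config, seed = NULL)
      record(snap)
    }
    out
  })
}

#' Tissue snapshot constructor
#'
#' Materialises current-frame positions, domain dimensions and layer
#' assignments from material coordinates and the expansion schedule.
#'
#' @param age_days Snapshot age.
#' @param cells Cell tibble in material coordinates (`x0_um`, `y0_um`,
#'   `z0_um`, plus identity columns).
#' @param config The generating [sim_config()].
#' @return An object of class `tissue_snapshot`.
#' @keywords internal
new_snapshot <- function(age_days, cells, config) {
  s <- scale_at(config, age_days)
  cells$x_um <- cells$x0_um * s[["sx"]]
  cells$y_um <- cells$y0_um * s[["sy"]]
  cells$z_um <- cells$z0_um * s[["sz"]]
  cells$layer <- layer_of(cells$z0_um, config$layers_um)
  layers <- config$layers_um
  layers$z0_um <- layers$z0_um * s[["sz"]]
  layers$z1_um <- layers$z1_um * s[["sz"]]
  structure(
    list(
      age_days = age_days,
      domain_um = config$domain_um * s[1:2],
      depth_um = max(config$layers_um$z1_um) * s[["sz"]],
      layers_um = layers,
      cells = cells,
      config = config
    ),
    class = "tissue_snapshot"
  )
}

# layer label from material-frame z (equivalent to current frame, since all
# z-boundaries scale by the same factor)
layer_of <- function(z0_um, layers_um) {
  out <- rep(NA_character_, length(z0_um))
  for (i in rev(seq_len(nrow(layers_um)))) {
    hit <- z0_um >= layers_um$z0_um[i] & z0_um <= layers_um$z1_um[i]
    out[hit] <- layers_um$layer[i]
  }
  out
}

strip_frame <- function(cells) {
  cells[, setdiff(names(cells), c("x_um", "y_um", "z_um", "layer"))]
}

#' @export
print.tissue_snapshot <- function(x, ...) {
  cat(sprintf("Tissue snapshot at age %g days\n", x$age_days))
  cat(sprintf("  domain : %.0f x %.0f um, depth %.0f um\n",
              x$domain_um[1], x$domain_um[2], x$depth_um))
  cat(sprintf("  cells  : %d (%d labelled, %d clones)\n",
              nrow(x$cells), sum(x$cells$labelled),
              length(unique(stats::na.omit(x$cells$clone_id)))))
  invisible(x)
}

#' Section-style areal density of a snapshot
#'
#' Emulates counting cells per mm^2 in a confocal whole-mount section of
#' fixed thickness: the volumetric density of the snapshot (total, and per
#' layer) multiplied by the section thickness. Because the section thickness
#' is held fixed across ages, ratios of these densities between ages equal
#' ratios of volumetric density, which is the assumption under which the
#' division-number estimator operates.
#'
#' @param snapshot A `tissue_snapshot`.
#' @param section_um Section thickness (µm), default 60.
#' @return Tibble with columns `layer` (including `"total"`) and
#'   `rho_per_mm2`.
#' @export
snapshot_density <- function(snapshot, section_um = 60) {
  area_mm2 <- prod(snapshot$domain_um) / 1e6
  per_layer <- lapply(seq_len(nrow(snapshot$layers_um)), function(i) {
    ly <- snapshot$layers_um[i, ]
    n <- sum(snapshot$cells$layer == ly$layer, na.rm = TRUE)
    thick <- ly$z1_um - ly$z0_um
    tibble::tibble(layer = ly$layer,
                   rho_per_mm2 = n / area_mm2 * section_um / thick)
  })
  total <- tibble::tibble(
    layer = "total",
    rho_per_mm2 = nrow(snapshot$cells) / area_mm2 * section_um / snapshot$depth_um
  )
  dplyr::bind_rows(c(per_layer, list(total)))
}

# evaluate `expr` under a temporary seed without disturbing the caller's RNG;
# seed = NULL runs in the current stream
run_seeded <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}
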