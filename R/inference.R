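#' Estimate the fibroblast division number from morphometry and density tables
#'
#' End-to-end estimator: models the trunk as a cylinder, computes each
#' animal's dermis volume as a cylindrical shell, averages volumes within
#' sex and then across sexes at each age, combines the volume ratio with the
#' areal-density ratio into the relative cell-number ratio
#' `N/N0 = (dv1/dv0) * (rho1/rho0)`, and returns `n = log2(N/N0)` — the
#' number of divisions per cell under exponential growth.
#'
#' @param measurements Tibble, one row per animal: `age_days`, `sex`
#'   (`"male"`, `"female"` or `"pooled"`), `length_cm`, `width_cm`,
#'   `dermis_depth_cm`.
#' @param densities Tibble, one row per replicate: `age_days`, `layer`,
#'   `rho_per_mm2`, `n_regions`.
#' @param t0,t1 Ages (days) to compare; both must be present in both tables.
#' @param layer Which density layer enters the estimate (default
#'   `"total"`, the whole-dermis density).
#' @param n_boot Bootstrap replicates over animals (and density replicates)
#'   for a percentile confidence interval on `n`; 0 disables.
#' @param conf Confidence level for the bootstrap interval.
#' @param seed RNG seed for the bootstrap.
#' @return A [division_estimate()] whose `details` carry the per-age pooled
#'   volumes (`dv_t0`, `dv_t1`, cm^3) and densities (`rho_t0`, `rho_t1`).
#' @export
estimate_division_number <- function(measurements, densities, t0, t1,
                                     layer = "total",
                                     n_boot = 0, conf = 0.95, seed = 0L) {
  measurements <- validate_table(measurements, "measurements")
  densities <- validate_table(densities, "densities")
  for (a in c(t0, t1)) {
    if (!any(measurements$age_days == a)) {
      stop(sprintf("no measurements at age %s days", a), call. = FALSE)
    }
    if (!any(densities$age_days == a & densities$layer == layer)) {
      stop(sprintf("no `%s` density at age %s days", layer, a), call. = FALSE)
    }
  }

  point <- division_point_estimate(measurements, densities, t0, t1, layer)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ns <- withr::with_seed(as.integer(seed), {
      replicate(n_boot, {
        m_b <- resample_within(measurements, c("age_days", "sex"))
        d_b <- resample_within(densities[densities$layer == layer, ], "age_days")
        division_point_estimate(m_b, d_b, t0, t1, layer)$n
      })
    })
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(ns, c(alpha, 1 - alpha), type = 7))
  }

  division_estimate(
    cell_ratio = point$vr * point$dr,
    volume_ratio = point$vr,
    density_ratio = point$dr,
    ci_low = ci[1], ci_high = ci[2],
    details = list(dv_t0 = point$dv0, dv_t1 = point$dv1,
                   rho_t0 = point$rho0, rho_t1 = point$rho1,
                   t0 = t0, t1 = t1, layer = layer,
                   n_boot = n_boot, conf = conf, seed = seed)
  )
}

# pooled volumes/densities and their ratios at two ages
division_point_estimate <- function(measurements, densities, t0, t1, layer) {
  dv <- function(age) pooled_dermis_volume(measurements, age)
  rho <- function(age) {
    d <- densities[densities$age_days == age & densities$layer == layer, ]
    mean(d$rho_per_mm2)
  }
  dv0 <- dv(t0); dv1 <- dv(t1)
  rho0 <- rho(t0); rho1 <- rho(t1)
  n0 <- relative_cell_number(dv0, rho0)
  n1 <- relative_cell_number(dv1, rho1)
  list(dv0 = dv0, dv1 = dv1, rho0 = rho0, rho1 = rho1,
       vr = dv1 / dv0, dr = rho1 / rho0,
       n = log2(n1 / n0))
}

#' Pooled dermis volume at an age
#'
#' Per-animal shell volumes, averaged within sex and then across sexes
#' (so a sex with fewer animals is not under-weighted).
#'
#' @inheritParams estimate_division_number
#' @param age_days Age to pool at.
#' @return Pooled dermis volume (cm^3).
#' @export
pooled_dermis_volume <- function(measurements, age_days) {
  m <- measurements[measurements$age_days == age_days, ]
  if (nrow(m) == 0) stop(sprintf("no measurements at age %s", age_days), call. = FALSE)
  dv <- dermis_volume(m$width_cm / 2, m$length_cm, m$dermis_depth_cm)
  mean(tapply(dv, m$sex, mean))
}

# resample rows with replacement within each group defined by `keys`
resample_within <- function(df, keys) {
  split_idx <- split(seq_len(nrow(df)), df[keys], drop = TRUE)
  take <- unlist(lapply(split_idx, function(ix) {
    if (length(ix) == 1) ix else sample(ix, length(ix), replace = TRUE)
  }), use.names = FALSE)
  df[take, ]
}

#' Recover the division rate from an observed clone-size summary
#'
#' Simulation-based inference for the simulator's division rate: for each
#' candidate rate on a grid, runs `reps` seeded simulator replicates,
#' summarises called clones as mean cells per clone per compartment, and
#' scores the candidate by the sum of squared differences to the observed
#' summary. Returns the grid argmin with a bootstrap confidence interval
#' obtained by resampling replicate summaries.
#'
#' @param observed Tibble with `compartment`, `mean_cells` — the observed
#'   clone-size summary (e.g. `clone_sizes_by_compartment()$summary`).
#' @param config A [sim_config()] template; `division_rate` is overridden by
#'   each grid value.
#' @param rate_grid Non-empty numeric grid of candidate division rates.
#' @param reps Simulator replicates per grid point (>= 1).
#' @param n_boot Bootstrap resamples of the replicate summaries for the CI.
#' @param params Clone-calling parameters used on each simulated snapshot.
#' @param seed RNG seed; the whole fit is deterministic given
#'   (config, grid, reps, seed).
#' @return An object of class `fit_result`: list with `rate` (fitted),
#'   `objective`, `grid` (tibble `rate`, `sse`), `ci_low`, `ci_high`,
#'   `seed`.
#' @export
fit_division_rate <- function(observed, config, rate_grid,
                              reps = 20, n_boot = 200,
                              params = clone_calling_params(),
                              seed = 0L) {
  if (length(rate_grid) == 0) stop("`rate_grid` must be non-empty", call. = FALSE)
  stopifnot(reps >= 1)
  if (!all(c("compartment", "mean_cells") %in% names(observed)) ||
      nrow(observed) == 0) {
    stop("`observed` must be a non-empty compartment summary", call. = FALSE)
  }
  rate_grid <- sort(rate_grid)

  withr::with_seed(as.integer(seed), {
    # per grid point x replicate: mean cells per clone per compartment
    rep_means <- lapply(seq_along(rate_grid), function(gi) {
      cfg <- config
      cfg$division_rate <- rate_grid[gi]
      lapply(seq_len(reps), function(r) {
        cfg$seed <- sample.int(.Machine$integer.max, 1)
        snap <- run_expansion(cfg)[[1]]
        ct <- call_clones(snap$cells, params)
        if (nrow(ct$assignments) == 0) return(NULL)
        sz <- clone_sizes_by_compartment(ct, snap$cells,
                                         compartments = config$layers_um$layer)
        stats::setNames(sz$summary$mean_cells, sz$summary$compartment)
      })
    })
    obs <- stats::setNames(observed$mean_cells, observed$compartment)
    sse_from <- function(means_list) {
      vapply(means_list, function(ml) {
        ml <- ml[!vapply(ml, is.null, logical(1))]
        if (length(ml) == 0) return(Inf)
        avg <- Reduce(`+`, ml) / length(ml)
        comps <- intersect(names(obs), names(avg))
        if (length(comps) == 0) {
          stop("observed compartments do not match the simulated layers", call. = FALSE)
        }
        sum((avg[comps] - obs[comps])^2)
      }, numeric(1))
    }
    sse <- sse_from(rep_means)
    fitted_i <- which.min(sse)

    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0 && reps > 1) {
      boot_rates <- replicate(n_boot, {
        pick <- sample.int(reps, reps, replace = TRUE)
        b <- sse_from(lapply(rep_means, function(ml) ml[pick]))
        rate_grid[which.min(b)]
      })
      ci <- unname(stats::quantile(boot_rates, c(0.025, 0.975), type = 1))
    }

    structure(
      list(rate = rate_grid[fitted_i],
           objective = sse[fitted_i],
           grid = tibble::tibble(rate = rate_grid, sse = sse),
           ci_low = ci[1], ci_high = ci[2],
           reps = reps, seed = as.integer(seed)),
      class = "fit_result"
    )
  })
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Division-rate fit (grid search, least squares on clone sizes)\n")
  cat(sprintf("  fitted rate : %.4g (objective %.4g, %d reps/point)\n",
              x$rate, x$objective, x$reps))
  if (is.finite(x$ci_low)) {
    cat(sprintf("  bootstrap CI: [%.4g, %.4g]\n", x$ci_low, x$ci_high))
  }
  invisible(x)
}
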