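#' Default dermal layer geometry at the start age
#'
#' z-intervals (µm, measured downward from the dermo-epidermal junction) for
#' the papillary dermis, reticular dermis and dermal white adipose tissue
#' (DWAT) in neonatal back skin. Absolute boundaries are plausible
#' order-of-magnitude choices, not literature measurements; only their
#' ordering and disjointness matter to the model.
#'
#' @return A tibble with columns `layer`, `z0_um`, `z1_um`.
#' @export
default_layers <- function() {
  tibble::tibble(
    layer = c("papillary", "reticular", "DWAT"),
    z0_um = c(0, 60, 140),
    z1_um = c(60, 140, 200)
  )
}

#' Simulator configuration
#'
#' Bundles every parameter of the expansion simulator: the tissue domain at
#' the start age, per-layer seeding densities, division and death budgets over
#' the simulated interval, the anisotropic expansion schedule, and the sparse
#' labelling design.
#'
#' @param domain_um Length-2 numeric, the x/y extent (µm) of the simulated
#'   whole-mount field at `start_age_days`.
#' @param layers_um Tibble with columns `layer`, `z0_um`, `z1_um` giving
#'   disjoint, ordered z-intervals at the start age; see [default_layers()].
#' @param start_age_days,end_age_days Simulated interval (days; embryonic
#'   ages may be negative relative to birth).
#' @param density_per_mm2 Named numeric, expected cells per mm^2 of field for
#'   each layer in `layers_um`.
#' @param division_rate Expected number of divisions per cell over the whole
#'   interval, on the doubling scale: the expected fold change in cell number
#'   is `2^division_rate`.
#' @param death_rate Expected number of death events per cell over the
#'   interval; founder survival is `exp(-death_rate)`.
#' @param division_mode `"hazard"` (memoryless exponential hazard, the
#'   postnatal default) or `"rounds"` (near-synchronous division waves, used
#'   for embryonic growth where cell cycles are fast and entrained).
#' @param n_rounds Number of division waves when `division_mode = "rounds"`.
#' @param expansion Tibble with columns `age_days`, `sx`, `sy`, `sz`:
#'   per-axis linear scale factors relative to the start age, interpolated
#'   piecewise-linearly. Must start at scale 1 and be non-decreasing. See
#'   [expansion_from_measurements()] and [expansion_isotropic()].
#' @param label_time_days Age at which sparse labelling is induced.
#' @param labels_per_region Expected labelled cells per inter-HF region tile.
#' @param region_pitch_um Side length (µm) of one inter-HF region tile.
#' @param daughter_radius_um Daughters are placed uniformly in a ball of this
#'   radius (µm) around the mother (about one cell diameter).
#' @param step_days Time step for hazard draws; at most 1 day.
#' @param seed Integer RNG seed; every run is a pure function of
#'   (config, seed).
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(domain_um = c(1000, 1000),
                       layers_um = default_layers(),
                       start_age_days = 2,
                       end_age_days = 50,
                       density_per_mm2 = c(papillary = 550, reticular = 400, DWAT = 250),
                       division_rate = 1.3,
                       death_rate = 0,
                       division_mode = c("hazard", "rounds"),
                       n_rounds = 3,
                       expansion = NULL,
                       label_time_days = start_age_days,
                       labels_per_region = 1.5,
                       region_pitch_um = 250,
                       daughter_radius_um = 10,
                       step_days = 1,
                       seed = 0L) {
  division_mode <- match.arg(division_mode)
  if (length(domain_um) != 2 || any(!is.finite(domain_um)) || any(domain_um <= 0)) {
    stop("`domain_um` must be two positive extents (zero-area domain not allowed)",
         call. = FALSE)
  }
  stopifnot(is.data.frame(layers_um),
            all(c("layer", "z0_um", "z1_um") %in% names(layers_um)))
  o <- order(layers_um$z0_um)
  layers_um <- layers_um[o, ]
  if (any(layers_um$z1_um <= layers_um$z0_um) ||
      any(utils::head(layers_um$z1_um, -1) > utils::tail(layers_um$z0_um, -1))) {
    stop("layer z-intervals must be disjoint and ordered", call. = FALSE)
  }
  if (end_age_days < start_age_days) {
    stop("`end_age_days` must be >= `start_age_days`", call. = FALSE)
  }
  if (division_rate < 0 || death_rate < 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  if (!all(layers_um$layer %in% names(density_per_mm2))) {
    stop("`density_per_mm2` must name every layer", call. = FALSE)
  }
  if (is.null(expansion)) {
    expansion <- tibble::tibble(
      age_days = c(start_age_days, end_age_days),
      sx = c(1, 1), sy = c(1, 1), sz = c(1, 1)
    )
  }
  stopifnot(all(c("age_days", "sx", "sy", "sz") %in% names(expansion)))
  expansion <- expansion[order(expansion$age_days), ]
  sc <- as.matrix(expansion[, c("sx", "sy", "sz")])
  if (any(sc < 1) || any(diff(as.matrix(sc)) < -1e-12)) {
    stop("expansion scale factors must be >= 1 and non-decreasing in age", call. = FALSE)
  }
  if (abs(expansion$age_days[1] - start_age_days) > 1e-9 ||
      any(abs(sc[1, ] - 1) > 1e-9)) {
    stop("expansion schedule must start at scale 1 at `start_age_days`", call. = FALSE)
  }
  if (label_time_days < start_age_days || label_time_days > end_age_days) {
    stop("`label_time_days` must lie within the simulated interval", call. = FALSE)
  }
  if (step_days <= 0 || step_days > 1) {
    stop("`step_days` must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(
      domain_um = as.numeric(domain_um),
      layers_um = tibble::as_tibble(layers_um),
      start_age_days = start_age_days,
      end_age_days = end_age_days,
      density_per_mm2 = density_per_mm2,
      division_rate = division_rate,
      death_rate = death_rate,
      division_mode = division_mode,
      n_rounds = as.integer(n_rounds),
      expansion = tibble::as_tibble(expansion),
      label_time_days = label_time_days,
      labels_per_region = labels_per_region,
      region_pitch_um = region_pitch_um,
      daughter_radius_um = daughter_radius_um,
      step_days = step_days,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Per-axis expansion scale at an age
#'
#' Piecewise-linear interpolation of the configured expansion schedule;
#' constant beyond its endpoints.
#'
#' @param config A [sim_config()].
#' @param age_days Age at which to evaluate the schedule.
#' @return Named numeric `c(sx, sy, sz)`.
#' @export
scale_at <- function(config, age_days) {
  e <- config$expansion
  f <- function(col) {
    if (nrow(e) == 1) return(e[[col]][1])
    stats::approx(e$age_days, e[[col]], xout = age_days, rule = 2)$y
  }
  c(sx = f("sx"), sy = f("sy"), sz = f("sz"))
}

#' Isotropic expansion schedule from a volume fold change
#'
#' Each axis scales as the cube root of the volume ratio, linearly in age.
#'
#' @param volume_fold Total volume fold change over the interval (>= 1).
#' @param start_age_days,end_age_days Interval endpoints.
#' @return Expansion tibble usable as `sim_config(expansion = ...)`.
#' @export
expansion_isotropic <- function(volume_fold, start_age_days, end_age_days) {
  stopifnot(volume_fold >= 1)
  s <- volume_fold^(1 / 3)
  tibble::tibble(
    age_days = c(start_age_days, end_age_days),
    sx = c(1, s), sy = c(1, s), sz = c(1, s)
  )
}

#' Anisotropic expansion schedule from morphometry tables
#'
#' Derives per-axis linear scale factors between two ages from a measurement
#' table: the axial (x) scale is the trunk-length ratio, the lateral (y)
#' scale the body-width ratio, and the depth (z) scale the dermis-depth
#' ratio; sexes are averaged dimension-wise.
#'
#' @param measurements Measurement tibble (see [read_measurements()] for the
#'   schema).
#' @param t0,t1 The two ages (days) to anchor the schedule.
#' @return Expansion tibble usable as `sim_config(expansion = ...)`.
#' @export
expansion_from_measurements <- function(measurements, t0, t1) {
  dims <- function(age) {
    m <- measurements[measurements$age_days == age, ]
    if (nrow(m) == 0) stop(sprintf("no measurements at age %s", age), call. = FALSE)
    by_sex <- dplyr::summarise(
      dplyr::group_by(m, .data$sex),
      length_cm = mean(.data$length_cm),
      width_cm = mean(.data$width_cm),
      dermis_depth_cm = mean(.data$dermis_depth_cm),
      .groups = "drop"
    )
    colMeans(by_sex[, c("length_cm", "width_cm", "dermis_depth_cm")])
  }
  d0 <- dims(t0); d1 <- dims(t1)
  tibble::tibble(
    age_days = c(t0, t1),
    sx = c(1, d1[["length_cm"]] / d0[["length_cm"]]),
    sy = c(1, d1[["width_cm"]] / d0[["width_cm"]]),
    sz = c(1, d1[["dermis_depth_cm"]] / d0[["dermis_depth_cm"]])
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Expansion simulator configuration\n")
  cat(sprintf("  ages        : %g -> %g days (label at %g)\n",
              x$start_age_days, x$end_age_days, x$label_time_days))
  cat(sprintf("  domain      : %g x %g um, %d layers\n",
              x$domain_um[1], x$domain_um[2], nrow(x$layers_um)))
  cat(sprintf("  division    : %.3g doublings (%s), death %.3g\n",
              x$division_rate, x$division_mode, x$death_rate))
  s <- scale_at(x, x$end_age_days)
  cat(sprintf("  final scale : sx %.3g, sy %.3g, sz %.3g (volume %.3g-fold)\n",
              s[1], s[2], s[3], prod(s)))
  cat(sprintf("  seed        : %d\n", x$seed))
  invisible(x)
}
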