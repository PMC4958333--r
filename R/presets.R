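# Study-condition presets for the expansion simulator. Ages are postnatal
# days; embryonic ages are negative (E12.5 ~ 7 days before birth).

#' Embryonic labelling preset (E12.5 label, analysed at P2)
#'
#' Sparse labelling at E12.5 followed by rapid, near-synchronous embryonic
#' growth: a 2.5-doubling division budget delivered in three division waves
#' (expected clone size `2^2.5 ~ 5.7`, most clones 4-8 cells), negligible
#' death, and isotropic tissue growth with a linear scale of 3 by P2. Under
#' these conditions labelled founders give rise to compact multicellular
#' clones spanning the dermal layers.
#'
#' @param seed RNG seed.
#' @param domain_um Field extent at E12.5.
#' @return A [sim_config()].
#' @export
preset_embryonic_labelling <- function(seed = 0L, domain_um = c(600, 600)) {
  sim_config(
    domain_um = domain_um,
    start_age_days = -7, end_age_days = 2,
    density_per_mm2 = c(papillary = 500, reticular = 350, DWAT = 200),
    division_rate = 2.5, death_rate = 0,
    division_mode = "rounds", n_rounds = 3,
    expansion = tibble::tibble(age_days = c(-7, 2),
                               sx = c(1, 3), sy = c(1, 3), sz = c(1, 3)),
    label_time_days = -7,
    labels_per_region = 1.5, region_pitch_um = 200,
    seed = seed
  )
}

#' Postnatal expansion preset (P2 label, analysed up to P50)
#'
#' The core postnatal scenario: a 13-fold dermal volume increase between P2
#' and P50 carried almost entirely by expansion, with a division budget of
#' only 1.3 doublings per cell (exponential hazard) and negligible death.
#' The anisotropic expansion schedule is derived from the calibrated
#' synthetic morphometry tables (axial scale = trunk-length ratio, lateral =
#' width ratio, depth = dermis-depth ratio). Clonally related cells
#' therefore disperse rather than accumulate.
#'
#' @param seed RNG seed.
#' @param domain_um Field extent at P2.
#' @param division_rate Doubling budget over P2 to P50 (default 1.3).
#' @return A [sim_config()].
#' @export
preset_postnatal_expansion <- function(seed = 0L, domain_um = c(1200, 1200),
                                       division_rate = 1.3) {
  tabs <- gen_measurements(noise_cv = 0, seed = 0L)
  sched <- expansion_from_measurements(tabs$measurements, 2, 50)
  sim_config(
    domain_um = domain_um,
    start_age_days = 2, end_age_days = 50,
    density_per_mm2 = c(papillary = 550, reticular = 400, DWAT = 250),
    division_rate = division_rate, death_rate = 0,
    division_mode = "hazard",
    expansion = sched,
    label_time_days = 2,
    labels_per_region = 1.5, region_pitch_um = 250,
    seed = seed
  )
}
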