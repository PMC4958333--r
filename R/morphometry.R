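#' Cylinder volume of the mouse trunk
#'
#' The trunk is modelled as a cylinder of radius `radius_cm` (half the body
#' width at its widest point) and height `height_cm` (trunk length, scapulae
#' to tail base).
#'
#' @param radius_cm Cylinder radius in cm (half the body width). Must be
#'   non-negative.
#' @param height_cm Cylinder height in cm (trunk length). Must be
#'   non-negative.
#' @return Volume in cm^3: `pi * r^2 * h`. Vectorised over both arguments.
#' @examples
#' cylinder_volume(1, 1)        # pi
#' cylinder_volume(0.6, 2.5)    # neonatal mouse trunk
#' @export
cylinder_volume <- function(radius_cm, height_cm) {
  check_nonneg(radius_cm, "radius_cm")
  check_nonneg(height_cm, "height_cm")
  pi * radius_cm^2 * height_cm
}

#' Dermis volume as a cylindrical shell
#'
#' The dermis is the shell between the trunk cylinder and an inner cylinder
#' whose radius is reduced by the dermis depth `depth_cm`:
#' `dv = pi*r^2*h - pi*(r - dd)^2*h = pi*h*(2*r*dd - dd^2)`.
#'
#' @param radius_cm Outer radius in cm (half the body width).
#' @param height_cm Trunk length in cm.
#' @param depth_cm Dermis depth in cm; must satisfy `0 <= depth_cm <= radius_cm`.
#' @return Shell volume in cm^3. Vectorised.
#' @examples
#' dermis_volume(0.6, 2.5, 0.0194)   # ~0.18 cm^3 at P2
#' @export
dermis_volume <- function(radius_cm, height_cm, depth_cm) {
  check_nonneg(radius_cm, "radius_cm")
  check_nonneg(height_cm, "height_cm")
  check_nonneg(depth_cm, "depth_cm")
  if (any(depth_cm > radius_cm)) {
    stop("`depth_cm` must not exceed `radius_cm` (dermis cannot be deeper than the trunk radius)",
         call. = FALSE)
  }
  pi * height_cm * (2 * radius_cm * depth_cm - depth_cm^2)
}

#' Dermis depth giving a target shell volume
#'
#' Inverse of [dermis_volume()] in `depth_cm`: solves
#' `pi*h*(2*r*dd - dd^2) = volume_cm3` for the root in `[0, r]`,
#' `dd = r - sqrt(r^2 - v / (pi*h))`. Used by the synthetic measurement
#' generator to construct morphometry that encodes a chosen dermis volume.
#'
#' @param radius_cm Outer radius in cm.
#' @param height_cm Trunk length in cm.
#' @param volume_cm3 Target dermis volume in cm^3; must not exceed the full
#'   cylinder volume.
#' @return Dermis depth in cm.
#' @export
dermis_depth_for_volume <- function(radius_cm, height_cm, volume_cm3) {
  check_nonneg(volume_cm3, "volume_cm3")
  disc <- radius_cm^2 - volume_cm3 / (pi * height_cm)
  if (any(disc < 0)) {
    stop("`volume_cm3` exceeds the total cylinder volume", call. = FALSE)
  }
  radius_cm - sqrt(disc)
}

#' Relative fibroblast number from dermis volume and areal density
#'
#' Multiplies a dermis volume (cm^3) by an areal fibroblast density
#' (cells per mm^2 of section). Because the density is areal, the product is
#' proportional to the true cell number only up to the effective optical
#' section thickness; that constant cancels in every `N/N0` ratio the package
#' forms, so the division-number estimate is invariant to it. The result is
#' therefore reported in *relative units*, never as an absolute count.
#'
#' @param dermis_volume_cm3 Dermis volume in cm^3.
#' @param rho_per_mm2 Fibroblast density in cells per mm^2 of section.
#' @return Relative cell number (arbitrary units). Vectorised.
#' @export
relative_cell_number <- function(dermis_volume_cm3, rho_per_mm2) {
  check_nonneg(dermis_volume_cm3, "dermis_volume_cm3")
  check_nonneg(rho_per_mm2, "rho_per_mm2")
  dermis_volume_cm3 * rho_per_mm2
}

#' Division number under exponential growth
#'
#' Under exponential cellular growth the number of divisions separating two
#' population sizes is `n = log2(N / N0)`. Negative `n` indicates net cell
#' loss. Input units cancel, so relative cell numbers (see
#' [relative_cell_number()]) are valid inputs.
#'
#' @param n0_relative Cell number (relative units) at the earlier age; > 0.
#' @param n_relative Cell number (relative units) at the later age; > 0.
#' @param volume_ratio,density_ratio Optional decomposition of the cell-number
#'   ratio (`cell_ratio = volume_ratio * density_ratio`) recorded for
#'   provenance when the inputs came from the volume-times-density pipeline.
#' @return A `division_estimate` object; see [division_estimate()].
#' @examples
#' estimate_divisions(100, 200)   # one doubling, n = 1
#' @export
estimate_divisions <- function(n0_relative, n_relative,
                               volume_ratio = NA_real_,
                               density_ratio = NA_real_) {
  if (!is.finite(n0_relative) || n0_relative <= 0) {
    stop("`n0_relative` must be a positive finite number", call. = FALSE)
  }
  if (!is.finite(n_relative) || n_relative <= 0) {
    stop("`n_relative` must be a positive finite number", call. = FALSE)
  }
  division_estimate(
    cell_ratio = n_relative / n0_relative,
    volume_ratio = volume_ratio,
    density_ratio = density_ratio
  )
}

#' Division-number estimate record
#'
#' Container for the output of the division-number estimator. Enforces the
#' two defining identities: `n_divisions = log2(cell_ratio)` and, when the
#' decomposition is supplied, `cell_ratio = volume_ratio * density_ratio`.
#'
#' @param cell_ratio `N/N0`, the fold change in (relative) cell number.
#' @param volume_ratio `dv1/dv0`, fold change in dermis volume (or `NA`).
#' @param density_ratio `rho1/rho0`, fold change in areal density (or `NA`).
#' @param ci_low,ci_high Optional bootstrap confidence bounds on
#'   `n_divisions`.
#' @param details Optional named list of provenance (per-group volumes,
#'   densities, bootstrap settings).
#' @return An object of class `division_estimate`: a list with fields
#'   `n_divisions`, `cell_ratio`, `volume_ratio`, `density_ratio`, `ci_low`,
#'   `ci_high`, `details`.
#' @export
division_estimate <- function(cell_ratio,
                              volume_ratio = NA_real_,
                              density_ratio = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              details = list()) {
  if (!is.finite(cell_ratio) || cell_ratio <= 0) {
    stop("`cell_ratio` must be positive and finite", call. = FALSE)
  }
  if (is.finite(volume_ratio) && is.finite(density_ratio)) {
    if (abs(cell_ratio - volume_ratio * density_ratio) >
        1e-8 * max(1, abs(cell_ratio))) {
      stop("`cell_ratio` must equal `volume_ratio * density_ratio`", call. = FALSE)
    }
  }
  if (is.finite(ci_low) && is.finite(ci_high) && ci_low > ci_high) {
    stop("confidence bounds must be ordered", call. = FALSE)
  }
  structure(
    list(
      n_divisions = log2(cell_ratio),
      cell_ratio = cell_ratio,
      volume_ratio = volume_ratio,
      density_ratio = density_ratio,
      ci_low = ci_low,
      ci_high = ci_high,
      details = details
    ),
    class = "division_estimate"
  )
}

#' @export
print.division_estimate <- function(x, ...) {
  cat("Division-number estimate (exponential growth model)\n")
  cat(sprintf("  n divisions : %.4f\n", x$n_divisions))
  cat(sprintf("  N/N0 ratio  : %.4f\n", x$cell_ratio))
  if (is.finite(x$volume_ratio)) {
    cat(sprintf("  volume fold : %.4f\n", x$volume_ratio))
  }
  if (is.finite(x$density_ratio)) {
    cat(sprintf("  density fold: %.4f\n", x$density_ratio))
  }
  if (is.finite(x$ci_low)) {
    cat(sprintf("  bootstrap CI: [%.4f, %.4f]\n", x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Fold change between two values
#'
#' @param value_t0 Baseline value; must be strictly positive.
#' @param value_t1 Later value.
#' @return `value_t1 / value_t0`.
#' @seealso [fold_report()] for the companion rounded report.
#' @examples
#' fold_change(0.18, 2.32)   # ~12.9, reported as "13-fold"
#' @export
fold_change <- function(value_t0, value_t1) {
  if (any(!is.finite(value_t0)) || any(value_t0 <= 0)) {
    stop("`value_t0` must be strictly positive", call. = FALSE)
  }
  value_t1 / value_t0
}

#' Rounded fold-change report
#'
#' Rounds a fold change to the nearest integer for "k-fold" reporting; the
#' raw ratio should always be retained alongside.
#'
#' @inheritParams fold_change
#' @return Integer fold (nearest integer to the raw ratio).
#' @export
fold_report <- function(value_t0, value_t1) {
  as.integer(round(fold_change(value_t0, value_t1)))
}

# shared domain check
check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and non-negative", name), call. = FALSE)
  }
  invisible(x)
}
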