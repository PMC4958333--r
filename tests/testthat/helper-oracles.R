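# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: full enumeration, generic numerical quadrature,
# closed-form expectations — no code shared with the package internals.

# Shell volume by generic 1-D quadrature of the annulus cross-section.
oracle_shell_volume <- function(r, h, dd) {
  h * stats::integrate(function(s) 2 * pi * s, lower = r - dd, upper = r,
                       rel.tol = 1e-10)$value
}

# All set partitions of 1..n as restricted-growth strings, in lexicographic
# order. Cached per n.
.rgs_cache <- new.env(parent = emptyenv())
all_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(.rgs_cache[[key]])) return(.rgs_cache[[key]])
  res <- list()
  rec <- function(s, m) {
    if (length(s) == n) {
      res[[length(res) + 1]] <<- s
      return()
    }
    for (v in seq_len(m + 1) - 1L) rec(c(s, v), max(m, v + 1L))
  }
  rec(integer(0), 0L)
  .rgs_cache[[key]] <- res
  res
}

# Brute-force optimal clone partition: among partitions whose blocks all
# have pairwise distances <= cutoff, take the one with the fewest blocks,
# then minimal total within-block pairwise distance, then the first in
# lexicographic order. Points are assumed ordered by cell id.
oracle_partition <- function(dm, cutoff) {
  n <- nrow(dm)
  if (n == 1) return(1L)
  best <- NULL
  best_k <- Inf
  best_cost <- Inf
  for (p in all_partitions(n)) {
    feasible <- TRUE
    cost <- 0
    for (b in unique(p)) {
      idx <- which(p == b)
      if (length(idx) > 1) {
        d <- dm[idx, idx]
        if (max(d) > cutoff) { feasible <- FALSE; break }
        cost <- cost + sum(d) / 2
      }
    }
    if (!feasible) next
    k <- length(unique(p))
    if (k < best_k || (k == best_k && cost < best_cost - 1e-9)) {
      best <- p; best_k <- k; best_cost <- cost
    }
  }
  best + 1L
}

# canonical form: clone labels renumbered by first appearance
canon_part <- function(p) match(p, unique(p))

# quick labelled-cells tibble from a coordinate matrix
cells_from_xy <- function(xy, ids = seq_len(nrow(xy))) {
  tibble::tibble(cell_id = ids, x_um = xy[, 1], y_um = xy[, 2],
                 z_um = 0, labelled = TRUE)
}

# small config used across simulator tests; rates off unless asked for
small_config <- function(division_rate = 0, death_rate = 0, ...) {
  sim_config(
    domain_um = c(400, 400),
    start_age_days = 0, end_age_days = 10,
    density_per_mm2 = c(papillary = 400, reticular = 300, DWAT = 200),
    division_rate = division_rate, death_rate = death_rate,
    labels_per_region = 1, region_pitch_um = 100,
    ...
  )
}
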