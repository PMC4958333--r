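# Delimited-text IO with schema validation. All tables are comma-separated
# UTF-8 with a header row; columns carry unit suffixes in their names
# (µm -> `_um`, cm -> `_cm`, days -> `_days`, cells/mm^2 -> `_per_mm2`).

table_schemas <- list(
  measurements = list(
    cols = c(age_days = "numeric", sex = "character", length_cm = "numeric",
             width_cm = "numeric", dermis_depth_cm = "numeric"),
    no_na = c("age_days", "sex", "length_cm", "width_cm", "dermis_depth_cm")
  ),
  densities = list(
    cols = c(age_days = "numeric", layer = "character",
             rho_per_mm2 = "numeric", n_regions = "numeric"),
    no_na = c("age_days", "layer", "rho_per_mm2")
  ),
  cells = list(
    cols = c(cell_id = "numeric", x_um = "numeric", y_um = "numeric",
             z_um = "numeric", layer = "character", labelled = "logical"),
    no_na = c("cell_id", "x_um", "y_um")
  ),
  clone_calls = list(
    cols = c(cell_id = "numeric", clone_call = "numeric"),
    no_na = c("cell_id", "clone_call")
  ),
  wound_sections = list(
    cols = c(wound_id = "numeric", section_id = "numeric",
             n_new_hfs = "numeric"),
    no_na = c("wound_id", "section_id", "n_new_hfs")
  )
)

#' Read a validated pipeline table
#'
#' Reads a comma-separated UTF-8 table and validates it against one of the
#' package's schemas, reporting exactly which column is missing, wrongly
#' typed, or holds a disallowed missing value. A zero-row table with a
#' valid header is accepted.
#'
#' @param path File path.
#' @param schema One of `"measurements"`, `"densities"`, `"cells"`,
#'   `"clone_calls"`, `"wound_sections"`.
#' @return A validated tibble.
#' @export
read_table <- function(path, schema) {
  schema <- match.arg(schema, names(table_schemas))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_table(df, schema)
}

#' @rdname read_table
#' @param df A data frame to validate in place of a file.
#' @export
validate_table <- function(df, schema) {
  schema <- match.arg(schema, names(table_schemas))
  sc <- table_schemas[[schema]]
  missing <- setdiff(names(sc$cols), names(df))
  if (length(missing)) {
    stop(sprintf("%s table is missing column(s): %s", schema,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in names(sc$cols)) {
    want <- sc$cols[[col]]
    v <- df[[col]]
    ok <- switch(want,
                 numeric = is.numeric(v),
                 character = is.character(v) || is.factor(v),
                 logical = is.logical(v) || all(v %in% c(0, 1, NA)))
    if (nrow(df) > 0 && !ok) {
      stop(sprintf("%s table column `%s` must be %s", schema, col, want),
           call. = FALSE)
    }
    if (col %in% sc$no_na && anyNA(v)) {
      row <- which(is.na(v))[1]
      stop(sprintf("%s table column `%s` has a missing value (row %d)",
                   schema, col, row), call. = FALSE)
    }
    if (want == "numeric" && nrow(df) > 0 && any(is.nan(v))) {
      stop(sprintf("%s table column `%s` contains NaN", schema, col),
           call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

#' Write a pipeline table
#'
#' Validates against the schema and writes comma-separated UTF-8 with full
#' floating-point precision, so a write/read round trip reproduces the
#' input values exactly.
#'
#' @inheritParams read_table
#' @param df Table to write.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema) {
  df <- validate_table(df, schema)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_table
#' @export
read_measurements <- function(path) read_table(path, "measurements")

#' @rdname read_table
#' @export
read_densities <- function(path) read_table(path, "densities")

#' @rdname read_table
#' @export
read_cells <- function(path) read_table(path, "cells")

#' @rdname read_table
#' @export
read_wound_sections <- function(path) read_table(path, "wound_sections")

#' Write / read a simulator configuration as JSON
#'
#' @param config A [sim_config()].
#' @param path JSON file path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$density_per_mm2 <- as.list(x$density_per_mm2)  # keep layer names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_config(
    domain_um = x$domain_um,
    layers_um = tibble::as_tibble(x$layers_um),
    start_age_days = x$start_age_days,
    end_age_days = x$end_age_days,
    density_per_mm2 = unlist(x$density_per_mm2),
    division_rate = x$division_rate,
    death_rate = x$death_rate,
    division_mode = x$division_mode,
    n_rounds = x$n_rounds,
    expansion = tibble::as_tibble(x$expansion),
    label_time_days = x$label_time_days,
    labels_per_region = x$labels_per_region,
    region_pitch_um = x$region_pitch_um,
    daughter_radius_um = x$daughter_radius_um,
    step_days = x$step_days,
    seed = x$seed
  )
}

#' Provenance record for a run
#'
#' A small structured record identifying what produced an output: a hash of
#' the configuration, the seed, the package version and a timestamp.
#'
#' @param config Any R object describing the run configuration.
#' @param seed The seed used.
#' @return Named list suitable for `jsonlite::write_json()`.
#' @export
provenance_record <- function(config, seed) {
  list(
    config_hash = rlang::hash(config),
    seed = as.integer(seed),
    package = "dermclone",
    version = as.character(utils::packageVersion("dermclone")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}
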