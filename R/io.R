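#' Read and write the package's delimited tables
#'
#' All tables are comma-separated, dot-decimal, UTF-8, with a mandatory
#' header row, so that every writer's output is accepted bit-identically by
#' the corresponding reader. Readers validate the required columns and fail
#' with a clear message listing what is missing.
#'
#' Table shapes:
#' * tablet table — `material, weight_g, diameter_mm, thickness_mm, force_N,
#'   true_density_g_cm3`
#' * point table — `material, porosity, tensile_strength`
#' * profile table — `material, sigma0_MPa, k, eps_min, eps_max, n_points,
#'   n_excluded, rss`
#' * measured-mixture table — `mixture_id, porosity, tensile_strength`
#' * composition table — `mixture_id, material, volume_fraction`
#'
#' @param path File path.
#' @param data Data frame to write.
#' @return Readers return a tibble; writers return `data` invisibly.
#' @name compactmix_io
NULL

read_table_checked <- function(path, required, what) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    stop_compactmix("io", sprintf(
      "%s '%s' is missing required column(s): %s",
      what, path, paste(missing, collapse = ", ")))
  }
  out
}

#' @rdname compactmix_io
#' @export
read_tablet_table <- function(path) {
  read_table_checked(path, c("material", "weight_g", "diameter_mm",
                             "thickness_mm", "force_N", "true_density_g_cm3"),
                     "tablet table")
}

#' @rdname compactmix_io
#' @export
read_point_table <- function(path) {
  read_table_checked(path, c("material", "porosity", "tensile_strength"),
                     "point table")
}

#' @rdname compactmix_io
#' @export
read_profile_table <- function(path) {
  read_table_checked(path, c("material", "sigma0_MPa", "k"), "profile table")
}

#' @rdname compactmix_io
#' @export
read_mixture_table <- function(path) {
  read_table_checked(path, c("mixture_id", "porosity", "tensile_strength"),
                     "measured-mixture table")
}

#' @rdname compactmix_io
#' @export
read_composition_table <- function(path) {
  read_table_checked(path, c("mixture_id", "material", "volume_fraction"),
                     "composition table")
}

#' @rdname compactmix_io
#' @export
write_delim_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

#' @rdname compactmix_io
#' @export
write_profile_table <- function(data, path) write_delim_table(data, path)
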