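#' Read a per-field disector tally CSV
#'
#' Reads manual optical-disector field tallies for re-analysis. The file must
#' have columns `section`, `x`, `y`, `Q_minus` (nuclei counted in the field)
#' and `t_measured` (measured thickness, µm).
#'
#' @param path CSV path.
#' @return A `disector_tally` object built from the table: `sum_Q` is the sum
#'   of `Q_minus`, `sum_P` the number of field records, `t_bar` the mean
#'   measured thickness, and `per_section` the ordered per-section counts.
#' @export
read_field_tally_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("section", "x", "y", "Q_minus", "t_measured")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("missing column(s): ", toString(miss)))
  per_section <- df |>
    dplyr::group_by(section = .data$section) |>
    dplyr::summarise(Q = sum(.data$Q_minus), P = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$section)
  structure(
    list(
      cell_class = NA_character_,
      sum_Q = sum(df$Q_minus),
      sum_P = nrow(df),
      t_bar = mean(df$t_measured),
      fields = tibble::as_tibble(df),
      per_section = per_section,
      window = NULL
    ),
    class = "disector_tally"
  )
}

#' Read a 2-D point pattern CSV
#'
#' Reads a point pattern with columns `x_um` and `y_um` (or `x`, `y`). The
#' window defaults to the points' bounding box.
#'
#' @param path CSV path.
#' @param window Optional window `c(xmin, xmax, ymin, ymax)` in µm.
#' @return A [point_pattern()].
#' @export
read_point_pattern_csv <- function(path, window = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (all(c("x_um", "y_um") %in% names(df))) {
    df <- dplyr::rename(df, x = "x_um", y = "y_um")
  }
  if (!all(c("x", "y") %in% names(df))) {
    abort("expected columns x_um/y_um (or x/y)")
  }
  if (is.null(window)) window <- c(range(df$x), range(df$y))
  point_pattern(df, window)
}

#' Read per-section Cavalieri point counts from CSV
#'
#' Reads a table with columns `section_index` and `P` (points counted on the
#' section) and returns it ready for [cavalieri_volume()] given a grid.
#'
#' @param path CSV path.
#' @param grid A [point_grid()] supplying the area per point.
#' @return A tibble with `section_index`, `point_count` and `area`.
#' @export
read_point_counts_csv <- function(path, grid) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("section_index", "P") %in% names(df))) {
    abort("expected columns section_index and P")
  }
  tibble::tibble(
    section_index = df$section_index,
    point_count = as.integer(df$P),
    area = df$P * grid$area_per_point
  )
}
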