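#' Voronoi polygon areas of a point pattern
#'
#' Builds the Voronoi (Dirichlet) tessellation of the pattern's points inside
#' its rectangular window and returns one polygon area per retained generator.
#' Under `edge_policy = "exclude_boundary"` every polygon touching the window
#' edge (whose area is truncated by the window rather than by neighbouring
#' cells) is dropped; under `"clip_to_window"` all polygons are kept, clipped
#' to the window, so their areas sum exactly to the window area.
#'
#' @param pattern A [point_pattern()] with at least 4 points.
#' @param edge_policy `"exclude_boundary"` (default) or `"clip_to_window"`.
#' @return A tibble with columns `x`, `y` (generator), `area` (µm²) and
#'   `boundary` (logical; present under both policies, rows filtered under
#'   `exclude_boundary`).
#' @examples
#' pp <- rpp_poisson(100, seed = 1)
#' areas <- tessellate_areas(pp)
#' head(areas)
#' @export
tessellate_areas <- function(pattern,
                             edge_policy = c("exclude_boundary", "clip_to_window")) {
  edge_policy <- match.arg(edge_policy)
  stopifnot(inherits(pattern, "point_pattern"))
  pts <- pattern$points
  if (nrow(pts) < 4) abort("at least 4 points are required for a tessellation")
  if (sd(pts$x) == 0 || sd(pts$y) == 0) abort("points are collinear")
  dd <- deldir::deldir(pts$x, pts$y, rw = pattern$window, suppressMsge = TRUE)
  # a tile touches the window edge iff one of its Dirichlet segments was
  # clipped by the window (bp flags in the segment table)
  sg <- dd$dirsgs
  clipped <- sg$bp1 | sg$bp2
  edge_idx <- unique(c(sg$ind1[clipped], sg$ind2[clipped]))
  out <- tibble::tibble(
    x = dd$summary$x,
    y = dd$summary$y,
    area = dd$summary$dir.area,
    boundary = seq_len(nrow(dd$summary)) %in% edge_idx
  )
  if (edge_policy == "exclude_boundary") {
    out <- out[!out$boundary, ]
  }
  if (any(out$area <= 0)) out <- out[out$area > 0, ]
  out
}

#' Coefficient of variation of polygon areas, in percent
#'
#' `cv = sd(areas) / mean(areas) * 100` with the sample (n - 1) standard
#' deviation. Scale-free: multiplying all areas by a constant leaves it
#' unchanged.
#'
#' @param areas Numeric vector of polygon areas (µm²), length >= 2,
#'   positive mean.
#' @return CV in percent.
#' @examples
#' cv_percent(c(1, 3)) # 70.71
#' @export
cv_percent <- function(areas) {
  if (length(areas) < 2) abort("at least 2 areas are required")
  m <- mean(areas)
  if (m <= 0) abort("mean area must be > 0")
  sd(areas) / m * 100
}

#' Classify a spatial arrangement from the polygon-area CV
#'
#' Applies the CV bands used for Voronoi-based classification of cellular
#' arrangements: CV < 33% regular, 33-64% (closed band) random, > 64%
#' clustered.
#'
#' @param cv CV of Voronoi polygon areas, percent (vectorised).
#' @return Character vector: `"regular"`, `"random"` or `"clustered"`.
#' @examples
#' classify_distribution(c(32.27, 35.99, 70))
#' @export
classify_distribution <- function(cv) {
  if (any(cv < 0)) abort("`cv` must be >= 0")
  dplyr::case_when(
    cv < 33 ~ "regular",
    cv <= 64 ~ "random",
    TRUE ~ "clustered"
  )
}

#' Summarise the Voronoi tessellation of a point pattern
#'
#' Tessellates, computes the polygon-area mean and CV, and classifies the
#' arrangement.
#'
#' @inheritParams tessellate_areas
#' @return An object of class `voronoi_summary` with fields `n_polygons`,
#'   `mean_area`, `cv`, `classification` and `areas`.
#' @examples
#' voronoi_summary(rpp_poisson(200, seed = 1))
#' @export
voronoi_summary <- function(pattern,
                            edge_policy = c("exclude_boundary", "clip_to_window")) {
  edge_policy <- match.arg(edge_policy)
  tiles <- tessellate_areas(pattern, edge_policy)
  if (nrow(tiles) < 2) abort("fewer than 2 interior polygons; enlarge the pattern")
  cv <- cv_percent(tiles$area)
  structure(
    list(
      n_polygons = nrow(tiles),
      mean_area = mean(tiles$area),
      cv = cv,
      classification = classify_distribution(cv),
      areas = tiles$area,
      edge_policy = edge_policy
    ),
    class = "voronoi_summary"
  )
}

#' @export
print.voronoi_summary <- function(x, ...) {
  cat("<voronoi_summary>", x$n_polygons, "polygons, mean area =",
      format(x$mean_area, digits = 4), "µm², CV =", round(x$cv, 2), "% ->",
      x$classification, "\n")
  invisible(x)
}

#' @export
tidy.voronoi_summary <- function(x, ...) {
  tibble::tibble(n_polygons = x$n_polygons, mean_area = x$mean_area,
                 cv = x$cv, classification = x$classification)
}

#' @export
autoplot.voronoi_summary <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(area = object$areas), ggplot2::aes(x = .data$area)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::labs(x = "Voronoi polygon area (µm²)", y = "polygons",
                  subtitle = paste0("CV = ", round(object$cv, 1), "% (",
                                    object$classification, ")")) +
    ggplot2::theme_minimal()
}

#' Distribution of polygon areas over size bands
#'
#' Tallies polygon areas into half-open bands `[e1, e2), [e2, e3), ...` and
#' reports the percentage of polygons per band. The default bands include the
#' 1-50 µm² range used to describe left/right shifts of the polygon-area
#' distribution.
#'
#' @param areas Numeric vector of polygon areas (µm²).
#' @param band_edges Strictly increasing band edges; must cover all areas.
#' @return A tibble with columns `lower`, `upper` and `percent`
#'   (sums to 100).
#' @examples
#' polygon_area_histogram(c(10, 60), band_edges = c(1, 50, Inf))
#' @export
polygon_area_histogram <- function(areas,
                                   band_edges = c(0, 1, 50, 100, 250, 500, Inf)) {
  if (length(areas) == 0) abort("`areas` must be non-empty")
  if (any(diff(band_edges) <= 0)) abort("`band_edges` must be strictly increasing")
  if (any(areas < band_edges[1]) || any(areas >= band_edges[length(band_edges)] &
                                          is.finite(band_edges[length(band_edges)]))) {
    abort("`band_edges` must cover all areas")
  }
  bin <- cut(areas, band_edges, right = FALSE, include.lowest = FALSE)
  counts <- tabulate(bin, nbins = length(band_edges) - 1)
  tibble::tibble(
    lower = band_edges[-length(band_edges)],
    upper = band_edges[-1],
    percent = counts / length(areas) * 100
  )
}
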