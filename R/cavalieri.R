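#' Square point grid for Cavalieri point counting
#'
#' A square test grid with a uniformly random offset. Each test point carries
#' an area `a(p) = spacing^2`, so that a profile hit by `P` points has
#' estimated area `P * a(p)`. The offset is drawn once per ganglion and reused
#' across its sections, as in real point counting.
#'
#' @param spacing Grid spacing in µm.
#' @param seed Optional integer seed for the random offset.
#' @param offset Optional explicit offset `c(dx, dy)` in `[0, spacing)^2`.
#' @return An object of class `point_grid`.
#' @examples
#' g <- point_grid(65, seed = 1)
#' g$area_per_point
#' @export
point_grid <- function(spacing = 65, seed = NULL, offset = NULL) {
  if (spacing <= 0) abort("`spacing` must be > 0")
  if (is.null(offset)) {
    set_seed_if(seed)
    offset <- runif(2, 0, spacing)
  }
  if (any(offset < 0) || any(offset >= spacing)) {
    abort("`offset` must lie in [0, spacing)^2")
  }
  structure(list(spacing = spacing, area_per_point = spacing^2, offset = offset),
            class = "point_grid")
}

#' Planar regions for point counting
#'
#' Constructors for the two region types understood by [point_count_area()]:
#' an axis-aligned ellipse and a simple polygon.
#'
#' @param center Ellipse centre `c(x, y)`, µm.
#' @param semi_axes Ellipse semi-axes `c(a, b)`, µm (either may be 0 for an
#'   empty region).
#' @return A region object (a tagged list).
#' @export
region_ellipse <- function(center = c(0, 0), semi_axes) {
  stopifnot(length(center) == 2, length(semi_axes) == 2, all(semi_axes >= 0))
  structure(list(type = "ellipse", center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes)), class = "pc_region")
}

#' @rdname region_ellipse
#' @param x,y Polygon vertex coordinates (closed implicitly), µm.
#' @export
region_polygon <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  structure(list(type = "polygon", x = as.numeric(x), y = as.numeric(y)),
            class = "pc_region")
}

region_bbox <- function(region) {
  if (region$type == "ellipse") {
    c(region$center[1] - region$semi_axes[1], region$center[1] + region$semi_axes[1],
      region$center[2] - region$semi_axes[2], region$center[2] + region$semi_axes[2])
  } else {
    c(range(region$x), range(region$y))
  }
}

in_region <- function(x, y, region) {
  if (region$type == "ellipse") {
    if (any(region$semi_axes == 0)) return(rep(FALSE, length(x)))
    ((x - region$center[1]) / region$semi_axes[1])^2 +
      ((y - region$center[2]) / region$semi_axes[2])^2 <= 1
  } else {
    pracma::inpolygon(x, y, region$x, region$y, boundary = TRUE)
  }
}

region_shape_ratio <- function(region) {
  if (region$type == "ellipse") {
    a <- region$semi_axes[1]; b <- region$semi_axes[2]
    if (a <= 0 || b <= 0) return(NA_real_)
    ellipse_perimeter(a, b) / sqrt(pi * a * b)
  } else {
    n <- length(region$x)
    per <- sum(sqrt(diff(c(region$x, region$x[1]))^2 +
                      diff(c(region$y, region$y[1]))^2))
    ar <- abs(sum(region$x * c(region$y[-1], region$y[1]) -
                    c(region$x[-1], region$x[1]) * region$y)) / 2
    if (ar <= 0) return(NA_real_)
    per / sqrt(ar)
  }
}

#' Count grid points falling on a profile and estimate its area
#'
#' Applies the Cavalieri point-counting rule to one section profile: the
#' number of grid test points hitting the region is `P`, and the estimated
#' area is `P * a(p)`.
#'
#' @param region A [region_ellipse()] or [region_polygon()].
#' @param grid A [point_grid()].
#' @return A one-row tibble with columns `point_count` and `area` (µm²).
#' @examples
#' pg <- point_grid(10, offset = c(5, 5))
#' point_count_area(region_polygon(c(0, 100, 100, 0), c(0, 0, 100, 100)), pg)
#' @export
point_count_area <- function(region, grid) {
  stopifnot(inherits(region, "pc_region"), inherits(grid, "point_grid"))
  bb <- region_bbox(region)
  s <- grid$spacing
  ix <- seq(ceiling((bb[1] - grid$offset[1]) / s), floor((bb[2] - grid$offset[1]) / s))
  iy <- seq(ceiling((bb[3] - grid$offset[2]) / s), floor((bb[4] - grid$offset[2]) / s))
  if (length(ix) == 0 || length(iy) == 0 || bb[2] <= bb[1] || bb[4] <= bb[3]) {
    return(tibble::tibble(point_count = 0L, area = 0))
  }
  pts <- expand.grid(x = grid$offset[1] + ix * s, y = grid$offset[2] + iy * s)
  P <- sum(in_region(pts$x, pts$y, region))
  tibble::tibble(point_count = as.integer(P), area = P * grid$area_per_point)
}

#' Systematic uniform random sampling of sections
#'
#' Chooses a sampling period `k` so that every `k`-th section, starting from a
#' uniformly random start in `1..k`, yields a number of sampled sections
#' within `target_range` (when feasible), and returns the sampled indices.
#'
#' @param n_total Total number of serial sections.
#' @param target_range Desired `c(min, max)` number of sampled sections.
#' @param k Optional explicit period, overriding the automatic choice.
#' @param seed Optional integer seed for the random start.
#' @return A list with `indices`, `k` and `start` (0-based offset).
#' @examples
#' sample_sections_systematic(40, k = 4, seed = 1)$indices
#' @export
sample_sections_systematic <- function(n_total, target_range = c(8, 12),
                                       k = NULL, seed = NULL) {
  if (n_total < 1) abort("`n_total` must be >= 1")
  set_seed_if(seed)
  lo <- target_range[1]; hi <- target_range[2]
  if (n_total < lo) {
    warn(paste0("only ", n_total, " sections available; sampling all of them"))
    return(list(indices = seq_len(n_total), k = 1L, start = 0L))
  }
  if (is.null(k)) {
    ks <- seq_len(n_total)
    feasible <- floor(n_total / ks) >= lo & ceiling(n_total / ks) <= hi
    if (any(feasible)) {
      cand <- ks[feasible]
      k <- cand[which.min(abs(n_total / cand - mean(target_range)))]
    } else {
      k <- max(1L, round(n_total / mean(target_range)))
    }
  }
  k <- as.integer(k)
  start <- sample.int(k, 1) - 1L
  list(indices = seq(1L + start, n_total, by = k), k = k, start = start)
}

#' Gundersen-Jensen coefficient of error for Cavalieri point counts
#'
#' Predicts the relative standard error of a Cavalieri estimate from the
#' ordered per-section point counts, using the systematic-sampling variance
#' estimator for smoothness class m = 1,
#' \deqn{Var_{SURS} = (3 (C_0 - \nu) - 4 C_1 + C_2) / 240,}
#' with \eqn{C_q = \sum_i P_i P_{i+q}}, plus the point-counting noise
#' (nugget) \eqn{\nu = 0.0724 (\bar B/\sqrt{\bar A}) \sqrt{n \sum P}} where
#' \eqn{\bar B/\sqrt{\bar A}} is the mean profile boundary-to-root-area shape
#' ratio. The CE is \eqn{\sqrt{\nu + Var_{SURS}} / \sum P}.
#'
#' @param point_counts Ordered per-section point counts.
#' @param shape_ratio Mean profile shape ratio \eqn{\bar B/\sqrt{\bar A}};
#'   the default is the value for circular profiles, \eqn{2\sqrt{\pi}}.
#' @param nugget Include the point-counting noise term? Set `FALSE` to obtain
#'   the pure systematic-sampling component.
#' @return The coefficient of error (unitless, >= 0).
#' @examples
#' gundersen_ce_volume(c(10, 12, 11, 13, 12, 11, 12, 13, 11, 12), nugget = FALSE)
#' @export
gundersen_ce_volume <- function(point_counts, shape_ratio = 2 * sqrt(pi),
                                nugget = TRUE) {
  P <- as.numeric(point_counts)
  n <- length(P)
  if (n < 3) abort("the CE estimator requires at least 3 sampled sections")
  sP <- sum(P)
  if (sP <= 0) abort("total point count must be positive")
  C0 <- sum(P * P)
  C1 <- sum(P[-n] * P[-1])
  C2 <- sum(P[seq_len(n - 2)] * P[seq(3, n)])
  nu <- if (nugget) 0.0724 * shape_ratio * sqrt(n * sP) else 0
  var_surs <- max(0, (3 * (C0 - nu) - 4 * C1 + C2) / 240)
  sqrt(var_surs + nu) / sP
}

#' Cavalieri volume from per-section area estimates
#'
#' Applies the Cavalieri principle `V = sum(A) * d`, where `d` is the distance
#' between sampled section planes, and attaches the Gundersen-Jensen CE when
#' point counts are available.
#'
#' @param area_estimates A data frame with column `area` (µm²) and optionally
#'   `point_count`, one row per sampled section in order.
#' @param d Distance between sampled sections, µm (`k * BA`).
#' @param shape_ratio Profile shape ratio for the CE nugget; see
#'   [gundersen_ce_volume()].
#' @param nugget Include the point-counting noise term in the CE?
#' @return An object of class `volume_estimate` with fields `sum_area`,
#'   `d`, `volume` (µm³), `ce` and `n_sections`.
#' @examples
#' tbl <- tibble::tibble(area = c(1.0, 1.2, 0.8) * 1e6)
#' cavalieri_volume(tbl, d = 300)$volume
#' @export
cavalieri_volume <- function(area_estimates, d, shape_ratio = 2 * sqrt(pi),
                             nugget = TRUE) {
  area_estimates <- tibble::as_tibble(area_estimates)
  if (nrow(area_estimates) == 0) abort("`area_estimates` must be non-empty")
  if (d <= 0) abort("`d` must be > 0")
  sum_area <- sum(area_estimates$area)
  ce <- NA_real_
  if ("point_count" %in% names(area_estimates) &&
      nrow(area_estimates) >= 3 && sum(area_estimates$point_count) > 0) {
    ce <- gundersen_ce_volume(area_estimates$point_count, shape_ratio, nugget)
  }
  structure(
    list(sum_area = sum_area, d = d, volume = sum_area * d, ce = ce,
         n_sections = nrow(area_estimates), area_estimates = area_estimates),
    class = "volume_estimate"
  )
}

#' Estimate a ganglion's volume from a virtual section stack
#'
#' Full Cavalieri pipeline on a [section_phantom()] stack: systematically
#' sample 8-12 sections with a random start, point-count each sampled
#' section's boundary ellipse with a random-offset square grid (one offset per
#' ganglion), and apply `V = sum(A) * d` with `d = k * BA`. The CE uses the
#' mean analytic shape ratio of the sampled profiles.
#'
#' @param stack A `section_stack`.
#' @param grid Optional [point_grid()]; by default a grid with `spacing` and a
#'   random offset is created.
#' @param spacing Grid spacing (µm) used when `grid` is not supplied.
#' @param target_sections Desired range of sampled section counts.
#' @param seed Optional integer seed (random start and grid offset).
#' @param nugget Include the point-counting noise term in the CE?
#' @return A `volume_estimate` with additional fields `sampled_sections`
#'   and `k`.
#' @export
estimate_volume <- function(stack, grid = NULL, spacing = 65,
                            target_sections = c(8, 12), seed = NULL,
                            nugget = TRUE) {
  stopifnot(inherits(stack, "section_stack"))
  set_seed_if(seed)
  samp <- sample_sections_systematic(stack$n_sections, target_sections)
  if (is.null(grid)) grid <- point_grid(spacing)
  sec <- stack$sections[samp$indices, ]
  regions <- purrr::map2(sec$ellipse_a, sec$ellipse_b,
                         ~region_ellipse(c(0, 0), c(.x, .y)))
  counts <- purrr::map_dfr(regions, point_count_area, grid = grid)
  ratios <- vapply(regions, region_shape_ratio, numeric(1))
  shape_ratio <- mean(ratios, na.rm = TRUE)
  if (!is.finite(shape_ratio)) shape_ratio <- 2 * sqrt(pi)
  est <- cavalieri_volume(
    tibble::tibble(section_index = samp$indices,
                   point_count = counts$point_count, area = counts$area),
    d = samp$k * stack$BA, shape_ratio = shape_ratio, nugget = nugget
  )
  est$sampled_sections <- samp$indices
  est$k <- samp$k
  est$grid <- grid
  est
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat("<volume_estimate> V =", format(x$volume, digits = 5), "µm³ (",
      x$n_sections, "sections, d =", x$d, "µm )\n")
  cat("  sum A =", format(x$sum_area, digits = 5), "µm², CE =",
      ifelse(is.na(x$ce), "NA", format(x$ce, digits = 3)), "\n")
  invisible(x)
}

#' @export
tidy.volume_estimate <- function(x, ...) {
  tibble::tibble(
    n_sections = x$n_sections, d = x$d, sum_area = x$sum_area,
    volume = x$volume, ce = x$ce
  )
}
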