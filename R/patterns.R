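#' Planar point pattern with an observation window
#'
#' A minimal container for a 2-D point pattern: a tibble of coordinates (µm)
#' and a rectangular observation window `c(xmin, xmax, ymin, ymax)`.
#'
#' @param points A data frame with numeric columns `x` and `y`.
#' @param window Numeric length-4 vector `c(xmin, xmax, ymin, ymax)`.
#' @return An object of class `point_pattern`.
#' @examples
#' pp <- point_pattern(data.frame(x = runif(10), y = runif(10)), c(0, 1, 0, 1))
#' n_points(pp)
#' @export
point_pattern <- function(points, window) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("x", "y") %in% names(points)))
  window <- as.numeric(window)
  if (length(window) != 4 || window[1] >= window[2] || window[3] >= window[4]) {
    abort("`window` must be c(xmin, xmax, ymin, ymax) with positive extents")
  }
  inside <- points$x >= window[1] & points$x <= window[2] &
    points$y >= window[3] & points$y <= window[4]
  if (!all(inside)) {
    warn(paste0(sum(!inside), " point(s) outside the window were dropped"))
    points <- points[inside, ]
  }
  structure(list(points = points[, c("x", "y")], window = window),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat("<point_pattern>", nrow(x$points), "points in [",
      x$window[1], ",", x$window[2], "] x [", x$window[3], ",", x$window[4], "]\n")
  invisible(x)
}

#' Number of points in a pattern
#' @param pattern A [point_pattern()].
#' @return Integer count.
#' @export
n_points <- function(pattern) nrow(pattern$points)

window_area <- function(window) {
  (window[2] - window[1]) * (window[4] - window[3])
}

#' Crop a point pattern to a smaller window
#'
#' Keeps the points falling inside `window` and replaces the observation
#' window. Used to restrict elliptical sections to an interior rectangle
#' before tessellation so that tissue-boundary effects do not masquerade as
#' spatial pattern.
#'
#' @param pattern A [point_pattern()].
#' @param window New window `c(xmin, xmax, ymin, ymax)`.
#' @return A [point_pattern()].
#' @export
crop_pattern <- function(pattern, window) {
  p <- pattern$points
  keep <- p$x >= window[1] & p$x <= window[2] &
    p$y >= window[3] & p$y <= window[4]
  point_pattern(p[keep, ], window)
}

#' Simulate a binomial (complete spatial randomness) pattern
#'
#' `n` independent uniform points in the window: the finite-n version of the
#' homogeneous Poisson process used as the "random" reference pattern.
#'
#' @param n Number of points.
#' @param window Observation window `c(xmin, xmax, ymin, ymax)`.
#' @param seed Optional integer seed.
#' @return A [point_pattern()].
#' @export
rpp_poisson <- function(n, window = c(0, 1000, 0, 1000), seed = NULL) {
  set_seed_if(seed)
  point_pattern(
    tibble::tibble(x = runif(n, window[1], window[2]),
                   y = runif(n, window[3], window[4])),
    window
  )
}

#' Simulate a jittered square-lattice (regular) pattern
#'
#' Square lattice with pitch chosen so about `n` points fill the window, with
#' independent Gaussian positional jitter of `jitter_frac` times the pitch.
#'
#' @param n Target number of points.
#' @param window Observation window.
#' @param jitter_frac Jitter sd as a fraction of the lattice pitch.
#' @param seed Optional integer seed.
#' @return A [point_pattern()].
#' @export
rpp_lattice <- function(n, window = c(0, 1000, 0, 1000), jitter_frac = 0.05,
                        seed = NULL) {
  set_seed_if(seed)
  pitch <- sqrt(window_area(window) / n)
  off <- runif(2, 0, pitch)
  gx <- seq(window[1] - pitch, window[2] + pitch, by = pitch) + off[1]
  gy <- seq(window[3] - pitch, window[4] + pitch, by = pitch) + off[2]
  g <- expand.grid(x = gx, y = gy)
  g$x <- g$x + rnorm(nrow(g), 0, jitter_frac * pitch)
  g$y <- g$y + rnorm(nrow(g), 0, jitter_frac * pitch)
  keep <- g$x >= window[1] & g$x <= window[2] &
    g$y >= window[3] & g$y <= window[4]
  point_pattern(g[keep, ], window)
}

#' Simulate a Thomas cluster-process pattern
#'
#' Poisson number of parents uniform in the window, each with a Poisson
#' number of offspring scattered with isotropic Gaussian spread
#' `sd_frac * min(window side)`. Offspring falling outside the window are
#' discarded.
#'
#' @param n_parents Expected number of cluster parents.
#' @param offspring_mean Expected offspring per parent.
#' @param window Observation window.
#' @param sd_frac Cluster spread as a fraction of the shorter window side.
#' @param seed Optional integer seed.
#' @return A [point_pattern()].
#' @export
rpp_thomas <- function(n_parents = 25, offspring_mean = 20,
                       window = c(0, 1000, 0, 1000), sd_frac = 0.02,
                       seed = NULL) {
  set_seed_if(seed)
  np <- max(1L, rpois(1, n_parents))
  px <- runif(np, window[1], window[2])
  py <- runif(np, window[3], window[4])
  n_off <- rpois(np, offspring_mean)
  idx <- rep(seq_len(np), n_off)
  sdev <- sd_frac * min(window[2] - window[1], window[4] - window[3])
  x <- px[idx] + rnorm(length(idx), 0, sdev)
  y <- py[idx] + rnorm(length(idx), 0, sdev)
  keep <- x >= window[1] & x <= window[2] & y >= window[3] & y <= window[4]
  point_pattern(tibble::tibble(x = x[keep], y = y[keep]), window)
}

#' @export
autoplot.point_pattern <- function(object, ...) {
  w <- object$window
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::coord_fixed(xlim = w[1:2], ylim = w[3:4], expand = FALSE) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
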