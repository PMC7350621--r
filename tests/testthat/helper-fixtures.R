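# Shared fixtures and independent oracles. Everything here is built in code;
# oracles deliberately use naive/brute-force formulations, independent of the
# package's implementation paths.

# A small single-group config for fast simulations.
small_config <- function(n_neurons = 2000, glia = 1, pattern = "random", seed = 1) {
  study_config(
    groups = "control",
    neuron_count_true = n_neurons,
    glia_per_neuron_mean = glia,
    pattern = c(control = pattern),
    apoptosis_prob = c(control = 0.05),
    effect_multipliers = list(control = c(volume = 1, neuron = 1, glia = 1)),
    seed = seed
  )
}

# Section stack carrying only geometry (no cells); for volume pipelines.
geometry_stack <- function(seed = 1) {
  cfg <- small_config(n_neurons = 0, glia = 0, seed = seed)
  ph <- generate_phantom(cfg, "control")
  suppressWarnings(section_phantom(ph, seed = seed + 1000))
}

# Hand-rolled stack constructor for rule-level disector tests.
manual_stack <- function(profiles, ellipse_a = 100, ellipse_b = 100, t = 23,
                         BA = 25) {
  n_sec <- max(1L, suppressWarnings(max(profiles$section, -Inf)))
  structure(
    list(
      BA = BA, shrinkage_factor = t / BA, semi_axes = c(ellipse_a, ellipse_b, BA * n_sec / 2),
      n_sections = n_sec,
      sections = tibble::tibble(
        section = seq_len(n_sec),
        z_lo = (seq_len(n_sec) - 1) * BA,
        z_mid = (seq_len(n_sec) - 0.5) * BA,
        ellipse_a = ellipse_a, ellipse_b = ellipse_b, t = t
      ),
      profiles = profiles
    ),
    class = "section_stack"
  )
}

manual_profiles <- function(x, y, z_depth, radius = 5, cell_class = "neuron",
                            section = 1L) {
  n <- length(x)
  tibble::tibble(
    cell_id = seq_len(n), section = rep(as.integer(section), length.out = n),
    x = x, y = y, radius = rep(radius, length.out = n),
    cell_class = rep(cell_class, length.out = n),
    apoptotic = FALSE, z_depth = rep(z_depth, length.out = n)
  )
}

# Brute-force Gundersen-Jensen m = 1 variance of a systematic sample,
# written as explicit loops (the spreadsheet oracle).
surs_var_oracle <- function(P, nu = 0) {
  n <- length(P)
  C0 <- 0; C1 <- 0; C2 <- 0
  for (i in seq_len(n)) C0 <- C0 + P[i] * P[i]
  for (i in seq_len(n - 1)) C1 <- C1 + P[i] * P[i + 1]
  for (i in seq_len(n - 2)) C2 <- C2 + P[i] * P[i + 2]
  (3 * (C0 - nu) - 4 * C1 + C2) / 240
}

# Rasterized nearest-generator areas: the pixel-counting oracle for Voronoi
# tile areas inside a rectangular window.
raster_voronoi_areas <- function(pattern, res = 1) {
  w <- pattern$window
  xs <- seq(w[1] + res / 2, w[2] - res / 2, by = res)
  ys <- seq(w[3] + res / 2, w[4] - res / 2, by = res)
  px <- pattern$points$x
  py <- pattern$points$y
  counts <- integer(length(px))
  for (yy in ys) {
    d2 <- outer(xs, px, function(a, b) (a - b)^2) +
      rep((yy - py)^2, each = length(xs))
    nn <- max.col(-matrix(d2, nrow = length(xs)))
    counts <- counts + tabulate(nn, nbins = length(px))
  }
  counts * res^2
}

# Variance/mean ratio of counts over a k^3 cubic partition of the inscribed
# box of a phantom's ellipsoid: a dispersion index for 3-D point patterns.
quadrat_vmr <- function(phantom, k = 6) {
  semi <- phantom$semi_axes
  half <- semi / sqrt(3)
  cells <- phantom$cells[phantom$cells$cell_class == "neuron", ]
  inside <- abs(cells$x) < half[1] & abs(cells$y) < half[2] & abs(cells$z) < half[3]
  cells <- cells[inside, ]
  bx <- findInterval(cells$x, seq(-half[1], half[1], length.out = k + 1),
                     rightmost.closed = TRUE)
  by <- findInterval(cells$y, seq(-half[2], half[2], length.out = k + 1),
                     rightmost.closed = TRUE)
  bz <- findInterval(cells$z, seq(-half[3], half[3], length.out = k + 1),
                     rightmost.closed = TRUE)
  counts <- tabulate((bx - 1) * k * k + (by - 1) * k + bz, nbins = k^3)
  var(counts) / mean(counts)
}
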