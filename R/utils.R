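# Internal helpers shared across the package.

# Deterministic per-task seed derived from a base seed and integer keys.
# Kept below 2^31 - 1 so set.seed() always accepts it.
derive_seed <- function(seed, ...) {
  keys <- as.double(c(...))
  primes <- c(1000003, 10007, 7919, 101, 13)[seq_along(keys)]
  as.integer((as.double(seed) + sum(keys * primes)) %% 2147483629)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

ellipsoid_volume <- function(semi_axes) {
  4 / 3 * pi * prod(semi_axes)
}

# Ramanujan's approximation; exact enough for shape ratios.
ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

# Uniform points inside an axis-aligned ellipsoid centred at the origin.
runif_ellipsoid <- function(n, semi_axes) {
  if (n == 0) {
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  out <- matrix(NA_real_, nrow = 0, ncol = 3)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) / (pi / 6) * 1.2) + 10
    p <- cbind(
      runif(m, -semi_axes[1], semi_axes[1]),
      runif(m, -semi_axes[2], semi_axes[2]),
      runif(m, -semi_axes[3], semi_axes[3])
    )
    keep <- (p[, 1] / semi_axes[1])^2 + (p[, 2] / semi_axes[2])^2 +
      (p[, 3] / semi_axes[3])^2 <= 1
    out <- rbind(out, p[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  out
}

inside_ellipsoid <- function(x, y, z, semi_axes) {
  (x / semi_axes[1])^2 + (y / semi_axes[2])^2 + (z / semi_axes[3])^2 <= 1
}

cell_classes <- c("neuron", "satellite_glia")
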