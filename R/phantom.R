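#' Generate a ground-truthed ganglion phantom
#'
#' Simulates the 3-D cell population of one animal's ganglion: neuron somata
#' arranged inside an ellipsoid according to the group's spatial pattern
#' (jittered lattice, homogeneous Poisson, or Thomas cluster process),
#' satellite glial cells attached around neurons, log-normal nucleus radii,
#' and i.i.d. Bernoulli apoptosis labels. The group's effect multipliers scale
#' the true volume (via the semi-axes) and the expected cell counts, and the
#' realised counts carry Poisson noise.
#'
#' The phantom is deterministic given `(config$seed, group, animal_index)`.
#'
#' @param config A [study_config()].
#' @param group A group label present in `config$groups`.
#' @param animal_index Integer animal index within the group.
#'
#' @return An object of class `ganglion_phantom` with elements `semi_axes`,
#'   `cells` (a tibble with columns `cell_id`, `x`, `y`, `z`, `radius`,
#'   `cell_class`, `apoptotic`), `true_volume` (µm³), and `true_counts`
#'   (tibble of per-class tallies).
#' @examples
#' cfg <- study_config(neuron_count_true = 500, glia_per_neuron_mean = 1)
#' ph <- generate_phantom(cfg, "control")
#' ph$true_counts
#' @export
generate_phantom <- function(config, group, animal_index = 1L) {
  validate_study_config(config)
  if (!group %in% config$groups) {
    abort(paste0("unknown group label: '", group, "'"))
  }
  gi <- match(group, config$groups)
  set.seed(derive_seed(config$seed, gi, animal_index, 1))

  mult <- config$effect_multipliers[[group]]
  semi <- config$ellipsoid_semi_axes * mult[["volume"]]^(1 / 3)
  n_neuron_target <- config$neuron_count_true * mult[["neuron"]]
  if (is.na(n_neuron_target) || n_neuron_target < 0) {
    abort("non-positive neuron count after group scaling")
  }

  neurons <- place_neurons(n_neuron_target, semi, config$pattern[[group]],
                           config$lattice_jitter_frac, config$cluster_params)
  n_n <- nrow(neurons)

  glia_target <- config$neuron_count_true * config$glia_per_neuron_mean * mult[["glia"]]
  n_g <- if (n_n == 0) 0L else rpois(1, glia_target)

  r_n <- rlnorm(n_n, config$neuron_radius_log[["meanlog"]],
                config$neuron_radius_log[["sdlog"]])
  r_g <- rlnorm(n_g, config$glia_radius_log[["meanlog"]],
                config$glia_radius_log[["sdlog"]])

  glia <- place_glia(n_g, neurons, r_n, r_g, semi)

  cells <- tibble::tibble(
    cell_id = seq_len(n_n + nrow(glia)),
    x = c(neurons[, "x"], glia$x),
    y = c(neurons[, "y"], glia$y),
    z = c(neurons[, "z"], glia$z),
    radius = c(r_n, glia$radius),
    cell_class = c(rep("neuron", n_n), rep("satellite_glia", nrow(glia)))
  )
  p <- config$apoptosis_prob[[group]]
  cells$apoptotic <- as.logical(rbinom(nrow(cells), 1, p))

  structure(
    list(
      group = group,
      animal_index = as.integer(animal_index),
      pattern = config$pattern[[group]],
      semi_axes = semi,
      cells = cells,
      true_volume = ellipsoid_volume(semi),
      true_counts = dplyr::count(cells, .data$cell_class, name = "n"),
      config = config
    ),
    class = "ganglion_phantom"
  )
}

place_neurons <- function(n_target, semi, pattern, jitter_frac, cluster_params) {
  empty <- matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  if (n_target <= 0) {
    return(empty)
  }
  if (pattern == "random") {
    n <- rpois(1, n_target)
    return(runif_ellipsoid(n, semi))
  }
  if (pattern == "regular") {
    pitch <- (ellipsoid_volume(semi) / n_target)^(1 / 3)
    offs <- runif(3, 0, pitch)
    gx <- seq(-semi[1] - pitch, semi[1] + pitch, by = pitch) + offs[1]
    gy <- seq(-semi[2] - pitch, semi[2] + pitch, by = pitch) + offs[2]
    gz <- seq(-semi[3] - pitch, semi[3] + pitch, by = pitch) + offs[3]
    g <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    g <- g + matrix(rnorm(length(g), 0, jitter_frac * pitch), ncol = 3)
    keep <- inside_ellipsoid(g[, 1], g[, 2], g[, 3], semi)
    g <- g[keep, , drop = FALSE]
    colnames(g) <- c("x", "y", "z")
    return(g)
  }
  # clustered: Thomas process restricted to the ellipsoid; offspring intensity
  # rescaled so the expected total matches the group truth
  n_par <- max(1L, rpois(1, cluster_params$n_parents))
  parents <- runif_ellipsoid(n_par, semi)
  n_off <- rpois(n_par, n_target / n_par)
  idx <- rep(seq_len(n_par), n_off)
  if (length(idx) == 0) return(empty)
  pts <- parents[idx, , drop = FALSE] +
    matrix(rnorm(3 * length(idx), 0, cluster_params$sd), ncol = 3)
  keep <- inside_ellipsoid(pts[, 1], pts[, 2], pts[, 3], semi)
  pts <- pts[keep, , drop = FALSE]
  colnames(pts) <- c("x", "y", "z")
  pts
}

# Satellite glia hug neuron somata: random parent neuron, radial offset just
# outside the neuron nucleus, resampled (a few rounds) if outside the ellipsoid.
place_glia <- function(n_g, neurons, r_n, r_g, semi) {
  if (n_g == 0 || nrow(neurons) == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          radius = numeric(0)))
  }
  parent <- sample.int(nrow(neurons), n_g, replace = TRUE)
  pos <- matrix(NA_real_, n_g, 3)
  todo <- seq_len(n_g)
  for (round in 1:30) {
    if (!length(todo)) break
    m <- length(todo)
    u <- matrix(rnorm(3 * m), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    dist <- r_n[parent[todo]] + r_g[todo] + rexp(m, rate = 0.5)
    cand <- neurons[parent[todo], , drop = FALSE] + u * dist
    ok <- inside_ellipsoid(cand[, 1], cand[, 2], cand[, 3], semi)
    pos[todo[ok], ] <- cand[ok, , drop = FALSE]
    todo <- todo[!ok]
  }
  if (length(todo)) {
    # stubborn edge cases sit at their parent neuron's centre offset inward
    pos[todo, ] <- neurons[parent[todo], , drop = FALSE] * 0.99
  }
  tibble::tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3], radius = r_g)
}

#' @export
print.ganglion_phantom <- function(x, ...) {
  cat("<ganglion_phantom>", x$group, "animal", x$animal_index, "\n")
  cat("  semi-axes (µm):", toString(round(x$semi_axes, 1)),
      "| true volume:", format(x$true_volume, digits = 4), "µm³\n")
  cat("  pattern:", x$pattern, "| cells:",
      paste(x$true_counts$cell_class, x$true_counts$n, collapse = ", "), "\n")
  invisible(x)
}

#' Virtually section a ganglion phantom
#'
#' Cuts the phantom into serial sections of nominal thickness `BA` (the block
#' advance) perpendicular to the longitudinal axis, starting at the rostral
#' pole. Each cell is assigned to the unique section containing the leading
#' (top) edge of its nucleus — the optical-disector unique counting event —
#' and its focal depth within the section is rescaled by the section's
#' measured thickness, which is shrunken relative to `BA` by
#' `shrinkage_factor` with small per-section noise.
#'
#' @param phantom A [generate_phantom()] result.
#' @param BA Block advance of the microtome, µm.
#' @param shrinkage_factor Ratio of mean measured thickness to block advance
#'   (in (0, 1\]); the default 0.92 turns 25-µm cuts into ~23-µm sections.
#' @param seed Optional integer seed for the per-section thickness noise.
#' @param thickness_cv Coefficient of variation of measured thickness across
#'   sections.
#'
#' @return An object of class `section_stack`: `BA`, `semi_axes`,
#'   `n_sections`, `sections` (tibble: `section`, `z_lo`, `z_mid`,
#'   `ellipse_a`, `ellipse_b`, `t`) and `profiles` (tibble: `cell_id`,
#'   `section`, `x`, `y`, `radius`, `cell_class`, `apoptotic`, `z_depth` with
#'   0 <= `z_depth` <= `t`).
#' @examples
#' cfg <- study_config(neuron_count_true = 500, glia_per_neuron_mean = 0)
#' st <- section_phantom(generate_phantom(cfg, "control"), seed = 1)
#' st$n_sections
#' @export
section_phantom <- function(phantom, BA = 25, shrinkage_factor = 0.92,
                            seed = NULL, thickness_cv = 0.02) {
  stopifnot(inherits(phantom, "ganglion_phantom"))
  if (BA <= 0) abort("`BA` must be > 0")
  if (shrinkage_factor <= 0 || shrinkage_factor > 1) {
    abort("`shrinkage_factor` must be in (0, 1]")
  }
  set_seed_if(seed)
  semi <- phantom$semi_axes
  c_ax <- semi[3]
  extent <- 2 * c_ax
  n_sec <- max(1L, as.integer(ceiling(extent / BA - 1e-9)))
  z0 <- -c_ax

  z_mid <- z0 + (seq_len(n_sec) - 0.5) * BA
  s <- sqrt(pmax(0, 1 - (z_mid / c_ax)^2))
  t_meas <- shrinkage_factor * BA * (1 + rnorm(n_sec, 0, thickness_cv))
  t_meas <- pmin(pmax(t_meas, 0.5 * shrinkage_factor * BA), BA)
  sections <- tibble::tibble(
    section = seq_len(n_sec),
    z_lo = z0 + (seq_len(n_sec) - 1) * BA,
    z_mid = z_mid,
    ellipse_a = semi[1] * s,
    ellipse_b = semi[2] * s,
    t = t_meas
  )

  cells <- phantom$cells
  if (nrow(cells) == 0) {
    warn("empty phantom: returning a section stack with no profiles")
    profiles <- tibble::tibble(
      cell_id = integer(0), section = integer(0), x = numeric(0),
      y = numeric(0), radius = numeric(0), cell_class = character(0),
      apoptotic = logical(0), z_depth = numeric(0)
    )
  } else {
    z_lead <- cells$z - cells$radius
    idx <- pmin(pmax(floor((z_lead - z0) / BA) + 1, 1L), n_sec)
    z_within <- pmin(pmax(z_lead - z0 - (idx - 1) * BA, 0), BA * (1 - 1e-12))
    profiles <- tibble::tibble(
      cell_id = cells$cell_id,
      section = as.integer(idx),
      x = cells$x,
      y = cells$y,
      radius = cells$radius,
      cell_class = cells$cell_class,
      apoptotic = cells$apoptotic,
      z_depth = z_within / BA * t_meas[idx]
    )
  }

  structure(
    list(
      BA = BA,
      shrinkage_factor = shrinkage_factor,
      semi_axes = semi,
      n_sections = n_sec,
      sections = sections,
      profiles = profiles
    ),
    class = "section_stack"
  )
}

#' @export
print.section_stack <- function(x, ...) {
  cat("<section_stack>", x$n_sections, "sections, BA =", x$BA, "µm, mean t =",
      round(mean(x$sections$t), 2), "µm\n")
  cat("  profiles:", nrow(x$profiles), "\n")
  invisible(x)
}

#' Extract a 2-D point pattern from one section
#'
#' Returns the in-plane coordinates of one cell class in one section, together
#' with the section's bounding window, optionally restricted to a focal-depth
#' range within the measured thickness.
#'
#' @param stack A [section_phantom()] result.
#' @param section_index Section number (1-based).
#' @param cell_class `"neuron"` or `"satellite_glia"`.
#' @param depth_range Optional `c(lo, hi)` focal-depth window in µm;
#'   profiles with `lo <= z_depth < hi` are kept.
#'
#' @return A [point_pattern()] whose window is the bounding box of the
#'   section's boundary ellipse.
#' @export
extract_section_points <- function(stack, section_index,
                                   cell_class = "neuron", depth_range = NULL) {
  stopifnot(inherits(stack, "section_stack"))
  if (length(section_index) != 1 || section_index < 1 ||
      section_index > stack$n_sections) {
    abort("`section_index` out of range")
  }
  cl <- match.arg(cell_class, cell_classes)
  sec <- stack$sections[section_index, ]
  pr <- stack$profiles[stack$profiles$section == section_index &
                         stack$profiles$cell_class == cl, ]
  if (!is.null(depth_range)) {
    pr <- pr[pr$z_depth >= depth_range[1] & pr$z_depth < depth_range[2], ]
  }
  # window covers the mid-plane ellipse and every profile (cells near the
  # section faces can lie slightly outside the mid-plane boundary)
  half_a <- max(sec$ellipse_a, if (nrow(pr)) max(abs(pr$x)) else 0, 1e-6)
  half_b <- max(sec$ellipse_b, if (nrow(pr)) max(abs(pr$y)) else 0, 1e-6)
  point_pattern(tibble::tibble(x = pr$x, y = pr$y),
                window = c(-half_a, half_a, -half_b, half_b))
}

#' Extract the densest focal slab of a section as a 2-D pattern
#'
#' Emulates focusing a thick section on its most cell-rich optical plane: the
#' focal-depth window of width `thickness` (default 10 µm, about one soma
#' diameter) containing the most profiles of the requested class is selected,
#' and the profiles inside it are returned as a point pattern. Used for
#' Voronoi analysis of sections, where a single cell layer should be captured.
#'
#' @inheritParams extract_section_points
#' @param thickness Slab thickness, µm.
#' @return A [point_pattern()].
#' @export
section_focus_pattern <- function(stack, section_index, cell_class = "neuron",
                                  thickness = 10) {
  stopifnot(inherits(stack, "section_stack"))
  cl <- match.arg(cell_class, cell_classes)
  t_sec <- stack$sections$t[section_index]
  pr <- stack$profiles[stack$profiles$section == section_index &
                         stack$profiles$cell_class == cl, ]
  if (nrow(pr) == 0 || thickness >= t_sec) {
    return(extract_section_points(stack, section_index, cl))
  }
  starts <- seq(0, t_sec - thickness, length.out = 32)
  counts <- vapply(starts, function(s) {
    sum(pr$z_depth >= s & pr$z_depth < s + thickness)
  }, numeric(1))
  best <- starts[which.max(counts)]
  extract_section_points(stack, section_index, cl,
                         depth_range = c(best, best + thickness))
}
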