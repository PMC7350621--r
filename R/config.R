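#' Study configuration for the virtual-ganglion simulator
#'
#' Bundles every parameter needed to simulate a six-group stereological study
#' of the superior cervical ganglion (SCG): the experimental design (groups and
#' animals per group), the geometry of the ganglion, the true cell population,
#' the spatial arrangement of neurons, and per-group effects on volume, cell
#' numbers and apoptosis.
#'
#' The defaults emulate the design of a chronic sleep deprivation (CSD) /
#' curcumin experiment: six groups of six animals, an ellipsoidal ganglion cut
#' across its long axis into 25-µm sections, a regular (jittered-lattice)
#' neuronal arrangement in all groups except CSD (random), and group effect
#' multipliers that reduce volume, neuron number and glia number in the CSD
#' group by 31.93%, 12.63% and 26.45% relative to control.
#'
#' @param groups Character vector of group labels.
#' @param animals_per_group Animals simulated per group.
#' @param ellipsoid_semi_axes Semi-axes of the ganglion ellipsoid in µm. The
#'   third component is the longitudinal axis along which the block is
#'   sectioned.
#' @param neuron_count_true True number of neurons in a control ganglion.
#' @param glia_per_neuron_mean Mean number of satellite glial cells per neuron.
#' @param neuron_radius_log,glia_radius_log Length-2 numeric `(meanlog, sdlog)`
#'   of the log-normal nucleus-radius distribution, in µm.
#' @param pattern Named character vector mapping each group to a spatial
#'   arrangement: `"regular"` (jittered 3-D lattice), `"random"` (homogeneous
#'   Poisson) or `"clustered"` (Thomas process).
#' @param lattice_jitter_frac Positional jitter of the regular lattice,
#'   as a fraction of the lattice pitch (Gaussian sd).
#' @param cluster_params Named list with `n_parents` (expected Thomas parent
#'   count), `offspring_mean` (expected offspring per parent; rescaled so the
#'   total matches the group's true count) and `sd` (cluster spread, µm).
#' @param apoptosis_prob Named numeric vector of per-group apoptosis
#'   probabilities in \[0, 1\].
#' @param effect_multipliers Named list mapping each group to a numeric vector
#'   with elements `volume`, `neuron` and `glia`: multiplicative effects on
#'   the group's true volume and cell counts (all > 0).
#' @param seed Base integer seed; per-animal seeds are derived from it.
#'
#' @return An object of class `study_config` (a named list).
#' @examples
#' cfg <- study_config(neuron_count_true = 2000, animals_per_group = 2)
#' cfg$groups
#' @export
study_config <- function(groups = c("control", "curcumin", "CSD", "CSD_curcumin",
                                    "grid_floor", "grid_floor_curcumin"),
                         animals_per_group = 6,
                         ellipsoid_semi_axes = c(200, 150, 300),
                         neuron_count_true = 10000,
                         glia_per_neuron_mean = 2,
                         neuron_radius_log = c(meanlog = log(6), sdlog = 0.15),
                         glia_radius_log = c(meanlog = log(2.5), sdlog = 0.15),
                         pattern = NULL,
                         lattice_jitter_frac = 0.05,
                         cluster_params = list(n_parents = 25, offspring_mean = 20, sd = 30),
                         apoptosis_prob = NULL,
                         effect_multipliers = NULL,
                         seed = 1L) {
  if (is.null(pattern)) {
    pattern <- setNames(rep("regular", length(groups)), groups)
    if ("CSD" %in% groups) pattern[["CSD"]] <- "random"
  }
  if (is.null(apoptosis_prob)) {
    defaults <- c(control = 0.02, curcumin = 0.01, CSD = 0.20, CSD_curcumin = 0.08,
                  grid_floor = 0.02, grid_floor_curcumin = 0.01)
    apoptosis_prob <- setNames(
      ifelse(groups %in% names(defaults), defaults[groups], 0.02), groups)
  }
  if (is.null(effect_multipliers)) {
    effect_multipliers <- lapply(groups, function(g) {
      switch(g,
        CSD = c(volume = 1 - 0.3193, neuron = 1 - 0.1263, glia = 1 - 0.2645),
        curcumin = c(volume = 1.05, neuron = 1.05, glia = 1.02),
        CSD_curcumin = c(volume = 0.95, neuron = 0.98, glia = 0.95),
        grid_floor_curcumin = c(volume = 1.05, neuron = 1.05, glia = 1.02),
        c(volume = 1, neuron = 1, glia = 1)
      )
    })
    names(effect_multipliers) <- groups
  }
  cfg <- structure(
    list(
      groups = groups,
      animals_per_group = as.integer(animals_per_group),
      ellipsoid_semi_axes = as.numeric(ellipsoid_semi_axes),
      neuron_count_true = neuron_count_true,
      glia_per_neuron_mean = glia_per_neuron_mean,
      neuron_radius_log = neuron_radius_log,
      glia_radius_log = glia_radius_log,
      pattern = pattern,
      lattice_jitter_frac = lattice_jitter_frac,
      cluster_params = cluster_params,
      apoptosis_prob = apoptosis_prob,
      effect_multipliers = effect_multipliers,
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
  validate_study_config(cfg)
  cfg
}

#' Validate a study configuration
#'
#' Checks the invariants of a [study_config()]: non-negative counts,
#' probabilities in \[0, 1\], positive semi-axes and positive effect
#' multipliers.
#'
#' @param config A `study_config` object.
#' @return `config`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_study_config <- function(config) {
  if (!inherits(config, "study_config")) {
    abort("`config` must be a `study_config` object")
  }
  if (length(config$groups) < 1) abort("at least one group is required")
  if (config$animals_per_group < 0) abort("`animals_per_group` must be >= 0")
  if (length(config$ellipsoid_semi_axes) != 3 || any(config$ellipsoid_semi_axes <= 0)) {
    abort("`ellipsoid_semi_axes` must be three positive lengths (µm)")
  }
  if (config$neuron_count_true < 0) abort("`neuron_count_true` must be >= 0")
  if (config$glia_per_neuron_mean < 0) abort("`glia_per_neuron_mean` must be >= 0")
  miss <- setdiff(config$groups, names(config$pattern))
  if (length(miss)) abort(paste0("`pattern` missing for group(s): ", toString(miss)))
  if (!all(config$pattern[config$groups] %in% c("regular", "random", "clustered"))) {
    abort("`pattern` values must be 'regular', 'random' or 'clustered'")
  }
  pr <- config$apoptosis_prob[config$groups]
  if (anyNA(pr) || any(pr < 0) || any(pr > 1)) {
    abort("`apoptosis_prob` must be defined in [0, 1] for every group")
  }
  for (g in config$groups) {
    m <- config$effect_multipliers[[g]]
    if (is.null(m) || !all(c("volume", "neuron", "glia") %in% names(m)) || any(m <= 0)) {
      abort(paste0("`effect_multipliers` for group '", g,
                   "' must be positive and named volume/neuron/glia"))
    }
  }
  invisible(config)
}

#' Read a study configuration from a YAML file
#'
#' Reads a YAML file whose top-level keys match the arguments of
#' [study_config()] and constructs the configuration, applying defaults for
#' any key not present.
#'
#' @param path Path to a YAML file.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) abort(paste0("unknown config field(s): ", toString(bad)))
  for (nm in c("pattern", "apoptosis_prob")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$effect_multipliers)) {
    raw$effect_multipliers <- lapply(raw$effect_multipliers, unlist)
  }
  for (nm in c("neuron_radius_log", "glia_radius_log")) {
    if (!is.null(raw[[nm]])) {
      v <- unlist(raw[[nm]])
      names(v) <- c("meanlog", "sdlog")
      raw[[nm]] <- v
    }
  }
  do.call(study_config, raw)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  groups:", toString(x$groups), "\n")
  cat("  animals/group:", x$animals_per_group, "\n")
  cat("  semi-axes (µm):", toString(x$ellipsoid_semi_axes),
      "| true neurons:", x$neuron_count_true,
      "| glia/neuron:", x$glia_per_neuron_mean, "\n")
  cat("  patterns:", toString(paste0(names(x$pattern), "=", x$pattern)), "\n")
  invisible(x)
}
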