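#' Run all estimators on one simulated animal
#'
#' Generates the animal's phantom, sections it, and runs the full estimator
#' battery: Cavalieri volume with CE on 8-12 systematically sampled sections,
#' optical-disector neuron and satellite-glia numbers with CE on the same
#' sections, a TUNEL-style apoptotic index over 10 random fields, and a
#' Voronoi summary of the neuronal arrangement pooled over the three most
#' central sampled sections (each reduced to its densest ~10-µm focal slab
#' and cropped to the ellipse's inscribed rectangle).
#'
#' Deterministic given `(config$seed, group, animal_index)`; [run_study()]
#' calls this per animal, so re-running one animal reproduces exactly its
#' rows of the study report.
#'
#' @param config A [study_config()].
#' @param group Group label.
#' @param animal_index Animal index within the group.
#' @param grid_spacing Cavalieri grid spacing, µm.
#' @param disector_steps Field steps `c(x, y)` for the disector, µm.
#' @return A one-row tibble of per-animal estimates.
#' @export
analyze_animal <- function(config, group, animal_index, grid_spacing = 65,
                           disector_steps = c(155, 155)) {
  gi <- match(group, config$groups)
  if (is.na(gi)) abort(paste0("unknown group label: '", group, "'"))
  phantom <- generate_phantom(config, group, animal_index)
  stack <- section_phantom(phantom, seed = derive_seed(config$seed, gi, animal_index, 2))

  vol <- estimate_volume(stack, spacing = grid_spacing,
                         seed = derive_seed(config$seed, gi, animal_index, 3))
  sampled <- vol$sampled_sections

  n_neu <- estimate_number(
    stack, disector_config("neuron", step_x = disector_steps[1],
                           step_y = disector_steps[2]),
    volume = vol$volume, seed = derive_seed(config$seed, gi, animal_index, 4),
    section_indices = sampled
  )
  n_gli <- estimate_number(
    stack, disector_config("satellite_glia", step_x = disector_steps[1],
                           step_y = disector_steps[2]),
    volume = vol$volume, seed = derive_seed(config$seed, gi, animal_index, 5),
    section_indices = sampled
  )

  tunel <- simulate_tunel_fields(stack, n_fields = 10,
                                 seed = derive_seed(config$seed, gi, animal_index, 6))
  ai <- apoptotic_index(tunel)

  vs <- animal_voronoi(stack, sampled)

  tibble::tibble(
    group = group,
    animal = as.integer(animal_index),
    true_volume = phantom$true_volume,
    true_n_neuron = sum(phantom$cells$cell_class == "neuron"),
    true_n_glia = sum(phantom$cells$cell_class == "satellite_glia"),
    volume = vol$volume,
    ce_volume = vol$ce,
    n_sections_sampled = vol$n_sections,
    n_neuron = n_neu$n_total,
    ce_neuron = n_neu$ce,
    sum_Q_neuron = n_neu$sum_Q,
    n_glia = n_gli$n_total,
    ce_glia = n_gli$ce,
    apoptotic_index = ai$index,
    voronoi_cv = vs$cv,
    classification = vs$classification,
    mean_polygon_area = vs$mean_area,
    n_polygons = vs$n_polygons
  )
}

# Pool interior Voronoi polygon areas over the three most central sampled
# sections, each analysed on its densest focal slab inside the inscribed
# rectangle of the section ellipse.
animal_voronoi <- function(stack, sampled, n_sections = 3) {
  ord <- sampled[order(abs(stack$sections$z_mid[sampled]))]
  use <- head(ord, n_sections)
  areas <- numeric(0)
  for (si in use) {
    pat <- section_focus_pattern(stack, si, "neuron")
    ea <- stack$sections$ellipse_a[si] / sqrt(2)
    eb <- stack$sections$ellipse_b[si] / sqrt(2)
    pat <- crop_pattern(pat, c(-ea, ea, -eb, eb))
    if (n_points(pat) < 10) next
    tiles <- tessellate_areas(pat, "exclude_boundary")
    areas <- c(areas, tiles$area)
  }
  if (length(areas) < 2) {
    return(list(cv = NA_real_, classification = NA_character_,
                mean_area = NA_real_, n_polygons = length(areas)))
  }
  cv <- cv_percent(areas)
  list(cv = cv, classification = classify_distribution(cv),
       mean_area = mean(areas), n_polygons = length(areas))
}

#' Simulate and analyse a complete multi-group study
#'
#' Drives the whole virtual experiment: for every group and animal in the
#' configuration it generates a phantom, sections it, runs every estimator
#' ([analyze_animal()]), then assembles per-group summaries (mean ± SEM) and
#' the group comparisons used in stereological studies: pairwise Mann-Whitney
#' for volume and cell numbers, the ANOVA/Kruskal-Wallis decision tree for
#' the apoptotic index and mean polygon area, and Levene's test for
#' polygon-area variability (via the per-animal CVs).
#'
#' All randomness derives from `master_seed` through a counter-based
#' splitting scheme keyed on (group, animal, stage), so changing one animal's
#' derived seed changes only that animal's rows.
#'
#' @param config A [study_config()]; its `seed` is replaced by `master_seed`.
#' @param master_seed Integer master seed.
#' @param grid_spacing Cavalieri grid spacing, µm.
#' @param disector_steps Disector field steps `c(x, y)`, µm.
#' @param verbose Print per-animal progress?
#' @return An object of class `study_report` with `animals` (per-animal
#'   tibble), `group_summary` (mean ± SEM per endpoint), `comparisons`
#'   (named list of [compare_groups()] results plus the Levene table) and the
#'   config echo.
#' @examples
#' \donttest{
#' cfg <- study_config(animals_per_group = 2, neuron_count_true = 2000,
#'                     groups = c("control", "CSD"))
#' rep <- run_study(cfg, master_seed = 1)
#' tidy(rep)
#' }
#' @export
run_study <- function(config = study_config(), master_seed = 1,
                      grid_spacing = 65, disector_steps = c(155, 155),
                      verbose = FALSE) {
  validate_study_config(config)
  config$seed <- as.integer(master_seed)
  grid <- expand.grid(animal = seq_len(config$animals_per_group),
                      group = config$groups, stringsAsFactors = FALSE)
  animals <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    g <- grid$group[i]; a <- grid$animal[i]
    if (verbose) message("analysing ", g, " animal ", a)
    analyze_animal(config, g, a, grid_spacing, disector_steps)
  })
  animals$group <- factor(animals$group, levels = config$groups)

  endpoints <- c("volume", "n_neuron", "n_glia", "apoptotic_index",
                 "voronoi_cv", "mean_polygon_area")
  group_summary <- animals |>
    tidyr::pivot_longer(dplyr::all_of(endpoints), names_to = "endpoint") |>
    dplyr::group_by(.data$group, .data$endpoint) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sem = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    )

  comparisons <- list()
  if (length(config$groups) >= 2 && config$animals_per_group >= 2) {
    comparisons$volume <- compare_groups(animals, .data$volume, .data$group,
                                         design = "pairwise")
    comparisons$n_neuron <- compare_groups(animals, .data$n_neuron, .data$group,
                                           design = "pairwise")
    comparisons$n_glia <- compare_groups(animals, .data$n_glia, .data$group,
                                         design = "pairwise")
    comparisons$apoptotic_index <- compare_groups(animals, .data$apoptotic_index,
                                                  .data$group, design = "one_way")
    ok <- !is.na(animals$mean_polygon_area)
    if (sum(ok) == nrow(animals)) {
      comparisons$mean_polygon_area <- compare_groups(animals, .data$mean_polygon_area,
                                                      .data$group, design = "one_way")
      comparisons$voronoi_variability <- levene_test(animals, .data$voronoi_cv,
                                                     .data$group)
    }
  }

  structure(
    list(animals = animals, group_summary = group_summary,
         comparisons = comparisons, config = config,
         master_seed = as.integer(master_seed)),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", length(x$config$groups), "groups x",
      x$config$animals_per_group, "animals (master seed", x$master_seed, ")\n\n")
  print(x$group_summary, n = 20)
  invisible(x)
}

#' @export
tidy.study_report <- function(x, ...) {
  x$animals
}

#' @export
glance.study_report <- function(x, ...) {
  x$group_summary
}

#' @export
autoplot.study_report <- function(object, endpoint = "volume", ...) {
  df <- object$animals
  if (!endpoint %in% names(df)) abort(paste0("unknown endpoint: ", endpoint))
  sm <- object$group_summary[object$group_summary$endpoint == endpoint, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data[[endpoint]])) +
    ggplot2::geom_jitter(width = 0.08, size = 1.6, alpha = 0.8) +
    ggplot2::geom_pointrange(
      data = sm,
      ggplot2::aes(x = .data$group, y = .data$mean,
                   ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      colour = "firebrick", shape = 95, size = 0.8
    ) +
    ggplot2::labs(x = NULL, y = endpoint) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Write a study report to disk
#'
#' Writes the per-animal table, the group summaries, the post hoc tables and
#' a JSON manifest (config, seeds, package version) into a directory.
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$animals, file.path(dir, "animals.csv"))
  readr::write_csv(report$group_summary, file.path(dir, "group_summary.csv"))
  cmp <- purrr::imap_dfr(report$comparisons, function(x, nm) {
    if (inherits(x, "group_comparison")) {
      dplyr::mutate(glance(x), endpoint = nm, .before = 1)
    } else {
      dplyr::mutate(x, endpoint = nm, .before = 1)
    }
  })
  readr::write_csv(cmp, file.path(dir, "comparisons.csv"))
  ph <- purrr::imap_dfr(report$comparisons, function(x, nm) {
    if (inherits(x, "group_comparison")) {
      dplyr::mutate(x$posthoc, endpoint = nm, .before = 1)
    } else {
      NULL
    }
  })
  readr::write_csv(ph, file.path(dir, "posthoc.csv"))
  manifest <- list(
    package = "ganglia",
    version = as.character(utils::packageVersion("ganglia")),
    master_seed = report$master_seed,
    config = report$config[setdiff(names(report$config), "effect_multipliers")],
    effect_multipliers = report$config$effect_multipliers,
    created = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
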