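#' Optical-disector sampling configuration
#'
#' Parameters of the optical-disector counting design: the unbiased counting
#' frame area (default 3492 µm², a square frame of side ~59.1 µm), the
#' systematic X/Y field steps, the guard-zone fractions of measured section
#' thickness, and the block advance. Guard defaults follow the Z-axis
#' histogram convention for each cell class: neurons discard the upper 10%
#' and lower 20% of the thickness, satellite glia the upper 20% and lower
#' 10%.
#'
#' @param cell_class `"neuron"` or `"satellite_glia"`.
#' @param frame_area Counting-frame area `a/f`, µm².
#' @param step_x,step_y Systematic field spacing, µm (must be at least the
#'   frame side).
#' @param guard_top,guard_bottom Guard-zone fractions of measured thickness;
#'   defaults depend on `cell_class`.
#' @param BA Block advance, µm.
#' @return An object of class `disector_config`.
#' @examples
#' disector_config("neuron")$guard_top
#' @export
disector_config <- function(cell_class = c("neuron", "satellite_glia"),
                            frame_area = 3492, step_x = 155, step_y = 155,
                            guard_top = NULL, guard_bottom = NULL, BA = 25) {
  cell_class <- match.arg(cell_class)
  if (frame_area <= 0) abort("`frame_area` must be > 0")
  side <- sqrt(frame_area)
  if (step_x < side || step_y < side) {
    abort("field steps must be at least the counting-frame side")
  }
  if (is.null(guard_top)) guard_top <- if (cell_class == "neuron") 0.10 else 0.20
  if (is.null(guard_bottom)) guard_bottom <- if (cell_class == "neuron") 0.20 else 0.10
  if (guard_top < 0 || guard_bottom < 0 || guard_top + guard_bottom >= 1) {
    abort("guard fractions must be >= 0 and sum to < 1")
  }
  structure(
    list(cell_class = cell_class, frame_area = frame_area, frame_side = side,
         step_x = step_x, step_y = step_y, guard_top = guard_top,
         guard_bottom = guard_bottom, BA = BA),
    class = "disector_config"
  )
}

#' Z-axis distribution of nuclei through the section thickness
#'
#' Bins the focal depths of counted nuclei into ten equal slabs of their
#' section's measured thickness, from the top (0%) downward (100%), and
#' reports the percentage of nuclei per slab. The histogram is used to choose
#' guard zones: depleted top/bottom bins reveal lost caps.
#'
#' @param depths Either a data frame with numeric columns `z` (focal depth,
#'   µm) and `t` (measured section thickness, µm), or a `section_stack`
#'   (then `cell_class` selects the nuclei and `z_depth`/section `t` are
#'   used).
#' @param cell_class Cell class used when `depths` is a `section_stack`.
#' @return An object of class `zaxis_histogram`: a tibble with columns `bin`,
#'   `lower`, `upper` (fractions of thickness) and `percent` (sums to 100).
#' @examples
#' zaxis_histogram(data.frame(z = runif(100, 0, 23), t = 23))
#' @export
zaxis_histogram <- function(depths, cell_class = "neuron") {
  if (inherits(depths, "section_stack")) {
    pr <- depths$profiles[depths$profiles$cell_class == cell_class, ]
    depths <- tibble::tibble(z = pr$z_depth,
                             t = depths$sections$t[pr$section])
  }
  depths <- tibble::as_tibble(depths)
  if (nrow(depths) == 0) abort("no nuclei supplied")
  if (any(depths$z < 0 | depths$z > depths$t)) {
    abort("focal depths must satisfy 0 <= z <= t")
  }
  rel <- pmin(depths$z / depths$t, 1 - 1e-12)
  bin <- pmin(floor(rel * 10) + 1L, 10L)
  counts <- tabulate(bin, nbins = 10)
  structure(
    tibble::tibble(
      bin = 1:10,
      lower = (0:9) / 10,
      upper = (1:10) / 10,
      percent = counts / sum(counts) * 100
    ),
    class = c("zaxis_histogram", "tbl_df", "tbl", "data.frame")
  )
}

#' @export
autoplot.zaxis_histogram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$bin), y = .data$percent)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "depth bin (10% of thickness, top to bottom)",
                  y = "% of counted nuclei") +
    ggplot2::theme_minimal()
}

#' Select the optical-disector counting window from guard zones
#'
#' Computes the disector height `h = (1 - guard_top - guard_bottom) * t_bar`
#' and, when a Z-axis histogram is supplied, the percentage of nuclei whose
#' focal depth falls inside the window (interpolating within boundary bins).
#' For a uniform depth distribution the included fraction equals the window's
#' share of the thickness; empirical histograms concentrated mid-section give
#' larger included fractions.
#'
#' @param hist Optional [zaxis_histogram()].
#' @param guard_top,guard_bottom Guard fractions of measured thickness.
#' @param t_bar Mean measured section thickness, µm.
#' @return An object of class `counting_window` with fields `guard_top`,
#'   `guard_bottom`, `t_bar`, `h` (µm) and `included_fraction` (percent).
#' @examples
#' select_counting_window(guard_top = 0.1, guard_bottom = 0.2, t_bar = 23)$h
#' @export
select_counting_window <- function(hist = NULL, guard_top, guard_bottom, t_bar) {
  if (guard_top < 0 || guard_bottom < 0 || guard_top + guard_bottom >= 1) {
    abort("guard fractions must be >= 0 and leave a non-empty window")
  }
  h <- (1 - guard_top - guard_bottom) * t_bar
  if (h <= 0) abort("counting window is empty")
  lo <- guard_top
  hi <- 1 - guard_bottom
  if (is.null(hist)) {
    frac <- (hi - lo) * 100
  } else {
    overlap <- pmax(0, pmin(hist$upper, hi) - pmax(hist$lower, lo)) /
      (hist$upper - hist$lower)
    frac <- sum(hist$percent * overlap)
  }
  if (frac <= 0) abort("counting window contains no nuclei")
  structure(
    list(guard_top = guard_top, guard_bottom = guard_bottom, t_bar = t_bar,
         h = h, included_fraction = frac),
    class = "counting_window"
  )
}

# Tally one section. Returns list(fields = tibble, events = tibble).
# Q is tallied over the full systematic tiling covering the section (so
# boundary nuclei are never lost), while `placed` marks fields whose centre
# lies on tissue: only those count toward SumP.
tally_section <- function(profiles, sec, config, z_lo_frac, z_hi_frac) {
  side <- config$frame_side
  sx <- config$step_x; sy <- config$step_y
  ea <- sec$ellipse_a; eb <- sec$ellipse_b
  t_sec <- sec$t
  max_r <- if (nrow(profiles)) max(profiles$radius) else 0

  # grid of frame origins with random phase; extends beyond both the section
  # ellipse and every profile so the tiling is complete at the edges
  lo_x <- min(-ea, if (nrow(profiles)) min(profiles$x) else Inf)
  hi_x <- max(ea, if (nrow(profiles)) max(profiles$x) else -Inf)
  lo_y <- min(-eb, if (nrow(profiles)) min(profiles$y) else Inf)
  hi_y <- max(eb, if (nrow(profiles)) max(profiles$y) else -Inf)
  x0 <- lo_x - side - max_r - sx + runif(1, 0, sx)
  y0 <- lo_y - side - max_r - sy + runif(1, 0, sy)
  nx <- max(0L, floor((hi_x + max_r - x0) / sx)) + 2L
  ny <- max(0L, floor((hi_y + max_r - y0) / sy)) + 2L
  ox <- x0 + (seq_len(nx) - 1L) * sx
  oy <- y0 + (seq_len(ny) - 1L) * sy

  frames <- expand.grid(fx = ox, fy = oy)
  cx <- frames$fx + side / 2
  cy <- frames$fy + side / 2
  placed <- if (ea > 0 && eb > 0) (cx / ea)^2 + (cy / eb)^2 <= 1 else rep(FALSE, nrow(frames))

  # z window (half-open) in this section's measured thickness
  keep <- profiles$z_depth >= z_lo_frac * t_sec &
    profiles$z_depth < z_hi_frac * t_sec
  cells <- profiles[keep, ]

  q_key <- integer(0)
  if (nrow(cells)) {
    x <- cells$x; y <- cells$y; r <- cells$radius
    # candidate frames: origins with X in [x - side - r, x + r], Y likewise
    # (the staircase exclusion line can push the counting frame diagonally)
    i_lo <- ceiling((x - side - r - x0) / sx)
    j_lo <- ceiling((y - side - r - y0) / sy)
    n_cand_x <- floor((side + 2 * max_r) / sx) + 2L
    n_cand_y <- floor((side + 2 * max_r) / sy) + 2L
    hits_f <- integer(0)
    for (oxi in 0:(n_cand_x - 1L)) {
      i <- i_lo + oxi
      X <- x0 + i * sx
      okx <- X <= x + r
      for (oyi in 0:(n_cand_y - 1L)) {
        j <- j_lo + oyi
        Y <- y0 + j * sy
        cand <- okx & Y <= y + r
        if (!any(cand)) next
        # profile intersects the frame (exact, corners rounded)
        dx <- pmax(X - x, x - X - side, 0)
        dy <- pmax(Y - y, y - Y - side, 0)
        inter <- dx * dx + dy * dy < r * r
        # forbidden staircase: left edge + its upward extension,
        # bottom edge, right edge's downward extension
        dxl <- abs(x - X)
        cl <- sqrt(pmax(r * r - dxl * dxl, 0))
        t_left <- dxl < r & (y + cl > Y)
        dyb <- abs(y - Y)
        cb <- sqrt(pmax(r * r - dyb * dyb, 0))
        t_bot <- dyb < r & (x - cb < X + side) & (x + cb > X)
        dxr <- abs(x - (X + side))
        cr <- sqrt(pmax(r * r - dxr * dxr, 0))
        t_right <- dxr < r & (y - cr < Y)
        hit <- cand & inter & !(t_left | t_bot | t_right)
        if (any(hit)) {
          hits_f <- c(hits_f, (i[hit] + 1L) * 100000L + (j[hit] + 1L))
        }
      }
    }
    q_key <- hits_f
  }

  frame_key <- (round((frames$fx - x0) / sx) + 1L) * 100000L +
    (round((frames$fy - y0) / sy) + 1L)
  q_by_frame <- table(factor(q_key, levels = frame_key))
  fields <- tibble::tibble(
    section = sec$section,
    frame_x = frames$fx, frame_y = frames$fy,
    placed = placed,
    Q = as.integer(q_by_frame),
    t = t_sec
  )
  # events landing outside the enumerated grid cannot occur (margin covers r)
  list(fields = fields, n_events = length(q_key))
}

#' Optical-disector tally over a section stack
#'
#' Scans systematically placed unbiased counting frames over each requested
#' section and counts every nucleus of the configured class whose focus event
#' (nucleus leading edge) lies inside the counting window's depth range and
#' whose profile lies at least partly inside a frame without touching the
#' forbidden line — the staircase exclusion line formed by the left border
#' with its infinite upward extension, the bottom border, and the infinite
#' downward extension of the right border below the bottom-right corner.
#' This is the standard disambiguation that makes a complete tiling of
#' frames count every convex profile exactly once.
#' Frames form a systematic grid with a uniform random origin per section.
#' Fields whose centre lies on tissue count toward `sum_P` (including fields
#' with zero counts); counting events are tallied over the complete tiling so
#' that nuclei at the tissue edge are never lost.
#'
#' @param stack A `section_stack`.
#' @param config A [disector_config()].
#' @param window Optional [select_counting_window()]; by default built from
#'   the config's guard fractions and the mean measured thickness of the
#'   tallied sections.
#' @param seed Optional integer seed for the random frame origins.
#' @param section_indices Sections to tally (default: all).
#' @return An object of class `disector_tally`: `sum_Q`, `sum_P`, `t_bar`,
#'   `fields` (per-field records) and `per_section` (ordered per-section `Q`
#'   and `P`).
#' @export
optical_disector_tally <- function(stack, config, window = NULL, seed = NULL,
                                   section_indices = NULL) {
  stopifnot(inherits(stack, "section_stack"), inherits(config, "disector_config"))
  set_seed_if(seed)
  if (is.null(section_indices)) section_indices <- seq_len(stack$n_sections)
  secs <- stack$sections[section_indices, ]
  if (is.null(window)) {
    window <- select_counting_window(
      guard_top = config$guard_top, guard_bottom = config$guard_bottom,
      t_bar = mean(secs$t)
    )
  }
  z_lo <- window$guard_top
  z_hi <- 1 - window$guard_bottom
  profiles <- stack$profiles[stack$profiles$cell_class == config$cell_class, ]

  out <- purrr::map(seq_len(nrow(secs)), function(i) {
    sec <- secs[i, ]
    tally_section(profiles[profiles$section == sec$section, ], sec, config,
                  z_lo, z_hi)
  })
  fields <- dplyr::bind_rows(purrr::map(out, "fields"))
  sum_P <- sum(fields$placed)
  if (sum_P == 0) abort("zero counting frames were placed on tissue")
  per_section <- fields |>
    dplyr::group_by(section = .data$section) |>
    dplyr::summarise(Q = sum(.data$Q), P = sum(.data$placed), .groups = "drop") |>
    dplyr::arrange(.data$section)
  structure(
    list(
      cell_class = config$cell_class,
      sum_Q = sum(fields$Q),
      sum_P = as.integer(sum_P),
      t_bar = mean(fields$t[fields$placed]),
      fields = fields,
      per_section = per_section,
      window = window
    ),
    class = "disector_tally"
  )
}

#' @export
print.disector_tally <- function(x, ...) {
  cat("<disector_tally>", x$cell_class, ": SumQ =", x$sum_Q, ", SumP =",
      x$sum_P, ", t_bar =", round(x$t_bar, 2), "µm\n")
  invisible(x)
}

#' Numerical density from a disector tally
#'
#' Applies the optical-disector formula with thickness correction,
#' \deqn{N_v = \frac{\sum Q^-}{\sum P \cdot (a/f) \cdot h} \cdot \frac{\bar t}{BA},}
#' where the `t/BA` factor corrects for the overestimation introduced by
#' counting in shrunken sections relative to the block advance. Setting
#' `t_bar = BA` recovers the uncorrected disector formula.
#'
#' @param tally A [optical_disector_tally()] result, or a list with numeric
#'   `sum_Q`, `sum_P` and `t_bar`.
#' @param config A [disector_config()] supplying `a/f` and `BA`.
#' @param window A [select_counting_window()] supplying the disector height
#'   `h`; defaults to the window stored in the tally.
#' @return Numerical density in cells/µm³.
#' @examples
#' cfg <- disector_config("neuron")
#' w <- select_counting_window(guard_top = 0.1, guard_bottom = 0.2, t_bar = 23)
#' estimate_nv(list(sum_Q = 100, sum_P = 200, t_bar = 23), cfg,
#'             window = list(h = 15))
#' @export
estimate_nv <- function(tally, config, window = NULL) {
  if (is.null(window)) window <- tally$window
  if (tally$sum_P <= 0) abort("`sum_P` must be > 0")
  if (window$h <= 0) abort("disector height must be > 0")
  tally$sum_Q / (tally$sum_P * config$frame_area * window$h) *
    (tally$t_bar / config$BA)
}

#' Total cell number from numerical density and reference volume
#'
#' @param nv Numerical density, cells/µm³.
#' @param volume Reference volume, µm³ (e.g. a Cavalieri estimate).
#' @param ce Optional coefficient of error to attach.
#' @return An object of class `number_estimate` with `nv`, `volume`,
#'   `n_total` and `ce`.
#' @examples
#' estimate_total_number(8.782e-6, 3e7)$n_total
#' @export
estimate_total_number <- function(nv, volume, ce = NA_real_) {
  if (nv < 0 || volume < 0) abort("`nv` and `volume` must be >= 0")
  structure(list(nv = nv, volume = volume, n_total = nv * volume, ce = ce),
            class = "number_estimate")
}

#' @export
print.number_estimate <- function(x, ...) {
  cat("<number_estimate> Nv =", format(x$nv, digits = 4), "cells/µm³, N =",
      format(x$n_total, digits = 5), ", CE =",
      ifelse(is.na(x$ce), "NA", format(x$ce, digits = 3)), "\n")
  invisible(x)
}

#' @export
tidy.number_estimate <- function(x, ...) {
  tibble::tibble(nv = x$nv, volume = x$volume, n_total = x$n_total, ce = x$ce)
}

#' Coefficient of error of a disector number estimate
#'
#' Combines the Poisson counting component `1/sum(Q)` with the
#' systematic-sampling variance of the ordered per-section counts
#' (Gundersen-Jensen m = 1, as in [gundersen_ce_volume()] without the
#' point-counting nugget):
#' \deqn{CE = \sqrt{1/\Sigma Q + Var_{SURS}(Q_i)/(\Sigma Q)^2}.}
#'
#' @param tally A [optical_disector_tally()] result, or a list with `sum_Q`.
#' @param per_section_Q Optional ordered per-section counts; defaults to the
#'   tally's `per_section$Q`. With fewer than 3 sections only the Poisson
#'   term is used.
#' @return The coefficient of error (unitless).
#' @examples
#' ce_number(list(sum_Q = 400), per_section_Q = rep(40, 10))
#' @export
ce_number <- function(tally, per_section_Q = NULL) {
  if (is.null(per_section_Q)) per_section_Q <- tally$per_section$Q
  sQ <- tally$sum_Q %||% sum(per_section_Q)
  if (sQ <= 0) abort("`sum_Q` must be > 0")
  var_surs <- 0
  Q <- as.numeric(per_section_Q)
  n <- length(Q)
  if (n >= 3) {
    C0 <- sum(Q * Q)
    C1 <- sum(Q[-n] * Q[-1])
    C2 <- sum(Q[seq_len(n - 2)] * Q[seq(3, n)])
    var_surs <- max(0, (3 * C0 - 4 * C1 + C2) / 240)
  }
  sqrt(1 / sQ + var_surs / sQ^2)
}

#' Estimate total neuron or glia number from a section stack
#'
#' Full optical-disector pipeline: Z-axis histogram of the class's focal
#' depths, counting-window selection from the configured guard zones,
#' systematic frame tally over the sampled sections, the Nv formula with
#' `t/BA` correction, and `N = Nv * V` with its CE.
#'
#' @param stack A `section_stack`.
#' @param config A [disector_config()].
#' @param volume Reference volume in µm³ (e.g. `estimate_volume(stack)$volume`).
#' @param seed Optional integer seed for frame placement.
#' @param section_indices Sections to tally (default: all). Use the same
#'   systematically sampled sections as the volume estimate for a matched
#'   design.
#' @return A `number_estimate` with extra fields `sum_Q`, `sum_P`, `h`,
#'   `t_bar`, `included_fraction` and `zaxis` (the histogram).
#' @export
estimate_number <- function(stack, config, volume, seed = NULL,
                            section_indices = NULL) {
  stopifnot(inherits(stack, "section_stack"))
  set_seed_if(seed)
  if (is.null(section_indices)) section_indices <- seq_len(stack$n_sections)
  pr <- stack$profiles[stack$profiles$cell_class == config$cell_class &
                         stack$profiles$section %in% section_indices, ]
  hist <- NULL
  if (nrow(pr) > 0) {
    hist <- zaxis_histogram(tibble::tibble(z = pr$z_depth,
                                           t = stack$sections$t[pr$section]))
  }
  window <- select_counting_window(
    hist, guard_top = config$guard_top, guard_bottom = config$guard_bottom,
    t_bar = mean(stack$sections$t[section_indices])
  )
  tally <- optical_disector_tally(stack, config, window = window,
                                  section_indices = section_indices)
  nv <- estimate_nv(tally, config, window)
  ce <- if (tally$sum_Q > 0) ce_number(tally) else NA_real_
  est <- estimate_total_number(nv, volume, ce = ce)
  est$cell_class <- config$cell_class
  est$sum_Q <- tally$sum_Q
  est$sum_P <- tally$sum_P
  est$h <- window$h
  est$t_bar <- tally$t_bar
  est$included_fraction <- window$included_fraction
  est$zaxis <- hist
  est$tally <- tally
  est
}
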