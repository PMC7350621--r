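#' Apoptotic index from per-field TUNEL counts
#'
#' Computes the apoptotic index, `apoptotic cells / total cells * 100%`, over
#' a set of sampled microscope fields. Two pooling conventions are offered:
#' `"pooled_counts"` (default) divides the summed apoptotic count by the
#' summed total before converting to percent; `"mean_of_fields"` averages the
#' per-field percentages. The two agree when all fields have equal totals.
#'
#' @param fields A data frame with integer columns `apoptotic` and `total`
#'   (one row per field; `0 <= apoptotic <= total`), and optionally
#'   `field_id`.
#' @param pooling `"pooled_counts"` or `"mean_of_fields"`.
#' @return An object of class `apoptotic_index` with fields `index`
#'   (percent), `per_field` (tibble of per-field indices), `n_fields` and
#'   `pooling`.
#' @examples
#' apoptotic_index(data.frame(apoptotic = c(10, 30), total = c(100, 100)))
#' @export
apoptotic_index <- function(fields, pooling = c("pooled_counts", "mean_of_fields")) {
  pooling <- match.arg(pooling)
  fields <- tibble::as_tibble(fields)
  if (nrow(fields) == 0) abort("at least one field is required")
  if (any(fields$apoptotic < 0) || any(fields$apoptotic > fields$total)) {
    abort("each field must satisfy 0 <= apoptotic <= total")
  }
  if (sum(fields$total) == 0) abort("all fields have zero total cells")
  per_field <- fields |>
    dplyr::mutate(index = ifelse(.data$total > 0,
                                 .data$apoptotic / .data$total * 100, NA_real_))
  index <- if (pooling == "pooled_counts") {
    sum(fields$apoptotic) / sum(fields$total) * 100
  } else {
    mean(per_field$index, na.rm = TRUE)
  }
  structure(
    list(index = index, per_field = per_field, n_fields = nrow(fields),
         pooling = pooling),
    class = "apoptotic_index"
  )
}

#' @export
print.apoptotic_index <- function(x, ...) {
  cat("<apoptotic_index>", round(x$index, 2), "% over", x$n_fields,
      "fields (", x$pooling, ")\n")
  invisible(x)
}

#' @export
tidy.apoptotic_index <- function(x, ...) {
  tibble::tibble(index = x$index, n_fields = x$n_fields, pooling = x$pooling)
}

#' Percent body-weight change between first and last day
#'
#' `[(weight on day 21) * 100 / (weight on day 1)] - 100`; negative values
#' are weight loss. Vectorised over animals.
#'
#' @param weight_day1 Weight on the first day, grams (> 0).
#' @param weight_day21 Weight on the last (21st) day, grams.
#' @return Percent change.
#' @examples
#' body_weight_percent(250, 295) # +18
#' body_weight_percent(300, 292) # -2.67
#' @export
body_weight_percent <- function(weight_day1, weight_day21) {
  if (anyNA(weight_day1) || anyNA(weight_day21)) {
    abort("day-1 and day-21 weights are both required")
  }
  if (any(weight_day1 <= 0)) abort("day-1 weight must be > 0")
  weight_day21 * 100 / weight_day1 - 100
}

#' Simulate TUNEL-style field sampling on a section stack
#'
#' Draws `n_fields` square fields at random positions on randomly chosen
#' sections (restricted to sections whose boundary ellipse can contain the
#' field) and tallies total and apoptotic cells of the requested class whose
#' profile centre falls inside the field.
#'
#' @param stack A `section_stack`.
#' @param n_fields Number of fields (default 10).
#' @param field_size Field side length, µm.
#' @param cell_class Cell class tallied.
#' @param seed Optional integer seed.
#' @return A tibble with columns `field_id`, `section`, `apoptotic`, `total`,
#'   suitable for [apoptotic_index()].
#' @export
simulate_tunel_fields <- function(stack, n_fields = 10, field_size = 150,
                                  cell_class = "neuron", seed = NULL) {
  stopifnot(inherits(stack, "section_stack"))
  set_seed_if(seed)
  half <- field_size / 2
  ok <- which(stack$sections$ellipse_a > half & stack$sections$ellipse_b > half)
  if (!length(ok)) abort("no section is large enough for the requested field size")
  pr <- stack$profiles[stack$profiles$cell_class == cell_class, ]
  out <- purrr::map_dfr(seq_len(n_fields), function(f) {
    sec_i <- ok[sample.int(length(ok), 1)]
    ea <- stack$sections$ellipse_a[sec_i]
    eb <- stack$sections$ellipse_b[sec_i]
    # field centre uniform on the inscribed region that keeps the field inside
    repeat {
      cx <- runif(1, -ea + half, ea - half)
      cy <- runif(1, -eb + half, eb - half)
      if ((cx / ea)^2 + (cy / eb)^2 <= 0.9) break
    }
    inside <- pr$section == sec_i &
      abs(pr$x - cx) <= half & abs(pr$y - cy) <= half
    tibble::tibble(field_id = f, section = sec_i,
                   apoptotic = sum(pr$apoptotic[inside]),
                   total = sum(inside))
  })
  out
}
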