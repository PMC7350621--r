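#' Group comparison following the stereological decision tree
#'
#' Compares an endpoint across experimental groups with the decision tree
#' used in stereological studies: Kolmogorov-Smirnov normality per group and
#' Levene variance homogeneity decide between a parametric branch (one- or
#' two-way ANOVA followed by Tukey's post hoc) and a nonparametric branch
#' (Kruskal-Wallis followed by Dunn's post hoc). The `pairwise` design runs
#' two-tailed Mann-Whitney U tests on all group pairs. Constant (degenerate)
#' groups are flagged and routed to the nonparametric branch.
#'
#' @param data A data frame in long format.
#' @param value Bare column name of the endpoint values.
#' @param group Bare column name of the group labels.
#' @param design `"one_way"`, `"pairwise"` or `"two_way"`.
#' @param block Bare column name of the second factor (required for
#'   `"two_way"`, e.g. day for body weight).
#' @param test `"auto"` follows the decision tree; `"anova"`, `"kruskal"` or
#'   `"mann_whitney"` force a branch.
#' @param alpha Significance threshold.
#' @param p_adjust Adjustment method for Dunn's post hoc p-values
#'   (see [stats::p.adjust()]); default `"none"`.
#' @return An object of class `group_comparison` recording the normality and
#'   variance-homogeneity checks, the branch taken, the omnibus statistic and
#'   p-value, and the post hoc pairwise table.
#' @examples
#' df <- data.frame(g = rep(c("a", "b", "c"), each = 6), y = rnorm(18))
#' compare_groups(df, y, g)
#' @export
compare_groups <- function(data, value, group, design = c("one_way", "pairwise", "two_way"),
                           block = NULL, test = c("auto", "anova", "kruskal", "mann_whitney"),
                           alpha = 0.05, p_adjust = "none") {
  design <- match.arg(design)
  test <- match.arg(test)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  bq <- rlang::enquo(block)
  b <- if (!rlang::quo_is_null(bq)) factor(rlang::eval_tidy(bq, data)) else NULL
  if (design == "two_way" && is.null(b)) abort("`two_way` design requires `block`")
  if (nlevels(g) < 2) abort("at least 2 groups are required")
  ns <- table(g)
  if (any(ns < 2)) abort("every group needs at least 2 values")

  # per-group KS normality (estimated parameters); constant groups flagged
  normality <- purrr::map_dfr(levels(g), function(lv) {
    x <- v[g == lv]
    if (sd(x) == 0) {
      return(tibble::tibble(group = lv, statistic = NA_real_, p_value = NA_real_,
                            degenerate = TRUE))
    }
    kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
    tibble::tibble(group = lv, statistic = unname(kt$statistic),
                   p_value = kt$p.value, degenerate = FALSE)
  })
  lev <- levene_p(v, g)
  normal_ok <- !any(normality$degenerate) && all(normality$p_value > alpha)
  variance_ok <- is.na(lev$p_value) || lev$p_value > alpha

  branch <- if (test != "auto") {
    test
  } else if (design == "pairwise") {
    "mann_whitney"
  } else if (design == "two_way") {
    "anova"
  } else if (normal_ok && variance_ok) {
    "anova"
  } else {
    "kruskal"
  }

  if (branch == "anova") {
    if (design == "two_way") {
      fit <- aov(v ~ g * b)
      tab <- summary(fit)[[1]]
      statistic <- tab[1, "F value"] # group main effect is the first term
      p_value <- tab[1, "Pr(>F)"]
      test_name <- "two-way ANOVA"
      ph <- tukey_table(fit, which = "g")
    } else {
      fit <- aov(v ~ g)
      tab <- summary(fit)[[1]]
      statistic <- tab[1, "F value"]
      p_value <- tab[1, "Pr(>F)"]
      test_name <- "one-way ANOVA"
      ph <- tukey_table(fit, which = "g")
    }
    posthoc_name <- "Tukey HSD"
  } else if (branch == "kruskal") {
    kt <- kruskal.test(v, g)
    statistic <- unname(kt$statistic)
    p_value <- kt$p.value
    if (is.nan(p_value)) p_value <- 1 # all values identical
    test_name <- "Kruskal-Wallis"
    ph <- dunn_posthoc(v, g, p_adjust)
    posthoc_name <- "Dunn"
  } else {
    pairs <- utils::combn(levels(g), 2)
    ph <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      x <- v[g == pairs[1, i]]
      y <- v[g == pairs[2, i]]
      wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
      tibble::tibble(group1 = pairs[1, i], group2 = pairs[2, i],
                     statistic = unname(wt$statistic), p_value = wt$p.value)
    })
    statistic <- NA_real_
    p_value <- min(1, min(ph$p_value))
    test_name <- "Mann-Whitney U (pairwise)"
    posthoc_name <- "Mann-Whitney U"
  }

  structure(
    list(
      design = design, branch = branch, test = test_name,
      posthoc_test = posthoc_name,
      statistic = statistic, p_value = p_value,
      normality = normality, levene = lev,
      normality_passed = normal_ok, variance_passed = variance_ok,
      posthoc = ph, alpha = alpha,
      significant = !is.na(p_value) && p_value < alpha,
      n_groups = nlevels(g), n = length(v)
    ),
    class = "group_comparison"
  )
}

levene_p <- function(v, g) {
  tryCatch({
    lt <- suppressWarnings(car::leveneTest(v ~ g, center = mean))
    list(statistic = lt[1, "F value"], p_value = lt[1, "Pr(>F)"])
  }, error = function(e) list(statistic = NA_real_, p_value = NA_real_))
}

tukey_table <- function(fit, which) {
  th <- TukeyHSD(fit, which = which)[[which]]
  cmp <- strsplit(rownames(th), "-", fixed = TRUE)
  tibble::tibble(
    group1 = vapply(cmp, `[`, "", 1),
    group2 = vapply(cmp, `[`, "", 2),
    estimate = th[, "diff"],
    p_value = th[, "p adj"]
  )
}

# Dunn's rank-sum post hoc with tie correction; standard z statistic
# z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))
dunn_posthoc <- function(v, g, p_adjust = "none") {
  r <- rank(v)
  N <- length(v)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab)
  s2 <- N * (N + 1) / 12 - tie_corr / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  ns <- table(g)
  pairs <- utils::combn(levels(g), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se <- sqrt(s2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    z <- if (se > 0) (rbar[[g1]] - rbar[[g2]]) / se else 0
    tibble::tibble(group1 = g1, group2 = g2, statistic = z,
                   p_value = 2 * pnorm(-abs(z)))
  })
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", x$test, "(", x$design, "design )\n")
  cat("  normality passed:", x$normality_passed,
      "| equal variance:", x$variance_passed, "\n")
  if (!is.na(x$statistic)) {
    cat("  statistic =", format(x$statistic, digits = 4), "\n")
  }
  cat("  p =", format(x$p_value, digits = 4),
      if (x$significant) "(significant)" else "", "\n")
  cat("  post hoc:", x$posthoc_test, "-", nrow(x$posthoc), "pairs\n")
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  x$posthoc
}

#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    design = x$design, test = x$test, statistic = x$statistic,
    p_value = x$p_value, significant = x$significant,
    normality_passed = x$normality_passed,
    variance_passed = x$variance_passed,
    n_groups = x$n_groups, n = x$n
  )
}

#' Levene's test of variance homogeneity across groups
#'
#' Thin wrapper (mean-centred, matching SPSS) used for endpoints where the
#' question is equality of variances rather than of means — e.g. Voronoi
#' polygon-area variability across groups.
#'
#' @inheritParams compare_groups
#' @return A one-row tibble with `statistic`, `df1`, `df2` and `p_value`.
#' @export
levene_test <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  lt <- suppressWarnings(car::leveneTest(v ~ g, center = mean))
  tibble::tibble(statistic = lt[1, "F value"], df1 = lt[1, "Df"],
                 df2 = lt[2, "Df"], p_value = lt[1, "Pr(>F)"])
}
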