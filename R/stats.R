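#' Per-condition, per-phase foci summaries
#'
#' Collapses per-cell foci counts to the schema of a condition summary
#' table: mean foci per cell, SEM (sample SD / sqrt(n); 0 by convention
#' for n = 1, with a warning), and the number of cells, per grouping-key
#' combination.
#'
#' @param records Data frame of cell records with a `foci_count` column,
#'   a `phase` column (every record must be gated), and the grouping keys.
#' @param group_keys Character vector of grouping columns.
#' @return Tibble with the group keys plus `mean_foci`, `sem`, `n_cells`,
#'   of class `"foci_summary"`.
#' @examples
#' summarize_foci(tibble::tibble(line_id = "hDF", phase = "G1",
#'                               foci_count = c(1, 2, 3)),
#'                group_keys = c("line_id", "phase"))
#' @export
summarize_foci <- function(records,
                           group_keys = c("line_id", "marker", "dose_gy",
                                          "time_h", "phase")) {
  if (!is.data.frame(records) || nrow(records) == 0)
    abort("records must be a non-empty data frame",
          class = "dsbfoci_invalid_params")
  group_keys <- intersect(group_keys, names(records))
  if ("phase" %in% names(records) && any(!records$phase %in% c("G1", "SG2")))
    abort("every record must have an assigned phase (G1 or SG2)",
          class = "dsbfoci_invalid_params")
  out <- records %>%
    group_by(dplyr::across(dplyr::all_of(group_keys))) %>%
    summarise(mean_foci = mean(.data$foci_count),
              sem = ifelse(n() > 1, sd(.data$foci_count) / sqrt(n()), 0),
              n_cells = n(), .groups = "drop")
  if (any(out$n_cells == 1))
    warn("groups with a single cell: SEM reported as 0")
  class(out) <- c("foci_summary", class(out))
  out
}

#' Fold change between two group means
#'
#' @param mean_num Numerator mean (e.g. irradiated, or S/G2).
#' @param mean_den Denominator mean (> 0; e.g. control, or G1).
#' @return The raw ratio `mean_num / mean_den`.
#' @seealso [format_fold()] for the conventional rounded report.
#' @export
fold_change <- function(mean_num, mean_den) {
  if (any(mean_den <= 0))
    abort("denominator mean must be > 0", class = "dsbfoci_invalid_params")
  mean_num / mean_den
}

#' Round a fold change the way it is conventionally reported
#'
#' Nearest integer for folds of 10 and above ("18-fold", "10-fold"), one
#' decimal below ("2.1-times", "4.6-times").
#'
#' @param fold Raw ratio from [fold_change()].
#' @return Numeric rounded fold.
#' @export
format_fold <- function(fold) {
  ifelse(fold >= 10, round(fold), round(fold, 1))
}

#' Percent increase of a treated mean over a control mean
#'
#' @param ctrl_mean Control mean (> 0).
#' @param irr_mean Treated (e.g. irradiated) mean.
#' @return `100 * (irr_mean - ctrl_mean) / ctrl_mean`; negative for a
#'   decrease. Satisfies `fold = 1 + percent / 100` exactly.
#' @export
percent_increase <- function(ctrl_mean, irr_mean) {
  if (any(ctrl_mean <= 0))
    abort("control mean must be > 0", class = "dsbfoci_invalid_params")
  100 * (irr_mean - ctrl_mean) / ctrl_mean
}

#' Two-group comparison of foci counts (Student's t test)
#'
#' Equal-variance two-sided two-sample t test by default (Welch behind the
#' flag), as used for pairwise comparisons of per-cell foci counts.
#'
#' @param a,b Numeric vectors of per-cell counts (each n >= 2).
#' @param var_equal Pooled-variance (Student) form when `TRUE`.
#' @param alpha Significance level.
#' @return Object of class `"foci_comparison"`.
#' @export
compare_two_groups <- function(a, b, var_equal = TRUE, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2)
    abort("each group needs at least 2 observations",
          class = "dsbfoci_invalid_params")
  tt <- t.test(a, b, var.equal = var_equal)
  structure(list(kind = "t_test", statistic = unname(tt$statistic),
                 p_value = tt$p.value, df = unname(tt$parameter),
                 estimate = unname(diff(rev(tt$estimate))),
                 alpha = alpha,
                 pairwise = tibble(group_a = "a", group_b = "b",
                                   adjusted_p = tt$p.value,
                                   significant = tt$p.value < alpha)),
            class = "foci_comparison")
}

#' Multi-group comparison: one-way ANOVA with Tukey HSD
#'
#' One-way analysis of variance across three or more groups of per-cell
#' counts, followed by Tukey's honestly-significant-difference test for
#' all pairwise contrasts (Tukey-Kramer for unequal group sizes).
#'
#' @param groups Named list of numeric vectors (>= 3 groups, each n >= 2),
#'   or a data frame with columns `group` and `value`.
#' @param alpha Family-wise significance level.
#' @return Object of class `"foci_comparison"` with the ANOVA F statistic
#'   and p value, and a `pairwise` tibble (`group_a`, `group_b`, `diff`,
#'   `adjusted_p`, `significant`).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    df <- tibble(group = as.character(groups$group), value = groups$value)
  } else {
    if (is.null(names(groups)) || any(names(groups) == ""))
      abort("groups must be named", class = "dsbfoci_invalid_params")
    df <- tibble(group = rep(names(groups), lengths(groups)),
                 value = unlist(groups, use.names = FALSE))
  }
  gs <- table(df$group)
  if (length(gs) < 3)
    abort("fewer than 3 groups: use compare_two_groups()",
          class = "dsbfoci_too_few_groups")
  if (any(gs < 2))
    abort("each group needs at least 2 observations",
          class = "dsbfoci_invalid_params")
  df$group <- factor(df$group)
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$group
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  structure(list(kind = "anova_tukey",
                 statistic = an[["F value"]][1],
                 p_value = an[["Pr(>F)"]][1],
                 df = c(an[["Df"]][1], an[["Df"]][2]),
                 alpha = alpha,
                 pairwise = tibble(
                   group_a = vapply(pairs, `[`, "", 1),
                   group_b = vapply(pairs, `[`, "", 2),
                   diff = tk[, "diff"],
                   adjusted_p = tk[, "p adj"],
                   significant = tk[, "p adj"] < alpha)),
            class = "foci_comparison")
}

#' @export
print.foci_comparison <- function(x, ...) {
  cat(sprintf("<foci_comparison> %s: statistic = %.4g, p = %.4g\n",
              x$kind, x$statistic, x$p_value))
  if (x$kind == "anova_tukey")
    cat(sprintf("  %d of %d Tukey pairs significant at alpha = %g\n",
                sum(x$pairwise$significant), nrow(x$pairwise), x$alpha))
  invisible(x)
}

#' @rdname compare_two_groups
#' @param x,object A `foci_comparison` object.
#' @param ... Unused.
#' @export
tidy.foci_comparison <- function(x, ...) x$pairwise

#' @rdname compare_two_groups
#' @export
glance.foci_comparison <- function(x, ...) {
  tibble(kind = x$kind, statistic = x$statistic, p_value = x$p_value)
}

#' Repair time course after irradiation
#'
#' Summarises a 0 / 0.5 / 2 / 6 h post-irradiation series per (line,
#' marker, phase): the four means, plus the percentage of foci remaining
#' at 2 h and 6 h relative to the 0.5 h peak (damage recognition peaks at
#' half an hour; steeper decline = faster repair).
#'
#' @param summaries A summary table from [summarize_foci()] (or any data
#'   frame with `line_id`, `marker`, `phase`, `time_h`, `mean_foci`)
#'   containing all four time points per series.
#' @return Tibble, one row per (line_id, marker, phase): `mean_0h`,
#'   `mean_0.5h`, `mean_2h`, `mean_6h`, `percent_remaining_2h`,
#'   `percent_remaining_6h`.
#' @export
repair_time_course <- function(summaries) {
  need <- c("line_id", "marker", "phase", "time_h", "mean_foci")
  if (!all(need %in% names(summaries)))
    abort(paste("summaries must contain:", paste(need, collapse = ", ")),
          class = "dsbfoci_invalid_params")
  wide <- summaries %>%
    select("line_id", "marker", "phase", "time_h", "mean_foci") %>%
    tidyr::pivot_wider(names_from = "time_h", values_from = "mean_foci",
                       names_prefix = "t")
  need_t <- c("t0", "t0.5", "t2", "t6")
  if (!all(need_t %in% names(wide)) || anyNA(wide[need_t]))
    abort("missing time point: each series needs means at 0, 0.5, 2 and 6 h",
          class = "dsbfoci_missing_timepoint")
  wide %>%
    mutate(percent_remaining_2h = ifelse(.data$`t0.5` > 0,
                                         100 * .data$t2 / .data$`t0.5`, NA_real_),
           percent_remaining_6h = ifelse(.data$`t0.5` > 0,
                                         100 * .data$t6 / .data$`t0.5`, NA_real_)) %>%
    rename(mean_0h = "t0", `mean_0.5h` = "t0.5", mean_2h = "t2",
           mean_6h = "t6") %>%
    arrange(.data$line_id, .data$marker, .data$phase)
}

#' Published per-condition foci summary table
#'
#' The transcribed condition-by-phase summary (mean foci per cell, SEM,
#' number of cells) for five cell lines at low/high passage, two DSB
#' markers, non-irradiated and 0.5 h after 1 Gy, split into G1
#' (EdU-negative) and S/G2 (EdU-positive) populations. Used as the worked
#' example for the fold-change arithmetic and as the source of generative
#' rates for the synthetic pipeline.
#'
#' @return Tibble with columns `line`, `passage`, `marker`, `treatment`
#'   (`"control"` / `"irradiated_1gy_0.5h"`), `phase` (`"G1"` / `"SG2"`),
#'   `mean_foci`, `sem`, `n_cells`.
#' @export
table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "dsbfoci",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    line = readr::col_character(),
                    passage = readr::col_character(),
                    marker = readr::col_character(),
                    treatment = readr::col_character(),
                    phase = readr::col_character(),
                    mean_foci = readr::col_double(),
                    sem = readr::col_double(),
                    n_cells = readr::col_integer()))
}
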