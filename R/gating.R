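#' Per-nucleus total EdU intensity
#'
#' Sums the EdU-channel intensity over each nucleus's labelled voxels —
#' the image-cytometry quantity on which G1/S-G2 gating operates.
#'
#' @param edu_volume Numeric 3D array (EdU channel) or a `channel_stack`.
#' @param nuclei A `labeled_nuclei` object of the same shape.
#' @return Tibble `nucleus_id, edu_total, voxels`, one row per nucleus.
#' @export
edu_totals <- function(edu_volume, nuclei) {
  if (inherits(edu_volume, "channel_stack")) edu_volume <- edu_volume$edu
  stopifnot(inherits(nuclei, "labeled_nuclei"))
  if (!identical(dim(edu_volume), dim(nuclei$labels)))
    abort("EdU volume and nucleus labels have different shapes",
          class = "dsbfoci_shape_mismatch")
  if (nrow(nuclei$nuclei) == 0)
    return(tibble(nucleus_id = integer(), edu_total = numeric(),
                  voxels = integer()))
  idx <- which(nuclei$labels > 0L)
  li <- nuclei$labels[idx]
  tot <- tapply(edu_volume[idx], li, sum)
  tibble(nucleus_id = as.integer(names(tot)),
         edu_total = as.numeric(tot)) %>%
    left_join(select(nuclei$nuclei, "nucleus_id", "voxels"),
              by = "nucleus_id") %>%
    arrange(.data$nucleus_id)
}

#' One-dimensional Otsu threshold on per-cell totals
#'
#' Classical two-class Otsu on an `n_bins` linear-scale histogram of the
#' values: the returned threshold is the bin edge maximizing between-class
#' variance (ties broken by the smallest threshold). Cells with
#' `value < threshold` form the lower (EdU-negative) class.
#'
#' @param values Numeric vector of per-cell totals (>= 2 distinct values).
#' @param n_bins Number of histogram bins.
#' @return The threshold (a single number).
#' @export
otsu_1d <- function(values, n_bins = 256) {
  v <- as.numeric(values)
  if (length(unique(v)) < 2)
    abort("Otsu gating needs at least 2 distinct values",
          class = "dsbfoci_degenerate_histogram")
  rng <- range(v)
  bw <- (rng[2] - rng[1]) / n_bins
  w <- cpp_hist_counts(v, rng[1], rng[2], n_bins)
  centers <- rng[1] + (seq_len(n_bins) - 0.5) * bw
  cw <- cumsum(w)
  cs <- cumsum(w * centers)
  W <- cw[n_bins]; S <- cs[n_bins]; mu <- S / W
  i <- seq_len(n_bins - 1)
  w0 <- cw[i]; s0 <- cs[i]
  w1 <- W - w0; s1 <- S - s0
  ssb <- ifelse(w0 > 0, (s0 - w0 * mu)^2 / w0, 0) +
         ifelse(w1 > 0, (s1 - w1 * mu)^2 / w1, 0)
  k <- which.max(ssb)                      # first max: smallest threshold
  rng[1] + k * bw
}

#' Assign cell-cycle phase by an EdU threshold
#'
#' Cells with `edu_total < threshold` are called G1 (EdU-negative), the
#' rest S/G2 (EdU-positive; cells exactly at the threshold are positive).
#'
#' @param records Tibble with at least `edu_total` (e.g. from
#'   [edu_totals()] joined to foci counts).
#' @param threshold Gating threshold, typically from [otsu_1d()].
#' @param n_bins Bins used for the report histogram.
#' @return List of class `"edu_gate"`: `records` (input plus a `phase`
#'   column), `threshold`, `n_total`, `n_neg`, `n_pos`,
#'   `frac_neg_percent`, and `histogram` (tibble `mid, count` of totals).
#' @export
assign_phase <- function(records, threshold, n_bins = 64) {
  if (!is.data.frame(records) || nrow(records) == 0)
    abort("records must be a non-empty data frame",
          class = "dsbfoci_invalid_params")
  if (!"edu_total" %in% names(records)) abort("records needs an edu_total column")
  if (!is.finite(threshold)) abort("threshold must be finite")
  recs <- mutate(records, phase = ifelse(.data$edu_total < threshold, "G1", "SG2"))
  n_neg <- sum(recs$phase == "G1")
  n_tot <- nrow(recs)
  h <- graphics::hist(records$edu_total, breaks = n_bins, plot = FALSE)
  structure(list(records = as_tibble(recs), threshold = threshold,
                 n_total = n_tot, n_neg = n_neg, n_pos = n_tot - n_neg,
                 frac_neg_percent = 100 * n_neg / n_tot,
                 histogram = tibble(mid = h$mids, count = h$counts)),
            class = "edu_gate")
}

#' Gate a table of cell records in one step
#'
#' Computes the slide-level Otsu threshold on the pooled `edu_total`
#' values and assigns phases. One threshold per slide (pooling all its
#' fields) mirrors per-sample histogram gating.
#'
#' @inheritParams assign_phase
#' @param otsu_bins Bins for the Otsu threshold search.
#' @return An `"edu_gate"` object (see [assign_phase()]).
#' @export
gate_cells <- function(records, otsu_bins = 256, n_bins = 64) {
  thr <- otsu_1d(records$edu_total, otsu_bins)
  assign_phase(records, thr, n_bins = n_bins)
}

#' @export
print.edu_gate <- function(x, ...) {
  cat(sprintf("<edu_gate> threshold %.4g: %d / %d EdU-negative (%.1f%%)\n",
              x$threshold, x$n_neg, x$n_total, x$frac_neg_percent))
  invisible(x)
}

#' @rdname assign_phase
#' @param x An `edu_gate` object.
#' @param ... Unused.
#' @export
tidy.edu_gate <- function(x, ...) x$records

#' @rdname assign_phase
#' @export
glance.edu_gate <- function(x, ...) {
  tibble(threshold = x$threshold, n_total = x$n_total, n_neg = x$n_neg,
         n_pos = x$n_pos, frac_neg_percent = x$frac_neg_percent)
}

#' @rdname assign_phase
#' @param object An `edu_gate` object.
#' @export
autoplot.edu_gate <- function(object, ...) {
  ggplot2::ggplot(object$records, ggplot2::aes(x = .data$edu_total)) +
    ggplot2::geom_histogram(bins = 64, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$threshold, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "per-nucleus total EdU intensity", y = "cells",
                  title = sprintf("EdU gate: %.1f%% EdU-negative",
                                  object$frac_neg_percent)) +
    ggplot2::theme_minimal()
}
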