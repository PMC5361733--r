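#' Gaussian preprocessing of a 3D volume
#'
#' Smooths with SD `sigma_px` in y and x and `sigma_px * spacing_y /
#' spacing_z` in z, so the physical kernel is isotropic in the lateral
#' plane and shrinks with the coarse axial sampling (at 3 um z-steps and
#' 124 nm pixels the axial SD is ~0.04 voxels, i.e. no axial smoothing).
#' Mirror boundary handling; `sigma_px = 0` is the identity.
#'
#' @param volume Numeric 3D array, dim order (z, y, x).
#' @param sigma_px Lateral SD in pixels.
#' @param spacing_zyx Voxel spacing in nm, order (z, y, x).
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth <- function(volume, sigma_px = 1, spacing_zyx = c(3000, 124, 124)) {
  if (sigma_px < 0) abort("sigma_px must be >= 0", class = "dsbfoci_invalid_params")
  stopifnot(is.array(volume), length(dim(volume)) == 3)
  if (!all(is.finite(volume))) abort("volume must be finite")
  if (sigma_px == 0) return(volume)
  sig <- c(sigma_px * spacing_zyx[2] / spacing_zyx[1], sigma_px, sigma_px)
  cpp_gauss_sep(volume, dim(volume), sig)
}

#' Two-level Otsu thresholds of a 3D volume
#'
#' Builds an `n_bins` histogram over `[min, max]` and exhaustively searches
#' the pair of cut points maximizing the between-class variance of the
#' three-class partition. Ties are broken by the lexicographically smallest
#' `(t_low, t_high)`. Thresholds are returned as bin lower edges, so a
#' voxel belongs to the upper class when `v >= t`.
#'
#' @param volume Numeric array (any shape) or vector of intensities.
#' @param n_bins Number of histogram bins.
#' @return Named numeric vector `c(t_low, t_high)` with `t_low < t_high`.
#' @export
two_level_otsu <- function(volume, n_bins = 256) {
  v <- as.numeric(volume)
  if (length(unique(v)) < 3)
    abort("two-level Otsu needs at least 3 distinct intensity values",
          class = "dsbfoci_degenerate_histogram")
  rng <- range(v)
  bw <- (rng[2] - rng[1]) / n_bins
  w <- cpp_hist_counts(v, rng[1], rng[2], n_bins)
  centers <- rng[1] + (seq_len(n_bins) - 0.5) * bw
  cw <- cumsum(w)
  cs <- cumsum(w * centers)
  W <- cw[n_bins]; S <- cs[n_bins]; mu <- S / W

  ssb_term <- function(wk, sk) ifelse(wk > 0, (sk - wk * mu)^2 / wk, 0)
  best <- -Inf; bi <- 1L; bj <- 2L
  for (i in seq_len(n_bins - 2)) {
    j <- (i + 1):(n_bins - 1)
    w0 <- cw[i];            s0 <- cs[i]
    w1 <- cw[j] - w0;       s1 <- cs[j] - s0
    w2 <- W - cw[j];        s2 <- S - cs[j]
    ssb <- ssb_term(w0, s0) + ssb_term(w1, s1) + ssb_term(w2, s2)
    k <- which.max(ssb)                                    # first max: smallest j
    if (ssb[k] > best) { best <- ssb[k]; bi <- i; bj <- j[k] }
  }
  c(t_low = rng[1] + bi * bw, t_high = rng[1] + bj * bw)
}

#' Hysteresis thresholding
#'
#' Foreground is every voxel `>= t_low` that is 26-connected to a seed
#' voxel `>= t_high`, so `{v >= t_high}` is contained in the mask and the
#' mask is contained in `{v >= t_low}`.
#'
#' @param volume Numeric 3D array.
#' @param t_low,t_high Low and high thresholds, `t_low <= t_high`.
#' @return Logical 3D array.
#' @export
hysteresis_mask <- function(volume, t_low, t_high) {
  if (t_low > t_high)
    abort("t_low must not exceed t_high", class = "dsbfoci_invalid_params")
  stopifnot(is.array(volume), length(dim(volume)) == 3)
  low <- volume >= t_low
  lab <- cpp_label_components(low, dim(volume))
  seeds <- unique(lab[volume >= t_high])
  seeds <- seeds[seeds > 0]
  out <- array(lab %in% seeds, dim(volume))
  out
}

#' Label nucleus instances in a binary mask
#'
#' 26-connected components with at least `min_voxels` voxels become nucleus
#' instances; components touching a volume face are optionally discarded
#' (only whole cells are analysed). Labels are assigned in decreasing
#' component-size order.
#'
#' @param mask Logical 3D array.
#' @param params A [segmentation_params()] object.
#' @return Object of class `"labeled_nuclei"`: list with `labels` (integer
#'   3D array, 0 = background), `n_nuclei`, and `nuclei` — a tibble with
#'   `nucleus_id`, `voxels`, `centroid_z/y/x` (0-based voxel coordinates).
#' @export
label_nuclei <- function(mask, params = segmentation_params()) {
  stopifnot(is.array(mask), length(dim(mask)) == 3, is.logical(mask))
  dims <- dim(mask)
  lab <- cpp_label_components(mask, dims)
  n_raw <- max(lab)
  if (n_raw == 0) {
    return(structure(list(labels = array(0L, dims), n_nuclei = 0L,
                          nuclei = tibble(nucleus_id = integer(),
                                          voxels = integer(),
                                          centroid_z = numeric(),
                                          centroid_y = numeric(),
                                          centroid_x = numeric())),
                     class = "labeled_nuclei"))
  }
  sizes <- tabulate(lab[lab > 0L], nbins = n_raw)
  drop <- sizes < params$min_voxels
  if (params$exclude_border) {
    faces <- unique(c(lab[1, , ], lab[dims[1], , ],
                      lab[, 1, ], lab[, dims[2], ],
                      lab[, , 1], lab[, , dims[3]]))
    faces <- faces[faces > 0]
    drop[faces] <- TRUE
  }
  keep <- which(!drop)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  remap <- integer(n_raw)
  remap[keep] <- seq_along(keep)

  out <- array(0L, dims)
  idx <- which(lab > 0L)
  new_lab <- remap[lab[idx]]
  sel <- new_lab > 0L
  out[idx[sel]] <- new_lab[sel]

  if (length(keep) == 0) {
    nuclei <- tibble(nucleus_id = integer(), voxels = integer(),
                     centroid_z = numeric(), centroid_y = numeric(),
                     centroid_x = numeric())
  } else {
    vi <- idx[sel]
    li <- new_lab[sel]
    co <- arrayInd(vi, dims) - 1L               # 0-based (z, y, x)
    nuclei <- tibble(
      nucleus_id = seq_along(keep),
      voxels = as.integer(tabulate(li, nbins = length(keep))),
      centroid_z = as.numeric(tapply(co[, 1], li, mean)),
      centroid_y = as.numeric(tapply(co[, 2], li, mean)),
      centroid_x = as.numeric(tapply(co[, 3], li, mean))
    )
  }
  structure(list(labels = out, n_nuclei = length(keep), nuclei = nuclei),
            class = "labeled_nuclei")
}

#' Segment nuclei from the nuclear-stain channel
#'
#' Full instance segmentation: Gaussian preprocessing, two-level Otsu on
#' the smoothed volume (lower level = hysteresis low threshold, upper
#' level = seed threshold), hysteresis masking, then size/border filtered
#' 26-connected labelling.
#'
#' @param x A `channel_stack` or a numeric 3D array (nuclear channel).
#' @param params A [segmentation_params()] object.
#' @param spacing_zyx Voxel spacing in nm (taken from the stack if given).
#' @return A `labeled_nuclei` object; the Otsu thresholds are attached as
#'   attribute `"thresholds"`.
#' @export
segment_nuclei <- function(x, params = segmentation_params(),
                           spacing_zyx = c(3000, 124, 124)) {
  if (inherits(x, "channel_stack")) {
    spacing_zyx <- x$spacing_zyx
    x <- x$nuclear
  }
  sm <- gaussian_smooth(x, params$sigma_px, spacing_zyx)
  th <- two_level_otsu(sm, params$n_bins)
  mask <- hysteresis_mask(sm, th[["t_low"]], th[["t_high"]])
  out <- label_nuclei(mask, params)
  attr(out, "thresholds") <- th
  out
}

#' Match segmented nuclei against simulator ground truth
#'
#' Each true nucleus is matched to the detected label at its centroid (or
#' the nearest detected centroid within one lateral radius), and the Dice
#' overlap between the true ellipsoid voxel set and the detected region is
#' computed.
#'
#' @param truth A `ground_truth` object.
#' @param labeled A `labeled_nuclei` object on the rendered volume.
#' @return Tibble with one row per true nucleus: `nucleus_id`,
#'   `matched_label` (NA if undetected), `dice`.
#' @export
evaluate_segmentation <- function(truth, labeled) {
  stopifnot(inherits(truth, "ground_truth"), inherits(labeled, "labeled_nuclei"))
  dims <- dim(labeled$labels)
  res <- lapply(seq_len(nrow(truth$nuclei)), function(i) {
    nu <- truth$nuclei[i, ]
    zi <- min(max(round(nu$centroid_z), 0), dims[1] - 1) + 1
    yi <- min(max(round(nu$centroid_y), 0), dims[2] - 1) + 1
    xi <- min(max(round(nu$centroid_x), 0), dims[3] - 1) + 1
    lb <- labeled$labels[zi, yi, xi]
    if (lb == 0 && nrow(labeled$nuclei) > 0) {
      d <- sqrt((labeled$nuclei$centroid_y - nu$centroid_y)^2 +
                (labeled$nuclei$centroid_x - nu$centroid_x)^2 +
                (labeled$nuclei$centroid_z - nu$centroid_z)^2)
      j <- which.min(d)
      if (d[j] <= max(nu$semi_y, nu$semi_x)) lb <- labeled$nuclei$nucleus_id[j]
    }
    if (lb == 0) {
      tibble(nucleus_id = nu$nucleus_id, matched_label = NA_integer_,
             dice = 0)
    } else {
      tm <- true_nucleus_mask(truth, nu$nucleus_id)
      dm <- labeled$labels == lb
      dice <- 2 * sum(tm & dm) / (sum(tm) + sum(dm))
      tibble(nucleus_id = nu$nucleus_id, matched_label = as.integer(lb),
             dice = dice)
    }
  })
  bind_rows(res)
}

#' @export
print.labeled_nuclei <- function(x, ...) {
  cat(sprintf("<labeled_nuclei> %d nuclei in %s volume\n", x$n_nuclei,
              paste(dim(x$labels), collapse = "x")))
  invisible(x)
}
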