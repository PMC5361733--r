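#' Extended-maxima (h-maxima) transform
#'
#' Suppresses peaks shallower than `height_h` by grayscale morphological
#' reconstruction of `volume - height_h` under `volume`, then returns the
#' 26-connected regional-maxima components of the reconstruction: the
#' connected voxel sets on which the volume stands at least `height_h`
#' above its surrounding reconstruction level. Adding a constant to the
#' volume leaves the components unchanged. A reconstruction that is
#' globally flat (blank volume, or a single peak shallower than `height_h`)
#' yields no components.
#'
#' @param volume Numeric 3D array.
#' @param height_h Spot height threshold (> 0).
#' @return Integer 3D array labelling the maxima components (0 elsewhere);
#'   the number of components is attached as attribute `"n_components"`.
#' @export
extended_maxima <- function(volume, height_h) {
  stopifnot(is.array(volume), length(dim(volume)) == 3)
  if (!all(is.finite(volume))) abort("volume must be finite")
  if (height_h <= 0) abort("height_h must be > 0", class = "dsbfoci_invalid_params")
  dims <- dim(volume)
  rec <- cpp_reconstruct(volume - height_h, volume, dims)
  rmax <- cpp_regional_maxima(rec, dims)
  lab <- cpp_label_components(rmax, dims)
  attr(lab, "n_components") <- max(lab)
  lab
}

#' Grayscale morphological reconstruction by dilation
#'
#' Iteratively dilates `marker` (26-neighbourhood) while clamping below
#' `mask`, to the fixpoint. The workhorse behind [extended_maxima()],
#' exposed for direct use and testing.
#'
#' @param marker,mask Numeric 3D arrays of equal shape.
#' @return The reconstructed array.
#' @export
morph_reconstruct <- function(marker, mask) {
  stopifnot(is.array(marker), is.array(mask),
            identical(dim(marker), dim(mask)))
  cpp_reconstruct(marker, mask, dim(mask))
}

#' Detect and count foci per nucleus
#'
#' The spot-detection pipeline applied to the DSB-marker channel: lateral
#' Gaussian smoothing, extended-maxima transform at `height_h`, removal of
#' components larger than `max_spot_voxels`, and assignment of each
#' surviving component to the nucleus label at its centroid (components
#' centred on background are discarded). Every segmented nucleus appears
#' in the output, including zero-count ones.
#'
#' @param foci_volume Numeric 3D array (marker channel), or a
#'   `channel_stack` (its `foci` channel is used).
#' @param nuclei A `labeled_nuclei` object of the same shape.
#' @param params A [foci_params()] object.
#' @param spacing_zyx Voxel spacing in nm (taken from the stack if given).
#' @return List of class `"foci_result"` with
#'   * `cells` — tibble `nucleus_id, foci_count`, one row per nucleus;
#'   * `spots` — tibble of calls: `nucleus_id, z, y, x` (0-based centroid),
#'     `voxels`, `peak` (peak smoothed intensity in the component).
#' @export
detect_foci <- function(foci_volume, nuclei, params = foci_params(),
                        spacing_zyx = c(3000, 124, 124)) {
  if (inherits(foci_volume, "channel_stack")) {
    spacing_zyx <- foci_volume$spacing_zyx
    foci_volume <- foci_volume$foci
  }
  stopifnot(inherits(nuclei, "labeled_nuclei"))
  if (!identical(dim(foci_volume), dim(nuclei$labels)))
    abort("foci volume and nucleus labels have different shapes",
          class = "dsbfoci_shape_mismatch")
  dims <- dim(foci_volume)

  sm <- gaussian_smooth(foci_volume, params$sigma_px, spacing_zyx)
  lab <- extended_maxima(sm, params$height_h)
  n_comp <- attr(lab, "n_components")

  spots <- tibble(nucleus_id = integer(), z = numeric(), y = numeric(),
                  x = numeric(), voxels = integer(), peak = numeric())
  if (n_comp > 0) {
    idx <- which(lab > 0L)
    li <- lab[idx]
    sizes <- tabulate(li, nbins = n_comp)
    co <- arrayInd(idx, dims) - 1L
    cz <- tapply(co[, 1], li, mean)
    cy <- tapply(co[, 2], li, mean)
    cx <- tapply(co[, 3], li, mean)
    pk <- tapply(sm[idx], li, max)
    comp <- tibble(z = as.numeric(cz), y = as.numeric(cy), x = as.numeric(cx),
                   voxels = as.integer(sizes), peak = as.numeric(pk)) %>%
      filter(.data$voxels <= params$max_spot_voxels)
    if (nrow(comp) > 0) {
      zi <- pmin(pmax(round(comp$z), 0), dims[1] - 1) + 1
      yi <- pmin(pmax(round(comp$y), 0), dims[2] - 1) + 1
      xi <- pmin(pmax(round(comp$x), 0), dims[3] - 1) + 1
      comp$nucleus_id <- as.integer(nuclei$labels[cbind(zi, yi, xi)])
      spots <- comp %>%
        filter(.data$nucleus_id > 0L) %>%
        select("nucleus_id", "z", "y", "x", "voxels", "peak")
    }
  }

  counts <- if (nrow(spots) > 0) {
    spots %>% count(.data$nucleus_id, name = "foci_count")
  } else {
    tibble(nucleus_id = integer(), foci_count = integer())
  }
  all_ids <- if (nrow(nuclei$nuclei) > 0) nuclei$nuclei$nucleus_id else integer()
  cells <- tibble(nucleus_id = all_ids) %>%
    left_join(counts, by = "nucleus_id") %>%
    mutate(foci_count = as.integer(ifelse(is.na(.data$foci_count), 0L,
                                          .data$foci_count)))
  structure(list(cells = cells, spots = spots), class = "foci_result")
}

#' @export
print.foci_result <- function(x, ...) {
  cat(sprintf("<foci_result> %d spots across %d nuclei (mean %.2f foci/cell)\n",
              nrow(x$spots), nrow(x$cells),
              if (nrow(x$cells)) mean(x$cells$foci_count) else NA_real_))
  invisible(x)
}
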