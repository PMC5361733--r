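#' Experimental condition parameters for the synthetic generator
#'
#' One virtual slide corresponds to one cell line stained for one DSB marker
#' at one radiation dose and fixation time. Per-phase foci counts are drawn
#' from Poisson distributions whose rates are typically taken from published
#' per-condition means (see [table1()]), and the G1/SG2 split from a
#' Bernoulli draw with probability `frac_g1` (the EdU-negative fraction).
#'
#' @param line_id Cell-line label, e.g. `"hDF"` or `"CBIA-5-low"`.
#' @param marker DSB marker imaged on the slide: `"gH2AX"` or `"53BP1"`.
#' @param dose_gy Radiation dose in gray (0 for non-irradiated controls).
#' @param time_h Hours between irradiation and fixation.
#' @param lambda_g1 Mean foci per G1 (EdU-negative) cell; Poisson rate.
#' @param lambda_sg2 Mean foci per S/G2 (EdU-positive) cell; Poisson rate.
#' @param frac_g1 Expected fraction of EdU-negative cells, in `[0, 1]`.
#' @param n_cells Total number of nuclei on the virtual slide.
#'
#' @return A list of class `"condition_params"`.
#' @examples
#' condition_params(line_id = "hDF", lambda_g1 = 1.13, lambda_sg2 = 29.9,
#'                  frac_g1 = 0.872, n_cells = 100)
#' @export
condition_params <- function(line_id = "hDF", marker = c("gH2AX", "53BP1"),
                             dose_gy = 0, time_h = 0,
                             lambda_g1 = 1, lambda_sg2 = 10,
                             frac_g1 = 0.85, n_cells = 100) {
  marker <- match.arg(marker)
  stopifnot(is.character(line_id), length(line_id) == 1)
  if (dose_gy < 0 || time_h < 0)
    abort("dose_gy and time_h must be non-negative", class = "dsbfoci_invalid_params")
  if (lambda_g1 < 0 || lambda_sg2 < 0)
    abort("Poisson rates must be non-negative", class = "dsbfoci_invalid_params")
  if (frac_g1 < 0 || frac_g1 > 1)
    abort("frac_g1 must lie in [0, 1]", class = "dsbfoci_invalid_params")
  if (n_cells < 1 || n_cells != round(n_cells))
    abort("n_cells must be a positive integer", class = "dsbfoci_invalid_params")
  structure(list(line_id = line_id, marker = marker, dose_gy = dose_gy,
                 time_h = time_h, lambda_g1 = lambda_g1,
                 lambda_sg2 = lambda_sg2, frac_g1 = frac_g1,
                 n_cells = as.integer(n_cells)),
            class = "condition_params")
}

#' Rendering parameters for the synthetic image generator
#'
#' Defaults reproduce the acquisition geometry of the study being emulated:
#' 30 optical slices at 3 um spacing, 1392 x 1040 px fields with 124 nm
#' pixels, rendered as 16-bit-style camera counts. Nuclei are axis-aligned
#' ellipsoids with lateral semi-axes drawn from `nucleus_radius_um` and
#' axial semi-axes from `nucleus_axial_slices` (in z-slices). Foci are
#' in-plane Gaussian spots of SD `psf_sigma_px` and peak `foci_amplitude`;
#' pairs of foci closer than one z-slice keep at least `min_foci_sep_px`
#' lateral separation so that diffraction-scale spots remain individually
#' resolvable by the detector.
#'
#' @param shape_zyx Volume dimensions in voxels, order (z, y, x).
#' @param spacing_zyx Voxel spacing in nm, order (z, y, x).
#' @param nucleus_radius_um Range of lateral semi-axes in micrometres.
#' @param nucleus_axial_slices Range of axial semi-axes in z-slices.
#' @param nucleus_base_intensity Nucleoplasm level in the nuclear channel.
#' @param foci_amplitude Peak height of a rendered focus (camera counts).
#' @param edu_neg_intensity,edu_pos_intensity Per-voxel EdU level of a
#'   reference-volume EdU-negative and EdU-positive nucleus. Each cell's
#'   total EdU intensity is drawn with 10% Gaussian scatter around the
#'   phase target and spread over its nucleus volume, giving bimodal
#'   total-intensity clusters separated by well over 6 within-cluster SD.
#' @param noise_sd Additive Gaussian read-noise SD (0 = noise-free).
#' @param psf_sigma_px Lateral SD of a rendered spot, in pixels.
#' @param min_foci_sep_px Minimum lateral separation (px) enforced between
#'   foci lying within one z-slice of each other.
#' @param placement_gap_px Minimum lateral gap (px) between nucleus
#'   boundaries and between a nucleus and the field border.
#'
#' @return A list of class `"render_params"`.
#' @export
render_params <- function(shape_zyx = c(30L, 1040L, 1392L),
                          spacing_zyx = c(3000, 124, 124),
                          nucleus_radius_um = c(4, 7),
                          nucleus_axial_slices = c(1.5, 2.5),
                          nucleus_base_intensity = 100,
                          foci_amplitude = 200,
                          edu_neg_intensity = 20,
                          edu_pos_intensity = 400,
                          noise_sd = 0,
                          psf_sigma_px = 1,
                          min_foci_sep_px = 8,
                          placement_gap_px = 10) {
  if (length(shape_zyx) != 3 || any(shape_zyx < 1))
    abort("shape_zyx must be three positive integers", class = "dsbfoci_invalid_params")
  if (length(spacing_zyx) != 3 || any(spacing_zyx <= 0))
    abort("spacing_zyx must be three positive values (nm)", class = "dsbfoci_invalid_params")
  if (any(c(nucleus_base_intensity, foci_amplitude, edu_neg_intensity,
            edu_pos_intensity) < 0) || noise_sd < 0)
    abort("intensity levels and noise_sd must be non-negative", class = "dsbfoci_invalid_params")
  if (edu_pos_intensity <= edu_neg_intensity)
    abort("edu_pos_intensity must exceed edu_neg_intensity", class = "dsbfoci_invalid_params")
  if (diff(range(nucleus_radius_um)) < 0 || min(nucleus_radius_um) <= 0)
    abort("nucleus_radius_um must be a positive range", class = "dsbfoci_invalid_params")
  structure(list(shape_zyx = as.integer(shape_zyx), spacing_zyx = spacing_zyx,
                 nucleus_radius_um = nucleus_radius_um,
                 nucleus_axial_slices = nucleus_axial_slices,
                 nucleus_base_intensity = nucleus_base_intensity,
                 foci_amplitude = foci_amplitude,
                 edu_neg_intensity = edu_neg_intensity,
                 edu_pos_intensity = edu_pos_intensity,
                 noise_sd = noise_sd, psf_sigma_px = psf_sigma_px,
                 min_foci_sep_px = min_foci_sep_px,
                 placement_gap_px = placement_gap_px),
            class = "render_params")
}

#' Nucleus segmentation parameters
#'
#' @param sigma_px Gaussian preprocessing SD in lateral pixels; the axial SD
#'   is scaled by the spacing ratio (effectively no axial smoothing at 3 um
#'   z-steps).
#' @param min_voxels Minimum object size; smaller 26-connected components
#'   are discarded as debris or fragments of adjacent cells.
#' @param exclude_border Drop components touching any volume face, mimicking
#'   the selection of whole cells.
#' @param n_bins Histogram bins for the two-level Otsu threshold.
#'
#' @return A list of class `"segmentation_params"`.
#' @export
segmentation_params <- function(sigma_px = 1, min_voxels = 2000,
                                exclude_border = TRUE, n_bins = 256) {
  if (sigma_px < 0) abort("sigma_px must be >= 0", class = "dsbfoci_invalid_params")
  if (min_voxels < 1) abort("min_voxels must be >= 1", class = "dsbfoci_invalid_params")
  if (n_bins < 2) abort("n_bins must be >= 2", class = "dsbfoci_invalid_params")
  structure(list(sigma_px = sigma_px, min_voxels = as.integer(min_voxels),
                 exclude_border = isTRUE(exclude_border),
                 n_bins = as.integer(n_bins)),
            class = "segmentation_params")
}

#' Extended-maxima foci detection parameters
#'
#' Defaults follow the empirically set spot-detector parameters of the
#' emulated analysis: smoothing sigma 1 px, spot height threshold 80 camera
#' counts, maximum spot size 800 voxels, 26-connectivity.
#'
#' @param sigma_px Lateral smoothing SD in pixels before spot detection.
#' @param height_h Spot height threshold: a focus must stand at least this
#'   far above its surrounding reconstruction level.
#' @param max_spot_voxels Maxima components larger than this are discarded
#'   (diffuse signal, not a focus).
#'
#' @return A list of class `"foci_params"`.
#' @export
foci_params <- function(sigma_px = 1, height_h = 80, max_spot_voxels = 800) {
  if (height_h <= 0) abort("height_h must be > 0", class = "dsbfoci_invalid_params")
  if (max_spot_voxels < 1) abort("max_spot_voxels must be >= 1", class = "dsbfoci_invalid_params")
  if (sigma_px < 0) abort("sigma_px must be >= 0", class = "dsbfoci_invalid_params")
  structure(list(sigma_px = sigma_px, height_h = height_h,
                 max_spot_voxels = as.integer(max_spot_voxels),
                 connectivity = 26L),
            class = "foci_params")
}
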