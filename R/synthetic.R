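#' Sample a ground-truth field of nuclei
#'
#' Draws `cond$n_cells` non-overlapping ellipsoidal nuclei inside the render
#' volume, assigns each a cell-cycle phase (Bernoulli with probability
#' `frac_g1` of G1), a Poisson foci count at the phase-specific rate, a
#' per-cell total EdU intensity (two-level model with 10% scatter, spread
#' over the nucleus volume as a per-voxel level), and
#' uniform foci positions inside the nucleus. The generative model is the
#' simplest structure consistent with published per-condition summaries:
#' the studies being emulated report means and SEMs, not raw distributions.
#'
#' @param cond A [condition_params()] object.
#' @param render A [render_params()] object.
#' @param seed Integer seed; output is bit-reproducible per seed.
#' @param max_tries Placement attempts per nucleus before giving up.
#'
#' @return An object of class `"ground_truth"`: a list with
#'   * `nuclei` — tibble, one row per nucleus: `nucleus_id`, `phase`
#'     (`"G1"`/`"SG2"`), `foci_count`, `edu_level`, centroid and semi-axes
#'     in voxel units (`centroid_z/y/x`, `semi_z/y/x`, 0-based);
#'   * `foci` — tibble of true focus positions `nucleus_id, z, y, x`;
#'   * `cond`, `render` — the generating parameters.
#' @export
sample_ground_truth <- function(cond, render = render_params(), seed = 1L,
                                max_tries = 200L) {
  stopifnot(inherits(cond, "condition_params"), inherits(render, "render_params"))
  dims <- render$shape_zyx
  px_nm <- render$spacing_zyx[2]
  r_px <- render$nucleus_radius_um * 1000 / px_nm
  gap <- render$placement_gap_px

  withr::with_seed(seed, {
    cz <- cy <- cx <- az <- ay <- ax <- numeric(cond$n_cells)
    for (i in seq_len(cond$n_cells)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        a_lat <- runif(1, r_px[1], r_px[2])
        a_y <- a_lat
        a_x <- a_lat * runif(1, 0.85, 1)
        a_z <- runif(1, render$nucleus_axial_slices[1], render$nucleus_axial_slices[2])
        if (2 * (a_z + 1) + 2 > dims[1] ||
            2 * (a_y + gap) + 2 > dims[2] || 2 * (a_x + gap) + 2 > dims[3])
          abort("volume too small for the configured nucleus size",
                class = "dsbfoci_field_too_crowded")
        c_z <- runif(1, a_z + 1, dims[1] - 1 - a_z - 1)
        c_y <- runif(1, a_y + gap, dims[2] - 1 - a_y - gap)
        c_x <- runif(1, a_x + gap, dims[3] - 1 - a_x - gap)
        ok <- TRUE
        if (i > 1) {
          r_i <- max(a_y, a_x)
          r_j <- pmax(ay[seq_len(i - 1)], ax[seq_len(i - 1)])
          d <- sqrt((cy[seq_len(i - 1)] - c_y)^2 + (cx[seq_len(i - 1)] - c_x)^2)
          ok <- all(d >= r_i + r_j + gap)
        }
        if (ok) {
          cz[i] <- c_z; cy[i] <- c_y; cx[i] <- c_x
          az[i] <- a_z; ay[i] <- a_y; ax[i] <- a_x
          placed <- TRUE
          break
        }
      }
      if (!placed)
        abort(sprintf("field too crowded: could not place nucleus %d of %d",
                      i, cond$n_cells),
              class = "dsbfoci_field_too_crowded")
    }

    phase <- ifelse(rbinom(cond$n_cells, 1L, cond$frac_g1) == 1L, "G1", "SG2")
    lambda <- ifelse(phase == "G1", cond$lambda_g1, cond$lambda_sg2)
    foci_count <- rpois(cond$n_cells, lambda)
    # per-cell total EdU intensity is drawn around a phase-specific target
    # (incorporated EdU reflects DNA synthesis, not nucleus size), then
    # expressed as a per-voxel level over the nucleus volume; 10% CV keeps
    # the two total-intensity clusters separated by far more than 6 SD
    edu_base <- ifelse(phase == "G1", render$edu_neg_intensity,
                       render$edu_pos_intensity)
    v_ref <- 4 / 3 * pi * mean(render$nucleus_axial_slices) *
      mean(r_px)^2 * 0.925            # reference nucleus volume in voxels
    v_i <- 4 / 3 * pi * az * ay * ax
    edu_total_target <- pmax(0, rnorm(cond$n_cells, edu_base * v_ref,
                                      0.10 * edu_base * v_ref))
    edu_level <- edu_total_target / v_i

    foci <- vector("list", cond$n_cells)
    for (i in seq_len(cond$n_cells)) {
      k <- foci_count[i]
      if (k == 0) next
      fz <- fy <- fx <- numeric(k)
      for (f in seq_len(k)) {
        for (try in seq_len(max_tries)) {
          # uniform point in the 0.9-scaled ellipsoid, by rejection in a cube
          repeat {
            u <- runif(3, -1, 1)
            if (sum(u^2) <= 1) break
          }
          p_z <- cz[i] + 0.9 * az[i] * u[1]
          p_y <- cy[i] + 0.9 * ay[i] * u[2]
          p_x <- cx[i] + 0.9 * ax[i] * u[3]
          # the rendered spot sits at the rounded voxel: require that voxel
          # to be comfortably inside the ellipsoid too, so a spot near the
          # axial rim cannot round onto a slice outside the nucleus
          ok <- ((round(p_z) - cz[i]) / az[i])^2 +
            ((round(p_y) - cy[i]) / ay[i])^2 +
            ((round(p_x) - cx[i]) / ax[i])^2 <= 0.93^2
          if (f > 1) {
            near_z <- abs(round(fz[seq_len(f - 1)]) - round(p_z)) <= 1
            if (any(near_z)) {
              d <- sqrt((fy[seq_len(f - 1)][near_z] - p_y)^2 +
                        (fx[seq_len(f - 1)][near_z] - p_x)^2)
              ok <- ok && all(d >= render$min_foci_sep_px)
            }
          }
          if (ok || try == max_tries) {
            fz[f] <- p_z; fy[f] <- p_y; fx[f] <- p_x
            break
          }
        }
      }
      foci[[i]] <- tibble(nucleus_id = i, z = fz, y = fy, x = fx)
    }
    foci <- if (all(foci_count == 0)) {
      tibble(nucleus_id = integer(), z = numeric(), y = numeric(), x = numeric())
    } else {
      bind_rows(foci)
    }

    nuclei <- tibble(
      nucleus_id = seq_len(cond$n_cells),
      phase = phase, foci_count = as.integer(foci_count),
      edu_level = edu_level,
      centroid_z = cz, centroid_y = cy, centroid_x = cx,
      semi_z = az, semi_y = ay, semi_x = ax
    )
    structure(list(nuclei = nuclei, foci = foci, cond = cond, render = render),
              class = "ground_truth")
  })
}

#' Voxel mask of one true nucleus ellipsoid
#'
#' Utility for truth-based evaluation (e.g. Dice overlap): the set of voxel
#' centres lying inside nucleus `i`'s ellipsoid.
#'
#' @param truth A `ground_truth` object.
#' @param i Nucleus id.
#' @return Logical 3D array of the render volume's shape.
#' @export
true_nucleus_mask <- function(truth, i) {
  stopifnot(inherits(truth, "ground_truth"))
  dims <- truth$render$shape_zyx
  nu <- truth$nuclei[truth$nuclei$nucleus_id == i, ]
  if (nrow(nu) != 1) abort("unknown nucleus_id")
  dz2 <- ((seq_len(dims[1]) - 1 - nu$centroid_z) / nu$semi_z)^2
  dy2 <- ((seq_len(dims[2]) - 1 - nu$centroid_y) / nu$semi_y)^2
  dx2 <- ((seq_len(dims[3]) - 1 - nu$centroid_x) / nu$semi_x)^2
  outer(outer(dz2, dy2, "+"), dx2, "+") <= 1
}

#' Render a ground-truth field into a three-channel image stack
#'
#' Forward model: the nuclear channel holds `nucleus_base_intensity` inside
#' each ellipsoid; the EdU channel holds the nucleus's `edu_level`; the
#' foci channel is a sum of in-plane Gaussian spots of SD `psf_sigma_px`
#' and peak `foci_amplitude` at the true focus positions (one z-slice per
#' spot — at 3 um optical sections a diffraction-scale spot lives in a
#' single slice). Optional additive Gaussian read noise, then clipping at 0.
#'
#' @param truth A `ground_truth` object from [sample_ground_truth()].
#' @param render Optional [render_params()]; defaults to the ones stored in
#'   `truth`.
#' @param seed Seed for the read-noise draw (ignored when `noise_sd = 0`).
#'
#' @return An object of class `"channel_stack"`: list with 3D arrays
#'   `nuclear`, `foci`, `edu` (dim = shape_zyx), `spacing_zyx`, and the
#'   generating `cond`.
#' @export
render_stack <- function(truth, render = NULL, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(render)) render <- truth$render
  dims <- render$shape_zyx
  nuclear <- array(0, dims)
  edu <- array(0, dims)
  foci_ch <- array(0, dims)

  for (i in seq_len(nrow(truth$nuclei))) {
    nu <- truth$nuclei[i, ]
    z0 <- max(1, floor(nu$centroid_z - nu$semi_z) + 1)
    z1 <- min(dims[1], ceiling(nu$centroid_z + nu$semi_z) + 1)
    y0 <- max(1, floor(nu$centroid_y - nu$semi_y) + 1)
    y1 <- min(dims[2], ceiling(nu$centroid_y + nu$semi_y) + 1)
    x0 <- max(1, floor(nu$centroid_x - nu$semi_x) + 1)
    x1 <- min(dims[3], ceiling(nu$centroid_x + nu$semi_x) + 1)
    dz2 <- (((z0:z1) - 1 - nu$centroid_z) / nu$semi_z)^2
    dy2 <- (((y0:y1) - 1 - nu$centroid_y) / nu$semi_y)^2
    dx2 <- (((x0:x1) - 1 - nu$centroid_x) / nu$semi_x)^2
    m <- outer(outer(dz2, dy2, "+"), dx2, "+") <= 1
    sub_n <- nuclear[z0:z1, y0:y1, x0:x1, drop = FALSE]
    sub_e <- edu[z0:z1, y0:y1, x0:x1, drop = FALSE]
    sub_n[m] <- render$nucleus_base_intensity
    sub_e[m] <- nu$edu_level
    nuclear[z0:z1, y0:y1, x0:x1] <- sub_n
    edu[z0:z1, y0:y1, x0:x1] <- sub_e
  }

  if (nrow(truth$foci) > 0) {
    s <- render$psf_sigma_px
    r <- max(1L, ceiling(4 * s))
    for (f in seq_len(nrow(truth$foci))) {
      fz <- min(max(round(truth$foci$z[f]), 0), dims[1] - 1) + 1
      fy <- truth$foci$y[f]
      fx <- truth$foci$x[f]
      y0 <- max(1, floor(fy) - r + 1); y1 <- min(dims[2], ceiling(fy) + r + 1)
      x0 <- max(1, floor(fx) - r + 1); x1 <- min(dims[3], ceiling(fx) + r + 1)
      gy <- exp(-(((y0:y1) - 1 - fy)^2) / (2 * s^2))
      gx <- exp(-(((x0:x1) - 1 - fx)^2) / (2 * s^2))
      foci_ch[fz, y0:y1, x0:x1] <- foci_ch[fz, y0:y1, x0:x1] +
        render$foci_amplitude * outer(gy, gx)
    }
  }

  if (render$noise_sd > 0) {
    withr::with_seed(seed, {
      n <- prod(dims)
      nuclear <- nuclear + array(rnorm(n, 0, render$noise_sd), dims)
      foci_ch <- foci_ch + array(rnorm(n, 0, render$noise_sd), dims)
      edu <- edu + array(rnorm(n, 0, render$noise_sd), dims)
    })
    nuclear <- pmax(nuclear, 0)
    foci_ch <- pmax(foci_ch, 0)
    edu <- pmax(edu, 0)
  }

  structure(list(nuclear = nuclear, foci = foci_ch, edu = edu,
                 spacing_zyx = render$spacing_zyx, cond = truth$cond),
            class = "channel_stack")
}

#' How many nuclei fit comfortably in one field
#'
#' Random sequential placement of non-overlapping nuclei saturates well
#' below close packing; this heuristic (45% of the disc-packing bound on
#' the usable field area at the maximum nucleus radius) keeps placement
#' reliable while matching typical field occupancies (about 50 nuclei at
#' the full 1392 x 1040 geometry).
#'
#' @param render A [render_params()] object.
#' @return Integer number of nuclei per field (at least 1).
#' @export
field_capacity <- function(render = render_params()) {
  px_nm <- render$spacing_zyx[2]
  rmax <- max(render$nucleus_radius_um) * 1000 / px_nm
  m <- rmax + render$placement_gap_px
  usable <- max(0, render$shape_zyx[2] - 2 * m) *
            max(0, render$shape_zyx[3] - 2 * m)
  max(1L, as.integer(floor(0.45 * usable / (pi * rmax^2))))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d nuclei (%d G1 / %d SG2), %d foci, volume %s\n",
              nrow(x$nuclei), sum(x$nuclei$phase == "G1"),
              sum(x$nuclei$phase == "SG2"), nrow(x$foci),
              paste(x$render$shape_zyx, collapse = "x")))
  invisible(x)
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("<channel_stack> %s voxels, spacing %s nm, channels: nuclear, foci, edu\n",
              paste(dim(x$nuclear), collapse = "x"),
              paste(x$spacing_zyx, collapse = "x")))
  invisible(x)
}

#' Simulate per-cell ground-truth records for a whole slide
#'
#' Samples the generative model at slide scale without rendering images:
#' the slide's nuclei are spread over fields of [field_capacity()] size
#' (placement included, so geometric invariants still hold) and returned
#' as one record per cell, with the per-nucleus total EdU intensity the
#' noise-free imaging pipeline would measure (`edu_level` times the
#' ellipsoid voxel volume).
#'
#' @param cond A [condition_params()] object (slide-level `n_cells`).
#' @param render A [render_params()] object.
#' @param seed Integer seed; per-field seeds are derived deterministically.
#' @return Tibble with `field_id`, `nucleus_id`, `phase`, `foci_count`,
#'   `edu_level`, `edu_total`, `voxels`, and the nucleus geometry columns.
#' @export
simulate_cell_truth <- function(cond, render = render_params(), seed = 1L) {
  stopifnot(inherits(cond, "condition_params"))
  cap <- field_capacity(render)
  n_fields <- ceiling(cond$n_cells / cap)
  per_field <- diff(round(seq(0, cond$n_cells, length.out = n_fields + 1)))
  out <- vector("list", n_fields)
  for (f in seq_len(n_fields)) {
    seed_f <- as.integer((as.numeric(seed) + 104729 * f) %% 2147483647)
    cond_f <- cond
    cond_f$n_cells <- as.integer(per_field[f])
    truth <- sample_ground_truth(cond_f, render, seed = seed_f)
    out[[f]] <- truth$nuclei %>%
      mutate(field_id = f,
             voxels = round(4 / 3 * pi * .data$semi_z * .data$semi_y *
                            .data$semi_x),
             edu_total = .data$edu_level * .data$voxels)
  }
  bind_rows(out)
}
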