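test_that("extended maxima: height criterion, additive invariance, degenerate flatness", {
  dims <- c(7, 21, 21)
  spot <- spot_volume(dims, data.frame(z = 3, y = 10, x = 10),
                      amplitude = 100, sigma = 1.5)
  em <- extended_maxima(spot, 80)
  expect_equal(attr(em, "n_components"), 1L)

  weak <- spot_volume(dims, data.frame(z = 3, y = 10, x = 10),
                      amplitude = 50, sigma = 1.5)
  expect_equal(attr(extended_maxima(weak, 80), "n_components"), 0L)

  # adding a constant changes nothing
  em2 <- extended_maxima(spot + 137.5, 80)
  expect_identical(unclass(em), unclass(em2))

  # blank and constant volumes carry no maxima
  expect_equal(attr(extended_maxima(array(0, dims), 80), "n_components"), 0L)
  expect_equal(attr(extended_maxima(array(42, dims), 10), "n_components"), 0L)
})

test_that("extended maxima agree with the fixpoint-reconstruction oracle on small volumes", {
  set.seed(71)
  for (rep in 1:6) {
    dims <- c(sample(4:9, 1), sample(6:12, 1), sample(6:12, 1))
    v <- gaussian_smooth(array(runif(prod(dims), 0, 150), dims), 1,
                         spacing_zyx = c(100, 100, 100))
    h <- sample(c(10, 25, 50), 1)
    em <- extended_maxima(v, h)
    oracle_mask <- r_extended_maxima_mask(v, h)
    expect_identical(array(em > 0, dims), oracle_mask,
                     info = sprintf("rep %d h=%g", rep, h))
  }
})

test_that("grayscale reconstruction matches the iterative oracle", {
  set.seed(72)
  for (rep in 1:5) {
    dims <- c(5, 7, 6)
    mask <- array(runif(prod(dims), 0, 100), dims)
    marker <- mask - runif(1, 5, 40)
    rec <- morph_reconstruct(marker, mask)
    expect_equal(rec, r_reconstruct(marker, mask), tolerance = 1e-12)
  }
})

test_that("foci counting honours the size filter, zero channels, and offsets", {
  # a labelled nucleus occupying most of a small volume
  mask <- array(FALSE, c(8, 30, 30))
  mask[2:7, 3:28, 3:28] <- TRUE
  nuclei <- label_nuclei(mask, segmentation_params(min_voxels = 100))
  expect_equal(nuclei$n_nuclei, 1L)

  blank <- array(0, c(8, 30, 30))
  fr <- detect_foci(blank, nuclei)
  expect_equal(fr$cells$foci_count, 0L)
  expect_equal(nrow(fr$spots), 0L)

  # a supra-threshold plateau of 900 voxels exceeds max_spot_voxels = 800
  plateau <- array(0, c(8, 30, 30))
  plateau[3:5, 6:23, 6:22] <- 200          # 3*18*17 = 918 voxels
  fr2 <- detect_foci(plateau, nuclei, foci_params(sigma_px = 0))
  expect_equal(fr2$cells$foci_count, 0L)
  fr2b <- detect_foci(plateau, nuclei,
                      foci_params(sigma_px = 0, max_spot_voxels = 1000))
  expect_equal(fr2b$cells$foci_count, 1L)

  # additive offsets do not change counts
  spots <- data.frame(z = c(3, 4, 5), y = c(8, 15, 22), x = c(8, 20, 12))
  v <- spot_volume(c(8, 30, 30), spots, amplitude = 200)
  f1 <- detect_foci(v, nuclei)
  f2 <- detect_foci(v + 500, nuclei)
  expect_equal(f1$cells$foci_count, 3L)
  expect_equal(f2$cells$foci_count, 3L)

  expect_error(detect_foci(array(0, c(2, 2, 2)), nuclei),
               class = "dsbfoci_shape_mismatch")
})

test_that("raising the height threshold never increases a count", {
  mask <- array(FALSE, c(8, 40, 40))
  mask[2:7, 3:38, 3:38] <- TRUE
  nuclei <- label_nuclei(mask, segmentation_params(min_voxels = 100))
  set.seed(73)
  for (rep in 1:4) {
    n <- sample(3:8, 1)
    spots <- data.frame(z = sample(2:6, n, replace = TRUE),
                        y = runif(n, 6, 34), x = runif(n, 6, 34))
    amp <- runif(1, 120, 260)
    v <- spot_volume(c(8, 40, 40), spots, amplitude = amp)
    counts <- vapply(c(30, 60, 90, 120), function(h)
      detect_foci(v, nuclei, foci_params(height_h = h))$cells$foci_count, 0L)
    expect_true(all(diff(counts) <= 0), info = sprintf("rep %d", rep))
  }
})

test_that("counts are invariant to nucleus relabelling", {
  cond <- condition_params(lambda_g1 = 4, frac_g1 = 1, n_cells = 3)
  render <- small_render()
  truth <- sample_ground_truth(cond, render, seed = 74)
  stack <- render_stack(truth, render, seed = 74)
  seg <- segment_nuclei(stack)
  fr <- detect_foci(stack, seg)
  # permute labels
  perm <- c(2L, 3L, 1L)
  seg2 <- seg
  seg2$labels[seg$labels > 0L] <- perm[seg$labels[seg$labels > 0L]]
  seg2$nuclei$nucleus_id <- perm[seg$nuclei$nucleus_id]
  fr2 <- detect_foci(stack, seg2)
  merged <- merge(fr$cells, data.frame(nucleus_id = seg$nuclei$nucleus_id,
                                       new_id = perm))
  merged2 <- merge(merged, fr2$cells, by.x = "new_id", by.y = "nucleus_id")
  expect_equal(merged2$foci_count.x, merged2$foci_count.y)
})

test_that("the full counting pipeline recovers a Poisson rate on a small slide", {
  lambda <- 5.69
  cond <- condition_params(lambda_g1 = lambda, frac_g1 = 1, n_cells = 40)
  render <- small_render()
  sa <- analyze_slide(cond, render, seed = 75, keep_truth = TRUE)
  true_counts <- do.call(rbind, lapply(sa$truth, function(t) t$nuclei))
  # detection matches the simulated truth exactly in the noise-free regime
  expect_equal(sum(sa$cells$foci_count), sum(true_counts$foci_count))
  expect_lt(abs(mean(sa$cells$foci_count) - lambda), 3 * sqrt(lambda / 40))
})
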