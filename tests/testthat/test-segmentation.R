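test_that("Gaussian smoothing: identity at sigma 0, constants preserved, impulse matches the separable kernel", {
  set.seed(61)
  v <- array(runif(5 * 6 * 7), c(5, 6, 7))
  expect_identical(gaussian_smooth(v, 0), v)

  const <- array(3.7, c(6, 6, 6))
  expect_equal(gaussian_smooth(const, 2), const, tolerance = 1e-12)

  # unit impulse at the centre of a 9^3 volume, isotropic spacing so all
  # three axes are smoothed; compare against a directly evaluated
  # normalized separable Gaussian
  imp <- array(0, c(9, 9, 9))
  imp[5, 5, 5] <- 1
  sm <- gaussian_smooth(imp, 1, spacing_zyx = c(100, 100, 100))
  r <- 3
  w <- exp(-0.5 * (-r:r)^2)
  w <- w / sum(w)
  expected <- outer(outer(c(0, w, 0), c(0, w, 0)), c(0, w, 0))
  expect_equal(sm, array(expected, c(9, 9, 9)), tolerance = 1e-12)

  # mean preservation within 1%
  set.seed(62)
  vol <- array(runif(10 * 20 * 20, 0, 100), c(10, 20, 20))
  expect_lt(abs(mean(gaussian_smooth(vol, 1.5)) - mean(vol)) / mean(vol), 0.01)

  expect_error(gaussian_smooth(vol, -1), class = "dsbfoci_invalid_params")
})

test_that("two-level Otsu matches exhaustive search and separates well-formed classes", {
  # three equal blocks at 0 / 128 / 255
  v <- array(rep(c(0, 128, 255), each = 128), c(8, 8, 6))
  th <- two_level_otsu(v, 256)
  expect_gt(th[["t_low"]], 0)
  expect_lte(th[["t_low"]], 128)
  expect_gt(th[["t_high"]], 128)
  expect_lte(th[["t_high"]], 255)

  # 8-bin histogram [10,0,0,8,0,0,0,12] over values 0..7
  vals <- c(rep(0, 10), rep(3, 8), rep(7, 12))
  th8 <- two_level_otsu(vals, 8)
  sp <- oracle_otsu2_splits(vals, 8)
  bw <- 7 / 8
  expect_equal(unname(th8), c((sp[1] + 1) * bw, (sp[2] + 1) * bw),
               tolerance = 1e-12)

  # property: exhaustive-search agreement on random small histograms
  # (integer data spanning 0..n_bins-1, so bins and values are in 1:1
  # correspondence and the oracle's split values map onto bin edges)
  set.seed(63)
  for (rep in 1:15) {
    n_bins <- sample(6:32, 1)
    vals <- c(0, n_bins - 1,
              sample(0:(n_bins - 1), 300, replace = TRUE,
                     prob = runif(n_bins)^2 + 0.01))
    if (length(unique(vals)) < 3) next
    th <- two_level_otsu(vals, n_bins)
    sp <- oracle_otsu2_splits(vals, n_bins)
    bw <- (n_bins - 1) / n_bins
    expect_equal(unname(th), c((sp[1] + 1) * bw, (sp[2] + 1) * bw),
                 tolerance = 1e-9, info = sprintf("rep %d", rep))
  }

  expect_error(two_level_otsu(array(c(1, 1, 2, 2), c(2, 2, 1))),
               class = "dsbfoci_degenerate_histogram")
})

test_that("two-level Otsu low threshold recovers the exact nucleus voxel set on a noise-free field", {
  cond <- condition_params(lambda_g1 = 2, frac_g1 = 1, n_cells = 2)
  render <- small_render()
  truth <- sample_ground_truth(cond, render, seed = 64)
  stack <- render_stack(truth, render, seed = 64)
  v <- stack$nuclear
  # plant a bright third class inside the first nucleus (0/100/300 field)
  m1 <- true_nucleus_mask(truth, 1)
  idx <- which(m1)[1:50]
  v[idx] <- 300
  th <- two_level_otsu(v, 256)
  expect_gt(th[["t_low"]], 0)
  expect_lte(th[["t_low"]], 100)
  expect_gt(th[["t_high"]], 100)
  truth_mask <- true_nucleus_mask(truth, 1) | true_nucleus_mask(truth, 2)
  expect_identical(v >= th[["t_low"]], truth_mask)
})

test_that("hysteresis mask obeys the sandwich property and the connectivity rule", {
  line <- array(c(200, 90, 90, 40, 90), c(1, 1, 5))
  m <- hysteresis_mask(line, 80, 150)
  expect_equal(as.logical(m), c(TRUE, TRUE, TRUE, FALSE, FALSE))

  v <- array(200, c(3, 3, 3))
  expect_true(all(hysteresis_mask(v, 10, 100)))
  expect_false(any(hysteresis_mask(array(5, c(3, 3, 3)), 10, 100)))

  set.seed(65)
  for (rep in 1:10) {
    v <- array(runif(8 * 8 * 8, 0, 100), c(8, 8, 8))
    tl <- runif(1, 10, 50)
    th <- runif(1, 50, 95)
    m <- hysteresis_mask(v, tl, th)
    expect_true(all(m[v >= th]))          # high set inside mask
    expect_true(all(v[m] >= tl))          # mask inside low set
  }
  expect_error(hysteresis_mask(line, 150, 80), class = "dsbfoci_invalid_params")
})

test_that("nucleus labelling filters by size and border contact and orders labels by size", {
  mask <- array(FALSE, c(10, 40, 40))
  mask[3:7, 2:25, 2:26] <- TRUE      # 5*24*25 = 3000 voxels
  mask[3:7, 28:37, 2:31] <- TRUE     # 5*10*30 = 1500 voxels
  lab <- label_nuclei(mask, segmentation_params(min_voxels = 2000,
                                                exclude_border = FALSE))
  expect_equal(lab$n_nuclei, 1L)
  lab2 <- label_nuclei(mask, segmentation_params(min_voxels = 1000,
                                                 exclude_border = FALSE))
  expect_equal(lab2$n_nuclei, 2L)
  # labels in decreasing size order
  expect_equal(lab2$nuclei$voxels, c(3000L, 1500L))

  # border component dropped when exclusion is on
  maskb <- mask
  maskb[1, 2:25, 2:26] <- TRUE
  maskb[2, 2:25, 2:26] <- TRUE
  lab3 <- label_nuclei(maskb, segmentation_params(min_voxels = 1000,
                                                  exclude_border = TRUE))
  expect_equal(lab3$n_nuclei, 1L)
  expect_equal(lab3$nuclei$voxels, 1500L)

  empty <- label_nuclei(array(FALSE, c(4, 4, 4)))
  expect_equal(empty$n_nuclei, 0L)
  expect_equal(nrow(empty$nuclei), 0L)
})

test_that("segmentation recovers every nucleus on noise-free fields with high overlap", {
  cond <- condition_params(lambda_g1 = 3, lambda_sg2 = 12, frac_g1 = 0.8,
                           n_cells = 5)
  render <- small_render()
  truth <- sample_ground_truth(cond, render, seed = 66)
  stack <- render_stack(truth, render, seed = 66)
  seg <- segment_nuclei(stack)
  expect_equal(seg$n_nuclei, nrow(truth$nuclei))
  ev <- evaluate_segmentation(truth, seg)
  expect_true(all(!is.na(ev$matched_label)))
  expect_true(all(ev$dice >= 0.8))
  expect_gt(mean(ev$dice), 0.95)
})

test_that("segmentation is invariant to affine intensity rescaling", {
  cond <- condition_params(lambda_g1 = 2, frac_g1 = 1, n_cells = 3)
  render <- small_render()
  truth <- sample_ground_truth(cond, render, seed = 67)
  stack <- render_stack(truth, render, seed = 67)
  seg1 <- segment_nuclei(stack)
  stack2 <- stack
  stack2$nuclear <- 2.5 * stack$nuclear + 40
  seg2 <- segment_nuclei(stack2)
  expect_identical(seg1$labels, seg2$labels)
})
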