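test_that("foci summaries reproduce mean, SEM and n, with the n = 1 convention", {
  s <- summarize_foci(tibble::tibble(line_id = "hDF", phase = "G1",
                                     foci_count = c(1, 2, 3)),
                      group_keys = c("line_id", "phase"))
  expect_equal(s$mean_foci, 2)
  expect_equal(s$sem, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(s$sem, 0.5773503, tolerance = 1e-6)
  expect_equal(s$n_cells, 3L)

  expect_warning(
    s1 <- summarize_foci(tibble::tibble(line_id = "x", phase = "G1",
                                        foci_count = 4),
                         group_keys = "line_id"),
    "single cell")
  expect_equal(s1$sem, 0)

  expect_error(summarize_foci(tibble::tibble(foci_count = 1:3,
                                             phase = c("G1", "UNSET", "G1"))),
               class = "dsbfoci_invalid_params")
})

test_that("summary statistics agree with a naive two-pass oracle", {
  set.seed(91)
  recs <- tibble::tibble(
    line_id = sample(c("a", "b", "c"), 300, replace = TRUE),
    phase = sample(c("G1", "SG2"), 300, replace = TRUE),
    foci_count = rpois(300, 7))
  s <- summarize_foci(recs, group_keys = c("line_id", "phase"))
  for (r in seq_len(nrow(s))) {
    v <- recs$foci_count[recs$line_id == s$line_id[r] &
                         recs$phase == s$phase[r]]
    m <- sum(v) / length(v)
    sem <- sqrt(sum((v - m)^2) / (length(v) - 1)) / sqrt(length(v))
    expect_equal(s$mean_foci[r], m, tolerance = 1e-9)
    expect_equal(s$sem[r], sem, tolerance = 1e-9)
  }
})

test_that("fold change and percent increase are consistent and round as reported", {
  expect_equal(fold_change(7.3, 7.3), 1)
  expect_equal(fold_change(19.89, 1.13), 17.60177, tolerance = 1e-6)
  expect_equal(format_fold(fold_change(19.89, 1.13)), 18)
  expect_equal(format_fold(fold_change(24.45, 11.57)), 2.1)
  expect_error(fold_change(1, 0), class = "dsbfoci_invalid_params")

  expect_equal(percent_increase(5, 5), 0)
  expect_equal(percent_increase(1.13, 19.89), 1660.177, tolerance = 1e-4)
  expect_equal(percent_increase(2, 1), -50)
  expect_error(percent_increase(0, 1), class = "dsbfoci_invalid_params")

  # fold = 1 + percent/100 exactly
  set.seed(92)
  for (rep in 1:20) {
    ctrl <- runif(1, 0.5, 10)
    irr <- runif(1, 0, 50)
    expect_equal(fold_change(irr, ctrl),
                 1 + percent_increase(ctrl, irr) / 100, tolerance = 1e-12)
  }
})

test_that("two-group comparison matches the closed-form pooled t computation", {
  same <- compare_two_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  a <- c(1, 2, 3, 4); b <- c(11, 12, 13, 14)
  cmp <- compare_two_groups(a, b)
  oracle <- oracle_pooled_t(a, b)
  expect_equal(cmp$statistic, oracle$t, tolerance = 1e-9)
  expect_equal(cmp$p_value, oracle$p, tolerance = 1e-9)
  expect_equal(cmp$df, oracle$df)

  expect_error(compare_two_groups(1, c(1, 2)), class = "dsbfoci_invalid_params")
})

test_that("the t test holds its type-I error rate under a Poisson null", {
  set.seed(93)
  n_rep <- 1000
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    a <- rpois(200, 5)
    b <- rpois(200, 5)
    rej[r] <- compare_two_groups(a, b)$p_value < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("one-way ANOVA with Tukey HSD matches the long-hand table and flags the right pairs", {
  flat <- anova_tukey(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(flat$statistic, 0)
  expect_false(any(flat$pairwise$significant))

  groups <- list(g1 = c(6, 8, 4, 5, 3, 4),
                 g2 = c(8, 12, 9, 11, 6, 8),
                 g3 = c(13, 9, 11, 8, 7, 12))
  cmp <- anova_tukey(groups)
  oracle <- oracle_anova_f(groups)
  expect_equal(cmp$statistic, oracle$f, tolerance = 1e-9)
  expect_equal(cmp$p_value, oracle$p, tolerance = 1e-9)

  # Tukey adjusted p is never below the unadjusted pairwise t p
  set.seed(94)
  for (rep in 1:5) {
    gs <- list(a = rpois(20, 5), b = rpois(25, 6), c = rpois(15, 5))
    tk <- anova_tukey(gs)
    for (r in seq_len(nrow(tk$pairwise))) {
      pa <- gs[[tk$pairwise$group_a[r]]]
      pb <- gs[[tk$pairwise$group_b[r]]]
      expect_gte(tk$pairwise$adjusted_p[r] + 1e-9,
                 oracle_pooled_t(pa, pb)$p)
    }
  }

  # hDF-vs-stem-cell pattern: only contrasts against the low-rate group
  set.seed(95)
  sim <- list(hDF = rpois(200, 1.1), lineA = rpois(200, 5.7),
              lineB = rpois(200, 5.7))
  pat <- anova_tukey(sim)
  involves_hdf <- pat$pairwise$group_a == "hDF" | pat$pairwise$group_b == "hDF"
  expect_true(all(pat$pairwise$significant[involves_hdf]))
  expect_false(any(pat$pairwise$significant[!involves_hdf]))

  expect_error(anova_tukey(list(a = 1:3, b = 1:3)),
               class = "dsbfoci_too_few_groups")
})

test_that("repair time courses report percent remaining relative to the 0.5 h peak", {
  mk <- function(means) tibble::tibble(
    line_id = "L", marker = "gH2AX", phase = "G1",
    time_h = c(0, 0.5, 2, 6), mean_foci = means)

  flat <- repair_time_course(mk(c(5, 5, 5, 5)))
  expect_equal(flat$percent_remaining_2h, 100)
  expect_equal(flat$percent_remaining_6h, 100)

  tc <- repair_time_course(mk(c(1, 20, 10, 5)))
  expect_equal(tc$percent_remaining_2h, 50)
  expect_equal(tc$percent_remaining_6h, 25)

  expect_error(repair_time_course(mk(c(1, 20, 10, 5))[-2, ]),
               class = "dsbfoci_missing_timepoint")

  # faster repair declines further by 6 h
  fast <- repair_time_course(mk(c(1, 20, 8, 3)))
  slow <- repair_time_course(mk(c(1, 12, 10, 9)))
  expect_lt(fast$percent_remaining_6h, slow$percent_remaining_6h)
})

test_that("the packaged condition summary table loads with the expected schema", {
  tab <- table1()
  expect_equal(nrow(tab), 72L)
  expect_named(tab, c("line", "passage", "marker", "treatment", "phase",
                      "mean_foci", "sem", "n_cells"))
  hdf <- tab[tab$line == "hDF" & tab$marker == "gH2AX" &
             tab$treatment == "control" & tab$phase == "G1", ]
  expect_equal(hdf$mean_foci, 1.13)
  expect_equal(hdf$n_cells, 463L)
  expect_true(all(tab$sem >= 0) && all(tab$n_cells >= 1))
})
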