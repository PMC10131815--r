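make_tc <- function(means, compartment = "cell", sd = 0) {
  rows <- do.call(rbind, lapply(names(means), function(t) {
    data.frame(timepoint_h = as.numeric(t), compartment = compartment,
               replicate = 1:3,
               value = means[[t]] + c(-sd, 0, sd))
  }))
  timecourse(rows)
}

test_that("timecourse validates its schema", {
  expect_error(timecourse(data.frame(timepoint_h = 1)), "lack columns")
  expect_error(timecourse(data.frame(timepoint_h = -1, compartment = "c",
                                     replicate = 1, value = 1)),
               "non-negative")
  bad_units <- data.frame(timepoint_h = c(1, 2), compartment = "c",
                          replicate = 1, value = 1, unit = c("a", "b"))
  expect_error(timecourse(bad_units), "consistent")
})

test_that("peak finding returns the argmax of per-timepoint means", {
  cells <- make_tc(list(`0.5` = 400, `1` = 1355, `5` = 434, `24` = 100),
                   sd = 10)
  pk <- find_peak(cells, "cell")
  expect_equal(pk$timepoint_h, 1)
  expect_equal(pk$mean, 1355)
  expect_false(pk$tie)

  evs <- make_tc(list(`0.5` = 2, `1` = 6, `5` = 31, `24` = 12),
                 compartment = "EV")
  expect_equal(find_peak(evs, "EV")$timepoint_h, 5)
  expect_equal(find_peak(evs, "EV")$mean, 31)

  flat <- make_tc(list(`1` = 7, `5` = 7, `24` = 7))
  pk_flat <- find_peak(flat, "cell")
  expect_equal(pk_flat$timepoint_h, 1)
  expect_true(pk_flat$tie)

  expect_error(find_peak(cells, "EV"), "no records")
})

test_that("peak finding is invariant to record order", {
  set.seed(2)
  tc <- make_tc(list(`0.5` = 10, `1` = 50, `5` = 30), sd = 3)
  shuffled <- timecourse(tc[sample(nrow(tc)), ])
  expect_equal(find_peak(shuffled, "cell"), find_peak(tc, "cell"))
})

test_that("compartment contrasts divide per-timepoint means", {
  tc <- timecourse(rbind(
    data.frame(timepoint_h = 1, compartment = "cell", replicate = 1:2,
               value = c(1350, 1360)),
    data.frame(timepoint_h = 1, compartment = "EV", replicate = 1:2,
               value = c(5, 7))
  ))
  expect_equal(compartment_contrast(tc, "cell", "EV", 1), 1355 / 6)
  expect_equal(compartment_contrast(tc, "cell", "cell", 1), 1)
  expect_error(compartment_contrast(tc, "cell", "EV", 5), "measured at")
})

test_that("Mann-Whitney matches full permutation enumeration", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1) # 2 / choose(6, 3)

  set.seed(19)
  for (n1 in 1:6) {
    for (n2 in n1:6) {
      x <- sample(seq_len(100), n1)
      y <- setdiff(seq_len(100), x)[seq_len(n2)]
      ours <- mann_whitney(x, y)
      ref <- mw_enum_oracle(x, y)
      expect_equal(ours$statistic, ref$u)
      expect_equal(ours$p_value, ref$p, tolerance = 1e-12)
    }
  }
})

test_that("Mann-Whitney null behaviour and tie handling", {
  # balanced interleaved samples sit exactly at the null centre
  expect_equal(mann_whitney(c(1, 4), c(2, 3))$p_value, 1)
  # identical multisets force the tie-corrected approximation, far from
  # significance
  res <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_match(res$method, "approximation")
  expect_gt(res$p_value, 0.5)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("rank tests are invariant under monotone transformations", {
  set.seed(23)
  x <- rnorm(8); y <- rnorm(8) + 1
  g <- list(a = rnorm(5), b = rnorm(5) + 0.5, c = rnorm(5) - 0.5)
  mono <- function(v) exp(v) # strictly increasing
  expect_equal(mann_whitney(mono(x), mono(y))$p_value,
               mann_whitney(x, y)$p_value, tolerance = 1e-12)
  expect_equal(kruskal_dunn(lapply(g, mono))$p_value,
               kruskal_dunn(g)$p_value, tolerance = 1e-12)
  m <- cbind(a = rnorm(6), b = rnorm(6), c = rnorm(6))
  expect_equal(friedman_dunn(mono(m))$statistic,
               friedman_dunn(m)$statistic, tolerance = 1e-12)
})

test_that("Kruskal-Wallis H matches the rank closed form; Dunn follows", {
  g <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  res <- kruskal_dunn(g)
  # H = 12 / (N (N + 1)) * sum n_i (rbar_i - (N + 1) / 2)^2, ranks 1..6
  h_hand <- 12 / (6 * 7) * (2 * (1.5 - 3.5)^2 + 2 * (3.5 - 3.5)^2 +
                              2 * (5.5 - 3.5)^2)
  expect_equal(res$statistic, h_hand, tolerance = 1e-12)

  # Dunn z against hand rank arithmetic: var0 = N (N + 1) / 12 = 3.5
  comp <- res$comparisons
  z_ac <- (1.5 - 5.5) / sqrt(3.5 * (1 / 2 + 1 / 2))
  expect_equal(comp$z[comp$group1 == "a" & comp$group2 == "c"], z_ac,
               tolerance = 1e-9)
  expect_equal(comp$p_value, 2 * pnorm(-abs(comp$z)), tolerance = 1e-12)

  # identical groups: H = 0, p = 1
  same <- kruskal_dunn(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(kruskal_dunn(list(1:3, 4:6)), "mann_whitney")
})

test_that("Dunn adjusted p-values dominate raw p-values and stay in [0,1]", {
  set.seed(41)
  for (i in 1:10) {
    g <- list(a = rnorm(4), b = rnorm(5), c = rnorm(6), d = rnorm(4))
    for (adj in c("holm", "bonferroni")) {
      comp <- kruskal_dunn(g, adjust = adj)$comparisons
      expect_true(all(comp$p_adjusted >= comp$p_value - 1e-15))
      expect_true(all(comp$p_adjusted <= 1))
      expect_true(all(comp$p_value >= 0))
    }
  }
})

test_that("Friedman test matches hand rank computation on a toy block", {
  m <- cbind(t1 = c(1, 2, 3, 4), t2 = c(3, 1, 4, 2), t3 = c(5, 6, 7, 8))
  # within-block ranks: t3 always 3; t1/t2 split depends on row
  ranks <- t(apply(m, 1, rank))
  n <- 4; k <- 3
  chi_hand <- 12 / (n * k * (k + 1)) * sum(colSums(ranks)^2) - 3 * n * (k + 1)
  res <- friedman_dunn(m)
  expect_equal(res$statistic, chi_hand, tolerance = 1e-12)

  # identical columns: statistic 0, p = 1
  same <- friedman_dunn(cbind(a = 1:4, b = 1:4, c = 1:4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(friedman_dunn(cbind(a = c(1, NA), b = 1:2, c = 1:2)),
               "missing cells")
})

test_that("null simulations hold the nominal type-I error", {
  set.seed(101)
  n_rep <- 4000
  kw_rej <- mean(replicate(n_rep, {
    kruskal_dunn(list(rnorm(8), rnorm(8), rnorm(8)))$p_value < 0.05
  }))
  expect_gt(kw_rej, 0.035)
  expect_lt(kw_rej, 0.065)

  fr_rej <- mean(replicate(n_rep, {
    friedman_dunn(matrix(rnorm(36), nrow = 12))$p_value < 0.05
  }))
  expect_gt(fr_rej, 0.03)
  expect_lt(fr_rej, 0.065)
})
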