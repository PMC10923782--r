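# Error metrics, growth-rate computation with the artifact filters,
# growing-fraction partitioning, smoothing, conditioned error tables.

test_that("across-time RMSE matches direct formula evaluation", {
  expect_identical(rmseTime(c(1, 2), c(1, 2)), 0)
  expect_identical(rmseTime(c(3, 3, 3), c(1, 1, 1)), 2)
  expect_equal(rmseTime(c(1, 3), c(0, 0)), sqrt(5))
  expect_true(is.na(rmseTime(c(NA, NA), c(1, 2))))
  # missing pairs excluded pairwise
  expect_equal(rmseTime(c(1, NA, 3), c(0, 5, 0)), sqrt(5))
})

test_that("across-cells RMSE matches direct formula evaluation", {
  F_mat <- rbind(c(3, 0), c(4, 0))
  expect_equal(rmseCells(F_mat, matrix(0, 2, 2)), c(5 / sqrt(2), 0))
  # single cell reduces to per-timepoint absolute error
  expect_equal(rmseCells(matrix(c(1, -2), 1), matrix(0, 1, 2)), c(1, 2))
})

test_that("both RMSE metrics agree with a brute-force double loop", {
  set.seed(4)
  F_mat <- matrix(rnorm(35), 5, 7)
  G_mat <- matrix(rnorm(35), 5, 7)
  brute_time <- vapply(1:5, function(n) {
    acc <- 0
    for (t in 1:7) acc <- acc + (F_mat[n, t] - G_mat[n, t])^2
    sqrt(acc / 7)
  }, numeric(1))
  brute_cells <- vapply(1:7, function(t) {
    acc <- 0
    for (n in 1:5) acc <- acc + (F_mat[n, t] - G_mat[n, t])^2
    sqrt(acc / 5)
  }, numeric(1))
  per_cell <- vapply(1:5, function(n) rmseTime(F_mat[n, ], G_mat[n, ]),
                     numeric(1))
  expect_lt(max(abs(per_cell - brute_time)), 1e-12)
  expect_lt(max(abs(rmseCells(F_mat, G_mat) - brute_cells)), 1e-12)
  # 1x1 consistency: both definitions coincide
  expect_identical(rmseCells(F_mat[1, 1, drop = FALSE],
                             G_mat[1, 1, drop = FALSE]),
                   rmseTime(F_mat[1, 1], G_mat[1, 1]))
})

test_that("growth-rate filters reproduce the hand-computed missing pattern", {
  # 10-point toy area series: constant growth, one division, one artifact
  area <- c(2.0, 2.1, 2.2, 1.1, 1.2, 1.3, 0.4, 1.4, 1.5, 1.6)
  fluo <- rep(500, 10)
  g <- growthRate(area, fluo)
  expect_length(g, 10)
  # division step: (1.1 - 2.2)/2.2 = -0.5 per interval = -6 1/h -> filtered
  expect_true(is.na(g[3]))
  # area 0.4 < 0.44 um^2 at t = 7: growth missing at t-1 and t
  expect_true(is.na(g[6]))
  expect_true(is.na(g[7]))
  # valid positions carry the per-hour conversion: (2.1-2.0)/2.0 * 12
  expect_equal(g[1], 0.05 * 12)
  expect_true(is.na(g[10]))  # last point has no forward difference
  # constant area gives zero growth
  expect_true(all(growthRate(rep(2, 5), rep(500, 5))[1:4] == 0))
  # low fluorescence filters the position too
  g2 <- growthRate(rep(2, 5), c(500, 500, 50, 500, 500))
  expect_true(is.na(g2[2]) && is.na(g2[3]))
})

test_that("growing fraction partitions at the 0.3 1/h threshold", {
  g <- rbind(matrix(1.4, 7, 4), matrix(0, 3, 4))
  expect_identical(growingFraction(g), rep(0.7, 4))
  expect_identical(growingFraction(matrix(1.4, 5, 3)), rep(1, 3))
  expect_identical(growingFraction(matrix(0, 5, 3)), rep(0, 3))
  # constructed 70/30 mixture with noise stays near 0.7
  set.seed(2)
  gm <- rbind(matrix(rnorm(70 * 10, 1.0, 0.05), 70),
              matrix(rnorm(30 * 10, 0.0, 0.05), 30))
  expect_lt(max(abs(growingFraction(gm) - 0.7)), 0.05)
  expect_true(all(is.na(growingFraction(matrix(NA_real_, 3, 2)))))
})

test_that("median filter removes spikes and preserves constants", {
  x <- rep(5, 30)
  expect_equal(smoothSeries(x, "median1h"), x)
  x2 <- x; x2[15] <- 100
  expect_equal(smoothSeries(x2, "median1h")[15], 5)
  # missing-aware: NA values are excluded, not propagated
  x3 <- x; x3[10] <- NA
  expect_equal(smoothSeries(x3, "median1h")[10], 5)
})

test_that("Savitzky-Golay(15,2) reproduces quadratics exactly in the interior", {
  t <- 1:40
  y <- 2 + 0.5 * t - 0.03 * t^2
  sm <- smoothSeries(y, "savgol")
  expect_lt(max(abs(sm[8:33] - y[8:33])), 1e-9)
  expect_equal(smoothSeries(rep(3, 20), "savgol"), rep(3, 20))
  # cross-check against the reference implementation on an NA-free interior
  skip_if_not_installed("signal")
  set.seed(6)
  y2 <- cumsum(rnorm(60))
  ref <- signal::sgolayfilt(y2, p = 2, n = 15)
  sm2 <- smoothSeries(y2, "savgol")
  expect_lt(max(abs(sm2[8:53] - ref[8:53])), 1e-9)
})

test_that("conditioned error bins behave on null and structured cases", {
  set.seed(7)
  pred <- matrix(rnorm(50 * 40, 0, 1), 50, 40)
  obj <- matrix(0, 50, 40)
  cov_indep <- matrix(runif(50 * 40), 50, 40)
  tab <- conditionedError(pred, obj, cov_indep, type = "value", n_bins = 5)
  # error independent of covariate: flat profile within sampling error
  expect_lt(diff(range(tab$rmse)), 0.3)
  # growth-percentile table covers percentiles 1..100 with no gaps
  tg <- conditionedError(pred, obj, cov_indep, type = "growth")
  expect_identical(tg$bin, 1:100)
  expect_false(anyNA(tg$n))
  # error scaling with |derivative| is detected
  cov_d <- matrix(seq(-100, 100, length.out = 40), 50, 40, byrow = TRUE)
  pred2 <- obj + matrix(rnorm(50 * 40), 50, 40) * (1 + abs(cov_d) / 50)
  td <- conditionedError(pred2, obj, cov_d, type = "derivative", n_bins = 9)
  ok <- !is.na(td$rmse)
  expect_gt(cor(abs(td$bin[ok]), td$rmse[ok], method = "spearman"), 0)
})
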