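# Stimulation design, normalization, sample extraction, ablation
# transforms, and the on-disk container.

test_that("random-walk stimulation binarizes the cumulative sum of normal steps", {
  s <- randomWalkStimulation(192, rng_seed = 1)
  b <- bits(s)
  expect_length(b, 192)
  expect_true(all(b %in% c(0, 1)))
  # dual-route: recompute from the same RNG stream
  set.seed(1)
  expect_identical(b, as.numeric(cumsum(rnorm(192)) > 0))
  expect_error(randomWalkStimulation(0), "T_points")
})

test_that("a walk that stays positive gives all-green", {
  # sign constancy: if every partial sum is positive the sequence is 1s
  found <- FALSE
  for (seed in 1:200) {
    set.seed(seed)
    w <- cumsum(rnorm(20))
    if (all(w > 0)) {
      expect_identical(bits(randomWalkStimulation(20, rng_seed = seed)),
                       rep(1, 20))
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("random-walk epochs are long: mean run length exceeds 5 intervals", {
  set.seed(10)
  runs <- vapply(1:1000, function(i) {
    b <- bits(randomWalkStimulation(192))
    mean(rle(b)$lengths)
  }, numeric(1))
  expect_gt(mean(runs), 5)
})

test_that("normalizer maps corpus bounds to [0,1] and round-trips", {
  m <- matrix(runif(8 * 50), 8, 50)
  m[3, ] <- seq(100, 2600, length.out = 50)  # known endpoints on one channel
  ts <- list(m)
  norm <- fitNormalizer(ts, robust = FALSE)
  expect_identical(norm@lo[3], 100)
  expect_identical(norm@hi[3], 2600)
  nm <- applyNormalizer(m, norm)
  expect_equal(nm[3, 1], 0)
  expect_equal(nm[3, 50], 1)
  expect_true(all(nm >= 0 & nm <= 1))
  # exact inversion on an in-range channel
  back <- denormalize(nm[3, ], norm, channel = 3)
  expect_lt(max(abs(back - m[3, ])), 1e-12)
  # binary channels pinned to (0, 1)
  expect_identical(norm@lo[1], 0)
  expect_identical(norm@hi[1], 1)
})

test_that("degenerate constant channels normalize to zero", {
  m <- matrix(runif(8 * 30), 8, 30)
  m[5, ] <- 7
  norm <- fitNormalizer(list(m), robust = FALSE)
  nm <- applyNormalizer(m, norm)
  expect_true(all(nm[5, ] == 0))
})

test_that("out-of-range values clip to the unit interval", {
  m <- matrix(runif(8 * 30), 8, 30)
  norm <- fitNormalizer(list(m), robust = FALSE)
  m2 <- m
  m2[2, 1] <- max(m[2, ]) * 10
  m2[2, 2] <- -5
  nm <- applyNormalizer(m2, norm)
  expect_identical(nm[2, 1], 1)
  expect_identical(nm[2, 2], 0)
  expect_error(applyNormalizer(m[1:5, ], norm), "8 channels")
})

test_that("normalizer JSON persistence round-trips exactly", {
  ts <- simulateCohort(simParams(), 3, 48, rng_seed = 5)
  norm <- fitNormalizer(ts)
  f <- tempfile(fileext = ".json")
  writeNormalizer(norm, f)
  norm2 <- readNormalizer(f)
  expect_identical(norm@lo, norm2@lo)
  expect_identical(norm@hi, norm2@hi)
})

test_that("training-sample extraction respects the stated past and split ranges", {
  m <- matrix(runif(8 * 192), 8, 192)
  m[1, ] <- rbinom(192, 1, 0.5)
  set.seed(3)
  for (k in 1:200) {
    s <- extractTrainingSample(m, 24)
    P <- ncol(s@past)
    expect_gte(P, 36)
    expect_lte(P, 144)
    expect_lte(s@split_index + 24, 192)
    # no future leakage: past ends exactly one step before the future
    expect_identical(s@past[2, P], m[2, s@split_index])
    expect_identical(s@future_fluo[1], m[2, s@split_index + 1])
    expect_identical(s@future_stims, m[1, (s@split_index + 1):(s@split_index + 24)])
  }
  # forced minimal split
  m2 <- m[, 1:(48 + 36)]
  s2 <- extractTrainingSample(m2, 48)
  expect_identical(ncol(s2@past), 36L)
  # too-short trace signals the caller to resample
  expect_null(extractTrainingSample(m[, 1:50], 24))
})

test_that("extracted past lengths are uniform over [36, 144]", {
  m <- matrix(runif(8 * 300), 8, 300)
  m[1, ] <- rbinom(300, 1, 0.5)
  set.seed(8)
  Ps <- vapply(1:10000, function(k) ncol(extractTrainingSample(m, 24)@past),
               numeric(1))
  tab <- table(factor(Ps, levels = 36:144))
  p <- chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("feature masking zeroes channels and is idempotent", {
  m <- matrix(runif(8 * 100), 8, 100)
  m[1, ] <- 1
  s <- extractTrainingSample(m, 12)
  s2 <- maskFeature(s, 2)
  expect_true(all(s2@past[2, ] == 0))
  expect_identical(maskFeature(s2, 2), s2)
  s3 <- maskFeature(s, c(2, 4))
  expect_true(all(s3@past[c(2, 4), ] == 0))
  expect_error(maskFeature(s, 9), "channel")
})

test_that("past truncation keeps the most recent points", {
  m <- matrix(seq_len(8 * 100), 8, 100)
  m[1, ] <- 0
  s <- extractTrainingSample(m, 12)
  P <- ncol(s@past)
  expect_identical(truncatePast(s, P), s)
  s2 <- truncatePast(s, 10)
  expect_identical(s2@past, s@past[, (P - 9):P])
  expect_error(truncatePast(s, 0), "keep")
})

test_that("the dataset container round-trips bit-exactly", {
  ts <- simulateCohort(simParams(), 4, 36, rng_seed = 13)
  d <- tempfile()
  writeTraces(ts, d)
  ts2 <- readTraces(d)
  for (f in featureNames())
    expect_identical(unname(SummarizedExperiment::assay(ts2, f)),
                     unname(SummarizedExperiment::assay(ts, f)))
  expect_identical(rownames(ts2), rownames(ts))
})
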