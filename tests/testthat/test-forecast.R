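# The encoder-decoder forecaster: gradients, contracts, determinism,
# batching, and small-scale training behavior.

test_that("analytic gradients match finite differences", {
  set.seed(42)
  H <- 12; P <- 4; B <- 2
  w <- optoMPC:::.initWeights(H, 42)
  X <- array(runif(8 * P * B), c(8, P, B))
  S <- matrix(rbinom(H * B, 1, 0.5), H, B)
  Y <- matrix(runif(H * B), H, B)
  res <- optoMPC:::.fc_grad(w, X, S, Y)
  eps <- 1e-6
  for (nm in names(w)) {
    idx <- sample(length(w[[nm]]), min(3, length(w[[nm]])))
    for (i in idx) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (optoMPC:::.fc_grad(wp, X, S, Y)$loss -
              optoMPC:::.fc_grad(wm, X, S, Y)$loss) / (2 * eps)
      expect_lt(abs(num - res$grads[[nm]][i]), 1e-5 * (1 + abs(num)))
    }
  }
  # the single-precision instantiation agrees to float accuracy
  resf <- optoMPC:::.fc_grad_sgl(w, X, S, Y)
  expect_lt(abs(resf$loss - res$loss), 1e-5 * (1 + abs(res$loss)))
  for (nm in c("W1", "U2", "D3", "Wo"))
    expect_lt(max(abs(resf$grads[[nm]] - res$grads[[nm]])),
              1e-4 * (1 + max(abs(res$grads[[nm]]))))
})

test_that("the latent dimension is 32 for any past length", {
  w <- optoMPC:::.initWeights(24, 7)
  cfg <- forecastConfig(2, preset = "tiny")
  m <- new("ForecastModel", weights = w, config = cfg,
           normalizer = new("Normalizer", lo = rep(0, 8), hi = rep(1, 8),
                            robust = FALSE),
           mask = numeric(0),
           history = data.frame(epoch = integer(0), loss = numeric(0)))
  z36 <- encodePast(m, matrix(runif(8 * 36), 8, 36))
  z144 <- encodePast(m, matrix(runif(8 * 144), 8, 144))
  expect_length(z36, 32)
  expect_length(z144, 32)
  # determinism
  past <- matrix(runif(8 * 50), 8, 50)
  expect_identical(encodePast(m, past), encodePast(m, past))
  # different pasts map to different latents
  expect_gt(sqrt(sum((z36 - z144)^2)), 0)
  expect_error(encodePast(m, matrix(0, 5, 36)), "8 channels")
})

test_that("batched decoding equals row-wise single calls", {
  w <- optoMPC:::.initWeights(24, 8)
  cfg <- forecastConfig(2, preset = "tiny")
  m <- new("ForecastModel", weights = w, config = cfg,
           normalizer = new("Normalizer", lo = rep(0, 8), hi = rep(1, 8),
                            robust = FALSE),
           mask = numeric(0),
           history = data.frame(epoch = integer(0), loss = numeric(0)))
  z <- rnorm(32)
  set.seed(3)
  Smat <- matrix(rbinom(1000 * 24, 1, 0.5), 1000, 24)
  batched <- decodeStrategies(m, z, Smat)
  expect_identical(dim(batched), c(1000L, 24L))
  for (i in c(1, 500, 1000))
    expect_equal(batched[i, ], decodeStrategies(m, z, Smat[i, ]),
                 tolerance = 1e-6)
  expect_error(decodeStrategies(m, z, matrix(0, 2, 12)), "24 bits")
})

test_that("training loss descends across epochs for most seeds", {
  ts <- simulateCohort(simParams(), 25, 84, rng_seed = 3)
  norm <- fitNormalizer(ts)
  drops <- vapply(1:10, function(seed) {
    cfg <- forecastConfig(1, epochs = 2, steps_per_epoch = 10,
                          batch_size = 16, seed = seed)
    m <- trainForecaster(ts, cfg, normalizer = norm)
    diff(m@history$loss) <= 0
  }, logical(1))
  expect_gte(sum(drops), 8)
})

test_that("training is exactly reproducible from its seed", {
  ts <- simulateCohort(simParams(), 15, 84, rng_seed = 4)
  norm <- fitNormalizer(ts)
  cfg <- forecastConfig(1, epochs = 1, steps_per_epoch = 8,
                        batch_size = 8, seed = 77)
  m1 <- trainForecaster(ts, cfg, normalizer = norm)
  m2 <- trainForecaster(ts, cfg, normalizer = norm)
  expect_identical(m1@weights, m2@weights)
  expect_identical(m1@history, m2@history)
})

test_that("perfect predictions evaluate to zero error everywhere", {
  m <- matrix(runif(8 * 100), 8, 100)
  m[1, ] <- rbinom(100, 1, 0.5)
  set.seed(5)
  samples <- lapply(1:20, function(i) extractTrainingSample(m, 12))
  oracle <- function(ss) t(vapply(ss, function(s) s@future_fluo, numeric(12)))
  ev <- evaluateForecaster(oracle, samples)
  expect_true(all(ev$rmse_time == 0))
  expect_true(all(ev$percentiles == 0))
  expect_true(all(ev$rmse_cells == 0))
})

test_that("model checkpoints round-trip through the JSON archive", {
  ts <- simulateCohort(simParams(), 10, 84, rng_seed = 6)
  cfg <- forecastConfig(1, epochs = 1, steps_per_epoch = 4, batch_size = 8,
                        seed = 9)
  m <- trainForecaster(ts, cfg, mask = 2)
  f <- tempfile(fileext = ".json")
  writeForecastModel(m, f)
  m2 <- readForecastModel(f)
  expect_equal(m2@weights, m@weights, tolerance = 0)
  expect_identical(m2@mask, m@mask)
  expect_identical(m2@normalizer@lo, m@normalizer@lo)
  past <- matrix(runif(8 * 40), 8, 40)
  expect_identical(encodePast(m, past), encodePast(m2, past))
})
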