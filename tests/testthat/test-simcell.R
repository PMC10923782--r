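# The stochastic plant: heterogeneity, closed-form limits, divisions,
# reproducibility, and the emitted 8-feature record.

test_that("per-cell multipliers have the configured log-normal spread", {
  p0 <- simParams(cv_cell = 0)
  s <- sampleCell(p0, 1)
  expect_identical(s@beta_cell, 1)
  expect_identical(s@mu_cell, 1)

  p <- simParams(cv_cell = 0.2)
  set.seed(123)
  draws <- vapply(1:10000, function(i)
    exp(rnorm(1, 0, sqrt(log(1 + 0.2^2)))), numeric(1))
  # Monte-Carlo reference for the stated parameterization
  expect_lt(abs(sd(draws) / mean(draws) - 0.2), 0.02)
  betas <- vapply(1:2000, function(i) sampleCell(p, i)@beta_cell, numeric(1))
  expect_lt(abs(sd(betas) / mean(betas) - 0.2), 0.02)
  expect_lt(abs(median(betas) - 1), 0.03)
})

test_that("sampling and stepping are seed-reproducible", {
  p <- simParams()
  expect_identical(sampleCell(p, 42), sampleCell(p, 42))
  ts1 <- simulateCohort(p, 5, 30, rng_seed = 9)
  ts2 <- simulateCohort(p, 5, 30, rng_seed = 9)
  expect_identical(fluoMatrix(ts1), fluoMatrix(ts2))
  expect_identical(areaMatrix(ts1), areaMatrix(ts2))
})

noiseless <- function(...) {
  defaults <- list(sigma_eta = 0, sigma_meas = 0, p_death = 0, p_fil = 0,
                   p_glitch = 0, cv_cell = 0)
  do.call(simParams, utils::modifyList(defaults, list(...)))
}

test_that("held green light drives activation and fluorescence to the ODE steady state", {
  p <- noiseless(leak = 0, k_age = 0)
  s <- sampleCell(p, 1)
  set.seed(1)
  # activation settles within 10/k_on = 50 min; the concentration needs a
  # few multiples of 1/(gamma_m + mu) ~ 40 min on top, so run 6 h
  for (k in 1:10) s <- stepCell(s, 1, p)
  expect_lt(abs(s@a - 1), 0.01)
  for (k in 1:62) s <- stepCell(s, 1, p)
  mu_inst <- p@mu0 / 60
  g_ss <- p@beta0 / (p@gamma_m + mu_inst)
  expect_lt(abs(s@g - g_ss) / g_ss, 0.01)
})

test_that("held red light from a deactivated state decays exponentially", {
  p <- noiseless(leak = 0, k_age = 0, dt_sim = 0.01)
  s <- sampleCell(p, 1)
  g0 <- 2000
  s@g <- g0
  set.seed(1)
  for (k in 1:6) s <- stepCell(s, 0, p)
  mu_inst <- p@mu0 / 60
  expect_lt(abs(s@g - g0 * exp(-(p@gamma_m + mu_inst) * 30)) / s@g, 1e-4)
})

test_that("division halves area and conserves concentration", {
  p <- noiseless(k_age = 0)
  s <- sampleCell(p, 3)
  s@A <- p@A_div * 0.999   # division happens within the next interval
  g_before <- s@g
  set.seed(1)
  s2 <- stepCell(s, 0, p)
  expect_lt(s2@A, p@A_div / 2 * exp(p@mu0 / 60 * p@dt_meas))
  # concentration is continuous through the division
  expect_lt(abs(s2@g - g_before) / g_before, 0.05)
  expect_equal(s2@n_chamber, 2)
})

test_that("area doubling time equals ln2/mu within 1 percent", {
  p <- noiseless(k_age = 0, A_div = 1e9)  # suppress divisions
  s <- sampleCell(p, 1)
  s@A <- 2                                # far below the division area
  A0 <- s@A
  set.seed(1)
  for (k in 1:24) s <- stepCell(s, 0, p)   # 2 h
  mu_hat <- log(s@A / A0) / 2              # 1/h
  t_double <- log(2) / mu_hat
  expect_lt(abs(t_double - log(2) / p@mu0) / (log(2) / p@mu0), 0.01)
})

test_that("noise-free integration matches a 10x finer-step reference", {
  p1 <- noiseless(dt_sim = 0.5)
  p2 <- noiseless(dt_sim = 0.05)
  stims <- rep(c(1, 1, 1, 0, 0, 1, 0, 0), length.out = 36)
  t1 <- simulateChamber(p1, stims, 36, rng_seed = 4)
  t2 <- simulateChamber(p2, stims, 36, rng_seed = 4)
  g1 <- fluoMatrix(t1)[1, ]
  g2 <- fluoMatrix(t2)[1, ]
  expect_lt(max(abs(g1 - g2) / pmax(g2, 1)), 1e-3)
})

test_that("the emitted record has 8 channels, valid values, and the right length", {
  p <- simParams()
  ts <- simulateCohort(p, 4, 192, rng_seed = 6)
  expect_identical(SummarizedExperiment::assayNames(ts), featureNames())
  expect_identical(dim(fluoMatrix(ts)), c(4L, 192L))  # 16 h at 5-min sampling
  m <- getTrace(ts, 2)
  expect_identical(dim(m), c(8L, 192L))
  expect_true(all(m[c(2, 3, 4, 5, 6), ] >= 0))
  expect_true(all(m[1, ] %in% c(0, 1)))
  expect_true(all(m[7, ] %in% c(0, 1)))
})

test_that("all-red with no leak and no noise keeps fluorescence at its floor", {
  p <- noiseless(leak = 0)
  ts <- simulateChamber(p, rep(0, 24), 24, rng_seed = 2)
  expect_true(all(fluoMatrix(ts) == 0))
})

test_that("constant green vs constant red spans a >5-fold dynamic range", {
  p <- fx_params()
  tsg <- simulateCohort(p, 250, 120, rng_seed = 31, stims = rep(1, 120))
  tsr <- simulateCohort(p, 250, 120, rng_seed = 32, stims = rep(0, 120))
  ratio <- median(fluoMatrix(tsg)[, 120]) / median(fluoMatrix(tsr)[, 120])
  expect_gt(ratio, 5)
})

test_that("dead cells freeze area and decay fluorescence", {
  p <- noiseless(p_death = 1)   # first step kills every cell
  s <- sampleCell(p, 1)
  s@g <- 1000
  set.seed(1)
  s1 <- stepCell(s, 1, p)
  expect_identical(s1@mode, "dead")
  A1 <- s1@A
  g1 <- s1@g
  s2 <- stepCell(s1, 1, p)
  expect_identical(s2@A, A1)
  expect_lt(s2@g, g1)
})
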