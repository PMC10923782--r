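# Linear-regression forecaster and the ODE + hybrid Kalman baseline.

make_linear_samples <- function(n, P, H, W_true, b_true, noise = 0) {
  lapply(seq_len(n), function(i) {
    past <- matrix(runif(8 * P), 8, P)
    stims <- rbinom(H, 1, 0.5)
    x <- c(as.numeric(past), stims)
    y <- as.numeric(W_true %*% x + b_true) + rnorm(H, 0, noise)
    new("ForecastSample", past = past, future_stims = as.numeric(stims),
        future_fluo = y, split_index = P, cell_id = as.character(i))
  })
}

test_that("least squares recovers a planted linear map exactly", {
  set.seed(21)
  P <- 36; H <- 12
  W_true <- matrix(rnorm(H * (8 * P + H), 0, 0.05), H)
  b_true <- rnorm(H)
  samples <- make_linear_samples(500, P, H, W_true, b_true)
  fit <- fitLinear(samples, P_fix = P)
  pred <- linearPredictSamples(fit, samples)
  truth <- t(vapply(samples, function(s) s@future_fluo, numeric(H)))
  expect_lt(max(abs(pred - truth)) / max(abs(truth)), 1e-6)
  # recovered coefficients match the planted map
  expect_lt(max(abs(t(fit@W[-1, ]) - W_true)), 1e-6)
})

test_that("all-zero inputs predict the fitted bias", {
  set.seed(22)
  P <- 36; H <- 6
  W_true <- matrix(0, H, 8 * P + H)
  b_true <- 1:6
  samples <- make_linear_samples(800, P, H, W_true, b_true, noise = 0.01)
  fit <- fitLinear(samples, P_fix = P)
  zero_sample <- samples[[1]]
  zero_sample@past[] <- 0
  zero_sample@future_stims[] <- 0
  pred <- linearPredictSamples(fit, list(zero_sample))
  expect_lt(max(abs(pred - fit@W[1, ])), 1e-12)
  expect_lt(max(abs(pred - b_true)), 0.05)
})

test_that("ODE predictions reach the closed-form steady state and decay", {
  p <- odeParams(k_a = 0.2, k_d = 0.1, beta = 60, gamma = 0.02)
  # u = 1 held long: a -> k_a/k_d, p -> beta k_a / (gamma k_d)
  t_ss <- ceiling(10 / min(p@k_d, p@gamma) / 5)
  pred <- odePredict(kalmanBelief(c(0, 0), diag(2)), p, rep(1, t_ss))
  p_ss <- p@beta * p@k_a / (p@gamma * p@k_d)
  expect_lt(abs(pred[t_ss] - p_ss) / p_ss, 0.01)
  # u = 0 from (a0 = 0, p0): pure exponential decay
  p0 <- 1500
  predd <- odePredict(kalmanBelief(c(0, p0), diag(2)), p, rep(0, 24))
  t_min <- 5 * (1:24)
  expect_lt(max(abs(predd - p0 * exp(-p@gamma * t_min)) / predd), 1e-6)
  # zero-length horizon
  expect_identical(odePredict(kalmanBelief(), p, numeric(0)), numeric(0))
  expect_error(odeParams(k_a = -1), "> 0")
})

test_that("an uninformative measurement leaves the prior unchanged", {
  p <- odeParams(r = 1e18)
  b0 <- kalmanBelief(c(0.3, 800), diag(c(0.1, 1e4)))
  b1 <- kalmanStep(b0, p, 1, 900)        # huge r: K ~ 0
  p2 <- odeParams(r = 1e18)
  b_pred <- kalmanStep(b0, p2, 1, NA)    # prediction only
  expect_lt(max(abs(b1@m - b_pred@m)) / max(abs(b_pred@m)), 1e-6)
  expect_lt(max(abs(b1@P - b_pred@P)) / max(abs(b_pred@P)), 1e-6)
})

test_that("the noise-free filter tracks an exact linear plant", {
  p <- odeParams(q_a = 1e-12, q_p = 1e-12, r = 1e-8)
  dd <- optoMPC:::.odeDiscretize(p, 5)
  x <- c(0.2, 500)
  b <- kalmanBelief(x, diag(c(1e-12, 1e-12)))
  set.seed(31)
  for (k in 1:60) {
    u <- rbinom(1, 1, 0.5)
    step <- if (u > 0.5) dd$u1 else dd$u0
    x <- as.numeric(step$Ad %*% x + step$bd)
    b <- kalmanStep(b, p, u, x[2])
  }
  expect_lt(max(abs(b@m - x)), 1e-8 * (1 + max(abs(x))))
})

# independent discretization oracle: truncated matrix-exponential series
# for the propagator and Riemann integration for the noise covariance
series_disc <- function(p, dt = 5) {
  F_mat <- matrix(c(-p@k_d, p@beta, 0, -p@gamma), 2, 2)
  expm_series <- function(M) {
    out <- diag(nrow(M))
    term <- diag(nrow(M))
    for (k in 1:40) {
      term <- term %*% M / k
      out <- out + term
    }
    out
  }
  Ad <- expm_series(F_mat * dt)
  B <- c(p@k_a, 0)
  n_sub <- 4000
  h <- dt / n_sub
  bd <- c(0, 0)
  Qd <- matrix(0, 2, 2)
  Q <- diag(c(p@q_a, p@q_p))
  for (k in 1:n_sub) {
    s <- (k - 0.5) * h
    E <- expm_series(F_mat * (dt - s))
    bd <- bd + E %*% B * h
    Qd <- Qd + E %*% Q %*% t(E) * h
  }
  list(Ad = Ad, bd = as.numeric(bd), Qd = Qd)
}

test_that("the hybrid filter equals a textbook discrete Kalman filter", {
  p <- odeParams(k_a = 0.15, k_d = 0.08, beta = 50, gamma = 0.025,
                 q_a = 1e-3, q_p = 30, r = 5e3)
  dsc <- series_disc(p)
  d0 <- series_disc(odeParams(k_a = 1e-12, k_d = p@k_d, beta = p@beta,
                              gamma = p@gamma, q_a = p@q_a, q_p = p@q_p,
                              r = p@r))
  Hm <- matrix(c(0, 1), 1, 2)
  m <- c(0.1, 600)
  P <- diag(c(0.2, 1e4))
  b <- kalmanBelief(m, P)
  set.seed(41)
  for (k in 1:100) {
    u <- rbinom(1, 1, 0.5)
    y <- 600 + rnorm(1, 0, 50)
    # reference discrete filter on the matched discretized system
    bd_u <- if (u > 0.5) dsc$bd else d0$bd
    m <- as.numeric(dsc$Ad %*% m + bd_u)
    P <- dsc$Ad %*% P %*% t(dsc$Ad) + dsc$Qd
    S <- as.numeric(Hm %*% P %*% t(Hm)) + p@r
    K <- P %*% t(Hm) / S
    m <- m + as.numeric(K) * (y - m[2])
    P <- (diag(2) - K %*% Hm) %*% P
    P <- (P + t(P)) / 2
    b <- kalmanStep(b, p, u, y)
    expect_lt(max(abs(b@m - m)), 1e-6 * (1 + max(abs(m))))
    expect_lt(max(abs(b@P - P)), 1e-6 * (1 + max(abs(P))))
  }
})

test_that("the covariance stays symmetric PSD over 10^4 random steps", {
  p <- odeParams()
  b <- kalmanBelief(c(0, 150), diag(c(0.25, 1e4)))
  set.seed(51)
  us <- rbinom(10000, 1, 0.5)
  ys <- 1000 + rnorm(10000, 0, 100)
  ys[sample(10000, 500)] <- NA           # missing measurements interleaved
  for (k in 1:10000) b <- kalmanStep(b, p, us[k], ys[k])
  expect_lt(max(abs(b@P - t(b@P))), 1e-9 * (1 + max(abs(b@P))))
  ev <- eigen(b@P, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-9 * (1 + max(abs(b@P))))
})

test_that("ODE parameters are recovered from self-generated data", {
  p_true <- odeParams(k_a = 0.12, k_d = 0.09, beta = 55, gamma = 0.022)
  dd <- optoMPC:::.odeDiscretize(p_true, 5)
  set.seed(61)
  T_len <- 192
  n <- 30
  stim <- t(vapply(1:n, function(i)
    as.numeric(bits(randomWalkStimulation(T_len))), numeric(T_len)))
  fluo <- matrix(0, n, T_len)
  for (i in 1:n) {
    x <- c(0, 150)
    for (t in 1:T_len) {
      step <- if (stim[i, t] > 0.5) dd$u1 else dd$u0
      x <- step$Ad %*% x + step$bd
      fluo[i, t] <- x[2]
    }
  }
  A <- list(stim = stim, fluo = fluo, area_px = matrix(500, n, T_len),
            chamber_mean = fluo, chamber_sd = fluo * 0.2,
            cell_count = matrix(1, n, T_len),
            neighbor_stim = stim, sharpness = matrix(1, n, T_len))
  se <- SummarizedExperiment::SummarizedExperiment(assays = A)
  rownames(se) <- sprintf("c%02d", 1:n)
  ts <- new("CellTraceSet", se)
  fit <- fitOde(ts, n_fit = 30, seed = 2)
  # the identifiable combinations: steady-state gain and loss rates
  gain_true <- p_true@beta * p_true@k_a / (p_true@gamma * p_true@k_d)
  gain_fit <- fit@beta * fit@k_a / (fit@gamma * fit@k_d)
  expect_lt(abs(gain_fit - gain_true) / gain_true, 0.05)
  expect_lt(abs(fit@gamma - p_true@gamma) / p_true@gamma, 0.05)
  # gamma equals the observed exponential decay rate of the off-step
  p0 <- 1500
  decay <- odePredict(kalmanBelief(c(0, p0), diag(2) * 0), fit, rep(0, 36))
  gamma_obs <- -log(decay[36] / decay[12]) / (5 * 24)
  expect_lt(abs(gamma_obs - p_true@gamma) / p_true@gamma, 0.05)
})

test_that("the linear control-loop predictor matches the sample predictor", {
  set.seed(77)
  P <- 40; H <- 12
  W_true <- matrix(rnorm(H * (8 * 36 + H), 0, 0.05), H)
  samples <- make_linear_samples(300, 36, H, W_true, rnorm(H))
  fit <- fitLinear(samples, P_fix = 36)
  norm <- new("Normalizer", lo = rep(0, 8), hi = rep(1, 8), robust = FALSE)
  pred <- linearPredictor(fit, norm)
  past <- matrix(runif(8 * P), 8, P)
  ctx <- pred$encode(past)
  S <- matrix(rbinom(5 * H, 1, 0.5), 5, H)
  out <- pred$predict(ctx, S)
  # reference: route the same window through the sample-based predictor
  ref <- t(vapply(1:5, function(i) {
    s <- new("ForecastSample", past = past[, (P - 35):P],
             future_stims = S[i, ], future_fluo = numeric(H),
             split_index = P, cell_id = "x")
    as.numeric(linearPredictSamples(fit, list(s)))
  }, numeric(H)))
  expect_equal(out, ref, tolerance = 1e-10)
  expect_identical(pred$counts$encode, 1L)
  expect_identical(pred$counts$decode, 5L)
})
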