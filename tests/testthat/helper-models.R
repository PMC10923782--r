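# Shared fixtures for the suite. Everything is generated in code and
# memoised so expensive objects (corpora, trained forecasters, control
# campaigns) are built at most once per test run. Problem sizes are the
# package's scaled-down study conditions: 500 training and 150 held-out
# cells of 16 h traces; the reference 2 h model at the scaled schedule
# (50 epochs x 50 steps x batch 64); the horizon-study models at an
# equal-budget schedule of 20 epochs x 50 steps x batch 64; the
# feature-ablation trio at an equal-budget 12 epochs x 40 steps x batch 64.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fx_params <- function() memo("params", function() simParams())

fx_train <- function() memo("train", function()
  simulateCohort(fx_params(), 500, 192, rng_seed = 11))

fx_valid <- function() memo("valid", function()
  simulateCohort(fx_params(), 150, 192, rng_seed = 12))

fx_norm <- function() memo("norm", function() fitNormalizer(fx_train()))

# the reference 2 h horizon model (scaled training schedule)
fx_deep24 <- function() memo("deep24", function()
  trainForecaster(fx_train(), forecastConfig(2, preset = "scaled", seed = 5),
                  normalizer = fx_norm()))

# horizon-study models, one per 1-4 h horizon, equal training budgets
fx_horizon <- function(L) {
  memo(paste0("horizon", L), function()
    trainForecaster(fx_train(),
                    forecastConfig(L, epochs = 12, steps_per_epoch = 40,
                                   batch_size = 64, seed = 5 + L),
                    normalizer = fx_norm()))
}

# feature-ablation models: identical schedule and seed as the 2 h horizon
# model above (which doubles as the unmasked reference), different masks
.abl_cfg <- function() forecastConfig(2, epochs = 12, steps_per_epoch = 40,
                                      batch_size = 64, seed = 7)

fx_ablation_full <- function() fx_horizon(2)

fx_mask_fluo <- function() memo("mask_fluo", function()
  trainForecaster(fx_train(), .abl_cfg(), normalizer = fx_norm(), mask = 2))

fx_mask_all <- function() memo("mask_all", function()
  trainForecaster(fx_train(), .abl_cfg(), normalizer = fx_norm(), mask = 1:8))

fx_linear <- function() memo("linear", function()
  fitLinear(drawSampleSet(fx_train(), fx_norm(), 24, 4000, seed = 7)))

fx_ode <- function() memo("ode", function()
  fitOde(fx_train(), n_fit = 30, seed = 3))

# held-out evaluation samples for the 2 h horizon
fx_vsamples <- function() memo("vsamples", function()
  drawSampleSet(fx_valid(), fx_norm(), 24, 1200, seed = 99))

# the flagship closed-loop campaign: 50 cells, 19 h, sinewave objective
# (offset 1200 a.u., amplitude 400 a.u., period 6 h), 2 h controller
.sine_obj <- function(T_pts) sinewaveObjective(400, 6, 0, 1200, T_pts)

fx_campaign24 <- function() memo("campaign24", function() {
  cfg <- experimentConfig("closed_loop", n_cells = 50, duration_h = 19,
                          equilibration_h = 3, control = controlConfig(2),
                          sim = fx_params(), seed = 21)
  runClosedLoop(cfg, deepPredictor(fx_deep24()), list(.sine_obj(228)))
})

fx_campaign_random <- function() memo("campaign_rnd", function() {
  cfg <- experimentConfig("closed_loop", n_cells = 50, duration_h = 19,
                          equilibration_h = 3, control = controlConfig(2),
                          sim = fx_params(), seed = 21)
  runClosedLoop(cfg, NULL, list(.sine_obj(228)))
})

# horizon-robustness campaigns: 24 cells, 11 h, controllers L = 1..4
fx_campaign_h <- function(L) {
  memo(paste0("campaign_h", L), function() {
    cfg <- experimentConfig("closed_loop", n_cells = 24, duration_h = 11,
                            equilibration_h = 3,
                            control = controlConfig(L), sim = fx_params(),
                            seed = 21 + L)
    runClosedLoop(cfg, deepPredictor(fx_horizon(L)), list(.sine_obj(132)))
  })
}

# a counting stub predictor for call-audit tests (planted cost surface
# with a known optimum encoded in the context)
stub_predictor <- function(target, H) {
  counts <- new.env(parent = emptyenv())
  counts$encode <- 0L
  counts$decode <- 0L
  list(
    encode = function(past) {
      counts$encode <- counts$encode + 1L
      target
    },
    predict = function(ctx, S) {
      counts$decode <- counts$decode + nrow(S)
      ## predicted trajectory deviates from 1000 wherever a bit mismatches
      matrix(1000, nrow(S), H) +
        500 * (S - matrix(ctx, nrow(S), H, byrow = TRUE))
    },
    horizon = H,
    counts = counts,
    reset_counts = function() {
      counts$encode <- 0L
      counts$decode <- 0L
    })
}
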