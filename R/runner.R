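## Orchestration of full in-silico experiments: open-loop dataset
## generation (random-walk stimulations) and closed-loop control campaigns
## (3 h all-red equilibration, then plan-apply-measure every 5 minutes).

#' Experiment configuration
#'
#' @slot mode `"open_loop"` or `"closed_loop"`
#' @slot n_cells number of cells
#' @slot duration_h total duration (h)
#' @slot equilibration_h all-red equilibration before control onset (h)
#' @slot predictor one of `"deep"`, `"linear"`, `"ode_kalman"`, `"none"`
#'   (random stimulations)
#' @slot control a [ControlConfig-class]
#' @slot sim a [SimParams-class]
#' @slot seed root seed; all randomness in the run derives from it
#' @export
setClass("ExperimentConfig", representation(
  mode = "character", n_cells = "numeric", duration_h = "numeric",
  equilibration_h = "numeric", predictor = "character",
  control = "ControlConfig", sim = "SimParams", seed = "numeric"))

setValidity("ExperimentConfig", function(object) {
  if (!object@mode %in% c("open_loop", "closed_loop"))
    return("mode must be open_loop or closed_loop")
  if (object@duration_h < object@equilibration_h)
    return("duration must be >= equilibration")
  if (object@n_cells < 1) return("n_cells must be >= 1")
  TRUE
})

#' Construct an experiment configuration
#'
#' @param mode `"open_loop"` or `"closed_loop"`
#' @param n_cells number of cells
#' @param duration_h total duration (h); 16 h = 192 timepoints
#' @param equilibration_h control onset (h); all red before
#' @param predictor predictor choice (closed loop)
#' @param control a [ControlConfig-class]
#' @param sim a [SimParams-class]
#' @param seed root seed
#' @return An [ExperimentConfig-class].
#' @export
experimentConfig <- function(mode = c("open_loop", "closed_loop"),
                             n_cells = 100, duration_h = 16,
                             equilibration_h = 3, predictor = "deep",
                             control = controlConfig(), sim = simParams(),
                             seed = 1L) {
  new("ExperimentConfig", mode = match.arg(mode), n_cells = n_cells,
      duration_h = duration_h, equilibration_h = equilibration_h,
      predictor = predictor, control = control, sim = sim,
      seed = as.numeric(seed))
}

setMethod("show", "ExperimentConfig", function(object) {
  cat(sprintf("ExperimentConfig: %s, %d cells, %g h (control onset %g h), predictor=%s, seed=%d\n",
              object@mode, as.integer(object@n_cells), object@duration_h,
              object@equilibration_h, object@predictor,
              as.integer(object@seed)))
})

#' Run an open-loop acquisition experiment
#'
#' Simulates `n_cells` independent chambers under independent binarized-
#' random-walk stimulation sequences — the design used to collect
#' forecaster training corpora — and optionally writes the dataset
#' container.
#'
#' @param config an [ExperimentConfig-class] with `mode = "open_loop"`
#' @param out_dir optional directory for [writeTraces()]
#' @return list with `traces` (a [CellTraceSet-class]) and `config`.
#' @export
runOpenLoop <- function(config, out_dir = NULL) {
  stopifnot(is(config, "ExperimentConfig"), config@mode == "open_loop")
  T_points <- round(config@duration_h * 12)
  traces <- simulateCohort(config@sim, config@n_cells, T_points,
                           rng_seed = config@seed)
  if (!is.null(out_dir)) writeTraces(traces, out_dir)
  list(traces = traces, config = config)
}

#' Split a cohort into disjoint train/validation sets by cell
#'
#' @param traces a [CellTraceSet-class]
#' @param frac training fraction
#' @param seed split seed
#' @return list with `train` and `validation` [CellTraceSet-class]s.
#' @export
splitCells <- function(traces, frac = 0.8, seed = 1L) {
  set.seed(as.integer(seed))
  n <- nrow(traces)
  tr <- sort(sample(n, round(frac * n)))
  list(train = traces[tr, ], validation = traces[setdiff(seq_len(n), tr), ])
}

## Batched swarm planning across all cells for predictors exposing
## predictBatch: every iteration decodes (n_cells * n_particles) candidate
## strategies in a single call.
.planBatch <- function(predictor, Z, obj_mat, config) {
  H <- ncol(obj_mat)
  n <- nrow(obj_mat)
  np <- config@n_particles
  Zrep <- Z[, rep(seq_len(n), each = np), drop = FALSE]
  obj_rep <- obj_mat[rep(seq_len(n), each = np), , drop = FALSE]
  grp <- rep(seq_len(n), each = np)
  x <- matrix(as.numeric(runif(n * np * H) < 0.5), n * np, H)
  v <- matrix(0, n * np, H)
  pbest <- x
  pbest_cost <- rep(Inf, n * np)
  gbest <- matrix(0, n, H)
  gbest_cost <- rep(Inf, n)
  gbest_pred <- matrix(NA_real_, n, H)
  for (it in seq_len(config@n_iterations)) {
    pred <- predictor$predictBatch(Zrep, x)
    costs <- sqrt(rowMeans((pred - obj_rep)^2))
    imp <- costs < pbest_cost
    pbest[imp, ] <- x[imp, , drop = FALSE]
    pbest_cost[imp] <- costs[imp]
    for (i in seq_len(n)) {
      rows <- which(grp == i)
      ib <- rows[which.min(pbest_cost[rows])]
      if (pbest_cost[ib] < gbest_cost[i]) {
        gbest_cost[i] <- pbest_cost[ib]
        gbest[i, ] <- pbest[ib, ]
      }
    }
    upd <- which(imp & costs <= gbest_cost[grp])
    if (length(upd)) gbest_pred[grp[upd], ] <- pred[upd, , drop = FALSE]
    r1 <- matrix(runif(n * np * H), n * np, H)
    r2 <- matrix(runif(n * np * H), n * np, H)
    v <- config@inertia * v + config@cognitive * r1 * (pbest - x) +
      config@social * r2 * (gbest[grp, , drop = FALSE] - x)
    v <- pmin(config@v_max, pmax(-config@v_max, v))
    x <- matrix(as.numeric(matrix(runif(n * np * H), n * np, H) <
                           1 / (1 + exp(-v))), n * np, H)
  }
  list(bits = gbest[, 1], strategies = gbest, costs = gbest_cost,
       predicted = gbest_pred)
}

#' Run a closed-loop control campaign
#'
#' Per 5-min step and per cell: append the new measurement, encode the
#' past (capped at the 144 most recent points, the longest past seen in
#' training), search the strategy space with the particle swarm against
#' the objective segment, and apply the first bit of the winning strategy
#' to the simulator. The equilibration phase applies all-red. With
#' `predictor = NULL` the control phase applies an independent
#' random-walk sequence per cell instead (the no-feedback reference).
#' Swarms are planned per cell (no shared state) but decoder calls are
#' batched across cells when the predictor supports it.
#'
#' @param config an [ExperimentConfig-class] with `mode = "closed_loop"`
#' @param predictor a predictor from [deepPredictor()] /
#'   [odeKalmanPredictor()], or `NULL`
#' @param objectives list of [ObjectiveTrack-class] (recycled if length
#'   1), values in a.u. on the experiment's 5-min grid
#' @return list with `traces`, `applied` (cells x T bit matrix),
#'   `objective` (cells x T matrix), `costs` (planning costs per control
#'   step), `rmse_time` (per-cell tracking error over the control phase),
#'   and `config`.
#' @export
runClosedLoop <- function(config, predictor, objectives) {
  stopifnot(is(config, "ExperimentConfig"), config@mode == "closed_loop")
  n <- as.integer(config@n_cells)
  T_total <- round(config@duration_h * 12)
  T_eq <- round(config@equilibration_h * 12)
  if (is(objectives, "ObjectiveTrack")) objectives <- list(objectives)
  if (length(objectives) == 1L) objectives <- rep(objectives, n)
  stopifnot(length(objectives) == n)
  obj_mat <- t(vapply(objectives, function(o) {
    v <- o@values
    if (length(v) < T_total) v <- c(v, rep(v[length(v)], T_total - length(v)))
    v[seq_len(T_total)]
  }, numeric(T_total)))
  set.seed(as.integer(config@seed))
  st <- .cohortInit(config@sim, n)
  neighbor <- t(vapply(seq_len(n), function(i)
    as.numeric(bits(randomWalkStimulation(T_total))), numeric(T_total)))
  random_bits <- if (is.null(predictor))
    t(vapply(seq_len(n), function(i)
      as.numeric(bits(randomWalkStimulation(T_total))), numeric(T_total)))
  else NULL
  feats <- array(NA_real_, c(n, 8, T_total))
  applied <- matrix(0, n, T_total)
  costs <- matrix(NA_real_, n, T_total)
  H <- config@control@horizon_hours * 12
  batched <- !is.null(predictor) && !is.null(predictor$encodeBatch)
  for (t in seq_len(T_total)) {
    if (t <= T_eq) {
      bits_t <- rep(0, n)
    } else if (is.null(predictor)) {
      bits_t <- random_bits[, t]
    } else {
      obj_seg <- obj_mat[, pmin(t:(t + H - 1), T_total), drop = FALSE]
      P_use <- min(t - 1, 144)
      past_idx <- (t - P_use):(t - 1)
      if (batched) {
        past <- feats[, , past_idx, drop = FALSE]
        past <- aperm(past, c(2, 3, 1))      # 8 x P x n
        Z <- predictor$encodeBatch(past)
        plan <- .planBatch(predictor, Z, obj_seg, config@control)
        bits_t <- plan$bits
        costs[, t] <- plan$costs
      } else {
        bits_t <- numeric(n)
        for (i in seq_len(n)) {
          past_i <- matrix(feats[i, , past_idx], nrow = 8)
          res <- mpcStep(predictor, past_i, obj_seg[i, ], config@control,
                         prev_bit = applied[i, t - 1])
          bits_t[i] <- res$bit
          costs[i, t] <- res$cost
        }
      }
    }
    applied[, t] <- bits_t
    out <- .cohortStep(st, bits_t, config@sim, neighbor[, t])
    st <- out$state
    feats[, , t] <- out$features
  }
  A <- lapply(seq_along(.FEATURES), function(j) feats[, j, , drop = TRUE])
  names(A) <- .FEATURES
  if (n == 1L) A <- lapply(A, function(v) matrix(v, nrow = 1))
  traces <- .makeTraceSet(A, sprintf("cell%05d", seq_len(n)),
                          as.integer(config@seed), config@sim)
  fl <- fluoMatrix(traces)
  rmse_time <- if (T_total > T_eq) {
    ctrl_idx <- (T_eq + 1):T_total
    vapply(seq_len(n), function(i)
      rmseTime(fl[i, ctrl_idx], obj_mat[i, ctrl_idx]), numeric(1))
  } else rep(NA_real_, n)
  list(traces = traces, applied = applied, objective = obj_mat,
       costs = costs, rmse_time = rmse_time, config = config)
}
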