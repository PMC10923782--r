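## Strategy search and the receding-horizon control step: cost evaluation
## against objectives, binary particle swarm optimization with an
## exhaustive-search oracle, and the predictor-agnostic planning step.

#' Size of the binary strategy space
#'
#' With a new red/green stimulation every 5 minutes (12 per hour), a
#' horizon of L hours admits 2^(12 L) strategies: 4096 at L = 1, ~3e14 at
#' L = 4 — the combinatorial wall that motivates swarm search.
#'
#' @param L horizon in hours (> 0)
#' @return exact count (double; exact up to 2^53).
#' @export
#' @examples
#' strategySpaceSize(1)  # 4096
strategySpaceSize <- function(L) {
  if (L <= 0) stop("L must be > 0")
  2^(12 * L)
}

#' Cost of a candidate strategy
#'
#' Across-time RMSE between the predicted fluorescence trajectory and the
#' control objective over the horizon (see [rmseTime()]).
#'
#' @param predicted,objective numeric vectors of equal length H
#' @return scalar cost.
#' @export
strategyCost <- function(predicted, objective) {
  if (length(predicted) != length(objective)) stop("lengths differ")
  rmseTime(predicted, objective)
}

.bitMatrix <- function(n_strat, H) {
  m <- matrix(0, n_strat, H)
  v <- 0:(n_strat - 1)
  for (j in seq_len(H)) m[, j] <- bitwAnd(v, bitwShiftL(1L, j - 1L)) > 0
  m * 1
}

#' Exhaustive strategy search (oracle)
#'
#' Enumerates all 2^H candidate strategies and returns the global
#' minimizer; ties are broken towards the lowest integer encoding (bit 1 =
#' least significant). Refuses H > 16 as intractable.
#'
#' @param cost_fn function taking an n x H 0/1 matrix and returning n
#'   costs (batched evaluation)
#' @param H strategy length in bits
#' @return list with `strategy` (numeric H), `cost`, and `n_evaluated`.
#' @export
#' @examples
#' target <- c(1, 0, 1, 1)
#' f <- function(S) rowSums(S != rep(target, each = nrow(S)))
#' exhaustiveOptimize(f, 4)
exhaustiveOptimize <- function(cost_fn, H) {
  if (H > 16) stop("exhaustive search refused for H > 16 (2^H candidates); ",
                   "use bpsoOptimize instead")
  cand <- .bitMatrix(2^H, H)
  costs <- cost_fn(cand)
  best <- which.min(costs)          # which.min takes the first = lowest encoding
  list(strategy = cand[best, ], cost = costs[best], n_evaluated = 2^H)
}

#' Binary particle swarm strategy search
#'
#' Canonical binary PSO: each particle's real-valued velocity is updated
#' with inertia, cognitive and social pulls towards its personal best and
#' the global best, clamped to ±v_max, and squashed through a logistic to
#' give the per-bit probability of green. Exactly
#' `n_particles * n_iterations` cost evaluations are performed (1000 at
#' the 40 x 25 defaults); the global-best cost is non-increasing across
#' iterations by construction.
#'
#' @param cost_fn function taking an n x H 0/1 matrix and returning n
#'   costs
#' @param config a [ControlConfig-class]
#' @param H override the strategy length (defaults to `12 * L`)
#' @param seed optional seed; when `NULL` the current RNG stream is used
#' @return list with `strategy`, `cost`, `n_evaluated`, and `trace` (the
#'   global-best cost after each iteration).
#' @export
#' @examples
#' target <- rep(c(1, 0), 6)
#' f <- function(S) rowSums(S != rep(target, each = nrow(S)))
#' bpsoOptimize(f, controlConfig(1), seed = 1)$cost
bpsoOptimize <- function(cost_fn, config, H = NULL, seed = NULL) {
  stopifnot(is(config, "ControlConfig"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(H)) H <- 12 * config@horizon_hours
  np <- as.integer(config@n_particles)
  x <- matrix(as.numeric(runif(np * H) < 0.5), np, H)
  v <- matrix(0, np, H)
  pbest <- x
  pbest_cost <- rep(Inf, np)
  gbest <- x[1, ]
  gbest_cost <- Inf
  trace <- numeric(config@n_iterations)
  n_eval <- 0L
  for (it in seq_len(config@n_iterations)) {
    costs <- cost_fn(x)
    n_eval <- n_eval + np
    imp <- costs < pbest_cost
    pbest[imp, ] <- x[imp, , drop = FALSE]
    pbest_cost[imp] <- costs[imp]
    ib <- which.min(pbest_cost)
    if (pbest_cost[ib] < gbest_cost) {
      gbest_cost <- pbest_cost[ib]
      gbest <- pbest[ib, ]
    }
    trace[it] <- gbest_cost
    r1 <- matrix(runif(np * H), np, H)
    r2 <- matrix(runif(np * H), np, H)
    v <- config@inertia * v +
      config@cognitive * r1 * (pbest - x) +
      config@social * r2 * (matrix(gbest, np, H, byrow = TRUE) - x)
    v <- pmin(config@v_max, pmax(-config@v_max, v))
    x <- matrix(as.numeric(matrix(runif(np * H), np, H) <
                           1 / (1 + exp(-v))), np, H)
  }
  list(strategy = gbest, cost = gbest_cost, n_evaluated = n_eval,
       trace = trace)
}

#' Wrap a trained forecaster as a control-loop predictor
#'
#' The predictor contract used by [mpcStep()] and [runClosedLoop()]:
#' `$encode(past)` consumes a raw (a.u.) 8 x P past block — normalized
#' internally with the model's own normalizer — and returns an opaque
#' context; `$predict(ctx, S)` evaluates an n x H matrix of candidate
#' strategies and returns predicted fluorescence in a.u. Call counts are
#' tracked in `$counts`.
#'
#' @param model a [ForecastModel-class]
#' @return predictor list (`encode`, `predict`, `normalizer`, `horizon`,
#'   `counts`, `reset_counts`).
#' @export
deepPredictor <- function(model) {
  counts <- new.env(parent = emptyenv())
  counts$encode <- 0L
  counts$decode <- 0L
  norm <- model@normalizer
  list(
    encode = function(past) {
      counts$encode <- counts$encode + 1L
      encodePast(model, applyNormalizer(past, norm))
    },
    predict = function(ctx, S) {
      counts$decode <- counts$decode + nrow(S)
      pred <- decodeStrategies(model, ctx, S)
      if (is.vector(pred)) pred <- matrix(pred, nrow = 1)
      denormalize(pred, norm)
    },
    encodeBatch = function(past_array) {
      counts$encode <- counts$encode + dim(past_array)[3]
      x <- past_array
      for (j in 1:8)
        x[j, , ] <- .normChannel(x[j, , ], norm@lo[j], norm@hi[j])
      encodePast(model, x)
    },
    predictBatch = function(Z, S) {
      counts$decode <- counts$decode + nrow(S)
      denormalize(decodeStrategies(model, Z, S), norm)
    },
    normalizer = norm,
    horizon = model@config@horizon,
    counts = counts,
    reset_counts = function() {
      counts$encode <- 0L
      counts$decode <- 0L
    })
}

#' One receding-horizon control step
#'
#' Encodes the cell's past once, searches the (unconstrained) binary
#' strategy space with the particle swarm using the predictor as a batched
#' cost oracle against the objective segment, and returns the first bit of
#' the winning strategy together with the full planning record. When the
#' objective segment is shorter than the horizon (near the end of an
#' experiment) the last objective value is held. If the predictor fails,
#' the previous applied bit is repeated and flagged.
#'
#' @param predictor a predictor as returned by [deepPredictor()] (or the
#'   baseline wrappers)
#' @param past raw 8 x P feature matrix of the cell so far
#' @param objective numeric objective values (a.u.) covering the horizon
#' @param config a [ControlConfig-class]
#' @param seed optional seed for the swarm
#' @param prev_bit fall-back bit on predictor failure
#' @return list with `bit`, `strategy`, `predicted` (a.u.), `cost`, and
#'   `fallback`.
#' @export
mpcStep <- function(predictor, past, objective, config, seed = NULL,
                    prev_bit = 0) {
  H <- predictor$horizon
  obj <- as.numeric(objective)
  if (length(obj) < H) obj <- c(obj, rep(obj[length(obj)], H - length(obj)))
  obj <- obj[seq_len(H)]
  res <- tryCatch({
    ctx <- predictor$encode(past)
    cache <- new.env(parent = emptyenv())
    cache$cost <- Inf
    cache$pred <- rep(NA_real_, H)
    cost_fn <- function(S) {
      pred <- predictor$predict(ctx, S)
      costs <- sqrt(rowMeans((pred - matrix(obj, nrow(S), H,
                                            byrow = TRUE))^2))
      b <- which.min(costs)
      if (costs[b] < cache$cost) {   # keep the winner's trajectory for the
        cache$cost <- costs[b]       # planning record without re-decoding
        cache$pred <- pred[b, ]
      }
      costs
    }
    opt <- bpsoOptimize(cost_fn, config, H = H, seed = seed)
    list(bit = opt$strategy[1], strategy = opt$strategy,
         predicted = as.numeric(cache$pred), cost = opt$cost,
         fallback = FALSE)
  }, error = function(e) {
    warning("predictor failure in mpcStep, repeating previous bit: ",
            conditionMessage(e))
    list(bit = prev_bit, strategy = rep(prev_bit, H),
         predicted = rep(NA_real_, H), cost = NA_real_, fallback = TRUE)
  })
  res
}
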