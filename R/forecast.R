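## The deep forecaster: training, encoding, decoding, evaluation.

## Glorot-uniform initial weights; forget-gate biases start at 1.
.initWeights <- function(H, seed) {
  set.seed(as.integer(seed))
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  lstm_b <- function(n) {
    b <- rep(0, 4 * n)
    b[(n + 1):(2 * n)] <- 1
    b
  }
  w <- list(
    W1 = glorot(256, 8), U1 = glorot(256, 64), b1 = lstm_b(64),
    W2 = glorot(64, 64), U2 = glorot(64, 16), b2 = lstm_b(16),
    Wz = glorot(32, 16), bz = rep(0, 32),
    D1 = glorot(32, 32 + H), bd1 = rep(0, 32))
  for (k in 2:5) {
    w[[paste0("D", k)]] <- glorot(32, 32)
    w[[paste0("bd", k)]] <- rep(0, 32)
  }
  w$Wo <- glorot(H, 32)
  w$bo <- rep(0, H)
  w
}

## Normalized per-cell traces as a list of 8 x T matrices.
.normTraceList <- function(traces, norm) {
  nts <- applyNormalizer(traces, norm)
  lapply(seq_len(nrow(nts)), function(i) getTrace(nts, i))
}

## Assemble one fixed-P training batch (all samples share P; buckets avoid
## padding ambiguity inside the recurrent layers).
.drawBatch <- function(tl, H, B, mask = integer(0)) {
  T_len <- ncol(tl[[1]])
  p_max <- min(144, T_len - H)
  P <- if (p_max == 36L) 36L else sample(36:p_max, 1L)
  cells <- sample(length(tl), B, replace = TRUE)
  ## sample() treats a length-1 vector as 1:n, so guard the split range
  splits <- P + sample.int(T_len - H - P + 1L, B, replace = TRUE) - 1L
  X <- array(0, c(8, P, B))
  S <- matrix(0, H, B)
  Y <- matrix(0, H, B)
  for (b in seq_len(B)) {
    m <- tl[[cells[b]]]
    sp <- splits[b]
    X[, , b] <- m[, (sp - P + 1):sp]
    S[, b] <- m[1, (sp + 1):(sp + H)]
    Y[, b] <- m[2, (sp + 1):(sp + H)]
  }
  if (length(mask)) X[mask, , ] <- 0
  list(X = X, S = S, Y = Y)
}

#' Train the encoder-decoder forecaster
#'
#' Trains the two-layer LSTM encoder + perceptron decoder on randomly
#' extracted (past, future stimulations, future fluorescence) samples from
#' the corpus, with mean squared error loss and Adam updates at the
#' configured learning rate. Past lengths vary between 36 and 144 points
#' (3-12 h); each batch shares one past length. Entirely determined by
#' `config@seed`.
#'
#' @param traces a [CellTraceSet-class] training corpus (raw units)
#' @param config a [ForecastConfig-class]
#' @param normalizer optional fitted [Normalizer-class]; fitted on
#'   `traces` when `NULL`
#' @param mask integer channel indices zeroed in every past block
#'   (feature-ablation training), empty for the full model
#' @param validation optional [CellTraceSet-class]; when given, the median
#'   held-out RMSE (normalized units) is recorded once per epoch
#' @param n_val number of validation samples per epoch
#' @return A trained [ForecastModel-class].
#' @export
trainForecaster <- function(traces, config, normalizer = NULL,
                            mask = integer(0), validation = NULL,
                            n_val = 200L) {
  stopifnot(is(config, "ForecastConfig"))
  if (nrow(traces) == 0) stop("empty training corpus")
  if (is.null(normalizer)) normalizer <- fitNormalizer(traces)
  H <- config@horizon
  tl <- .normTraceList(traces, normalizer)
  if (ncol(tl[[1]]) < 36 + H)
    stop("traces too short for past >= 36 plus horizon ", H)
  set.seed(as.integer(config@seed))
  w <- .initWeights(H, seed = as.integer(config@seed))
  mstate <- lapply(w, function(x) x * 0)
  vstate <- lapply(w, function(x) x * 0)
  lr <- config@learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  val_samples <- NULL
  if (!is.null(validation)) {
    vl <- .normTraceList(validation, normalizer)
    val_samples <- .drawBatch(vl, H, n_val, mask)
  }
  hist_loss <- numeric(config@epochs)
  hist_val <- rep(NA_real_, config@epochs)
  for (ep in seq_len(config@epochs)) {
    ep_loss <- 0
    for (it in seq_len(config@steps_per_epoch)) {
      batch <- .drawBatch(tl, H, config@batch_size, mask)
      res <- .fc_grad(w, batch$X, batch$S, batch$Y)
      ep_loss <- ep_loss + res$loss
      step <- step + 1L
      g <- res$grads
      corr <- lr * sqrt(1 - b2^step) / (1 - b1^step)
      for (nm in names(w)) {
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g[[nm]]
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g[[nm]]^2
        w[[nm]] <- w[[nm]] - corr * mstate[[nm]] / (sqrt(vstate[[nm]]) + eps)
      }
    }
    hist_loss[ep] <- ep_loss / config@steps_per_epoch
    if (!is.null(val_samples)) {
      pred <- .fc_forward(w, val_samples$X, val_samples$S)
      hist_val[ep] <- median(sqrt(colMeans((pred - val_samples$Y)^2)))
    }
  }
  history <- data.frame(epoch = seq_len(config@epochs), loss = hist_loss)
  if (!is.null(val_samples)) history$val_rmse <- hist_val
  new("ForecastModel", weights = w, config = config,
      normalizer = normalizer, mask = as.numeric(mask), history = history)
}

#' Encode a past block into the 32-d latent vector
#'
#' The encoder consumes a variable-length normalized 8 x P block
#' recurrently and returns a fixed 32-dimensional representation of the
#' cell's past regardless of P. Deterministic given the weights. When
#' `past` is a 3-d array (8 x P x B) a 32 x B matrix is returned.
#'
#' @param model a [ForecastModel-class]
#' @param past normalized 8 x P matrix (or 8 x P x B array)
#' @return numeric(32) latent vector, or 32 x B matrix for batched input.
#' @export
encodePast <- function(model, past) {
  if (is.matrix(past)) {
    if (nrow(past) != 8L) stop("past must have 8 channels")
    if (max(past, na.rm = TRUE) > 2 || min(past, na.rm = TRUE) < -1)
      warning("past block does not look normalized to [0,1]")
    x <- array(past, c(8, ncol(past), 1))
    if (length(model@mask)) x[model@mask, , ] <- 0
    return(as.numeric(.fc_encode(model@weights, x)))
  }
  stopifnot(length(dim(past)) == 3L, dim(past)[1] == 8L)
  if (length(model@mask)) past[model@mask, , ] <- 0
  .fc_encode(model@weights, past)
}

#' Predict fluorescence for candidate stimulation strategies
#'
#' Concatenates the latent vector with each candidate H-bit stimulation
#' sequence and runs the perceptron decoder. Many candidates are evaluated
#' against one (or many) latent vectors in a single batched call, the
#' pattern used 1000 times per cell in each control step.
#'
#' @param model a [ForecastModel-class]
#' @param z numeric(32) latent vector, or 32 x B matrix of latents
#' @param stims H-bit vector, or candidates x H matrix (paired column-wise
#'   with `z` when both are batched)
#' @return numeric(H) prediction, or candidates x H matrix, in normalized
#'   units.
#' @export
decodeStrategies <- function(model, z, stims) {
  H <- model@config@horizon
  if (is.vector(stims)) stims <- matrix(stims, nrow = 1)
  if (ncol(stims) != H)
    stop("strategies must have ", H, " bits, got ", ncol(stims))
  S <- t(stims)                       # H x n_cand
  if (is.vector(z)) {
    Z <- matrix(z, 32, ncol(S))
  } else {
    if (ncol(z) == 1L) Z <- matrix(z, 32, ncol(S))
    else {
      stopifnot(ncol(z) == ncol(S))
      Z <- z
    }
  }
  out <- t(.fc_decode(model@weights, Z, S))
  if (nrow(out) == 1L) as.numeric(out) else out
}

#' Predict forecast samples (bucketed by past length)
#'
#' @param model a [ForecastModel-class]
#' @param samples list of [ForecastSample-class] with normalized pasts
#' @return n x H matrix of normalized predictions, rows matching `samples`.
#' @export
predictSamples <- function(model, samples) {
  H <- model@config@horizon
  P_all <- vapply(samples, function(s) ncol(s@past), numeric(1))
  out <- matrix(NA_real_, length(samples), H)
  for (P in unique(P_all)) {
    idx <- which(P_all == P)
    X <- array(0, c(8, P, length(idx)))
    S <- matrix(0, H, length(idx))
    for (k in seq_along(idx)) {
      X[, , k] <- samples[[idx[k]]]@past
      S[, k] <- samples[[idx[k]]]@future_stims
    }
    if (length(model@mask)) X[model@mask, , ] <- 0
    out[idx, ] <- t(.fc_forward(model@weights, X, S))
  }
  out
}

#' Evaluate a forecaster on held-out samples
#'
#' Computes the per-sample across-time RMSE distribution (25th/50th/75th/
#' 95th percentiles) and the across-samples RMSE curve over the horizon,
#' in normalized units.
#'
#' @param model a [ForecastModel-class] (or any function mapping a sample
#'   list to an n x H prediction matrix, for baseline predictors)
#' @param samples list of [ForecastSample-class]
#' @return list with `rmse_time` (numeric n), `percentiles`,
#'   `rmse_cells` (numeric H), and `predictions`.
#' @export
evaluateForecaster <- function(model, samples) {
  pred <- if (is.function(model)) model(samples)
          else predictSamples(model, samples)
  truth <- t(vapply(samples, function(s) s@future_fluo,
                    numeric(length(samples[[1]]@future_fluo))))
  per_sample <- apply(pred - truth, 1, function(e) sqrt(mean(e^2)))
  list(rmse_time = per_sample,
       percentiles = quantile(per_sample, c(0.25, 0.5, 0.75, 0.95)),
       rmse_cells = rmseCells(pred, truth),
       predictions = pred)
}

#' Persistence baseline predictor
#'
#' Predicts the last observed (normalized) mother fluorescence for every
#' future timepoint; the natural no-model reference for forecast skill.
#'
#' @param samples list of [ForecastSample-class]
#' @return n x H matrix of predictions.
#' @export
persistencePredict <- function(samples) {
  H <- length(samples[[1]]@future_fluo)
  t(vapply(samples, function(s)
    rep(s@past[2, ncol(s@past)], H), numeric(H)))
}

#' Persist / load a trained forecaster
#'
#' Single JSON archive holding weights, configuration, mask and the bound
#' normalizer at full precision.
#'
#' @param model a [ForecastModel-class]
#' @param path file path
#' @return `readForecastModel` returns the [ForecastModel-class].
#' @export
writeForecastModel <- function(model, path) {
  cfg <- model@config
  obj <- list(
    weights = lapply(model@weights, function(x)
      if (is.matrix(x)) list(dim = dim(x), v = as.numeric(x))
      else list(dim = NULL, v = as.numeric(x))),
    config = list(horizon = cfg@horizon, learning_rate = cfg@learning_rate,
                  epochs = cfg@epochs, steps_per_epoch = cfg@steps_per_epoch,
                  batch_size = cfg@batch_size, seed = cfg@seed),
    mask = model@mask,
    normalizer = list(lo = model@normalizer@lo, hi = model@normalizer@hi,
                      robust = model@normalizer@robust))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeForecastModel
#' @export
readForecastModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- lapply(x$weights, function(e) {
    if (!is.null(e$dim) && length(e$dim)) matrix(e$v, e$dim[1], e$dim[2])
    else as.numeric(e$v)
  })
  cfg <- forecastConfig(x$config$horizon / 12,
                        epochs = x$config$epochs,
                        steps_per_epoch = x$config$steps_per_epoch,
                        batch_size = x$config$batch_size,
                        learning_rate = x$config$learning_rate,
                        seed = x$config$seed)
  norm <- new("Normalizer", lo = as.numeric(x$normalizer$lo),
              hi = as.numeric(x$normalizer$hi),
              robust = isTRUE(x$normalizer$robust))
  new("ForecastModel", weights = w, config = cfg, normalizer = norm,
      mask = as.numeric(x$mask),
      history = data.frame(epoch = integer(0), loss = numeric(0)))
}

#' Draw a held-out sample set from a trace cohort
#'
#' Normalizes the cohort with the model/corpus normalizer and extracts
#' `n` forecast samples (uniform past lengths and split points).
#'
#' @param traces a [CellTraceSet-class]
#' @param norm a [Normalizer-class]
#' @param H horizon in points
#' @param n number of samples
#' @param seed integer seed
#' @return list of [ForecastSample-class].
#' @export
drawSampleSet <- function(traces, norm, H, n, seed = 1L) {
  set.seed(as.integer(seed))
  tl <- .normTraceList(traces, norm)
  ids <- sample(length(tl), n, replace = TRUE)
  lapply(seq_len(n), function(k)
    extractTrainingSample(tl[[ids[k]]], H, cell_id = as.character(ids[k])))
}
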