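## Data model for the 8-feature timeseries: stimulation design, [0,1]
## normalization, training-sample extraction, ablation transforms, and the
## on-disk dataset container.

#' Binary red/green stimulation sequence
#'
#' One bit per 5-min interval; 0 = red (repressing), 1 = green (activating).
#'
#' @slot bits integer vector of 0/1 values
#' @export
setClass("StimulationSequence", representation(bits = "numeric"))

setValidity("StimulationSequence", function(object) {
  if (length(object@bits) < 1) return("sequence must have length >= 1")
  if (!all(object@bits %in% c(0, 1))) return("bits must be 0 or 1")
  TRUE
})

#' @describeIn stimulationSequence extract the bit vector
#' @export
bits <- function(x) x@bits

#' Construct a stimulation sequence
#' @param x binary vector
#' @return A [StimulationSequence-class].
#' @export
stimulationSequence <- function(x) {
  new("StimulationSequence", bits = as.numeric(x))
}

setMethod("show", "StimulationSequence", function(object) {
  b <- object@bits
  cat(sprintf("StimulationSequence: %d intervals (%.1f h), %.0f%% green\n",
              length(b), length(b) / 12, 100 * mean(b)))
})

#' Random-walk stimulation design
#'
#' Binarizes a one-dimensional random walk (cumulative sum of i.i.d.
#' standard normal steps; bit = 1 where the walk is positive). The walk's
#' long excursions guarantee extended correlated red and green epochs,
#' which expose the slow activation/dilution dynamics during open-loop
#' training-data acquisition.
#'
#' @param T_points sequence length (one bit per 5-min interval)
#' @param rng_seed optional integer seed; when `NULL` the current RNG
#'   stream is used
#' @return A [StimulationSequence-class].
#' @export
#' @examples
#' s <- randomWalkStimulation(192, rng_seed = 1)
#' mean(bits(s))
randomWalkStimulation <- function(T_points, rng_seed = NULL) {
  if (T_points <= 0) stop("T_points must be >= 1")
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  w <- cumsum(rnorm(T_points))
  stimulationSequence(as.numeric(w > 0))
}

.BINARY_CHANNELS <- c(1L, 7L)  # stim and neighbor_stim

#' Fit a per-channel [0,1] normalizer on a training corpus
#'
#' Bounds are per-channel 0.1/99.9 percentiles of the corpus by default
#' (robust to glitch spikes in the sharpness channel and to fluorescence
#' artifacts), or raw min/max with `robust = FALSE`. Binary stimulation
#' channels are pinned to (0, 1). Missing values are excluded. The fitted
#' object must be persisted with the model so that control-time
#' normalization uses the same parameters.
#'
#' @param corpus a [CellTraceSet-class], or a list of 8 x T matrices
#' @param robust use 0.1/99.9 percentiles instead of min/max
#' @return A [Normalizer-class].
#' @export
#' @examples
#' ts <- simulateCohort(simParams(), 5, 48, 1)
#' fitNormalizer(ts)
fitNormalizer <- function(corpus, robust = TRUE) {
  if (is(corpus, "CellTraceSet")) {
    chans <- lapply(.FEATURES, function(f)
      as.numeric(SummarizedExperiment::assay(corpus, f)))
  } else if (is.list(corpus) && length(corpus) > 0) {
    chans <- lapply(1:8, function(j)
      unlist(lapply(corpus, function(m) m[j, ])))
  } else stop("corpus must be a non-empty CellTraceSet or list of traces")
  lo <- hi <- numeric(8)
  for (j in 1:8) {
    v <- chans[[j]]
    v <- v[is.finite(v)]
    if (!length(v)) stop("channel ", j, " has no finite values")
    if (j %in% .BINARY_CHANNELS) {
      lo[j] <- 0; hi[j] <- 1
    } else if (robust) {
      q <- unname(quantile(v, c(0.001, 0.999), names = FALSE, type = 7))
      lo[j] <- q[1]; hi[j] <- q[2]
    } else {
      lo[j] <- min(v); hi[j] <- max(v)
    }
  }
  new("Normalizer", lo = lo, hi = hi, robust = robust)
}

#' Apply (or invert) a fitted normalizer
#'
#' Maps each channel affinely so `lo -> 0` and `hi -> 1`, clipping outside
#' [0,1]. A degenerate constant channel (`hi == lo`) maps to 0. Missing
#' values pass through unchanged. The number of clipped entries is
#' reported as a message when `verbose = TRUE`.
#'
#' @param series an 8 x T matrix, a [ForecastSample-class] past block, or
#'   a [CellTraceSet-class]
#' @param norm a fitted [Normalizer-class]
#' @param verbose report the number of clipped values
#' @return Object of the same shape, normalized.
#' @export
applyNormalizer <- function(series, norm, verbose = FALSE) {
  stopifnot(is(norm, "Normalizer"))
  if (is(series, "CellTraceSet")) {
    a <- lapply(seq_along(.FEATURES), function(j)
      .normChannel(SummarizedExperiment::assay(series, .FEATURES[j]),
                   norm@lo[j], norm@hi[j]))
    names(a) <- .FEATURES
    se <- series
    for (f in .FEATURES)
      SummarizedExperiment::assay(se, f, withDimnames = FALSE) <- a[[f]]
    return(se)
  }
  m <- as.matrix(series)
  if (nrow(m) != 8L) stop("expected 8 channels, got ", nrow(m))
  out <- m
  n_clip <- 0L
  for (j in 1:8) {
    out[j, ] <- .normChannel(m[j, ], norm@lo[j], norm@hi[j])
    n_clip <- n_clip + sum((m[j, ] < norm@lo[j] | m[j, ] > norm@hi[j]) &
                           is.finite(m[j, ]))
  }
  if (verbose && n_clip > 0)
    message(n_clip, " values clipped to [0,1] during normalization")
  out
}

.normChannel <- function(x, lo, hi) {
  y <- if (hi <= lo) ifelse(is.finite(x), 0, x)
       else pmin(1, pmax(0, (x - lo) / (hi - lo)))
  attributes(y) <- attributes(x)
  y
}

#' Invert a normalizer on one channel
#'
#' @param x normalized values in [0,1]
#' @param norm a [Normalizer-class]
#' @param channel channel index (default 2, mother fluorescence)
#' @return Values on the original scale.
#' @export
denormalize <- function(x, norm, channel = 2L) {
  norm@lo[channel] + x * (norm@hi[channel] - norm@lo[channel])
}

#' Persist / load a normalizer as JSON
#'
#' @param norm a [Normalizer-class]
#' @param path file path
#' @return `readNormalizer` returns the [Normalizer-class].
#' @export
writeNormalizer <- function(norm, path) {
  ## digits = I(17): significant-digit mode keeps doubles bit-exact
  jsonlite::write_json(list(lo = norm@lo, hi = norm@hi,
                            robust = norm@robust,
                            features = .FEATURES),
                       path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeNormalizer
#' @export
readNormalizer <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("Normalizer", lo = as.numeric(x$lo), hi = as.numeric(x$hi),
      robust = isTRUE(x$robust))
}

#' Extract one training sample from a trace
#'
#' Uniformly draws a past length P in [36, min(144, T - H)] (3-12 h) and a
#' split position such that H future points exist; the past block is the
#' full 8-channel window ending at the split, the future stimulations and
#' fluorescence are taken from the stimulation and mother-fluorescence
#' channels after it. The trace is assumed normalized already when feeding
#' the forecaster.
#'
#' @param series an 8 x T matrix (or [CellTraceSet-class] row via
#'   [getTrace()])
#' @param horizon_H number of future points (12, 24, 36, 48)
#' @param cell_id identifier stored in the sample
#' @return A [ForecastSample-class], or `NULL` if the trace is shorter
#'   than 36 + H (caller should resample).
#' @export
extractTrainingSample <- function(series, horizon_H, cell_id = "cell") {
  m <- as.matrix(series)
  T_len <- ncol(m)
  if (T_len < 36 + horizon_H) return(NULL)
  p_max <- min(144, T_len - horizon_H)
  P <- if (p_max == 36) 36L else sample(36:p_max, 1L)
  split <- if (P == T_len - horizon_H) P
           else sample(P:(T_len - horizon_H), 1L)
  new("ForecastSample",
      past = m[, (split - P + 1):split, drop = FALSE],
      future_stims = m[1, (split + 1):(split + horizon_H)],
      future_fluo = m[2, (split + 1):(split + horizon_H)],
      split_index = split, cell_id = as.character(cell_id))
}

#' Mask past feature channels (ablation transform)
#'
#' Replaces the selected past channels with constant 0, emulating
#' feature-ablation studies in which the forecaster is retrained without
#' access to a feature. Idempotent; supports multi-channel masks (e.g.,
#' both fluorescence channels 2 and 4).
#'
#' @param sample a [ForecastSample-class]
#' @param channels integer indices in 1..8
#' @return The masked [ForecastSample-class].
#' @export
maskFeature <- function(sample, channels) {
  channels <- as.integer(channels)
  if (any(channels < 1L | channels > 8L)) stop("channel index out of 1..8")
  sample@past[channels, ] <- 0
  sample
}

#' Truncate a sample's past to its most recent timepoints
#'
#' @param sample a [ForecastSample-class]
#' @param keep number of most recent past timepoints to retain
#' @return The truncated [ForecastSample-class].
#' @export
truncatePast <- function(sample, keep) {
  P <- ncol(sample@past)
  if (keep <= 0) stop("keep must be >= 1")
  keep <- min(keep, P)
  sample@past <- sample@past[, (P - keep + 1):P, drop = FALSE]
  sample
}

#' Write / read a trace cohort as a text dataset
#'
#' The container is one flat CSV holding the cells x 8 x T array (one row
#' per cell and feature, full 17-significant-digit precision so that
#' write/read round-trips bit-exactly) plus a CSV manifest with cell ids
#' and simulation provenance.
#'
#' @param x a [CellTraceSet-class]
#' @param dir output directory (created if needed)
#' @return `readTraces` returns the [CellTraceSet-class].
#' @export
#' @examples
#' ts <- simulateCohort(simParams(), 2, 24, 1)
#' d <- tempfile(); writeTraces(ts, d)
#' identical(fluoMatrix(readTraces(d)), fluoMatrix(ts))
writeTraces <- function(x, dir) {
  stopifnot(is(x, "CellTraceSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(.FEATURES), function(j) {
    m <- SummarizedExperiment::assay(x, .FEATURES[j])
    data.table::data.table(cell = rownames(x), feature = .FEATURES[j],
      values = apply(m, 1, function(r)
        paste(sprintf("%.17g", r), collapse = ";")))
  })
  data.table::fwrite(data.table::rbindlist(rows),
                     file.path(dir, "traces.csv"))
  rd <- SummarizedExperiment::rowData(x)
  data.table::fwrite(as.data.frame(rd), file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' @rdname writeTraces
#' @param dir dataset directory written by `writeTraces`
#' @export
readTraces <- function(dir) {
  dt <- data.table::fread(file.path(dir, "traces.csv"))
  man <- data.table::fread(file.path(dir, "manifest.csv"))
  cells <- unique(dt$cell)
  A <- lapply(.FEATURES, function(f) {
    sub <- dt[dt$feature == f, ]
    sub <- sub[match(cells, sub$cell), ]
    do.call(rbind, lapply(strsplit(sub$values, ";"), as.numeric))
  })
  names(A) <- .FEATURES
  rd <- S4Vectors::DataFrame(man)
  se <- SummarizedExperiment::SummarizedExperiment(assays = A, rowData = rd)
  rownames(se) <- cells
  new("CellTraceSet", se)
}
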