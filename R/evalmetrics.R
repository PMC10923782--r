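## Quantitative evaluation: the two RMSE metrics, growth-rate computation
## with the artifact filters, growing/dying partitioning, missing-aware
## smoothing, and covariate-conditioned error tables.

#' Root mean square error across time for one cell
#'
#' `sqrt(mean((f - g)^2))` over timepoints, excluding missing pairs
#' pairwise; returns `NA` when no valid pair exists.
#'
#' @param f,g numeric vectors of equal length (prediction / truth, or
#'   fluorescence / objective)
#' @return scalar RMSE.
#' @export
#' @examples
#' rmseTime(c(1, 3), c(0, 0))  # sqrt(5)
rmseTime <- function(f, g) {
  if (length(f) != length(g)) stop("lengths differ")
  ok <- is.finite(f) & is.finite(g)
  if (!any(ok)) return(NA_real_)
  sqrt(mean((f[ok] - g[ok])^2))
}

#' Root mean square error across cells at each timepoint
#'
#' @param F_mat,G_mat matched N x T matrices
#' @return numeric(T) per-timepoint RMSE across cells (missing pairs
#'   excluded pairwise; `NA` where no cell has valid data).
#' @export
#' @examples
#' rmseCells(rbind(c(3, 0), c(4, 0)), matrix(0, 2, 2))  # c(5/sqrt(2), 0)
rmseCells <- function(F_mat, G_mat) {
  F_mat <- as.matrix(F_mat); G_mat <- as.matrix(G_mat)
  if (!all(dim(F_mat) == dim(G_mat))) stop("shapes differ")
  e2 <- (F_mat - G_mat)^2
  sqrt(colMeans(e2, na.rm = TRUE))
}

#' Per-cell growth rate with artifact filters
#'
#' Area values where area < 0.44 um^2 or fluorescence < 100 a.u. (image
#' analysis artifacts typical of dying cells) are set missing first. The
#' relative area increment `(area(t+1) - area(t)) / area(t)` per 5-min
#' interval is then converted to 1/h, and values below -2.4 1/h are set
#' missing to remove division timepoints (a division halves area:
#' -0.5/interval = -6 1/h). Missingness propagates; positions are never
#' dropped, so the output stays aligned with the input (last entry `NA`).
#'
#' @param area numeric area series (um^2)
#' @param fluo numeric fluorescence series (a.u.), aligned with `area`
#' @param dt_min sampling interval in minutes
#' @param min_area,min_fluo,min_growth filter thresholds
#' @return numeric series of growth rates (1/h), same length as `area`.
#' @export
growthRate <- function(area, fluo, dt_min = 5, min_area = 0.44,
                       min_fluo = 100, min_growth = -2.4) {
  n <- length(area)
  if (n < 2) return(numeric(0))
  a <- area
  a[!is.finite(a) | a < min_area] <- NA_real_
  a[!is.finite(fluo) | fluo < min_fluo] <- NA_real_
  g <- c((a[-1] - a[-n]) / a[-n], NA_real_) / (dt_min / 60)
  g[!is.na(g) & g < min_growth] <- NA_real_
  g
}

#' Growth rates for a whole cohort
#'
#' @param traces a [CellTraceSet-class]
#' @param ... passed to [growthRate()]
#' @return cells x T matrix of growth rates (1/h).
#' @export
growthRateMatrix <- function(traces, ...) {
  area <- areaMatrix(traces) * 0.0044   # px -> um^2 at the default pixel size
  fluo <- fluoMatrix(traces)
  t(vapply(seq_len(nrow(area)), function(i)
    growthRate(area[i, ], fluo[i, ], ...), numeric(ncol(area))))
}

#' Fraction of cells in the growing sub-population
#'
#' Cells with (smoothed) growth rate at or above the heuristic threshold
#' of 0.3 1/h count as growing; the fraction is taken among cells with
#' valid data at each timepoint.
#'
#' @param growth cells x T matrix of (smoothed) growth rates (1/h)
#' @param threshold growing/dying threshold (1/h)
#' @return numeric(T) fraction per timepoint (`NA` where no valid cell).
#' @export
growingFraction <- function(growth, threshold = 0.3) {
  growth <- as.matrix(growth)
  apply(growth, 2, function(col) {
    ok <- is.finite(col)
    if (!any(ok)) return(NA_real_)
    mean(col[ok] >= threshold)
  })
}

#' Missing-aware smoothing
#'
#' Two filters: `"median1h"`, a sliding median over a one-hour window (13
#' points at 5-min sampling), and `"savgol"`, a Savitzky-Golay filter of
#' length 15 and polynomial order 2 implemented as a local least-squares
#' quadratic fit so that missing values are simply excluded from each
#' window. Edges are handled by window shrinkage. Quadratic series are
#' reproduced exactly by the Savitzky-Golay filter in the interior.
#'
#' @param x numeric series, may contain `NA`
#' @param method `"median1h"` or `"savgol"`
#' @param width override the window length
#' @return smoothed series, same length; entries with an empty window
#'   remain `NA`.
#' @export
smoothSeries <- function(x, method = c("median1h", "savgol"),
                         width = NULL) {
  method <- match.arg(method)
  n <- length(x)
  if (method == "median1h") {
    w <- if (is.null(width)) 13L else as.integer(width)
    half <- w %/% 2
    vapply(seq_len(n), function(i) {
      win <- x[max(1, i - half):min(n, i + half)]
      win <- win[is.finite(win)]
      if (!length(win)) NA_real_ else median(win)
    }, numeric(1))
  } else {
    w <- if (is.null(width)) 15L else as.integer(width)
    half <- w %/% 2
    vapply(seq_len(n), function(i) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      tt <- (lo:hi) - i
      vv <- x[lo:hi]
      ok <- is.finite(vv)
      if (sum(ok) < 3) {
        if (!any(ok)) return(NA_real_)
        return(mean(vv[ok]))
      }
      fit <- lm.fit(cbind(1, tt[ok], tt[ok]^2), vv[ok])
      unname(fit$coefficients[1])
    }, numeric(1))
  }
}

#' Covariate-conditioned error tables
#'
#' Bins prediction/tracking errors by a per-cell-and-timepoint covariate
#' and reports per-bin across-cells RMSE and absolute-error percentiles.
#' Supported covariates: the objective value (linear bins), the objective
#' time-derivative (signed log-scale bins, since derivatives span positive
#' and negative decades), and the growth-rate percentile (bins 1..100).
#'
#' @param pred,obj matched N x T matrices (measured fluorescence and
#'   objective, or predictions and ground truth)
#' @param covariate N x T matrix of covariate values (for
#'   `type = "growth"`, growth rates in 1/h)
#' @param type one of `"value"`, `"derivative"`, `"growth"`
#' @param n_bins number of bins for value/derivative types
#' @return data.frame with bin centers/labels, per-bin RMSE, median and
#'   25/75 percentile absolute error, and counts; empty bins have `NA`.
#' @export
conditionedError <- function(pred, obj, covariate,
                             type = c("value", "derivative", "growth"),
                             n_bins = 20L) {
  type <- match.arg(type)
  err <- as.numeric(pred) - as.numeric(obj)
  cv <- as.numeric(covariate)
  ok <- is.finite(err) & is.finite(cv)
  err <- err[ok]; cv <- cv[ok]
  if (type == "growth") {
    pct <- ceiling(100 * rank(cv, ties.method = "average") / length(cv))
    pct <- pmax(1L, pmin(100L, pct))
    idx <- factor(pct, levels = 1:100)
    centers <- 1:100
  } else if (type == "derivative") {
    slog <- sign(cv) * log10(1 + abs(cv))
    br <- seq(min(slog), max(slog), length.out = n_bins + 1)
    idx <- cut(slog, br, include.lowest = TRUE)
    centers <- (head(br, -1) + tail(br, -1)) / 2
    centers <- sign(centers) * (10^abs(centers) - 1)
  } else {
    br <- seq(min(cv), max(cv), length.out = n_bins + 1)
    idx <- cut(cv, br, include.lowest = TRUE)
    centers <- (head(br, -1) + tail(br, -1)) / 2
  }
  agg <- function(f) as.numeric(tapply(err, idx, f))
  data.frame(
    bin = centers,
    rmse = agg(function(e) sqrt(mean(e^2))),
    mae = agg(function(e) mean(abs(e))),
    abs_q25 = agg(function(e) quantile(abs(e), 0.25)),
    abs_median = agg(function(e) median(abs(e))),
    abs_q75 = agg(function(e) quantile(abs(e), 0.75)),
    n = as.numeric(tapply(err, idx, length)))
}
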