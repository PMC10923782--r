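## Stochastic simulator of optogenetically actuated mother-machine cells.
##
## The plant is a minimal two-state model: green light drives a promoter
## activation variable a in [0,1] with rate k_on, red light relaxes it with
## rate k_off; the activation gates production of a stable fluorescent
## species g, which is lost to maturation/degradation (gamma_m) and to
## dilution by exponential growth (mu). Growth slows with cell age, cells
## divide when they reach A_div (halving area, conserving concentration),
## and rare death/filamentation events create hard-to-predict traces.
## Production carries a clipped Ornstein-Uhlenbeck multiplicative noise.
## Integration is Euler-Maruyama on substeps dt_sim inside each 5-min
## measurement interval.

.paramsHash <- function(params) {
  v <- c(params@k_on, params@k_off, params@beta0, params@leak,
         params@gamma_m, params@mu0, params@k_age, params@A_birth,
         params@A_div, params@cv_cell, params@sigma_eta, params@tau_eta,
         params@sigma_meas, params@p_death, params@p_fil, params@p_glitch,
         params@chamber_cap, params@px_area, params@dt_sim, params@dt_meas)
  sprintf("%08x", sum(as.integer(abs(v * 1e6) %% 2147483647)) %% 4294967296)
}

## Vectorized cohort state held as a plain list of aligned vectors.
.cohortInit <- function(params, n) {
  sdlog <- sqrt(log(1 + params@cv_cell^2))
  beta_cell <- exp(rnorm(n, 0, sdlog))   # median 1, CV = cv_cell
  mu_cell <- exp(rnorm(n, 0, sdlog))
  A <- runif(n, params@A_birth, params@A_div)
  mu_init <- mu_cell * params@mu0 / 60
  g <- params@leak * beta_cell * params@beta0 / (params@gamma_m + mu_init)
  list(a = rep(0, n), g = g, eta = rep(0, n), A = A, age = rep(0, n),
       mode = rep(0L, n),  # 0 growing, 1 filamenting, 2 dead
       beta_cell = beta_cell, mu_cell = mu_cell,
       n_chamber = rep(1L, n), fil_left = rep(0, n), n = n)
}

## Advance all cells one measurement interval under per-cell light bits and
## emit the 8 features. Consumes the R RNG stream in a fixed order.
.cohortStep <- function(st, bits, params, neighbor_bits = NULL) {
  n <- st$n
  dt <- params@dt_sim
  n_sub <- round(params@dt_meas / dt)
  noisy_eta <- params@sigma_eta > 0
  ## Exponential integrator: within a substep the light input and the
  ## production-noise multiplier are frozen, making a, g and A linear ODEs
  ## that are advanced by their exact solutions; the OU noise state uses
  ## its exact Gaussian transition. The deterministic part is therefore
  ## step-size independent (up to division-event timing).
  for (k in seq_len(n_sub)) {
    dead <- st$mode == 2L
    mu_inst <- ifelse(dead, 0,
                      st$mu_cell * params@mu0 * exp(-params@k_age * st$age) / 60)
    r_act <- ifelse(bits > 0.5, params@k_on, params@k_off)
    a_eq <- as.numeric(bits > 0.5)
    e_r <- exp(-r_act * dt)
    a_old <- st$a
    st$a <- a_eq + (st$a - a_eq) * e_r
    noise_mult <- pmax(0, 1 + st$eta)
    if (noisy_eta) {
      e_t <- exp(-dt / params@tau_eta)
      st$eta <- st$eta * e_t +
        params@sigma_eta * sqrt(1 - e_t^2) * rnorm(n)
    }
    ## g' = c0 + c1 e^(-r t) - lambda g over the substep, solved exactly
    B <- st$beta_cell * params@beta0 * noise_mult
    B[dead] <- 0
    c0 <- B * (params@leak + (1 - params@leak) * a_eq)
    c1 <- B * (1 - params@leak) * (a_old - a_eq)
    lam <- pmax(params@gamma_m + mu_inst, 1e-12)
    e_l <- exp(-lam * dt)
    near <- abs(lam - r_act) < 1e-12
    part <- ifelse(near, c1 * dt * e_l,
                   c1 * (e_r - e_l) / (lam - r_act))
    st$g <- pmax(0, st$g * e_l + c0 * (1 - e_l) / lam + part)
    st$A <- st$A * exp(mu_inst * dt)    # frozen for dead cells (mu_inst = 0)
    div <- st$mode == 0L & st$A >= params@A_div
    if (any(div)) {
      st$A[div] <- st$A[div] / 2        # concentration g unchanged
      st$n_chamber[div] <- pmin(st$n_chamber[div] + 1L, params@chamber_cap)
    }
    ## filamenting cells keep growing without dividing; cap to keep finite
    st$A <- pmin(st$A, 6 * params@A_div)
    st$age <- st$age + dt / 60
  }
  ## mode transitions, sampled once per measurement step
  fil <- st$mode == 1L
  st$fil_left[fil] <- st$fil_left[fil] - params@dt_meas
  recovered <- fil & st$fil_left <= 0
  st$mode[recovered] <- 0L
  if (params@p_death > 0) {
    dies <- runif(n) < params@p_death & st$mode != 2L
    st$mode[dies] <- 2L
  }
  if (params@p_fil > 0) {
    fils <- runif(n) < params@p_fil & st$mode == 0L
    if (any(fils)) {
      st$mode[fils] <- 1L
      st$fil_left[fils] <- rexp(sum(fils), rate = 1 / 120)  # mean 2 h
    }
  }
  ## emitted features
  fluo <- st$g
  if (params@sigma_meas > 0)
    fluo <- fluo * (1 + params@sigma_meas * rnorm(n))
  fluo <- pmax(0, fluo)
  chamber_mean <- pmax(0, fluo * (1 + 0.05 * rnorm(n)))
  chamber_sd <- 0.25 * chamber_mean * abs(1 + 0.1 * rnorm(n))
  sharp <- 1 + 0.02 * rnorm(n)
  if (params@p_glitch > 0) {
    gl <- runif(n) < params@p_glitch
    if (any(gl)) sharp[gl] <- sharp[gl] + 2 + rexp(sum(gl), 1)
  }
  if (is.null(neighbor_bits)) neighbor_bits <- rep(0, n)
  feats <- cbind(stim = bits, fluo = fluo, area_px = st$A / params@px_area,
                 chamber_mean = chamber_mean, chamber_sd = chamber_sd,
                 cell_count = as.numeric(st$n_chamber),
                 neighbor_stim = neighbor_bits, sharpness = sharp)
  list(state = st, features = feats)
}

.stateToList <- function(state) {
  mode_code <- c(growing = 0L, filamenting = 1L, dead = 2L)[state@mode]
  list(a = state@a, g = state@g, eta = state@eta, A = state@A,
       age = state@age, mode = unname(mode_code),
       beta_cell = state@beta_cell, mu_cell = state@mu_cell,
       n_chamber = as.integer(state@n_chamber), fil_left = state@fil_left,
       n = 1L)
}

.listToState <- function(st) {
  new("CellState", a = st$a[1], g = st$g[1], eta = st$eta[1], A = st$A[1],
      age = st$age[1],
      mode = c("growing", "filamenting", "dead")[st$mode[1] + 1L],
      beta_cell = st$beta_cell[1], mu_cell = st$mu_cell[1],
      n_chamber = st$n_chamber[1], fil_left = st$fil_left[1])
}

#' Draw the initial state of a simulated mother cell
#'
#' Per-cell production and growth multipliers are drawn log-normally with
#' median 1 and coefficient of variation `cv_cell`, emulating cell-to-cell
#' rate heterogeneity. The cell starts inactive (a = 0) at the red-light
#' steady state of fluorescence, with area uniform between birth and
#' division size.
#'
#' @param params a [SimParams-class]
#' @param rng_seed integer seed
#' @return A [CellState-class].
#' @export
#' @examples
#' sampleCell(simParams(), 1)
sampleCell <- function(params, rng_seed = 1L) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  set.seed(as.integer(rng_seed))
  st <- .cohortInit(params, 1L)
  .listToState(st)
}

#' Advance one cell by one measurement interval
#'
#' Integrates the plant dynamics over one 5-min measurement interval
#' (Euler-Maruyama substeps of `dt_sim`) under a constant light input, then
#' samples death/filamentation transitions. Uses the current R RNG stream;
#' seed with [set.seed()] for reproducibility.
#'
#' @param state a [CellState-class]
#' @param light 0 (red) or 1 (green)
#' @param params a [SimParams-class]
#' @return The updated [CellState-class].
#' @export
#' @examples
#' p <- simParams(sigma_eta = 0, p_death = 0, p_fil = 0)
#' s <- sampleCell(p, 1)
#' stepCell(s, 1, p)
stepCell <- function(state, light, params) {
  stopifnot(light %in% c(0, 1))
  validObject(state)
  st <- .stateToList(state)
  out <- .cohortStep(st, light, params)
  .listToState(out$state)
}

.makeTraceSet <- function(assays_list, cell_ids, seed, params) {
  rd <- S4Vectors::DataFrame(cell_id = cell_ids, seed = seed,
                             params_hash = .paramsHash(params))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays_list, rowData = rd)
  rownames(se) <- cell_ids
  new("CellTraceSet", se)
}

#' Simulate a cohort of independent mother-machine chambers
#'
#' Each cell receives its own stimulation sequence and an independent
#' neighbor-chamber sequence (binarized random walks when not supplied),
#' and emits the 8 feature timeseries at 5-min resolution. Dead cells show
#' decaying fluorescence and frozen area.
#'
#' @param params a [SimParams-class]
#' @param n_cells number of cells
#' @param T_points number of 5-min timepoints (192 = 16 h)
#' @param rng_seed integer seed; the whole cohort is reproducible from it
#' @param stims optional n_cells x T matrix (or single vector recycled) of
#'   stimulation bits; defaults to independent binarized random walks
#' @return A [CellTraceSet-class] with `n_cells` rows.
#' @export
#' @examples
#' ts <- simulateCohort(simParams(), n_cells = 3, T_points = 48, rng_seed = 1)
#' dim(SummarizedExperiment::assay(ts, "fluo"))
simulateCohort <- function(params, n_cells, T_points, rng_seed = 1L,
                           stims = NULL) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  if (T_points <= 0) stop("T_points must be positive")
  set.seed(as.integer(rng_seed))
  if (is.null(stims)) {
    stims <- t(vapply(seq_len(n_cells), function(i)
      as.numeric(bits(randomWalkStimulation(T_points))),
      numeric(T_points)))
  } else if (is.vector(stims)) {
    if (length(stims) < T_points) stop("stims shorter than T_points")
    stims <- matrix(rep(as.numeric(stims[seq_len(T_points)]),
                        each = n_cells), nrow = n_cells)
  } else {
    if (ncol(stims) < T_points) stop("stims shorter than T_points")
    stims <- stims[, seq_len(T_points), drop = FALSE]
  }
  neighbor <- t(vapply(seq_len(n_cells), function(i)
    as.numeric(bits(randomWalkStimulation(T_points))), numeric(T_points)))
  st <- .cohortInit(params, n_cells)
  A <- lapply(.FEATURES, function(f) matrix(NA_real_, n_cells, T_points))
  names(A) <- .FEATURES
  for (t in seq_len(T_points)) {
    out <- .cohortStep(st, stims[, t], params, neighbor[, t])
    st <- out$state
    for (j in seq_along(.FEATURES)) A[[j]][, t] <- out$features[, j]
  }
  .makeTraceSet(A, sprintf("cell%05d", seq_len(n_cells)),
                as.integer(rng_seed), params)
}

#' Simulate a single chamber
#'
#' Convenience wrapper around [simulateCohort()] for one cell under a
#' given stimulation sequence.
#'
#' @param params a [SimParams-class]
#' @param stims a [StimulationSequence-class] or binary vector of length
#'   at least `T_points`
#' @param T_points number of timepoints to emit
#' @param rng_seed integer seed
#' @return A [CellTraceSet-class] with one row.
#' @export
#' @examples
#' s <- randomWalkStimulation(48, rng_seed = 7)
#' simulateChamber(simParams(), s, 48, rng_seed = 7)
simulateChamber <- function(params, stims, T_points, rng_seed = 1L) {
  if (T_points <= 0) stop("T_points must be positive")
  b <- if (is(stims, "StimulationSequence")) bits(stims) else as.numeric(stims)
  if (length(b) < T_points) stop("stims must cover T_points")
  simulateCohort(params, 1L, T_points, rng_seed,
                 stims = matrix(b[seq_len(T_points)], nrow = 1))
}

setMethod("show", "CellTraceSet", function(object) {
  cat(sprintf("CellTraceSet: %d cells x %d timepoints (%.1f h at 5-min sampling)\n",
              nrow(object), ncol(object), ncol(object) / 12))
  fl <- SummarizedExperiment::assay(object, "fluo")
  cat(sprintf("  fluorescence range [%.0f, %.0f] a.u.; features: %s\n",
              min(fl, na.rm = TRUE), max(fl, na.rm = TRUE),
              paste(.FEATURES, collapse = ", ")))
})

#' Extract one cell's 8 x T feature matrix
#'
#' @param x a [CellTraceSet-class]
#' @param i cell index or id
#' @return A numeric 8 x T matrix with feature names as rownames.
#' @export
#' @examples
#' ts <- simulateCohort(simParams(), 2, 24, 1)
#' dim(getTrace(ts, 1))
getTrace <- function(x, i) {
  stopifnot(is(x, "CellTraceSet"))
  m <- do.call(rbind, lapply(.FEATURES, function(f)
    SummarizedExperiment::assay(x, f)[i, ]))
  rownames(m) <- .FEATURES
  m
}

#' Accessors for common feature matrices
#'
#' `stimMatrix`, `fluoMatrix` and `areaMatrix` return the cells x timepoints
#' matrix for the stimulation, mother fluorescence and mother area (pixel)
#' channels respectively.
#'
#' @param x a [CellTraceSet-class]
#' @return A numeric matrix, cells x timepoints.
#' @export
stimMatrix <- function(x) SummarizedExperiment::assay(x, "stim")

#' @rdname stimMatrix
#' @export
fluoMatrix <- function(x) SummarizedExperiment::assay(x, "fluo")

#' @rdname stimMatrix
#' @export
areaMatrix <- function(x) SummarizedExperiment::assay(x, "area_px")
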