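#' @import methods
#' @importFrom stats rnorm runif rexp quantile median sd setNames optim
#'   lm.fit var rank
#' @importFrom utils head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData
#' @importFrom S4Vectors DataFrame
#' @useDynLib optoMPC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Canonical channel order of the 8-feature single-cell record. Everything in
## the package indexes features by these names; the order is part of the
## on-disk format.
.FEATURES <- c("stim", "fluo", "area_px", "chamber_mean", "chamber_sd",
               "cell_count", "neighbor_stim", "sharpness")

#' Names of the eight single-cell features
#'
#' The per-timepoint features recorded for each mother cell, in canonical
#' order: applied stimulation bit (0 = red, 1 = green), mother-cell
#' fluorescence (a.u.), mother-cell area (pixels), mean and standard
#' deviation of fluorescence across the chamber (a.u.), number of cells in
#' the chamber, stimulation bit applied to the neighboring chamber, and
#' image sharpness.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' featureNames()
featureNames <- function() .FEATURES

#' Simulator parameters for the optogenetic mother-machine cell
#'
#' Parameters of the stochastic in-silico plant: a light-switched promoter
#' activation state drives fluorescent protein production, diluted by
#' exponential cell growth with division events, with per-cell rate
#' heterogeneity, Ornstein-Uhlenbeck production noise, aging, and rare
#' death/filamentation transitions.
#'
#' @slot k_on activation rate under green light (1/min)
#' @slot k_off deactivation rate under red light (1/min)
#' @slot beta0 maximal production rate (a.u./min)
#' @slot leak basal production fraction in [0,1]
#' @slot gamma_m maturation/degradation rate (1/min)
#' @slot mu0 baseline specific growth rate (1/h)
#' @slot k_age aging decay rate of growth (1/h)
#' @slot A_birth,A_div birth and division areas (um^2)
#' @slot cv_cell log-normal coefficient of variation of the per-cell
#'   production and growth multipliers
#' @slot sigma_eta,tau_eta production-noise magnitude (dimensionless) and
#'   correlation time (min)
#' @slot sigma_meas relative fluorescence measurement noise
#' @slot p_death,p_fil per-measurement-step probabilities of death and
#'   filamentation onset
#' @slot p_glitch per-step probability of a sharpness spike artifact
#' @slot chamber_cap maximum number of cells in a chamber
#' @slot px_area area of one pixel (um^2)
#' @slot dt_sim integration substep (min); must divide dt_meas
#' @slot dt_meas measurement interval (min)
#' @export
setClass("SimParams", representation(
  k_on = "numeric", k_off = "numeric", beta0 = "numeric", leak = "numeric",
  gamma_m = "numeric", mu0 = "numeric", k_age = "numeric",
  A_birth = "numeric", A_div = "numeric", cv_cell = "numeric",
  sigma_eta = "numeric", tau_eta = "numeric", sigma_meas = "numeric",
  p_death = "numeric", p_fil = "numeric", p_glitch = "numeric",
  chamber_cap = "numeric", px_area = "numeric",
  dt_sim = "numeric", dt_meas = "numeric"))

setValidity("SimParams", function(object) {
  v <- c(k_on = object@k_on, k_off = object@k_off, beta0 = object@beta0,
         gamma_m = object@gamma_m, mu0 = object@mu0, k_age = object@k_age,
         cv_cell = object@cv_cell, sigma_eta = object@sigma_eta,
         tau_eta = object@tau_eta, sigma_meas = object@sigma_meas,
         p_death = object@p_death, p_fil = object@p_fil,
         p_glitch = object@p_glitch)
  if (any(!is.finite(v)) || any(v < 0))
    return("all rates and noise magnitudes must be finite and >= 0")
  if (object@leak < 0 || object@leak > 1) return("leak must be in [0,1]")
  if (!(object@A_birth < object@A_div)) return("A_birth must be < A_div")
  if (object@px_area <= 0) return("px_area must be > 0")
  if (object@dt_sim <= 0 || object@dt_meas <= 0)
    return("time steps must be positive")
  n_sub <- object@dt_meas / object@dt_sim
  if (abs(n_sub - round(n_sub)) > 1e-9)
    return("dt_sim must divide dt_meas")
  TRUE
})

#' Construct simulator parameters
#'
#' Defaults are calibrated so that the fully induced (constant green)
#' steady state is ~2500 a.u. and the repressed (constant red) state is
#' ~150 a.u., bracketing the 800-1800 a.u. objective band used in control
#' experiments, with minutes-scale activation kinetics and
#' dilution-dominated decay.
#'
#' @param k_on,k_off light-switched activation/deactivation rates (1/min)
#' @param beta0 maximal production rate (a.u./min)
#' @param leak basal production fraction
#' @param gamma_m maturation/degradation rate (1/min)
#' @param mu0 baseline specific growth rate (1/h)
#' @param k_age aging decay rate of growth (1/h)
#' @param A_birth,A_div birth and division areas (um^2)
#' @param cv_cell coefficient of variation of per-cell rate multipliers
#' @param sigma_eta,tau_eta production-noise magnitude and correlation
#'   time (min)
#' @param sigma_meas relative fluorescence measurement noise
#' @param p_death,p_fil per-step death/filamentation probabilities
#' @param p_glitch per-step probability of a sharpness spike
#' @param chamber_cap chamber capacity (cells)
#' @param px_area pixel area (um^2)
#' @param dt_sim,dt_meas integration substep and measurement interval (min)
#' @return A [SimParams-class] object.
#' @export
#' @examples
#' p <- simParams()
#' p
simParams <- function(k_on = 0.2, k_off = 0.1, beta0 = 63, leak = 0.06,
                      gamma_m = 0.002, mu0 = 1.4, k_age = 0.02,
                      A_birth = 1.5, A_div = 3.0, cv_cell = 0.2,
                      sigma_eta = 0.25, tau_eta = 20, sigma_meas = 0.05,
                      p_death = 5e-4, p_fil = 1e-3, p_glitch = 0.005,
                      chamber_cap = 8, px_area = 0.0044,
                      dt_sim = 0.5, dt_meas = 5) {
  new("SimParams", k_on = k_on, k_off = k_off, beta0 = beta0, leak = leak,
      gamma_m = gamma_m, mu0 = mu0, k_age = k_age, A_birth = A_birth,
      A_div = A_div, cv_cell = cv_cell, sigma_eta = sigma_eta,
      tau_eta = tau_eta, sigma_meas = sigma_meas, p_death = p_death,
      p_fil = p_fil, p_glitch = p_glitch, chamber_cap = chamber_cap,
      px_area = px_area, dt_sim = dt_sim, dt_meas = dt_meas)
}

setMethod("show", "SimParams", function(object) {
  cat("SimParams (optogenetic mother-machine plant)\n")
  cat(sprintf("  activation: k_on=%.3g k_off=%.3g 1/min; production: beta0=%.3g a.u./min, leak=%.3g\n",
              object@k_on, object@k_off, object@beta0, object@leak))
  cat(sprintf("  loss: gamma_m=%.3g 1/min; growth: mu0=%.3g 1/h, k_age=%.3g 1/h\n",
              object@gamma_m, object@mu0, object@k_age))
  cat(sprintf("  geometry: A_birth=%.3g A_div=%.3g um^2; heterogeneity cv=%.3g\n",
              object@A_birth, object@A_div, object@cv_cell))
  cat(sprintf("  noise: sigma_eta=%.3g (tau=%.3g min), sigma_meas=%.3g; p_death=%.2g p_fil=%.2g\n",
              object@sigma_eta, object@tau_eta, object@sigma_meas,
              object@p_death, object@p_fil))
  cat(sprintf("  steps: dt_sim=%.3g min, dt_meas=%.3g min\n",
              object@dt_sim, object@dt_meas))
})

#' Instantaneous state of one simulated cell
#'
#' @slot a promoter activation in [0,1]
#' @slot g fluorophore concentration (a.u.)
#' @slot eta Ornstein-Uhlenbeck production-noise state
#' @slot A cell area (um^2)
#' @slot age time since trace start (h)
#' @slot mode one of "growing", "filamenting", "dead"
#' @slot beta_cell,mu_cell per-cell rate multipliers (log-normal, median 1)
#' @slot n_chamber number of cells in the chamber
#' @slot fil_left remaining filamentation duration (min)
#' @export
setClass("CellState", representation(
  a = "numeric", g = "numeric", eta = "numeric", A = "numeric",
  age = "numeric", mode = "character", beta_cell = "numeric",
  mu_cell = "numeric", n_chamber = "numeric", fil_left = "numeric"))

setValidity("CellState", function(object) {
  if (object@a < -1e-12 || object@a > 1 + 1e-12) return("a must be in [0,1]")
  if (object@g < 0) return("g must be >= 0")
  if (object@A <= 0) return("A must be > 0")
  if (object@n_chamber < 1) return("n_chamber must be >= 1")
  if (!object@mode %in% c("growing", "filamenting", "dead"))
    return("unknown mode")
  TRUE
})

setMethod("show", "CellState", function(object) {
  cat(sprintf("CellState: a=%.3f g=%.1f a.u. A=%.2f um^2 age=%.2f h mode=%s\n",
              object@a, object@g, object@A, object@age, object@mode))
  cat(sprintf("  beta_cell=%.3f mu_cell=%.3f n_chamber=%d\n",
              object@beta_cell, object@mu_cell, as.integer(object@n_chamber)))
})

#' A cohort of 8-feature single-cell timeseries
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one assay per feature (see [featureNames()]), each a cells x timepoints
#' matrix sampled every 5 minutes. Row metadata carries per-cell identifiers
#' and simulation provenance.
#'
#' @export
setClass("CellTraceSet", contains = "SummarizedExperiment")

setValidity("CellTraceSet", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!identical(an, .FEATURES))
    return(sprintf("assays must be exactly the 8 features in order: %s",
                   paste(.FEATURES, collapse = ", ")))
  st <- SummarizedExperiment::assay(object, "stim")
  if (!all(st %in% c(0, 1), na.rm = TRUE))
    return("stimulation channel must be binary")
  fl <- SummarizedExperiment::assay(object, "fluo")
  if (any(fl < 0, na.rm = TRUE)) return("fluorescence must be >= 0 or NA")
  TRUE
})

#' Per-channel [0,1] normalizer
#'
#' Affine map per feature channel taking `lo` to 0 and `hi` to 1 and
#' clipping outside. Binary channels are pinned to bounds (0, 1).
#'
#' @slot lo,hi numeric(8) per-channel bounds
#' @slot robust logical; whether bounds were 0.1/99.9 percentiles rather
#'   than min/max
#' @export
setClass("Normalizer", representation(lo = "numeric", hi = "numeric",
                                      robust = "logical"))

setValidity("Normalizer", function(object) {
  if (length(object@lo) != 8L || length(object@hi) != 8L)
    return("lo and hi must have length 8")
  if (any(object@hi < object@lo)) return("hi must be >= lo")
  TRUE
})

setMethod("show", "Normalizer", function(object) {
  cat("Normalizer (per-channel [0,1] bounds",
      if (object@robust) ", robust percentiles" else ", min/max", ")\n",
      sep = "")
  m <- rbind(lo = object@lo, hi = object@hi)
  colnames(m) <- .FEATURES
  print(signif(m, 4))
})

#' One forecasting sample
#'
#' A variable-length normalized past block, the candidate/applied future
#' stimulation bits, and the future fluorescence ground truth.
#'
#' @slot past normalized 8 x P matrix, P in [36, 144]
#' @slot future_stims integer(H) bits
#' @slot future_fluo numeric(H) normalized ground truth
#' @slot split_index index of the last past timepoint in the source trace
#' @slot cell_id source cell identifier
#' @export
setClass("ForecastSample", representation(
  past = "matrix", future_stims = "numeric", future_fluo = "numeric",
  split_index = "numeric", cell_id = "character"))

setValidity("ForecastSample", function(object) {
  if (nrow(object@past) != 8L) return("past must have 8 rows")
  if (length(object@future_stims) != length(object@future_fluo))
    return("future_stims and future_fluo lengths must match")
  if (!all(object@future_stims %in% c(0, 1)))
    return("future_stims must be binary")
  TRUE
})

setMethod("show", "ForecastSample", function(object) {
  cat(sprintf("ForecastSample: past 8 x %d, horizon %d steps (cell %s, split %d)\n",
              ncol(object@past), length(object@future_stims),
              object@cell_id, as.integer(object@split_index)))
})

#' Forecaster architecture and training configuration
#'
#' @slot encoder_units integer(2), LSTM layer sizes
#' @slot latent_dim latent vector size
#' @slot decoder_units hidden width of the perceptron decoder
#' @slot decoder_layers number of hidden decoder layers
#' @slot horizon H, number of 5-min output steps (12, 24, 36 or 48)
#' @slot learning_rate Adam learning rate
#' @slot epochs,steps_per_epoch,batch_size training schedule
#' @slot seed integer seed determining the whole run
#' @export
setClass("ForecastConfig", representation(
  encoder_units = "numeric", latent_dim = "numeric",
  decoder_units = "numeric", decoder_layers = "numeric",
  horizon = "numeric", learning_rate = "numeric", epochs = "numeric",
  steps_per_epoch = "numeric", batch_size = "numeric", seed = "numeric"))

setValidity("ForecastConfig", function(object) {
  if (!object@horizon %in% c(12, 24, 36, 48))
    return("horizon must be one of 12, 24, 36, 48")
  if (object@latent_dim != 32) return("latent_dim is fixed at 32")
  if (object@learning_rate <= 0) return("learning_rate must be > 0")
  TRUE
})

#' Construct a forecaster configuration
#'
#' The reference architecture: two stacked LSTM layers of 64 and 16 units
#' compressing the variable-length 8-feature past into a 32-dimensional
#' latent vector, concatenated with the H future stimulation bits and
#' decoded by 5 rectified-linear layers of 32 units plus a linear output
#' head of H units. Trained with Adam at learning rate 1e-3 on mean squared
#' error. The full-scale evaluation schedule is 500 epochs x 200 steps x
#' batch 100; `preset` selects smaller documented schedules.
#'
#' @param horizon_hours prediction horizon in hours (1, 2, 3 or 4)
#' @param preset one of "paper" (500x200x100), "final" (200x200x100),
#'   "scaled" (50x50x64), "tiny" (4x20x32; smoke tests only)
#' @param epochs,steps_per_epoch,batch_size override the preset schedule
#' @param learning_rate Adam learning rate
#' @param seed integer seed
#' @return A [ForecastConfig-class].
#' @export
#' @examples
#' forecastConfig(2, preset = "scaled")
forecastConfig <- function(horizon_hours = 2,
                           preset = c("scaled", "paper", "final", "tiny"),
                           epochs = NULL, steps_per_epoch = NULL,
                           batch_size = NULL, learning_rate = 1e-3,
                           seed = 1L) {
  preset <- match.arg(preset)
  sched <- switch(preset,
    paper  = c(500, 200, 100),
    final  = c(200, 200, 100),
    scaled = c(50, 50, 64),
    tiny   = c(4, 20, 32))
  new("ForecastConfig", encoder_units = c(64, 16), latent_dim = 32,
      decoder_units = 32, decoder_layers = 5,
      horizon = 12 * horizon_hours, learning_rate = learning_rate,
      epochs = if (is.null(epochs)) sched[1] else epochs,
      steps_per_epoch = if (is.null(steps_per_epoch)) sched[2] else steps_per_epoch,
      batch_size = if (is.null(batch_size)) sched[3] else batch_size,
      seed = as.numeric(seed))
}

setMethod("show", "ForecastConfig", function(object) {
  cat(sprintf("ForecastConfig: LSTM(%d,%d) -> latent %d -> MLP %dx%d -> %d outputs\n",
              object@encoder_units[1], object@encoder_units[2],
              object@latent_dim, object@decoder_layers, object@decoder_units,
              object@horizon))
  cat(sprintf("  Adam lr=%.1e, %d epochs x %d steps x batch %d, seed %d\n",
              object@learning_rate, object@epochs, object@steps_per_epoch,
              object@batch_size, as.integer(object@seed)))
})

#' Trained encoder-decoder forecaster
#'
#' @slot weights named list of weight matrices/vectors
#' @slot config the [ForecastConfig-class] used for training
#' @slot normalizer the bound [Normalizer-class]
#' @slot mask integer indices of past channels zeroed during training
#'   (feature-ablation models), empty otherwise
#' @slot history data.frame of per-epoch training loss (and validation
#'   RMSE when a validation set was supplied)
#' @export
setClass("ForecastModel", representation(
  weights = "list", config = "ForecastConfig", normalizer = "Normalizer",
  mask = "numeric", history = "data.frame"))

setMethod("show", "ForecastModel", function(object) {
  np <- sum(vapply(object@weights, length, numeric(1)))
  cat(sprintf("ForecastModel: horizon %d steps (%g h), %d parameters\n",
              object@config@horizon, object@config@horizon / 12, np))
  if (length(object@mask))
    cat("  trained with masked channels:",
        paste(.FEATURES[object@mask], collapse = ", "), "\n")
  if (nrow(object@history))
    cat(sprintf("  final training loss %.5f after %d epochs\n",
                tail(object@history$loss, 1), nrow(object@history)))
})

#' Strategy-search (binary PSO) configuration
#'
#' @slot horizon_hours L, horizon in hours
#' @slot n_particles,n_iterations swarm size and iteration count; their
#'   product is the number of decoder evaluations per cell per control step
#' @slot inertia,cognitive,social canonical velocity-update coefficients
#' @slot v_max velocity clamp
#' @slot seed integer seed
#' @export
setClass("ControlConfig", representation(
  horizon_hours = "numeric", n_particles = "numeric",
  n_iterations = "numeric", inertia = "numeric", cognitive = "numeric",
  social = "numeric", v_max = "numeric", seed = "numeric"))

setValidity("ControlConfig", function(object) {
  if (!(12 * object@horizon_hours) %in% c(12, 24, 36, 48))
    return("horizon_hours must be 1, 2, 3 or 4")
  if (object@n_particles < 2) return("need at least 2 particles")
  TRUE
})

#' Construct a strategy-search configuration
#'
#' Defaults follow the canonical binary particle swarm: 40 particles
#' iterated 25 times (1000 cost evaluations per cell and control step),
#' inertia 0.7, cognitive = social = 1.5, velocity clamp 4.
#'
#' @param horizon_hours horizon L in hours (1-4)
#' @param n_particles,n_iterations swarm size and number of iterations
#' @param inertia,cognitive,social velocity-update coefficients
#' @param v_max velocity clamp
#' @param seed integer seed
#' @return A [ControlConfig-class].
#' @export
#' @examples
#' controlConfig(1)
controlConfig <- function(horizon_hours = 2, n_particles = 40,
                          n_iterations = 25, inertia = 0.7,
                          cognitive = 1.5, social = 1.5, v_max = 4,
                          seed = 1L) {
  new("ControlConfig", horizon_hours = horizon_hours,
      n_particles = n_particles, n_iterations = n_iterations,
      inertia = inertia, cognitive = cognitive, social = social,
      v_max = v_max, seed = as.numeric(seed))
}

setMethod("show", "ControlConfig", function(object) {
  cat(sprintf("ControlConfig: L=%g h (H=%d bits), %d particles x %d iterations = %d evaluations\n",
              object@horizon_hours, 12 * object@horizon_hours,
              object@n_particles, object@n_iterations,
              object@n_particles * object@n_iterations))
  cat(sprintf("  w=%.2f c1=%.2f c2=%.2f v_max=%.1f\n", object@inertia,
              object@cognitive, object@social, object@v_max))
})

#' Per-cell control objective trajectory
#'
#' @slot values target fluorescence (a.u.) per 5-min timepoint
#' @slot cell_id cell the objective is assigned to
#' @slot start_time control onset in hours (all-red equilibration before)
#' @export
setClass("ObjectiveTrack", representation(
  values = "numeric", cell_id = "character", start_time = "numeric"))

setValidity("ObjectiveTrack", function(object) {
  if (any(!is.finite(object@values)) || any(object@values < 0))
    return("objective values must be finite and >= 0")
  TRUE
})

setMethod("show", "ObjectiveTrack", function(object) {
  cat(sprintf("ObjectiveTrack: %d timepoints (%.1f h), range [%.0f, %.0f] a.u., onset %.1f h\n",
              length(object@values), length(object@values) / 12,
              min(object@values), max(object@values), object@start_time))
})

#' Parameters of the 2-state ODE baseline predictor
#'
#' Light-switched activation drives production of a fluorescent species:
#' da/dt = k_a u - k_d a; dp/dt = beta a - gamma p.
#'
#' @slot k_a activation gain (1/min)
#' @slot k_d deactivation rate (1/min)
#' @slot beta production gain (a.u./min)
#' @slot gamma effective loss rate (1/min)
#' @slot q_a,q_p process noise intensities
#' @slot r measurement noise variance (a.u.^2)
#' @export
setClass("OdeParams", representation(
  k_a = "numeric", k_d = "numeric", beta = "numeric", gamma = "numeric",
  q_a = "numeric", q_p = "numeric", r = "numeric"))

setValidity("OdeParams", function(object) {
  v <- c(object@k_a, object@k_d, object@beta, object@gamma,
         object@q_a, object@q_p, object@r)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all ODE/noise parameters must be finite and > 0")
  TRUE
})

#' Construct ODE baseline parameters
#' @param k_a,k_d,beta,gamma deterministic rates (see [OdeParams-class])
#' @param q_a,q_p process noise intensities
#' @param r measurement noise variance
#' @return An [OdeParams-class].
#' @export
odeParams <- function(k_a = 0.2, k_d = 0.1, beta = 63, gamma = 0.025,
                      q_a = 1e-3, q_p = 25, r = 1e4) {
  new("OdeParams", k_a = k_a, k_d = k_d, beta = beta, gamma = gamma,
      q_a = q_a, q_p = q_p, r = r)
}

setMethod("show", "OdeParams", function(object) {
  cat(sprintf("OdeParams: k_a=%.4g k_d=%.4g 1/min, beta=%.4g a.u./min, gamma=%.4g 1/min\n",
              object@k_a, object@k_d, object@beta, object@gamma))
  cat(sprintf("  noise: q_a=%.3g q_p=%.3g r=%.3g\n", object@q_a, object@q_p,
              object@r))
})

#' Gaussian belief state of the hybrid Kalman filter
#'
#' @slot m mean (a, p)
#' @slot P 2x2 symmetric positive semi-definite covariance
#' @export
setClass("KalmanBelief", representation(m = "numeric", P = "matrix"))

setValidity("KalmanBelief", function(object) {
  if (length(object@m) != 2L) return("mean must have length 2")
  if (!all(dim(object@P) == c(2L, 2L))) return("P must be 2x2")
  if (max(abs(object@P - t(object@P))) > 1e-8 * (1 + max(abs(object@P))))
    return("P must be symmetric")
  if (min(eigen(object@P, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8 * (1 + max(abs(object@P))))
    return("P must be positive semi-definite")
  TRUE
})

#' Construct a Kalman belief
#' @param m mean (a, p)
#' @param P 2x2 covariance
#' @return A [KalmanBelief-class].
#' @export
kalmanBelief <- function(m = c(0, 150), P = diag(c(0.25, 1e4))) {
  new("KalmanBelief", m = as.numeric(m), P = P)
}
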