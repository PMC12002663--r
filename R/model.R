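#' Build a coupled clock/cell-cycle model
#'
#' Assembles the kinetic parameterisation of one of three coupled circadian
#' clock / cell cycle gene-network variants and calibrates its two module
#' time scales so that, uncoupled and noise-free, the clock limit cycle has
#' the requested period (24 h by default) and the MPF limit cycle has the
#' requested autonomous cell cycle period.
#'
#' Model 1 carries the PER-CRY negative-feedback clock with a constitutive
#' (constant) BMAL1-CLOCK level and the single-MPF cell cycle; Model 2 adds
#' the REV-ERBa/BMAL1 secondary loop and with it the reverse-coupling route
#' (MPF repression of Rev-erba transcription, gain `C2`); Model 3 replaces
#' the single-MPF cell cycle by a four-cyclin cascade with the Cdk inhibitor
#' p21, itself repressed by REV-ERBa.  Forward coupling in every model is
#' BMAL1-CLOCK activation of Wee1 transcription with gain `C1`.
#'
#' @param model_id Integer 1, 2 or 3.
#' @param C1 Forward-coupling strength (dimensionless, >= 0).
#' @param C2 Reverse-coupling strength (dimensionless, >= 0; must be 0 for
#'   Model 1, which has no reverse route).
#' @param autonomous_TCC Target uncoupled cell cycle period in hours
#'   (10-36 h).
#' @param clock_period Target uncoupled circadian period in hours.
#' @param overrides Named numeric vector of kinetic-parameter overrides;
#'   names must be a subset of `cl_param_names`.
#' @param calibrate If `TRUE` (default), measure the two uncoupled periods
#'   and rescale the module time-scale factors to hit the targets to within
#'   0.5 h; a model that fails to oscillate raises a calibration error.
#' @return An object of class `clock_model`.
#' @examples
#' \donttest{
#' m <- build_model(2, C1 = 0.55, autonomous_TCC = 20)
#' m
#' }
#' @export
build_model <- function(model_id, C1 = 0, C2 = 0, autonomous_TCC = 20,
                        clock_period = 24, overrides = NULL,
                        calibrate = TRUE) {
  if (!model_id %in% 1:3) {
    stop("unknown model_id: ", model_id, " (must be 1, 2 or 3)")
  }
  if (C1 < 0 || C2 < 0) stop("coupling strengths must be >= 0")
  if (model_id == 1 && C2 != 0) {
    stop("Model 1 has no reverse-coupling route; C2 must be 0")
  }
  if (autonomous_TCC < 10 || autonomous_TCC > 36) {
    stop("autonomous_TCC must be within [10, 36] h")
  }
  params <- cl_default_params
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), cl_param_names)
    if (length(bad)) {
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    }
    params[names(overrides)] <- overrides
  }
  check_parameter_set(params)
  model <- structure(
    list(model_id = as.integer(model_id),
         species = cl_species_names(model_id),
         params = params,
         C1 = C1, C2 = C2,
         kl001_factor = 1,
         autonomous_TCC = autonomous_TCC,
         clock_period = clock_period,
         mpf_peak = NA_real_,
         init = cl_default_init(model_id)),
    class = "clock_model")
  if (calibrate) model <- calibrate_model(model) else model
}

check_parameter_set <- function(params) {
  if (any(params < 0)) {
    stop("all kinetic parameters must be nonnegative: ",
         paste(names(params)[params < 0], collapse = ", "))
  }
  hills <- params[grepl("^h", names(params))]
  if (any(hills < 1)) stop("Hill coefficients must be >= 1")
  km <- params[c("kmp", "kdp", "kdc", "k2g", "k4")]
  if (any(km <= 0)) stop("Michaelis constants must be > 0")
  invisible(params)
}

## full parameter vector in C++ order, with the live coupling strengths
model_param_vector <- function(model) {
  p <- model$params[cl_param_names]
  p["c1"] <- model$C1
  p["c2"] <- model$C2
  p
}

#' Evaluate the deterministic right-hand side of a model
#'
#' Returns dX/dt (conc/h) for a state vector under the model's mass-action /
#' Hill / Michaelis-Menten kinetics, optionally decomposed into the
#' nonnegative production and degradation fluxes used by the chemical
#' Langevin noise term.
#'
#' @param model A `clock_model`.
#' @param state Numeric vector, one nonnegative entry per model species.
#' @param decompose If `TRUE`, return `list(production, degradation)`
#'   instead of their difference.
#' @return A named numeric vector of derivatives, or a two-element list.
#' @export
rhs <- function(model, state, decompose = FALSE) {
  stopifnot(inherits(model, "clock_model"))
  if (length(state) != length(model$species)) {
    stop("state has length ", length(state), " but model ", model$model_id,
         " has ", length(model$species), " species")
  }
  if (any(!is.finite(state))) stop("state contains non-finite values")
  pd <- cl_rhs_cpp(model$model_id, unname(model_param_vector(model)),
                   as.numeric(state))
  names(pd$production) <- names(pd$degradation) <- model$species
  if (decompose) pd else pd$production - pd$degradation
}

#' Apply the KL001 perturbation to a model
#'
#' KL001 stabilises the CRY protein; because the networks carry PER-CRY as a
#' lumped complex, the drug is modelled by dividing the degradation rates of
#' the cytoplasmic and nuclear PER-CRY complex by a dose factor.  Factor 1
#' is the unperturbed control; increasing factors represent increasing
#' inhibitor concentration.
#'
#' @param model A `clock_model`.
#' @param factor Dose factor, >= 1.
#' @return A copy of the model with the PER-CRY degradation rates divided by
#'   `factor` and `kl001_factor` set; all other parameters are unchanged.
#' @export
apply_kl001 <- function(model, factor) {
  stopifnot(inherits(model, "clock_model"))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1) {
    stop("KL001 factor must be a single number >= 1")
  }
  out <- model
  out$params[cl_percry_degradation] <-
    out$params[cl_percry_degradation] / factor
  out$kl001_factor <- model$kl001_factor * factor
  out
}

#' Retune the autonomous cell cycle period
#'
#' Rescales the single global time-scale factor of the cell-cycle module so
#' that the uncoupled, noise-free MPF limit cycle has the requested period.
#' Clock parameters are untouched.  Because a uniform rescaling of all rate
#' constants of an autonomous module multiplies its period exactly by the
#' inverse factor, the calibration converges in one measurement step.
#'
#' @param model A `clock_model`.
#' @param target_TCC Target period in hours (10-36 h).
#' @return The recalibrated model.
#' @export
set_autonomous_period <- function(model, target_TCC) {
  stopifnot(inherits(model, "clock_model"))
  if (target_TCC < 10 || target_TCC > 36) {
    stop("target_TCC must be within [10, 36] h")
  }
  model$autonomous_TCC <- target_TCC
  calibrate_model(model, clock = FALSE)
}

## Deterministic uncoupled integration + peak-to-peak period measurement.
## Uses the model's own Euler integrator at a finer step than the default.
calibrate_model <- function(model, clock = TRUE, dt = 0.005) {
  uncoupled <- model
  uncoupled$C1 <- 0
  uncoupled$C2 <- 0
  measure <- function() {
    traj <- integrate_model(
      uncoupled, noise_spec("none"), init = uncoupled$init,
      config = integrator_config(dt = dt, t_max = 30 * model$clock_period,
                                 record_every = 10))
    clk <- peak_period(traj$times, traj$states[, "per_cry_n"])
    cc  <- peak_period(traj$times, traj$states[, "mpf"])
    list(clock = clk, cc = cc, traj = traj)
  }
  m <- measure()
  if (clock) {
    if (is.na(m$clock$period)) {
      stop("calibration failure: no clock limit cycle found for model ",
           model$model_id)
    }
    uncoupled$params["scl"] <-
      uncoupled$params["scl"] * m$clock$period / model$clock_period
  }
  if (is.na(m$cc$period)) {
    stop("calibration failure: no MPF limit cycle found for model ",
         model$model_id)
  }
  uncoupled$params["scc"] <-
    uncoupled$params["scc"] * m$cc$period / model$autonomous_TCC
  m2 <- measure()
  if (is.na(m2$clock$period) ||
      abs(m2$clock$period - model$clock_period) > 0.5) {
    stop("calibration failure: clock period ",
         formatC(m2$clock$period, digits = 3),
         " h not within 0.5 h of ", model$clock_period, " h")
  }
  if (is.na(m2$cc$period) ||
      abs(m2$cc$period - model$autonomous_TCC) > 0.5) {
    stop("calibration failure: MPF period ",
         formatC(m2$cc$period, digits = 3),
         " h not within 0.5 h of ", model$autonomous_TCC, " h")
  }
  model$params <- uncoupled$params
  half <- seq(floor(nrow(m2$traj$states) / 2), nrow(m2$traj$states))
  model$mpf_peak <- max(m2$traj$states[half, "mpf"])
  model$init <- m2$traj$states[nrow(m2$traj$states), ]
  model
}

## mean peak-to-peak interval over the last 60% of a trace; NA when the
## signal has no usable peaks (non-oscillatory)
peak_period <- function(times, x, discard = 0.4) {
  i0 <- max(1L, floor(length(x) * discard))
  x <- x[i0:length(x)]
  times <- times[i0:length(times)]
  rng <- range(x)
  if (diff(rng) < 1e-6) return(list(period = NA_real_, peaks = numeric()))
  pk <- which(diff(sign(diff(x))) == -2) + 1
  pk <- pk[x[pk] > rng[1] + 0.2 * diff(rng)]
  if (length(pk) < 3) return(list(period = NA_real_, peaks = times[pk]))
  list(period = mean(diff(times[pk])), peaks = times[pk])
}

#' @export
print.clock_model <- function(x, ...) {
  cat("<clock_model> Model", x$model_id, "\n")
  cat("  species:       ", length(x$species), "\n")
  cat("  C1 (forward):  ", x$C1, "\n")
  cat("  C2 (reverse):  ", x$C2, "\n")
  cat("  clock period:  ", x$clock_period, "h\n")
  cat("  autonomous TCC:", x$autonomous_TCC, "h\n")
  if (x$kl001_factor != 1) cat("  KL001 factor:  ", x$kl001_factor, "\n")
  invisible(x)
}

#' Write a model definition to a YAML config file
#'
#' Serialises model id, parameter overrides relative to the package
#' defaults, coupling strengths, KL001 factor and period targets.  The
#' round trip through [read_model_config()] is lossless.
#'
#' @param model A `clock_model`.
#' @param path File path.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  base <- cl_default_params
  kl <- model$kl001_factor
  p <- model$params
  p[cl_percry_degradation] <- p[cl_percry_degradation] * kl
  diff_idx <- which(abs(p - base[names(p)]) > 0)
  cfg <- list(
    model_id = model$model_id,
    C1 = model$C1, C2 = model$C2,
    kl001_factor = kl,
    autonomous_TCC = model$autonomous_TCC,
    clock_period = model$clock_period,
    overrides = as.list(p[diff_idx]))
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Read a model definition from a YAML config file
#'
#' @param path File written by [write_model_config()].
#' @param calibrate Recalibrate on load (default `FALSE`: the stored
#'   time-scale factors are already calibrated).
#' @return A `clock_model`.
#' @export
read_model_config <- function(path, calibrate = FALSE) {
  cfg <- yaml::read_yaml(path)
  ov <- unlist(cfg$overrides)
  model <- build_model(cfg$model_id, C1 = cfg$C1, C2 = cfg$C2,
                       autonomous_TCC = cfg$autonomous_TCC,
                       clock_period = cfg$clock_period,
                       overrides = ov, calibrate = calibrate)
  if (cfg$kl001_factor > 1) model <- apply_kl001(model, cfg$kl001_factor)
  model
}
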