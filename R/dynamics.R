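#' Spectral summary of an oscillatory signal
#'
#' Linear detrend, Hann taper and discrete Fourier transform; the dominant
#' frequency is the power argmax on (0, Nyquist].  The amplitude is
#' measured in the time domain as half the mean peak-to-trough excursion
#' over the final three discernible cycles, which remains meaningful for
#' damped, non-stationary signals.  A signal whose amplitude falls below
#' `amp_floor`, or with fewer than two usable peaks, is reported as
#' non-oscillatory with an undefined period.
#'
#' @param x A `trajectory`, or a numeric vector of samples.
#' @param species Species name (trajectory input).
#' @param times Sample times (numeric input; must be uniform).
#' @param discard Fraction of the record dropped as transient.
#' @param amp_floor Amplitude floor below which the signal is declared
#'   non-oscillatory.
#' @param max_period Optional upper bound (h) on the searched period band;
#'   components slower than this (e.g. residual drift in short windows) are
#'   excluded from the dominant-frequency search.
#' @return A `spectral_summary`: list with `frequency` (1/h), `period` (h),
#'   `amplitude`, `oscillatory`, `species`, `window` (h), `period_peaks`
#'   (mean final peak-to-peak interval).
#' @export
spectral_summary <- function(x, species = NULL, times = NULL, discard = 0.5,
                             amp_floor = 1e-3, max_period = NULL) {
  if (inherits(x, "trajectory")) {
    if (is.null(species)) stop("species must be given for a trajectory")
    values <- x$states[, species]
    times <- x$times
  } else {
    values <- as.numeric(x)
    if (is.null(times)) stop("times must be given for a numeric signal")
    if (is.null(species)) species <- "signal"
  }
  i0 <- max(1L, floor(length(values) * discard))
  v <- values[i0:length(values)]
  tt <- times[i0:length(times)]
  dt <- tt[2] - tt[1]
  n <- length(v)
  out <- list(frequency = NA_real_, period = NA_real_, amplitude = 0,
              oscillatory = FALSE, species = species,
              window = tt[n] - tt[1], period_peaks = NA_real_)
  class(out) <- "spectral_summary"
  if (diff(range(v)) < .Machine$double.eps^0.5) return(out)
  ## time-domain amplitude over the final 3 cycles; a light moving average
  ## suppresses sampling noise in short fraction series
  detr <- v - (lm.fit(cbind(1, tt), v)$fitted.values)
  if (n > 60) {
    k <- max(1L, min(round(n / 60), 11L))
    if (k > 1) detr <- stats::filter(detr, rep(1 / k, k), sides = 2) |>
        as.numeric()
    ok <- !is.na(detr)
    detr <- detr[ok]
    tt <- tt[ok]
    v <- v[ok]
    n <- length(detr)
  }
  pk <- which(diff(sign(diff(detr))) == -2) + 1
  tr <- which(diff(sign(diff(detr))) == 2) + 1
  rng <- diff(range(detr))
  pk <- pk[detr[pk] > 0.05 * rng / 2]
  tr <- tr[detr[tr] < -0.05 * rng / 2]
  if (length(pk) >= 2 && length(tr) >= 1) {
    lastpk <- tail(pk, 4)
    lasttr <- tr[tr > lastpk[1]]
    amp <- (mean(detr[tail(pk, 3)]) -
              mean(detr[tail(if (length(lasttr)) lasttr else tr, 3)])) / 2
    out$amplitude <- max(amp, 0)
    out$period_peaks <- mean(diff(tt[lastpk]))
  }
  if (out$amplitude < amp_floor || length(pk) < 2) return(out)
  ## dominant frequency from the tapered, zero-padded spectrum (padding
  ## interpolates between the raw frequency bins of short windows)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  npad <- 8 * 2^ceiling(log2(n))
  xw <- c(detr * w, rep(0, npad - n))
  pw <- Mod(fft(xw))^2
  freqs <- seq(0, npad - 1) / (npad * dt)
  f_lo <- 1 / (tt[n] - tt[1])
  if (!is.null(max_period)) f_lo <- max(f_lo, 1 / max_period)
  keep <- which(freqs > f_lo & freqs <= 1 / (2 * dt))
  fdom <- freqs[keep][which.max(pw[keep])]
  out$frequency <- fdom
  out$period <- 1 / fdom
  out$oscillatory <- TRUE
  out
}

#' @export
print.spectral_summary <- function(x, ...) {
  if (x$oscillatory) {
    cat("<spectral_summary>", x$species, ": period",
        signif(x$period, 4), "h, amplitude", signif(x$amplitude, 4), "\n")
  } else {
    cat("<spectral_summary>", x$species, ": non-oscillatory\n")
  }
  invisible(x)
}

#' @rdname spectral_summary
#' @param ... Unused.
#' @export
glance.spectral_summary <- function(x, ...) {
  tibble::tibble(species = x$species, frequency = x$frequency,
                 period = x$period, period_peaks = x$period_peaks,
                 amplitude = x$amplitude, oscillatory = x$oscillatory,
                 window = x$window)
}

#' Entrainment curve over a coupling-strength grid
#'
#' Deterministic frequency response of the coupled system: for each value
#' of the forward (C1) or reverse (C2) coupling strength, integrates the
#' model and reports the dominant frequency of MPF (forward sweep) or of
#' BMAL1-CLOCK (reverse sweep).  Non-oscillatory grid points are recorded
#' as such, not raised as errors.
#'
#' @param model A calibrated `clock_model` (its C1/C2 are overridden by the
#'   grid).
#' @param coupling `"forward"` or `"reverse"`.
#' @param grid Numeric vector of coupling strengths (should include 0).
#' @param config Integrator configuration; the default covers 60 clock
#'   periods so that a 1/20 vs 1/24 1/h shift spans several frequency bins.
#' @return A tibble with `coupling`, `value`, `species`, `frequency`,
#'   `period`, `amplitude`, `oscillatory`.
#' @export
entrainment_curve <- function(model, coupling = c("forward", "reverse"),
                              grid = seq(0, 1, by = 0.1),
                              config = integrator_config(t_max = 1440,
                                                         record_every = 10)) {
  coupling <- match.arg(coupling)
  species <- if (coupling == "forward") "mpf" else "bmal1_clock"
  rows <- lapply(grid, function(v) {
    m <- model
    if (coupling == "forward") m$C1 <- v else m$C2 <- v
    traj <- integrate_model(m, noise_spec("none"), config = config)
    ss <- spectral_summary(traj, species, discard = 0.6)
    tibble::tibble(coupling = coupling, value = v, species = species,
                   frequency = ss$frequency, period = ss$period,
                   period_peaks = ss$period_peaks,
                   amplitude = ss$amplitude, oscillatory = ss$oscillatory)
  })
  dplyr::bind_rows(rows)
}

#' KL001 dose-response of the clock oscillation
#'
#' Applies the KL001 transform over a factor grid and summarises period and
#' amplitude of a clock species from deterministic integrations.  The
#' signature behaviour is an abrupt period jump over a narrow factor range
#' with a continuous amplitude decay to (essentially) zero at the highest
#' factors.
#'
#' @param model A calibrated `clock_model`.
#' @param factors Increasing dose factors starting at 1 (control).
#' @param species Clock species to analyse; the default, the nuclear
#'   PER-CRY complex, is the direct target of the perturbation.
#' @param config Integrator configuration.
#' @return A tibble with `factor`, `period`, `period_peaks`, `amplitude`
#'   (absolute, detrended), `mean_level`, `modulation` (amplitude divided
#'   by the mean level, the reporter-style relative amplitude),
#'   `amplitude_rel` (modulation relative to control), `oscillatory`.
#' @export
kl001_dose_response <- function(model, factors = c(1, 2, 3, 5, 7, 10, 100,
                                                   1000),
                                species = "per_cry_n",
                                config = integrator_config(t_max = 1440,
                                                           record_every = 10)) {
  if (is.unsorted(factors, strictly = TRUE) || factors[1] != 1) {
    stop("factors must be strictly increasing and start at 1")
  }
  rows <- lapply(factors, function(f) {
    m <- apply_kl001(model, f)
    traj <- integrate_model(m, noise_spec("none"), config = config)
    ss <- spectral_summary(traj, species, discard = 0.6)
    lev <- mean(traj$states[seq(floor(nrow(traj$states) * 0.6),
                                nrow(traj$states)), species])
    tibble::tibble(factor = f, period = ss$period,
                   period_peaks = ss$period_peaks,
                   amplitude = ss$amplitude,
                   mean_level = lev,
                   modulation = if (lev > 0) ss$amplitude / lev else 0,
                   oscillatory = ss$oscillatory)
  })
  out <- dplyr::bind_rows(rows)
  ctrl <- out$modulation[1]
  out$amplitude_rel <- if (ctrl > 0) out$modulation / ctrl else NA_real_
  ## below the modulation floor the period is undefined
  floor_mask <- out$modulation < 0.01 * ctrl
  out$period[floor_mask] <- NA_real_
  out$period_peaks[floor_mask] <- NA_real_
  out$oscillatory[floor_mask] <- FALSE
  out
}

#' Fit an exponential growth rate to population counts
#'
#' Ordinary least squares of `log(count)` on time; the slope is the
#' proliferation rate lambda (1/h).
#'
#' @param counts A data frame with columns `time` and `count` (or `alive`).
#' @return A `growth_fit` with `lambda`, `intercept`, `r_squared`,
#'   `doubling_time`.
#' @export
fit_growth_rate <- function(counts) {
  counts <- as.data.frame(counts)
  if (!"count" %in% names(counts) && "alive" %in% names(counts)) {
    counts$count <- counts$alive
  }
  if (nrow(counts) < 3) stop("need at least 3 time points")
  if (any(counts$count <= 0)) stop("counts must be positive")
  if (length(unique(counts$time)) < 2) stop("degenerate time grid")
  fit <- lm(log(count) ~ time, data = counts)
  lambda <- unname(stats::coef(fit)[2])
  y <- log(counts$count)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(lambda = lambda,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 doubling_time = log(2) / lambda,
                 fit = fit, data = tibble::as_tibble(counts)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> lambda =", signif(x$lambda, 4), "1/h, doubling time",
      signif(x$doubling_time, 4), "h, R^2 =", signif(x$r_squared, 4), "\n")
  invisible(x)
}

#' @rdname fit_growth_rate
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "lambda"),
                 estimate = c(x$intercept, x$lambda),
                 std.error = summary(x$fit)$coefficients[, 2])
}

#' @rdname fit_growth_rate
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, intercept = x$intercept,
                 r_squared = x$r_squared, doubling_time = x$doubling_time,
                 n = nrow(x$data))
}

#' Ergodic age-structure prediction of a phase fraction
#'
#' In an exponentially growing population with per-capita rate `lambda`,
#' the fraction of cells whose age lies in `[a1, a2)` within a cycle of
#' deterministic length T is `2 (exp(-lambda a1) - exp(-lambda a2))`; the
#' factor 2 reflects the enrichment of young cells because each division
#' produces two daughters of age zero.  With `lambda = log(2) / T` the
#' fractions over a full partition of `[0, T]` sum to one.
#'
#' @param a1,a2 Age boundaries of the phase (h), `0 <= a1 < a2`.
#' @param lambda Population growth rate (1/h), > 0.
#' @return Predicted fraction.
#' @export
ergodic_prediction <- function(a1, a2, lambda) {
  if (any(a1 < 0) || any(a2 <= a1)) stop("need 0 <= a1 < a2")
  if (lambda <= 0) stop("lambda must be > 0")
  2 * (exp(-lambda * a1) - exp(-lambda * a2))
}

#' Ergodic predictions for a full phase partition
#'
#' @param durations Named numeric vector of phase durations (h), in cycle
#'   order.
#' @param lambda Growth rate (1/h).
#' @return A tibble with `phase`, `a1`, `a2`, `predicted`.
#' @export
ergodic_partition <- function(durations, lambda) {
  bounds <- c(0, cumsum(durations))
  tibble::tibble(phase = names(durations),
                 a1 = bounds[-length(bounds)],
                 a2 = bounds[-1],
                 predicted = ergodic_prediction(bounds[-length(bounds)],
                                                bounds[-1], lambda))
}

#' Phase-proportion time series with spectral and ergodic overlays
#'
#' Tracks the fraction of alive cells in each cell cycle phase over a time
#' grid, summarises the oscillation of the M-phase fraction, and overlays
#' the ergodic age-structure baseline computed from the run's mean phase
#' durations and fitted growth rate.
#'
#' @param run A `lineage_run` (phase-crossing events retained).
#' @param grid Time grid (h); defaults to 0.5 h spacing over the run.
#' @param min_alive Times with fewer alive cells are flagged low-count.
#' @return A `phase_proportions` object with `series`, `m_spectral`,
#'   `ergodic`, `growth`, `low_count_times`.
#' @export
phase_proportion_analysis <- function(run, grid = NULL, min_alive = 20) {
  stopifnot(inherits(run, "lineage_run"))
  if (is.null(grid)) grid <- seq(0, run$stop_time, by = 0.5)
  counts <- snapshot_phase_counts(run, grid)
  series <- counts |>
    dplyr::mutate(fraction = ifelse(.data$alive > 0,
                                    .data$count / .data$alive, NA_real_))
  low <- unique(series$time[series$alive < min_alive])
  mfrac <- series |> dplyr::filter(.data$phase == "M")
  ## the search band stops at twice the circadian period: slower components
  ## are unresolvable in the windows these runs afford
  m_spectral <- spectral_summary(mfrac$fraction, times = mfrac$time,
                                 discard = 0.25, amp_floor = 1e-4,
                                 max_period = 48)
  m_spectral$species <- "m_phase_fraction"
  growth <- fit_growth_rate(population_curve(run, grid))
  div <- run$cells[!run$cells$censored, ]
  durations <- c(
    G1 = mean(div$t_enter_s - div$birth_time, na.rm = TRUE),
    `S/G2` = mean(div$t_enter_m - div$t_enter_s, na.rm = TRUE),
    M = mean(div$division_time - div$t_enter_m, na.rm = TRUE))
  ## use the age-structure rate implied by the mean cycle length so the
  ## partition closes exactly
  ergodic <- ergodic_partition(durations, log(2) / sum(durations))
  structure(list(series = series, m_spectral = m_spectral,
                 ergodic = ergodic, growth = growth,
                 low_count_times = low),
            class = "phase_proportions")
}

#' @export
print.phase_proportions <- function(x, ...) {
  cat("<phase_proportions>", length(unique(x$series$time)), "time points;")
  if (x$m_spectral$oscillatory) {
    cat(" M-fraction period", signif(x$m_spectral$period, 4), "h\n")
  } else {
    cat(" M fraction non-oscillatory\n")
  }
  invisible(x)
}

#' @rdname phase_proportion_analysis
#' @param x A `phase_proportions`.
#' @param ... Unused.
#' @export
tidy.phase_proportions <- function(x, ...) x$series

#' Peak-phase offset between two oscillating fraction series
#'
#' Cross-correlation lag of the dominant (clock-period) component,
#' restricted to lags in `(-period/2, period/2]`.  Positive values mean the
#' second series peaks later.
#'
#' @param a,b Tibbles with `time` and `fraction` columns on the same grid
#'   (e.g. M-phase rows of two [phase_proportion_analysis()] series).
#' @param period Reference period (h).
#' @param discard Fraction of the record dropped as transient.
#' @return Offset in hours.
#' @export
peak_phase_offset <- function(a, b, period = 24, discard = 0.25) {
  stopifnot(nrow(a) == nrow(b))
  i0 <- max(1L, floor(nrow(a) * discard))
  xa <- a$fraction[i0:nrow(a)]
  xb <- b$fraction[i0:nrow(b)]
  dt <- a$time[2] - a$time[1]
  max_lag <- floor(period / 2 / dt)
  lags <- seq(-max_lag, max_lag)
  cc <- vapply(lags, function(k) {
    if (k >= 0) {
      cor(xa[seq_len(length(xa) - k)], xb[seq_len(length(xb) - k) + k])
    } else {
      cor(xa[seq_len(length(xa) + k) - k], xb[seq_len(length(xb) + k)])
    }
  }, numeric(1))
  lags[which.max(cc)] * dt
}
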