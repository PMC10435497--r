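#' Stimulation protocol
#'
#' Continuous-wave or pulsed-wave LIFU stimulation parameters.  For pulsed
#' waves the pulse duration T = duty_cycle / PRF is derived; a continuous
#' wave has duty cycle 1.
#'
#' @param waveform `"continuous"` or `"pulsed"`.
#' @param duration_ms total stimulation duration in ms.
#' @param prf_hz pulse repetition frequency in Hz (pulsed only).
#' @param duty_cycle on-fraction in (0, 1] (pulsed only).
#' @export
stimulus_protocol <- function(waveform = c("continuous", "pulsed"),
                              duration_ms = 100, prf_hz = NULL, duty_cycle = NULL) {
  waveform <- match.arg(waveform)
  if (duration_ms <= 0) stop("duration must be positive")
  if (waveform == "continuous") {
    duty_cycle <- 1; prf_hz <- NA_real_; T_ms <- NA_real_
  } else {
    if (is.null(prf_hz) || is.null(duty_cycle))
      stop("pulsed protocol needs prf_hz and duty_cycle")
    T_ms <- derive_pulse_duration(prf_hz, duty_cycle)
  }
  structure(list(waveform = waveform, duration_ms = duration_ms,
                 prf_hz = prf_hz, duty_cycle = duty_cycle, pulse_ms = T_ms),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  if (x$waveform == "continuous")
    cat(sprintf("<stimulus_protocol> continuous wave, %g ms\n", x$duration_ms))
  else
    cat(sprintf("<stimulus_protocol> pulsed, %g ms, PRF %g Hz, duty %.0f%% (T = %g ms)\n",
                x$duration_ms, x$prf_hz, 100 * x$duty_cycle, x$pulse_ms))
  invisible(x)
}

#' Pulse duration from PRF and duty cycle
#'
#' T = duty_cycle / PRF, returned in ms (e.g. PRF 1 kHz at 36% duty gives
#' T = 0.36 ms).
#'
#' @param prf_hz pulse repetition frequency in Hz (> 0).
#' @param duty_cycle on-fraction in (0, 1].
#' @export
derive_pulse_duration <- function(prf_hz, duty_cycle) {
  if (!is.numeric(prf_hz) || prf_hz <= 0) stop("prf must be positive")
  if (!is.numeric(duty_cycle) || duty_cycle <= 0 || duty_cycle > 1)
    stop("duty cycle must be in (0, 1]")
  duty_cycle / prf_hz * 1e3
}

# Excitation threshold emulation: a strength-duration (rheobase/chronaxie)
# curve calibrated so that a 100 ms continuous wave excites at ~0.05 W/cm^2,
# scaled for pulsed waves by duty cycle so that 36% duty at 100 ms gives
# ~0.45 W/cm^2 (both threshold values as simulated by intramembrane
# cavitation neuron models for regular-spiking neurons).
excitation_threshold <- function(protocol,
                                 rheobase = 0.05 / 1.2, chronaxie_ms = 20,
                                 duty_exponent = 2.15) {
  I_th <- rheobase * (1 + chronaxie_ms / protocol$duration_ms)
  if (protocol$waveform == "pulsed")
    I_th <- I_th * (1 / protocol$duty_cycle)^duty_exponent
  I_th
}

#' Neuronal response model (intensity -> spike count)
#'
#' A pluggable emulator of biophysical spiking responses to LIFU.  It is
#' parameterized by two intensity thresholds: I_h, the excitation threshold
#' the target must reach, and a conservative off-target threshold
#' I_l <= I_h.  By default the thresholds follow a strength-duration curve
#' (0.05 W/cm^2 at 100 ms for continuous waves) with a duty-cycle penalty
#' for pulsed waves (0.45 W/cm^2 at 36% duty), and I_l = ratio * I_h.
#'
#' `kind = "threshold"` maps intensity to 0/1 spiking; `kind = "spike_curve"`
#' adds a saturating logarithmic count growth for continuous waves and a
#' slower, optionally non-monotonic growth (configurable dip) for pulsed
#' waves.  Any user function `I -> count` can replace the built-in curve
#' via `curve_fun`.
#'
#' @param protocol a [stimulus_protocol()].
#' @param kind `"threshold"` or `"spike_curve"`.
#' @param ratio I_l / I_h in (0, 1], default 0.6.
#' @param I_h,I_l explicit threshold overrides in W/cm^2.
#' @param gain count growth rate of the curve per 100 ms (continuous).
#' @param pulsed_gain count growth rate for pulsed waves (slower).
#' @param dip_amplitude depth (in spikes) of the non-monotonic dip of the
#'   pulsed curve; 0 disables it.
#' @param curve_fun optional function(I) giving a continuous spike-count
#'   curve above threshold (overrides the built-ins).
#' @export
neuron_response_model <- function(protocol, kind = c("threshold", "spike_curve"),
                                  ratio = 0.6, I_h = NULL, I_l = NULL,
                                  gain = 8, pulsed_gain = 2, dip_amplitude = 1,
                                  curve_fun = NULL) {
  kind <- match.arg(kind)
  if (ratio <= 0 || ratio > 1) stop("ratio I_l/I_h must be in (0, 1]")
  if (is.null(I_h)) I_h <- excitation_threshold(protocol)
  if (is.null(I_l)) I_l <- ratio * I_h
  if (I_l > I_h) stop("I_l must not exceed I_h")
  structure(list(kind = kind, protocol = protocol, I_l = I_l, I_h = I_h,
                 ratio = I_l / I_h, gain = gain, pulsed_gain = pulsed_gain,
                 dip_amplitude = dip_amplitude, curve_fun = curve_fun),
            class = "neuron_response_model")
}

#' @export
print.neuron_response_model <- function(x, ...) {
  cat(sprintf("<neuron_response_model> %s, I_l = %.4g, I_h = %.4g W/cm^2 (%s)\n",
              x$kind, x$I_l, x$I_h, x$protocol$waveform))
  invisible(x)
}

#' Spike count elicited by a given intensity
#'
#' Zero below the model threshold; above it, integer counts (floored
#' continuous curve) that are non-decreasing in intensity and duration for
#' continuous waves, and grow more slowly -- with an optional dip -- for
#' pulsed waves of low duty cycle.
#'
#' @param I intensity (scalar or vector) in W/cm^2, >= 0.
#' @param protocol a [stimulus_protocol()] (defaults to the model's).
#' @param model a [neuron_response_model()].
#' @return non-negative integer spike counts.
#' @export
spike_count <- function(I, protocol = model$protocol, model) {
  if (any(I < 0)) stop("intensity must be non-negative")
  I_th <- model$I_h       # spiking onset: the excitation threshold
  out <- numeric(length(I))
  above <- I >= I_th & I_th > 0
  if (!any(above)) return(as.integer(out))
  dur_scale <- protocol$duration_ms / 100
  Ia <- I[above]
  cont <- if (!is.null(model$curve_fun)) {
    model$curve_fun(Ia)
  } else if (protocol$waveform == "continuous") {
    1 + model$gain * dur_scale * log1p(4 * (Ia / I_th - 1))
  } else {
    base <- 1 + model$pulsed_gain * dur_scale * protocol$duty_cycle * 3 *
      log1p(2 * (Ia / I_th - 1))
    dip <- model$dip_amplitude * exp(-((Ia / I_th - 2.5) / 0.5)^2)
    pmax(base - dip, 1)
  }
  cap <- protocol$duration_ms   # <= 1 kHz sustained firing
  out[above] <- pmin(floor(cont), cap)
  as.integer(out)
}

#' Spike-count map over the brain region
#'
#' Pointwise application of [spike_count()] over the brain mask; zero
#' elsewhere.
#'
#' @param I an [intensity_map()] (or nx x ny matrix, W/cm^2).
#' @param masks [region_masks()].
#' @param protocol,model protocol and response model.
#' @return integer matrix of class `spike_map`.
#' @export
spike_map <- function(I, masks, protocol = model$protocol, model) {
  if (!all(dim(I) == dim(masks$brain_mask))) stop("intensity and mask shapes differ")
  counts <- matrix(0L, nrow(I), ncol(I))
  sel <- masks$brain_mask
  counts[sel] <- spike_count(I[sel], protocol, model)
  structure(counts, class = c("spike_map", "matrix"), grid = masks$grid)
}
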