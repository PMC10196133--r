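#' Photoreceptoral (P3) model parameters
#'
#' Parameters of the delayed-Gaussian saturation model of the rod or cone
#' photoresponse leading edge:
#' \deqn{P3(i, t) = -R_{mP3} (1 - \exp[-i S (t - t_d)^2]), \quad t > t_d}
#' with \eqn{i} the flash energy in linear cd.s/m^2.
#'
#' @param rmp3 Saturated amplitude, microvolts (>= 0).
#' @param s Phototransduction sensitivity, (cd.s/m^2)^-1 s^-2 (> 0).
#' @param td Transduction delay, seconds (>= 0).
#' @return An object of class `"p3_params"`.
#' @export
p3_params <- function(rmp3, s, td) {
  check_scalar(rmp3, "rmp3", lower = 0)
  check_scalar(s, "s", lower = 0, strict_lower = TRUE)
  check_scalar(td, "td", lower = 0)
  structure(list(rmp3 = rmp3, s = s, td = td), class = "p3_params")
}

#' Bipolar-cell (P2) model parameters
#'
#' The P2 peak amplitude follows the Naka-Rushton intensity-response
#' relation \eqn{V(i) = V_{max} i^n / (i^n + K^n)}; the waveform itself is
#' a smooth gamma kernel whose peak carries that amplitude.
#'
#' @param vmax Saturated b-wave amplitude, microvolts (>= 0).
#' @param k Semi-saturation energy, linear cd.s/m^2 (> 0).
#' @param n Naka-Rushton exponent (> 0, default 1).
#' @param shape_tau Gamma-kernel time constant, seconds; the kernel peaks
#'   at `delay + 4 * shape_tau` after flash onset (default 0.0275 s).
#' @param delay Synaptic onset delay of the bipolar response, seconds
#'   (default 0); the kernel is zero before it.
#' @return An object of class `"p2_params"`.
#' @export
p2_params <- function(vmax, k, n = 1, shape_tau = 0.0275, delay = 0) {
  check_scalar(vmax, "vmax", lower = 0)
  check_scalar(k, "k", lower = 0, strict_lower = TRUE)
  check_scalar(n, "n", lower = 0, strict_lower = TRUE)
  check_scalar(shape_tau, "shape_tau", lower = 0, strict_lower = TRUE)
  check_scalar(delay, "delay", lower = 0)
  structure(list(vmax = vmax, k = k, n = n, shape_tau = shape_tau,
                 delay = delay),
            class = "p2_params")
}

#' Accessory signal parameters for the ERG generator
#'
#' @param op_amplitude Oscillatory-potential amplitude at saturation,
#'   microvolts; OPs are scaled with the Naka-Rushton fraction so dim
#'   flashes carry none.
#' @param op_band Frequency band of the OPs, Hz pair; the generator places
#'   a windowed oscillation at the band's geometric-mean frequency.
#' @param str_amplitude Scotopic threshold response peak, microvolts.
#' @param str_peak_time STR peak time after flash onset, seconds.
#' @param noise_sd White Gaussian noise SD, microvolts.
#' @param acquisition_band Amplifier band-pass corners, Hz pair with net
#'   -3 dB points, or `NULL` to disable.
#' @return An object of class `"accessory_params"`.
#' @export
accessory_params <- function(op_amplitude = 40, op_band = c(60, 235),
                             str_amplitude = 15, str_peak_time = 0.110,
                             noise_sd = 10,
                             acquisition_band = c(0.3, 1000)) {
  check_scalar(op_amplitude, "op_amplitude", lower = 0)
  check_scalar(str_amplitude, "str_amplitude", lower = 0)
  check_scalar(str_peak_time, "str_peak_time", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  stopifnot(length(op_band) == 2L, all(op_band > 0), op_band[1] < op_band[2])
  if (!is.null(acquisition_band)) {
    stopifnot(length(acquisition_band) == 2L,
              acquisition_band[1] < acquisition_band[2],
              all(acquisition_band > 0))
  }
  structure(list(op_amplitude = op_amplitude, op_band = op_band,
                 str_amplitude = str_amplitude,
                 str_peak_time = str_peak_time, noise_sd = noise_sd,
                 acquisition_band = acquisition_band),
            class = "accessory_params")
}

#' Evaluate the delayed-Gaussian P3 model
#'
#' @param t Time after flash onset, seconds (vectorized).
#' @param i Flash energy, linear cd.s/m^2.
#' @param rmp3,s,td Model parameters (see [p3_params()]).
#' @return P3 voltage in microvolts (non-positive).
#' @export
p3_model <- function(t, i, rmp3, s, td) {
  -rmp3 * (1 - exp(-i * s * pmax(t - td, 0)^2))
}

# Gamma kernel for the P2 waveform, normalized to unit peak at
# t = delay + 4*tau; zero before the synaptic delay.
p2_kernel <- function(t, tau, delay = 0) {
  s <- t - delay
  ifelse(s > 0, (s / (4 * tau))^4 * exp(4 - s / tau), 0)
}

naka_rushton <- function(i, vmax, k, n = 1) {
  vmax * i^n / (i^n + k^n)
}

# Windowed OP oscillation at the geometric-mean band frequency.
op_component <- function(t, amplitude, band, center = 0.040, width = 0.012) {
  f0 <- sqrt(band[1] * band[2])
  amplitude * sin(2 * pi * f0 * t) *
    exp(-(t - center)^2 / (2 * width^2)) * (t > 0)
}

# Positive STR bump (Gaussian in time).
str_component <- function(t, amplitude, peak_time, width = 0.030) {
  amplitude * exp(-(t - peak_time)^2 / (2 * width^2)) * (t > 0)
}

#' Generate the noiseless P3 component of an ERG
#'
#' @param p A [p3_params()].
#' @param stim A [flash_stimulus()].
#' @param tb A [timebase()].
#' @return An [erg_waveform()] holding the (non-positive) P3 component.
#' @export
#' @examples
#' w <- generate_p3(p3_params(450, 1.6, 0.004),
#'                  flash_stimulus(2.07), timebase())
#' min(w$samples)  # approaches -450 as the response saturates
generate_p3 <- function(p, stim, tb) {
  stopifnot(inherits(p, "p3_params"), inherits(stim, "flash_stimulus"),
            inherits(tb, "timebase"))
  t <- time_axis(tb)
  i <- 10^stim$log_energy
  erg_waveform(p3_model(t, i, p$rmp3, p$s, p$td), stim, tb)
}

#' Generate a full synthetic ERG trace for one flash
#'
#' Composes the P3 delayed-Gaussian, a gamma-kernel P2 scaled by the
#' Naka-Rushton amplitude, windowed oscillatory potentials, an optional
#' STR bump, the acquisition band-pass and white Gaussian noise.
#'
#' @param p3 A [p3_params()].
#' @param p2 A [p2_params()].
#' @param acc An [accessory_params()].
#' @param stim A [flash_stimulus()].
#' @param tb A [timebase()].
#' @param seed Integer seed (required; the generator never uses global
#'   RNG state implicitly).
#' @return An [erg_waveform()].
#' @export
generate_erg <- function(p3, p2, acc, stim, tb, seed) {
  stopifnot(inherits(p3, "p3_params"), inherits(p2, "p2_params"),
            inherits(acc, "accessory_params"), inherits(tb, "timebase"))
  fs <- tb$sampling_rate
  if (!is.null(acc$acquisition_band) && acc$acquisition_band[2] >= fs / 2) {
    stop("acquisition band upper corner must be below Nyquist")
  }
  if (acc$op_band[2] >= fs / 2) {
    stop("op_band upper edge must be below Nyquist")
  }
  t <- time_axis(tb)
  i <- 10^stim$log_energy
  v <- p3_model(t, i, p3$rmp3, p3$s, p3$td)
  amp_p2 <- naka_rushton(i, p2$vmax, p2$k, p2$n)
  v <- v + amp_p2 * p2_kernel(t, p2$shape_tau, p2$delay)
  op_scale <- if (p2$vmax > 0) amp_p2 / p2$vmax else 0
  v <- v + op_component(t, acc$op_amplitude * op_scale, acc$op_band)
  v <- v + str_component(t, acc$str_amplitude, acc$str_peak_time)
  if (!is.null(acc$acquisition_band)) {
    v <- bandpass_net(v, acc$acquisition_band, fs)
  }
  if (acc$noise_sd > 0) {
    v <- v + with_seed(seed, stats::rnorm(length(v), 0, acc$noise_sd))
  }
  erg_waveform(v, stim, tb)
}

#' Default dark-adapted flash protocol
#'
#' Ascending dark-adapted flash series spanning -5.01 to 2.07
#' log cd.s/m^2, including the pSTR pair (-5.01, -4.90) and the rod P3
#' pair (1.55, 2.07).
#'
#' @return List of [flash_stimulus()] objects.
#' @export
dark_protocol <- function() {
  en <- c(-5.01, -4.90, -4.02, -3.01, -2.01, -1.00, -0.02, 0.51, 1.02,
          1.55, 2.07)
  lapply(en, flash_stimulus, adaptation = "dark")
}

#' Default light-adapted flash protocol
#'
#' Ascending light-adapted (cone) series spanning 0.3 to 2.72
#' log cd.s/m^2, including the cone P3 pair (2.20, 2.72).
#'
#' @return List of [flash_stimulus()] objects.
#' @export
light_protocol <- function() {
  en <- c(0.30, 0.80, 1.30, 1.80, 2.20, 2.50, 2.72)
  lapply(en, flash_stimulus, adaptation = "light")
}

#' Generate a family of ERG waveforms for a flash protocol
#'
#' @param protocol Non-empty list of [flash_stimulus()] objects with
#'   unique energies per adaptation state.
#' @param p3,p2 Component parameters; either a single [p3_params()] /
#'   [p2_params()], or a list with elements `dark` and `light` when the
#'   protocol mixes adaptation states (rod vs cone pathways differ).
#' @param acc An [accessory_params()]. The STR bump is included only for
#'   flashes at or below `str_max_energy`.
#' @param tb A [timebase()].
#' @param seed Integer seed; each flash uses an independent child stream.
#' @param str_max_energy STR inclusion threshold, log cd.s/m^2
#'   (default -4.5, covering the -5.01 / -4.90 pair).
#' @return A [waveform_family()].
#' @export
generate_family <- function(protocol, p3, p2, acc = accessory_params(),
                            tb = timebase(), seed,
                            str_max_energy = -4.5) {
  if (length(protocol) == 0L) stop("protocol must be non-empty")
  stopifnot(all(vapply(protocol, inherits, TRUE, "flash_stimulus")))
  adap <- vapply(protocol, function(s) s$adaptation, "")
  en <- vapply(protocol, function(s) s$log_energy, 0)
  if (anyDuplicated(paste(adap, formatC(en, digits = 8)))) {
    stop("duplicate flash energies within an adaptation state")
  }
  pick <- function(par, a, cls) {
    if (inherits(par, cls)) return(par)
    if (is.list(par) && !is.null(par[[a]])) return(par[[a]])
    stop("parameters for ", a, "-adapted flashes not supplied")
  }
  waves <- vector("list", length(protocol))
  for (j in seq_along(protocol)) {
    stim <- protocol[[j]]
    acc_j <- acc
    if (stim$log_energy > str_max_energy) acc_j$str_amplitude <- 0
    waves[[j]] <- generate_erg(pick(p3, stim$adaptation, "p3_params"),
                               pick(p2, stim$adaptation, "p2_params"),
                               acc_j, stim, tb, child_seed(seed, j))
  }
  waveform_family(waves)
}

#' Typical rod and cone pathway parameters
#'
#' Convenience constructors with values typical of an adult wildtype
#' mouse: saturated rod P3 near 450 uV with sensitivity placing the
#' a-wave trough inside 15 ms at the brightest flashes; rod b-wave
#' saturating near 600 uV with semi-saturation around -1.5 log cd.s/m^2;
#' smaller, faster cone responses.
#'
#' @return [p3_params()] or [p2_params()] objects.
#' @export
default_rod_p3 <- function() p3_params(rmp3 = 450, s = 2500, td = 0.004)

#' @rdname default_rod_p3
#' @export
default_rod_p2 <- function() p2_params(vmax = 600, k = 0.03,
                                       shape_tau = 0.0275)

#' @rdname default_rod_p3
#' @export
default_cone_p3 <- function() p3_params(rmp3 = 35, s = 300, td = 0.003)

#' @rdname default_rod_p3
#' @export
default_cone_p2 <- function() p2_params(vmax = 250, k = 15,
                                        shape_tau = 0.0140, delay = 0.010)
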