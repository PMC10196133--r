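#' Fit the delayed-Gaussian P3 model to the a-wave leading edge
#'
#' A single (RmP3, S, td) triple is fit jointly (ensemble fit) to the
#' leading edges of the two brightest flashes by least squares. The fit
#' window for each flash runs from flash onset to the a-wave trough,
#' located on a 46.9 Hz low-pass-smoothed copy of the trace so noise does
#' not displace it; the leading edge is the only region the saturation
#' model describes.
#'
#' @param family A [waveform_family()].
#' @param energies Length-2 numeric: the two flash energies (log
#'   cd.s/m^2) whose a-waves are fit. Defaults to the rod pair
#'   `c(1.55, 2.07)`; use `c(2.20, 2.72)` for the cone pathway.
#' @param adaptation Adaptation state of the flashes (`"dark"` or
#'   `"light"`).
#' @param window Optional fixed fit window in seconds after onset,
#'   `c(lo, hi)`, overriding trough detection (applied to both flashes).
#' @param smooth_corner Corner (Hz) of the trough-finding smoother.
#' @return An object of class `"p3_fit"`: list with `params`
#'   ([p3_params()], RmP3 reported positive), `fit_window` (per-flash
#'   windows, seconds), `energies_used`, `residual_rms` (microvolts).
#' @export
fit_p3 <- function(family, energies = c(1.55, 2.07), adaptation = "dark",
                   window = NULL, smooth_corner = 46.9) {
  stopifnot(inherits(family, "waveform_family"), length(energies) == 2L)
  tb <- family$timebase
  fs <- tb$sampling_rate
  tt <- time_axis(tb)
  dat <- list()
  windows <- list()
  for (e in sort(energies)) {
    w <- family_get(family, e, adaptation)
    base <- mean(w$samples[tt < 0])
    v <- w$samples - base
    if (is.null(window)) {
      sm <- lowpass_net(v, smooth_corner, fs)
      post <- which(tt > 0)
      trough <- post[which.min(sm[post])]
      if (sm[trough] >= -1e-9) {
        stop("degenerate fit: no negative deflection after flash onset at ",
             e, " log cd.s/m^2")
      }
      win <- c(0, tt[trough])
    } else {
      win <- window
      if (min(v[tt > win[1] & tt <= win[2]]) >= -1e-9) {
        stop("degenerate fit: no negative deflection in window at ",
             e, " log cd.s/m^2")
      }
    }
    sel <- tt > win[1] & tt <= win[2]
    dat[[length(dat) + 1L]] <- data.frame(t = tt[sel], v = v[sel],
                                          i = 10^e)
    windows[[formatC(e, format = "g")]] <- win
  }
  df <- do.call(rbind, dat)
  rm0 <- max(-df$v)
  # coarse S grid picks the starting sensitivity; the model is highly
  # nonlinear in S so a single default start is unreliable
  s_grid <- 10^seq(-2, 6, by = 0.5)
  sse <- vapply(s_grid, function(s0) {
    sum((df$v - p3_model(df$t, df$i, rm0, s0, 0.003))^2)
  }, 0)
  s0 <- s_grid[which.min(sse)]
  fit <- minpack.lm::nlsLM(
    v ~ p3_model(t, i, rmp3, s, td), data = df,
    start = list(rmp3 = rm0, s = s0, td = 0.003),
    lower = c(0, 1e-9, 0),
    upper = c(Inf, Inf, max(df$t)),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  structure(list(params = p3_params(cf[["rmp3"]], cf[["s"]], cf[["td"]]),
                 fit_window = windows,
                 energies_used = sort(energies),
                 adaptation = adaptation,
                 residual_rms = sqrt(mean(stats::resid(fit)^2))),
            class = "p3_fit")
}

#' @export
print.p3_fit <- function(x, ...) {
  cat(sprintf(
    "P3 fit (%s, energies %s): RmP3 = %.1f uV, S = %.3g, td = %.2f ms (rms %.2f uV)\n",
    x$adaptation, paste(x$energies_used, collapse = ", "),
    x$params$rmp3, x$params$s, 1000 * x$params$td, x$residual_rms))
  invisible(x)
}

#' Subtract a fitted P3 model from every flash of a family
#'
#' Each flash's residual is the raw trace minus the P3 model evaluated at
#' that flash's energy, isolating the P2-OP complex.
#'
#' @param family A [waveform_family()].
#' @param fit A [fit_p3()] result (or a [p3_params()] object).
#' @return A [waveform_family()] of residual traces on the same timebase.
#' @export
subtract_p3 <- function(family, fit) {
  p <- if (inherits(fit, "p3_fit")) fit$params else fit
  stopifnot(inherits(p, "p3_params"), inherits(family, "waveform_family"))
  tt <- time_axis(family$timebase)
  waves <- lapply(family$waveforms, function(w) {
    i <- 10^w$stimulus$log_energy
    erg_waveform(w$samples - p3_model(tt, i, p$rmp3, p$s, p$td),
                 w$stimulus, w$timebase)
  })
  waveform_family(waves)
}

#' Extract the P2 (b-wave) from a P3-subtracted trace
#'
#' Applies a zero-phase low-pass with a net -3 dB corner (default
#' 46.9 Hz) to remove the oscillatory potentials, then measures the peak
#' as the maximum positive deflection after flash onset relative to the
#' pre-stimulus baseline.
#'
#' @param residual An [erg_waveform()] (typically from [subtract_p3()]).
#' @param corner Net -3 dB low-pass corner, Hz (default 46.9, must be
#'   below Nyquist).
#' @param order Butterworth order per pass (default 4).
#' @return List with `waveform` (the filtered [erg_waveform()]) and
#'   `peak` (microvolts, floored at 0).
#' @export
extract_p2 <- function(residual, corner = 46.9, order = 4L) {
  stopifnot(inherits(residual, "erg_waveform"))
  tb <- residual$timebase
  if (corner >= tb$sampling_rate / 2) {
    stop("low-pass corner must be below Nyquist (",
         tb$sampling_rate / 2, " Hz)")
  }
  filt <- lowpass_net(residual$samples, corner, tb$sampling_rate, order)
  tt <- time_axis(tb)
  base <- if (any(tt < 0)) mean(filt[tt < 0]) else 0
  peak <- max(0, max(filt[tt > 0] - base))
  list(waveform = erg_waveform(filt, residual$stimulus, tb), peak = peak)
}

#' Fit the Naka-Rushton intensity-response function
#'
#' Least-squares fit of \eqn{V(i) = V_{max} i^n / (i^n + K^n)} to P2 peak
#' amplitudes across flash energies, with the exponent fixed at 1
#' (saturated hyperbola) by default.
#'
#' @param amplitudes Named numeric vector of peak amplitudes (microvolts);
#'   names are flash energies in log cd.s/m^2.
#' @param fix_n If `TRUE` (default) the exponent is fixed at 1; otherwise
#'   it is a free parameter.
#' @return List of class `"naka_rushton_fit"` with `vmax`, `k`, `n`,
#'   `residual_rms`, `amplitudes` and a `degenerate` flag (all-zero
#'   input gives `vmax = 0`, `k = NA`).
#' @export
fit_naka_rushton <- function(amplitudes, fix_n = TRUE) {
  en <- as.numeric(names(amplitudes))
  if (length(amplitudes) < 3L || anyNA(en)) {
    stop("amplitudes must be a named vector (>= 3 points, names = log energies)")
  }
  v <- as.numeric(amplitudes)
  if (any(v < 0)) {
    warning("negative amplitudes clipped to 0")
    v <- pmax(v, 0)
  }
  i <- 10^en
  if (all(v == 0)) {
    return(structure(list(vmax = 0, k = NA_real_, n = if (fix_n) 1 else NA,
                          residual_rms = 0, amplitudes = amplitudes,
                          degenerate = TRUE),
                     class = "naka_rushton_fit"))
  }
  vmax0 <- max(v)
  k0 <- 10^stats::approx(v / vmax0, en, xout = 0.5, ties = mean,
                         rule = 2)$y
  df <- data.frame(i = i, v = v)
  if (fix_n) {
    fit <- minpack.lm::nlsLM(v ~ vmax * i / (i + k), data = df,
                             start = list(vmax = vmax0, k = k0),
                             lower = c(0, 1e-12),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- c(stats::coef(fit), n = 1)
  } else {
    fit <- minpack.lm::nlsLM(v ~ vmax * i^n / (i^n + k^n), data = df,
                             start = list(vmax = vmax0, k = k0, n = 1),
                             lower = c(0, 1e-12, 0.1), upper = c(Inf, Inf, 10),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- stats::coef(fit)
  }
  if (!any(i < cf[["k"]]) || !any(i > cf[["k"]])) {
    warning("flash energies do not span the fitted semi-saturation K; ",
            "K is weakly identified")
  }
  structure(list(vmax = cf[["vmax"]], k = cf[["k"]], n = cf[["n"]],
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 amplitudes = amplitudes, degenerate = FALSE),
            class = "naka_rushton_fit")
}

#' @export
print.naka_rushton_fit <- function(x, ...) {
  cat(sprintf("Naka-Rushton fit: Vmax = %.1f uV, K = %.3g cd.s/m^2, n = %.2f\n",
              x$vmax, x$k, x$n))
  invisible(x)
}

#' Measure the positive scotopic threshold response (pSTR)
#'
#' The pSTR amplitude is the arithmetic mean of the baseline-corrected
#' positive peaks at the two dimmest flashes, searched within a fixed
#' post-flash window.
#'
#' @param family A [waveform_family()].
#' @param energies The two dim flash energies, log cd.s/m^2 (default
#'   `c(-5.01, -4.90)`).
#' @param window Peak search window, seconds after onset (default
#'   `c(0.060, 0.200)`).
#' @return Object of class `"pstr_result"`: `amplitude` (microvolts, mean
#'   of the per-flash peaks), `per_flash` peaks, `energies_used`,
#'   `search_window`.
#' @export
measure_pstr <- function(family, energies = c(-5.01, -4.90),
                         window = c(0.060, 0.200)) {
  stopifnot(inherits(family, "waveform_family"), length(energies) == 2L)
  tt <- time_axis(family$timebase)
  sel <- tt >= window[1] & tt <= window[2]
  peaks <- vapply(sort(energies), function(e) {
    w <- family_get(family, e, "dark")
    base <- mean(w$samples[tt < 0])
    max(0, max(w$samples[sel] - base))
  }, 0)
  structure(list(amplitude = mean(peaks), per_flash = peaks,
                 energies_used = sort(energies), search_window = window),
            class = "pstr_result")
}

#' Decomposition configuration
#'
#' @param rod_p3_energies,cone_p3_energies The two brightest flashes used
#'   for the rod and cone P3 ensemble fits (log cd.s/m^2).
#' @param pstr_energies The two dim flashes averaged for the pSTR.
#' @param pstr_window pSTR peak search window, seconds after onset.
#' @param p2_corner Net -3 dB corner of the P2 low-pass, Hz.
#' @param fix_n Fix the Naka-Rushton exponent at 1.
#' @return A list of class `"decomp_config"`.
#' @export
decomp_config <- function(rod_p3_energies = c(1.55, 2.07),
                          cone_p3_energies = c(2.20, 2.72),
                          pstr_energies = c(-5.01, -4.90),
                          pstr_window = c(0.060, 0.200),
                          p2_corner = 46.9, fix_n = TRUE) {
  structure(list(rod_p3_energies = rod_p3_energies,
                 cone_p3_energies = cone_p3_energies,
                 pstr_energies = pstr_energies,
                 pstr_window = pstr_window,
                 p2_corner = p2_corner, fix_n = fix_n),
            class = "decomp_config")
}

has_energies <- function(family, energies, adaptation) {
  if (is.null(family)) return(FALSE)
  en <- family_energies(family)
  ad <- family_adaptations(family)
  all(vapply(energies, function(e)
    any(ad == adaptation & abs(en - e) < 1e-6), TRUE))
}

#' Decompose a waveform family into ERG endpoints
#'
#' Runs the full measurement chain: rod P3 ensemble fit on the two
#' brightest dark-adapted flashes, P3 subtraction, per-flash P2
#' extraction (46.9 Hz net low-pass) and Naka-Rushton fit across the
#' dark series; the same chain on the light-adapted subset for the cone
#' pathway; and the pSTR mean peak on the two dimmest flashes. Pathways
#' whose protocol energies are absent from the family are left `NULL`.
#'
#' @param family A [waveform_family()].
#' @param config A [decomp_config()].
#' @return Object of class `"decomposition_result"` with elements
#'   `rod_p3`, `cone_p3` ([fit_p3()] results), `rod_p2`, `cone_p2`
#'   ([fit_naka_rushton()] results with per-energy amplitudes), `pstr`
#'   ([measure_pstr()] result), and `config`.
#' @export
decompose <- function(family, config = decomp_config()) {
  stopifnot(inherits(family, "waveform_family"))
  res <- list(rod_p3 = NULL, rod_p2 = NULL, cone_p3 = NULL,
              cone_p2 = NULL, pstr = NULL, config = config)
  run_pathway <- function(sub, p3_energies, adaptation) {
    p3f <- tryCatch(
      fit_p3(sub, p3_energies, adaptation, smooth_corner = config$p2_corner),
      error = function(e) stop("P3 fit (", adaptation, "): ",
                               conditionMessage(e), call. = FALSE))
    resid_fam <- subtract_p3(sub, p3f)
    amps <- vapply(resid_fam$waveforms, function(w)
      extract_p2(w, config$p2_corner)$peak, 0)
    names(amps) <- formatC(family_energies(resid_fam), format = "g")
    nr <- tryCatch(fit_naka_rushton(amps, fix_n = config$fix_n),
                   error = function(e) stop("Naka-Rushton (", adaptation,
                                            "): ", conditionMessage(e),
                                            call. = FALSE))
    list(p3 = p3f, p2 = nr)
  }
  dark <- family_subset(family, "dark")
  if (has_energies(dark, config$rod_p3_energies, "dark")) {
    rod <- run_pathway(dark, config$rod_p3_energies, "dark")
    res$rod_p3 <- rod$p3
    res$rod_p2 <- rod$p2
  }
  light <- family_subset(family, "light")
  if (has_energies(light, config$cone_p3_energies, "light")) {
    cone <- run_pathway(light, config$cone_p3_energies, "light")
    res$cone_p3 <- cone$p3
    res$cone_p2 <- cone$p2
  }
  if (has_energies(dark, config$pstr_energies, "dark")) {
    res$pstr <- measure_pstr(dark, config$pstr_energies,
                             config$pstr_window)
  }
  structure(res, class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat("ERG decomposition result\n")
  for (nm in c("rod_p3", "cone_p3")) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("  %s: RmP3 = %.1f uV\n", nm, x[[nm]]$params$rmp3))
    }
  }
  for (nm in c("rod_p2", "cone_p2")) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("  %s: Vmax = %.1f uV, K = %.3g cd.s/m^2\n",
                  nm, x[[nm]]$vmax, x[[nm]]$k))
    }
  }
  if (!is.null(x$pstr)) {
    cat(sprintf("  pstr: %.1f uV\n", x$pstr$amplitude))
  }
  invisible(x)
}
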