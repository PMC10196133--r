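test_that("P3 fit recovers generator truth on a noiseless family", {
  fam <- p3_only_family(rmp3 = 450, s = 1.6, td = 0.004)
  fit <- fit_p3(fam, energies = c(1.55, 2.07))
  expect_lt(abs(fit$params$rmp3 - 450) / 450, 0.01)
  expect_lt(abs(fit$params$s - 1.6) / 1.6, 0.01)
  expect_lt(abs(fit$params$td - 0.004) / 0.004, 0.01)
  expect_lt(fit$residual_rms, 1)
  # cross-check that the optimizer found the global optimum: no point of
  # a coarse parameter grid beats the fitted SSE
  tt <- time_axis(fam$timebase)
  sse_of <- function(rmp3, s, td) {
    sum(vapply(c(1.55, 2.07), function(e) {
      w <- family_get(fam, e)
      sel <- tt > 0
      sum((w$samples[sel] - p3_model(tt[sel], 10^e, rmp3, s, td))^2)
    }, 0))
  }
  fitted_sse <- sse_of(fit$params$rmp3, fit$params$s, fit$params$td)
  grid <- expand.grid(rmp3 = seq(300, 600, by = 50),
                      s = 10^seq(-1, 1, by = 0.25),
                      td = c(0, 0.002, 0.004, 0.008))
  grid_sse <- min(mapply(sse_of, grid$rmp3, grid$s, grid$td))
  expect_lte(fitted_sse, grid_sse + 1e-6)
})

test_that("P3 fit rejects traces without a negative deflection", {
  tb <- timebase()
  zero <- lapply(c(1.55, 2.07), function(e) {
    erg_waveform(rep(0, tb$n_samples), flash_stimulus(e), tb)
  })
  expect_error(fit_p3(waveform_family(zero)), "degenerate")
})

test_that("P3 subtraction cancels the modelled component", {
  fam <- p3_only_family(rmp3 = 450, s = 1.6, td = 0.004)
  fit <- fit_p3(fam)
  resid <- subtract_p3(fam, fit)
  for (w in resid$waveforms) {
    expect_lt(max(abs(w$samples)), 1e-6 * 450)
  }
  # P3 + known P2 kernel: residual equals the P2 component
  tb <- timebase()
  t <- time_axis(tb)
  p3 <- default_rod_p3()
  p2_true <- 500 * retinerg:::p2_kernel(t, 0.0275)
  comb <- lapply(c(1.55, 2.07), function(e) {
    erg_waveform(p3_model(t, 10^e, p3$rmp3, p3$s, p3$td) + p2_true,
                 flash_stimulus(e), tb)
  })
  resid2 <- subtract_p3(waveform_family(comb), p3)
  for (w in resid2$waveforms) {
    expect_equal(w$samples, p2_true, tolerance = 1e-12)
  }
  # subtracting a zero-amplitude model changes nothing
  same <- subtract_p3(fam, p3_params(0, 1, 0))
  expect_equal(same$waveforms[[1]]$samples, fam$waveforms[[1]]$samples)
})

test_that("P2 extraction applies the -3 dB corner and measures the peak", {
  tb <- timebase()
  t <- time_axis(tb)
  # pure corner-frequency sinusoid comes out at 10^(-3/20) ~ 0.708
  sine <- erg_waveform(sin(2 * pi * 46.9 * (t - t[1])),
                       flash_stimulus(1), tb)
  out <- extract_p2(sine)
  mid <- which(t > 0.1 & t < 0.4)
  ratio <- max(abs(out$waveform$samples[mid]))
  expect_lt(abs(ratio - 10^(-3 / 20)), 0.01)
  # DC trace passes unchanged (gain 1)
  flat <- erg_waveform(rep(12, tb$n_samples), flash_stimulus(1), tb)
  expect_equal(extract_p2(flat)$waveform$samples,
               rep(12, tb$n_samples), tolerance = 1e-9)
  expect_equal(extract_p2(flat)$peak, 0)  # no deflection above baseline
  expect_error(extract_p2(sine, corner = 2000), "Nyquist")
})

test_that("Naka-Rushton fit recovers exact hyperbola samples", {
  en <- vapply(dark_protocol(), function(s) s$log_energy, 0)
  i <- 10^en
  v <- 600 * i / (i + 0.05)
  names(v) <- en
  fit <- fit_naka_rushton(v)
  expect_lt(abs(fit$vmax - 600) / 600, 0.01)
  expect_lt(abs(fit$k - 0.05) / 0.05, 0.01)
  # at i = K the fitted curve is Vmax / 2; at i -> Inf it is Vmax
  expect_equal(fit$vmax * fit$k / (fit$k + fit$k), fit$vmax / 2)
  # degenerate and clipping contracts
  z <- stats::setNames(rep(0, 5), seq(-3, 1))
  fz <- fit_naka_rushton(z)
  expect_true(fz$degenerate)
  expect_equal(fz$vmax, 0)
  expect_true(is.na(fz$k))
  neg <- stats::setNames(c(-5, 10, 100, 300, 500), seq(-3, 1))
  expect_warning(fit_naka_rushton(neg), "clipped")
})

test_that("Naka-Rushton amplitude sequence is monotone for clean data", {
  en <- seq(-4, 2, by = 0.5)
  v <- stats::setNames(400 * 10^en / (10^en + 0.02), en)
  fit <- fit_naka_rushton(v)
  pred <- fit$vmax * 10^en / (10^en + fit$k)
  expect_true(all(diff(pred) >= 0))
})

test_that("pSTR amplitude is the mean of baseline-corrected peaks", {
  tb <- timebase()
  t <- time_axis(tb)
  bump <- function(a) a * exp(-(t - 0.110)^2 / (2 * 0.03^2)) * (t > 0)
  fam <- waveform_family(list(
    erg_waveform(bump(15) + 3, flash_stimulus(-5.01), tb),  # +3 baseline
    erg_waveform(bump(12) + 3, flash_stimulus(-4.90), tb)))
  res <- measure_pstr(fam)
  expect_equal(res$amplitude, 13.5, tolerance = 1e-3)
  expect_equal(unname(res$per_flash), c(15, 12), tolerance = 1e-3)
  # identical traces at both energies -> amplitude equals single peak
  fam2 <- waveform_family(list(
    erg_waveform(bump(15), flash_stimulus(-5.01), tb),
    erg_waveform(bump(15), flash_stimulus(-4.90), tb)))
  expect_equal(measure_pstr(fam2)$amplitude, 15, tolerance = 1e-3)
  expect_error(measure_pstr(waveform_family(fam2$waveforms[1])), "no dark")
})

test_that("full decomposition recovers all planted endpoints", {
  fam <- full_synthetic_family(seed = 11)
  d <- decompose(fam)
  expect_lt(abs(d$rod_p3$params$rmp3 - 450) / 450, 0.01)
  expect_lt(abs(d$rod_p3$params$s - 2500) / 2500, 0.05)
  expect_lt(abs(d$rod_p3$params$td - 0.004) / 0.004, 0.05)
  expect_lt(abs(d$rod_p2$vmax - 600) / 600, 0.01)
  expect_lt(abs(d$rod_p2$k - 0.03) / 0.03, 0.05)
  expect_lt(abs(d$cone_p3$params$rmp3 - 35) / 35, 0.02)
  expect_lt(abs(d$cone_p2$vmax - 250) / 250, 0.01)
  expect_lt(abs(d$cone_p2$k - 15) / 15, 0.05)
  expect_lt(abs(d$pstr$amplitude - 15) / 15, 0.01)
})

test_that("pathways are populated only when their energies exist", {
  dark_only <- full_synthetic_family(seed = 2,
                                     protocol = dark_protocol())
  d <- decompose(dark_only)
  expect_null(d$cone_p3)
  expect_null(d$cone_p2)
  expect_false(is.null(d$rod_p3))
  expect_false(is.null(d$pstr))
  # decomposition is deterministic: identical reruns agree exactly
  d2 <- decompose(dark_only)
  expect_identical(d$rod_p3$params, d2$rod_p3$params)
  expect_identical(d$rod_p2$vmax, d2$rod_p2$vmax)
})

test_that("decomposing the residual of a pure-P3 family yields Vmax ~ 0", {
  fam <- p3_only_family(rmp3 = 450, s = 2500, td = 0.004,
                        energies = c(1.55, 2.07))
  fit <- fit_p3(fam)
  resid <- subtract_p3(fam, fit)
  amps <- vapply(resid$waveforms, function(w) extract_p2(w)$peak, 0)
  expect_lt(max(amps), 1e-3 * 450)
})

test_that("recovery degrades gracefully under recording noise", {
  errs <- vapply(1:10, function(k) {
    fam <- full_synthetic_family(seed = 100 + k, noise_sd = 20,
                                 protocol = dark_protocol())
    d <- decompose(fam)
    c(abs(d$rod_p3$params$rmp3 - 450) / 450,
      abs(d$rod_p2$vmax - 600) / 600)
  }, c(0, 0))
  expect_lt(stats::median(errs[1, ]), 0.10)
  expect_lt(stats::median(errs[2, ]), 0.10)
})
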