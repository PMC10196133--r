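# Shared builders for synthetic fixtures; everything is generated in
# code at test time.

quiet_acc <- function(noise_sd = 0, op = 0, str = 0, band = NULL) {
  accessory_params(op_amplitude = op, str_amplitude = str,
                   noise_sd = noise_sd, acquisition_band = band)
}

# Noiseless family containing only the P3 component at two energies.
p3_only_family <- function(rmp3 = 450, s = 1.6, td = 0.004,
                           energies = c(1.55, 2.07), tb = timebase()) {
  generate_family(lapply(energies, flash_stimulus),
                  p3 = p3_params(rmp3, s, td), p2 = p2_params(0, 1),
                  acc = quiet_acc(), tb = tb, seed = 1)
}

# Full dark + light family with the typical-animal defaults: OPs and the
# STR bump active, no acquisition filter.
full_synthetic_family <- function(seed = 1, noise_sd = 0,
                                  tb = timebase(),
                                  protocol = c(dark_protocol(),
                                               light_protocol())) {
  generate_family(protocol,
                  p3 = list(dark = default_rod_p3(),
                            light = default_cone_p3()),
                  p2 = list(dark = default_rod_p2(),
                            light = default_cone_p2()),
                  acc = accessory_params(noise_sd = noise_sd,
                                         acquisition_band = NULL),
                  tb = tb, seed = seed)
}

# Brute-force mid-rank by counting, independent of base rank().
midrank_bruteforce <- function(v) {
  vapply(seq_along(v), function(i) {
    1 + sum(v < v[i]) + (sum(v == v[i]) - 1) / 2
  }, 0)
}

pearson_of <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Direct textbook sums-of-squares for a balanced two-way layout.
balanced_anova_oracle <- function(v, g, a) {
  g <- factor(g); a <- factor(a)
  r <- length(v) / (nlevels(g) * nlevels(a))
  grand <- mean(v)
  mg <- tapply(v, g, mean)
  ma <- tapply(v, a, mean)
  mga <- tapply(v, list(g, a), mean)
  ss_g <- r * nlevels(a) * sum((mg - grand)^2)
  ss_a <- r * nlevels(g) * sum((ma - grand)^2)
  ss_cells <- r * sum((mga - grand)^2)
  ss_int <- ss_cells - ss_g - ss_a
  ss_res <- sum((v - mga[cbind(g, a)])^2)
  df <- c(nlevels(g) - 1, nlevels(a) - 1,
          (nlevels(g) - 1) * (nlevels(a) - 1),
          length(v) - nlevels(g) * nlevels(a))
  ss <- c(ss_g, ss_a, ss_int, ss_res)
  ms <- ss / df
  f <- c(ms[1:3] / ms[4], NA)
  p <- c(stats::pf(f[1:3], df[1:3], df[4], lower.tail = FALSE), NA)
  data.frame(factor = c("genotype", "age", "interaction", "residual"),
             ss = ss, df = df, F = f, p = p)
}
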