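test_that("ROUT flags a gross outlier and matches an FDR reference", {
  x <- c(retinerg:::with_seed(42, rnorm(20)), 10)
  sc <- rout_outliers(x, q = 1)
  expect_identical(sc$flagged, 21L)
  # independent reference: same robust center/RSDR definitions, but the
  # FDR step carried out by stats::p.adjust (Benjamini-Hochberg)
  n <- length(x)
  r <- x - median(x)
  rsdr <- quantile(abs(r), 0.6827, names = FALSE) * n / (n - 1)
  p <- 2 * pt(-abs(r) / rsdr, df = n - 1)
  ref_flag <- which(p.adjust(p, "BH") <= 0.01)
  expect_identical(sc$flagged, ref_flag)
  expect_equal(sc$robust_center, median(x))
  expect_equal(sc$rsdr, rsdr)
})

test_that("ROUT is quiet on degenerate and clean data", {
  expect_length(rout_outliers(rep(3.2, 10))$flagged, 0)
  expect_error(rout_outliers(c(1, 2)), "at least 3")
  expect_error(rout_outliers(rnorm(10), q = 0), "in \\(0, 100\\)")
  # family-wise flag rate on clean Gaussian data stays near Q
  hits <- vapply(1:200, function(k) {
    length(rout_outliers(retinerg:::with_seed(k, rnorm(20)), 1)$flagged) > 0
  }, TRUE)
  expect_lte(mean(hits), 0.05)
})

test_that("balanced two-way ANOVA matches the direct SS decomposition", {
  set.seed(5)
  g <- rep(c("WT", "HOM"), each = 12)
  a <- rep(rep(c(4, 6, 14), each = 4), 2)
  v <- rnorm(24, mean = 3 * (g == "HOM") + 0.5 * a)
  got <- two_way_anova(v, g, a)
  ref <- balanced_anova_oracle(v, g, a)
  expect_equal(got$ss, ref$ss, tolerance = 1e-10)
  expect_equal(got$df, ref$df)
  expect_equal(got$F[1:3], ref$F[1:3], tolerance = 1e-10)
  expect_equal(got$p[1:3], ref$p[1:3], tolerance = 1e-10)
  expect_equal(sum(got$df), length(v) - 1)
  # partition: SS sum to the total SS on balanced data
  expect_equal(sum(got$ss), sum((v - mean(v))^2), tolerance = 1e-9)
})

test_that("ANOVA isolates a pure genotype shift exactly", {
  g <- rep(c("WT", "HOM"), each = 9)
  a <- rep(rep(c(4, 6, 14), each = 3), 2)
  v <- c(-1, 0, 1)[rep(1:3, 6)] + 10 * (g == "HOM")
  got <- two_way_anova(v, g, a)
  expect_equal(got$F[got$factor == "age"], 0)
  expect_equal(got$F[got$factor == "interaction"], 0)
  expect_gt(got$F[got$factor == "genotype"], 100)
})

test_that("ANOVA degenerate and design-error contracts hold", {
  g <- rep(c("WT", "HOM"), each = 4)
  a <- rep(rep(c(4, 6), each = 2), 2)
  # zero residual variance with unequal cell means: F = Inf, p = 0
  v <- c(1, 1, 2, 2, 5, 5, 9, 9)
  got <- two_way_anova(v, g, a)
  expect_true(attr(got, "degenerate"))
  expect_equal(got$p[got$factor == "genotype"], 0)
  expect_true(is.infinite(got$F[got$factor == "genotype"]))
  # empty cell names the offending cell
  expect_error(two_way_anova(v[1:6], g[1:6], a[1:6]), "empty design cell")
  expect_error(two_way_anova(v, rep("WT", 8), a), "2 levels")
})

test_that("unbalanced designs are accepted and type-III SS reported", {
  set.seed(9)
  g <- c(rep("WT", 16), rep("HOM", 9))
  a <- c(rep(4, 9), rep(6, 7), rep(4, 4), rep(6, 5))
  v <- rnorm(25, 5 * (g == "HOM"))
  got <- two_way_anova(v, g, a)
  expect_equal(sum(got$df), 24)
  expect_true(all(got$ss >= 0))
  expect_lt(got$p[got$factor == "genotype"], 0.01)
})

test_that("Sidak adjustment follows its closed form and monotonicity", {
  expect_equal(sidak_adjust(0.2, 1), 0.2)
  expect_equal(sidak_adjust(0.01, 5), 1 - 0.99^5)
  expect_equal(sidak_adjust(0.01, 5), 0.0490099501, tolerance = 1e-9)
  # per-comparison threshold at family alpha 0.05, m = 3
  expect_equal(1 - 0.95^(1 / 3), 0.016952, tolerance = 1e-4)
  expect_equal(sidak_adjust(1 - 0.95^(1 / 3), 3), 0.05, tolerance = 1e-12)
  p <- seq(0, 1, by = 0.05)
  adj <- sidak_adjust(p, 4)
  expect_true(all(diff(adj) >= 0))       # monotone in p
  expect_true(all(adj >= p))             # never smaller than raw
  adj_m <- vapply(1:10, function(m) sidak_adjust(0.2, m), 0)
  expect_true(all(diff(adj_m) >= 0))     # monotone in m
  expect_error(sidak_adjust(0.5, 0), ">= 1")
  expect_error(sidak_adjust(1.4, 2), "\\[0, 1\\]")
})

test_that("per-age genotype comparisons use the pooled residual MS", {
  set.seed(3)
  g <- rep(c("WT", "HOM"), each = 15)
  a <- rep(rep(c(4, 6, 14), each = 5), 2)
  v <- rnorm(30) + 4 * (g == "HOM" & a == 14)
  cmp <- sidak_comparisons(v, g, a)
  expect_equal(nrow(cmp), 3)
  expect_equal(attr(cmp, "m"), 3L)
  expect_true(all(cmp$p_adj >= cmp$p_raw))
  expect_lt(cmp$p_adj[cmp$age == "14"], 0.01)
  expect_gt(min(cmp$p_adj[cmp$age != "14"]), 0.05)
  expect_equal(cmp$p_adj, sidak_adjust(cmp$p_raw, 3))
})

test_that("Deming regression recovers exact lines and the TLS oracle", {
  x <- c(0, 1, 2, 3, 4.5)
  y <- 2 * x + 1
  for (lam in c(0.25, 1, 4)) {
    f <- deming_fit(x, y, lambda = lam)
    expect_equal(f$slope, 2, tolerance = 1e-12)
    expect_equal(f$intercept, 1, tolerance = 1e-12)
  }
  # lambda = 1: slope equals the principal-axis (orthogonal) slope
  set.seed(8)
  xx <- rnorm(40)
  yy <- 1.7 * xx + rnorm(40, sd = 0.6)
  f1 <- deming_fit(xx, yy, lambda = 1)
  ev <- eigen(stats::cov(cbind(xx, yy)))$vectors[, 1]
  expect_equal(f1$slope, ev[2] / ev[1], tolerance = 1e-10)
  # swapping the axes inverts the slope
  f2 <- deming_fit(yy, xx, lambda = 1)
  expect_equal(f2$slope, 1 / f1$slope, tolerance = 1e-10)
  expect_error(deming_fit(rep(1, 5), rep(2, 5)), "zero variance")
  expect_error(deming_fit(x[1:2], y[1:2]), "at least 3")
})

test_that("Spearman equals the brute-force mid-rank Pearson with ties", {
  for (n in 3:8) {
    for (rep_k in 1:8) {
      xy <- retinerg:::with_seed(1000 * n + rep_k, {
        list(x = sample(1:4, n, replace = TRUE) + 0,
             y = sample(1:4, n, replace = TRUE) + 0)
      })
      if (length(unique(xy$x)) < 2 || length(unique(xy$y)) < 2) next
      got <- spearman_rank(xy$x, xy$y)
      ref <- pearson_of(midrank_bruteforce(xy$x), midrank_bruteforce(xy$y))
      expect_equal(got$rs, ref, tolerance = 1e-12)
      # and agrees with the standard library implementation
      expect_equal(got$rs, cor(xy$x, xy$y, method = "spearman"),
                   tolerance = 1e-12)
    }
  }
})

test_that("Spearman endpoints and p-values behave", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(spearman_rank(x, x^3)$rs, 1)
  expect_equal(spearman_rank(x, -x)$rs, -1)
  expect_equal(spearman_rank(x, x^3)$p, 0)
  expect_error(spearman_rank(rep(1, 5), x), "constant")
  # asymptotic p matches the t transform
  set.seed(2)
  a <- rnorm(30); b <- a + rnorm(30)
  got <- spearman_rank(a, b)
  tval <- got$rs * sqrt((30 - 2) / (1 - got$rs^2))
  expect_equal(got$p, 2 * pt(-abs(tval), 28))
  # permutation p is seeded and reproducible, and broadly agrees
  p1 <- spearman_rank(a, b, method = "permutation", n_perm = 2000,
                      seed = 5)$p
  p2 <- spearman_rank(a, b, method = "permutation", n_perm = 2000,
                      seed = 5)$p
  expect_identical(p1, p2)
  expect_error(spearman_rank(a, b, method = "permutation"), "seed")
})

test_that("percent-relative summaries give the closed-form reference CI", {
  ref <- c(10, 12, 8, 10)
  res <- percent_relative_summary(c(10, 12, 8, 10, 5, 20),
                                  c(rep("ref", 4), "other", "other"),
                                  ref)
  s <- res$summary
  expect_equal(s$mean_pct[s$group == "ref"], 100)
  half <- qt(0.975, 3) * (sd(ref) / sqrt(4)) / mean(ref) * 100
  expect_equal(res$reference_ci, c(100 - half, 100 + half),
               tolerance = 1e-12)
  expect_equal(s$mean_pct[s$group == "other"], 125)
  expect_error(percent_relative_summary(1:3, rep("a", 3), numeric(0)),
               "empty")
  expect_error(percent_relative_summary(1:3, rep("a", 3), c(-1, 1)),
               "zero")
})
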