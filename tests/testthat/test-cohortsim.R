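small_design <- function(n = 6) study_design(n_per_cell = matrix(n, 2, 3))

test_that("cohort simulation is seed-deterministic and well-formed", {
  co1 <- simulate_cohort(small_design(), effect_model(), seed = 4)
  co2 <- simulate_cohort(small_design(), effect_model(), seed = 4)
  co3 <- simulate_cohort(small_design(), effect_model(), seed = 5)
  expect_identical(co1, co2)
  expect_false(identical(co1$ONL, co3$ONL))
  expect_equal(nrow(co1), 36)
  expect_identical(anyDuplicated(co1$id), 0L)
  # TRT is exactly the sum of the five layers
  expect_equal(co1$trt,
               co1$RNFL + co1$GCIPL + co1$INL + co1$OPL + co1$ONL)
  # human / pSer129 alpha-synuclein strictly zero in wildtype
  wt <- co1$genotype == "WT"
  expect_true(all(co1$human_asyn[wt] == 0))
  expect_true(all(co1$pser129_asyn[wt] == 0))
  expect_true(any(co1$human_asyn[!wt] > 0))
  # severity is a HOM-only latent variable
  expect_true(all(co1$severity[wt] == 0))
})

test_that("default design mirrors the cross-sectional cohort sizes", {
  d <- study_design()
  expect_equal(unname(d$n_per_cell["WT", ]), c(16, 19, 29))
  expect_equal(unname(d$n_per_cell["HOM", ]), c(16, 15, 24))
  expect_equal(sum(d$n_per_cell), 119)
  expect_error(study_design(n_per_cell = matrix(2, 2, 3)), ">= 3")
  expect_error(study_design(ages = c(6, 4, 14)), "diff")
  expect_error(effect_model(baseline = default_baseline()[-3, ]),
               "missing endpoint")
  bad <- default_genotype_shift()
  rownames(bad)[1] <- "bogus"
  expect_error(effect_model(genotype_shift = bad), "unknown endpoint")
})

test_that("planted genotype effect directions are recovered", {
  co <- simulate_cohort(study_design(), effect_model(), seed = 10)
  sh <- default_genotype_shift()
  for (e in c("ONL", "OPL", "cone_vmax", "GCIPL")) {
    diff_hom <- mean(co[[e]][co$genotype == "HOM"]) -
      mean(co[[e]][co$genotype == "WT"])
    expect_equal(sign(diff_hom), sign(mean(sh[e, ])))
  }
  # group means stay near planted means (seeded, n = 16-29 per cell)
  pm <- attr(co, "planted_means")
  for (e in c("ONL", "rod_rmp3")) {
    for (g in c("WT", "HOM")) {
      sel <- co$genotype == g & co$age == 4
      sem <- sd(co[[e]][sel]) / sqrt(sum(sel))
      expect_lt(abs(mean(co[[e]][sel]) - pm[e, g, "4"]), 4 * sem)
    }
  }
})

test_that("severity coupling induces the alpha-synuclein correlations", {
  co <- simulate_cohort(study_design(), effect_model(), seed = 21)
  tot <- total_alpha_syn(co$mouse_asyn, co$human_asyn, co$pser129_asyn)
  expect_lt(spearman_rank(tot, co$ONL)$rs, -0.3)
  expect_lt(spearman_rank(tot, co$cone_vmax)$rs, -0.3)
  # within HOM alone the coupling is still visible
  hom <- co$genotype == "HOM"
  expect_lt(spearman_rank(co$pser129_asyn[hom], co$ONL[hom])$rs, 0)
})

test_that("simulated lanes recover abundances through normalization", {
  co <- simulate_cohort(small_design(4), effect_model(), seed = 2)
  lanes <- simulate_lanes(co, seed = 3)
  expect_equal(nrow(lanes), nrow(co) * 4)
  norm <- normalize_lane(lanes$band_density, lanes$total_protein)
  sel <- lanes$target == "mouse_asyn"
  expect_equal(norm[sel][match(co$id, lanes$animal_id[sel])],
               co$mouse_asyn, tolerance = 1e-12)
})

test_that("animal grids reproduce planted layer means over the annulus", {
  lm <- c(RNFL = 40, GCIPL = 70, INL = 28, OPL = 17, ONL = 60)
  g <- animal_grid(lm, nx = 256)
  s <- summarize_layers(g)
  for (l in names(lm)) {
    expect_lt(abs(s$layers[[l]] - lm[[l]]) / lm[[l]], 0.005)
  }
  expect_equal(s$trt, sum(s$layers))
})

test_that("zero-variance zero-effect study gives exactly 100% relatives", {
  base0 <- default_baseline()
  base0$sd[] <- 0
  eff <- effect_model(baseline = base0,
                      age_trend = default_age_trend() * 0,
                      genotype_shift = default_genotype_shift() * 0,
                      severity_loading = c(ONL = 0))
  res <- run_study(small_design(4), eff, seed = 1)
  for (e in c("ONL", "rod_rmp3", "trt")) {
    for (ag in c("4", "6", "14")) {
      s <- res$endpoints[[e]]$relative[[ag]]$summary
      expect_equal(s$mean_pct, rep(100, nrow(s)))
    }
  }
})

test_that("run_study bundles are reproducible and internally consistent", {
  r1 <- run_study(small_design(6), seed = 31)
  r2 <- run_study(small_design(6), seed = 31)
  expect_equal(r1$cohort, r2$cohort)
  expect_equal(r1$endpoints$ONL$anova, r2$endpoints$ONL$anova)
  expect_equal(r1$correlations$total_asyn_vs_ONL$spearman$rs,
               r2$correlations$total_asyn_vs_ONL$spearman$rs)
  # the human alpha-synuclein reference switched to the young HOM group
  expect_true(r1$abundance$human_asyn$switched)
  expect_identical(r1$abundance$human_asyn$reference_group, "HOM_4")
  expect_false(r1$abundance$mouse_asyn$switched)
  # every analyzed endpoint carries a full ANOVA and 3 comparisons
  for (e in names(r1$endpoints)) {
    expect_equal(nrow(r1$endpoints[[e]]$anova), 4)
    expect_equal(nrow(r1$endpoints[[e]]$comparisons), 3)
  }
})

test_that("raw-waveform pipeline agrees with directly simulated endpoints", {
  des <- small_design(3)
  res <- run_study(des, seed = 17, from_raw = TRUE, grid_nx = 64)
  co <- simulate_cohort(des, effect_model(), seed = 17)
  tol <- c(rod_rmp3 = 0.05, rod_vmax = 0.02, cone_vmax = 0.06,
           ONL = 0.005, trt = 0.005)
  for (e in names(tol)) {
    rel <- abs(res$cohort[[e]] - co[[e]]) / abs(co[[e]])
    expect_lt(stats::median(rel), tol[[e]] / 2)
    expect_lt(max(rel), tol[[e]])
  }
  # pSTR measured from raw traces tracks the planted bump amplitude
  expect_lt(stats::median(abs(res$cohort$pstr - co$pstr) /
                            abs(co$pstr)), 0.05)
})
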