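# Synthetic cross-sectional cohort generator: two genotypes x three ages
# with genotype deficits concentrated in the cone pathway and outer
# retina, and a latent severity factor coupling alpha-synuclein burden
# (HOM only) to ONL thickness and cone bipolar function.

COHORT_ENDPOINTS <- c("rod_rmp3", "rod_vmax", "pstr", "cone_rmp3",
                      "cone_vmax", "RNFL", "GCIPL", "INL", "OPL", "ONL",
                      "th", "mouse_asyn", "human_asyn", "pser129_asyn")
ABUNDANCE_ENDPOINTS <- c("th", "mouse_asyn", "human_asyn", "pser129_asyn")
HOM_ONLY_ENDPOINTS <- c("human_asyn", "pser129_asyn")

#' Cross-sectional study design
#'
#' @param genotypes Genotype labels; first is the control (default
#'   `c("WT", "HOM")`).
#' @param ages Ages in months, strictly increasing (default 4, 6, 14).
#' @param n_per_cell Matrix of animals per genotype (rows) x age
#'   (columns), each >= 3. Default mirrors a cross-sectional cohort of
#'   119 animals: WT 16/19/29 and HOM 16/15/24 at 4/6/14 months.
#' @param sex_balance If `TRUE` (default) sexes alternate within each
#'   cell; sex is recorded but carries no effect.
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(genotypes = c("WT", "HOM"), ages = c(4, 6, 14),
                         n_per_cell = NULL, sex_balance = TRUE) {
  stopifnot(length(genotypes) == 2L, all(diff(ages) > 0))
  if (is.null(n_per_cell)) {
    n_per_cell <- rbind(c(16, 19, 29), c(16, 15, 24))[, seq_along(ages),
                                                      drop = FALSE]
  }
  n_per_cell <- as.matrix(n_per_cell)
  if (!all(dim(n_per_cell) == c(length(genotypes), length(ages)))) {
    stop("n_per_cell must be a ", length(genotypes), " x ", length(ages),
         " matrix")
  }
  if (any(n_per_cell < 3)) stop("n_per_cell must be >= 3 everywhere")
  dimnames(n_per_cell) <- list(genotypes, ages)
  structure(list(genotypes = genotypes, ages = ages,
                 n_per_cell = n_per_cell, sex_balance = sex_balance),
            class = "study_design")
}

#' Default effect-model components
#'
#' Building blocks of the default [effect_model()]: the wildtype
#' 4-month baseline (mean and SD per endpoint), the age trend and the
#' HOM-minus-WT genotype shift (baseline-SD units per age, concentrated
#' in cone P2/P3 and OPL/ONL with a slight GCIPL thickening and
#' late-only RNFL thinning), and the latent-severity loadings coupling
#' HOM alpha-synuclein burden positively and ONL/cone-P2 negatively.
#' Copy and modify these to plant custom effects.
#'
#' @return `default_baseline()`: data frame of endpoint, mean, sd;
#'   `default_age_trend()`, `default_genotype_shift()`: endpoint x age
#'   matrices; `default_severity_loading()`: named numeric vector.
#' @export
default_baseline <- function() {
  data.frame(
    endpoint = COHORT_ENDPOINTS,
    mean = c(rod_rmp3 = 450, rod_vmax = 600, pstr = 15, cone_rmp3 = 35,
             cone_vmax = 250, RNFL = 40, GCIPL = 70, INL = 28, OPL = 17,
             ONL = 60, th = 100, mouse_asyn = 100, human_asyn = 100,
             pser129_asyn = 100),
    sd = c(rod_rmp3 = 60, rod_vmax = 70, pstr = 3, cone_rmp3 = 7,
           cone_vmax = 30, RNFL = 3, GCIPL = 4, INL = 2, OPL = 1.5,
           ONL = 3, th = 15, mouse_asyn = 20, human_asyn = 25,
           pser129_asyn = 25),
    row.names = NULL)
}

#' @rdname default_baseline
#' @export
default_age_trend <- function() {
  tr <- matrix(0, length(COHORT_ENDPOINTS), 3,
               dimnames = list(COHORT_ENDPOINTS, c(4, 6, 14)))
  tr["RNFL", ] <- c(0, -0.3, -1.0)
  tr["INL", ] <- c(0, -0.3, -0.8)
  tr["rod_rmp3", ] <- c(0, -0.2, -0.6)
  tr["rod_vmax", ] <- c(0, -0.2, -0.5)
  tr["cone_rmp3", ] <- c(0, -0.2, -0.5)
  tr["cone_vmax", ] <- c(0, -0.3, -0.8)
  tr["human_asyn", ] <- c(0, 0.3, 0.8)
  tr["pser129_asyn", ] <- c(0, 0.4, 1.0)
  tr
}

#' @rdname default_baseline
#' @export
default_genotype_shift <- function() {
  sh <- matrix(0, length(COHORT_ENDPOINTS), 3,
               dimnames = list(COHORT_ENDPOINTS, c(4, 6, 14)))
  sh["ONL", ] <- c(-1.2, -1.8, -2.4)        # earliest, largest deficit
  sh["OPL", ] <- c(-0.8, -1.3, -1.8)
  sh["GCIPL", ] <- c(0.5, 0.5, 0.5)         # slight thickening
  sh["RNFL", ] <- c(0, 0, -0.9)             # late-only thinning
  sh["cone_vmax", ] <- c(-1.2, -1.5, -1.8)  # early cone bipolar deficit
  sh["cone_rmp3", ] <- c(-1.0, -1.2, -1.5)
  sh["rod_rmp3", ] <- c(-0.6, -0.8, -1.0)
  sh["th", ] <- c(0.4, 0.5, 0.8)
  sh["mouse_asyn", ] <- c(0.8, 0.8, 0.3)
  sh
}

#' @rdname default_baseline
#' @export
default_severity_loading <- function() {
  c(human_asyn = 0.8, pser129_asyn = 0.8, mouse_asyn = 0.3,
    ONL = -0.6, cone_vmax = -0.6)
}

#' Endpoint effect model for the cohort simulator
#'
#' Defines, per endpoint: the wildtype 4-month baseline mean and SD; an
#' age trend (both genotypes) and a genotype shift (HOM minus WT), each
#' in baseline-SD units per age; and the loadings of a per-animal latent
#' severity factor `s ~ N(0, 1)` present only in HOM animals, which
#' couples alpha-synuclein abundance (positive loadings) to ONL
#' thickness and cone bipolar amplitude (negative loadings). Human and
#' pSer129 alpha-synuclein are identically zero in wildtype animals;
#' their baseline row is the 4-month HOM level.
#'
#' @param baseline Data frame with columns `endpoint`, `mean`, `sd`
#'   (SDs > 0) covering all endpoints.
#' @param age_trend,genotype_shift Numeric matrices, endpoints x ages,
#'   in SD units.
#' @param severity_loading Named numeric vector of SD-unit loadings.
#' @return An object of class `"effect_model"`.
#' @export
effect_model <- function(baseline = default_baseline(),
                         age_trend = default_age_trend(),
                         genotype_shift = default_genotype_shift(),
                         severity_loading = default_severity_loading()) {
  stopifnot(all(c("endpoint", "mean", "sd") %in% names(baseline)))
  unknown <- setdiff(c(baseline$endpoint, rownames(age_trend),
                       rownames(genotype_shift),
                       names(severity_loading)), COHORT_ENDPOINTS)
  if (length(unknown)) {
    stop("unknown endpoint(s) in effect model: ",
         paste(unknown, collapse = ", "))
  }
  missing <- setdiff(COHORT_ENDPOINTS, baseline$endpoint)
  if (length(missing)) {
    stop("baseline missing endpoint(s): ", paste(missing, collapse = ", "))
  }
  if (any(baseline$sd < 0)) {
    stop("baseline SDs must be >= 0 (0 only for deterministic checks)")
  }
  structure(list(baseline = baseline, age_trend = age_trend,
                 genotype_shift = genotype_shift,
                 severity_loading = severity_loading),
            class = "effect_model")
}

#' A zero-effect model (identical genotype distributions)
#'
#' All age trends, genotype shifts and severity loadings set to zero;
#' useful for null calibration of the statistical layer. Human and
#' pSer129 alpha-synuclein remain HOM-only by construction.
#'
#' @return An [effect_model()].
#' @export
null_effect_model <- function() {
  z <- default_age_trend(); z[] <- 0
  effect_model(age_trend = z, genotype_shift = z,
               severity_loading = c(ONL = 0))
}

#' Simulate a cross-sectional cohort with known ground truth
#'
#' Draws per-animal endpoints as Gaussians around genotype-by-age means
#' defined by the effect model, with the HOM-only latent severity factor
#' inducing negative alpha-synuclein vs ONL / cone-P2 correlations.
#' Abundance endpoints are floored at zero; total retinal thickness
#' (`trt`) is derived as the sum of the five layer endpoints.
#'
#' @param design A [study_design()].
#' @param effects An [effect_model()].
#' @param seed Integer seed (required).
#' @return A data frame of class `"cohort_dataset"`: one row per animal
#'   with `id`, `genotype`, `age`, `sex`, `severity` (the latent factor,
#'   0 for WT) and one column per endpoint plus `trt`. The planted
#'   cell means are attached as attribute `"planted_means"` (endpoint x
#'   genotype x age array); `design`, `effects` and `seed` are also
#'   attached.
#' @export
simulate_cohort <- function(design = study_design(),
                            effects = effect_model(), seed) {
  stopifnot(inherits(design, "study_design"),
            inherits(effects, "effect_model"))
  ages <- design$ages
  gts <- design$genotypes
  base <- effects$baseline
  mu <- stats::setNames(base$mean, base$endpoint)[COHORT_ENDPOINTS]
  sdv <- stats::setNames(base$sd, base$endpoint)[COHORT_ENDPOINTS]
  tr_of <- function(mat, e, ai) {
    if (!is.null(mat) && e %in% rownames(mat)) mat[e, ai] else 0
  }
  load_of <- function(e) {
    if (e %in% names(effects$severity_loading)) {
      effects$severity_loading[[e]]
    } else 0
  }
  planted <- array(0, dim = c(length(COHORT_ENDPOINTS), length(gts),
                              length(ages)),
                   dimnames = list(COHORT_ENDPOINTS, gts, ages))
  rows <- with_seed(seed, {
    out <- list()
    idn <- 0L
    for (ai in seq_along(ages)) {
      for (gi in seq_along(gts)) {
        n <- design$n_per_cell[gi, ai]
        hom <- gi == 2L
        s <- if (hom) stats::rnorm(n) else rep(0, n)
        cell <- data.frame(
          id = sprintf("%s_%02dmo_%03d", gts[gi], ages[ai],
                       idn + seq_len(n)),
          genotype = gts[gi], age = ages[ai],
          sex = if (design$sex_balance) {
            rep_len(c("F", "M"), n)
          } else {
            sample(c("F", "M"), n, replace = TRUE)
          },
          severity = s)
        idn <- idn + n
        for (e in COHORT_ENDPOINTS) {
          hom_only <- e %in% HOM_ONLY_ENDPOINTS
          if (hom_only && !hom) {
            cell[[e]] <- 0
            planted[e, gi, ai] <- 0
            next
          }
          m <- mu[[e]] + sdv[[e]] *
            (tr_of(effects$age_trend, e, ai) +
               (if (hom && !hom_only)
                 tr_of(effects$genotype_shift, e, ai) else 0))
          planted[e, gi, ai] <- m
          v <- m + sdv[[e]] * load_of(e) * s +
            stats::rnorm(n, 0, sdv[[e]])
          if (e %in% ABUNDANCE_ENDPOINTS) v <- pmax(v, 0)
          cell[[e]] <- v
        }
        out[[length(out) + 1L]] <- cell
      }
    }
    out
  })
  dat <- do.call(rbind, rows)
  dat$genotype <- factor(dat$genotype, levels = gts)
  dat$trt <- dat$RNFL + dat$GCIPL + dat$INL + dat$OPL + dat$ONL
  structure(dat, class = c("cohort_dataset", "data.frame"),
            planted_means = planted, design = design, effects = effects,
            seed = seed)
}

#' Simulate densitometry lane records for a cohort
#'
#' Emits one lane per animal and protein target with a lognormal
#' total-protein loading; band density is the animal's abundance times
#' the loading, so [normalize_lane()] recovers the abundance exactly.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param seed Integer seed.
#' @param tp_cv Coefficient of variation of the total-protein loading.
#' @return Data frame with `animal_id`, `genotype`, `age`, `target`,
#'   `band_density`, `total_protein`.
#' @export
simulate_lanes <- function(cohort, seed, tp_cv = 0.15) {
  targets <- ABUNDANCE_ENDPOINTS
  tp <- with_seed(seed, {
    1000 * exp(stats::rnorm(nrow(cohort) * length(targets), 0, tp_cv))
  })
  grid <- expand.grid(row = seq_len(nrow(cohort)),
                      target = targets, stringsAsFactors = FALSE)
  abundances <- unlist(lapply(targets, function(tg) cohort[[tg]]),
                       use.names = FALSE)
  data.frame(animal_id = cohort$id[grid$row],
             genotype = cohort$genotype[grid$row],
             age = cohort$age[grid$row],
             target = grid$target,
             band_density = abundances * tp,
             total_protein = tp)
}

#' Generate raw ERG waveform families for one animal
#'
#' Maps an animal's planted ERG endpoints onto generator parameters
#' (dark/rod and light/cone pathways) and produces one mixed-adaptation
#' waveform family over the default protocols.
#'
#' @param rod_rmp3,rod_vmax,pstr,cone_rmp3,cone_vmax Planted endpoint
#'   values, microvolts.
#' @param tb A [timebase()].
#' @param seed Integer seed.
#' @param noise_sd Recording noise SD, microvolts (default 0: the
#'   clean retinal signal).
#' @param acquisition_band Amplifier band-pass or `NULL` (default) for
#'   the unfiltered signal; see [accessory_params()].
#' @return A [waveform_family()] containing both protocols.
#' @export
animal_waveforms <- function(rod_rmp3, rod_vmax, pstr, cone_rmp3,
                             cone_vmax, tb = timebase(), seed,
                             noise_sd = 0, acquisition_band = NULL) {
  rod3 <- default_rod_p3(); rod3$rmp3 <- max(rod_rmp3, 0)
  con3 <- default_cone_p3(); con3$rmp3 <- max(cone_rmp3, 0)
  rod2 <- default_rod_p2(); rod2$vmax <- max(rod_vmax, 0)
  con2 <- default_cone_p2(); con2$vmax <- max(cone_vmax, 0)
  acc <- accessory_params(str_amplitude = max(pstr, 0),
                          noise_sd = noise_sd,
                          acquisition_band = acquisition_band)
  generate_family(c(dark_protocol(), light_protocol()),
                  p3 = list(dark = rod3, light = con3),
                  p2 = list(dark = rod2, light = con2),
                  acc = acc, tb = tb, seed = seed)
}

#' Generate a thickness grid for one animal from planted layer means
#'
#' Builds per-layer rasters with a gentle radial slope (5% of the mean
#' per scan radius) whose area-weighted annulus mean equals the planted
#' value analytically, so the OCT summarization stage can be run from
#' raster input with known truth.
#'
#' @param layer_means Named numeric: planted RNFL, GCIPL, INL, OPL, ONL
#'   means (micrometers).
#' @param annulus An [annulus_spec()]; the slope is anchored so the
#'   annulus mean matches the planted value.
#' @param nx Raster width in pixels (square grid).
#' @param extent_mm Scan width, mm (default 8.1).
#' @return A [thickness_grid()].
#' @export
animal_grid <- function(layer_means, annulus = annulus_spec(), nx = 96,
                        extent_mm = 8.1) {
  stopifnot(all(OCT_LAYERS %in% names(layer_means)))
  half <- extent_mm / 2
  x <- seq(-half, half, length.out = nx)
  r <- sqrt(outer((x - annulus$center[1])^2,
                  (x - annulus$center[2])^2, `+`))
  r1 <- annulus$inner_diameter / 2
  r2 <- annulus$outer_diameter / 2
  # area-weighted mean radius of the annulus: (2/3)(r2^3-r1^3)/(r2^2-r1^2)
  rbar <- (2 / 3) * (r2^3 - r1^3) / (r2^2 - r1^2)
  layers <- lapply(OCT_LAYERS, function(l) {
    m <- layer_means[[l]]
    b <- 0.05 * m / half
    pmax(m - b * rbar + b * r, 0)
  })
  names(layers) <- OCT_LAYERS
  thickness_grid(x, x, layers)
}

#' Run the full synthetic study end to end
#'
#' Simulates a cohort, optionally regenerates raw waveforms and
#' thickness rasters per animal and re-derives the endpoints through the
#' measurement pipeline ([decompose()], [summarize_layers()]), then
#' applies the statistical layer: densitometry normalization and
#' percent-of-reference scaling, per-cell ROUT screening, two-way
#' genotype x age ANOVA with Sidak per-age comparisons,
#' percent-relative-to-age-matched-WT summaries, and the
#' structure-function / alpha-synuclein correlation panel (Deming +
#' Spearman).
#'
#' @param design A [study_design()].
#' @param effects An [effect_model()].
#' @param seed Integer seed driving every stage.
#' @param from_raw If `TRUE`, ERG and OCT endpoints are re-measured from
#'   generated raw waveforms and rasters rather than taken from the
#'   simulated table.
#' @param raw_noise_sd Recording noise for raw waveform generation,
#'   microvolts.
#' @param grid_nx Raster width for generated thickness grids.
#' @param config A [decomp_config()] for the raw decomposition.
#' @param rout_q ROUT Q in percent applied within each genotype x age
#'   cell before the ANOVA.
#' @return List of class `"study_results"`: `cohort` (analysis table
#'   after any raw re-measurement), `endpoints` (per endpoint: ROUT
#'   masks, `anova_table`, `sidak_comparisons`, percent-relative
#'   summaries per age), `correlations` (per pair: `deming_fit`,
#'   `spearman_result`), `abundance` (percent-of-reference objects),
#'   `seed`.
#' @export
run_study <- function(design = study_design(), effects = effect_model(),
                      seed, from_raw = FALSE, raw_noise_sd = 0,
                      grid_nx = 96, config = decomp_config(),
                      rout_q = 1) {
  cohort <- simulate_cohort(design, effects, seed)
  if (from_raw) {
    tb <- timebase()
    ann <- annulus_spec()
    for (j in seq_len(nrow(cohort))) {
      fam <- animal_waveforms(cohort$rod_rmp3[j], cohort$rod_vmax[j],
                              cohort$pstr[j], cohort$cone_rmp3[j],
                              cohort$cone_vmax[j], tb,
                              seed = child_seed(seed, 100000 + j),
                              noise_sd = raw_noise_sd)
      dec <- decompose(fam, config)
      cohort$rod_rmp3[j] <- dec$rod_p3$params$rmp3
      cohort$rod_vmax[j] <- dec$rod_p2$vmax
      cohort$pstr[j] <- dec$pstr$amplitude
      cohort$cone_rmp3[j] <- dec$cone_p3$params$rmp3
      cohort$cone_vmax[j] <- dec$cone_p2$vmax
      lm_j <- stats::setNames(as.numeric(cohort[j, OCT_LAYERS]),
                              OCT_LAYERS)
      ls <- summarize_layers(animal_grid(lm_j, ann, nx = grid_nx), ann)
      for (l in OCT_LAYERS) cohort[[l]][j] <- ls$layers[[l]]
      cohort$trt[j] <- ls$trt
    }
  }
  # densitometry: lanes -> lane-normalized -> percent of reference
  lanes <- simulate_lanes(cohort, child_seed(seed, 9001))
  lanes$normalized <- normalize_lane(lanes$band_density,
                                     lanes$total_protein)
  grp <- paste(cohort$genotype, cohort$age, sep = "_")
  ref <- paste(levels(cohort$genotype)[1L], design$ages[1L], sep = "_")
  fallback <- paste(levels(cohort$genotype)[2L], design$ages[1L],
                    sep = "_")
  abundance <- list()
  for (tg in ABUNDANCE_ENDPOINTS) {
    sel <- lanes$target == tg
    vals <- lanes$normalized[sel][match(cohort$id,
                                        lanes$animal_id[sel])]
    abundance[[tg]] <- percent_of_reference(vals, grp, ref, fallback)
    cohort[[paste0(tg, "_pct")]] <- abundance[[tg]]$percent
  }
  cohort$total_asyn <- total_alpha_syn(cohort$mouse_asyn_pct,
                                       cohort$human_asyn_pct,
                                       cohort$pser129_asyn_pct)
  analysis_endpoints <- c("rod_rmp3", "rod_vmax", "pstr", "cone_rmp3",
                          "cone_vmax", OCT_LAYERS, "trt",
                          paste0(ABUNDANCE_ENDPOINTS, "_pct"))
  endpoints <- list()
  wt <- levels(cohort$genotype)[1L]
  for (e in analysis_endpoints) {
    v <- cohort[[e]]
    keep <- rep(TRUE, length(v))
    for (cell in unique(grp)) {
      sel <- which(grp == cell)
      keep[sel] <- rout_outliers(v[sel], q = rout_q)$mask
    }
    an <- two_way_anova(v[keep], cohort$genotype[keep],
                        cohort$age[keep])
    cmp <- sidak_comparisons(v[keep], cohort$genotype[keep],
                             cohort$age[keep])
    hom <- levels(cohort$genotype)[2L]
    rel <- lapply(design$ages, function(ag) {
      sel <- keep & cohort$age == ag
      ref_vals <- v[sel & cohort$genotype == wt]
      # HOM-only abundances have a zero WT reference; fall back to the
      # youngest HOM cohort, mirroring the densitometry reference rule
      if (mean(ref_vals) == 0) {
        ref_vals <- v[keep & cohort$genotype == hom &
                        cohort$age == design$ages[1L]]
      }
      percent_relative_summary(v[sel], as.character(cohort$genotype[sel]),
                               ref_vals)
    })
    names(rel) <- design$ages
    endpoints[[e]] <- list(rout_removed = sum(!keep), keep = keep,
                           anova = an, comparisons = cmp,
                           relative = rel)
  }
  pairs <- list(c("cone_vmax", "ONL"), c("cone_vmax", "OPL"),
                c("cone_rmp3", "ONL"), c("cone_rmp3", "OPL"),
                c("total_asyn", "ONL"), c("total_asyn", "cone_vmax"),
                c("pser129_asyn_pct", "ONL"),
                c("pser129_asyn_pct", "cone_vmax"))
  correlations <- lapply(pairs, function(pr) {
    x <- cohort[[pr[1L]]]
    y <- cohort[[pr[2L]]]
    # degenerate pairs (e.g. zero-variance calibration runs) are
    # recorded, not fatal for the rest of the bundle
    safely <- function(expr) tryCatch(expr, error = function(e)
      structure(list(message = conditionMessage(e)),
                class = "stage_error"))
    list(x = pr[1L], y = pr[2L], deming = safely(deming_fit(x, y)),
         spearman = safely(spearman_rank(x, y)))
  })
  names(correlations) <- vapply(pairs, paste, "", collapse = "_vs_")
  structure(list(cohort = cohort, endpoints = endpoints,
                 correlations = correlations, abundance = abundance,
                 seed = seed, design = design, effects = effects,
                 from_raw = from_raw),
            class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("Synthetic study results (seed %s, %s endpoints)\n",
              format(x$seed),
              if (x$from_raw) "raw-pipeline" else "direct"))
  cat(sprintf("  %d animals; %d endpoints analyzed; %d correlation pairs\n",
              nrow(x$cohort), length(x$endpoints),
              length(x$correlations)))
  gp <- vapply(x$endpoints, function(e)
    e$anova$p[e$anova$factor == "genotype"], 0)
  sig <- names(gp)[gp < 0.05]
  cat("  genotype effects p < 0.05: ",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}
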