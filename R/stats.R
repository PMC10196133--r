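# The study's statistical layer: ROUT outlier screening, two-way
# genotype x age ANOVA with Sidak post hoc comparisons, Deming
# errors-in-variables regression, Spearman rank correlation, and
# percent-of-reference summaries.

#' ROUT outlier screening for a univariate group
#'
#' The ROUT procedure (robust fit + FDR-controlled residual test)
#' reduced to the constant model, appropriate for screening a group of
#' replicate measurements: the robust center is the median; the robust
#' SD of residuals (RSDR) is the 68.27th percentile of absolute
#' residuals with the small-sample correction `n / (n - K)`, `K = 1`;
#' each residual's two-tailed p-value from `t = |r| / RSDR` on `n - K`
#' degrees of freedom is then tested by FDR step-up at rate `Q`.
#'
#' @param values Numeric vector, `n >= 3`.
#' @param q FDR coefficient Q in percent, in (0, 100); default 1.
#' @return Object of class `"outlier_screen"`: `mask` (TRUE = keep),
#'   `flagged` indices, `robust_center`, `rsdr`, `q`, `p` per value.
#' @export
#' @examples
#' x <- c(rnorm(20), 50)
#' rout_outliers(x)$flagged  # the planted extreme point
rout_outliers <- function(values, q = 1) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) stop("ROUT needs at least 3 values")
  if (!is.numeric(q) || q <= 0 || q >= 100) stop("q must be in (0, 100)")
  center <- stats::median(values)
  r <- values - center
  k <- 1L
  rsdr <- stats::quantile(abs(r), 0.6827, names = FALSE) * n / (n - k)
  mask <- rep(TRUE, n)
  p <- rep(1, n)
  if (rsdr > .Machine$double.eps * max(abs(values), 1)) {
    p <- 2 * stats::pt(-abs(r) / rsdr, df = n - k)
    # FDR step-up on the residual p-values at rate Q
    ord <- order(p)
    thresh <- (q / 100) * seq_len(n) / n
    passed <- which(p[ord] <= thresh)
    if (length(passed)) mask[ord[seq_len(max(passed))]] <- FALSE
  }
  structure(list(mask = mask, flagged = which(!mask),
                 robust_center = center, rsdr = rsdr, q = q, p = p),
            class = "outlier_screen")
}

#' @export
print.outlier_screen <- function(x, ...) {
  cat(sprintf("ROUT screen (Q = %g%%): %d of %d flagged; center %.3g, RSDR %.3g\n",
              x$q, length(x$flagged), length(x$mask), x$robust_center,
              x$rsdr))
  invisible(x)
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Genotype x age ANOVA on a (possibly unbalanced) design, using
#' Type-III sums of squares with sum-to-zero contrasts, which coincide
#' with the textbook decomposition on balanced designs.
#'
#' @param values Numeric response vector.
#' @param genotype,age Factors (or coercible) of the same length;
#'   each must have at least 2 levels and every cell at least one
#'   observation.
#' @return Object of class `"anova_table"`: data frame with rows
#'   `genotype`, `age`, `interaction`, `residual` and columns `ss`,
#'   `df`, `F`, `p`; attribute `degenerate` set when the residual
#'   variance is zero (F infinite, p reported as 0).
#' @export
two_way_anova <- function(values, genotype, age) {
  g <- factor(genotype)
  a <- factor(age)
  stopifnot(length(values) == length(g), length(values) == length(a))
  if (nlevels(g) < 2L || nlevels(a) < 2L) {
    stop("both factors need at least 2 levels")
  }
  cells <- table(g, a)
  if (any(cells == 0L)) {
    bad <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop("empty design cell: genotype ", levels(g)[bad[1L]], ", age ",
         levels(a)[bad[2L]])
  }
  dat <- data.frame(v = as.numeric(values), g = g, a = a)
  fit <- stats::lm(v ~ g * a, data = dat,
                   contrasts = list(g = stats::contr.sum,
                                    a = stats::contr.sum))
  rss_full <- sum(stats::resid(fit)^2)
  tot <- sum((dat$v - mean(dat$v))^2)
  scale2 <- max(tot, length(dat$v) * mean(dat$v)^2, .Machine$double.eps)
  degenerate <- rss_full <= 1e-12 * scale2
  df_terms <- c(nlevels(g) - 1L, nlevels(a) - 1L,
                (nlevels(g) - 1L) * (nlevels(a) - 1L))
  df_res <- length(dat$v) - nlevels(g) * nlevels(a)
  if (!degenerate) {
    a3 <- car::Anova(fit, type = 3)
    pick <- function(term) {
      row <- a3[rownames(a3) == term, , drop = FALSE]
      c(ss = row$`Sum Sq`, df = row$Df, F = row$`F value`,
        p = row$`Pr(>F)`)
    }
    out <- rbind(genotype = pick("g"), age = pick("a"),
                 interaction = pick("g:a"), residual = pick("Residuals"))
    tab <- data.frame(factor = rownames(out), ss = out[, "ss"],
                      df = out[, "df"], F = out[, "F"], p = out[, "p"],
                      row.names = NULL)
  } else {
    # zero residual variance: car refuses the fit, so compute the
    # Type-III term SS directly as full-vs-reduced RSS differences on
    # the sum-contrast design matrix; nonzero terms get the infinite-F
    # contract (p reported as 0)
    X <- stats::model.matrix(fit)
    asg <- attr(X, "assign")
    rss_of <- function(keep) {
      sum(qr.resid(qr(X[, keep, drop = FALSE]), dat$v)^2)
    }
    ss <- vapply(1:3, function(k) rss_of(asg != k) - rss_full, 0)
    ss <- pmax(ss, 0)
    nz <- ss > 1e-12 * scale2
    tab <- data.frame(
      factor = c("genotype", "age", "interaction", "residual"),
      ss = c(ss, rss_full), df = c(df_terms, df_res),
      F = c(ifelse(nz, Inf, NaN), NA),
      p = c(ifelse(nz, 0, NaN), NA))
  }
  structure(tab, class = c("anova_table", "data.frame"),
            degenerate = degenerate)
}

#' Sidak multiplicity adjustment
#'
#' @param p_raw Raw p-value(s) in \[0, 1\].
#' @param m Number of comparisons in the family (>= 1).
#' @return Adjusted p-value(s) `1 - (1 - p)^m`, clipped to \[0, 1\].
#' @export
#' @examples
#' sidak_adjust(0.01, 5)        # 0.04901...
#' 1 - (1 - 0.05)^(1 / 3)       # per-comparison threshold at alpha 0.05, m 3
sidak_adjust <- function(p_raw, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop("m must be a single number >= 1")
  }
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) {
    stop("p_raw must lie in [0, 1]")
  }
  pmin(1, pmax(0, 1 - (1 - p_raw)^m))
}

#' Per-age genotype comparisons with Sidak correction
#'
#' Post hoc WT-vs-HOM contrasts within each age, using the pooled
#' residual mean square of the two-way ANOVA fit (the customary post hoc
#' t after a factorial ANOVA), Sidak-adjusted over the number of ages.
#'
#' @param values,genotype,age As in [two_way_anova()]; `genotype` must
#'   have exactly 2 levels.
#' @return Data frame of class `"sidak_comparisons"`: one row per age
#'   with `difference` (second level minus first), `se`, `t`, `df`,
#'   `p_raw`, `p_adj`; attribute `m` = number of comparisons.
#' @export
sidak_comparisons <- function(values, genotype, age) {
  g <- factor(genotype)
  a <- factor(age)
  if (nlevels(g) != 2L) stop("genotype must have exactly 2 levels")
  tab <- two_way_anova(values, g, a)
  mse <- tab$ss[tab$factor == "residual"] /
    tab$df[tab$factor == "residual"]
  dfres <- tab$df[tab$factor == "residual"]
  m <- nlevels(a)
  rows <- lapply(levels(a), function(lv) {
    sel <- a == lv
    v1 <- values[sel & g == levels(g)[1L]]
    v2 <- values[sel & g == levels(g)[2L]]
    d <- mean(v2) - mean(v1)
    se <- sqrt(mse * (1 / length(v1) + 1 / length(v2)))
    tval <- d / se
    p <- 2 * stats::pt(-abs(tval), dfres)
    data.frame(age = lv, difference = d, se = se, t = tval, df = dfres,
               p_raw = p, p_adj = sidak_adjust(p, m))
  })
  structure(do.call(rbind, rows),
            class = c("sidak_comparisons", "data.frame"), m = m)
}

#' Deming errors-in-variables regression
#'
#' Fits a line minimizing weighted orthogonal residuals when both axes
#' carry measurement error, governed by the error-variance ratio
#' `lambda = var(error in y) / var(error in x)`. With `lambda = 1` this
#' is orthogonal (total least squares) regression.
#'
#' @param x,y Numeric vectors (pairs with missing values dropped),
#'   `n >= 3` complete pairs.
#' @param lambda Error-variance ratio (> 0), default 1.
#' @return Object of class `"deming_fit"`: `slope`, `intercept`,
#'   `lambda`, `n`.
#' @export
deming_fit <- function(x, y, lambda = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("Deming regression needs at least 3 complete pairs")
  check_scalar(lambda, "lambda", lower = 0, strict_lower = TRUE)
  sxx <- stats::var(x)
  syy <- stats::var(y)
  sxy <- stats::cov(x, y)
  if (sxx == 0 && syy == 0) stop("zero variance in both x and y")
  if (abs(sxy) < .Machine$double.eps * sqrt(max(sxx, 1) * max(syy, 1))) {
    stop("x and y are uncorrelated (covariance ~ 0); Deming slope undefined")
  }
  slope <- (syy - lambda * sxx +
              sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) /
    (2 * sxy)
  intercept <- mean(y) - slope * mean(x)
  structure(list(slope = slope, intercept = intercept, lambda = lambda,
                 n = n), class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("Deming fit (lambda = %g, n = %d): y = %.4g x + %.4g\n",
              x$lambda, x$n, x$slope, x$intercept))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Computes mid-ranks (average ranks for ties) and returns their Pearson
#' correlation, with an asymptotic t-approximation p-value by default or
#' a seeded permutation p-value.
#'
#' @param x,y Numeric vectors (pairs with missing values dropped),
#'   `n >= 3`; neither may be constant.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm Number of permutations (permutation method).
#' @param seed Integer seed (required for the permutation method).
#' @return Object of class `"spearman_result"`: `rs`, `p`, `n`,
#'   `method`.
#' @export
spearman_rank <- function(x, y, method = c("asymptotic", "permutation"),
                          n_perm = 10000, seed = NULL) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("Spearman correlation needs at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("rank correlation undefined for constant input")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rs_of <- function(ra, rb) {
    ra <- ra - mean(ra); rb <- rb - mean(rb)
    sum(ra * rb) / sqrt(sum(ra^2) * sum(rb^2))
  }
  rs <- rs_of(rx, ry)
  if (method == "asymptotic") {
    if (abs(rs) >= 1) {
      p <- 0
    } else {
      tval <- rs * sqrt((n - 2) / (1 - rs^2))
      p <- 2 * stats::pt(-abs(tval), n - 2)
    }
  } else {
    if (is.null(seed)) stop("permutation method requires a seed")
    p <- with_seed(seed, {
      hits <- sum(vapply(seq_len(n_perm), function(b) {
        abs(rs_of(rx, sample(ry))) >= abs(rs) - 1e-12
      }, TRUE))
      (1 + hits) / (n_perm + 1)
    })
  }
  structure(list(rs = rs, p = p, n = n, method = method),
            class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: Rs = %.4f, p = %.4g (n = %d, %s)\n",
              x$rs, x$p, x$n, x$method))
  invisible(x)
}

#' Percent-of-reference group summaries with a reference CI band
#'
#' Scales every value to percent of the reference group mean, then
#' summarizes each group (mean and SEM on the percent scale) and gives
#' the 95% t-interval of the reference group itself on that scale --
#' the "shaded band" presentation of group data relative to a control
#' cohort.
#'
#' @param values Numeric vector.
#' @param groups Group label per value.
#' @param reference_values Numeric vector of the reference group's
#'   values (non-empty, nonzero mean).
#' @return List of class `"percent_summary"`: `summary` (data frame of
#'   group, n, mean_pct, sem_pct), `reference_ci` (95% interval of the
#'   reference mean, percent scale), `reference_mean` (raw units).
#' @export
percent_relative_summary <- function(values, groups, reference_values) {
  if (length(reference_values) == 0L) stop("reference group is empty")
  m <- mean(reference_values)
  if (m == 0) {
    stop("reference mean is zero; use percent_of_reference() with a ",
         "fallback group")
  }
  pct <- 100 * values / m
  groups <- as.character(groups)
  rows <- lapply(unique(groups), function(gp) {
    v <- pct[groups == gp]
    data.frame(group = gp, n = length(v), mean_pct = mean(v),
               sem_pct = stats::sd(v) / sqrt(length(v)))
  })
  nr <- length(reference_values)
  ref_pct <- 100 * reference_values / m
  half <- if (nr > 1) {
    stats::qt(0.975, nr - 1) * stats::sd(ref_pct) / sqrt(nr)
  } else {
    NA_real_
  }
  structure(list(summary = do.call(rbind, rows),
                 reference_ci = c(100 - half, 100 + half),
                 reference_mean = m),
            class = "percent_summary")
}
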