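# Western-blot densitometry: total-protein lane normalization and
# reference-group scaling.

#' Normalize band densitometry to the lane's total protein
#'
#' The relative abundance of a lane is its band density divided by the
#' same lane's automated total-protein (stain-free) measurement, making
#' the value invariant to per-lane loading and gain.
#'
#' @param band_density Band densitometry, arbitrary units (>= 0);
#'   vectorized.
#' @param total_protein Total-protein measurement for the same lane(s)
#'   (> 0).
#' @return Dimensionless normalized abundance(s).
#' @export
#' @examples
#' normalize_lane(500, 1000)  # 0.5
normalize_lane <- function(band_density, total_protein) {
  stopifnot(is.numeric(band_density), is.numeric(total_protein),
            length(band_density) == length(total_protein))
  if (any(!is.finite(total_protein)) || any(total_protein <= 0)) {
    stop("total_protein must be positive and finite for every lane")
  }
  if (any(!is.finite(band_density)) || any(band_density < 0)) {
    stop("band_density must be non-negative and finite")
  }
  band_density / total_protein
}

#' Express values as percent of a reference group's mean
#'
#' Each value is scaled to 100 times its ratio to the reference group
#' mean. When the reference mean is indistinguishable from zero (as for
#' human and pSer129 alpha-synuclein in wildtype lanes), the fallback
#' group's mean is used instead and the switch is recorded.
#'
#' @param values Numeric vector of normalized abundances.
#' @param groups Group label per value (e.g. `"WT_4"`).
#' @param reference Label of the primary reference group (e.g. the
#'   4-month wildtype cohort).
#' @param fallback Label of the fallback reference group used when the
#'   primary mean is zero (e.g. the 4-month HOM cohort), or `NULL`.
#' @param zero_tol Fraction of `max(abs(values))` below which a reference
#'   mean counts as zero (real densitometry never returns exact zeros;
#'   the simulator does).
#' @return List of class `"relative_abundance"`: `percent` (one value per
#'   input), `reference_group` actually used, `reference_mean`, and
#'   `switched` flag.
#' @export
percent_of_reference <- function(values, groups, reference,
                                 fallback = NULL, zero_tol = 1e-12) {
  stopifnot(length(values) == length(groups))
  grp_mean <- function(g) {
    sel <- groups == g
    if (!any(sel)) stop("reference group '", g, "' is empty")
    mean(values[sel])
  }
  eps <- zero_tol * max(abs(values), 0)
  used <- reference
  m <- grp_mean(reference)
  switched <- FALSE
  if (abs(m) <= eps) {
    if (is.null(fallback)) {
      stop("reference group mean is zero and no fallback group given")
    }
    used <- fallback
    m <- grp_mean(fallback)
    switched <- TRUE
    if (abs(m) <= eps) {
      stop("undefined reference: both '", reference, "' and '", fallback,
           "' have zero mean")
    }
  }
  structure(list(percent = 100 * values / m, reference_group = used,
                 reference_mean = m, switched = switched),
            class = "relative_abundance")
}

#' Composite total alpha-synuclein abundance
#'
#' The "ALL" measure: arithmetic sum of mouse, human and phosphorylated
#' (pSer129) alpha-synuclein abundances on a common scale. Missing
#' components are an error; nothing is imputed.
#'
#' @param mouse,human,pser129 Numeric vectors of equal length on a common
#'   normalized scale (typically percent-of-reference).
#' @return Numeric vector of sums.
#' @export
total_alpha_syn <- function(mouse, human, pser129) {
  if (length(mouse) != length(human) || length(mouse) != length(pser129)) {
    stop("components must have equal length")
  }
  if (anyNA(mouse) || anyNA(human) || anyNA(pser129)) {
    stop("missing component value; no imputation is performed")
  }
  mouse + human + pser129
}
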