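# Retinal layer thickness summaries over an ETDRS-style annulus.
#
# The five segmented layers used throughout: inner to outer.
OCT_LAYERS <- c("RNFL", "GCIPL", "INL", "OPL", "ONL")

#' Retinal thickness grid
#'
#' Per-layer thickness rasters on a shared regular grid. Matrices are
#' indexed `[ix, iy]`: rows follow `x`, columns follow `y`. Total retinal
#' thickness (TRT, ILM to OLM) is always derived as the sum of the five
#' layers, never stored.
#'
#' @param x,y Strictly increasing pixel-center coordinates, mm; the scan
#'   center is at (0, 0).
#' @param layers Named list of thickness matrices (micrometers,
#'   non-negative, NA allowed) with `dim = c(length(x), length(y))`; must
#'   include RNFL, GCIPL, INL, OPL, ONL.
#' @return An object of class `"thickness_grid"`.
#' @export
thickness_grid <- function(x, y, layers) {
  stopifnot(is.numeric(x), is.numeric(y), all(diff(x) > 0),
            all(diff(y) > 0), is.list(layers), length(layers) > 0,
            !is.null(names(layers)))
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || !all(dim(m) == c(length(x), length(y)))) {
      stop("layer ", nm, " must be a length(x) x length(y) matrix")
    }
    if (any(m < 0, na.rm = TRUE)) stop("layer ", nm,
                                       " has negative thickness")
  }
  structure(list(x = x, y = y, layers = layers), class = "thickness_grid")
}

#' Layer thicknesses from segmentation boundary surfaces
#'
#' Converts an ordered stack of boundary surfaces (axial depth in
#' micrometers, inner to outer) into per-layer thicknesses by adjacent
#' differencing.
#'
#' @param surfaces List of `length(x) x length(y)` depth matrices,
#'   ordered inner to outer (e.g. ILM first); length must be one more
#'   than the number of layers.
#' @param x,y Pixel-center coordinates, mm.
#' @param layer_names Names of the resulting layers; default the five
#'   standard layers when six surfaces are given.
#' @return A [thickness_grid()].
#' @export
thickness_from_boundaries <- function(surfaces, x, y,
                                      layer_names = OCT_LAYERS) {
  if (length(surfaces) != length(layer_names) + 1L) {
    stop("need exactly one more surface than layers")
  }
  layers <- vector("list", length(layer_names))
  names(layers) <- layer_names
  for (l in seq_along(layer_names)) {
    d <- surfaces[[l + 1L]] - surfaces[[l]]
    bad <- which(d < 0)
    if (length(bad)) {
      stop("segmentation integrity: surfaces ", l, " and ", l + 1L,
           " (", layer_names[l], ") cross at ", length(bad),
           " pixel(s), first at index ", bad[1L])
    }
    layers[[l]] <- d
  }
  thickness_grid(x, y, layers)
}

#' Annulus specification
#'
#' An annulus centered on a retinal landmark (here the optic nerve
#' head), defaulting to the ETDRS outer ring: the 3-6 mm diameter band.
#'
#' @param center Annulus center, mm pair (default scan center `c(0, 0)`).
#' @param inner_diameter,outer_diameter Diameters in mm,
#'   `0 <= inner < outer`; defaults 3 and 6.
#' @return An object of class `"annulus_spec"`.
#' @export
annulus_spec <- function(center = c(0, 0), inner_diameter = 3,
                         outer_diameter = 6) {
  stopifnot(length(center) == 2L, is.numeric(center),
            inner_diameter >= 0, outer_diameter > inner_diameter)
  structure(list(center = center, inner_diameter = inner_diameter,
                 outer_diameter = outer_diameter), class = "annulus_spec")
}

annulus_mask <- function(grid, annulus) {
  r <- sqrt(outer((grid$x - annulus$center[1])^2,
                  (grid$y - annulus$center[2])^2, `+`))
  r >= annulus$inner_diameter / 2 & r < annulus$outer_diameter / 2
}

#' Mean layer thickness over an annulus
#'
#' Pixels are included when their centers fall in the half-open radial
#' band `[inner/2, outer/2)`; on a regular raster each pixel carries
#' equal area, so the area-weighted mean is the plain mean over included
#' pixels. NA pixels are excluded and counted.
#'
#' @param grid A [thickness_grid()].
#' @param annulus An [annulus_spec()].
#' @param layer Layer name present in `grid`.
#' @return Mean thickness in micrometers, with attributes
#'   `n_pixels_used` and `n_na_excluded`.
#' @export
annulus_mean <- function(grid, annulus, layer) {
  stopifnot(inherits(grid, "thickness_grid"),
            inherits(annulus, "annulus_spec"))
  if (!layer %in% names(grid$layers)) {
    stop("layer ", layer, " not present in grid")
  }
  mask <- annulus_mask(grid, annulus)
  if (!any(mask)) stop("annulus does not intersect the grid")
  vals <- grid$layers[[layer]][mask]
  ok <- !is.na(vals)
  if (!any(ok)) stop("annulus contains no finite pixels for layer ", layer)
  structure(mean(vals[ok]), n_pixels_used = sum(ok),
            n_na_excluded = sum(!ok))
}

#' Summarize all layers over an annulus
#'
#' Annulus means for the five standard layers plus the derived total
#' retinal thickness (TRT, ILM to OLM) as the sum of the layer means.
#'
#' @param grid A [thickness_grid()]; must contain RNFL, GCIPL, INL, OPL
#'   and ONL.
#' @param annulus An [annulus_spec()].
#' @return Object of class `"layer_summary"`: named list of per-layer
#'   means (micrometers), `trt`, and `n_pixels_used`.
#' @export
summarize_layers <- function(grid, annulus = annulus_spec()) {
  missing <- setdiff(OCT_LAYERS, names(grid$layers))
  if (length(missing)) {
    stop("missing layer(s): ", paste(missing, collapse = ", "))
  }
  means <- vapply(OCT_LAYERS, function(l)
    as.numeric(annulus_mean(grid, annulus, l)), 0)
  n_used <- attr(annulus_mean(grid, annulus, OCT_LAYERS[1]),
                 "n_pixels_used")
  structure(list(layers = means, trt = sum(means),
                 n_pixels_used = n_used, annulus = annulus),
            class = "layer_summary")
}

#' @export
print.layer_summary <- function(x, ...) {
  cat(sprintf("Layer summary over %g-%g mm annulus (%d pixels):\n",
              x$annulus$inner_diameter, x$annulus$outer_diameter,
              x$n_pixels_used))
  for (l in names(x$layers)) {
    cat(sprintf("  %-6s %7.2f um\n", l, x$layers[[l]]))
  }
  cat(sprintf("  %-6s %7.2f um\n", "TRT", x$trt))
  invisible(x)
}

#' Read a thickness grid from a long-form delimited table
#'
#' Expects tab- or comma-delimited columns `x_mm`, `y_mm`, `layer`,
#' `thickness_um`, one row per pixel per layer, covering a full regular
#' raster.
#'
#' @param file Path to the table.
#' @return A [thickness_grid()].
#' @export
read_thickness_grid <- function(file) {
  tab <- utils::read.delim(file, sep = "", check.names = TRUE)
  if (ncol(tab) == 1L) tab <- utils::read.csv(file)
  need <- c("x_mm", "y_mm", "layer", "thickness_um")
  if (!all(need %in% names(tab))) {
    stop("grid table must have columns: ", paste(need, collapse = ", "))
  }
  x <- sort(unique(tab$x_mm))
  y <- sort(unique(tab$y_mm))
  layers <- lapply(split(tab, tab$layer), function(d) {
    m <- matrix(NA_real_, length(x), length(y))
    m[cbind(match(d$x_mm, x), match(d$y_mm, y))] <- d$thickness_um
    m
  })
  thickness_grid(x, y, layers)
}

#' Write one or more layer summaries as a delimited table
#'
#' @param summaries A single [summarize_layers()] result or a named list
#'   of them (names become the `eye` column).
#' @param file Output path (tab-delimited).
#' @return `file`, invisibly.
#' @export
write_layer_summary <- function(summaries, file) {
  if (inherits(summaries, "layer_summary")) {
    summaries <- list(eye = summaries)
  }
  rows <- lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(eye = nm, t(s$layers), TRT = s$trt,
               n_pixels = s$n_pixels_used)
  })
  utils::write.table(do.call(rbind, rows), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
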