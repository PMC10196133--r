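#' Acquisition timebase for ERG recordings
#'
#' Describes the uniform sampling of an ERG trace: sampling rate, record
#' duration and the sample index of flash onset. The default matches a
#' 4 kHz acquisition over 640 ms with a 50 ms pre-stimulus baseline.
#'
#' @param sampling_rate Samples per second (> 0). Default 4000.
#' @param duration Record length in seconds (> 0). Default 0.640.
#' @param onset_index 0-based sample index of flash onset; must lie within
#'   the record. Default 200 (50 ms at 4 kHz), leaving a pre-stimulus
#'   baseline for peak referencing.
#'
#' @return An object of class `"timebase"`: a list with the three fields
#'   plus `n_samples`.
#' @export
#' @examples
#' tb <- timebase()
#' tb$n_samples  # 2560
timebase <- function(sampling_rate = 4000, duration = 0.640,
                     onset_index = 200L) {
  stopifnot(is.numeric(sampling_rate), length(sampling_rate) == 1L,
            is.finite(sampling_rate), sampling_rate > 0,
            is.numeric(duration), length(duration) == 1L,
            is.finite(duration), duration > 0)
  n <- as.integer(round(sampling_rate * duration))
  onset_index <- as.integer(onset_index)
  if (onset_index < 0L || onset_index >= n) {
    stop("onset_index must lie in [0, n_samples)")
  }
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 onset_index = onset_index, n_samples = n),
            class = "timebase")
}

#' Sample times of a timebase
#'
#' @param tb A [timebase()].
#' @param from_onset If `TRUE` (default), times are seconds relative to
#'   flash onset (negative during the pre-stimulus baseline); otherwise
#'   seconds from the start of the record.
#' @return Numeric vector of length `tb$n_samples`.
#' @export
time_axis <- function(tb, from_onset = TRUE) {
  t <- (seq_len(tb$n_samples) - 1L) / tb$sampling_rate
  if (from_onset) t <- t - tb$onset_index / tb$sampling_rate
  t
}

#' Flash stimulus descriptor
#'
#' @param log_energy Flash luminous energy, log10 cd.s/m^2.
#' @param adaptation `"dark"` or `"light"`.
#' @return An object of class `"flash_stimulus"`.
#' @export
flash_stimulus <- function(log_energy, adaptation = c("dark", "light")) {
  adaptation <- match.arg(adaptation)
  stopifnot(is.numeric(log_energy), length(log_energy) == 1L,
            is.finite(log_energy))
  structure(list(log_energy = log_energy, adaptation = adaptation),
            class = "flash_stimulus")
}

#' Single ERG waveform
#'
#' @param samples Voltage trace in microvolts, one value per sample of `tb`.
#' @param stimulus A [flash_stimulus()].
#' @param tb A [timebase()].
#' @return An object of class `"erg_waveform"`.
#' @export
erg_waveform <- function(samples, stimulus, tb) {
  stopifnot(inherits(tb, "timebase"), inherits(stimulus, "flash_stimulus"))
  samples <- as.numeric(samples)
  if (length(samples) != tb$n_samples) {
    stop("samples length (", length(samples), ") != timebase n_samples (",
         tb$n_samples, ")")
  }
  if (!all(is.finite(samples))) stop("samples must all be finite")
  structure(list(timebase = tb, stimulus = stimulus, samples = samples),
            class = "erg_waveform")
}

#' @export
print.erg_waveform <- function(x, ...) {
  cat(sprintf("ERG waveform: %s-adapted, %.2f log cd.s/m^2, %d samples @ %g Hz\n",
              x$stimulus$adaptation, x$stimulus$log_energy,
              x$timebase$n_samples, x$timebase$sampling_rate))
  invisible(x)
}

#' Family of ERG waveforms sharing one timebase
#'
#' Waveforms are stored sorted by adaptation state then ascending
#' log energy; duplicate (adaptation, energy) keys are rejected.
#'
#' @param waveforms List of [erg_waveform()] objects on a common timebase.
#' @return An object of class `"waveform_family"`.
#' @export
waveform_family <- function(waveforms) {
  if (length(waveforms) == 0L) stop("waveform family must be non-empty")
  stopifnot(all(vapply(waveforms, inherits, TRUE, "erg_waveform")))
  tb0 <- waveforms[[1L]]$timebase
  same <- vapply(waveforms, function(w)
    identical(unclass(w$timebase), unclass(tb0)), TRUE)
  if (!all(same)) stop("all waveforms must share one timebase")
  adap <- vapply(waveforms, function(w) w$stimulus$adaptation, "")
  en <- vapply(waveforms, function(w) w$stimulus$log_energy, 0)
  key <- paste(adap, formatC(en, format = "f", digits = 6))
  if (anyDuplicated(key)) {
    stop("duplicate (adaptation, log_energy) keys in family")
  }
  ord <- order(adap, en)
  structure(list(waveforms = waveforms[ord], timebase = tb0),
            class = "waveform_family")
}

#' @export
print.waveform_family <- function(x, ...) {
  adap <- family_adaptations(x)
  en <- family_energies(x)
  cat(sprintf("ERG waveform family: %d flashes (%d dark, %d light)\n",
              length(x$waveforms), sum(adap == "dark"), sum(adap == "light")))
  for (a in unique(adap)) {
    cat(sprintf("  %s: %s log cd.s/m^2\n", a,
                paste(format(en[adap == a]), collapse = ", ")))
  }
  invisible(x)
}

#' @export
length.waveform_family <- function(x) length(x$waveforms)

family_energies <- function(family) {
  vapply(family$waveforms, function(w) w$stimulus$log_energy, 0)
}

family_adaptations <- function(family) {
  vapply(family$waveforms, function(w) w$stimulus$adaptation, "")
}

#' Retrieve one waveform from a family by stimulus key
#'
#' @param family A [waveform_family()].
#' @param log_energy Flash energy, log10 cd.s/m^2 (matched to 1e-6).
#' @param adaptation `"dark"` or `"light"`.
#' @return The matching [erg_waveform()].
#' @export
family_get <- function(family, log_energy, adaptation = "dark") {
  hit <- which(family_adaptations(family) == adaptation &
                 abs(family_energies(family) - log_energy) < 1e-6)
  if (length(hit) != 1L) {
    stop(sprintf("no %s-adapted flash at %.2f log cd.s/m^2 in family",
                 adaptation, log_energy))
  }
  family$waveforms[[hit]]
}

#' Keep only one adaptation state of a family
#'
#' @param family A [waveform_family()].
#' @param adaptation `"dark"` or `"light"`.
#' @return A [waveform_family()], or `NULL` if no flash matches.
#' @export
family_subset <- function(family, adaptation) {
  keep <- family_adaptations(family) == adaptation
  if (!any(keep)) return(NULL)
  waveform_family(family$waveforms[keep])
}

#' Write a waveform family as a delimited table
#'
#' Column 1 is `time_s` (seconds from record start); remaining columns are
#' named `dark_-5.01`, `light_2.72`, ... by adaptation state and log flash
#' energy. A sidecar `<file>.meta` records sampling rate, duration and
#' onset index as `key<TAB>value` lines.
#'
#' @param family A [waveform_family()].
#' @param file Output path for the tab-delimited table.
#' @param meta Optional named list of extra metadata written to the sidecar
#'   (e.g. seed, ground-truth parameters); values are deparsed one per line.
#' @return `file`, invisibly.
#' @export
write_waveforms <- function(family, file, meta = list()) {
  tb <- family$timebase
  tab <- data.frame(time_s = (seq_len(tb$n_samples) - 1L) / tb$sampling_rate)
  for (w in family$waveforms) {
    nm <- sprintf("%s_%s", w$stimulus$adaptation,
                  formatC(w$stimulus$log_energy, format = "g"))
    tab[[nm]] <- w$samples
  }
  utils::write.table(tab, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  side <- c(sampling_rate = tb$sampling_rate, duration = tb$duration,
            onset_index = tb$onset_index)
  lines <- paste(names(side), side, sep = "\t")
  if (length(meta)) {
    lines <- c(lines, paste(names(meta),
                            vapply(meta, function(v)
                              paste(deparse(v), collapse = " "), ""),
                            sep = "\t"))
  }
  writeLines(lines, paste0(file, ".meta"))
  invisible(file)
}

#' Read a waveform family written by [write_waveforms()]
#'
#' @param file Path to the tab-delimited waveform table; the
#'   `<file>.meta` sidecar must exist alongside it.
#' @return A [waveform_family()].
#' @export
read_waveforms <- function(file) {
  tab <- utils::read.delim(file, check.names = FALSE)
  meta_file <- paste0(file, ".meta")
  if (!file.exists(meta_file)) stop("missing sidecar file: ", meta_file)
  kv <- utils::read.delim(meta_file, header = FALSE,
                          col.names = c("key", "value"),
                          colClasses = "character")
  get_num <- function(k) as.numeric(kv$value[match(k, kv$key)])
  tb <- timebase(get_num("sampling_rate"), get_num("duration"),
                 get_num("onset_index"))
  cols <- setdiff(names(tab), "time_s")
  waves <- lapply(cols, function(nm) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1L]]
    erg_waveform(tab[[nm]],
                 flash_stimulus(as.numeric(paste(parts[-1L], collapse = "_")),
                                parts[1L]),
                 tb)
  })
  waveform_family(waves)
}
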