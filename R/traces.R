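# Trace containers and plain-text I/O.

#' Construct a set of intensity time traces
#'
#' @param times Numeric vector of acquisition times (seconds), strictly
#'   increasing.
#' @param intensities Numeric matrix, one column per species (named), one row
#'   per time point; intensities must be non-negative.
#' @return An object of class `time_traces`.
#' @export
time_traces <- function(times, intensities) {
  times <- as.numeric(times)
  intensities <- as.matrix(intensities)
  if (is.null(colnames(intensities)) || anyDuplicated(colnames(intensities)))
    .stop_validation("intensities must have unique column names")
  if (nrow(intensities) != length(times))
    .stop_validation("times and intensities have different lengths")
  if (length(times) > 1 && any(diff(times) <= 0))
    .stop_validation("times must be strictly increasing")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    .stop_validation("intensities must be finite and non-negative")
  structure(list(times = times, intensities = intensities),
            class = "time_traces")
}

#' @export
print.time_traces <- function(x, ...) {
  cat(sprintf("Time traces: %d points x %d species (%s), t = [%g, %g] s\n",
              length(x$times), ncol(x$intensities),
              paste(colnames(x$intensities), collapse = ", "),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Construct normalized relative-intensity traces
#'
#' The DRL observable: per time point, the fraction of each species within a
#' normalization group.  Fractions at unmasked time points sum to 1.
#'
#' @param times Times in seconds.
#' @param fractions Matrix of per-species fractions (named columns).
#' @param group_id Label of the normalization group.
#' @param t_L Labelled-ligand addition time carried along for fitting
#'   (`NA` when unknown).
#' @param masked Integer indices of time points that carried no signal and
#'   were masked (fractions set to `NA`).
#' @return An object of class `relative_traces`.
#' @export
relative_traces <- function(times, fractions, group_id = "group",
                            t_L = NA_real_, masked = integer(0)) {
  times <- as.numeric(times)
  fractions <- as.matrix(fractions)
  if (nrow(fractions) != length(times))
    .stop_validation("times and fractions have different lengths")
  ok <- setdiff(seq_along(times), masked)
  sums <- rowSums(fractions[ok, , drop = FALSE])
  if (any(abs(sums - 1) > 1e-9))
    .stop_validation("fractions must sum to 1 at each unmasked time point")
  if (any(fractions[ok, ] < -1e-12 | fractions[ok, ] > 1 + 1e-12))
    .stop_validation("fractions must lie in [0, 1]")
  structure(list(times = times, fractions = fractions, group_id = group_id,
                 t_L = t_L, masked = as.integer(masked)),
            class = "relative_traces")
}

#' @export
print.relative_traces <- function(x, ...) {
  cat(sprintf("Relative traces [%s]: %d points x %d species (%s)",
              x$group_id, length(x$times), ncol(x$fractions),
              paste(colnames(x$fractions), collapse = ", ")))
  if (length(x$masked)) cat(sprintf(", %d masked", length(x$masked)))
  cat("\n")
  invisible(x)
}

# ---- I/O: long CSV, columns (time_s, species, value-ish) -------------------

#' Write/read intensity traces as long CSV
#'
#' Columns `time_s, species, intensity`.
#' @param traces A [time_traces()] object.
#' @param path File path.
#' @return `write_time_traces` returns `path` invisibly; `read_time_traces`
#'   returns a [time_traces()].
#' @export
write_time_traces <- function(traces, path) {
  stopifnot(inherits(traces, "time_traces"))
  sp <- colnames(traces$intensities)
  df <- data.frame(
    time_s = rep(traces$times, times = length(sp)),
    species = rep(sp, each = length(traces$times)),
    intensity = as.vector(traces$intensities))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_time_traces
#' @export
read_time_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "species", "intensity")
  if (!all(need %in% names(df)))
    .stop_validation("trace CSV must have columns: ", paste(need, collapse = ", "))
  times <- sort(unique(df$time_s))
  sp <- unique(df$species)
  m <- matrix(NA_real_, length(times), length(sp), dimnames = list(NULL, sp))
  m[cbind(match(df$time_s, times), match(df$species, sp))] <- df$intensity
  if (anyNA(m)) .stop_validation("trace CSV is not a complete time x species grid")
  time_traces(times, m)
}

#' Write/read centroided peak-list series as CSV
#'
#' Columns `time_s, mz, intensity`; one row per centroided peak per scan.
#' @param peaks A `peak_list_series` data frame.
#' @param path File path.
#' @return `read_peak_list` returns a `peak_list_series` data frame.
#' @export
write_peak_list <- function(peaks, path) {
  stopifnot(is.data.frame(peaks))
  utils::write.csv(peaks[, c("time_s", "mz", "intensity")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peak_list
#' @export
read_peak_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "mz", "intensity")
  if (!all(need %in% names(df)))
    .stop_validation("peak-list CSV must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) .stop_validation("peak-list CSV is empty")
  class(df) <- c("peak_list_series", "data.frame")
  df
}

#' Write/read relative traces as long CSV
#'
#' Columns `time_s, species, fraction`; masked time points are written with
#' `NA` fractions and restored on reading.
#' @param rel A [relative_traces()] object.
#' @param path File path.
#' @param group_id,t_L Metadata applied on reading.
#' @return `read_relative_traces` returns a [relative_traces()].
#' @export
write_relative_traces <- function(rel, path) {
  stopifnot(inherits(rel, "relative_traces"))
  sp <- colnames(rel$fractions)
  frac <- rel$fractions
  if (length(rel$masked)) frac[rel$masked, ] <- NA_real_
  df <- data.frame(
    time_s = rep(rel$times, times = length(sp)),
    species = rep(sp, each = length(rel$times)),
    fraction = as.vector(frac))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_relative_traces
#' @export
read_relative_traces <- function(path, group_id = "group", t_L = NA_real_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "species", "fraction")
  if (!all(need %in% names(df)))
    .stop_validation("relative-trace CSV must have columns: ",
                     paste(need, collapse = ", "))
  times <- sort(unique(df$time_s))
  sp <- unique(df$species)
  m <- matrix(NA_real_, length(times), length(sp), dimnames = list(NULL, sp))
  m[cbind(match(df$time_s, times), match(df$species, sp))] <- df$fraction
  masked <- which(apply(m, 1L, function(r) all(is.na(r))))
  relative_traces(times, m, group_id = group_id, t_L = t_L, masked = masked)
}
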