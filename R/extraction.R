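# From raw peak-list series to the normalized DRL observable: XIC
# extraction, optional isotope-envelope overlap correction, group
# normalization, and the bis-complex renormalization.

#' Extract ion chronograms from a peak-list series
#'
#' Per time point, peak intensities with `|mz - target| <= half_width` are
#' summed into each window's trace.  Windows are closed intervals: a peak
#' exactly on the boundary is included.
#'
#' @param peaklists A `peak_list_series` data frame (`time_s, mz, intensity`),
#'   e.g. from [read_peak_list()] or [render_spectra()].
#' @param windows A list of [xic_window()] (a single window is accepted).
#' @return A [time_traces()] with one column per window's species label.
#' @export
extract_xic <- function(peaklists, windows) {
  if (!is.data.frame(peaklists) || nrow(peaklists) == 0L)
    .stop_validation("peaklists must be a non-empty peak_list_series")
  if (inherits(windows, "xic_window")) windows <- list(windows)
  labels <- vapply(windows, function(w) w$species, character(1))
  if (anyDuplicated(labels)) .stop_validation("window species labels must be unique")
  times <- sort(unique(peaklists$time_s))
  idx <- match(peaklists$time_s, times)
  m <- matrix(0, length(times), length(windows),
              dimnames = list(NULL, labels))
  for (j in seq_along(windows)) {
    w <- windows[[j]]
    inw <- abs(peaklists$mz - w$target_mz) <= w$half_width
    if (any(inw)) {
      rs <- rowsum(peaklists$intensity[inw], idx[inw])
      m[as.integer(rownames(rs)), j] <- rs[, 1L]
    }
  }
  time_traces(times, m)
}

#' Mixing matrix of isotope-envelope overlap between extraction windows
#'
#' Entry `[i, j]` is the fraction of species `j`'s isotope envelope that
#' falls inside window `i`, so `observed = mixing %*% true` per time point.
#'
#' @param species List of [species_spec()] with formulas or patterns.
#' @param windows List of [xic_window()], same length and order as the true
#'   species they are meant to capture.
#' @param abundance_floor Passed to [isotope_pattern()].
#' @return A square matrix with window labels as rownames and species names
#'   as colnames.
#' @export
overlap_matrix <- function(species, windows, abundance_floor = 1e-6) {
  if (inherits(species, "species_spec")) species <- list(species)
  if (inherits(windows, "xic_window")) windows <- list(windows)
  if (length(species) != length(windows))
    .stop_validation("need one window per species")
  M <- matrix(0, length(windows), length(species),
              dimnames = list(vapply(windows, function(w) w$species, character(1)),
                              vapply(species, function(s) s$name, character(1))))
  for (j in seq_along(species)) {
    s <- species[[j]]
    pat <- if (!is.null(s$pattern)) s$pattern
           else if (!is.null(s$formula)) isotope_pattern(s$formula, abundance_floor)
           else .stop_validation("species ", s$name, " has neither formula nor pattern")
    mzs <- s$mz + pat$offsets / s$charge
    for (i in seq_along(windows)) {
      w <- windows[[i]]
      M[i, j] <- sum(pat$abundances[abs(mzs - w$target_mz) <= w$half_width])
    }
  }
  M
}

#' Correct extracted traces for isotope-envelope overlap
#'
#' Solves the non-negative linear system `observed = mixing %*% true` for
#' the true species intensities at every time point (non-negative least
#' squares), undoing e.g. the bleed of a light species' M+5 line into the
#' window of its 5 Da-shifted labelled partner.
#'
#' @param traces Observed [time_traces()]; columns must match the mixing
#'   matrix rownames.
#' @param mixing Square mixing matrix, e.g. from [overlap_matrix()]; must be
#'   diagonally dominant by columns (each species lands mostly in its own
#'   window) and well-conditioned.
#' @return A [time_traces()] of corrected intensities, columns named after
#'   the mixing matrix colnames.
#' @export
correct_overlap <- function(traces, mixing) {
  stopifnot(inherits(traces, "time_traces"))
  mixing <- as.matrix(mixing)
  if (nrow(mixing) != ncol(mixing))
    .stop_validation("mixing matrix must be square")
  if (is.null(rownames(mixing)) || is.null(colnames(mixing)))
    .stop_validation("mixing matrix needs window rownames and species colnames")
  if (!all(rownames(mixing) %in% colnames(traces$intensities)))
    .stop_validation("traces lack windows: ",
                     paste(setdiff(rownames(mixing),
                                   colnames(traces$intensities)), collapse = ", "))
  dd <- diag(mixing) > colSums(abs(mixing)) - abs(diag(mixing))
  if (!all(dd))
    .stop_validation("mixing matrix is not diagonally dominant")
  kappa <- kappa(mixing, exact = TRUE)
  if (!is.finite(kappa) || kappa > 1e8)
    .stop_numerical("mixing matrix is singular or ill-conditioned (kappa = ",
                    format(kappa), ")")
  obs <- traces$intensities[, rownames(mixing), drop = FALSE]
  true <- t(apply(obs, 1L, function(b) pracma::lsqnonneg(mixing, b)$x))
  colnames(true) <- colnames(mixing)
  time_traces(traces$times, true)
}

#' Normalize a species group into relative-intensity traces
#'
#' The DRL observable: per time point, each species' share of the group
#' total.  Common-mode intensity factors (spray drift, infusion rate)
#' cancel.  Time points where the whole group is zero carry no information
#' and are masked (with a message), not silently dropped.
#'
#' @param traces A [time_traces()].
#' @param group Character vector of species (column) names to normalize
#'   together.
#' @param group_id Label for the group (defaults to the joined names).
#' @param t_L Addition time attached for downstream fitting.
#' @return A [relative_traces()]; masked indices are recorded in `$masked`.
#' @export
normalize_group <- function(traces, group, group_id = NULL, t_L = NA_real_) {
  stopifnot(inherits(traces, "time_traces"))
  group <- as.character(group)
  missing_sp <- setdiff(group, colnames(traces$intensities))
  if (length(missing_sp))
    .stop_validation("traces lack species: ", paste(missing_sp, collapse = ", "))
  if (is.null(group_id)) group_id <- paste(group, collapse = "+")
  m <- traces$intensities[, group, drop = FALSE]
  tot <- rowSums(m)
  masked <- which(tot <= 0)
  frac <- m / tot
  if (length(masked)) {
    frac[masked, ] <- NA_real_
    message(sprintf("normalize_group [%s]: masked %d zero-signal time point(s)",
                    group_id, length(masked)))
  }
  relative_traces(traces$times, frac, group_id = group_id, t_L = t_L,
                  masked = masked)
}

#' Renormalize a bis-complex pair, excluding the mixed species
#'
#' For a two-site host the fully-unlabelled (`PP`) and fully-labelled (`LL`)
#' complexes are renormalized together, leaving out the mixed (`PL`)
#' species.  Once the fast site has equilibrated, this pair relaxes with the
#' slow site's dissociation rate, so a first-order fit of the renormalized
#' traces recovers it.  Meaningful when the two sites' rates are well
#' separated; with comparable rates the renormalized trace is not
#' single-exponential.
#'
#' @param traces A [time_traces()].
#' @param species_a,species_b The two column names (e.g. the `PP` and `LL`
#'   ions' traces).
#' @inheritParams normalize_group
#' @return A [relative_traces()] over the two species.
#' @export
renormalize_pair <- function(traces, species_a, species_b, t_L = NA_real_) {
  normalize_group(traces, c(species_a, species_b),
                  group_id = paste0("renorm:", species_a, "/", species_b),
                  t_L = t_L)
}
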