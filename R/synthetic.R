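# Synthetic DRL datasets: noisy intensity traces and centroided peak-list
# series with isotope envelopes, generated from known ground truth.

#' Parse an elemental formula
#'
#' @param formula Either a named count vector (`c(C = 5, H = 5, N = 1)`) or a
#'   Hill-style string (`"C5H5N"`).  `D` denotes deuterium explicitly.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (is.null(names(formula)) || any(!nzchar(names(formula))))
      .stop_validation("numeric formula must be a named count vector")
    counts <- formula
  } else if (is.character(formula) && length(formula) == 1L) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1L]]
    parts <- regmatches(formula, list(m))[[1L]]
    parts <- parts[nzchar(parts)]
    if (!nzchar(formula) || sum(nchar(parts)) != nchar(formula))
      .stop_validation("cannot parse formula string: ", formula)
    el <- sub("[0-9]*$", "", parts)
    n <- sub("^[A-Za-z]+", "", parts)
    counts <- stats::setNames(ifelse(nzchar(n), as.numeric(n), 1), el)
    counts <- tapply(counts, names(counts), sum)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  } else {
    .stop_validation("formula must be a named numeric vector or a string")
  }
  if (any(counts < 0) || any(counts != round(counts)))
    .stop_validation("element counts must be non-negative integers")
  counts[counts > 0]
}

#' Aggregated (nominal-mass) isotope pattern of a formula
#'
#' Convolves per-element binomial/multinomial distributions of the natural
#' isotope abundances (IUPAC 2021 representative values, compiled into the
#' package) at unit mass offsets, truncates lines below `abundance_floor`
#' and renormalizes.  Nominal-mass aggregation is all the DRL observable
#' needs: the relevant interference is envelope overlap at a 5 Da label
#' shift, not fine structure.
#'
#' @param formula A formula accepted by [parse_formula()].  Known elements:
#'   C, H, D, N, O, Cl, Co, P, F.
#' @param abundance_floor Lines below this fraction are dropped
#'   (in `[0, 1)`).
#' @return An `isotope_pattern`: list of integer `offsets` (Da from the
#'   monoisotopic mass) and `abundances` summing to 1.
#' @examples
#' isotope_pattern(c(C = 1))           # M+1 at the 13C abundance
#' isotope_pattern("C44H30CoN4O4")
#' @export
isotope_pattern <- function(formula, abundance_floor = 1e-6) {
  counts <- parse_formula(formula)
  if (abundance_floor < 0 || abundance_floor >= 1)
    .stop_validation("abundance_floor must lie in [0, 1)")
  unknown <- setdiff(names(counts), names(.iso_abundances))
  if (length(unknown))
    .stop_validation("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  pat <- 1
  for (el in names(counts)) {
    base <- .iso_abundances[[el]]
    for (i in seq_len(counts[[el]])) pat <- .convolve_pattern(pat, base)
  }
  keep <- pat >= abundance_floor & pat > 0
  keep[1L] <- TRUE                       # never drop the monoisotopic line
  offsets <- which(keep) - 1L
  ab <- pat[keep]
  structure(list(offsets = offsets, abundances = ab / sum(ab)),
            class = "isotope_pattern")
}

.convolve_pattern <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (j in seq_along(b))
    out[j:(j + length(a) - 1L)] <- out[j:(j + length(a) - 1L)] + a * b[j]
  out
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("Isotope pattern (nominal mass):\n")
  for (i in seq_along(x$offsets))
    cat(sprintf("  M+%d  %.5f\n", x$offsets[i], x$abundances[i]))
  invisible(x)
}

#' Generate a synthetic DRL dataset from known ground truth
#'
#' Simulates the exchange scheme (single- or two-site, chosen by the class
#' of `truth`), maps the observable classes onto ion species, scales
#' concentrations into intensities, and applies the noise model: a
#' log-normal common-mode spray-drift factor shared by all species at a time
#' point, intensity-proportional (shot-like) noise, and additive baseline
#' noise; negative intensities are clipped at the detector floor (0).
#' Seeded runs are bit-reproducible.
#'
#' @param truth A [rate_constants()] or [two_site_rate_constants()].
#' @param comp A [solution_composition()].
#' @param species List of [species_spec()]; their `class` fields must map
#'   one-to-one onto the model's observable classes (`unlabelled`/`labelled`
#'   or `PP`/`PL`/`LL`).
#' @param noise A [noise_model()].
#' @param times Acquisition grid (seconds).
#' @param scale Intensity per mol/L of complex (arbitrary detector counts).
#' @param cross_contamination Fraction of bis-complex signal fragmenting into
#'   the 1:1 channels after ion selection (two-site truth only; requires
#'   species of class `unlabelled`/`labelled` to receive it, with a
#'   50/50 split of the mixed `PL` state).
#' @return A [time_traces()] with one column per species name; the
#'   trajectory and noise-free intensities are attached as attributes
#'   `trajectory` and `clean`.
#' @export
generate_drl_dataset <- function(truth, comp, species, noise = noise_model(),
                                 times = NULL, scale = 1e11,
                                 cross_contamination = 0) {
  stopifnot(inherits(comp, "solution_composition"),
            inherits(noise, "noise_model"))
  if (inherits(species, "species_spec")) species <- list(species)
  if (is.null(times)) {
    k_slow <- if (inherits(truth, "rate_constants")) truth$k_off
              else truth$inner$k_off
    span <- 5 / k_slow
    times <- seq(comp$t_L, comp$t_L + span, length.out = 601L)
  }
  traj <- if (inherits(truth, "rate_constants")) {
    simulate_single_site(truth, comp, times)
  } else if (inherits(truth, "two_site_rate_constants")) {
    simulate_two_site(truth, comp, times)
  } else {
    .stop_validation("truth must be rate_constants or two_site_rate_constants")
  }
  classes <- names(traj$classes)
  sp_class <- vapply(species, function(s) s$class, character(1))
  sp_name <- vapply(species, function(s) s$name, character(1))
  extra <- if (traj$model == "two_site" && cross_contamination > 0)
    c("unlabelled", "labelled") else character(0)
  bad <- setdiff(sp_class, c(classes, extra))
  if (length(bad))
    .stop_validation("species class(es) not among model observables: ",
                     paste(unique(bad), collapse = ", "))
  if (anyDuplicated(sp_class))
    .stop_validation("species must map one-to-one onto observable classes")

  conc <- vapply(classes, function(cl)
    rowSums(traj$species[, traj$classes[[cl]], drop = FALSE]),
    numeric(length(traj$times)))
  if (length(extra)) {
    frag <- cross_contamination
    conc <- cbind(conc,
                  unlabelled = frag * (conc[, "PP"] + 0.5 * conc[, "PL"]),
                  labelled = frag * (conc[, "LL"] + 0.5 * conc[, "PL"]))
    conc[, c("PP", "PL", "LL")] <- (1 - frag) * conc[, c("PP", "PL", "LL")]
  }
  clean <- vapply(seq_along(species), function(i)
    scale * species[[i]]$response_factor * conc[, sp_class[i]],
    numeric(length(traj$times)))
  colnames(clean) <- sp_name

  withr_seed <- noise$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(withr_seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  nt <- nrow(clean)
  drift <- if (noise$spray_drift_sd > 0)
    exp(stats::rnorm(nt, 0, noise$spray_drift_sd)) else rep(1, nt)
  intens <- clean * drift
  if (noise$shot_scale > 0)
    intens <- intens + stats::rnorm(length(intens),
                                    sd = sqrt(noise$shot_scale * pmax(intens, 0)))
  if (noise$additive_sd > 0)
    intens <- intens + stats::rnorm(length(intens), sd = noise$additive_sd)
  intens[intens < 0] <- 0

  out <- time_traces(traj$times, intens)
  attr(out, "trajectory") <- traj
  attr(out, "clean") <- clean
  out
}

#' Render centroided spectra (peak-list series) from intensity traces
#'
#' Each species contributes peaks at `mz + offset / charge` for every line of
#' its isotope pattern, with intensity = trace x line abundance.  Peaks from
#' different species falling within `mz_tol` of each other are merged into a
#' single centroid (intensity-weighted position) — this is how a 5 Da-shifted
#' labelled species overlaps the light species' M+5 line.
#'
#' @param traces A [time_traces()] whose columns match the species names.
#' @param species List of [species_spec()]; each needs a `formula` (pattern
#'   computed with [isotope_pattern()]) or an attached `pattern` element.
#' @param mz_tol Centroid merge width, Da (m/z units).
#' @param abundance_floor Passed to [isotope_pattern()].
#' @return A `peak_list_series` data frame (`time_s, mz, intensity`).
#' @export
render_spectra <- function(traces, species, mz_tol = 0.02,
                           abundance_floor = 1e-6) {
  stopifnot(inherits(traces, "time_traces"))
  if (inherits(species, "species_spec")) species <- list(species)
  sp_name <- vapply(species, function(s) s$name, character(1))
  missing_sp <- setdiff(sp_name, colnames(traces$intensities))
  if (length(missing_sp))
    .stop_validation("traces lack species: ", paste(missing_sp, collapse = ", "))
  pats <- lapply(species, function(s) {
    if (!is.null(s$pattern)) return(s$pattern)
    if (is.null(s$formula))
      .stop_validation("species ", s$name, " has neither formula nor pattern")
    isotope_pattern(s$formula, abundance_floor)
  })
  rows <- vector("list", length(species))
  for (i in seq_along(species)) {
    s <- species[[i]]
    pat <- pats[[i]]
    tr <- traces$intensities[, s$name]
    rows[[i]] <- data.frame(
      time_s = rep(traces$times, times = length(pat$offsets)),
      mz = rep(s$mz + pat$offsets / s$charge, each = length(traces$times)),
      intensity = as.vector(outer(tr, pat$abundances)))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$time_s, df$mz), ]
  # merge coincident centroids (e.g. light M+5 under the labelled M+0)
  grp <- cumsum(c(TRUE, diff(df$mz) > mz_tol | diff(df$time_s) != 0))
  inten <- as.vector(tapply(df$intensity, grp, sum))
  mz <- as.vector(tapply(df$mz * df$intensity, grp, sum)) / pmax(inten, .Machine$double.xmin)
  mz0 <- as.vector(tapply(df$mz, grp, mean))  # fallback for zero-intensity groups
  mz[!is.finite(mz) | inten == 0] <- mz0[!is.finite(mz) | inten == 0]
  out <- data.frame(time_s = as.vector(tapply(df$time_s, grp, min)),
                    mz = mz, intensity = inten)
  out <- out[order(out$time_s, out$mz), ]
  rownames(out) <- NULL
  class(out) <- c("peak_list_series", "data.frame")
  out
}
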