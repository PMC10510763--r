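# Domain types: parameter containers with validation, and their print methods.
# Plain lists with S3 classes, in the style of the kinetics/fitting packages
# this builds on (deSolve takes named vectors, minpack.lm takes lists).

.stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("drl_validation_error", "error")))
}

.check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stop_validation(name, " must be a single finite number")
  if (positive && x <= 0) .stop_validation(name, " must be > 0")
  if (nonneg && x < 0) .stop_validation(name, " must be >= 0")
  as.numeric(x)
}

#' Rate constants of the single-site ligand-exchange scheme
#'
#' The exchange of a bound ligand for one from solution is modelled with a
#' second-order association step (rate constant `k_on`, M^-1 s^-1) and a
#' first-order dissociation step (`k_off`, s^-1).  Labelled and unlabelled
#' isotopologues share the same constants (no kinetic isotope effect).
#'
#' @param k_on Association rate constant, per molar per second.
#' @param k_off Dissociation rate constant, per second.
#' @return An object of class `rate_constants`.
#' @examples
#' rate_constants(k_on = 5e4, k_off = 5.4e-4)
#' @export
rate_constants <- function(k_on, k_off) {
  structure(
    list(k_on = .check_scalar(k_on, "k_on", positive = TRUE),
         k_off = .check_scalar(k_off, "k_off", positive = TRUE)),
    class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf("Exchange rate constants: k_on = %.4g M^-1 s^-1, k_off = %.4g s^-1\n",
              x$k_on, x$k_off))
  invisible(x)
}

#' Rate constants for a two-site (bis-complex) host
#'
#' Hosts with two inequivalent binding sites (e.g. inside and outside a cage
#' cavity) exchange the ligand at each site independently.  Each site carries
#' its own [rate_constants()]; in the four-bound-state dynamics only the
#' per-site `k_off` enters (rebinding is taken in the fast, well-mixed limit
#' and draws from the free pools in proportion to their fractions).
#'
#' @param inner Rate constants of the inner (cavity) site.
#' @param outer Rate constants of the outer site.
#' @return An object of class `two_site_rate_constants`.
#' @export
two_site_rate_constants <- function(inner, outer) {
  if (!inherits(inner, "rate_constants") || !inherits(outer, "rate_constants"))
    .stop_validation("inner and outer must be rate_constants objects")
  structure(list(inner = inner, outer = outer), class = "two_site_rate_constants")
}

#' @export
print.two_site_rate_constants <- function(x, ...) {
  cat("Two-site exchange rate constants\n")
  cat(sprintf("  inner: k_off = %.4g s^-1\n", x$inner$k_off))
  cat(sprintf("  outer: k_off = %.4g s^-1\n", x$outer$k_off))
  invisible(x)
}

#' Solution composition of a delayed reactant labelling experiment
#'
#' Describes the three-phase DRL experiment: the host is equilibrated with
#' unlabelled ligand added at `t_u`, then the labelled isotopologue is added
#' at `t_L > t_u` and the system relaxes to an isotope-scrambled equilibrium.
#'
#' @param host_total Total host concentration, mol/L.
#' @param ligand_unlabelled Unlabelled ligand concentration added at `t_u`, mol/L.
#' @param ligand_labelled Labelled ligand concentration added at `t_L`, mol/L.
#' @param t_u,t_L Addition times in seconds (`t_L > t_u`).
#' @param temperature Temperature in kelvin.
#' @return An object of class `solution_composition` with a computed
#'   `f_label` element, the labelled fraction of the total ligand pool.
#' @examples
#' # host 10 uM, 100 equivalents each of unlabelled and labelled ligand
#' solution_composition(1e-5, 1e-3, 1e-3, t_u = -600, t_L = 0)
#' @export
solution_composition <- function(host_total, ligand_unlabelled, ligand_labelled,
                                 t_u = -600, t_L = 0, temperature = 297.15) {
  host_total <- .check_scalar(host_total, "host_total", positive = TRUE)
  lu <- .check_scalar(ligand_unlabelled, "ligand_unlabelled", nonneg = TRUE)
  ll <- .check_scalar(ligand_labelled, "ligand_labelled", nonneg = TRUE)
  t_u <- .check_scalar(t_u, "t_u")
  t_L <- .check_scalar(t_L, "t_L")
  if (t_L <= t_u) .stop_validation("t_L must be greater than t_u")
  temperature <- .check_scalar(temperature, "temperature", positive = TRUE)
  if (lu + ll <= 0) .stop_validation("total ligand concentration must be > 0")
  structure(
    list(host_total = host_total, ligand_unlabelled = lu, ligand_labelled = ll,
         t_u = t_u, t_L = t_L, temperature = temperature,
         f_label = ll / (lu + ll)),
    class = "solution_composition")
}

#' Build a composition from host concentration and ligand equivalents
#'
#' Convenience wrapper: experiments are usually specified as equivalents of
#' each ligand isotopologue relative to the host.
#'
#' @param host_total Host concentration, mol/L.
#' @param equivalents_unlabelled,equivalents_labelled Ligand-to-host ratios.
#' @inheritParams solution_composition
#' @return A [solution_composition()].
#' @export
composition_from_equivalents <- function(host_total,
                                         equivalents_unlabelled,
                                         equivalents_labelled,
                                         t_u = -600, t_L = 0,
                                         temperature = 297.15) {
  host_total <- .check_scalar(host_total, "host_total", positive = TRUE)
  solution_composition(
    host_total,
    ligand_unlabelled = equivalents_unlabelled * host_total,
    ligand_labelled = equivalents_labelled * host_total,
    t_u = t_u, t_L = t_L, temperature = temperature)
}

#' @export
print.solution_composition <- function(x, ...) {
  cat(sprintf(
    "DRL composition: host %.3g M; ligand %.3g M (unlabelled, t_u = %g s) + %.3g M (labelled, t_L = %g s)\n",
    x$host_total, x$ligand_unlabelled, x$t_u, x$ligand_labelled, x$t_L))
  cat(sprintf("  labelled fraction f_label = %.4f; T = %.2f K\n", x$f_label, x$temperature))
  invisible(x)
}

#' Fitting options for first-order DRL fits
#'
#' @param float_t_L Float the labelled-ligand addition time instead of fixing
#'   it to the metadata value.
#' @param float_f_eq Float the equilibrium plateau instead of fixing it to the
#'   known labelled fraction (useful for imperfect stock ratios).
#' @param weighting `"none"` or `"inverse_variance"`; the latter expects a
#'   per-point variance attached to the traces.
#' @param quantitation_limit Rates above this value (s^-1) are flagged as too
#'   fast for the DRL protocol; the default reflects the dead time of manual
#'   labelled-ligand addition and infusion.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(float_t_L = FALSE, float_f_eq = FALSE,
                        weighting = c("none", "inverse_variance"),
                        quantitation_limit = 0.5) {
  weighting <- match.arg(weighting)
  structure(
    list(float_t_L = isTRUE(float_t_L), float_f_eq = isTRUE(float_f_eq),
         weighting = weighting,
         quantitation_limit = .check_scalar(quantitation_limit,
                                            "quantitation_limit", positive = TRUE)),
    class = "fit_options")
}

#' Noise model for synthetic DRL intensity traces
#'
#' Emulates the dominant ESI-MS noise sources: a multiplicative common-mode
#' spray-drift factor shared by all species at a time point (log-normal,
#' `sdlog = spray_drift_sd`), shot noise with variance proportional to
#' intensity, and additive baseline noise.  The common-mode factor is the
#' reason relative intensities are the robust DRL observable.
#'
#' @param spray_drift_sd Relative SD of the common-mode factor (>= 0).
#' @param additive_sd Absolute intensity noise SD (>= 0).
#' @param shot_scale Variance per unit intensity for Poisson-like noise (>= 0).
#' @param seed Integer seed; seeded runs are bit-reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(spray_drift_sd = 0, additive_sd = 0, shot_scale = 0,
                        seed = 1L) {
  structure(
    list(spray_drift_sd = .check_scalar(spray_drift_sd, "spray_drift_sd", nonneg = TRUE),
         additive_sd = .check_scalar(additive_sd, "additive_sd", nonneg = TRUE),
         shot_scale = .check_scalar(shot_scale, "shot_scale", nonneg = TRUE),
         seed = as.integer(.check_scalar(seed, "seed"))),
    class = "noise_model")
}

#' Observed ion species of a DRL experiment
#'
#' Maps an observable class of the kinetic model onto an ion: its m/z, an
#' optional elemental formula (used for isotope envelopes), a relative
#' ionization response, and the charge state.  Isotopologues ionize with the
#' same efficiency, hence `response_factor` defaults to 1.
#'
#' @param name Species label, e.g. `"CoC_Py"`.
#' @param mz Monoisotopic mass-to-charge of the ion (> 0).
#' @param class Observable class of the kinetic model this ion reports on:
#'   `"unlabelled"`/`"labelled"` for single-site runs, `"PP"`/`"PL"`/`"LL"`
#'   for two-site runs.  Defaults to `name`.
#' @param formula Elemental composition: a named count vector
#'   (`c(C = 10, H = 8)`) or a string (`"C10H8"`). Optional.
#' @param response_factor Relative ionization efficiency (> 0).
#' @param charge Charge state (positive integer).
#' @param pattern Optional explicit `isotope_pattern`, overriding the one
#'   computed from `formula`.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(name, mz, class = name, formula = NULL,
                         response_factor = 1, charge = 1L, pattern = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    .stop_validation("name must be a non-empty string")
  if (!is.null(formula)) formula <- parse_formula(formula)
  if (!is.null(pattern) && !inherits(pattern, "isotope_pattern"))
    .stop_validation("pattern must be an isotope_pattern")
  structure(
    list(name = name,
         mz = .check_scalar(mz, "mz", positive = TRUE),
         class = as.character(class),
         formula = formula,
         response_factor = .check_scalar(response_factor, "response_factor",
                                         positive = TRUE),
         charge = as.integer(.check_scalar(charge, "charge", positive = TRUE)),
         pattern = pattern),
    class = "species_spec")
}

#' m/z extraction window for extracted-ion chronograms
#'
#' @param target_mz Window centre (> 0).
#' @param species Label given to the extracted trace.
#' @param half_width Half width in Da; the window is the closed interval
#'   `[target_mz - half_width, target_mz + half_width]`.
#' @return An object of class `xic_window`.
#' @export
xic_window <- function(target_mz, species, half_width = 0.5) {
  structure(
    list(target_mz = .check_scalar(target_mz, "target_mz", positive = TRUE),
         species = as.character(species),
         half_width = .check_scalar(half_width, "half_width", positive = TRUE)),
    class = "xic_window")
}
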