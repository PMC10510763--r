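# Eyring analysis: temperature-resolved rate constants -> activation
# parameters, and the inverse transform.  Internally everything is in
# thermochemical calories; reports use the conventional mixed units
# (kcal/mol for enthalpies and free energies, cal/mol/K for entropies).

#' Activation parameters of a rate process
#'
#' @param dH Activation enthalpy, kcal mol^-1.
#' @param dS Activation entropy, cal mol^-1 K^-1.
#' @param covariance 2x2 covariance matrix of `(dH, dS)` in the same units
#'   (symmetric, positive semi-definite); defaults to zero.
#' @param reference Free-form fit metadata.
#' @return An object of class `activation_parameters`.
#' @export
activation_parameters <- function(dH, dS, covariance = matrix(0, 2, 2),
                                  reference = NULL) {
  dH <- .check_scalar(dH, "dH")
  dS <- .check_scalar(dS, "dS")
  covariance <- as.matrix(covariance)
  if (!all(dim(covariance) == c(2L, 2L)) ||
      max(abs(covariance - t(covariance))) > 1e-8 * (1 + max(abs(covariance))))
    .stop_validation("covariance must be a symmetric 2x2 matrix")
  if (any(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
    .stop_validation("covariance must be positive semi-definite")
  dimnames(covariance) <- list(c("dH", "dS"), c("dH", "dS"))
  structure(list(dH = dH, dS = dS, covariance = covariance,
                 reference = reference),
            class = "activation_parameters")
}

#' @export
print.activation_parameters <- function(x, ...) {
  se <- sqrt(pmax(diag(x$covariance), 0))
  cat(sprintf("Activation parameters: dH = %.4g +/- %.2g kcal/mol, dS = %.4g +/- %.2g cal/mol/K\n",
              x$dH, se[1L], x$dS, se[2L]))
  g <- gibbs_at(x, 298.15)
  cat(sprintf("  dG(298.15 K) = %.4g +/- %.2g kcal/mol\n", g[["dG"]], g[["sd"]]))
  invisible(x)
}

# ln(k_B/h), the Eyring intercept offset
.ln_kb_over_h <- function() log(drl_constants$kB / drl_constants$h)

#' Fit the Eyring equation to temperature-resolved rate constants
#'
#' Linear regression of `ln(k/T)` on `1/T`:
#' \deqn{\ln(k/T) = \ln(k_B/h) + \Delta S^\ddagger/R - \Delta H^\ddagger/(R T)}
#' so `dH = -slope * R` and `dS = R * (intercept - ln(kB/h))`.  With
#' replicate spreads available, points are weighted by the inverse variance
#' of `ln(k/T)` obtained from the delta method (`var = (sd/k)^2`); without
#' them the fit is unweighted.  The parameter covariance is propagated from
#' the regression covariance.
#'
#' @param points Data frame with columns `temperature` (K), `k` (s^-1) and
#'   optionally `sd` (replicate SD of `k`, s^-1) and `n` (replicates).
#' @param weighting `"inverse_variance"` (default, requires finite positive
#'   `sd`) or `"none"`.
#' @return An [activation_parameters()] whose `reference` records the
#'   regression (`n`, residual SE, weighting).
#' @export
eyring_fit <- function(points, weighting = c("inverse_variance", "none")) {
  weighting <- match.arg(weighting)
  points <- as.data.frame(points)
  if (!all(c("temperature", "k") %in% names(points)))
    .stop_validation("points must have columns temperature and k")
  if (any(points$temperature <= 0)) .stop_validation("temperatures must be > 0 K")
  if (any(points$k <= 0)) .stop_validation("rate constants must be > 0")
  if (length(unique(points$temperature)) < 2L)
    .stop_validation("need at least 2 distinct temperatures")
  R <- drl_constants$R_cal
  x <- 1 / points$temperature
  y <- log(points$k / points$temperature)
  w <- NULL
  if (weighting == "inverse_variance") {
    sd <- points$sd
    if (!is.null(sd) && all(is.finite(sd)) && all(sd > 0)) {
      w <- (points$k / sd)^2            # 1 / var(ln k) by the delta method
    } else {
      weighting <- "none"               # no usable spreads: unweighted fallback
    }
  }
  fit <- stats::lm(y ~ x, weights = w)
  co <- stats::coef(fit)
  dH <- -co[["x"]] * R / 1000           # kcal/mol
  dS <- R * (co[["(Intercept)"]] - .ln_kb_over_h())
  # colinear points give a zero-residual fit: vcov degenerates to NaN/0
  V <- suppressWarnings(stats::vcov(fit))   # (intercept, slope)
  if (any(!is.finite(V))) V <- matrix(0, 2, 2)
  A <- rbind(dH = c(0, -R / 1000), dS = c(R, 0))
  cov_hs <- A %*% V %*% t(A)
  activation_parameters(
    dH, dS, covariance = cov_hs,
    reference = list(n = nrow(points), weighting = weighting,
                     sigma = suppressWarnings(stats::sigma(fit))))
}

#' Activation free energy at a given temperature
#'
#' `dG = dH - T * dS` with `dS` converted from cal to kcal; the standard
#' deviation uses the full parameter covariance:
#' `var = var_H + (T/1000)^2 var_S - 2 (T/1000) cov_HS`.
#'
#' @param params An [activation_parameters()].
#' @param temperature Kelvin (> 0); default 25 C.
#' @return Named numeric vector `c(dG = ..., sd = ...)` in kcal mol^-1.
#' @examples
#' gibbs_at(activation_parameters(39.1, 58.2), 298.15)
#' @export
gibbs_at <- function(params, temperature = 298.15) {
  stopifnot(inherits(params, "activation_parameters"))
  temperature <- .check_scalar(temperature, "temperature", positive = TRUE)
  Tk <- temperature / 1000                       # dS cal -> kcal via T/1000
  dG <- params$dH - Tk * params$dS
  v <- params$covariance
  var <- v[1L, 1L] + Tk^2 * v[2L, 2L] - 2 * Tk * v[1L, 2L]
  c(dG = dG, sd = sqrt(max(var, 0)))
}

#' Rate constant from activation parameters (Eyring equation)
#'
#' `k = (k_B T / h) * exp(-dG(T) / (R T))` with transmission coefficient 1.
#'
#' @param params An [activation_parameters()].
#' @param temperature Kelvin (> 0).
#' @return Rate constant in s^-1.
#' @export
eyring_rate <- function(params, temperature) {
  stopifnot(inherits(params, "activation_parameters"))
  temperature <- .check_scalar(temperature, "temperature", positive = TRUE)
  dG_cal <- gibbs_at(params, temperature)[["dG"]] * 1000
  expo <- -dG_cal / (drl_constants$R_cal * temperature)
  if (expo > 700) .stop_numerical("eyring_rate overflow: barrier too low/negative")
  drl_constants$kB * temperature / drl_constants$h * exp(expo)
}

#' Read a temperature/rate table for Eyring analysis
#'
#' Accepts `temperature_K` or `temperature_C` (converted to kelvin), plus
#' `k_per_s` and optional `sd`, `n` columns.
#'
#' @param path CSV file path.
#' @return Data frame with columns `temperature` (K), `k`, `sd`, `n`, and an
#'   attribute `converted_from_celsius`.
#' @export
read_rate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  from_c <- FALSE
  if ("temperature_K" %in% names(df)) {
    temp <- df$temperature_K
  } else if ("temperature_C" %in% names(df)) {
    temp <- df$temperature_C + 273.15
    from_c <- TRUE
  } else {
    .stop_validation("rate CSV needs a temperature_K or temperature_C column")
  }
  if (!"k_per_s" %in% names(df))
    .stop_validation("rate CSV needs a k_per_s column")
  out <- data.frame(temperature = temp, k = df$k_per_s,
                    sd = if ("sd" %in% names(df)) df$sd else NA_real_,
                    n = if ("n" %in% names(df)) df$n else NA_integer_)
  attr(out, "converted_from_celsius") <- from_c
  out
}
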