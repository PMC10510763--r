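# First-order fitting of DRL relative-intensity curves.
#
# The two fractions of a group are complementary; fitting both with shared
# parameters keeps the estimator symmetric in the labelled/unlabelled roles
# (and matches how fitted lines are drawn through both curves).

.stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("drl_degenerate_data", "drl_numerical_error",
                                "error")))
}

new_observed_rate <- function(k_ms, stderr, t_L, f_eq, residual_rms, n_points,
                              converged = TRUE, flags = character(0),
                              group_id = NA_character_) {
  structure(list(k_ms = k_ms, stderr = stderr, t_L = t_L, f_eq = f_eq,
                 residual_rms = residual_rms, n_points = n_points,
                 converged = converged, flags = flags, group_id = group_id),
            class = "observed_rate")
}

#' @export
print.observed_rate <- function(x, ...) {
  cat(sprintf("Observed DRL rate%s: k_MS = %.6g +/- %.2g s^-1 (n = %d, rms = %.3g)\n",
              if (is.na(x$group_id)) "" else paste0(" [", x$group_id, "]"),
              x$k_ms, x$stderr, x$n_points, x$residual_rms))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.observed_rate <- function(x, ...) {
  data.frame(group_id = x$group_id, k_ms = x$k_ms, stderr = x$stderr,
             t_L = x$t_L, f_eq = x$f_eq, residual_rms = x$residual_rms,
             n_points = x$n_points, converged = x$converged,
             flags = paste(x$flags, collapse = ";"))
}

# crude half-decay start value for k from the decaying trace
.k_start <- function(t, pu, f_eq) {
  q <- (pu - (1 - f_eq)) / max(f_eq, 1e-12)
  below <- which(q < 0.5)
  if (length(below) && t[below[1L]] > t[1L])
    log(2) / (t[below[1L]] - t[1L])
  else
    2 / (max(t) - min(t) + .Machine$double.eps)
}

#' Fit the first-order DRL law to relative-intensity traces
#'
#' Global least-squares fit of both complementary fractions of a
#' two-species group with the shared-parameter model of
#' [closed_form_relative()]:
#' \deqn{p_u(t) = (1 - f_{eq}) + f_{eq} e^{-k (t - t_L)}}
#' Only samples with `t >= t_L` enter the fit.  By default `f_eq` is fixed
#' to the known labelled fraction of the ligand pool and `t_L` to the
#' metadata value; both can be floated.  Standard errors come from the
#' Gauss-Newton covariance scaled by the residual variance.
#'
#' @param rel A [relative_traces()] with exactly two species; the decaying
#'   (unlabelled) species is the column named `"unlabelled"` if present,
#'   otherwise the one starting higher.
#' @param f_label Known labelled fraction of the ligand pool (sets the
#'   equilibrium plateau unless `opts$float_f_eq`).
#' @param opts A [fit_options()].
#' @param t_L Labelled-ligand addition time; defaults to the value carried by
#'   `rel`.
#' @return An `observed_rate`: `k_ms`, `stderr`, fitted/fixed `t_L` and
#'   `f_eq`, `residual_rms`, `n_points`, convergence flag.
#' @export
fit_first_order <- function(rel, f_label, opts = fit_options(), t_L = NULL) {
  stopifnot(inherits(rel, "relative_traces"))
  opts <- if (inherits(opts, "fit_options")) opts else do.call(fit_options, opts)
  if (ncol(rel$fractions) != 2L)
    .stop_validation("fit_first_order needs a two-species group; got ",
                     ncol(rel$fractions))
  f_label <- .check_scalar(f_label, "f_label")
  if (f_label <= 0 || f_label > 1)
    .stop_validation("f_label must lie in (0, 1]")
  if (is.null(t_L)) t_L <- rel$t_L
  if (!opts$float_t_L && (is.null(t_L) || is.na(t_L)))
    .stop_validation("t_L is unknown: supply it or set float_t_L")
  if (is.na(t_L)) t_L <- min(rel$times)

  keep <- setdiff(which(rel$times >= t_L), rel$masked)
  if (length(keep) < 3L)
    .stop_validation("need at least 3 post-addition time points, got ",
                     length(keep))
  t <- rel$times[keep]
  cn <- colnames(rel$fractions)
  dec <- if ("unlabelled" %in% cn) match("unlabelled", cn)
         else which.max(rel$fractions[keep[1L], ])
  pu <- rel$fractions[keep, dec]
  pl <- rel$fractions[keep, -dec]

  if (diff(range(pu)) < 1e-3)
    .stop_degenerate("insufficient dynamic range: the decaying fraction is ",
                     "flat (range ", format(diff(range(pu)), digits = 3),
                     "); the rate is unidentifiable")

  wts <- rep(1, length(t))
  if (opts$weighting == "inverse_variance") {
    v <- attr(rel, "variance")
    if (!is.null(v)) wts <- 1 / sqrt(pmax(v[keep, dec], 1e-12))
  }

  par <- c(k = .k_start(t, pu, f_label))
  lower <- c(k = 0); upper <- c(k = Inf)
  if (opts$float_t_L) {
    par <- c(par, t_L = t_L)
    lower <- c(lower, t_L = -Inf); upper <- c(upper, t_L = max(t))
  }
  if (opts$float_f_eq) {
    par <- c(par, f_eq = f_label)
    lower <- c(lower, f_eq = 0); upper <- c(upper, f_eq = 1)
  }

  model_pu <- function(p) {
    tl <- if (opts$float_t_L) p[["t_L"]] else t_L
    fe <- if (opts$float_f_eq) p[["f_eq"]] else f_label
    (1 - fe) + fe * exp(-p[["k"]] * pmax(t - tl, 0))
  }
  fit <- minpack.lm::nls.lm(
    par = par, lower = lower, upper = upper,
    fn = function(p) { m <- model_pu(p); c(pu - m, pl - (1 - m)) * c(wts, wts) },
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  if (!(fit$info %in% 1:4))
    .stop_numerical("first-order fit did not converge: ", fit$message)
  est <- fit$par
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  names(se) <- names(est)
  n <- length(t)
  # the two stacked fractions are complementary and carry the same
  # information; rescale the naive 2n-point covariance to the effective
  # single-trace degrees of freedom
  npar <- length(est)
  se <- se * sqrt((2 * n - npar) / max(n - npar, 1))
  new_observed_rate(
    k_ms = est[["k"]],
    stderr = unname(se["k"]),
    t_L = if (opts$float_t_L) est[["t_L"]] else t_L,
    f_eq = if (opts$float_f_eq) est[["f_eq"]] else f_label,
    residual_rms = sqrt(fit$deviance / max(2 * n - length(est), 1)),
    n_points = n,
    converged = TRUE,
    group_id = rel$group_id)
}

#' Competitive multi-host fitting
#'
#' Several hosts monitored in one experiment are fitted independently with
#' the shared addition time; one host failing (flat or degenerate data) does
#' not abort the others.  Dissociation-rate ratios between hosts come from a
#' single run, cancelling common experimental factors.
#'
#' @param rel_by_host Named list of two-species [relative_traces()], one per
#'   host, sharing a time base.
#' @param f_label Labelled fraction of the ligand pool.
#' @param opts A [fit_options()].
#' @param t_L Shared addition time (default: taken from the first element).
#' @return A list with `rates` (per host: `observed_rate` or the error
#'   condition), `ratios` (data frame `host_a, host_b, ratio` of k_MS
#'   values for successfully fitted pairs), and `errors` (named character
#'   vector of failure messages).
#' @export
fit_competitive <- function(rel_by_host, f_label, opts = fit_options(),
                            t_L = NULL) {
  if (!is.list(rel_by_host) || length(rel_by_host) < 2L)
    .stop_validation("fit_competitive needs at least 2 host groups")
  if (is.null(names(rel_by_host)) || any(!nzchar(names(rel_by_host))))
    .stop_validation("rel_by_host must be a named list")
  if (is.null(t_L)) t_L <- rel_by_host[[1L]]$t_L
  rates <- lapply(rel_by_host, function(rel)
    tryCatch(fit_first_order(rel, f_label, opts, t_L = t_L),
             error = function(e) e))
  ok <- vapply(rates, inherits, logical(1), "observed_rate")
  errors <- vapply(rates[!ok], conditionMessage, character(1))
  hosts <- names(rates)[ok]
  ratios <- if (length(hosts) >= 2L) {
    pairs <- utils::combn(hosts, 2L)
    data.frame(
      host_a = pairs[1L, ], host_b = pairs[2L, ],
      ratio = vapply(seq_len(ncol(pairs)), function(i)
        rates[[pairs[1L, i]]]$k_ms / rates[[pairs[2L, i]]]$k_ms, numeric(1)))
  } else {
    data.frame(host_a = character(0), host_b = character(0),
               ratio = numeric(0))
  }
  list(rates = rates, ratios = ratios, errors = errors)
}

#' Flag rates outside the quantitation range of the DRL protocol
#'
#' The dead time of labelled-ligand addition and infusion limits DRL to
#' processes slower than the quantitation limit (0.5 s^-1 by default); a rate
#' is also unreliable when the sampling misses the decay, i.e. fewer than 3
#' points fall within the first `1/k` after `t_L`.  Flags are attached to the
#' rate (warning semantics, the value is kept).
#'
#' @param rate An `observed_rate`.
#' @param opts A [fit_options()] carrying the quantitation limit.
#' @param times Acquisition times used for the fit (seconds); when supplied,
#'   sampling adequacy is checked.
#' @param t_L Addition time (defaults to the one stored in `rate`).
#' @return The rate with updated `flags`: `"too_fast_to_quantify"` and/or
#'   `"undersampled"`.
#' @export
check_quantitation_limit <- function(rate, opts = fit_options(), times = NULL,
                                     t_L = rate$t_L) {
  stopifnot(inherits(rate, "observed_rate"))
  flags <- rate$flags
  if (is.finite(rate$k_ms) && rate$k_ms > opts$quantitation_limit)
    flags <- union(flags, "too_fast_to_quantify")
  if (!is.null(times) && is.finite(rate$k_ms) && rate$k_ms > 0) {
    n_early <- sum(times >= t_L & times <= t_L + 1 / rate$k_ms)
    if (n_early < 3L) flags <- union(flags, "undersampled")
  }
  rate$flags <- flags
  rate
}
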