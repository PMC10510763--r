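# Mechanistic simulation of the ligand-exchange scheme and prediction of the
# MS-observed rate k_MS.
#
# Single site:   host.L  <-k_off/k_on->  host + L     (L = unlabelled or
# labelled isotopologue, identical constants).  Free host is eliminated
# algebraically, and the free ligand pools follow from conservation, so the
# integrated state is just the two bound species: host conservation is exact
# by construction, not up to solver tolerance.

.stop_numerical <- function(...) {
  stop(errorCondition(paste0(...), class = c("drl_numerical_error", "error")))
}

.check_grid <- function(times, t_L) {
  times <- as.numeric(times)
  if (length(times) < 2L || any(diff(times) <= 0))
    .stop_validation("times must be a sorted, strictly increasing grid")
  if (t_L < times[1L] || t_L > times[length(times)])
    .stop_validation("time grid must cover the labelled-ligand addition time t_L")
  times
}

# Solver round-off can leave concentrations a hair below zero; anything
# materially negative is a model/integration defect and is raised.
.clip_tiny_negative <- function(m, what) {
  floor_tol <- 1e-6 * max(m)
  if (any(m < -floor_tol))
    .stop_numerical(what, ": negative concentrations beyond round-off")
  m[m < 0] <- 0
  m
}

# Equilibrium bound-host concentration for host + L <-> host.L:
# smaller root of k_on*(H - P)*(Lt - P) = k_off*P.
.bind_equilibrium <- function(k_on, k_off, host_total, ligand_total) {
  if (ligand_total <= 0) return(0)
  b <- k_on * (host_total + ligand_total) + k_off
  disc <- b^2 - 4 * k_on^2 * host_total * ligand_total
  (b - sqrt(max(disc, 0))) / (2 * k_on)
}

.run_ode <- function(y, times, func, parms, rtol, atol, what) {
  if (length(times) == 1L)
    return(matrix(y, nrow = 1L, dimnames = list(NULL, names(y))))
  out <- deSolve::ode(y = y, times = times, func = func, parms = parms,
                      method = "lsoda", rtol = rtol, atol = atol)
  di <- attr(out, "istate")
  if (anyNA(out) || (length(di) && di[1L] < 0))
    .stop_numerical(what, ": ODE integration failed (istate = ",
                    if (length(di)) di[1L] else NA, "); ",
                    "try loosening rtol/atol or refining the grid")
  out[, -1L, drop = FALSE]
}

#' Simulate the single-site delayed reactant labelling experiment
#'
#' Integrates the exchange scheme with explicit free-ligand bookkeeping
#' (pools are depleted as the host binds, so small-excess regimes are
#' meaningful).  The labelled pool is zero before `t_L` and steps up
#' instantaneously at `t_L` (or relaxes in with time constant `mixing_tau`
#' when that is positive).  Labelled and unlabelled ligand share the same
#' rate constants.
#'
#' @param rates A [rate_constants()] object.
#' @param comp A [solution_composition()]; the grid must cover `comp$t_L`.
#' @param times Output time grid (seconds), strictly increasing.
#' @param pre_equilibrate Start from the host/unlabelled-ligand binding
#'   equilibrium (the phase-I steady state) instead of free host.
#' @param mixing_tau Time constant (s) of labelled-ligand mixing; 0 means an
#'   instantaneous concentration step.
#' @param rtol,atol Solver tolerances; `k_on` and `k_off` typically differ by
#'   many orders of magnitude, hence the stiff-capable integrator and tight
#'   defaults (`atol` defaults to `1e-12 * host_total`).
#' @return A `drl_trajectory`: times plus molar concentrations of
#'   `host_free`, `bound_unlabelled`, `bound_labelled`, `ligand_unlabelled`,
#'   `ligand_labelled`.  The host-containing species sum to `host_total`
#'   exactly at every time point.
#' @examples
#' tr <- simulate_single_site(
#'   rate_constants(5e4, 5.4e-4),
#'   composition_from_equivalents(1e-5, 100, 100, t_L = 0),
#'   times = seq(-50, 5000, by = 10))
#' @export
simulate_single_site <- function(rates, comp, times, pre_equilibrate = TRUE,
                                 mixing_tau = 0, rtol = 1e-8, atol = NULL) {
  stopifnot(inherits(rates, "rate_constants"),
            inherits(comp, "solution_composition"))
  times <- .check_grid(times, comp$t_L)
  if (is.null(atol)) atol <- 1e-12 * comp$host_total
  mixing_tau <- .check_scalar(mixing_tau, "mixing_tau", nonneg = TRUE)

  H <- comp$host_total
  Lu <- comp$ligand_unlabelled   # total unlabelled ligand, bound + free
  Ll <- comp$ligand_labelled
  p <- c(k_on = rates$k_on, k_off = rates$k_off, H = H, Lu = Lu, Ll = Ll,
         tau = mixing_tau)

  # state: P bound-unlabelled, L bound-labelled, R undissolved labelled
  # reservoir; free pools by conservation.
  deriv <- function(t, y, p) {
    P <- y[1L]; L <- y[2L]; R <- y[3L]
    Ffree <- p[["H"]] - P - L
    Py <- p[["Lu"]] - P
    PyL <- p[["Ll"]] - L - R
    dP <- p[["k_on"]] * Ffree * Py - p[["k_off"]] * P
    dL <- p[["k_on"]] * Ffree * PyL - p[["k_off"]] * L
    dR <- if (p[["tau"]] > 0) -R / p[["tau"]] else 0
    list(c(dP, dL, dR))
  }

  P0 <- if (pre_equilibrate) .bind_equilibrium(rates$k_on, rates$k_off, H, Lu) else 0
  pre <- times[times <= comp$t_L]
  post <- times[times > comp$t_L]

  # phase I/II: no labelled ligand in the system at all
  y <- c(P = P0, L = 0, R = 0)
  parms_pre <- p; parms_pre[["Ll"]] <- 0
  out_pre <- .run_ode(y, unique(c(pre, comp$t_L)), deriv, parms_pre, rtol, atol,
                      "simulate_single_site")
  rows_pre <- out_pre[seq_along(pre), , drop = FALSE]

  # phase III: labelled ligand added at t_L
  y1 <- out_pre[nrow(out_pre), ]
  y1[["R"]] <- if (mixing_tau > 0) Ll else 0
  out_post <- .run_ode(y1, c(comp$t_L, post), deriv, p, rtol, atol,
                       "simulate_single_site")
  rows_post <- out_post[-1L, , drop = FALSE]

  st <- rbind(rows_pre, rows_post)
  if (mixing_tau > 0) st[times == comp$t_L, "R"] <- Ll
  labelled_avail <- ifelse(times >= comp$t_L, Ll, 0)  # t_L row is post-addition
  species <- cbind(
    host_free = H - st[, "P"] - st[, "L"],
    bound_unlabelled = st[, "P"],
    bound_labelled = st[, "L"],
    ligand_unlabelled = Lu - st[, "P"],
    ligand_labelled = labelled_avail - st[, "L"] - st[, "R"])
  species <- .clip_tiny_negative(species, "simulate_single_site")
  new_trajectory(times, species, comp, model = "single_site",
                 classes = list(unlabelled = "bound_unlabelled",
                                labelled = "bound_labelled"))
}

new_trajectory <- function(times, species, comp, model, classes) {
  structure(list(times = times, species = species,
                 host_total = comp$host_total, t_L = comp$t_L,
                 f_label = comp$f_label, model = model, classes = classes),
            class = "drl_trajectory")
}

#' @export
print.drl_trajectory <- function(x, ...) {
  cat(sprintf("DRL trajectory (%s model): %d points, t = [%g, %g] s\n",
              x$model, length(x$times), min(x$times), max(x$times)))
  cat("  species:", paste(colnames(x$species), collapse = ", "), "\n")
  invisible(x)
}

#' Convert a trajectory as a long data frame
#'
#' @param x A `drl_trajectory`.
#' @param ... Unused.
#' @return A data frame with columns `time_s, species, value` (molar).
#' @export
as.data.frame.drl_trajectory <- function(x, ...) {
  sp <- colnames(x$species)
  data.frame(time_s = rep(x$times, times = length(sp)),
             species = rep(sp, each = length(x$times)),
             value = as.vector(x$species))
}

#' Closed-form relative-intensity curves in the large-excess limit
#'
#' Under pseudo-first-order conditions (ligand pools effectively constant)
#' the unlabelled bound fraction relaxes exponentially from 1 to its
#' equilibrium plateau, which equals the unlabelled fraction of the ligand
#' pool:
#' \deqn{p(t) = (1 - f) + f \exp(-k_{off} (t - t_L)), \quad t \ge t_L}
#' with `f` the labelled fraction; `p = 1` before `t_L`.  The labelled
#' fraction is the complement.  This is the first-order law used to fit DRL
#' curves; in this limit the signal evolution depends only on the
#' dissociation rate constant.
#'
#' @param k_off Dissociation rate constant (s^-1, >= 0).
#' @param f_label Labelled fraction of the ligand pool, in `[0, 1]`.
#' @param t_L Labelled-ligand addition time (s).
#' @param times Output grid (s).
#' @return A [relative_traces()] with species `unlabelled` and `labelled`.
#' @export
closed_form_relative <- function(k_off, f_label, t_L, times) {
  k_off <- .check_scalar(k_off, "k_off", nonneg = TRUE)
  f_label <- .check_scalar(f_label, "f_label")
  if (f_label < 0 || f_label > 1) .stop_validation("f_label must lie in [0, 1]")
  times <- as.numeric(times)
  dt <- pmax(times - t_L, 0)
  p <- (1 - f_label) + f_label * exp(-k_off * dt)
  relative_traces(times, cbind(unlabelled = p, labelled = 1 - p),
                  group_id = "closed_form", t_L = t_L)
}

#' Normalized bound-species fractions of a trajectory
#'
#' Collapses a trajectory onto the observable classes seen in the mass
#' spectrum and normalizes within the host-complex group: for the single-site
#' model the unlabelled/labelled bound complexes; for the two-site model the
#' `PP` (both unlabelled), `PL` (one labelled, sum of both mixed states) and
#' `LL` (both labelled) classes.
#'
#' @param traj A `drl_trajectory`.
#' @return A [relative_traces()].
#' @export
bound_fractions <- function(traj) {
  stopifnot(inherits(traj, "drl_trajectory"))
  cols <- lapply(traj$classes, function(nm)
    rowSums(traj$species[, nm, drop = FALSE]))
  m <- do.call(cbind, cols)
  colnames(m) <- names(traj$classes)
  tot <- rowSums(m)
  if (any(tot <= 0)) .stop_numerical("bound_fractions: zero bound host")
  relative_traces(traj$times, m / tot, group_id = traj$model, t_L = traj$t_L)
}

#' Predict the MS-observed rate constant k_MS for given conditions
#'
#' Simulates a noise-free trajectory of the exchange scheme, converts it to
#' the relative-intensity observable, and fits the first-order law, exactly
#' as one would treat experimental data.  At large ligand excess (around 100
#' equivalents and above) the fitted `k_MS` equals `k_off`; at small excess
#' pool depletion accelerates the relaxation and `k_MS` exceeds `k_off`.
#' `k_MS` is insensitive to `k_on` at large excess.
#'
#' @param rates A [rate_constants()].
#' @param comp A [solution_composition()].
#' @param fit_protocol A [fit_options()].
#' @param times Optional fitting grid; defaults to 1 point per second from
#'   `t_L` over `5 / k_off` seconds (capped at 20000 intervals for very slow
#'   exchange).
#' @return An `observed_rate` (see [fit_first_order()]).
#' @export
predict_kms <- function(rates, comp, fit_protocol = fit_options(), times = NULL) {
  stopifnot(inherits(rates, "rate_constants"),
            inherits(comp, "solution_composition"))
  if (is.null(times)) {
    span <- 5 / rates$k_off
    times <- seq(comp$t_L, comp$t_L + span, by = max(1, span / 20000))
  }
  traj <- simulate_single_site(rates, comp, times)
  rel <- bound_fractions(traj)
  fit_first_order(rel, f_label = comp$f_label, opts = fit_protocol)
}

#' Predicted k_MS as a function of total ligand equivalents
#'
#' Reproduces the concentration scan used to establish the pseudo-first-order
#' regime: for each total-ligand load (unlabelled + labelled, in equivalents
#' of the host) the observed rate is predicted with [predict_kms()].  The
#' sequence is non-increasing in the equivalents and converges to `k_off`.
#'
#' @param rates A [rate_constants()].
#' @param equivalents_list Positive, sorted total equivalents
#'   (unlabelled + labelled combined).
#' @param f_label Labelled fraction of the ligand load (default 1:1).
#' @param host_total Host concentration, mol/L.
#' @param fit_protocol A [fit_options()].
#' @return A data frame with columns `equivalents`, `k_ms`, `stderr`.
#' @export
scan_kms_vs_equivalents <- function(rates, equivalents_list, f_label = 0.5,
                                    host_total = 1e-5,
                                    fit_protocol = fit_options()) {
  eq <- as.numeric(equivalents_list)
  if (length(eq) < 1L || any(eq <= 0) || is.unsorted(eq))
    .stop_validation("equivalents_list must be positive and sorted")
  rows <- lapply(eq, function(E) {
    comp <- composition_from_equivalents(
      host_total,
      equivalents_unlabelled = (1 - f_label) * E,
      equivalents_labelled = f_label * E)
    r <- predict_kms(rates, comp, fit_protocol)
    data.frame(equivalents = E, k_ms = r$k_ms, stderr = r$stderr)
  })
  do.call(rbind, rows)
}

#' Simulate the two-site (bis-complex) delayed reactant labelling experiment
#'
#' Hosts carrying two inequivalent ligand sites (e.g. inside and outside a
#' cage cavity) are tracked through the four bound states (inner x outer,
#' each unlabelled/labelled).  Each site exchanges independently at its own
#' `k_off`; the leaving ligand is replaced from the shared, well-mixed free
#' pools in proportion to their current fractions (fast-rebinding limit, so
#' the per-site `k_on` does not enter and every host stays doubly bound).
#' Requires at least 2 equivalents of unlabelled ligand so both sites can be
#' occupied before `t_L`.
#'
#' @param rates A [two_site_rate_constants()].
#' @inheritParams simulate_single_site
#' @return A `drl_trajectory` with species `PP` (both unlabelled),
#'   `PL_outer_labelled`, `PL_inner_labelled`, `LL`, plus the free pools;
#'   observable classes `PP`, `PL` (sum of the mixed states) and `LL`.
#' @export
simulate_two_site <- function(rates, comp, times, rtol = 1e-8, atol = NULL) {
  stopifnot(inherits(rates, "two_site_rate_constants"),
            inherits(comp, "solution_composition"))
  times <- .check_grid(times, comp$t_L)
  H <- comp$host_total
  if (comp$ligand_unlabelled < 2 * H)
    .stop_validation("two-site model needs >= 2 equivalents of unlabelled ligand ",
                     "to saturate both sites before t_L")
  if (is.null(atol)) atol <- 1e-12 * H
  free_u0 <- comp$ligand_unlabelled - 2 * H  # free pool before t_L
  p <- c(ki = rates$inner$k_off, ko = rates$outer$k_off, H = H,
         free_total = free_u0 + comp$ligand_labelled)

  # state: nUL (inner unlab, outer lab), nLU, nLL, PyL (free labelled);
  # nUU and free unlabelled by conservation (exact host conservation).
  deriv <- function(t, y, p) {
    nUL <- y[1L]; nLU <- y[2L]; nLL <- y[3L]; PyL <- y[4L]
    H <- p[["H"]]; ki <- p[["ki"]]; ko <- p[["ko"]]
    nUU <- H - nUL - nLU - nLL
    Py <- p[["free_total"]] - PyL
    phiL <- PyL / (Py + PyL)
    phiU <- 1 - phiL
    dUL <- ko * phiL * nUU + ki * phiU * nLL - (ki * phiL + ko * phiU) * nUL
    dLU <- ki * phiL * nUU + ko * phiU * nLL - (ko * phiL + ki * phiU) * nLU
    dLL <- ki * phiL * nUL + ko * phiL * nLU - (ki + ko) * phiU * nLL
    dPyL <- ki * (nLU + nLL) + ko * (nUL + nLL) - (ki + ko) * H * phiL
    list(c(dUL, dLU, dLL, dPyL))
  }

  pre <- times[times < comp$t_L]
  post <- times[times >= comp$t_L]
  # phase I/II is static in the fast-rebinding limit: all hosts doubly
  # unlabelled, no labelled pool.
  y0 <- c(nUL = 0, nLU = 0, nLL = 0, PyL = comp$ligand_labelled)
  out_post <- .run_ode(y0, unique(c(comp$t_L, post)), deriv, p, rtol, atol,
                       "simulate_two_site")
  if (length(post) && post[1L] > comp$t_L) out_post <- out_post[-1L, , drop = FALSE]
  n_pre <- length(pre)
  zeros <- matrix(0, n_pre, 4L,
                  dimnames = list(NULL, c("nUL", "nLU", "nLL", "PyL")))
  st <- rbind(zeros, out_post)
  species <- cbind(
    PP = H - st[, "nUL"] - st[, "nLU"] - st[, "nLL"],
    PL_outer_labelled = st[, "nUL"],
    PL_inner_labelled = st[, "nLU"],
    LL = st[, "nLL"],
    ligand_unlabelled = c(rep(free_u0, n_pre),
                          p[["free_total"]] - out_post[, "PyL"]),
    ligand_labelled = c(rep(0, n_pre), out_post[, "PyL"]))
  species <- .clip_tiny_negative(species, "simulate_two_site")
  new_trajectory(times, species, comp, model = "two_site",
                 classes = list(
                   PP = "PP",
                   PL = c("PL_outer_labelled", "PL_inner_labelled"),
                   LL = "LL"))
}
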