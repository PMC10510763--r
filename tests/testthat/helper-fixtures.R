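# Shared fixtures: the reference exchange system (a 10 uM host with a 1:1
# labelled/unlabelled ligand load) and small builders used across tests.

ref_rates <- function() rate_constants(k_on = 5e4, k_off = 5.4e-4)

ref_comp <- function(equiv = 100) {
  composition_from_equivalents(1e-5, equiv, equiv, t_u = -600, t_L = 0)
}

ref_species <- function() {
  list(species_spec("P", 1480.4, class = "unlabelled"),
       species_spec("L", 1485.4, class = "labelled"))
}

# full-scale intensity of the default generator: scale * host_total
ref_full_scale <- function() 1e11 * 1e-5

# relative traces of a synthetic single-site dataset, ready for fitting
make_rel_traces <- function(noise = noise_model(), times = NULL,
                            rates = ref_rates(), comp = ref_comp()) {
  d <- generate_drl_dataset(rates, comp, ref_species(), noise, times)
  rel <- normalize_group(d, c("P", "L"), t_L = comp$t_L)
  colnames(rel$fractions) <- c("unlabelled", "labelled")
  rel
}

# Analytic oracle for the two-site model at constant pool fractions (exact
# in the large-excess limit): each site is an independent two-state Markov
# chain, so the bound-state probabilities are products of
# p_site(t) = (1 - f) + f * exp(-k_site * t).  Independent of the ODE code.
two_site_oracle <- function(k_inner, k_outer, f, t) {
  pin <- (1 - f) + f * exp(-k_inner * t)
  pout <- (1 - f) + f * exp(-k_outer * t)
  cbind(PP = pin * pout,
        PL = pin * (1 - pout) + (1 - pin) * pout,
        LL = (1 - pin) * (1 - pout))
}

# least-squares first-order rate of a renormalized pair, fitted with a
# plain 1-D optimizer -- an oracle independent of minpack.lm
oracle_first_order_rate <- function(t, p_unlab, f_eq, interval) {
  obj <- function(lk) {
    m <- (1 - f_eq) + f_eq * exp(-exp(lk) * t)
    sum((p_unlab - m)^2)
  }
  exp(stats::optimize(obj, log(interval), tol = 1e-12)$minimum)
}
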