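# Single-site and two-site exchange simulations and k_MS prediction.

test_that("parameter containers reject invalid values", {
  expect_error(rate_constants(-1, 1), class = "drl_validation_error")
  expect_error(rate_constants(1, 0), class = "drl_validation_error")
  expect_error(solution_composition(0, 1e-3, 1e-3), class = "drl_validation_error")
  expect_error(solution_composition(1e-5, 1e-3, 1e-3, t_u = 0, t_L = -1),
               class = "drl_validation_error")
  comp <- ref_comp()
  expect_equal(comp$f_label, 0.5)
  expect_error(simulate_single_site(ref_rates(), comp, seq(10, 20)),
               class = "drl_validation_error")  # grid misses t_L
})

test_that("closed-form relative traces have the textbook shape", {
  times <- c(0, 100, log(2) / 1e-3, 1e6)
  rel <- closed_form_relative(1e-3, f_label = 0.5, t_L = 0, times = times)
  p <- rel$fractions[, "unlabelled"]
  expect_equal(p[[1]], 1)                      # exchange starts at t_L
  expect_equal(p[[3]], 0.75)                   # half-decay of the labile part
  expect_equal(p[[4]], 0.5, tolerance = 1e-12) # plateau = pool composition
  expect_equal(rowSums(rel$fractions), rep(1, 4))
  # before t_L everything is unlabelled
  rel2 <- closed_form_relative(1e-3, 0.5, t_L = 50, times = c(0, 25, 50))
  expect_equal(rel2$fractions[, "unlabelled"], rep(1, 3))
})

test_that("single-site ODE conserves host mass and matches the analytic law", {
  rates <- ref_rates()
  comp <- ref_comp(100)
  times <- seq(-100, 5 / rates$k_off, by = 20)
  traj <- simulate_single_site(rates, comp, times)
  host <- rowSums(traj$species[, c("host_free", "bound_unlabelled", "bound_labelled")])
  expect_lt(max(abs(host / comp$host_total - 1)), 1e-9)
  expect_true(all(traj$species >= 0))
  # at 100 equivalents the relative trace follows the pseudo-first-order law
  rel <- bound_fractions(traj)
  ana <- closed_form_relative(rates$k_off, comp$f_label, comp$t_L, times)
  post <- times >= comp$t_L
  expect_lt(max(abs(rel$fractions[post, "unlabelled"] -
                    ana$fractions[post, "unlabelled"])), 0.005)
})

test_that("without a labelled source nothing labelled is ever formed", {
  comp <- solution_composition(1e-5, 1e-3, 0, t_u = -600, t_L = 0)
  traj <- simulate_single_site(ref_rates(), comp, seq(-10, 2000, by = 10))
  expect_equal(max(traj$species[, "bound_labelled"]), 0)
  # pre-equilibrated binding stays at equilibrium (monotone, here constant)
  p <- traj$species[, "bound_unlabelled"]
  expect_lt(diff(range(p)) / comp$host_total, 1e-6)
})

test_that("labelled addition is a step at t_L; mixing_tau smooths it", {
  rates <- ref_rates()
  comp <- ref_comp()
  times <- seq(-50, 3000, by = 10)
  traj <- simulate_single_site(rates, comp, times)
  lig <- traj$species[, "ligand_labelled"]
  expect_equal(max(lig[times < 0]), 0)
  expect_gt(lig[times == 0], 0.99 * comp$ligand_labelled)
  traj2 <- simulate_single_site(rates, comp, times, mixing_tau = 300)
  lig2 <- traj2$species[, "ligand_labelled"]
  expect_lt(lig2[times == 10] / comp$ligand_labelled, 0.1)
  expect_gt(lig2[times == 3000] / comp$ligand_labelled, 0.99)
})

test_that("equilibrium plateau equals the pool composition for any f_label", {
  rates <- ref_rates()
  for (f in c(0.25, 0.5, 0.8)) {
    comp <- composition_from_equivalents(1e-5, 100 * (1 - f), 100 * f, t_L = 0)
    times <- seq(0, 20 / rates$k_off, length.out = 400)
    rel <- bound_fractions(simulate_single_site(rates, comp, times))
    expect_equal(unname(rel$fractions[400, "labelled"]), f, tolerance = 1e-4)
  }
})

test_that("predicted k_MS equals k_off at large excess and exceeds it below", {
  rates <- ref_rates()
  r100 <- predict_kms(rates, ref_comp(100))
  expect_equal(r100$k_ms, rates$k_off, tolerance = 0.01)
  r2.5 <- predict_kms(rates, ref_comp(2.5))
  expect_gt(r2.5$k_ms, rates$k_off * 1.05)
  # huge excess: the analytic limit
  r1e4 <- predict_kms(rates, ref_comp(1e4))
  expect_true(r1e4$k_ms / rates$k_off > 0.99 && r1e4$k_ms / rates$k_off < 1.01)
})

test_that("k_MS is insensitive to k_on at 100 equivalents", {
  comp <- ref_comp(100)
  ks <- vapply(c(5e3, 5e4, 5e5), function(kon)
    predict_kms(rate_constants(kon, 5.4e-4), comp)$k_ms, numeric(1))
  expect_lt(diff(range(ks)) / mean(ks), 0.01)
})

test_that("k_MS scan is non-increasing and converges to k_off", {
  rates <- ref_rates()
  tbl <- scan_kms_vs_equivalents(rates, c(5, 25, 100, 200))
  expect_equal(tbl$equivalents, c(5, 25, 100, 200))
  expect_true(all(diff(tbl$k_ms) <= 1e-12))
  expect_equal(tbl$k_ms[4], 5.4e-4, tolerance = 0.01)
  # single entry consistent with predict_kms
  one <- scan_kms_vs_equivalents(rates, 50)
  comp <- composition_from_equivalents(1e-5, 25, 25)
  expect_equal(one$k_ms, predict_kms(rates, comp)$k_ms, tolerance = 1e-10)
})

test_that("two-site simulation conserves host and reaches binomial equilibrium", {
  rates <- two_site_rate_constants(rate_constants(5e4, 5.4e-4),
                                   rate_constants(5e4, 0.54))
  comp <- ref_comp(100)
  times <- seq(-10, 15 / 5.4e-4, by = 25)
  traj <- simulate_two_site(rates, comp, times)
  host <- rowSums(traj$species[, c("PP", "PL_outer_labelled",
                                   "PL_inner_labelled", "LL")])
  expect_lt(max(abs(host / comp$host_total - 1)), 1e-9)
  rel <- bound_fractions(traj)
  n <- length(times)
  expect_equal(unname(rel$fractions[n, c("PP", "PL", "LL")]),
               c(0.25, 0.5, 0.25), tolerance = 1e-3)
})

test_that("two-site classes follow the independent-site analytic oracle", {
  k_in <- 5.4e-4; k_out <- 0.54
  rates <- two_site_rate_constants(rate_constants(5e4, k_in),
                                   rate_constants(5e4, k_out))
  # very large excess so the constant-pool oracle applies
  comp <- ref_comp(5000)
  times <- seq(0, 5 / k_in, by = 20)
  rel <- bound_fractions(simulate_two_site(rates, comp, times))
  oracle <- two_site_oracle(k_in, k_out, 0.5, times)
  expect_lt(max(abs(rel$fractions - oracle)), 0.005)
  # separated rates: the mixed class rises to its plateau much faster than LL
  i_early <- which(times >= 5 / k_out)[1]
  expect_gt(rel$fractions[i_early, "PL"], 0.45)
  expect_lt(rel$fractions[i_early, "LL"], 0.05)
})

test_that("two-site model demands enough ligand to fill both sites", {
  rates <- two_site_rate_constants(ref_rates(), ref_rates())
  expect_error(simulate_two_site(rates, ref_comp(1.25), seq(-1, 100)),
               class = "drl_validation_error")
})
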