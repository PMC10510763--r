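# First-order DRL fitting, competitive fits, quantitation limits.

test_that("noise-free closed-form curves are fit to machine-level accuracy", {
  for (k in c(1e-3, 5.4e-4, 0.1)) {
    rel <- closed_form_relative(k, 0.5, t_L = 0,
                                times = seq(0, 5 / k, length.out = 200))
    fit <- fit_first_order(rel, 0.5)
    expect_equal(fit$k_ms, k, tolerance = 1e-6)
    expect_lt(fit$residual_rms, 1e-9)
  }
  # asymmetric labelled fraction
  rel <- closed_form_relative(2e-3, 0.3, t_L = 10,
                              times = seq(0, 3000, length.out = 150))
  expect_equal(fit_first_order(rel, 0.3)$k_ms, 2e-3, tolerance = 1e-6)
})

test_that("flat data raise a degenerate-data error", {
  times <- seq(0, 100, length.out = 50)
  rel <- relative_traces(times, cbind(unlabelled = rep(0.5, 50),
                                      labelled = rep(0.5, 50)), t_L = 0)
  expect_error(fit_first_order(rel, 0.5), class = "drl_degenerate_data")
  expect_error(fit_first_order(rel, 0.5), "dynamic range")
})

test_that("fits need at least 3 post-addition points and a known t_L", {
  rel <- closed_form_relative(1e-3, 0.5, t_L = 0, times = c(-10, -5, 0, 10))
  expect_error(fit_first_order(rel, 0.5), class = "drl_validation_error")
  rel2 <- closed_form_relative(1e-3, 0.5, t_L = 0, times = seq(0, 5000, 100))
  rel2$t_L <- NA_real_
  expect_error(fit_first_order(rel2, 0.5), class = "drl_validation_error")
})

test_that("floated parameters recover the generating values", {
  times <- seq(0, 5000, length.out = 300)
  rel <- closed_form_relative(1e-3, 0.42, t_L = 120, times = times)
  fit <- fit_first_order(rel, f_label = 0.5, t_L = 120,
                         opts = fit_options(float_f_eq = TRUE))
  expect_equal(fit$f_eq, 0.42, tolerance = 1e-6)
  expect_equal(fit$k_ms, 1e-3, tolerance = 1e-5)
  fit2 <- fit_first_order(rel, f_label = 0.42, t_L = 100,
                          opts = fit_options(float_t_L = TRUE))
  expect_equal(fit2$t_L, 120, tolerance = 1e-3)
})

test_that("fitted half-life matches the empirical half-decay of the data", {
  rel <- make_rel_traces(noise_model(spray_drift_sd = 0.05, additive_sd = 1e4,
                                     seed = 5),
                         seq(0, 9000, length.out = 400))
  fit <- fit_first_order(rel, 0.5)
  # time at which the decaying fraction first crosses (1 + f_eq/...) halfway
  p <- rel$fractions[, "unlabelled"]
  t_half_emp <- rel$times[which(p <= 0.75)[1]]
  expect_equal(log(2) / fit$k_ms, t_half_emp, tolerance = 0.05)
})

test_that("k_MS is invariant to any common positive intensity factor", {
  times <- seq(0, 9000, length.out = 300)
  d <- generate_drl_dataset(ref_rates(), ref_comp(), ref_species(),
                            noise_model(additive_sd = 5e3, seed = 9), times)
  rel_a <- normalize_group(d, c("P", "L"), t_L = 0)
  wobble <- exp(sin(times / 300))    # arbitrary positive common factor
  d2 <- time_traces(times, d$intensities * wobble)
  rel_b <- normalize_group(d2, c("P", "L"), t_L = 0)
  colnames(rel_a$fractions) <- colnames(rel_b$fractions) <- c("unlabelled", "labelled")
  expect_equal(fit_first_order(rel_a, 0.5)$k_ms,
               fit_first_order(rel_b, 0.5)$k_ms, tolerance = 1e-12)
})

test_that("noisy synthetic data are recovered within tight bounds", {
  # 10% spray drift, 1% full-scale additive noise, 600 points over 5/k
  times <- seq(0, 5 / 5.4e-4, length.out = 600)
  fit <- fit_first_order(
    make_rel_traces(noise_model(spray_drift_sd = 0.1,
                                additive_sd = 0.01 * ref_full_scale(),
                                seed = 11), times), 0.5)
  expect_equal(fit$k_ms, 5.4e-4, tolerance = 0.05)
  expect_lt(abs(fit$k_ms - 5.4e-4), 4 * fit$stderr + 0.01 * 5.4e-4)
})

test_that("competitive fitting resolves two hosts and isolates failures", {
  k1 <- 1.5e-2; k2 <- 3.7e-3
  times <- seq(0, 5 / k2, length.out = 500)
  mk <- function(k, seed) {
    d <- generate_drl_dataset(rate_constants(5e4, k), ref_comp(),
                              ref_species(),
                              noise_model(spray_drift_sd = 0.1,
                                          additive_sd = 0.005 * ref_full_scale(),
                                          seed = seed), times)
    rel <- normalize_group(d, c("P", "L"), t_L = 0)
    colnames(rel$fractions) <- c("unlabelled", "labelled")
    rel
  }
  res <- fit_competitive(list(fast_host = mk(k1, 1), slow_host = mk(k2, 2)),
                         f_label = 0.5)
  expect_s3_class(res$rates$fast_host, "observed_rate")
  expect_s3_class(res$rates$slow_host, "observed_rate")
  expect_equal(res$ratios$ratio[1], k1 / k2, tolerance = 0.05)
  # identical hosts: statistically indistinguishable rates
  res_same <- fit_competitive(list(a = mk(k2, 3), b = mk(k2, 4)), 0.5)
  dk <- abs(res_same$rates$a$k_ms - res_same$rates$b$k_ms)
  se <- sqrt(res_same$rates$a$stderr^2 + res_same$rates$b$stderr^2)
  expect_lt(dk, 4 * se)
  # one flat host fails alone
  flat <- relative_traces(times,
                          cbind(unlabelled = rep(0.5, 500),
                                labelled = rep(0.5, 500)), t_L = 0)
  res_mix <- fit_competitive(list(dead = flat, live = mk(k2, 5)), 0.5)
  expect_s3_class(res_mix$rates$live, "observed_rate")
  expect_true(inherits(res_mix$rates$dead, "drl_degenerate_data"))
  expect_match(res_mix$errors[["dead"]], "dynamic range")
})

test_that("quantitation limit flags fast rates and inadequate sampling", {
  opts <- fit_options()
  fast <- drlkin:::new_observed_rate(0.6, 0.01, 0, 0.5, 0.01, 100)
  expect_true("too_fast_to_quantify" %in%
                check_quantitation_limit(fast, opts)$flags)
  slow <- drlkin:::new_observed_rate(1e-3, 1e-5, 0, 0.5, 0.01, 100)
  dense <- seq(0, 5000, by = 10)
  expect_length(check_quantitation_limit(slow, opts, times = dense)$flags, 0)
  # rate below the limit but first sample long after t_L + 1/k
  late <- seq(10 / 1e-3, 5e4, by = 100)
  flags <- check_quantitation_limit(slow, opts, times = late, t_L = 0)$flags
  expect_equal(flags, "undersampled")
})
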