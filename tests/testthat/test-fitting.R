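# Likelihood evaluation and maximum-likelihood fitting.

test_that("negative log-likelihood has its closed-form special cases", {
  d <- rhi_design("ownership")
  counts <- simulate_responses(d, typical_bci(), seed = 1)
  # a full lapser predicts a fair coin everywhere: NLL = N log 2
  coin <- coin_flipper()
  expect_equal(neg_log_likelihood(counts, coin), 252 * log(2),
               tolerance = 1e-6)
  # single cell, all-yes, p = 0.95: -12 log 0.95 (huge criterion, lapse 0.1)
  cell <- tibble::tibble(noise = 0, asynchrony_ms = 0, n_trials = 12L,
                         n_yes = 12L)
  p95 <- observer_params("FC", k0 = 1e6, sigma = c("0" = 100), lapse = 0.1)
  expect_equal(neg_log_likelihood(cell, p95), -12 * log(0.95),
               tolerance = 1e-9)
})

test_that("cell likelihood equals the trial-by-trial Bernoulli expansion", {
  d <- rhi_design("ownership")
  params <- typical_bci(p_same = 0.7, lapse = 0.12)
  counts <- simulate_responses(d, params, seed = 4)
  # expansion oracle: one Bernoulli term per trial
  p <- p_report_common(counts$asynchrony_ms, params, counts$noise)
  oracle <- -sum(unlist(purrr::map(seq_len(nrow(counts)), function(i) {
    c(rep(log(p[i]), counts$n_yes[i]),
      rep(log(1 - p[i]), counts$n_trials[i] - counts$n_yes[i]))
  })))
  expect_equal(neg_log_likelihood(counts, params), oracle, tolerance = 1e-9)
})

test_that("likelihood is invariant to row order, cell splitting, and scale", {
  d <- rhi_design("ownership")
  params <- typical_bci()
  counts <- simulate_responses(d, params, seed = 6)
  shuffled <- counts[sample(nrow(counts)), ]
  expect_equal(neg_log_likelihood(shuffled, params),
               neg_log_likelihood(counts, params), tolerance = 1e-12)
  # split one cell into two rows with the same key
  split <- counts
  split$n_trials[1] <- split$n_trials[1] - 5L
  extra <- counts[1, ]
  extra$n_trials <- 5L
  y1 <- min(counts$n_yes[1], split$n_trials[1])
  split$n_yes[1] <- y1
  extra$n_yes <- counts$n_yes[1] - y1
  expect_equal(neg_log_likelihood(dplyr::bind_rows(split, extra), params),
               neg_log_likelihood(counts, params), tolerance = 1e-12)
  # ms units are arbitrary: scaling all times leaves the likelihood fixed
  scaled_counts <- dplyr::mutate(counts, asynchrony_ms = asynchrony_ms * 3)
  scaled_params <- observer_params("BCI", p_same = params$p_same,
                                   sigma = params$sigma * 3,
                                   sigma_s = params$sigma_s * 3,
                                   lapse = params$lapse)
  expect_equal(neg_log_likelihood(scaled_counts, scaled_params),
               neg_log_likelihood(counts, params), tolerance = 1e-9)
})

test_that("refitting with the same seed reproduces the fit exactly", {
  d <- rhi_design("ownership")
  counts <- simulate_responses(d, typical_bci(), seed = 8)
  f1 <- fit_observer(counts, "BCI", n_starts = 8, seed = 3)
  f2 <- fit_observer(counts, "BCI", n_starts = 8, seed = 3)
  expect_identical(f1, f2)
})

test_that("fits recover generating parameters at high trial counts", {
  d <- rhi_design("ownership", reps_per_cell = 1200)
  truth <- typical_bci(p_same = 0.8, lapse = 0.05)
  counts <- simulate_responses(d, truth, seed = 3)
  fit <- fit_observer(counts, "BCI", n_starts = 16, seed = 1)
  est <- tidy(fit)
  expect_equal(est$estimate[est$term == "p_same"], 0.8, tolerance = 0.05)
  expect_equal(est$estimate[est$term == "sigma_0"], 116, tolerance = 0.05)
  expect_equal(est$estimate[est$term == "sigma_30"], 141, tolerance = 0.05)
  expect_equal(est$estimate[est$term == "sigma_50"], 178, tolerance = 0.05)
})

test_that("freeing a parameter never hurts the maximised likelihood", {
  d <- rhi_design("ownership")
  counts <- simulate_responses(d, typical_bci(lapse = 0.05), seed = 10)
  f_bci <- fit_observer(counts, "BCI", n_starts = 16, seed = 1)
  f_star <- fit_observer(counts, "BCI*", n_starts = 24, seed = 1)
  expect_gte(f_star$logLik, f_bci$logLik - 1e-3)
  # information criteria obey their defining identities
  expect_equal(f_bci$aic, 2 * 5 - 2 * f_bci$logLik, tolerance = 1e-12)
  expect_equal(f_bci$bic, 5 * log(252) - 2 * f_bci$logLik, tolerance = 1e-12)
  expect_equal(f_star$n_par, 6)
})

test_that("on one noise level the fixed criterion nests the Bayesian rule", {
  d <- rhi_design("ownership", noise_levels = 0)
  counts <- simulate_responses(d, observer_params(
    "BCI", p_same = 0.8, sigma = c("0" = 116), sigma_s = 348, lapse = 0.05
  ), seed = 12)
  f_bci <- fit_observer(counts, "BCI", n_starts = 16, seed = 2)
  f_fc <- fit_observer(counts, "FC", n_starts = 16, seed = 2)
  expect_gte(f_fc$logLik, f_bci$logLik - 1e-3)
})

test_that("extension fits share sensory parameters and nest correctly", {
  own_d <- rhi_design("ownership")
  syn_d <- rhi_design("synchrony")
  own <- simulate_responses(own_d, typical_bci(p_same = 0.85, lapse = 0.05),
                            seed = 21)
  syn <- simulate_responses(syn_d, typical_bci(p_same = 0.60, lapse = 0.05),
                            seed = 21)
  shared <- fit_extension(own, syn, shared_p_same = TRUE, n_starts = 12,
                          seed = 1)
  separate <- fit_extension(own, syn, shared_p_same = FALSE, n_starts = 12,
                            seed = 1)
  expect_gte(separate$logLik, shared$logLik - 1e-3)   # nesting
  expect_equal(shared$n_par, 5)
  expect_equal(separate$n_par, 6)
  expect_equal(shared$n_trials, 504)
  # shared fit carries one prior; separate fit two
  expect_identical(shared$params$ownership$p_same,
                   shared$params$synchrony$p_same)
  expect_false(isTRUE(all.equal(separate$params$ownership$p_same,
                                separate$params$synchrony$p_same)))
  # sensory parameters are shared in both variants
  expect_identical(separate$params$ownership$sigma,
                   separate$params$synchrony$sigma)
})

test_that("transfer evaluation matches its definitions", {
  own_d <- rhi_design("ownership")
  syn_d <- rhi_design("synchrony")
  own <- simulate_responses(own_d, typical_bci(p_same = 0.85), seed = 31)
  syn <- simulate_responses(syn_d, typical_bci(p_same = 0.60), seed = 31)
  src <- fit_observer(own, "BCI", n_starts = 16, seed = 1)
  full <- transfer_evaluate(src, syn, mode = "full")
  partial <- transfer_evaluate(src, syn, mode = "partial")
  # full transfer is a pure prediction: likelihood at the source parameters
  expect_equal(full$logLik, -neg_log_likelihood(syn, src$params),
               tolerance = 1e-12)
  expect_equal(full$n_par, 0)
  expect_equal(full$aic, -2 * full$logLik, tolerance = 1e-12)
  # partial transfer re-fits the prior only, so it can only improve
  expect_gte(partial$logLik, full$logLik - 1e-9)
  expect_equal(partial$n_par, 1)
  # only p_same moved; sensory parameters are carried over
  expect_identical(partial$params$sigma, src$params$sigma)
  expect_identical(partial$params$lapse, src$params$lapse)
})

test_that("parameter recovery tabulates true against estimated values", {
  rec <- run_parameter_recovery("BCI", n_observers = 3,
                                design = rhi_design("ownership"),
                                n_starts = 8, seed = 5)
  expect_s3_class(rec, "recovery_report")
  expect_equal(nrow(rec$results), 3 * 5)   # 5 parameters per BCI observer
  expect_setequal(unique(rec$results$parameter),
                  c("p_same", "sigma_0", "sigma_30", "sigma_50", "lapse"))
  expect_true(all(rec$results$abs_error >= 0))
  expect_equal(rec$results$abs_error,
               abs(rec$results$estimated - rec$results$true))
})

test_that("fits refuse multi-participant or multi-task tables", {
  d <- rhi_design("ownership")
  two <- dplyr::bind_rows(
    simulate_responses(d, typical_bci(), "P01", seed = 1),
    simulate_responses(d, typical_bci(), "P02", seed = 1)
  )
  expect_error(fit_observer(two, "BCI", n_starts = 2), "single participant")
  mixed <- dplyr::bind_rows(
    simulate_responses(rhi_design("ownership"), typical_bci(), seed = 1),
    simulate_responses(rhi_design("synchrony"), typical_bci(), seed = 1)
  )
  expect_error(neg_log_likelihood(mixed, typical_bci()), "single task")
})
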