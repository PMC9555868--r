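# Forward observer models: criterion, posterior log-odds, psychometric
# function, and agreement with the Monte-Carlo decision oracle.

test_that("decision criterion matches closed-form and root-finding values", {
  # p_same = 0.5: prior log-odds vanish, K = 2 sigma^2 ln 2 at sigma_s = sigma
  expect_equal(decision_criterion(0.5, 100, 100), sqrt(20000 * log(2)),
               tolerance = 1e-12)
  # frozen value from independent numeric root-finding of d(x) = 0 with
  # direct normal-density evaluation (sigma_s = 3 sigma so the variance
  # ratio is exactly 10)
  expect_equal(decision_criterion(0.8, 116, 348), 275.462316,
               tolerance = 1e-6)
  # very low prior: the bracket term is negative, no criterion exists
  expect_true(is.na(decision_criterion(0.01, 100, 300)))
})

test_that("decision criterion is undefined exactly when K <= 0", {
  # direct sign evaluation of the bracket term as the oracle
  grid <- expand.grid(p = c(0.01, 0.05, 0.2, 0.5, 0.9),
                      sigma = c(50, 116, 200), sigma_s = c(100, 348))
  bracket <- 2 * log(grid$p / (1 - grid$p)) +
    log((grid$sigma_s^2 + grid$sigma^2) / grid$sigma^2)
  k <- decision_criterion(grid$p, grid$sigma, grid$sigma_s)
  expect_identical(is.na(k), bracket <= 0)
})

test_that("criterion grows with the prior and with sensory noise", {
  ps <- seq(0.3, 0.99, by = 0.01)
  k <- decision_criterion(ps, 116, 348)
  expect_true(all(diff(k) > 0))
  # k keeps growing (like sqrt(log)) as the prior approaches 1
  expect_gt(decision_criterion(1 - 1e-12, 116, 348),
            decision_criterion(0.999, 116, 348))
  # the Bayesian signature: wider criterion under more sensory noise
  k_noise <- decision_criterion(0.8, c(116, 141, 178), 348)
  expect_true(all(diff(k_noise) > 0))
})

test_that("posterior log-odds agree with direct density evaluation", {
  expect_equal(posterior_log_odds(0, 0.5, 116, 348),
               0.5 * log((348^2 + 116^2) / 116^2), tolerance = 1e-12)
  expect_equal(posterior_log_odds(0, 0.8, 116, 348), log(4) + 0.5 * log(10),
               tolerance = 1e-12)
  # independent oracle: prior log ratio + log ratio of dnorm densities
  d_oracle <- function(x, p, s, ss) {
    log(p / (1 - p)) + log(dnorm(x, 0, s) / dnorm(x, 0, sqrt(ss^2 + s^2)))
  }
  for (x in c(-400, -50, 10, 250)) {
    expect_equal(posterior_log_odds(x, 0.65, 90, 250),
                 d_oracle(x, 0.65, 90, 250), tolerance = 1e-10)
  }
})

test_that("log-odds are zero on the criterion boundary and share its sign", {
  k <- decision_criterion(0.8, 116, 348)
  expect_equal(posterior_log_odds(k, 0.8, 116, 348), 0, tolerance = 1e-9)
  expect_equal(posterior_log_odds(-k, 0.8, 116, 348), 0, tolerance = 1e-9)
  for (x in c(0, 50, 150, 274, 277, 400, 1000)) {
    d <- posterior_log_odds(x, 0.8, 116, 348)
    expect_identical(sign(d), sign(k - abs(x)))
  }
})

test_that("psychometric function is lapse-bounded, even, and unimodal", {
  params <- typical_bci(lapse = 0.1)
  s <- seq(-600, 600, by = 50)
  p <- p_report_common(s, params, noise = 0)
  expect_true(all(p >= params$lapse / 2 - 1e-12))
  expect_true(all(p <= 1 - params$lapse / 2 + 1e-12))
  expect_equal(p, rev(p), tolerance = 1e-12)               # even in s
  right <- p_report_common(seq(0, 600, by = 25), params, 0)
  expect_true(all(diff(right) < 0))                        # decreasing in |s|
  # pure lapse: flat at one half
  full_lapse <- coin_flipper()
  expect_equal(p_report_common(c(-500, 0, 500), full_lapse, 30),
               rep(0.5, 3), tolerance = 1e-6)
})

test_that("undefined criterion reduces the response to pure lapsing", {
  low_prior <- observer_params("BCI", p_same = 0.01,
                               sigma = c("0" = 100), sigma_s = 300,
                               lapse = 0.2)
  expect_equal(p_report_common(c(-300, 0, 300), low_prior, 0),
               rep(0.1, 3), tolerance = 1e-12)
})

test_that("a fixed criterion equal to the Bayesian one gives identical curves", {
  bci <- typical_bci(lapse = 0.05)
  k <- decision_criterion(bci$p_same, bci$sigma[["0"]], bci$sigma_s)
  fc <- observer_params("FC", k0 = k, sigma = c("0" = 116), lapse = 0.05)
  s <- seq(-500, 500, by = 100)
  expect_equal(p_report_common(s, bci, 0), p_report_common(s, fc, 0),
               tolerance = 1e-12)
})

test_that("predicted_curve covers the design grid with symmetric columns", {
  design <- rhi_design("ownership")
  curve <- predicted_curve(design, typical_bci())
  expect_equal(nrow(curve), 21)
  expect_true(all(curve$p_yes >= 0.04 - 1e-12 & curve$p_yes <= 0.96 + 1e-12))
  sym <- curve |>
    dplyr::mutate(a = abs(asynchrony_ms)) |>
    dplyr::group_by(noise, a) |>
    dplyr::summarise(spread = diff(range(p_yes)), .groups = "drop")
  expect_true(all(sym$spread < 1e-12))
  # mismatched noise levels are refused
  narrow <- observer_params("BCI", p_same = 0.8, sigma = c("0" = 116))
  expect_error(predicted_curve(design, narrow), "noise level")
})

test_that("Monte-Carlo oracle reproduces the analytic psychometric function", {
  params <- typical_bci(lapse = 0)
  frac <- mc_decision_oracle(0, params, noise = 0, n_samples = 1e5, seed = 11)
  expect_within_3se(frac, p_report_common(0, params, 0), 1e5)
  # symmetric asynchronies give equal fractions within sampling error
  f_pos <- mc_decision_oracle(500, params, 0, n_samples = 1e5, seed = 12)
  f_neg <- mc_decision_oracle(-500, params, 0, n_samples = 1e5, seed = 13)
  p_true <- p_report_common(500, params, 0)
  expect_within_3se(f_pos, p_true, 1e5)
  expect_within_3se(f_neg, p_true, 1e5)
  # pure lapsing: a fair coin
  lapsy <- coin_flipper()
  expect_within_3se(mc_decision_oracle(123, lapsy, 30, 1e5, seed = 14),
                    0.5, 1e5)
})

test_that("parameter bundles enforce their domain", {
  expect_error(observer_params("BCI", p_same = 1.2, sigma = c("0" = 100)),
               "p_same")
  expect_error(observer_params("BCI", k0 = 100, sigma = c("0" = 100)),
               "p_same")
  expect_error(observer_params("FC", p_same = 0.5, sigma = c("0" = 100)),
               "k0")
  expect_error(observer_params("BCI", p_same = 0.5, sigma = c("0" = -5)),
               "positive")
  expect_error(observer_params("BCI", p_same = 0.5, sigma = c("0" = 100),
                               lapse = 1.5), "lapse")
  expect_error(decision_criterion(0.5, -1, 100), "sigma")
})
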