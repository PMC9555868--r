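#' Information criteria from a maximised log-likelihood
#'
#' `AIC = 2 n_par - 2 logL*` and `BIC = n_par log(n_trials) - 2 logL*`.
#' Lower is better; BIC penalises free parameters more heavily for the
#' trial counts used here.
#'
#' @param log_likelihood Maximised log-likelihood L*.
#' @param n_par Number of free parameters (>= 0).
#' @param n_trials Number of trials entering the likelihood (>= 1).
#' @return A tibble with columns `aic` and `bic`.
#' @export
information_criteria <- function(log_likelihood, n_par, n_trials) {
  stopifnot(all(n_par >= 0), all(n_trials >= 1))
  tibble::tibble(
    aic = 2 * n_par - 2 * log_likelihood,
    bic = n_par * log(n_trials) - 2 * log_likelihood
  )
}

#' Bootstrap CI for a summed participant-level difference
#'
#' Given per-participant differences of a criterion (e.g. AIC or BIC)
#' between two models, resamples the participants with replacement
#' (original sample size), sums each resample, and reports the percentile
#' interval of the resampled sums together with the raw (unresampled) sum.
#'
#' @param per_participant_diffs Numeric vector of per-participant
#'   differences.
#' @param n_boot Number of bootstrap resamples (default 10,000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; the resampling is deterministic given it.
#' @return A one-row tibble with `lower`, `raw_sum`, `upper`.
#' @export
bootstrap_summed_diff_ci <- function(per_participant_diffs, n_boot = 10000,
                                     level = 0.95, seed = 1) {
  x <- per_participant_diffs
  if (length(x) == 0) stop("`per_participant_diffs` is empty", call. = FALSE)
  sums <- with_preserved_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) sum(sample(x, length(x), replace = TRUE)),
           numeric(1))
  })
  q <- stats::quantile(sums, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  tibble::tibble(lower = q[1], raw_sum = sum(x), upper = q[2])
}

#' Participant-level model comparison table
#'
#' Per-participant AIC and BIC differences between two lists of fits
#' (matched by position), their raw sums, and bootstrap 95% CIs of the
#' sums. A negative sum favours the first model.
#'
#' @param fits_a,fits_b Lists of `"rhi_fit"` objects of equal length, fitted
#'   to the same participants' data.
#' @param n_boot,level,seed Passed to [bootstrap_summed_diff_ci()].
#' @return A tibble with one row per criterion (`aic`, `bic`) and columns
#'   `criterion`, `lower`, `raw_sum`, `upper`.
#' @export
comparison_table <- function(fits_a, fits_b, n_boot = 10000, level = 0.95,
                             seed = 1) {
  stopifnot(length(fits_a) == length(fits_b), length(fits_a) >= 1)
  d_aic <- vapply(seq_along(fits_a),
                  function(i) fits_a[[i]]$aic - fits_b[[i]]$aic, numeric(1))
  d_bic <- vapply(seq_along(fits_a),
                  function(i) fits_a[[i]]$bic - fits_b[[i]]$bic, numeric(1))
  dplyr::bind_rows(
    dplyr::mutate(bootstrap_summed_diff_ci(d_aic, n_boot, level, seed),
                  criterion = "aic", .before = 1),
    dplyr::mutate(bootstrap_summed_diff_ci(d_bic, n_boot, level, seed + 1),
                  criterion = "bic", .before = 1)
  )
}

#' Max-corrected Nagelkerke pseudo-R-squared
#'
#' Nagelkerke's coefficient of determination for a binary-response model
#' against the fair-coin null (every response "yes" with probability 0.5,
#' so `logL(M0) = n log 0.5`):
#' \deqn{R^2 = 1 - \exp\!\left(-\tfrac{2}{n}(\log L(M) - \log L(M_0))\right),}
#' divided by its maximum attainable value
#' \eqn{\max(R^2) = 1 - \exp(\tfrac{2}{n}\log L(M_0))} so that a perfect
#' predictor scores 1.
#'
#' @param log_l_model Log-likelihood of the fitted model.
#' @param n_trials Number of binary responses.
#' @return The corrected pseudo-R-squared.
#' @export
pseudo_r2 <- function(log_l_model, n_trials) {
  stopifnot(all(n_trials >= 1))
  log_l0 <- n_trials * log(0.5)
  r2 <- 1 - exp(-2 / n_trials * (log_l_model - log_l0))
  r2_max <- 1 - exp(2 / n_trials * log_l0)
  r2 / r2_max
}
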