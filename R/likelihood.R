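#' Negative log-likelihood of condition counts under an observer
#'
#' Bernoulli/binomial likelihood of per-cell yes-counts under the forward
#' model: for each cell with true asynchrony s and noise level,
#' `p = p_report_common(s, params, noise)` and the contribution is
#' `n_yes * log(p) + (n_trials - n_yes) * log(1 - p)`. Binomial coefficients
#' are omitted (constant in the parameters, so irrelevant to estimation and
#' to information-criterion differences on fixed data). Probabilities are
#' clamped to `[1e-10, 1 - 1e-10]` so the objective stays finite at the
#' lapse-rate boundary.
#'
#' @param counts A tibble of condition counts (columns `noise`,
#'   `asynchrony_ms`, `n_trials`, `n_yes`) from a single task.
#' @param params An [observer_params()] object covering the counts' noise
#'   levels.
#' @return The negative log-likelihood (non-negative).
#' @export
neg_log_likelihood <- function(counts, params) {
  counts <- validate_counts(counts, require_ids = FALSE)
  if ("task" %in% names(counts) && dplyr::n_distinct(counts$task) > 1) {
    stop("`counts` must come from a single task; use fit_extension() for ",
         "joint fits", call. = FALSE)
  }
  p <- p_report_common(counts$asynchrony_ms, params, counts$noise)
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  -sum(counts$n_yes * log(p) + (counts$n_trials - counts$n_yes) * log1p(-p))
}

validate_counts <- function(counts, require_ids = TRUE) {
  needed <- c("noise", "asynchrony_ms", "n_trials", "n_yes")
  if (require_ids) needed <- c("participant", "task", needed)
  miss <- setdiff(needed, names(counts))
  if (length(miss) > 0) {
    stop("counts table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(counts$n_yes < 0 | counts$n_yes > counts$n_trials |
                 counts$n_trials < 1)
  if (length(bad) > 0) {
    stop("invalid counts (need 0 <= n_yes <= n_trials, n_trials >= 1) in ",
         "row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  counts
}
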