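#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted observer model
#'
#' @param x An `"rhi_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`, and for
#'   extension fits the `task` the parameter applies to (`"both"` for
#'   shared parameters).
#' @export
tidy.rhi_fit <- function(x, ...) {
  if (x$kind == "extension") {
    own <- params_as_vector(x$params$ownership)
    syn <- params_as_vector(x$params$synchrony)
    shared <- names(own)[own[names(own)] == syn[names(own)]]
    rows <- dplyr::bind_rows(
      tibble::tibble(term = names(own), estimate = unname(own),
                     task = ifelse(names(own) %in% shared, "both",
                                   "ownership")),
      tibble::tibble(term = names(syn), estimate = unname(syn),
                     task = "synchrony")
    )
    rows <- dplyr::distinct(rows, .data$term, .data$estimate, .data$task)
    rows[!(rows$task == "synchrony" &
             paste(rows$term, rows$estimate) %in%
             paste(names(own)[own == syn], own[own == syn])), ]
  } else {
    v <- params_as_vector(x$params)
    tibble::tibble(term = names(v), estimate = unname(v))
  }
}

#' Glance at a fitted observer model
#'
#' @param x An `"rhi_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble with `model`, `kind`, `logLik`, `aic`, `bic`,
#'   `n_par`, `n_trials`, `pseudo_r2`, `n_starts`, `converged`.
#' @export
glance.rhi_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, kind = x$kind, logLik = x$logLik, aic = x$aic,
    bic = x$bic, n_par = x$n_par, n_trials = x$n_trials,
    pseudo_r2 = pseudo_r2(x$logLik, x$n_trials),
    n_starts = x$n_starts, converged = x$converged
  )
}

#' Tidy a group-level model-selection result
#'
#' @param x A `"bms_result"` object.
#' @param ... Unused.
#' @return A tibble with one row per model: Dirichlet weight, expected
#'   frequency, exceedance and protected exceedance probability.
#' @export
tidy.bms_result <- function(x, ...) {
  tibble::tibble(
    model = x$models,
    dirichlet_alpha = unname(x$dirichlet_alpha),
    expected_frequency = unname(x$expected_frequencies),
    exceedance_probability = unname(x$exceedance_probabilities),
    protected_exceedance_probability =
      unname(x$protected_exceedance_probabilities)
  )
}

#' @export
glance.bms_result <- function(x, ...) {
  tibble::tibble(
    n_models = length(x$models), bor = x$bor, free_energy = x$free_energy,
    null_free_energy = x$null_free_energy, n_iterations = x$n_iterations
  )
}

#' Tidy a parameter-recovery report
#'
#' @param x A `"recovery_report"` object.
#' @param ... Unused.
#' @return The per-observer, per-parameter results tibble.
#' @export
tidy.recovery_report <- function(x, ...) x$results

#' @export
glance.recovery_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "parameter",
                     values_from = c("correlation", "median_rel_error"))
}
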