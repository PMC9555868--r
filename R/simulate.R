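#' Simulate per-cell yes-counts from a known observer
#'
#' Forward-samples a complete session of a detection task: for every
#' (noise, asynchrony) cell of the design, the number of "yes" responses is
#' drawn as Binomial(reps_per_cell, p) with p given by the observer's
#' psychometric function [p_report_common()]. Trial order within a session
#' carries no information under independent trials, so only counts are
#' generated.
#'
#' The random stream is derived deterministically from `seed` and the
#' (participant, task) pair, so cohorts can be simulated participant by
#' participant or all at once with identical results.
#'
#' @param design An [rhi_design()] object.
#' @param params An [observer_params()] object.
#' @param participant Participant identifier (string).
#' @param seed Master integer seed.
#' @return A tibble of condition counts with columns `participant`, `task`,
#'   `noise`, `asynchrony_ms`, `n_trials`, `n_yes`.
#' @examples
#' d <- rhi_design("ownership")
#' p <- observer_params("BCI", p_same = 0.8,
#'                      sigma = c("0" = 116, "30" = 141, "50" = 178),
#'                      lapse = 0.08)
#' simulate_responses(d, p, participant = "P01", seed = 1)
#' @export
simulate_responses <- function(design, params, participant = "P01", seed = 1) {
  stopifnot(inherits(design, "rhi_design"), inherits(params, "observer_params"))
  curve <- predicted_curve(design, params)
  cell_seed <- stream_seed(seed, participant, design$task)
  n_yes <- with_preserved_seed(cell_seed, {
    stats::rbinom(nrow(curve), size = curve$n_trials, prob = curve$p_yes)
  })
  tibble::tibble(
    participant = as.character(participant),
    task = curve$task,
    noise = curve$noise,
    asynchrony_ms = curve$asynchrony_ms,
    n_trials = as.integer(curve$n_trials),
    n_yes = as.integer(n_yes)
  )
}

# One deterministic sub-stream seed per (participant, task), kept < 2^31.
stream_seed <- function(master, participant, task) {
  h <- 0
  for (ch in utf8ToInt(paste(participant, task, sep = "/"))) {
    h <- (h * 131 + ch) %% 2147483587
  }
  as.integer((as.numeric(master) * 48271 + h) %% 2147483587 + 1)
}

#' Simulate a cohort of observers
#'
#' Convenience wrapper around [simulate_responses()]: one set of counts per
#' observer, bound into a single tidy table.
#'
#' @param design An [rhi_design()] object.
#' @param params_list A single [observer_params()] object (shared by all
#'   observers) or a list with one per observer.
#' @param n_participants Number of observers when `params_list` is a single
#'   parameter set; otherwise taken from `length(params_list)`.
#' @param seed Master integer seed.
#' @return A tibble of condition counts for the whole cohort.
#' @export
simulate_cohort <- function(design, params_list, n_participants = NULL,
                            seed = 1) {
  if (inherits(params_list, "observer_params")) {
    if (is.null(n_participants)) {
      stop("give `n_participants` when sharing one parameter set",
           call. = FALSE)
    }
    params_list <- rep(list(params_list), n_participants)
  }
  ids <- sprintf("P%02d", seq_along(params_list))
  purrr::map2_dfr(params_list, ids, function(p, id) {
    simulate_responses(design, p, participant = id, seed = seed)
  })
}

#' Draw ground-truth observer parameters for recovery studies
#'
#' Samples observer parameter sets uniformly within stated ranges, for use
#' as the generating truth in parameter-recovery simulations. One
#' measurement-noise SD is drawn per visual-noise level, then sorted
#' increasing so that noisier viewing conditions get larger SDs, matching
#' the experimental manipulation.
#'
#' @param model `"BCI"`, `"BCI*"` or `"FC"`.
#' @param ranges Named list of `c(lo, hi)` ranges. Recognised names:
#'   `p_same` (BCI/BCI*), `k0` (FC), `sigma`, `sigma_s` (BCI*), `lapse`.
#'   Defaults: `p_same` in \[0.3, 0.95\], `sigma` in \[60, 300\] ms,
#'   `lapse` in \[0, 0.2\], `k0` in \[50, 500\] ms, `sigma_s` in
#'   \[100, 600\] ms.
#' @param n_observers Number of parameter sets to draw.
#' @param seed Integer seed.
#' @param noise_levels Visual-noise labels the `sigma` entries cover.
#' @param sigma_s Fixed assumed SD for BCI/FC observers, ms.
#' @return A list of [observer_params()] objects.
#' @export
sample_ground_truth_params <- function(model = c("BCI", "BCI*", "FC"),
                                       ranges = list(),
                                       n_observers = 20,
                                       seed = 1,
                                       noise_levels = c(0, 30, 50),
                                       sigma_s = 348) {
  model <- match.arg(model)
  defaults <- list(p_same = c(0.3, 0.95), sigma = c(60, 300),
                   lapse = c(0, 0.2), k0 = c(50, 500), sigma_s = c(100, 600))
  ranges <- utils::modifyList(defaults, ranges)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || !all(is.finite(r)) || r[2] < r[1]) {
      stop("range for `", nm, "` must be a finite c(lo, hi) with lo <= hi",
           call. = FALSE)
    }
  }
  if (n_observers == 0) return(list())
  with_preserved_seed(seed, {
    purrr::map(seq_len(n_observers), function(i) {
      runit <- function(r) stats::runif(1, r[1], r[2])
      sig <- sort(stats::runif(length(noise_levels),
                               ranges$sigma[1], ranges$sigma[2]))
      names(sig) <- as.character(noise_levels)
      switch(model,
        "BCI" = observer_params("BCI", p_same = runit(ranges$p_same),
                                sigma = sig, sigma_s = sigma_s,
                                lapse = runit(ranges$lapse)),
        "BCI*" = observer_params("BCI*", p_same = runit(ranges$p_same),
                                 sigma = sig, sigma_s = runit(ranges$sigma_s),
                                 lapse = runit(ranges$lapse)),
        "FC" = observer_params("FC", k0 = runit(ranges$k0),
                               sigma = sig, sigma_s = sigma_s,
                               lapse = runit(ranges$lapse))
      )
    })
  })
}
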