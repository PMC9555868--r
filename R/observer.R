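#' Observer parameter bundles
#'
#' Bundles the parameters of one forward observer model:
#' \describe{
#'   \item{BCI}{Bayesian causal-inference observer. Compares the measured
#'     asynchrony against an uncertainty-dependent criterion derived from
#'     the posterior probability of a common cause. Free parameters:
#'     `p_same` (prior probability of a common cause), one measurement-noise
#'     SD per visual-noise level, and the lapse rate; `sigma_s` is fixed.}
#'   \item{BCI*}{As BCI, but the assumed SD of the distinct-cause asynchrony
#'     distribution `sigma_s` is itself free.}
#'   \item{FC}{Fixed-criterion observer: the decision threshold `k0` is a
#'     free constant that ignores trial-to-trial sensory uncertainty (the
#'     encoding stage is still noise-dependent).}
#' }
#'
#' @param model `"BCI"`, `"BCI*"` or `"FC"`.
#' @param p_same Prior probability of a common cause, in (0, 1). BCI/BCI*
#'   only.
#' @param k0 Fixed decision criterion in ms, > 0. FC only.
#' @param sigma Named numeric vector of measurement-noise SDs in ms, one per
#'   visual-noise level, e.g. `c("0" = 116, "30" = 141, "50" = 178)`.
#' @param sigma_s Assumed SD (ms) of the distinct-cause asynchrony
#'   distribution; a fixed constant for BCI and FC, the sixth free parameter
#'   for BCI*.
#' @param lapse Lapse rate: probability of an attention-independent random
#'   guess, split 50/50 between "yes" and "no". The forward model accepts
#'   any value in \[0, 1\] (lapse = 1 is a pure coin-flipper); fits
#'   constrain it to \[0, 0.5\] to keep it interpretable.
#'
#' @return An object of class `"observer_params"`.
#' @examples
#' observer_params("BCI", p_same = 0.8,
#'                 sigma = c("0" = 116, "30" = 141, "50" = 178),
#'                 lapse = 0.08)
#' @export
observer_params <- function(model = c("BCI", "BCI*", "FC"),
                            p_same = NULL, k0 = NULL,
                            sigma, sigma_s = 348, lapse = 0) {
  model <- match.arg(model)
  if (is.null(names(sigma)) || anyDuplicated(names(sigma))) {
    stop("`sigma` must be a named vector with one unique entry per noise level",
         call. = FALSE)
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("all measurement-noise SDs must be positive and finite", call. = FALSE)
  }
  if (!is.finite(sigma_s) || sigma_s <= 0) {
    stop("`sigma_s` must be a positive SD in ms", call. = FALSE)
  }
  if (!is.finite(lapse) || lapse < 0 || lapse > 1) {
    stop("`lapse` must lie in [0, 1]", call. = FALSE)
  }
  if (model %in% c("BCI", "BCI*")) {
    if (is.null(p_same) || !is.null(k0)) {
      stop("Bayesian observers take `p_same` (and no `k0`)", call. = FALSE)
    }
    if (!is.finite(p_same) || p_same <= 0 || p_same >= 1) {
      stop("`p_same` must lie strictly inside (0, 1)", call. = FALSE)
    }
  } else {
    if (is.null(k0) || !is.null(p_same)) {
      stop("the fixed-criterion observer takes `k0` (and no `p_same`)",
           call. = FALSE)
    }
    if (!is.finite(k0) || k0 <= 0) stop("`k0` must be > 0 ms", call. = FALSE)
  }
  structure(
    list(model = model, p_same = p_same, k0 = k0,
         sigma = sigma, sigma_s = as.numeric(sigma_s),
         lapse = as.numeric(lapse)),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>", x$model, "\n")
  if (!is.null(x$p_same)) cat("  p_same :", signif(x$p_same, 3), "\n")
  if (!is.null(x$k0)) cat("  k0     :", signif(x$k0, 3), "ms\n")
  cat("  sigma  :", paste(names(x$sigma), signif(x$sigma, 3),
                          sep = "=", collapse = ", "), "ms\n")
  cat("  sigma_s:", signif(x$sigma_s, 3), "ms",
      if (x$model == "BCI*") "(free)" else "(fixed)", "\n")
  cat("  lapse  :", signif(x$lapse, 3), "\n")
  invisible(x)
}

sigma_for_noise <- function(params, noise) {
  key <- as.character(noise)
  missing_lvls <- setdiff(unique(key), names(params$sigma))
  if (length(missing_lvls) > 0) {
    stop("no measurement-noise SD declared for noise level(s): ",
         paste(missing_lvls, collapse = ", "), call. = FALSE)
  }
  unname(params$sigma[key])
}

check_bci_domain <- function(p_same, sigma, sigma_s) {
  if (any(!is.finite(p_same)) || any(p_same <= 0) || any(p_same >= 1)) {
    stop("`p_same` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("`sigma` must be > 0", call. = FALSE)
  }
  if (any(!is.finite(sigma_s)) || any(sigma_s <= 0)) {
    stop("`sigma_s` must be > 0", call. = FALSE)
  }
}

#' Uncertainty-dependent decision criterion of the Bayesian observer
#'
#' The Bayesian observer reports a common cause when the measured
#' asynchrony `x` satisfies `|x| < k`, where
#' \deqn{k = \sqrt{K}, \quad
#'   K = \frac{\sigma^2(\sigma_S^2+\sigma^2)}{\sigma_S^2}
#'   \left[2\ln\frac{p_{same}}{1-p_{same}} +
#'         \ln\frac{\sigma_S^2+\sigma^2}{\sigma^2}\right].}
#' The criterion widens with the measurement noise \eqn{\sigma}: this is the
#' signature property that separates the Bayesian observer from a
#' fixed-criterion one. When the bracketed term is negative (`p_same` very
#' small) no measurement favours a common cause and the criterion is
#' undefined; `NA` is returned and the response probability reduces to pure
#' lapsing.
#'
#' @param p_same Prior probability of a common cause, in (0, 1).
#' @param sigma Measurement-noise SD, ms.
#' @param sigma_s Assumed distinct-cause SD, ms.
#' @return The criterion k in ms, or `NA` where K <= 0. Vectorised over all
#'   arguments.
#' @examples
#' decision_criterion(0.5, 100, 100)   # 117.74 ms
#' decision_criterion(0.8, 116, 348)   # 275.46 ms
#' decision_criterion(0.01, 100, 300)  # NA: never favours a common cause
#' @export
decision_criterion <- function(p_same, sigma, sigma_s) {
  check_bci_domain(p_same, sigma, sigma_s)
  v <- sigma^2
  vs <- sigma_s^2
  K <- v * (vs + v) / vs *
    (2 * log(p_same / (1 - p_same)) + log((vs + v) / v))
  ifelse(K > 0, sqrt(pmax(K, 0)), NA_real_)
}

#' Posterior log-odds of a common cause given a measurement
#'
#' For a measured asynchrony `x`, the log posterior ratio of the
#' common-cause versus distinct-cause hypotheses is the log prior ratio plus
#' the log likelihood ratio of `x` under N(0, sigma^2) (common cause: the
#' true asynchrony is 0) versus N(0, sigma_s^2 + sigma^2) (distinct causes:
#' the true asynchrony is itself dispersed with SD sigma_s):
#' \deqn{d = \ln\frac{p_{same}}{1-p_{same}} +
#'   \ln\frac{N(x; 0, \sigma^2)}{N(x; 0, \sigma_S^2+\sigma^2)}.}
#' `d > 0` is equivalent to `|x| <` [decision_criterion()] whenever the
#' criterion is defined.
#'
#' @inheritParams decision_criterion
#' @param x Measured asynchrony, ms.
#' @return The log-odds d (unitless), vectorised.
#' @export
posterior_log_odds <- function(x, p_same, sigma, sigma_s) {
  check_bci_domain(p_same, sigma, sigma_s)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  log(p_same / (1 - p_same)) +
    stats::dnorm(x, 0, sigma, log = TRUE) -
    stats::dnorm(x, 0, sqrt(sigma_s^2 + sigma^2), log = TRUE)
}

criterion_for <- function(params, sigma) {
  if (params$model == "FC") {
    rep(params$k0, length(sigma))
  } else {
    v <- sigma^2
    vs <- params$sigma_s^2
    K <- v * (vs + v) / vs *
      (2 * log(params$p_same / (1 - params$p_same)) + log((vs + v) / v))
    ifelse(K > 0, sqrt(pmax(K, 0)), NA_real_)
  }
}

#' Probability of reporting a common cause at a given asynchrony
#'
#' The forward psychometric function of an observer: the probability of a
#' "yes" report (rubber hand felt as one's own / touches felt synchronous)
#' at true asynchrony `s` under a given visual-noise level. With criterion
#' c (the Bayesian k or the fixed k0) and measurement noise sigma,
#' \deqn{p(\hat C = 1 \mid s) = \tfrac{\lambda}{2} + (1-\lambda)
#'   \left[\Phi\!\left(\frac{c-s}{\sigma}\right) -
#'         \Phi\!\left(\frac{-c-s}{\sigma}\right)\right],}
#' i.e. the probability mass of the measurement distribution N(s, sigma^2)
#' inside (-c, c), mixed with a 50/50 lapse. When the Bayesian criterion is
#' undefined the bracket is 0 and the probability is lambda/2. The function
#' is even in `s` and bounded by \[lambda/2, 1 - lambda/2\].
#'
#' @param s True asynchrony in ms (vectorised).
#' @param params An [observer_params()] object.
#' @param noise Visual-noise label(s); must be declared in `params$sigma`.
#'   Scalar or the same length as `s`.
#' @return Probabilities, same length as `s`.
#' @examples
#' p <- observer_params("BCI", p_same = 0.8, sigma = c("0" = 116),
#'                      sigma_s = 348, lapse = 0)
#' p_report_common(0, p, noise = 0) # 0.982
#' @export
p_report_common <- function(s, params, noise) {
  stopifnot(inherits(params, "observer_params"))
  if (any(!is.finite(s))) stop("`s` must be finite", call. = FALSE)
  sigma <- sigma_for_noise(params, noise)
  if (length(sigma) == 1) sigma <- rep(sigma, length(s))
  if (length(sigma) != length(s)) {
    stop("`noise` must be scalar or match the length of `s`", call. = FALSE)
  }
  k <- criterion_for(params, sigma)
  inside <- ifelse(
    is.na(k), 0,
    stats::pnorm((k - s) / sigma) - stats::pnorm((-k - s) / sigma)
  )
  params$lapse / 2 + (1 - params$lapse) * inside
}

#' Predicted response probabilities over a whole design
#'
#' Evaluates [p_report_common()] on every (noise, asynchrony) cell of a
#' design.
#'
#' @param design An [rhi_design()] object.
#' @param params An [observer_params()] object covering the design's noise
#'   levels.
#' @return A tibble with columns `task`, `noise`, `asynchrony_ms`,
#'   `n_trials`, `p_yes`.
#' @export
predicted_curve <- function(design, params) {
  stopifnot(inherits(design, "rhi_design"), inherits(params, "observer_params"))
  missing_lvls <- setdiff(as.character(design$noise_levels), names(params$sigma))
  if (length(missing_lvls) > 0) {
    stop("params declare no sigma for design noise level(s): ",
         paste(missing_lvls, collapse = ", "), call. = FALSE)
  }
  grid <- design_grid(design)
  grid$p_yes <- p_report_common(grid$asynchrony_ms, params, grid$noise)
  grid
}

#' Monte-Carlo decision oracle for the Bayesian observer
#'
#' Simulates the decision process measurement by measurement instead of
#' using the closed-form psychometric function: draws noisy measurements
#' x ~ N(s, sigma^2), computes the posterior log-odds of a common cause for
#' each, reports "common" when the log-odds are positive, and overrides the
#' report on lapse trials (probability `lapse`) with a fair coin. Used to
#' cross-validate [p_report_common()].
#'
#' @inheritParams p_report_common
#' @param noise A single visual-noise label.
#' @param n_samples Number of simulated trials.
#' @param seed Integer seed for reproducibility.
#' @return The empirical fraction of common-cause reports.
#' @export
mc_decision_oracle <- function(s, params, noise, n_samples = 1e5, seed = 1) {
  stopifnot(inherits(params, "observer_params"), length(s) == 1,
            length(noise) == 1, n_samples >= 1)
  if (params$model == "FC") {
    stop("the Monte-Carlo oracle simulates the Bayesian decision rule; ",
         "use BCI-family parameters", call. = FALSE)
  }
  sigma <- sigma_for_noise(params, noise)
  with_preserved_seed(seed, {
    x <- stats::rnorm(n_samples, mean = s, sd = sigma)
    d <- posterior_log_odds(x, params$p_same, sigma, params$sigma_s)
    report <- d > 0
    if (params$lapse > 0) {
      lapsed <- stats::runif(n_samples) < params$lapse
      guess <- stats::runif(n_samples) < 0.5
      report[lapsed] <- guess[lapsed]
    }
    mean(report)
  })
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
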