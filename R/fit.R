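# Multi-start bounded maximum-likelihood estimation for the observer models.
#
# The likelihood surface has at most 6 free parameters on 21-42 cells, so a
# multi-start local strategy is reliable: starts are drawn uniformly inside
# the box bounds from a seeded stream, and each start is polished with two
# local methods (L-BFGS-B, gradient-based; nlminb/PORT, quasi-Newton); the
# best incumbent over all runs is kept.

default_bounds <- function() {
  list(
    p_same = c(1e-3, 1 - 1e-3),
    sigma = c(1, 2000),
    sigma_s = c(10, 2000),
    k0 = c(1, 2000),
    lapse = c(0, 0.5)
  )
}

# Free-parameter layout for one model over a set of noise levels.
param_layout <- function(model, noise_levels, bounds = default_bounds(),
                         n_p_same = 1) {
  sig_names <- paste0("sigma_", noise_levels)
  if (model == "FC") {
    nm <- c("k0", sig_names, "lapse")
    lo <- c(bounds$k0[1], rep(bounds$sigma[1], length(sig_names)),
            bounds$lapse[1])
    hi <- c(bounds$k0[2], rep(bounds$sigma[2], length(sig_names)),
            bounds$lapse[2])
  } else {
    p_names <- if (n_p_same == 1) "p_same" else
      paste0("p_same_", c("ownership", "synchrony"))
    nm <- c(p_names, sig_names,
            if (model == "BCI*") "sigma_s",
            "lapse")
    lo <- c(rep(bounds$p_same[1], n_p_same),
            rep(bounds$sigma[1], length(sig_names)),
            if (model == "BCI*") bounds$sigma_s[1],
            bounds$lapse[1])
    hi <- c(rep(bounds$p_same[2], n_p_same),
            rep(bounds$sigma[2], length(sig_names)),
            if (model == "BCI*") bounds$sigma_s[2],
            bounds$lapse[2])
  }
  list(names = nm, lower = lo, upper = hi, sigma_names = sig_names)
}

theta_to_params <- function(theta, model, noise_levels, sigma_s_fixed,
                            p_same_name = "p_same") {
  sig <- theta[paste0("sigma_", noise_levels)]
  names(sig) <- as.character(noise_levels)
  switch(model,
    "BCI" = observer_params("BCI", p_same = unname(theta[p_same_name]),
                            sigma = sig, sigma_s = sigma_s_fixed,
                            lapse = unname(theta["lapse"])),
    "BCI*" = observer_params("BCI*", p_same = unname(theta[p_same_name]),
                             sigma = sig, sigma_s = unname(theta["sigma_s"]),
                             lapse = unname(theta["lapse"])),
    "FC" = observer_params("FC", k0 = unname(theta["k0"]), sigma = sig,
                           sigma_s = sigma_s_fixed,
                           lapse = unname(theta["lapse"]))
  )
}

# Fast likelihood path used inside the optimiser loop: plain vectors, no
# S3 construction or re-validation per evaluation. The reported final
# log-likelihood is recomputed through neg_log_likelihood() on the fitted
# observer_params, so the two routes cannot drift apart silently.
nll_kernel <- function(counts, noise_levels) {
  list(
    s = counts$asynchrony_ms,
    idx = match(as.character(counts$noise), as.character(noise_levels)),
    n = counts$n_trials,
    y = counts$n_yes
  )
}

kernel_nll <- function(kern, sig_levels, lapse, p_same = NULL,
                       sigma_s = NULL, k0 = NULL) {
  sig <- sig_levels[kern$idx]
  s <- kern$s
  if (is.null(k0)) {
    v <- sig * sig
    vs <- sigma_s * sigma_s
    K <- v * (vs + v) / vs *
      (2 * log(p_same / (1 - p_same)) + log((vs + v) / v))
    undef <- K <= 0
    K[undef] <- 1  # placeholder; masked below
    k <- sqrt(K)
    inside <- stats::pnorm((k - s) / sig) - stats::pnorm((-k - s) / sig)
    inside[undef] <- 0
  } else {
    inside <- stats::pnorm((k0 - s) / sig) - stats::pnorm((-k0 - s) / sig)
  }
  p <- 0.5 * lapse + (1 - lapse) * inside
  p[p < 1e-10] <- 1e-10
  p[p > 1 - 1e-10] <- 1 - 1e-10
  -sum(kern$y * log(p) + (kern$n - kern$y) * log1p(-p))
}

multistart_optimize <- function(objective, layout, n_starts, seed) {
  npar <- length(layout$names)
  starts <- with_preserved_seed(seed, {
    matrix(stats::runif(n_starts * npar,
                        rep(layout$lower, each = n_starts),
                        rep(layout$upper, each = n_starts)),
           nrow = n_starts, ncol = npar,
           dimnames = list(NULL, layout$names))
  })
  lo <- layout$lower
  hi <- layout$upper
  safe_obj <- function(th) {
    # guard the open (0,1) domain of priors against FD probes at the bounds
    th[th < lo] <- lo[th < lo]
    th[th > hi] <- hi[th > hi]
    v <- objective(th)
    if (!is.finite(v)) 1e12 else v
  }
  best <- list(value = Inf, par = starts[1, ], start = 1L, converged = FALSE)
  for (i in seq_len(n_starts)) {
    th0 <- starts[i, ]
    fits <- list(
      tryCatch(
        stats::optim(th0, safe_obj, method = "L-BFGS-B",
                     lower = layout$lower, upper = layout$upper,
                     control = list(maxit = 500,
                                    ndeps = rep(1e-6, npar))),
        error = function(e) NULL
      ),
      tryCatch({
        r <- stats::nlminb(th0, safe_obj, lower = layout$lower,
                           upper = layout$upper,
                           control = list(iter.max = 500, eval.max = 1000))
        list(par = r$par, value = r$objective,
             convergence = as.integer(r$convergence != 0))
      }, error = function(e) NULL)
    )
    for (f in fits) {
      if (!is.null(f) && is.finite(f$value) && f$value < best$value) {
        par <- pmin(pmax(f$par, layout$lower), layout$upper)
        names(par) <- layout$names
        best <- list(value = f$value, par = par, start = i,
                     converged = f$convergence == 0)
      }
    }
  }
  best
}

new_rhi_fit <- function(model, params, logLik, n_par, n_trials, n_starts,
                        best_start, converged, task = NULL,
                        participant = NULL, kind = "single",
                        shared_p_same = NA) {
  structure(
    list(model = model, params = params, logLik = logLik, n_par = n_par,
         n_trials = n_trials, aic = 2 * n_par - 2 * logLik,
         bic = n_par * log(n_trials) - 2 * logLik, n_starts = n_starts,
         best_start = best_start, converged = converged, task = task,
         participant = participant, kind = kind,
         shared_p_same = shared_p_same),
    class = "rhi_fit"
  )
}

#' @export
print.rhi_fit <- function(x, ...) {
  cat("<rhi_fit>", x$model,
      switch(x$kind, single = "single-task fit",
             extension = if (isTRUE(x$shared_p_same))
               "extension fit (shared p_same)" else
               "extension fit (task-specific p_same)",
             transfer_full = "full transfer evaluation",
             transfer_partial = "partial transfer (p_same/k0 refit)"),
      "\n")
  cat(sprintf("  logLik %.3f | AIC %.2f | BIC %.2f | n_par %d | n_trials %d\n",
              x$logLik, x$aic, x$bic, x$n_par, x$n_trials))
  cat("  converged:", x$converged, "| best start:", x$best_start, "of",
      x$n_starts, "\n")
  invisible(x)
}

#' Fit one observer model to one participant's counts
#'
#' Maximum-likelihood estimation of a single observer model (BCI, BCI* or
#' FC) on one participant x task counts table, by multi-start bounded local
#' optimisation of [neg_log_likelihood()]. Free parameters: BCI has
#' `p_same`, one sigma per noise level and `lapse` (5 with three noise
#' levels; `sigma_s` fixed); BCI* additionally frees `sigma_s` (6); FC has
#' `k0`, the sigmas and `lapse` (5).
#'
#' @param counts Counts tibble for a single participant and task.
#' @param model `"BCI"`, `"BCI*"` or `"FC"`.
#' @param n_starts Number of random starts (default 100), drawn uniformly
#'   inside the bounds from a stream seeded by `seed`; each start is
#'   polished by two local optimisers and the best result overall is kept.
#' @param seed Integer seed; refits with the same seed are identical.
#' @param sigma_s Fixed assumed distinct-cause SD in ms for BCI/FC.
#' @param bounds Optional list overriding elements of the default box
#'   bounds: `p_same` in \[1e-3, 1-1e-3\], `sigma` and `k0` in \[1, 2000\]
#'   ms, `sigma_s` in \[10, 2000\] ms, `lapse` in \[0, 0.5\].
#' @return An object of class `"rhi_fit"` with the fitted
#'   [observer_params()], the maximised log-likelihood, parameter and trial
#'   counts, AIC/BIC and optimiser diagnostics. `tidy()` and `glance()`
#'   methods are provided.
#' @examples
#' d <- rhi_design("ownership")
#' truth <- observer_params("BCI", p_same = 0.8,
#'                          sigma = c("0" = 116, "30" = 141, "50" = 178),
#'                          lapse = 0.05)
#' counts <- simulate_responses(d, truth, "P01", seed = 7)
#' fit <- fit_observer(counts, "BCI", n_starts = 10, seed = 1)
#' glance(fit)
#' @export
fit_observer <- function(counts, model = c("BCI", "BCI*", "FC"),
                         n_starts = 100, seed = 1, sigma_s = 348,
                         bounds = NULL) {
  model <- match.arg(model)
  counts <- validate_counts(counts, require_ids = FALSE)
  for (col in c("participant", "task")) {
    if (col %in% names(counts) && dplyr::n_distinct(counts[[col]]) > 1) {
      stop("`counts` must cover a single ", col,
           "; split the table (e.g. with dplyr::group_split()) first",
           call. = FALSE)
    }
  }
  b <- utils::modifyList(default_bounds(), bounds %||% list())
  noise_levels <- sort(unique(counts$noise))
  layout <- param_layout(model, noise_levels, b)
  kern <- nll_kernel(counts, noise_levels)
  sig_pos <- match(layout$sigma_names, layout$names)
  lapse_pos <- match("lapse", layout$names)
  obj <- switch(model,
    "BCI" = function(theta) kernel_nll(kern, theta[sig_pos],
                                       theta[lapse_pos],
                                       p_same = theta[1],
                                       sigma_s = sigma_s),
    "BCI*" = function(theta) kernel_nll(kern, theta[sig_pos],
                                        theta[lapse_pos],
                                        p_same = theta[1],
                                        sigma_s = theta[match("sigma_s",
                                                              layout$names)]),
    "FC" = function(theta) kernel_nll(kern, theta[sig_pos],
                                      theta[lapse_pos], k0 = theta[1])
  )
  best <- multistart_optimize(obj, layout, n_starts, seed)
  params <- theta_to_params(best$par, model, noise_levels, sigma_s)
  new_rhi_fit(
    model = model, params = params,
    logLik = -neg_log_likelihood(counts, params),
    n_par = length(layout$names), n_trials = sum(counts$n_trials),
    n_starts = n_starts, best_start = best$start, converged = best$converged,
    task = if ("task" %in% names(counts)) counts$task[1] else NULL,
    participant = if ("participant" %in% names(counts))
      counts$participant[1] else NULL
  )
}

#' Joint (extension) fit of the ownership and synchrony tasks
#'
#' Fits the Bayesian observer jointly to one participant's data from both
#' tasks. Sensory noise SDs and the lapse rate are always shared between
#' tasks (the stimulation is identical; only the judgment differs); the
#' prior probability of a common cause is either shared too
#' (`shared_p_same = TRUE`, 5 free parameters) or task-specific
#' (`FALSE`, 6 free parameters: `p_same_ownership`, `p_same_synchrony`).
#' The joint likelihood is the sum of the two tasks' likelihoods and
#' `n_trials` is the combined trial count.
#'
#' @param own_counts,sync_counts Counts tibbles for the ownership and
#'   synchrony tasks of the same participant.
#' @param shared_p_same Share one common-cause prior across tasks?
#' @inheritParams fit_observer
#' @return An `"rhi_fit"` whose `params` is a list with elements
#'   `ownership` and `synchrony` (identical when the prior is shared).
#' @export
fit_extension <- function(own_counts, sync_counts, shared_p_same = TRUE,
                          n_starts = 100, seed = 1, sigma_s = 348,
                          bounds = NULL) {
  own_counts <- validate_counts(own_counts, require_ids = FALSE)
  sync_counts <- validate_counts(sync_counts, require_ids = FALSE)
  b <- utils::modifyList(default_bounds(), bounds %||% list())
  noise_levels <- sort(unique(c(own_counts$noise, sync_counts$noise)))
  n_p <- if (shared_p_same) 1L else 2L
  layout <- param_layout("BCI", noise_levels, b, n_p_same = n_p)
  p_own <- if (shared_p_same) "p_same" else "p_same_ownership"
  p_syn <- if (shared_p_same) "p_same" else "p_same_synchrony"
  kern_own <- nll_kernel(own_counts, noise_levels)
  kern_syn <- nll_kernel(sync_counts, noise_levels)
  sig_pos <- match(layout$sigma_names, layout$names)
  lapse_pos <- match("lapse", layout$names)
  p_syn_pos <- if (shared_p_same) 1L else 2L
  obj <- function(theta) {
    kernel_nll(kern_own, theta[sig_pos], theta[lapse_pos],
               p_same = theta[1], sigma_s = sigma_s) +
      kernel_nll(kern_syn, theta[sig_pos], theta[lapse_pos],
                 p_same = theta[p_syn_pos], sigma_s = sigma_s)
  }
  best <- multistart_optimize(obj, layout, n_starts, seed)
  params <- list(
    ownership = theta_to_params(best$par, "BCI", noise_levels, sigma_s,
                                p_same_name = p_own),
    synchrony = theta_to_params(best$par, "BCI", noise_levels, sigma_s,
                                p_same_name = p_syn)
  )
  new_rhi_fit(
    model = "BCI", params = params,
    logLik = -neg_log_likelihood(own_counts, params$ownership) -
      neg_log_likelihood(sync_counts, params$synchrony),
    n_par = length(layout$names),
    n_trials = sum(own_counts$n_trials) + sum(sync_counts$n_trials),
    n_starts = n_starts, best_start = best$start, converged = best$converged,
    participant = if ("participant" %in% names(own_counts))
      own_counts$participant[1] else NULL,
    kind = "extension", shared_p_same = shared_p_same
  )
}

#' Transfer a fitted observer to the other task's data
#'
#' Evaluates how well the parameters estimated on one task predict the data
#' of the other. In a *full* transfer every source parameter is reused and
#' nothing is re-fitted (0 free parameters: the log-likelihood is a pure
#' prediction score). In a *partial* transfer only the common-cause prior
#' `p_same` (or the criterion `k0` for the fixed-criterion observer) is
#' re-optimised on the target data (1 free parameter). AIC/BIC are computed
#' with these parameter counts and the target task's trial count.
#'
#' @param source_fit An `"rhi_fit"` from [fit_observer()] on the source
#'   task.
#' @param target_counts Counts tibble of the other task (same participant).
#' @param mode `"full"` or `"partial"`.
#' @param n_starts Grid resolution used to bracket the 1-D optimum in
#'   partial mode (the refit itself is deterministic).
#' @param seed Unused in full mode; kept for interface symmetry.
#' @return An `"rhi_fit"` describing the transfer evaluation.
#' @export
transfer_evaluate <- function(source_fit, target_counts,
                              mode = c("full", "partial"),
                              n_starts = 100, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(source_fit, "rhi_fit"))
  if (source_fit$kind != "single") {
    stop("`source_fit` must be a single-task fit", call. = FALSE)
  }
  target_counts <- validate_counts(target_counts, require_ids = FALSE)
  params <- source_fit$params
  n_trials <- sum(target_counts$n_trials)
  if (mode == "full") {
    ll <- -neg_log_likelihood(target_counts, params)
    return(new_rhi_fit(source_fit$model, params, ll, n_par = 0L,
                       n_trials = n_trials, n_starts = 0L, best_start = NA,
                       converged = TRUE,
                       task = if ("task" %in% names(target_counts))
                         target_counts$task[1] else NULL,
                       participant = source_fit$participant,
                       kind = "transfer_full"))
  }
  b <- default_bounds()
  free <- if (params$model == "FC") "k0" else "p_same"
  rng <- b[[free]]
  refit <- function(value) {
    p <- params
    p[[free]] <- value
    neg_log_likelihood(target_counts, p)
  }
  grid <- seq(rng[1], rng[2], length.out = max(n_starts, 10))
  vals <- vapply(grid, refit, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(refit, lower = lo, upper = hi, tol = 1e-9)
  best_val <- if (opt$objective < vals[i]) opt$objective else vals[i]
  best_par <- if (opt$objective < vals[i]) opt$minimum else grid[i]
  new_params <- params
  new_params[[free]] <- best_par
  new_rhi_fit(source_fit$model, new_params, -best_val, n_par = 1L,
              n_trials = n_trials, n_starts = length(grid), best_start = i,
              converged = TRUE,
              task = if ("task" %in% names(target_counts))
                target_counts$task[1] else NULL,
              participant = source_fit$participant,
              kind = "transfer_partial")
}

params_as_vector <- function(params) {
  out <- c(
    if (!is.null(params$p_same)) c(p_same = params$p_same),
    if (!is.null(params$k0)) c(k0 = params$k0),
    stats::setNames(as.numeric(params$sigma),
                    paste0("sigma_", names(params$sigma))),
    if (params$model == "BCI*") c(sigma_s = params$sigma_s),
    lapse = params$lapse
  )
  out
}

#' Parameter-recovery simulation
#'
#' Validates the estimation pipeline end to end: draws ground-truth
#' observers at random ([sample_ground_truth_params()]), simulates each
#' one's session ([simulate_responses()]), refits the generating model
#' ([fit_observer()]) and tabulates estimated against true parameters.
#'
#' @param model `"BCI"`, `"BCI*"` or `"FC"`.
#' @param n_observers Number of simulated observers.
#' @param design An [rhi_design()]; defaults to the ownership task.
#' @param ranges Passed to [sample_ground_truth_params()].
#' @param n_starts,seed Passed to the simulation and fitting stages.
#' @param sigma_s Fixed assumed distinct-cause SD (BCI/FC), ms.
#' @return An object of class `"recovery_report"`: a list with `results`
#'   (one row per observer x parameter: `true`, `estimated`, `abs_error`,
#'   `rel_error`) and `summary` (per parameter: correlation of true and
#'   estimated values, median absolute and relative error).
#' @export
run_parameter_recovery <- function(model = c("BCI", "BCI*", "FC"),
                                   n_observers = 20,
                                   design = rhi_design("ownership"),
                                   ranges = list(), n_starts = 100,
                                   seed = 1, sigma_s = 348) {
  model <- match.arg(model)
  truths <- sample_ground_truth_params(model, ranges, n_observers, seed,
                                       noise_levels = design$noise_levels,
                                       sigma_s = sigma_s)
  results <- purrr::imap_dfr(truths, function(truth, i) {
    id <- sprintf("S%03d", i)
    counts <- simulate_responses(design, truth, participant = id, seed = seed)
    fit <- fit_observer(counts, model, n_starts = n_starts,
                        seed = seed + i, sigma_s = sigma_s)
    tv <- params_as_vector(truth)
    ev <- params_as_vector(fit$params)[names(tv)]
    tibble::tibble(
      observer = id, parameter = names(tv),
      true = unname(tv), estimated = unname(ev),
      abs_error = abs(unname(ev) - unname(tv)),
      rel_error = abs(unname(ev) - unname(tv)) / pmax(abs(unname(tv)), 1e-12)
    )
  })
  summary <- results |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      correlation = if (stats::sd(.data$true) > 0)
        stats::cor(.data$true, .data$estimated) else NA_real_,
      median_abs_error = stats::median(.data$abs_error),
      median_rel_error = stats::median(.data$rel_error),
      .groups = "drop"
    )
  structure(list(results = results, summary = summary, model = model,
                 n_observers = n_observers),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", x$model, "model,", x$n_observers, "observers\n")
  print(x$summary)
  invisible(x)
}
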