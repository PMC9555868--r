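# Random-effects Bayesian model selection at the group level.
#
# Variational scheme over model frequencies (Stephan et al. 2009,
# NeuroImage 46:1004-1017): model frequencies r ~ Dirichlet(alpha), each
# participant's model assignment m_n ~ Multinomial(r), observed through the
# per-participant log model evidence. The posterior Dirichlet weights,
# exceedance probabilities, the Bayes omnibus risk (Rigoux et al. 2014,
# NeuroImage 84:971-985) and protected exceedance probabilities are
# returned.

#' Random-effects group-level Bayesian model selection
#'
#' Treats the model identity as a random effect across participants:
#' population model frequencies get a Dirichlet prior (alpha0 = 1 per
#' model), and a variational scheme alternates participant-wise model
#' responsibilities with Dirichlet weight updates until the weights change
#' by less than `tol`. Log model evidence per participant and model is
#' approximated from information criteria (conventionally `-AIC/2` or
#' `-BIC/2`; see [log_evidence_matrix()]).
#'
#' The exceedance probability (EP) of a model is the posterior probability
#' that it is the most frequent one in the population, estimated from
#' seeded Dirichlet Monte-Carlo draws. The Bayes omnibus risk (BOR) is the
#' posterior probability that all models are equally frequent, from the
#' free-energy comparison of the random-effects model against the
#' equal-frequency null; the protected EP discounts the EP by it:
#' `pEP = EP * (1 - BOR) + BOR / K`.
#'
#' @param log_evidence Numeric matrix, participants x models, of log model
#'   evidence; column names label the models.
#' @param families Optional named list mapping family names to column
#'   indices or model names, e.g. `list(bayesian = c("BCI", "BCI*"),
#'   fixed = "FC")`. Family-level frequencies aggregate the Dirichlet
#'   weights by summation and family EPs are computed from the same
#'   Dirichlet draws.
#' @param n_samples Dirichlet Monte-Carlo draws for the EPs (default 1e5).
#' @param seed Integer seed for the Monte-Carlo step.
#' @param tol,max_iter Convergence control for the variational updates.
#' @return An object of class `"bms_result"`: a list with
#'   `dirichlet_alpha`, `expected_frequencies`,
#'   `exceedance_probabilities`, `bor`, `protected_exceedance_probabilities`,
#'   `free_energy`, `null_free_energy`, and optionally `family_frequencies`
#'   and `family_exceedance`.
#' @examples
#' L <- cbind(BCI = c(-120, -118, -130), FC = c(-125, -124, -129))
#' rfx_bms(L, n_samples = 1e4, seed = 1)
#' @export
rfx_bms <- function(log_evidence, families = NULL, n_samples = 1e5,
                    seed = 1, tol = 1e-6, max_iter = 1e4) {
  L <- as.matrix(log_evidence)
  if (ncol(L) < 2) stop("need at least two models", call. = FALSE)
  if (any(!is.finite(L))) {
    stop("`log_evidence` must be finite", call. = FALSE)
  }
  K <- ncol(L)
  N <- nrow(L)
  models <- colnames(L) %||% paste0("M", seq_len(K))
  alpha0 <- rep(1, K)
  alpha <- alpha0
  g <- matrix(1 / K, N, K)
  for (iter in seq_len(max_iter)) {
    eln_r <- digamma(alpha) - digamma(sum(alpha))
    lu <- sweep(L, 2, eln_r, `+`)
    lu <- lu - apply(lu, 1, max)
    g <- exp(lu) / rowSums(exp(lu))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  eln_r <- digamma(alpha) - digamma(sum(alpha))

  # negative free energy of the random-effects model
  e_log_joint <- sum(g * (L + matrix(eln_r, N, K, byrow = TRUE)))
  e_log_p_r <- lgamma(sum(alpha0)) - sum(lgamma(alpha0)) +
    sum((alpha0 - 1) * eln_r)
  e_log_q_r <- lgamma(sum(alpha)) - sum(lgamma(alpha)) +
    sum((alpha - 1) * eln_r)
  ent_q_m <- -sum(g[g > 0] * log(g[g > 0]))
  f_rfx <- e_log_joint + e_log_p_r - e_log_q_r + ent_q_m
  # null: every participant's data marginalised over equally frequent models
  row_lse <- apply(L, 1, function(r) {
    m <- max(r)
    m + log(sum(exp(r - m)))
  })
  f_null <- sum(row_lse - log(K))
  bor <- 1 / (1 + exp(f_rfx - f_null))

  draws <- with_preserved_seed(seed, {
    m <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each =
                                                           n_samples)),
                nrow = n_samples, ncol = K)
    m / rowSums(m)
  })
  winner <- max.col(draws, ties.method = "first")
  ep <- tabulate(winner, nbins = K) / n_samples
  pep <- ep * (1 - bor) + bor / K

  out <- list(
    models = models,
    dirichlet_alpha = stats::setNames(alpha, models),
    expected_frequencies = stats::setNames(alpha / sum(alpha), models),
    exceedance_probabilities = stats::setNames(ep, models),
    bor = bor,
    protected_exceedance_probabilities = stats::setNames(pep, models),
    free_energy = f_rfx,
    null_free_energy = f_null,
    n_iterations = iter
  )
  if (!is.null(families)) {
    fam_idx <- lapply(families, function(f) {
      if (is.character(f)) match(f, models) else as.integer(f)
    })
    if (any(is.na(unlist(fam_idx)))) {
      stop("`families` refer to unknown models", call. = FALSE)
    }
    fam_alpha <- vapply(fam_idx, function(i) sum(alpha[i]), numeric(1))
    fam_share <- vapply(fam_idx, function(i) rowSums(draws[, i, drop = FALSE]),
                        numeric(n_samples))
    fam_winner <- max.col(fam_share, ties.method = "first")
    fam_ep <- tabulate(fam_winner, nbins = length(fam_idx)) / n_samples
    out$family_frequencies <- fam_alpha / sum(fam_alpha)
    out$family_exceedance <- stats::setNames(fam_ep, names(families))
  }
  structure(out, class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result>", length(x$models), "models,",
      x$n_iterations, "variational iterations\n")
  tab <- data.frame(
    alpha = round(x$dirichlet_alpha, 3),
    freq = round(x$expected_frequencies, 3),
    ep = round(x$exceedance_probabilities, 3),
    protected_ep = round(x$protected_exceedance_probabilities, 3)
  )
  print(tab)
  cat("Bayes omnibus risk:", signif(x$bor, 3), "\n")
  if (!is.null(x$family_exceedance)) {
    cat("family EP:", paste(names(x$family_exceedance),
                            round(x$family_exceedance, 3),
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Log-evidence matrix from a list-column of fits
#'
#' Approximates each fit's log model evidence as `-AIC/2` (default) or
#' `-BIC/2`, arranged as a participants x models matrix for [rfx_bms()].
#'
#' @param fits_by_model Named list of lists of `"rhi_fit"` objects; each
#'   element is one model's fits across the same participants, in the same
#'   order.
#' @param criterion `"aic"` or `"bic"`.
#' @return A numeric matrix, participants x models.
#' @export
log_evidence_matrix <- function(fits_by_model, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  n <- unique(vapply(fits_by_model, length, integer(1)))
  if (length(n) != 1) {
    stop("all models must be fitted to the same participants", call. = FALSE)
  }
  sapply(fits_by_model, function(fits) {
    vapply(fits, function(f) -f[[criterion]] / 2, numeric(1))
  })
}
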