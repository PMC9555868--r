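#' Build a factorial stimulus design for a detection task
#'
#' Constructs the factorial grid of a yes/no visuotactile detection
#' experiment: signed asynchronies between the seen and the felt touch,
#' crossed with categorical visual-noise levels, each cell repeated a fixed
#' number of times. The default designs are the two tasks of the rubber-hand
#' paradigm: the body-ownership judgment uses asynchronies of 0, +/-150,
#' +/-300 and +/-500 ms, the synchrony judgment 0, +/-50, +/-150 and
#' +/-300 ms; both cross 7 asynchronies with 3 noise levels (0, 30, 50
#' percent white-noise pixels) and 12 repetitions, i.e. 252 trials per
#' participant and task.
#'
#' Positive asynchronies mean the participant's real hand was touched first;
#' negative ones mean the rubber hand was touched first. The design also
#' carries `sigma_s`, the spread (SD, ms) of the asynchrony distribution the
#' observer is assumed to expect under distinct causes; the default is the
#' 348 ms value obtained by rounding the root-mean-square of the six nonzero
#' ownership asynchronies (see [assumed_sigma_s()]).
#'
#' @param task `"ownership"` or `"synchrony"`.
#' @param asynchronies Signed asynchronies in ms. Must be symmetric about 0
#'   and include 0. Defaults to the task's canonical levels.
#' @param noise_levels Visual-noise labels (percent), default `c(0, 30, 50)`.
#' @param reps_per_cell Repetitions of each (asynchrony, noise) cell.
#' @param sigma_s Assumed SD (ms) of the distinct-cause asynchrony
#'   distribution used by Bayesian observers fitted to this design.
#'
#' @return An object of class `"rhi_design"`: a list with fields `task`,
#'   `asynchronies`, `noise_levels`, `reps_per_cell`, `sigma_s`.
#' @seealso [design_grid()], [assumed_sigma_s()], [simulate_responses()]
#' @examples
#' d <- rhi_design("ownership")
#' nrow(design_grid(d)) # 21 cells
#' @export
rhi_design <- function(task = c("ownership", "synchrony"),
                       asynchronies = NULL,
                       noise_levels = c(0, 30, 50),
                       reps_per_cell = 12,
                       sigma_s = 348) {
  task <- match.arg(task)
  if (is.null(asynchronies)) {
    asynchronies <- switch(task,
      ownership = c(-500, -300, -150, 0, 150, 300, 500),
      synchrony = c(-300, -150, -50, 0, 50, 150, 300)
    )
  }
  asynchronies <- sort(unique(as.numeric(asynchronies)))
  if (!0 %in% asynchronies) {
    stop("`asynchronies` must include 0 (the synchronous condition)",
         call. = FALSE)
  }
  if (!setequal(asynchronies, -asynchronies)) {
    stop("`asynchronies` must be symmetric about 0", call. = FALSE)
  }
  if (length(noise_levels) < 1 || anyDuplicated(noise_levels)) {
    stop("`noise_levels` must be a non-empty set of distinct labels",
         call. = FALSE)
  }
  if (reps_per_cell < 1) stop("`reps_per_cell` must be >= 1", call. = FALSE)
  if (!is.numeric(sigma_s) || sigma_s <= 0) {
    stop("`sigma_s` must be a positive SD in ms", call. = FALSE)
  }
  structure(
    list(
      task = task,
      asynchronies = asynchronies,
      noise_levels = as.numeric(noise_levels),
      reps_per_cell = as.integer(reps_per_cell),
      sigma_s = as.numeric(sigma_s)
    ),
    class = "rhi_design"
  )
}

#' @export
print.rhi_design <- function(x, ...) {
  cat("<rhi_design> task:", x$task, "\n")
  cat("  asynchronies (ms):", paste(x$asynchronies, collapse = ", "), "\n")
  cat("  noise levels (%): ", paste(x$noise_levels, collapse = ", "), "\n")
  cat("  reps per cell:    ", x$reps_per_cell,
      " (", length(x$asynchronies) * length(x$noise_levels) *
        x$reps_per_cell, " trials)\n", sep = "")
  cat("  assumed sigma_s:  ", x$sigma_s, "ms\n")
  invisible(x)
}

#' Expand a design into its cell grid
#'
#' @param design An [rhi_design()] object.
#' @return A tibble with one row per (noise, asynchrony) cell and columns
#'   `task`, `noise`, `asynchrony_ms`, `n_trials`.
#' @export
design_grid <- function(design) {
  stopifnot(inherits(design, "rhi_design"))
  tidyr::expand_grid(
    task = design$task,
    noise = design$noise_levels,
    asynchrony_ms = design$asynchronies
  ) |>
    dplyr::mutate(n_trials = design$reps_per_cell)
}

#' Root-mean-square spread of the nonzero asynchronies
#'
#' The Bayesian observers assume that under distinct causes the asynchrony
#' is normally distributed around 0. The natural choice for its SD is the
#' population SD (divisor n, about 0) of the nonzero asynchronies actually
#' presented, i.e. their root-mean-square. For the ownership task levels
#' (+/-150, +/-300, +/-500 ms) this is 347.6 ms, conventionally rounded to
#' 348 ms; for the synchrony levels (+/-50, +/-150, +/-300 ms) it is
#' 195.8 ms.
#'
#' @param nonzero_asynchronies Numeric vector of signed asynchronies in ms
#'   (zeros are not expected; signs are irrelevant).
#' @return The RMS value in ms.
#' @examples
#' assumed_sigma_s(c(-500, -300, -150, 150, 300, 500)) # 347.61
#' @export
assumed_sigma_s <- function(nonzero_asynchronies) {
  if (length(nonzero_asynchronies) == 0) {
    stop("`nonzero_asynchronies` must be non-empty", call. = FALSE)
  }
  sqrt(mean(as.numeric(nonzero_asynchronies)^2))
}
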