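counts_cols <- c("participant", "task", "noise", "asynchrony_ms",
                 "n_trials", "n_yes")

#' Read and write tidy condition-count tables
#'
#' The canonical on-disk format is a tidy CSV with one row per
#' (participant, task, noise, asynchrony) cell and columns `participant`,
#' `task`, `noise`, `asynchrony_ms`, `n_trials`, `n_yes`. Reading validates
#' the header, the count invariants (0 <= n_yes <= n_trials) and key
#' uniqueness, naming the offending rows; writing then reading returns the
#' same rows.
#'
#' @param path File path.
#' @return `read_counts_csv()` returns a validated tibble;
#'   `write_counts_csv()` returns `path` invisibly.
#' @export
read_counts_csv <- function(path) {
  counts <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              participant = readr::col_character(),
                              task = readr::col_character(),
                              .default = readr::col_double()
                            ))
  miss <- setdiff(counts_cols, names(counts))
  if (length(miss) > 0) {
    stop("counts file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  counts <- counts[counts_cols]
  counts$n_trials <- as.integer(counts$n_trials)
  counts$n_yes <- as.integer(counts$n_yes)
  validate_counts(counts, require_ids = TRUE)
  keys <- paste(counts$participant, counts$task, counts$noise,
                counts$asynchrony_ms)
  if (anyDuplicated(keys)) {
    stop("duplicate (participant, task, noise, asynchrony) keys in row(s): ",
         paste(utils::head(which(duplicated(keys)), 5), collapse = ", "),
         call. = FALSE)
  }
  counts
}

#' @param counts A counts tibble with the canonical columns.
#' @rdname read_counts_csv
#' @export
write_counts_csv <- function(counts, path) {
  counts <- validate_counts(counts, require_ids = TRUE)
  readr::write_csv(counts[counts_cols], path)
  invisible(path)
}

#' Load a wide-format (one column per asynchrony) counts table
#'
#' Loader shim for deposited source-data-style spreadsheets in which each
#' asynchrony level is a column of yes-counts and rows identify the
#' participant and noise level. Columns other than `participant`, `task`,
#' `noise` and `n_trials` are interpreted as signed asynchronies in ms.
#'
#' @param path CSV file path.
#' @param task Task label to assign when the file has no `task` column.
#' @param n_trials Trials per cell when the file has no `n_trials` column.
#' @return A tidy counts tibble in the canonical layout.
#' @export
read_counts_wide <- function(path, task = "ownership", n_trials = 12) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  if (!"participant" %in% names(wide)) {
    stop("wide counts file needs a `participant` column", call. = FALSE)
  }
  if (!"task" %in% names(wide)) wide$task <- task
  if (!"n_trials" %in% names(wide)) wide$n_trials <- n_trials
  if (!"noise" %in% names(wide)) {
    stop("wide counts file needs a `noise` column", call. = FALSE)
  }
  id_cols <- c("participant", "task", "noise", "n_trials")
  asyn_cols <- setdiff(names(wide), id_cols)
  if (any(is.na(suppressWarnings(as.numeric(asyn_cols))))) {
    stop("non-numeric asynchrony column name(s): ",
         paste(asyn_cols[is.na(suppressWarnings(as.numeric(asyn_cols)))],
               collapse = ", "), call. = FALSE)
  }
  long <- tidyr::pivot_longer(wide, cols = dplyr::all_of(asyn_cols),
                              names_to = "asynchrony_ms",
                              values_to = "n_yes")
  long$asynchrony_ms <- as.numeric(long$asynchrony_ms)
  long$n_trials <- as.integer(long$n_trials)
  long$n_yes <- as.integer(long$n_yes)
  long$participant <- as.character(long$participant)
  validate_counts(long[counts_cols], require_ids = TRUE)
}

#' Group-level descriptive response proportions
#'
#' Per-participant percentage of "yes" responses in each (noise,
#' asynchrony) cell, summarised across participants as mean and standard
#' error of the mean (SD/sqrt(n)).
#'
#' @param counts A counts tibble (canonical columns).
#' @return A tibble with one row per (task, noise, asynchrony_ms) and
#'   columns `mean_pct_yes`, `sem_pct_yes`, `n_participants`.
#' @export
descriptive_proportions <- function(counts) {
  counts <- validate_counts(counts, require_ids = TRUE)
  if (nrow(counts) == 0) stop("`counts` is empty", call. = FALSE)
  counts |>
    dplyr::mutate(pct_yes = 100 * .data$n_yes / .data$n_trials) |>
    dplyr::group_by(.data$task, .data$noise, .data$asynchrony_ms) |>
    dplyr::summarise(
      mean_pct_yes = mean(.data$pct_yes),
      sem_pct_yes = if (dplyr::n() > 1)
        stats::sd(.data$pct_yes) / sqrt(dplyr::n()) else 0,
      n_participants = dplyr::n(),
      .groups = "drop"
    )
}

#' Paired t statistic
#'
#' Classical paired t-test on matched samples:
#' `t = mean(a - b) / (sd(a - b) / sqrt(n))` with `df = n - 1`.
#'
#' @param a,b Numeric vectors of equal length (n >= 2).
#' @return A one-row tibble with `t`, `df` and the two-sided `p_value`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("`a` and `b` must have equal length >= 2", call. = FALSE)
  }
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) {
    stop("degenerate input: the paired differences have zero variance",
         call. = FALSE)
  }
  n <- length(d)
  t <- mean(d) / (s / sqrt(n))
  tibble::tibble(t = t, df = n - 1,
                 p_value = 2 * stats::pt(-abs(t), df = n - 1))
}

#' Pearson product-moment correlation
#'
#' @param a,b Numeric vectors of equal length (n >= 3) with nonzero
#'   variance.
#' @return The correlation coefficient r.
#' @export
pearson_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3) {
    stop("`a` and `b` must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  da <- a - mean(a)
  db <- b - mean(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}
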