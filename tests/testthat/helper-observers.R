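# Shared fixtures: group-typical observer parameters and small builders.

typical_sigma <- c("0" = 116, "30" = 141, "50" = 178)

coin_flipper <- function() typical_bci(lapse = 1)

typical_bci <- function(p_same = 0.8, lapse = 0.08, sigma_s = 348) {
  observer_params("BCI", p_same = p_same, sigma = typical_sigma,
                  sigma_s = sigma_s, lapse = lapse)
}

# A small counts table built by hand (valid by construction).
tiny_counts <- function() {
  tibble::tibble(
    participant = "P01", task = "ownership",
    noise = c(0, 0, 30), asynchrony_ms = c(0, 300, 0),
    n_trials = c(12L, 12L, 12L), n_yes = c(11L, 4L, 12L)
  )
}

# Binomial 3-SE check helper: |phat - p| <= 3 * sqrt(p(1-p)/n)
expect_within_3se <- function(phat, p, n) {
  se <- sqrt(p * (1 - p) / n)
  expect_lte(abs(phat - p), 3 * se + 1e-12)
}
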