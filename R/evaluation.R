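#' Observed vs. expected composition comparison
#'
#' Pairs each species' observed relative proportion (percent) with its
#' expected proportion. An expected value of 0 marks a false-positive
#' species; the per-species difference is `observed - expected`.
#'
#' @param species Character (or taxid) vector of unique species keys.
#' @param expected Expected percents, in [0, 100].
#' @param observed Observed percents, in [0, 100].
#' @return A `composition_comparison` data.frame with columns `species`,
#'   `expected`, `observed`, `diff`.
#' @export
composition_comparison <- function(species, expected, observed) {
  species <- as.character(species)
  if (length(species) == 0L) stop("at least one species is required")
  if (anyDuplicated(species)) stop("species keys must be unique")
  stopifnot(length(expected) == length(species),
            length(observed) == length(species),
            all(expected >= 0 & expected <= 100),
            all(observed >= 0 & observed <= 100))
  structure(data.frame(species = species, expected = expected,
                       observed = observed, diff = observed - expected,
                       stringsAsFactors = FALSE),
            class = c("composition_comparison", "data.frame"))
}

#' Median absolute difference between observed and expected proportions
#'
#' For each true-positive species, the absolute difference of the observed
#' proportion from the known proportion; for each false-positive species
#' (expected 0), the observed proportion itself. The median over all listed
#' species is the headline accuracy statistic (even counts average the
#' central pair).
#'
#' @param comparison A [composition_comparison()].
#' @return Median absolute difference, in percent.
#' @export
median_abs_difference <- function(comparison) {
  stopifnot(inherits(comparison, "composition_comparison"),
            nrow(comparison) >= 1L)
  stats::median(abs(comparison$diff))
}

#' Species with the largest divergence from its target proportion
#'
#' Among species with an expected proportion above zero, the one whose
#' observed proportion diverges most (by absolute difference), returned
#' with the signed difference. Ties break by species key order.
#'
#' @param comparison A [composition_comparison()].
#' @return A list with `species` and `divergence` (signed percent).
#' @export
max_divergence <- function(comparison) {
  stopifnot(inherits(comparison, "composition_comparison"))
  pos <- comparison[comparison$expected > 0, , drop = FALSE]
  if (nrow(pos) == 0L)
    stop("no species with expected proportion > 0")
  pos <- pos[order(-abs(pos$diff), pos$species), , drop = FALSE]
  list(species = pos$species[1L], divergence = pos$diff[1L])
}

#' Chi-square comparison of observed and expected compositions
#'
#' Pearson statistic `sum((observed - expected)^2 / expected)` over the
#' included species, with `df = (rows - 1) * (cols - 1)` for rows = species
#' and cols = 2 (observed, expected), i.e. `df = species - 1`, and a
#' one-sided p-value from the chi-square survival function. Species with
#' expected 0 are excluded by default, since the statistic divides by the
#' expected value; with exclusion off their presence is an explicit error
#' rather than a silent infinity.
#'
#' @param comparison A [composition_comparison()].
#' @param exclude_zero_expected Drop expected-zero species before computing
#'   the statistic (default `TRUE`).
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
chi_square_composition <- function(comparison, exclude_zero_expected = TRUE) {
  stopifnot(inherits(comparison, "composition_comparison"))
  inc <- comparison
  if (exclude_zero_expected) {
    inc <- inc[inc$expected > 0, , drop = FALSE]
  } else if (any(inc$expected == 0)) {
    stop("expected proportion of 0 for species ",
         inc$species[inc$expected == 0][1L],
         " would divide by zero; use exclude_zero_expected = TRUE")
  }
  if (nrow(inc) < 2L)
    stop("need at least 2 species with expected > 0")
  statistic <- sum((inc$observed - inc$expected)^2 / inc$expected)
  df <- nrow(inc) - 1L
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE))
}

#' Combined observed proportion of the true-positive species
#'
#' Sum of observed percents over all species with expected proportion
#' above zero — how much of the species-assigned signal lands on truly
#' present ingredients.
#'
#' @param comparison A [composition_comparison()].
#' @return Percent in [0, 100 + rounding].
#' @export
true_positive_mass <- function(comparison) {
  stopifnot(inherits(comparison, "composition_comparison"))
  sum(comparison$observed[comparison$expected > 0])
}
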