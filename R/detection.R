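#' Probability of detecting a species in a read subsample
#'
#' Sampling n reads without replacement from a library of N reads of which
#' K come from species S, the number of sampled S-reads is hypergeometric.
#' This returns the exact upper tail Pr(X >= r): the probability that a
#' subsample of size `n` contains at least `r` reads from S — the chance of
#' detecting S at a read-count limit of detection of r.
#'
#' @param N Total reads in the full sample.
#' @param n Subsample size (0 <= n <= N).
#' @param r Required number of S-reads in the subsample (the limit of
#'   detection when used as a target).
#' @param K Reads from S in the full sample; give either `K` or `f`.
#' @param f Frequency of S in the full sample; `K` is derived as
#'   `round(N * f)` (or `floor` via `rounding`).
#' @param rounding How `K` is derived from `f`: `"round"` (default) or
#'   `"floor"`.
#' @return `Pr(X >= r)`, a number in [0, 1]. The complementary probability
#'   of at most `r - 1` sampled S-reads is its complement, `1 - P`.
#'   `r > n` returns 0 with a warning (more successes than draws is
#'   impossible); `r = 0` returns 1.
#' @details Computed with the numerically stable survival routine
#'   `stats::phyper(r - 1, K, N - K, n, lower.tail = FALSE)`; both tails of
#'   the same distribution, so `P + P' = 1` exactly.
#' @export
detection_probability <- function(N, n, r, K = NULL, f = NULL,
                                  rounding = c("round", "floor")) {
  rounding <- match.arg(rounding)
  if (is.null(K)) {
    if (is.null(f)) stop("give either K or f")
    stopifnot(f >= 0, f <= 1)
    K <- if (rounding == "round") round(N * f) else floor(N * f)
  }
  stopifnot(N >= 0, K >= 0, K <= N, n >= 0, n <= N, r >= 0)
  if (r == 0) return(1)
  if (r > n) {
    warning("r > n: cannot draw ", r, " successes in ", n, " draws; P = 0")
    return(0)
  }
  if (K == 0) return(0)
  stats::phyper(r - 1, K, N - K, n, lower.tail = FALSE)
}

#' Minimum subsample size for a target limit of detection
#'
#' The smallest subsample size n such that a species at frequency `f` in a
#' library of `N` reads yields at least `L` sampled reads with probability
#' at least `P_target`. Found by bisection over n; the hypergeometric upper
#' tail is non-decreasing in n (verified as a tested property), so
#' bisection is exact.
#'
#' @param N Total reads in the full sample.
#' @param f Species frequency in the full sample (0 < f <= 1).
#' @param L Limit of detection: required sampled reads (>= 1).
#' @param P_target Required detection probability (0 < P_target < 1).
#' @param rounding Passed to [detection_probability()] for `K = N*f`.
#' @return The minimal integer subsample size `n*`.
#' @details If fewer than `L` reads of the species exist in the full sample
#'   (`K < L`) no subsample can reach the target and an infeasibility error
#'   is raised.
#' @export
min_subsample_size <- function(N, f, L, P_target,
                               rounding = c("round", "floor")) {
  rounding <- match.arg(rounding)
  stopifnot(f > 0, f <= 1, L >= 1, P_target > 0, P_target < 1)
  K <- if (rounding == "round") round(N * f) else floor(N * f)
  if (K < L)
    stop("infeasible: only K = ", K, " reads of the species exist in the ",
         "full sample, fewer than the limit of detection L = ", L)
  p <- function(n) detection_probability(N, n, L, K = K)
  lo <- L; hi <- N
  if (p(hi) < P_target)  # only possible through floating-point corner cases
    stop("infeasible: even the full sample misses the target probability")
  while (lo < hi) {
    mid <- floor((lo + hi) / 2)
    if (p(mid) >= P_target) hi <- mid else lo <- mid + 1
  }
  lo
}

#' Minimum subsample size across a grid of species frequencies
#'
#' Vectorises [min_subsample_size()] over `f_grid`; the required subsample
#' size is non-increasing in the species frequency. Infeasible grid points
#' (fewer than `L` reads of the species exist) yield `NA`.
#'
#' @param N Total reads in the full sample.
#' @param L Limit of detection (sampled reads).
#' @param P_target Required detection probability.
#' @param f_grid Vector of species frequencies.
#' @param rounding Passed to [min_subsample_size()].
#' @return A data.frame with columns `f` and `n`.
#' @export
detection_curve <- function(N, L, P_target, f_grid,
                            rounding = c("round", "floor")) {
  rounding <- match.arg(rounding)
  n <- vapply(f_grid, function(f) {
    tryCatch(as.numeric(min_subsample_size(N, f, L, P_target, rounding)),
             error = function(e) NA_real_)
  }, numeric(1))
  data.frame(f = f_grid, n = n)
}
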