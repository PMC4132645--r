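#' Fisher's exact p-value for a 2x2 contingency table
#'
#' The per-voxel association test of the mass-univariate engine, for the
#' table `(a, b; c, d)` = (damaged & affected, damaged & unaffected;
#' undamaged & affected, undamaged & unaffected).
#'
#' `mode = "exact"` gives the two-sided hypergeometric p-value under the
#' point-probability convention: with all margins fixed, the sum of the
#' probabilities of every table whose point probability does not exceed that
#' of the observed table (a tiny relative tolerance absorbs floating-point
#' ties). `mode = "asymptotic"` gives the chi-square (1 df, no continuity
#' correction) approximation. Degenerate margins (any margin zero) carry no
#' information and return 1.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param mode `"exact"` or `"asymptotic"`.
#' @return A p-value in `[0, 1]`.
#' @export
#' @examples
#' fisher_exact_p(4, 0, 0, 6)   # 1 / choose(10, 4)
#' fisher_exact_p(1, 1, 1, 1)   # 1: no association
fisher_exact_p <- function(a, b, c, d, mode = c("exact", "asymptotic")) {
  mode <- match.arg(mode)
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  n <- a + b + c + d
  if (n < 1) stop("empty table")
  m1 <- a + b   # damaged
  k1 <- a + c   # affected
  if (m1 == 0 || k1 == 0 || m1 == n || k1 == n) return(1)
  if (mode == "asymptotic") {
    stat <- n * (a * d - b * c)^2 / (m1 * (n - m1) * k1 * (n - k1))
    return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  support <- max(0, k1 + m1 - n):min(k1, m1)
  probs <- stats::dhyper(support, m1, n - m1, k1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

#' Two-sided exact p-value lookup table for fixed margins
#'
#' For a fixed cohort size `n_total` and a fixed number of affected subjects
#' `n_affected`, the per-voxel table is determined by the voxel's hit count
#' `h` and the damaged-and-affected count `a`. This precomputes the exact
#' two-sided p for every `(h, a)`, turning a voxel-wise sweep into a table
#' lookup: `P[h + 1, a + 1]` (NA where `a` is impossible for `h`).
#'
#' @param n_affected Number of affected subjects (column margin).
#' @param n_total Cohort size.
#' @return `(n_total + 1) x (n_total + 1)` numeric matrix.
#' @export
fisher_p_lookup <- function(n_affected, n_total) {
  stopifnot(is_count(n_affected), is_count(n_total), n_affected <= n_total)
  P <- matrix(NA_real_, n_total + 1L, n_total + 1L)
  if (n_affected == 0 || n_affected == n_total) {
    # degenerate label margin: every table is uninformative
    for (h in 0:n_total) P[h + 1L, 1:(h + 1L)] <- 1
    return(P)
  }
  for (h in 0:n_total) {
    if (h == 0 || h == n_total) {
      P[h + 1L, 1:(h + 1L)] <- 1
      next
    }
    support <- max(0, n_affected + h - n_total):min(n_affected, h)
    probs <- stats::dhyper(support, h, n_total - h, n_affected)
    s <- sort(probs)
    cs <- cumsum(s)
    idx <- findInterval(probs * (1 + 1e-9), s)
    P[h + 1L, support + 1L] <- pmin(1, cs[idx])
  }
  P
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha Familywise error rate, in `(0, 1)`.
#' @param n_tests Number of tests (>= 1); in a sweep this is the number of
#'   tested voxels, not the full grid.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, is_count(n_tests), n_tests >= 1)
  alpha / n_tests
}
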