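#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o` and chance agreement `p_e` from the product of
#' the raters' marginal distributions. Returns 1 when the raters agree on
#' every item; errors when `p_e = 1` with imperfect agreement (undefined).
#'
#' @param ratings_a,ratings_b equal-length vectors of categorical ratings.
#' @return kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b) || length(ratings_a) < 2)
    stop("ratings must be two equal-length vectors of length >= 2")
  n <- length(ratings_a)
  p_o <- mean(ratings_a == ratings_b)
  if (p_o == 1) return(1)
  cats <- sort(unique(c(ratings_a, ratings_b)))
  pa <- table(factor(ratings_a, levels = cats)) / n
  pb <- table(factor(ratings_b, levels = cats)) / n
  p_e <- sum(as.numeric(pa) * as.numeric(pb))
  if (p_e >= 1) stop("chance agreement is 1 with imperfect agreement; kappa undefined")
  (p_o - p_e) / (1 - p_e)
}

#' Gwet's chance-corrected agreement coefficient with ordinal weights
#'
#' Weighted generalization of Gwet's AC1: with linear weights
#' `w(i, j) = 1 - |i - j| / (K - 1)` on an ordered K-category scale,
#' near-miss disagreements are partially credited. The chance-agreement
#' term uses Gwet's category propensities `pi_k = (p_k. + p_.k) / 2`:
#' `p_e = T_w / (K (K - 1)) * sum_k pi_k (1 - pi_k)` where `T_w` is the sum
#' of all weights. With identity weights this reduces to unweighted AC1.
#'
#' @param ratings_a,ratings_b equal-length vectors of ordinal ratings.
#' @param categories the full ordered category set (default `0:3`); both
#'   rating vectors must take values in it.
#' @param weights `"linear"` or `"identity"`.
#' @return The agreement coefficient in \[-1, 1\]. Two identical constant
#'   rating vectors return 1 (perfect agreement) with a note.
#' @export
gwet_weighted <- function(ratings_a, ratings_b, categories = 0:3,
                          weights = c("linear", "identity")) {
  weights <- match.arg(weights)
  if (length(ratings_a) != length(ratings_b) || length(ratings_a) < 2)
    stop("ratings must be two equal-length vectors of length >= 2")
  if (!all(c(ratings_a, ratings_b) %in% categories))
    stop("ratings outside the declared category set")
  K <- length(categories)
  if (K < 2) stop("at least two categories must be declared")
  ia <- match(ratings_a, categories)
  ib <- match(ratings_b, categories)
  W <- if (weights == "linear")
    1 - abs(outer(seq_len(K), seq_len(K), "-")) / (K - 1)
  else diag(K)
  n <- length(ia)
  p_a <- sum(W[cbind(ia, ib)]) / n
  pi_k <- (tabulate(ia, K) + tabulate(ib, K)) / (2 * n)
  p_e <- sum(W) / (K * (K - 1)) * sum(pi_k * (1 - pi_k))
  if (p_e >= 1) {
    if (p_a == 1) {
      message("single shared constant rating; returning perfect agreement")
      return(1)
    }
    stop("chance agreement is 1 with imperfect agreement; coefficient undefined")
  }
  if (p_a == 1 && all(ia == ib) && length(unique(ia)) == 1)
    message("single shared constant rating; returning perfect agreement")
  (p_a - p_e) / (1 - p_e)
}

#' Collapse ordinal 0-3 grades to binary presence
#'
#' Grade 0 maps to absent (0); grades 1-3 map to present (1).
#'
#' @param grades vector of grades in 0:3.
#' @return Integer 0/1 vector.
#' @export
binarize_grades <- function(grades) {
  if (!all(grades %in% 0:3)) stop("grades must be in {0, 1, 2, 3}")
  as.integer(grades >= 1)
}

#' Average two readers' ordinal grades
#'
#' Rounded mean of the two readers per item (round-half-up so e.g. grades
#' 1 and 2 average to 2), the collapse used before binary RCM-vs-histology
#' comparison.
#'
#' @param reader_a,reader_b equal-length grade vectors in 0:3.
#' @return Integer vector of averaged grades.
#' @export
average_reader_grades <- function(reader_a, reader_b) {
  if (length(reader_a) != length(reader_b))
    stop("reader vectors must have equal length")
  if (!all(c(reader_a, reader_b) %in% 0:3)) stop("grades must be in {0, 1, 2, 3}")
  as.integer(floor((reader_a + reader_b) / 2 + 0.5))
}

#' Spearman rank correlation with a two-tailed p-value
#'
#' Pearson correlation of average-ranked data (ties averaged) with the
#' usual two-tailed t-approximation for the p-value.
#'
#' @param x,y equal-length numeric vectors of length >= 4.
#' @return List with `rho` and `p_value`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4)
    stop("x and y must have equal length >= 4")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) stop("zero rank variance; correlation undefined")
  rho <- cor(rx, ry)
  n <- length(x)
  if (abs(rho) >= 1) return(list(rho = rho, p_value = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * pt(-abs(tstat), df = n - 2))
}
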