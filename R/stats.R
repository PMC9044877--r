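# Shared statistical primitives.  The signed-rank test is implemented here
# rather than via stats::wilcox.test because the evaluation pipeline needs
# a fixed, documented variant: Pratt treatment of zero differences,
# mid-rank ties, and an exact sign-convolution null for small samples.

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Thin wrapper over `p.adjust(method = "BH")` kept as a named operation;
#' returns an empty vector for empty input.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return numeric vector of FDR values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric())
  stats::p.adjust(p, method = "BH")
}

#' Harmonic-mean p-value
#'
#' `n / sum(1/p)`: the plain (unweighted) harmonic mean of the inputs.
#' Always lies between `min(p)` and `max(p)`.
#'
#' @param p numeric vector of p-values.
#' @return single numeric value.
#' @export
harmonic_mean_p <- function(p) {
  stopifnot(length(p) >= 1L, all(p > 0))
  length(p) / sum(1 / p)
}

#' Rank-based inverse normal transformation
#'
#' `qnorm((rank - offset) / (n + 1 - 2 * offset))` with mid-ranks for ties;
#' the default offset 3/8 is the Blom variant.  An all-identical input maps
#' to all zeros.
#'
#' @param values numeric vector, `n >= 2`.
#' @param offset rank offset (default 3/8).
#' @return numeric vector of approximately standard-normal scores.
#' @export
rank_inverse_normal <- function(values, offset = 3 / 8) {
  n <- length(values)
  stopifnot(n >= 2L)
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - offset) / (n + 1 - 2 * offset))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of paired differences `x - y` (or of a single difference
#' vector when `y` is `NULL`).  Zero differences are handled by the Pratt
#' method: they participate in the ranking of absolute differences and are
#' then discarded.  Tied absolute differences receive mid-ranks.  For up to
#' `exact_max` non-zero differences the null distribution of the positive
#' rank sum is computed exactly by sign convolution (valid under ties and
#' Pratt zeros, since ranks are fixed); larger samples use the normal
#' approximation with the tie-robust variance `sum(r^2) / 4`.
#'
#' @param x,y paired numeric vectors (`y = NULL` treats `x` as differences).
#' @param exact_max largest number of non-zero differences for which the
#'   exact null is enumerated (default 25).
#' @return list with `statistic` (positive rank sum `V`), `p_value`,
#'   `n_nonzero`, and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  r_all <- rank(abs(d), ties.method = "average")
  nz <- d != 0
  r <- r_all[nz]
  s <- sign(d[nz])
  n <- length(r)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L,
                method = "degenerate"))
  }
  v <- sum(r[s > 0])
  if (n <= exact_max) {
    # exact null: each sign independently +/- with prob 1/2; work on 2*rank
    # so mid-ranks become integers
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L)  # counts[w+1] = #sign vectors with sum w
    counts[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(total + 1L - ri)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    w2 <- as.integer(round(2 * v))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[seq.int(w2 + 1L, total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (v - mu) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(statistic = v, p_value = p, n_nonzero = n, method = method)
}
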