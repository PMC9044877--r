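# Independent brute-force oracles.  These deliberately avoid the package's
# own interval/statistics code paths: coverage is a per-base boolean array,
# the signed-rank null is a full sign enumeration, Fisher is a
# hypergeometric tail sum, BH is the textbook step-up formula.

coverage_bits <- function(iv, L, chrom = "chr1") {
  bits <- logical(L)
  iv <- iv[iv$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(iv))) {
    if (iv$end[i] > iv$start[i]) {
      bits[(iv$start[i] + 1L):iv$end[i]] <- TRUE
    }
  }
  bits
}

bits_to_intervals <- function(bits, chrom = "chr1") {
  if (!any(bits)) return(genomic_intervals())
  r <- rle(bits)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  genomic_intervals(chrom, starts[r$values], ends[r$values])
}

random_intervals <- function(n, L, max_len = 200L, chrom = "chr1") {
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(L - l, 1L) - 1L, 0L)
  genomic_intervals(chrom, start, start + len)
}

# per-base nearest-TSS assignment; equidistant bases go downstream
oracle_nearest_gene <- function(tss, gene_ids, L) {
  out <- character(L)
  for (b in 0:(L - 1L)) {
    d <- abs(b - tss)
    cand <- which(d == min(d))
    out[b + 1L] <- gene_ids[cand[length(cand)]]  # tss sorted: downstream
  }
  out
}

# full 2^n sign enumeration of the Pratt signed-rank null
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  r_all <- rank(abs(d), ties.method = "average")
  r <- r_all[d != 0]
  s <- sign(d[d != 0])
  n <- length(r)
  if (n == 0L) return(1)
  v_obs <- sum(r[s > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# two-sided Fisher p by enumerating all tables with fixed margins
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0L, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}
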