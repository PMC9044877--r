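# Benchmarking a definition against labeled enhancer-gene pairs and
# comparing pair datasets by overlap coefficient.  A benchmark pair is
# "predicted positive" when some definition locus overlaps its enhancer by
# >= 1 bp and is linked to the same gene.

#' Construct a benchmark pair set
#'
#' @param pairs data frame `chrom,start,end,gene_id,label` with labels
#'   `positive`/`negative`.
#' @param name label of the dataset.
#' @param ratio_mode `natural` or `fixed_1_to_4` (bookkeeping only; use
#'   [fix_negative_ratio()] to subsample).
#' @return object of class `BenchmarkPairSet`.
#' @export
benchmark_pair_set <- function(pairs, name = "benchmark",
                               ratio_mode = c("natural", "fixed_1_to_4")) {
  stopifnot(all(pairs$label %in% c("positive", "negative")))
  structure(list(pairs = pairs, name = name,
                 ratio_mode = match.arg(ratio_mode)),
            class = "BenchmarkPairSet")
}

#' @export
print.BenchmarkPairSet <- function(x, ...) {
  cat(sprintf("BenchmarkPairSet '%s' (%s): %d positive, %d negative\n",
              x$name, x$ratio_mode, sum(x$pairs$label == "positive"),
              sum(x$pairs$label == "negative")))
  invisible(x)
}

#' Preprocess enhancer-gene pairs for comparison
#'
#' Trims promoter windows out of the pair enhancers (pairs whose enhancer
#' vanishes are dropped), merges overlapping enhancer intervals within the
#' dataset, and re-attaches each original gene link to every merged
#' enhancer its trimmed enhancer contributed to.  Optionally drops
#' ambiguous pairs whose original enhancer ends lie within `drop_ambiguous`
#' bp of the TSSs of two or more genes.
#'
#' @param pairs data frame `chrom,start,end,gene_id` (+ optional columns,
#'   carried per pair).
#' @param registry `GeneRegistry`.
#' @param window promoter half-width in bp.
#' @param drop_ambiguous `NULL`, or a distance in bp for the ambiguity
#'   filter.
#' @return preprocessed pair data frame (merged enhancer coordinates).
#' @export
preprocess_pairs <- function(pairs, registry, window = 5000L,
                             drop_ambiguous = NULL) {
  if (!is.null(drop_ambiguous)) {
    d <- as.integer(drop_ambiguous)
    g <- registry$genes
    near <- function(pos, chrom) {
      ends <- genomic_intervals(chrom, pmax(0L, pos - d),
                                pmin(as.integer(registry$sizes[chrom]),
                                     pos + d))
      tss_hits <- .point_in_pairs(g$chrom, g$tss, ends)
      counts <- integer(nrow(pairs))
      tb <- table(tss_hits$subject)
      counts[as.integer(names(tb))] <- as.integer(tb)
      counts
    }
    n_genes_near <- pmax(near(pairs$start, pairs$chrom),
                         near(pairs$end, pairs$chrom))
    pairs <- pairs[n_genes_near < 2L, , drop = FALSE]
  }
  trimmed <- trim_promoter_windows(pairs, registry, window)
  if (nrow(trimmed) == 0L) return(trimmed)
  merged <- merge_intervals(trimmed)
  ov <- .overlap_pairs(trimmed, merged)
  out <- trimmed[ov$query, , drop = FALSE]
  out$start <- merged$start[ov$subject]
  out$end <- merged$end[ov$subject]
  out <- out[!duplicated(out[, c("chrom", "start", "end", "gene_id")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  sort_intervals(out)
}

#' Score a definition against a labeled benchmark
#'
#' Each benchmark pair is predicted positive iff some non-fallback-or-
#' fallback definition record overlaps the pair's enhancer by >= 1 bp and
#' carries the pair's gene.  TP/FP/TN/FN over pair labels, with
#' sensitivity, specificity, precision, and F1 `2TP/(2TP+FP+FN)`.
#'
#' @param entdef `EnTDef` (or any object with interval `records` carrying
#'   `gene_id`).
#' @param bench `BenchmarkPairSet`.
#' @param drop_missing_genes drop benchmark pairs whose gene has no record
#'   anywhere in the definition universe (reported in the result).
#' @return list of class `BenchmarkScore`.
#' @export
call_pairs <- function(entdef, bench, drop_missing_genes = FALSE) {
  pairs <- bench$pairs
  if (nrow(pairs) == 0L) stop("empty benchmark")
  rec <- entdef$records
  n_dropped <- 0L
  if (drop_missing_genes) {
    keep <- pairs$gene_id %in% rec$gene_id
    n_dropped <- sum(!keep)
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) == 0L) stop("no benchmark pairs left after gene filter")
  }
  ov <- .overlap_pairs(pairs, rec)
  match_gene <- pairs$gene_id[ov$query] == rec$gene_id[ov$subject]
  predicted <- logical(nrow(pairs))
  predicted[unique(ov$query[match_gene])] <- TRUE
  is_pos <- pairs$label == "positive"
  TP <- sum(is_pos & predicted)
  FP <- sum(!is_pos & predicted)
  TN <- sum(!is_pos & !predicted)
  FN <- sum(is_pos & !predicted)
  structure(list(
    TP = TP, FP = FP, TN = TN, FN = FN,
    sensitivity = if (TP + FN > 0L) TP / (TP + FN) else NA_real_,
    specificity = if (TN + FP > 0L) TN / (TN + FP) else NA_real_,
    precision = if (TP + FP > 0L) TP / (TP + FP) else NA_real_,
    f1 = if (2 * TP + FP + FN > 0L) 2 * TP / (2 * TP + FP + FN) else 0,
    n_pairs = nrow(pairs), n_dropped_missing_gene = n_dropped
  ), class = "BenchmarkScore")
}

#' @export
print.BenchmarkScore <- function(x, ...) {
  cat(sprintf(
    "BenchmarkScore: TP %d FP %d TN %d FN %d | sens %.3f spec %.3f F1 %.3f\n",
    x$TP, x$FP, x$TN, x$FN, x$sensitivity, x$specificity, x$f1))
  invisible(x)
}

#' Fix the positive:negative ratio of a benchmark
#'
#' Uniformly subsamples the negatives to `ratio` times the number of
#' positives (seeded).  When there are not enough negatives all are kept
#' with a warning.  Positives are never touched.
#'
#' @param bench `BenchmarkPairSet`.
#' @param ratio negatives per positive (default 4).
#' @param seed RNG seed.
#' @return `BenchmarkPairSet` with `ratio_mode = "fixed_1_to_4"`.
#' @export
fix_negative_ratio <- function(bench, ratio = 4L, seed = 1L) {
  pairs <- bench$pairs
  pos <- which(pairs$label == "positive")
  neg <- which(pairs$label == "negative")
  want <- ratio * length(pos)
  if (length(neg) < want) {
    warning("fewer negatives (", length(neg), ") than ", want,
            "; keeping all")
    keep_neg <- neg
  } else {
    keep_neg <- .with_seed(seed, sort(sample(neg, want)))
  }
  benchmark_pair_set(pairs[sort(c(pos, keep_neg)), , drop = FALSE],
                     name = bench$name, ratio_mode = "fixed_1_to_4")
}

#' Overlap coefficient between two pair datasets
#'
#' Shared pairs divided by the size of the smaller dataset.  A pair of the
#' smaller set counts as shared when the larger set contains a pair with
#' the same gene whose enhancer overlaps by >= 1 bp.  Both inputs should
#' be preprocessed ([preprocess_pairs()]).
#'
#' @param a,b pair data frames `chrom,start,end,gene_id`.
#' @return fraction in `[0, 1]`.
#' @export
overlap_coefficient <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty pair set")
  if (nrow(a) <= nrow(b)) { small <- a; large <- b } else {
    small <- b; large <- a
  }
  ov <- .overlap_pairs(small, large)
  match_gene <- small$gene_id[ov$query] == large$gene_id[ov$subject]
  shared <- length(unique(ov$query[match_gene]))
  shared / nrow(small)
}
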