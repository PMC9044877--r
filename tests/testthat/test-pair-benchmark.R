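test_that("pair preprocessing trims promoters and merges enhancers", {
  reg <- mk_registry(c(100000L, 300000L), L = 400000L)
  pairs <- data.frame(
    chrom = "chr1",
    start = c(98000L, 150000L, 150400L, 200000L),
    end = c(102000L, 150500L, 150900L, 200300L),
    gene_id = c("g01", "g01", "g02", "g02"))
  out <- preprocess_pairs(pairs, reg)
  # pair 1 lies wholly inside g01's promoter window: dropped
  expect_false(any(out$start < 105000L))
  # pairs 2 and 3 overlap: one merged enhancer, two gene links
  merged <- out[out$start == 150000L, ]
  expect_equal(nrow(merged), 2L)
  expect_equal(unique(merged$end), 150900L)
  expect_setequal(merged$gene_id, c("g01", "g02"))
  # random sets match compose(trim, merge) at the coverage level
  set.seed(71)
  rnd <- random_intervals(40L, 400000L, max_len = 3000L)
  rnd$gene_id <- sample(reg$genes$gene_id, 40L, replace = TRUE)
  got <- preprocess_pairs(rnd, reg)
  want <- merge_intervals(trim_promoter_windows(rnd, reg))
  expect_identical(merge_intervals(got), want)
})

test_that("pair calling matches a hand-built 8-pair confusion table", {
  reg <- mk_registry(c(100000L, 300000L), L = 400000L)
  rec <- genomic_intervals(
    "chr1", c(50000L, 50000L, 150000L), c(51000L, 51000L, 151000L),
    gene_id = c("g01", "g02", "g01"),
    sources = "s", link_methods = "m", fallback = FALSE)
  def <- entforge:::new_entdef(rec, NULL, reg)
  bench <- benchmark_pair_set(data.frame(
    chrom = "chr1",
    start = c(50200L, 50200L, 150200L, 150200L, 250000L, 250000L,
              50200L, 150900L),
    end = c(50400L, 50400L, 150400L, 150400L, 250200L, 250200L,
            50400L, 151200L),
    gene_id = c("g01", "g02", "g01", "g02", "g01", "g02", "g02", "g01"),
    label = c("positive", "positive", "positive", "negative", "positive",
              "negative", "negative", "positive")))
  sc <- call_pairs(def, bench)
  # manual table: overlap+gene -> predicted: pairs 1,2,3,7,8 predicted
  # labels: pos,pos,pos,neg,pos,neg,neg,pos
  expect_equal(sc$TP, 4L)  # pairs 1,2,3,8
  expect_equal(sc$FP, 1L)  # pair 7
  expect_equal(sc$TN, 2L)  # pairs 4? no: pair 4 neg, overlap but gene g02
  expect_equal(sc$FN, 1L)  # pair 5 (no overlapping locus)
  expect_equal(sc$TP + sc$FP + sc$TN + sc$FN, 8L)
  expect_equal(sc$sensitivity, 4 / 5)
  expect_equal(sc$specificity, 2 / 3)
  expect_equal(sc$f1, 2 * 4 / (2 * 4 + 1 + 1))
  expect_error(call_pairs(def, benchmark_pair_set(bench$pairs[0, ])),
               "empty")
})

test_that("fixed-ratio subsampling only touches negatives", {
  pairs <- data.frame(chrom = "chr1",
                      start = seq(1000L, 110000L, by = 1000L),
                      end = seq(1200L, 110200L, by = 1000L),
                      gene_id = "g01",
                      label = c(rep("positive", 10L),
                                rep("negative", 100L)))
  bench <- benchmark_pair_set(pairs)
  fixed <- fix_negative_ratio(bench, ratio = 4L, seed = 3L)
  expect_equal(sum(fixed$pairs$label == "positive"), 10L)
  expect_equal(sum(fixed$pairs$label == "negative"), 40L)
  expect_identical(fix_negative_ratio(bench, 4L, seed = 3L)$pairs,
                   fixed$pairs)
  few <- benchmark_pair_set(pairs[1:30, ])  # only 20 negatives
  expect_warning(out <- fix_negative_ratio(few, 4L, seed = 3L),
                 "keeping all")
  expect_equal(nrow(out$pairs), 30L)
  # sensitivity is invariant to negative subsampling, precision is not
  reg <- mk_registry(100000L, L = 1000000L)
  rec <- genomic_intervals("chr1", seq(1000L, 59000L, 2000L),
                           seq(1400L, 59400L, 2000L), gene_id = "g01",
                           sources = "s", link_methods = "m",
                           fallback = FALSE)
  def <- entforge:::new_entdef(rec, NULL, reg)
  full <- call_pairs(def, bench)
  sub <- call_pairs(def, fixed)
  expect_equal(sub$sensitivity, full$sensitivity)
  expect_equal(sub$TP, full$TP)
  expect_equal(sub$FN, full$FN)
})

test_that("overlap coefficient uses the smaller set as denominator", {
  a <- data.frame(chrom = "chr1",
                  start = c(1000L, 5000L, 9000L, 13000L),
                  end = c(1500L, 5500L, 9500L, 13500L),
                  gene_id = c("g01", "g01", "g02", "g02"))
  expect_equal(overlap_coefficient(a, a), 1)
  b <- rbind(a[1:2, ], within(a, start <- start + 100000L))
  b$end[3:6] <- b$start[3:6] + 500L
  # only a's first two pairs are matched in b: 2 / min(4, 6)
  expect_equal(overlap_coefficient(a, b), 0.5)
  expect_equal(overlap_coefficient(b, a), 0.5)  # symmetric
  expect_error(overlap_coefficient(a[0, ], b), "empty")
  # exhaustive scan oracle on random sets
  set.seed(72)
  for (i in 1:20) {
    x <- random_intervals(8L, 50000L, max_len = 900L)
    x$gene_id <- sample(c("g01", "g02"), 8L, replace = TRUE)
    y <- random_intervals(12L, 50000L, max_len = 900L)
    y$gene_id <- sample(c("g01", "g02"), 12L, replace = TRUE)
    shared <- 0L
    for (r in seq_len(nrow(x))) {
      hit <- any(y$gene_id == x$gene_id[r] & y$start < x$end[r] &
                   y$end > x$start[r])
      shared <- shared + hit
    }
    expect_equal(overlap_coefficient(x, y), shared / 8L)
  }
})
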