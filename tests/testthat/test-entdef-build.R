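test_that("promoter trimming removes 5-kb TSS windows", {
  reg <- mk_registry(100000L)
  out <- trim_promoter_windows(
    genomic_intervals("chr1", 97000L, 107000L), reg, 5000L)
  expect_equal(out$start, 105000L)
  expect_equal(out$end, 107000L)
  # region wholly inside a window vanishes
  expect_equal(nrow(trim_promoter_windows(
    genomic_intervals("chr1", 96000L, 104000L), reg, 5000L)), 0L)
  # overlapping windows of nearby TSSs subtract as one union
  reg2 <- mk_registry(c(100000L, 107000L))
  out2 <- trim_promoter_windows(
    genomic_intervals("chr1", 90000L, 120000L), reg2, 5000L)
  bits <- coverage_bits(genomic_intervals("chr1", 90000L, 120000L), 130000L)
  bits[(100000L - 5000L + 1L):(100000L + 5000L)] <- FALSE
  bits[(107000L - 5000L + 1L):(107000L + 5000L)] <- FALSE
  expect_identical(merge_intervals(out2), bits_to_intervals(bits))
})

test_that("short enhancers are extended about their midpoint and re-trimmed", {
  reg <- mk_registry(500000L)
  out <- extend_enhancers(genomic_intervals("chr1", 1000L, 1400L), 1000L,
                          reg, 5000L)
  expect_equal(out$start, 700L)
  expect_equal(out$end, 1700L)
  long <- genomic_intervals("chr1", 10000L, 12000L)
  expect_equal(extend_enhancers(long, 1000L, reg)[, 1:3], long)
  expect_error(extend_enhancers(long, 999L, reg), "even")
  # extension invading a promoter window is re-trimmed
  inv <- extend_enhancers(genomic_intervals("chr1", 494600L, 494900L),
                          1000L, reg, 5000L)
  expect_equal(inv$start, 494250L)     # midpoint 494750 minus 500
  expect_equal(inv$end, 495000L)       # window of TSS 500000 starts there
})

test_that("pair-table links require >= 1 bp overlap and dedupe", {
  reg <- mk_registry(c(100000L, 200000L, 300000L))
  enh <- genomic_intervals("chr1", c(150L, 400L, 50000L),
                           c(400L, 600L, 50100L))
  pairs <- data.frame(chrom = "chr1", start = c(100L, 100L, 700L),
                      end = c(200L, 200L, 800L),
                      gene_id = c("g01", "g01", "g02"))
  lk <- import_pair_links(pairs, enh, reg)
  expect_equal(lk$enh, 1L)       # only enhancer 1 overlaps; dedup applied
  expect_equal(lk$gene_id, "g01")
  expect_warning(import_pair_links(
    data.frame(chrom = "chr1", start = 150L, end = 250L, gene_id = "nope"),
    enh, reg), "unknown gene")
  # a pair spanning two trimmed fragments creates two links
  frag <- genomic_intervals("chr1", c(100L, 300L), c(200L, 420L))
  lk2 <- import_pair_links(data.frame(chrom = "chr1", start = 150L,
                                      end = 350L, gene_id = "g02"),
                           frag, reg)
  expect_equal(sort(lk2$enh), c(1L, 2L))
})

test_that("anchor pairs link enhancers to promoter-window genes", {
  reg <- mk_registry(c(100000L, 104000L, 300000L))
  enh <- genomic_intervals("chr1", 50000L, 50500L)
  anchors <- data.frame(chrom1 = "chr1", start1 = 50100L, end1 = 50200L,
                        chrom2 = "chr1", start2 = 99000L, end2 = 99500L)
  lk <- map_anchor_pairs_to_links(anchors, enh, reg, 5000L)
  # anchor2 covers windows of both g01 (95000-105000) and g02 (99000-109000)
  expect_setequal(lk$gene_id, c("g01", "g02"))
  # orientation swap gives the same links
  swapped <- anchors[, c(4:6, 1:3)]
  names(swapped) <- names(anchors)
  expect_setequal(map_anchor_pairs_to_links(swapped, enh, reg)$gene_id,
                  c("g01", "g02"))
  # neither anchor near a TSS: nothing
  far <- data.frame(chrom1 = "chr1", start1 = 50100L, end1 = 50200L,
                    chrom2 = "chr1", start2 = 200000L, end2 = 200100L)
  expect_equal(nrow(map_anchor_pairs_to_links(far, enh, reg)), 0L)
})

test_that("loop linking respects the max-genes variant", {
  reg <- mk_registry(c(100000L, 120000L, 500000L))
  enh <- genomic_intervals("chr1", 108000L, 109000L)
  loop <- genomic_intervals("chr1", 95000L, 125000L)  # spans g01 and g02
  expect_equal(nrow(links_from_loops(loop, enh, reg, max_genes = 1L)), 0L)
  lk2 <- links_from_loops(loop, enh, reg, max_genes = 2L)
  expect_setequal(lk2$gene_id, c("g01", "g02"))
  # exhaustive loop x gene x enhancer oracle on random loops
  set.seed(21)
  reg2 <- mk_registry(seq(50000L, 950000L, by = 100000L))
  enh2 <- random_intervals(30L, 1000000L, max_len = 5000L)
  loops <- random_intervals(10L, 1000000L, max_len = 300000L)
  for (mg in 1:3) {
    got <- links_from_loops(loops, enh2, reg2, max_genes = mg)
    want <- list()
    for (li in seq_len(nrow(loops))) {
      gin <- which(reg2$genes$tss >= loops$start[li] &
                     reg2$genes$tss < loops$end[li])
      if (length(gin) < 1L || length(gin) > mg) next
      ein <- which(enh2$start < loops$end[li] & enh2$end > loops$start[li])
      for (e in ein) for (g in gin) {
        want[[length(want) + 1L]] <- paste(e, reg2$genes$gene_id[g])
      }
    }
    expect_setequal(paste(got$enh, got$gene_id), unique(unlist(want)))
  }
})

test_that("nearest-TSS partition splits at midpoints and tiles the genome", {
  reg <- mk_registry(c(10000L, 30000L), L = 50000L)
  part <- nearest_tss_partition(reg)
  expect_equal(part$start, c(0L, 20000L))
  expect_equal(part$end, c(20000L, 50000L))
  expect_equal(part$gene_id, c("g01", "g02"))
  # per-base argmin oracle on a small genome with 5 genes
  tss <- c(500L, 1700L, 1711L, 4000L, 9000L)
  rego <- mk_registry(tss, L = 10000L, body_len = 100L)
  parto <- nearest_tss_partition(rego)
  want <- oracle_nearest_gene(tss, rego$genes$gene_id, 10000L)
  got <- character(10000L)
  for (i in seq_len(nrow(parto))) {
    got[(parto$start[i] + 1L):parto$end[i]] <- parto$gene_id[i]
  }
  expect_identical(got, want)
})

test_that("nearest_all fallback covers exactly the unclaimed distal bases", {
  reg <- mk_registry(c(10000L, 30000L), L = 50000L)
  rec <- genomic_intervals("chr1", 12000L, 13000L, gene_id = "g02",
                           sources = "s", link_methods = "m",
                           fallback = FALSE)
  def <- entforge:::new_entdef(rec, NULL, reg)
  out <- add_nearest_all(def, reg, 5000L)
  fb <- out$records[out$records$fallback, ]
  # the enhancer locus is excised from the fallback territory
  expect_false(any(fb$start < 13000L & fb$end > 12000L))
  # distal coverage is complete: promoters + loci + fallback tile chr1
  all_iv <- rbind(out$records[, 1:3], promoter_windows(reg, 5000L)[, 1:3])
  expect_equal(total_coverage(all_iv), 50000L)
})

test_that("assembly composes the pipeline deterministically", {
  toy <- default_toy()
  reg <- toy$registry
  rgl <- toy$regulome
  cfg <- entdef_config("src1", links = "pairsA")
  def1 <- assemble_entdef(cfg, rgl$sources, rgl$evidence, reg)
  def2 <- assemble_entdef(cfg, rgl$sources, rgl$evidence, reg)
  expect_identical(def1, def2)  # pure function of inputs
  # single source + single pair table equals import_pair_links output
  enh <- trim_promoter_windows(merge_intervals(rgl$sources$src1), reg)
  lk <- import_pair_links(rgl$evidence$pairsA$payload, enh, reg)
  expect_equal(nrow(def1$records),
               nrow(unique(cbind(lk$enh, lk$gene_id))))
  expect_error(assemble_entdef(entdef_config("nope", links = "pairsA"),
                               rgl$sources, rgl$evidence, reg), "unknown")
})

test_that("no assembled locus overlaps a promoter window", {
  toy <- default_toy()
  cfg <- entdef_config(c("src1", "src2"), links = c("pairsA", "chia"),
                       loop_variant = 2L, extend = TRUE)
  def <- assemble_entdef(cfg, toy$regulome$sources, toy$regulome$evidence,
                         toy$registry)
  prom <- promoter_windows(toy$registry, 5000L)
  expect_equal(nrow(intersect_intervals(def$records, prom)), 0L)
})

test_that("adding link evidence never removes links", {
  toy <- default_toy()
  small <- assemble_entdef(entdef_config("src1", links = "pairsA"),
                           toy$regulome$sources, toy$regulome$evidence,
                           toy$registry)
  big <- assemble_entdef(entdef_config("src1",
                                       links = c("pairsA", "pairsB", "chia")),
                         toy$regulome$sources, toy$regulome$evidence,
                         toy$registry)
  key <- function(d) paste(d$records$chrom, d$records$start, d$records$end,
                           d$records$gene_id)
  expect_true(all(key(small) %in% key(big)))
})

test_that("nearest_all definitions cover all distal space", {
  toy <- default_toy()
  cfg <- entdef_config("src1", links = "pairsA", nearest_all = TRUE)
  def <- assemble_entdef(cfg, toy$regulome$sources, toy$regulome$evidence,
                         toy$registry)
  covered <- rbind(def$records[, 1:3],
                   promoter_windows(toy$registry, 5000L)[, 1:3])
  expect_equal(total_coverage(covered),
               unname(toy$registry$sizes["chr1"]))
  # loci cover everything except the promoter windows
  st <- entdef_stats(def, toy$registry)
  prom_bp <- total_coverage(promoter_windows(toy$registry, 5000L))
  expect_equal(st$genome_coverage_fraction,
               1 - prom_bp / sum(as.numeric(toy$registry$sizes)))
})

test_that("enumeration matches the closed-form counts", {
  count <- function(s, k, v, tog = c(FALSE, TRUE), ct = FALSE) {
    length(enumerate_definitions(s, k, loop_variants = v, extend = tog,
                                 nearest_all = tog, ct_mode = ct))
  }
  for (s in 1:4) for (k in 1:3) for (v in 0:3) {
    expected <- (2^s - 1) * ((2^k - 1) * (1 + v) + v) * 4
    expect_equal(count(s, k, v), expected)
  }
  # CT mode: interaction and/or one loop variant
  expect_equal(count(4, 1, 3, ct = TRUE), 15 * 7 * 4)
  # configurations are distinct
  ids <- vapply(enumerate_definitions(3, 2, 2), config_id, "")
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("entdef_stats reports coverage and distal peak catch", {
  reg <- mk_registry(c(100000L, 300000L), L = 1000000L)
  rec <- genomic_intervals("chr1", c(150000L, 200000L),
                           c(160000L, 210000L),
                           gene_id = c("g01", "g02"), sources = "s",
                           link_methods = "m", fallback = FALSE)
  def <- entforge:::new_entdef(rec, NULL, reg)
  pk <- peak_set(genomic_intervals(
    "chr1", c(155000L, 205000L, 500000L, 600000L),
    c(155100L, 205100L, 500100L, 600100L)), "toy")
  st <- entdef_stats(def, reg, pk)
  expect_equal(st$genome_coverage_fraction, 20000 / 1000000)
  expect_equal(st$distal_peak_catch_fraction, 0.5)
  expect_equal(st$n_enhancers, 2L)
  expect_null(entdef_stats(def, reg)$distal_peak_catch_fraction)
})
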