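test_that("positive-term construction follows the DAG scheme", {
  sets <- mk_chain_sets()
  # chain A <- B <- C <- D with D assigned
  ann <- build_positive_terms("tf", "D", sets, "standard", min_size = 10L)
  expect_setequal(ann$positive_terms, c("D", "C", "B", "A"))
  # conservative: leaf, parent, grandparent only (A excluded)
  cons <- build_positive_terms("tf", "D", sets, "conservative_no_iea",
                               min_size = 10L)
  expect_setequal(cons$positive_terms, c("D", "C", "B"))
  # IEA-only assignments are removed before anything else
  expect_error(build_positive_terms("tf", "D", sets, "conservative_no_iea",
                                    iea_only = "D", min_size = 10L),
               "no positive terms")
  # assigned non-leaves collapse onto the leaf's ancestry
  ann2 <- build_positive_terms("tf", c("B", "D"), sets, "standard",
                               min_size = 10L)
  expect_setequal(ann2$positive_terms, c("D", "C", "B", "A"))
  # size filter removes small terms
  tiny <- gene_set_collection(list(A = sprintf("g%02d", 1:30),
                                   B = sprintf("g%02d", 1:5)),
                              list(B = "A"))
  ann3 <- build_positive_terms("tf", "B", tiny, "standard", min_size = 15L)
  expect_setequal(ann3$positive_terms, "A")
})

test_that("negative sampling is size-matched, exclusion-aware, reproducible", {
  set.seed(61)
  n_terms <- 60L
  sizes <- c(18L, 95L, rep(c(15L, 35L, 55L, 85L, 95L, 110L), 10L)[1:58])
  terms <- lapply(sizes, function(s) sprintf("g%04d", sample(5000L, s)))
  names(terms) <- sprintf("T%02d", seq_len(n_terms))
  dag <- list(T03 = "T01", T04 = "T01", T05 = "T03")
  sets <- gene_set_collection(terms, dag)
  ann <- tf_annotation("tf1", c("T01", "T02"))
  plan <- negative_sampling_plan(bin_size = 20L, rng_seed = 9L)
  neg <- sample_negative_terms(ann, sets, plan, repetition = 1L,
                               min_size = 15L, max_size = 2000L)
  expect_length(neg, 2L)
  # same bins as the positives: [0,20) and [80,100)
  negsz <- lengths(sets$terms[neg])
  expect_equal(sort(unname(negsz) %/% 20L), sort(c(18L, 95L) %/% 20L))
  # excluded: positives, their offspring (T03,T04,T05) and siblings
  expect_false(any(neg %in% c("T01", "T02", "T03", "T04", "T05")))
  expect_identical(neg, sample_negative_terms(ann, sets, plan, 1L,
                                              15L, 2000L))
  expect_false(identical(neg, sample_negative_terms(ann, sets, plan, 2L,
                                                    15L, 2000L)))
  # empty target bin falls back to the nearest non-empty bin
  sparse <- gene_set_collection(list(P = sprintf("g%04d", 1:95),
                                     N1 = sprintf("g%04d", 1:22),
                                     N2 = sprintf("g%04d", 1:130)))
  annp <- tf_annotation("tf2", "P")
  negp <- sample_negative_terms(annp, sparse, plan, 1L, 15L, 2000L)
  expect_equal(negp, "N2")  # bin 6 nearer to bin 4 than bin 1
})

test_that("confusion counts and F1 follow the four-way definitions", {
  gse <- data.frame(
    term_id = c("P1", "P2", "P3", "N1", "N2"),
    n_set_genes = 20L,
    statistic = c(3, 2.5, -2, 3, 0),
    direction = c("enriched", "enriched", "depleted", "enriched",
                  "enriched"),
    p_value = c(0.001, 0.002, 0.001, 0.003, 0.8),
    fdr = c(0.01, 0.01, 0.01, 0.02, 0.9))
  ann <- tf_annotation("tf", c("P1", "P2", "P3"))
  row <- confusion_and_f1(gse, ann, c("N1", "N2"))
  # P3 is significant but depleted: counted FN
  expect_equal(row$TP, 2L)
  expect_equal(row$FN, 1L)
  expect_equal(row$FP, 1L)
  expect_equal(row$TN, 1L)
  expect_equal(row$TP + row$FN, 3L)
  expect_equal(row$TN + row$FP, 2L)
  # direct formula check
  expect_equal(row$precision, 2 / 3)
  expect_equal(row$recall, 2 / 3)
  expect_equal(row$f1, 2 / 3)
  # perfect case
  perfect <- confusion_and_f1(gse[1:2, ], tf_annotation("tf", c("P1", "P2")),
                              "N2")
  expect_equal(perfect$f1, 1)
  # nothing called: F1 defined as 0
  none <- confusion_and_f1(gse[5, ], ann, "N2")
  expect_equal(none$f1, 0)
})

test_that("worked confusion example reproduces its closed-form F1", {
  # TP=30 FP=10 FN=20 TN=40 -> precision .75, recall .6, F1 = 2/3
  p <- 30 / 40; r <- 30 / 50
  expect_equal(2 * p * r / (p + r), 2 / 3)
})

test_that("top-set selection walks ranks with the paired signed-rank test", {
  mk_results <- function(m) {
    per_tf <- expand.grid(definition = rownames(m), tf = colnames(m),
                          stringsAsFactors = FALSE)
    per_tf$f1 <- m[cbind(per_tf$definition, per_tf$tf)]
    ranking <- data.frame(definition = rownames(m),
                          mean_f1 = rowMeans(m))
    ranking <- ranking[order(-ranking$mean_f1, ranking$definition), ]
    ranking$rank <- seq_len(nrow(ranking))
    structure(list(rows = NULL, per_tf = per_tf, ranking = ranking),
              class = "EvaluationResult")
  }
  tfs <- sprintf("tf%02d", 1:12)
  base <- matrix(0.6, 3, 12, dimnames = list(c("d1", "d2", "d3"), tfs))
  # identical F1s: zero differences give p = 1, no cutoff
  out <- select_top_set(mk_results(base))
  expect_true(is.na(out$cutoff_rank))
  expect_setequal(out$top_set, c("d1", "d2", "d3"))
  # rank 3 uniformly 0.2 lower: cutoff at 3, top set = ranks 1-2
  worse <- base
  worse["d3", ] <- 0.4
  out2 <- select_top_set(mk_results(worse))
  expect_equal(out2$cutoff_rank, 3L)
  expect_setequal(out2$top_set, c("d1", "d2"))
  expect_equal(out2$p_values[3], 2 / 2^12)  # exact enumeration minimum
})

test_that("baseline comparison uses paired tests with BH control", {
  tfs <- sprintf("tf%02d", 1:12)
  m <- rbind(base = rep(0.5, 12), same = rep(0.5, 12),
             up = rep(0.6, 12))
  colnames(m) <- tfs
  per_tf <- expand.grid(definition = rownames(m), tf = tfs,
                        stringsAsFactors = FALSE)
  per_tf$f1 <- m[cbind(per_tf$definition, per_tf$tf)]
  ranking <- data.frame(definition = rownames(m), mean_f1 = rowMeans(m))
  ranking <- ranking[order(-ranking$mean_f1, ranking$definition), ]
  ranking$rank <- seq_len(nrow(ranking))
  results <- structure(list(rows = NULL, per_tf = per_tf,
                            ranking = ranking),
                       class = "EvaluationResult")
  cmp <- compare_to_baseline(results, "base")
  expect_equal(cmp$p[cmp$definition == "same"], 1)
  expect_false(cmp$better[cmp$definition == "same"])
  expect_true(cmp$better[cmp$definition == "up"])
  expect_equal(cmp$p[cmp$definition == "up"], 2 / 2^12)
  expect_true(all(cmp$fdr >= cmp$p))
  expect_error(compare_to_baseline(results, "nope"), "not evaluated")
})

test_that("method contribution pairs configurations by one feature", {
  tfs <- sprintf("tf%02d", 1:8)
  cfg <- list(
    a_plain = entdef_config("s1", links = "l1"),
    a_ext = entdef_config("s1", links = "l1", extend = TRUE),
    b_plain = entdef_config(c("s1", "s2"), links = "l1"),
    b_ext = entdef_config(c("s1", "s2"), links = "l1", extend = TRUE))
  m <- rbind(a_plain = rep(0.4, 8), a_ext = rep(0.55, 8),
             b_plain = rep(0.5, 8), b_ext = rep(0.45, 8))
  colnames(m) <- tfs
  per_tf <- expand.grid(definition = rownames(m), tf = tfs,
                        stringsAsFactors = FALSE)
  per_tf$f1 <- m[cbind(per_tf$definition, per_tf$tf)]
  ranking <- data.frame(definition = rownames(m), mean_f1 = rowMeans(m))
  ranking <- ranking[order(-ranking$mean_f1), ]
  ranking$rank <- seq_len(nrow(ranking))
  results <- structure(list(rows = NULL, per_tf = per_tf,
                            ranking = ranking),
                       class = "EvaluationResult")
  out <- method_contribution(results, cfg, "extension")
  expect_equal(out$n_pairs, 2L)
  # with 8 TFs the exact two-sided floor is 2/256 < 0.05: a_ext improves,
  # b_ext does not
  expect_equal(out$percent_improved, 50)
  expect_error(method_contribution(results, cfg, "link:l1"), "no with")
})

test_that("ROC/PR sweep behaves at the separability extremes", {
  gse <- data.frame(term_id = sprintf("T%02d", 1:20),
                    n_set_genes = 20L, statistic = 0,
                    direction = "enriched",
                    p_value = seq(0.001, 0.99, length.out = 20),
                    fdr = seq(0.001, 0.99, length.out = 20))
  pos <- sprintf("T%02d", 1:10)   # the 10 smallest p-values
  neg <- sprintf("T%02d", 11:20)
  out <- roc_pr_over_cutoffs(gse, pos, neg)
  expect_equal(out$auroc, 1)
  expect_equal(out$auprc, 1)
  rev_out <- roc_pr_over_cutoffs(gse, neg, pos)
  expect_equal(rev_out$auroc, 1 - out$auroc)
  expect_error(roc_pr_over_cutoffs(gse, character(), neg), "both classes")
  # random labels hover around 0.5
  set.seed(62)
  aucs <- replicate(300, {
    sh <- sample(gse$term_id)
    roc_pr_over_cutoffs(gse, sh[1:10], sh[11:20])$auroc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.03)
  # agreement with an independent ROC implementation, ties included
  set.seed(63)
  p <- round(runif(40), 1)
  labels <- rbinom(40, 1, 0.5)
  gse2 <- data.frame(term_id = sprintf("U%02d", 1:40), n_set_genes = 10L,
                     statistic = 0, direction = "enriched", p_value = p,
                     fdr = p)
  mine <- roc_pr_over_cutoffs(gse2, gse2$term_id[labels == 1],
                              gse2$term_id[labels == 0])$auroc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, p, quiet = TRUE,
                                        direction = ">")))
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("concordance AUC is 1 for identical results and reproducible", {
  set.seed(64)
  n <- 150L
  p <- c(runif(30, 0, 0.001), runif(120, 0.5, 1))
  gse <- data.frame(term_id = sprintf("T%03d", 1:n),
                    n_set_genes = sample(15:200, n, replace = TRUE),
                    statistic = 0, direction = "enriched",
                    p_value = p, fdr = bh_fdr(p))
  out <- concordance_auc(gse, gse, n_top = 20L, n_neg = 20L,
                         n_samplings = 10L, seed = 5L)
  expect_equal(out$mean_auc, 1)
  out2 <- concordance_auc(gse, gse, n_top = 20L, n_neg = 20L,
                          n_samplings = 10L, seed = 5L)
  expect_identical(out$auc, out2$auc)
  # shuffled regulome scores drift to chance
  sh <- gse
  set.seed(65)
  aucs <- replicate(40, {
    sh$p_value <- sample(gse$p_value)
    concordance_auc(sh, gse, n_top = 20L, n_neg = 20L, n_samplings = 2L,
                    seed = 6L)$mean_auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.08)
})

test_that("per-TF aggregation is invariant to processing order", {
  toy <- default_toy()
  rgl <- toy$regulome
  pks <- lapply(names(rgl$tf_terms), function(tf) {
    make_tf_peaks(toy$spec, toy$registry, rgl, tf)
  })
  tf_of <- setNames(names(rgl$tf_terms), names(rgl$tf_terms))
  plan <- negative_sampling_plan(n_repetitions = 3L, rng_seed = 2L)
  defs <- list(truth = rgl$truth)
  r1 <- evaluate_definitions(defs, pks, tf_of, rgl$sets, rgl$annotations,
                             toy$registry, plan = plan)
  r2 <- evaluate_definitions(defs, rev(pks), tf_of, rgl$sets,
                             rgl$annotations, toy$registry, plan = plan)
  expect_equal(r1$ranking$mean_f1, r2$ranking$mean_f1)
  expect_true(all(r1$rows$TP + r1$rows$FN ==
                    lengths(rgl$tf_terms)[r1$rows$tf]))
})
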