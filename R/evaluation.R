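# F1-based evaluation of definitions against TF GO annotations: positive
# terms come from the ontology assignments of each TF, negatives are
# size-matched random terms outside the positives' DAG neighbourhood, and a
# definition is scored by how well significantly-enriched GSE terms recover
# the positives.

.hash_string <- function(s) {
  v <- utf8ToInt(s)
  sum(v * seq_along(v)) %% 1000003L
}

.derive_seed <- function(seed, tf_id, repetition) {
  (as.integer(seed) %% 65521L) * 32003L + .hash_string(tf_id) * 17L +
    as.integer(repetition)
}

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' TF annotation: positive GO terms for one transcription factor
#'
#' @param tf_id TF identifier.
#' @param positive_terms character vector of positive term ids.
#' @param scheme `standard` or `conservative_no_iea` (controls which DAG
#'   neighbourhood is excluded from the negative pool later).
#' @return object of class `TFAnnotation`.
#' @export
tf_annotation <- function(tf_id, positive_terms,
                          scheme = c("standard", "conservative_no_iea")) {
  structure(list(tf_id = tf_id,
                 positive_terms = unique(positive_terms),
                 scheme = match.arg(scheme)),
            class = "TFAnnotation")
}

#' Build the positive term set of a TF
#'
#' Standard scheme: the most specific assigned terms (leaves of the
#' assigned set) plus all their DAG ancestors.  Conservative scheme: terms
#' flagged as IEA-only are removed first, then leaves plus parents and
#' grandparents only.  Both are size-filtered to `[min_size, max_size]`
#' genes (after intersection with `universe` when given).
#'
#' @param tf_id TF identifier (used in error messages).
#' @param tf_terms term ids assigned to the TF.
#' @param sets `GeneSetCollection`.
#' @param scheme `standard` or `conservative_no_iea`.
#' @param iea_only term ids whose assignment to this TF is IEA-only
#'   (dropped under the conservative scheme).
#' @param min_size,max_size gene-count bounds for kept terms.
#' @param universe optional gene universe for size computation.
#' @return `TFAnnotation`.
#' @export
build_positive_terms <- function(tf_id, tf_terms, sets,
                                 scheme = c("standard",
                                            "conservative_no_iea"),
                                 iea_only = character(),
                                 min_size = 15L, max_size = 2000L,
                                 universe = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "conservative_no_iea") {
    tf_terms <- setdiff(tf_terms, iea_only)
  }
  leaves <- dag_leaves_of(sets, tf_terms)
  pos <- if (scheme == "standard") {
    union(leaves, dag_ancestors(sets, leaves))
  } else {
    parents <- dag_parents(sets, leaves)
    union(leaves, union(parents, dag_parents(sets, parents)))
  }
  pos <- intersect(pos, names(sets$terms))
  sz <- .term_sizes(sets, universe)[pos]
  pos <- pos[sz >= min_size & sz <= max_size]
  if (length(pos) == 0L) {
    stop("no positive terms left for TF '", tf_id, "' after size filtering")
  }
  tf_annotation(tf_id, pos, scheme)
}

.term_sizes <- function(sets, universe = NULL) {
  if (is.null(universe)) return(lengths(sets$terms))
  vapply(sets$terms, function(g) length(intersect(g, universe)), 0L)
}

#' Negative-sampling plan
#'
#' @param bin_size width of the term-size bins in genes (default 20; bins
#'   are fixed half-open windows `[0,20), [20,40), ...`).
#' @param n_repetitions number of independent sampling repetitions.
#' @param rng_seed base seed; each draw is seeded by
#'   (rng_seed, tf_id, repetition) so results are reproducible and
#'   repetitions are fresh draws.
#' @return object of class `NegativeSamplingPlan`.
#' @export
negative_sampling_plan <- function(bin_size = 20L, n_repetitions = 10L,
                                   rng_seed = 1L) {
  stopifnot(bin_size >= 1L, n_repetitions >= 1L)
  structure(list(bin_size = as.integer(bin_size),
                 n_repetitions = as.integer(n_repetitions),
                 rng_seed = as.integer(rng_seed)),
            class = "NegativeSamplingPlan")
}

# draw one pool member per target size, same size bin, without replacement;
# empty bin falls back to the nearest non-empty bin (ties to the lower bin)
.sample_size_matched <- function(pool_ids, pool_sizes, target_sizes,
                                 bin_size) {
  if (length(pool_ids) < length(target_sizes)) {
    stop("negative pool (", length(pool_ids),
         ") smaller than number of targets (", length(target_sizes), ")")
  }
  pool_bin <- pool_sizes %/% bin_size
  taken <- logical(length(pool_ids))
  out <- character(length(target_sizes))
  for (i in seq_along(target_sizes)) {
    tb <- target_sizes[i] %/% bin_size
    avail_bins <- unique(pool_bin[!taken])
    use_bin <- if (tb %in% avail_bins) tb else {
      d <- abs(avail_bins - tb)
      min(avail_bins[d == min(d)])
    }
    cand <- which(!taken & pool_bin == use_bin)
    pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
    taken[pick] <- TRUE
    out[i] <- pool_ids[pick]
  }
  out
}

#' Sample size-matched negative terms for one TF
#'
#' Eligible negatives are all size-filtered terms that are not positives
#' and lie outside the excluded DAG neighbourhood of the positives
#' (standard scheme: their offspring and siblings; conservative scheme:
#' their ancestors, siblings of those ancestors, and offspring).  One
#' negative is drawn per positive, without replacement within a
#' repetition, matched on the positive's term-size bin.
#'
#' @param annotation `TFAnnotation`.
#' @param sets `GeneSetCollection`.
#' @param plan `NegativeSamplingPlan`.
#' @param repetition repetition index (1-based) used in the seed.
#' @param min_size,max_size size filter applied to the pool.
#' @param universe optional gene universe for size computation.
#' @return character vector of negative term ids, one per positive.
#' @export
sample_negative_terms <- function(annotation, sets, plan, repetition = 1L,
                                  min_size = 15L, max_size = 2000L,
                                  universe = NULL) {
  pos <- annotation$positive_terms
  excluded <- if (annotation$scheme == "standard") {
    c(dag_offspring(sets, pos), dag_siblings(sets, pos))
  } else {
    anc <- dag_ancestors(sets, pos)
    c(anc, dag_siblings(sets, anc), dag_offspring(sets, pos))
  }
  sz <- .term_sizes(sets, universe)
  pool <- setdiff(names(sets$terms)[sz >= min_size & sz <= max_size],
                  c(pos, excluded))
  if (length(pool) == 0L) stop("empty negative pool for TF '",
                               annotation$tf_id, "'")
  .with_seed(
    .derive_seed(plan$rng_seed, annotation$tf_id, repetition),
    .sample_size_matched(pool, sz[pool], sz[pos], plan$bin_size))
}

#' Confusion counts and F1 for one GSE result
#'
#' A term is called significantly enriched when `fdr < alpha` and its
#' direction is `enriched`; depleted terms are never called regardless of
#' FDR.  Terms absent from the GSE result count as not significant.
#'
#' @param gse `GSEResult`.
#' @param annotation `TFAnnotation` (supplies the positives).
#' @param negatives character vector of sampled negative term ids.
#' @param alpha FDR threshold (default 0.05).
#' @return one-row data frame with `TP, FP, TN, FN, precision, recall, f1`.
#' @export
confusion_and_f1 <- function(gse, annotation, negatives, alpha = 0.05) {
  sig <- gse$term_id[gse$fdr < alpha & gse$direction == "enriched"]
  pos <- annotation$positive_terms
  TP <- length(intersect(pos, sig))
  FN <- length(pos) - TP
  FP <- length(intersect(negatives, sig))
  TN <- length(negatives) - FP
  precision <- if (TP + FP > 0L) TP / (TP + FP) else 0
  recall <- if (TP + FN > 0L) TP / (TP + FN) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  data.frame(TP = TP, FP = FP, TN = TN, FN = FN,
             precision = precision, recall = recall, f1 = f1)
}

#' Evaluate and rank definitions against TF annotations
#'
#' For every (definition, peak set): assign peaks under the definition, run
#' the GSE test, and for each sampling repetition draw negatives and
#' compute confusion counts and F1.  F1 is averaged over repetitions, then
#' over a TF's peak sets, then over TFs, giving one mean F1 per definition
#' (so TFs with many datasets do not dominate).
#'
#' @param definitions named list of `EnTDef` objects.
#' @param peaksets list of `PeakSet`s; each `name` must appear in `tf_of`.
#' @param tf_of named character vector mapping peak-set name to TF id.
#' @param sets `GeneSetCollection`.
#' @param annotations named list of `TFAnnotation` keyed by TF id.
#' @param registry `GeneRegistry`.
#' @param spec `GSEModelSpec`.
#' @param plan `NegativeSamplingPlan`.
#' @param locdef_mode `entdef` (default) or `entdef_plus5kb`; ignored for
#'   elements of `definitions` that are already `LocusDefinition` objects
#'   (baselines).
#' @param min_size,max_size term-size bounds for testing and sampling.
#' @param alpha FDR threshold for the enriched call.
#' @return object of class `EvaluationResult`: `rows` (per definition, TF,
#'   peak set, repetition), `per_tf` (mean F1 per definition and TF) and
#'   `ranking` (per-definition mean F1, descending).
#' @export
evaluate_definitions <- function(definitions, peaksets, tf_of, sets,
                                 annotations, registry,
                                 spec = gse_model_spec(),
                                 plan = negative_sampling_plan(),
                                 locdef_mode = "entdef",
                                 min_size = 15L, max_size = 2000L,
                                 alpha = 0.05) {
  rows <- list()
  for (def_name in names(definitions)) {
    def <- definitions[[def_name]]
    locdef <- if (inherits(def, "LocusDefinition")) def else {
      build_locusdef(locdef_mode, registry, entdef = def)
    }
    for (ps in peaksets) {
      tf <- tf_of[[ps$name]]
      if (is.null(tf) || !tf %in% names(annotations)) {
        warning("peak set '", ps$name, "' has no annotated TF; skipped")
        next
      }
      ann <- annotations[[tf]]
      profile <- assign_peaks(locdef, ps)
      gse <- tryCatch(
        gse_test(profile, sets, spec, min_size, max_size),
        error = function(e) {
          warning("GSE failed for ", def_name, " / ", ps$name, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(gse)) next
      universe <- profile$genes$gene_id[profile$genes$locus_length > 0]
      for (rep_i in seq_len(plan$n_repetitions)) {
        neg <- sample_negative_terms(ann, sets, plan, rep_i,
                                     min_size, max_size, universe)
        row <- confusion_and_f1(gse, ann, neg, alpha)
        row$definition <- def_name
        row$tf <- tf
        row$peakset <- ps$name
        row$repetition <- rep_i
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stop("no evaluation rows produced")
  # mean over repetitions -> peak set; mean over peak sets -> TF
  by_ps <- stats::aggregate(f1 ~ definition + tf + peakset, rows, mean)
  per_tf <- stats::aggregate(f1 ~ definition + tf, by_ps, mean)
  ranking <- stats::aggregate(f1 ~ definition, per_tf, mean)
  names(ranking)[2L] <- "mean_f1"
  ranking <- ranking[order(-ranking$mean_f1, ranking$definition), ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  structure(list(rows = rows, per_tf = per_tf, ranking = ranking),
            class = "EvaluationResult")
}

#' @export
print.EvaluationResult <- function(x, ...) {
  cat(sprintf("EvaluationResult: %d definitions, %d TFs\n",
              nrow(x$ranking), length(unique(x$per_tf$tf))))
  print(utils::head(x$ranking, 10L))
  invisible(x)
}

# definitions x TFs matrix of mean F1, rows ordered like ranking
.f1_matrix <- function(results) {
  wide <- stats::reshape(results$per_tf, idvar = "definition",
                         timevar = "tf", direction = "wide")
  rownames(wide) <- wide$definition
  m <- as.matrix(wide[, -1L, drop = FALSE])
  colnames(m) <- sub("^f1\\.", "", colnames(m))
  m[results$ranking$definition, , drop = FALSE]
}

#' Select the top set of definitions
#'
#' Walks the ranking from rank 2 downward and performs a paired (per-TF)
#' two-sided Wilcoxon signed-rank test against the rank-1 definition; the
#' first rank with `p < p_cutoff` is the cutoff, and the top set is every
#' rank strictly above it.
#'
#' @param results `EvaluationResult`.
#' @param p_cutoff significance threshold for the walk (default 0.01).
#' @return list of class `RankingOutcome`: `ranking`, `cutoff_rank`
#'   (`NA` when no rank reaches the threshold), `top_set` (definition
#'   names), and `p_values` (per rank >= 2 vs rank 1).
#' @export
select_top_set <- function(results, p_cutoff = 0.01) {
  m <- .f1_matrix(results)
  if (nrow(m) < 2L) stop("need >= 2 definitions")
  if (ncol(m) < 2L) stop("need >= 2 TFs for the paired test")
  means <- rowMeans(m)
  if (any(diff(means) > 1e-12)) {
    stop("ranking must be descending by mean F1")
  }
  pvals <- rep(NA_real_, nrow(m))
  cutoff <- NA_integer_
  for (k in 2:nrow(m)) {
    pvals[k] <- wilcoxon_signed_rank(m[1L, ], m[k, ])$p_value
    if (pvals[k] < p_cutoff) { cutoff <- k; break }
  }
  top <- if (is.na(cutoff)) rownames(m) else rownames(m)[seq_len(cutoff - 1L)]
  structure(list(ranking = results$ranking, cutoff_rank = cutoff,
                 top_set = top, p_values = pvals),
            class = "RankingOutcome")
}

#' @export
print.RankingOutcome <- function(x, ...) {
  cat(sprintf("RankingOutcome: top set of %d definition(s), cutoff rank %s\n",
              length(x$top_set),
              if (is.na(x$cutoff_rank)) "none" else x$cutoff_rank))
  invisible(x)
}

#' Compare every definition to a baseline
#'
#' Paired per-TF Wilcoxon signed-rank test of each definition against the
#' baseline, BH-adjusted; `better` requires `fdr < alpha` and a positive
#' mean F1 difference.
#'
#' @param results `EvaluationResult` containing the baseline.
#' @param baseline_id definition name of the baseline.
#' @param alpha FDR threshold.
#' @return data frame `definition, mean_diff, p, fdr, better`.
#' @export
compare_to_baseline <- function(results, baseline_id, alpha = 0.05) {
  m <- .f1_matrix(results)
  if (!baseline_id %in% rownames(m)) stop("baseline '", baseline_id,
                                          "' not evaluated")
  if (anyNA(m)) stop("definitions were not evaluated on the same TFs")
  base <- m[baseline_id, ]
  others <- setdiff(rownames(m), baseline_id)
  p <- vapply(others, function(d) wilcoxon_signed_rank(m[d, ], base)$p_value,
              0)
  diffs <- vapply(others, function(d) mean(m[d, ] - base), 0)
  fdr <- bh_fdr(p)
  data.frame(definition = others, mean_diff = diffs, p = p, fdr = fdr,
             better = fdr < alpha & diffs > 0, row.names = NULL)
}

.config_features <- function(config) {
  c(paste0("src:", config$sources),
    paste0("link:", config$links),
    if (!is.na(config$loop_variant)) paste0("link:L", config$loop_variant),
    if (config$extend) "extension",
    if (config$nearest_all) "nearest_all")
}

#' Per-method contribution to definition performance
#'
#' Pairs every evaluated configuration containing `feature` with the
#' configuration differing from it by that feature only, runs a paired
#' per-TF Wilcoxon test within each pair, and reports the share of pairs in
#' which the with-feature member is significantly better.
#'
#' @param results `EvaluationResult`.
#' @param configs named list of `EnTDefConfig` matching the evaluated
#'   definition names.
#' @param feature feature label as produced internally: `src:<name>`,
#'   `link:<name>`, `link:L<v>`, `extension`, or `nearest_all`.
#' @param alpha per-pair significance threshold (default 0.05).
#' @return list with `percent_improved`, `n_pairs`, `pairs` (data frame).
#' @export
method_contribution <- function(results, configs, feature, alpha = 0.05) {
  m <- .f1_matrix(results)
  feats <- lapply(configs, .config_features)
  ids <- names(configs)
  with_f <- ids[vapply(feats, function(f) feature %in% f, logical(1L))]
  pairs <- list()
  for (w in with_f) {
    target <- setdiff(feats[[w]], feature)
    partner <- ids[vapply(feats, function(f) setequal(f, target),
                          logical(1L))]
    if (length(partner) == 1L && partner %in% rownames(m) &&
        w %in% rownames(m)) {
      pairs[[length(pairs) + 1L]] <- c(with = w, without = partner)
    }
  }
  if (length(pairs) == 0L) stop("no with/without pairs found for feature '",
                                feature, "'")
  res <- do.call(rbind, lapply(pairs, function(pr) {
    wt <- wilcoxon_signed_rank(m[pr[["with"]], ], m[pr[["without"]], ])
    data.frame(with = pr[["with"]], without = pr[["without"]],
               p = wt$p_value,
               mean_diff = mean(m[pr[["with"]], ] - m[pr[["without"]], ]))
  }))
  improved <- res$p < alpha & res$mean_diff > 0
  list(percent_improved = 100 * mean(improved), n_pairs = nrow(res),
       pairs = res)
}

# ROC / PR machinery -------------------------------------------------------

.roc_pr <- function(p_scores, labels) {
  # smaller p = stronger call; sweep thresholds over observed p values
  stopifnot(length(p_scores) == length(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("need both classes for ROC/PR")
  o <- order(p_scores)
  p_sorted <- p_scores[o]
  l_sorted <- labels[o]
  # collapse ties: one operating point per distinct p value
  idx <- which(!duplicated(p_sorted, fromLast = TRUE))
  tp <- cumsum(l_sorted == 1L)[idx]
  fp <- cumsum(l_sorted == 0L)[idx]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  auprc <- sum(diff(c(0, rec)) * prec)  # step interpolation
  list(auroc = auroc, auprc = auprc)
}

#' ROC and PR areas over GSE p-value cutoffs
#'
#' Sweeps significance thresholds over the observed GSE p-values and
#' computes the trapezoidal AUROC and step-interpolated AUPRC of
#' recovering the positive terms.  Terms absent from the GSE result are
#' treated as never called (p = 1).
#'
#' @param gse `GSEResult`.
#' @param positives,negatives term-id vectors defining the labels.
#' @return list with `auroc` and `auprc`.
#' @export
roc_pr_over_cutoffs <- function(gse, positives, negatives) {
  terms <- c(positives, negatives)
  labels <- c(rep(1L, length(positives)), rep(0L, length(negatives)))
  p <- stats::setNames(rep(1, length(terms)), terms)
  hit <- intersect(terms, gse$term_id)
  p[hit] <- gse$p_value[match(hit, gse$term_id)]
  .roc_pr(unname(p), labels)
}

#' Regulome-vs-expression concordance AUC
#'
#' True positives are the `n_top` most significant expression terms
#' (`fdr < 0.05`); each sampling draws `n_neg` size-matched insignificant
#' terms (`p > 0.5`) as true negatives, scores all of them by the regulome
#' GSE p-values, and computes the AUROC.  The mean over samplings is
#' returned.
#'
#' @param regulome_gse,expression_gse `GSEResult`s over a shared term
#'   universe.
#' @param n_top maximum number of true-positive terms.
#' @param n_neg negatives per sampling.
#' @param n_samplings number of negative-sampling repetitions.
#' @param seed RNG seed.
#' @param bin_size term-size bin width for matching.
#' @return list with `mean_auc` and the per-sampling `auc` vector.
#' @export
concordance_auc <- function(regulome_gse, expression_gse, n_top = 100L,
                            n_neg = 100L, n_samplings = 100L, seed = 1L,
                            bin_size = 20L) {
  ex <- expression_gse[order(expression_gse$p_value), ]
  tp <- utils::head(ex$term_id[ex$fdr < 0.05], n_top)
  if (length(tp) < 2L) stop("fewer than 2 significant expression terms")
  pool <- ex[ex$p_value > 0.5 & !ex$term_id %in% tp, ]
  if (nrow(pool) == 0L) stop("empty insignificant-term pool")
  sizes <- stats::setNames(ex$n_set_genes, ex$term_id)
  target_sizes <- rep_len(sizes[tp], n_neg)
  aucs <- .with_seed(seed, {
    vapply(seq_len(n_samplings), function(i) {
      tn <- .sample_size_matched(pool$term_id, pool$n_set_genes,
                                 target_sizes, bin_size)
      roc_pr_over_cutoffs(regulome_gse, tp, tn)$auroc
    }, 0)
  })
  list(mean_auc = mean(aucs), auc = aucs)
}
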