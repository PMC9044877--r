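# Interceding-gene analysis: for every enhancer-gene link, count the genes
# whose bodies fall in the span between the enhancer's and the target's
# outermost coordinates; target genes with many interceding genes are the
# ones a naive nearest-gene assignment is most likely to get wrong.

#' Mean interceding-gene count per target gene
#'
#' For each non-fallback link (E, g) the query span runs from
#' `min(E.start, body.start)` to `max(E.end, body.end)`; the interceding
#' count is the number of genes other than g whose body overlaps that span
#' by >= 1 bp.  Per gene, counts are averaged over its links.
#'
#' @param entdef `EnTDef` (fallback records are ignored).
#' @param registry `GeneRegistry`.
#' @return object of class `IntercedingProfile`: data frame `gene_id,
#'   n_links, mean_interceding` plus an `int_score` column of rank-based
#'   inverse-normal scores.
#' @export
mean_interceding_per_gene <- function(entdef, registry) {
  rec <- entdef$records[!entdef$records$fallback, , drop = FALSE]
  if (nrow(rec) == 0L) stop("definition has no non-fallback links")
  g <- registry$genes
  gi <- match(rec$gene_id, g$gene_id)
  bodies <- genomic_intervals(g$chrom, g$body_start, g$body_end,
                              gene_id = g$gene_id)
  queries <- genomic_intervals(
    chrom = rec$chrom,
    start = pmin(rec$start, g$body_start[gi]),
    end = pmax(rec$end, g$body_end[gi]))
  hits <- .overlap_pairs(queries, bodies)
  # count overlapping genes per query, excluding the target itself
  not_self <- bodies$gene_id[hits$subject] != rec$gene_id[hits$query]
  cnt <- integer(nrow(rec))
  tb <- table(hits$query[not_self])
  cnt[as.integer(names(tb))] <- as.integer(tb)
  per_gene <- stats::aggregate(cnt, list(gene_id = rec$gene_id), mean)
  names(per_gene)[2L] <- "mean_interceding"
  n_links <- table(rec$gene_id)
  per_gene$n_links <- as.integer(n_links[per_gene$gene_id])
  per_gene$int_score <- if (nrow(per_gene) >= 2L) {
    rank_inverse_normal(per_gene$mean_interceding)
  } else 0
  per_gene <- per_gene[, c("gene_id", "n_links", "mean_interceding",
                           "int_score")]
  structure(per_gene, class = c("IntercedingProfile", "data.frame"))
}

# Firth-penalized logistic regression (intercept + one covariate); used as
# the fallback under complete separation, where plain ML diverges
.firth_logistic <- function(x, yb, maxit = 50L, tol = 1e-8) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    XWX <- crossprod(X, X * W)
    inv <- solve(XWX)
    # hat values of the weighted design
    H <- rowSums((X %*% inv) * X) * W
    U <- crossprod(X, yb - mu + H * (0.5 - mu))
    step <- drop(inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(crossprod(X, X * (mu * (1 - mu))))))
  list(coef = unname(beta[2L]), se = unname(se[2L]),
       p = unname(2 * stats::pnorm(-abs(beta[2L] / se[2L]))))
}

#' Logistic-regression term enrichment on interceding scores
#'
#' Per term, regresses set membership on the per-gene INT score with a
#' two-sided Wald test on the slope.  The reported statistic is the
#' negated slope, so positive values indicate terms enriched among genes
#' with fewer interceding genes (direction `fewer_interceding`).  Complete
#' separation triggers a Firth-penalized refit, flagged in the result.
#'
#' @param profile `IntercedingProfile`.
#' @param sets `GeneSetCollection`.
#' @param min_size,max_size term-size bounds after universe intersection.
#' @return `GSEResult`-style data frame `term_id, n_set_genes, statistic,
#'   direction, p_value, fdr, firth`.
#' @export
logistic_enrichment <- function(profile, sets, min_size = 10L,
                                max_size = 1000L) {
  universe <- profile$gene_id
  x <- profile$int_score
  rows <- list()
  for (id in names(sets$terms)) {
    mem <- universe %in% sets$terms[[id]]
    n <- sum(mem)
    if (n < min_size || n > max_size || n == length(universe)) next
    if (stats::sd(x) == 0) {
      rows[[id]] <- c(stat = 0, p = 1, firth = 0)
      next
    }
    fit <- suppressWarnings(stats::glm(mem ~ x, family = stats::binomial()))
    sm <- summary(fit)$coefficients
    separated <- !fit$converged || any(fit$fitted.values < 1e-8) ||
      any(fit$fitted.values > 1 - 1e-8) || abs(sm["x", 1L]) > 15
    if (separated) {
      fl <- .firth_logistic(x, as.numeric(mem))
      rows[[id]] <- c(stat = -fl$coef, p = fl$p, firth = 1)
    } else {
      rows[[id]] <- c(stat = -sm["x", 1L], p = sm["x", 4L], firth = 0)
    }
  }
  if (length(rows) == 0L) stop("no terms within size bounds")
  res <- data.frame(
    term_id = names(rows),
    n_set_genes = vapply(names(rows), function(id)
      sum(universe %in% sets$terms[[id]]), 0L),
    statistic = vapply(rows, `[[`, 0, "stat"),
    direction = ifelse(vapply(rows, `[[`, 0, "stat") >= 0,
                       "fewer_interceding", "more_interceding"),
    p_value = .clamp_p(vapply(rows, `[[`, 0, "p")),
    firth = vapply(rows, `[[`, 0, "firth") == 1,
    row.names = NULL, stringsAsFactors = FALSE)
  res$fdr <- bh_fdr(res$p_value)
  class(res) <- c("GSEResult", "data.frame")
  res
}

#' Combine term results across definitions and filter redundant terms
#'
#' Per term: the harmonic-mean p-value across definitions, BH-adjusted;
#' significant terms (`hm_fdr < alpha`) are ranked by `hm_p` ascending
#' within each direction, and a term is marked redundant when any of its
#' parents, children, or siblings ranks higher in the same list.
#'
#' @param results list (length >= 2) of results from
#'   [logistic_enrichment()] sharing a term universe.
#' @param sets `GeneSetCollection` (supplies the DAG).
#' @param alpha FDR threshold for the significant list.
#' @return data frame `term_id, direction, hm_p, hm_fdr, significant,
#'   rank_in_direction, kept_after_redundancy`.
#' @export
combine_and_filter <- function(results, sets, alpha = 0.05) {
  stopifnot(length(results) >= 2L)
  ids <- results[[1L]]$term_id
  for (r in results[-1L]) {
    if (!setequal(r$term_id, ids)) stop("results do not share a term universe")
  }
  pmat <- vapply(results, function(r) r$p_value[match(ids, r$term_id)],
                 numeric(length(ids)))
  hm_p <- apply(pmat, 1L, harmonic_mean_p)
  # direction: majority sign of the statistic across definitions
  smat <- vapply(results, function(r) r$statistic[match(ids, r$term_id)],
                 numeric(length(ids)))
  direction <- ifelse(rowMeans(smat >= 0) >= 0.5,
                      "fewer_interceding", "more_interceding")
  out <- data.frame(term_id = ids, direction = direction, hm_p = hm_p,
                    hm_fdr = bh_fdr(hm_p), stringsAsFactors = FALSE)
  out$significant <- out$hm_fdr < alpha
  out$rank_in_direction <- NA_integer_
  out$kept_after_redundancy <- FALSE
  for (dir in unique(out$direction[out$significant])) {
    sel <- which(out$significant & out$direction == dir)
    sel <- sel[order(out$hm_p[sel])]
    out$rank_in_direction[sel] <- seq_along(sel)
    ranked_ids <- out$term_id[sel]
    for (i in seq_along(sel)) {
      id <- ranked_ids[i]
      rel <- c(dag_parents(sets, id), dag_children(sets, id),
               dag_siblings(sets, id))
      higher <- ranked_ids[seq_len(i - 1L)]
      out$kept_after_redundancy[sel[i]] <- !any(rel %in% higher)
    }
  }
  out
}
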