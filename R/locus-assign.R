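# Baseline locus definitions and peak-to-gene assignment.  A locus
# definition is a set of (interval, gene) records; a peak is assigned by
# its midpoint to every gene owning a record containing that midpoint.

#' Construct a peak set
#'
#' @param peaks interval data frame.
#' @param name label (for example TF and cell type).
#' @param sizes optional chromosome sizes used to validate the peaks.
#' @return object of class `PeakSet`.
#' @export
peak_set <- function(peaks, name = "peaks", sizes = NULL) {
  if (!is.null(sizes)) validate_intervals(peaks, sizes, what = "peak")
  structure(list(name = name, peaks = peaks[, c("chrom", "start", "end")]),
            class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s': %d peaks\n", x$name, nrow(x$peaks)))
  invisible(x)
}

#' Build a locus definition
#'
#' Modes: `nearest_tss` tiles the genome by nearest TSS; `within_5kb` is the
#' promoter windows (one record per gene, overlaps allowed); `beyond_5kb` is
#' the nearest-TSS partition minus all promoter windows; `entdef` uses an
#' EnTDef's records; `entdef_plus5kb` is the union of `entdef` and
#' `within_5kb` records.
#'
#' @param mode one of the five modes above.
#' @param registry `GeneRegistry`.
#' @param window promoter half-width in bp.
#' @param entdef `EnTDef`, required for the entdef-based modes.
#' @return object of class `LocusDefinition` with records
#'   `chrom,start,end,gene_id`.
#' @export
build_locusdef <- function(mode = c("nearest_tss", "within_5kb", "beyond_5kb",
                                    "entdef", "entdef_plus5kb"),
                           registry, window = 5000L, entdef = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("entdef", "entdef_plus5kb") && is.null(entdef)) {
    stop("mode '", mode, "' requires an entdef")
  }
  prom <- function() promoter_windows(registry, window)[, c("chrom", "start",
                                                            "end", "gene_id")]
  rec <- switch(mode,
    nearest_tss = nearest_tss_partition(registry),
    within_5kb = prom(),
    beyond_5kb = subtract_intervals(nearest_tss_partition(registry),
                                    promoter_windows(registry, window)),
    entdef = entdef$records[, c("chrom", "start", "end", "gene_id")],
    entdef_plus5kb = rbind(
      entdef$records[, c("chrom", "start", "end", "gene_id")], prom()))
  rec <- rec[order(rec$chrom, rec$start, rec$end, rec$gene_id), ]
  rownames(rec) <- NULL
  structure(list(records = rec, mode = mode), class = "LocusDefinition")
}

#' @export
print.LocusDefinition <- function(x, ...) {
  cat(sprintf("LocusDefinition (%s): %d records, %d genes\n", x$mode,
              nrow(x$records), length(unique(x$records$gene_id))))
  invisible(x)
}

#' Assign peaks to genes under a locus definition
#'
#' Each peak is represented by its midpoint `floor((start + end) / 2)`
#' (rule `"midpoint"`, the default) or by its full interval with a 1-bp
#' overlap rule (`"any"`).  A peak increments the count of every gene having at
#' least one matching record; a gene is counted at most once per peak.
#' Optional per-peak weights accumulate into `weighted_count`.
#'
#' @param locdef `LocusDefinition`.
#' @param peaks `PeakSet`.
#' @param overlap_rule `"midpoint"` or `"any"`.
#' @param weights optional numeric vector, one weight per peak (default 1).
#' @return object of class `AssignmentProfile`: per-gene `peak_count`,
#'   `weighted_count`, `locus_length`, `has_peak`; counts of assigned and
#'   unassigned peaks; and the peak-to-gene map used (for the binomial
#'   test).
#' @export
assign_peaks <- function(locdef, peaks, overlap_rule = c("midpoint", "any"),
                         weights = NULL) {
  overlap_rule <- match.arg(overlap_rule)
  rec <- locdef$records
  pk <- peaks$peaks
  if (is.null(weights)) weights <- rep(1, nrow(pk))
  stopifnot(length(weights) == nrow(pk))
  if (overlap_rule == "midpoint") {
    mids <- (pk$start + pk$end) %/% 2L
    hits <- .point_in_pairs(pk$chrom, mids, rec)
  } else {
    hits <- .overlap_pairs(pk, rec)
  }
  pg <- unique(data.frame(peak = hits$query,
                          gene_id = rec$gene_id[hits$subject],
                          stringsAsFactors = FALSE))
  genes <- sort(unique(rec$gene_id))
  cnt <- stats::setNames(rep(0L, length(genes)), genes)
  wcnt <- stats::setNames(rep(0, length(genes)), genes)
  if (nrow(pg)) {
    tab <- table(pg$gene_id)
    cnt[names(tab)] <- as.integer(tab)
    ws <- tapply(weights[pg$peak], pg$gene_id, sum)
    wcnt[names(ws)] <- as.numeric(ws)
  }
  len <- tapply(rec$end - rec$start, rec$gene_id, sum)
  structure(list(
    peakset_name = peaks$name,
    genes = data.frame(gene_id = genes,
                       peak_count = as.integer(cnt),
                       weighted_count = as.numeric(wcnt),
                       locus_length = as.numeric(len[genes]),
                       has_peak = cnt > 0L,
                       row.names = NULL, stringsAsFactors = FALSE),
    n_assigned_peaks = length(unique(pg$peak)),
    n_unassigned_peaks = nrow(pk) - length(unique(pg$peak)),
    peak_gene = pg
  ), class = "AssignmentProfile")
}

#' @export
print.AssignmentProfile <- function(x, ...) {
  cat(sprintf(
    "AssignmentProfile '%s': %d genes, %d assigned / %d unassigned peaks\n",
    x$peakset_name, nrow(x$genes), x$n_assigned_peaks, x$n_unassigned_peaks))
  invisible(x)
}

#' Read an assignment profile from TSV
#'
#' Restores the per-gene table written by [write_profile()].  The
#' peak-to-gene map is not stored in the TSV, so profiles read from disk
#' support the count-based and Fisher GSE methods but not the binomial one.
#'
#' @param path TSV written by [write_profile()].
#' @param name peak-set label to record.
#' @return `AssignmentProfile`.
#' @export
read_profile <- function(path, name = basename(path)) {
  g <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  g$weighted_count <- as.numeric(g$peak_count)
  structure(list(peakset_name = name,
                 genes = g[, c("gene_id", "peak_count", "weighted_count",
                               "locus_length", "has_peak")],
                 n_assigned_peaks = sum(g$peak_count),
                 n_unassigned_peaks = NA_integer_,
                 peak_gene = NULL),
            class = "AssignmentProfile")
}

#' Write an assignment profile as TSV
#' @param profile `AssignmentProfile`.
#' @param path output file (`gene_id peak_count locus_length has_peak`).
#' @export
write_profile <- function(profile, path) {
  utils::write.table(
    profile$genes[, c("gene_id", "peak_count", "locus_length", "has_peak")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
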