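# All coordinates in this package are 0-based, half-open [start, end)
# (BED convention).  GRanges (1-based, closed) is used internally for the
# set algebra; conversion happens only at these two helpers.

.as_granges <- function(iv, sizes = NULL) {
  if (nrow(iv) == 0L) {
    return(GenomicRanges::GRanges())
  }
  sl <- if (is.null(sizes)) NA else sizes[unique(iv$chrom)]
  GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end)
  )
}

.as_intervals <- function(gr) {
  if (length(gr) == 0L) return(genomic_intervals())
  genomic_intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Construct a table of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`
#' (0-based, half-open).  Extra columns are carried through all interval
#' operations that preserve records.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end`.
#' @param ... further equal-length columns (labels, provenance).
#' @return a `data.frame` with at least `chrom`, `start`, `end`.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   ...,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Read a chromosome-sizes table
#'
#' @param path two-column TSV `chrom<TAB>length`.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "integer"))
  chrom_sizes(tab$length, tab$chrom)
}

#' Construct a chromosome-sizes object
#'
#' @param lengths positive integer lengths in bp.
#' @param chroms chromosome names, unique.
#' @return named integer vector.
#' @export
chrom_sizes <- function(lengths, chroms) {
  lengths <- as.integer(lengths)
  if (anyDuplicated(chroms)) stop("duplicate chromosome names")
  if (any(lengths <= 0L)) stop("chromosome lengths must be > 0")
  stats::setNames(lengths, chroms)
}

#' Validate intervals against chromosome sizes
#'
#' Checks `0 <= start < end`, chromosome membership and `end <= length`.
#' Returns the input invisibly so it can be used in pipelines.
#'
#' @param iv interval data frame.
#' @param sizes named lengths from [chrom_sizes()].
#' @param what label used in error messages.
#' @export
validate_intervals <- function(iv, sizes, what = "interval") {
  if (nrow(iv) == 0L) return(invisible(iv))
  bad <- which(iv$start < 0L | iv$start >= iv$end)
  if (length(bad)) {
    stop(sprintf("%s %d invalid: start=%d end=%d (need 0 <= start < end)",
                 what, bad[1L], iv$start[bad[1L]], iv$end[bad[1L]]))
  }
  unknown <- setdiff(unique(iv$chrom), names(sizes))
  if (length(unknown)) {
    stop(sprintf("%s on unknown chromosome(s): %s", what,
                 paste(unknown, collapse = ", ")))
  }
  over <- which(iv$end > sizes[iv$chrom])
  if (length(over)) {
    stop(sprintf("%s %d exceeds chromosome %s length %d",
                 what, over[1L], iv$chrom[over[1L]], sizes[iv$chrom[over[1L]]]))
  }
  invisible(iv)
}

#' Sort intervals by (chrom, start, end)
#' @param iv interval data frame.
#' @export
sort_intervals <- function(iv) {
  iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
}

#' Merge overlapping and touching intervals
#'
#' Returns the minimal sorted set of disjoint intervals covering the same
#' bases.  Touching intervals (`end == start` of the next) are merged:
#' the semantics are base coverage, not records.  Extra columns are dropped.
#'
#' @param iv interval data frame.
#' @return merged interval data frame, sorted.
#' @export
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(genomic_intervals())
  sort_intervals(.as_intervals(GenomicRanges::reduce(.as_granges(iv))))
}

#' Subtract interval coverage
#'
#' Removes from each record of `a` every base covered by `b`.  A record may
#' split into several pieces or vanish; pieces inherit the record's extra
#' columns.  Duplicate records in `a` are preserved.
#'
#' @param a,b interval data frames.
#' @return interval data frame of remnants of `a`, sorted.
#' @export
subtract_intervals <- function(a, b) {
  if (nrow(a) == 0L) return(a[0, , drop = FALSE])
  if (nrow(b) == 0L) return(sort_intervals(a))
  bm <- merge_intervals(b)
  hits <- GenomicRanges::findOverlaps(.as_granges(a), .as_granges(bm))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  untouched <- setdiff(seq_len(nrow(a)), unique(qh))
  pieces <- vector("list", length(unique(qh)) + 1L)
  pieces[[1L]] <- a[untouched, , drop = FALSE]
  k <- 1L
  for (i in unique(qh)) {
    cuts <- bm[sh[qh == i], , drop = FALSE]
    s <- a$start[i]; e <- a$end[i]
    # merged cuts are disjoint & sorted; walk the gaps
    keep_s <- integer(); keep_e <- integer()
    pos <- s
    for (j in seq_len(nrow(cuts))) {
      cs <- max(cuts$start[j], s); ce <- min(cuts$end[j], e)
      if (cs > pos) { keep_s <- c(keep_s, pos); keep_e <- c(keep_e, cs) }
      pos <- max(pos, ce)
    }
    if (pos < e) { keep_s <- c(keep_s, pos); keep_e <- c(keep_e, e) }
    k <- k + 1L
    if (length(keep_s)) {
      rec <- a[rep(i, length(keep_s)), , drop = FALSE]
      rec$start <- keep_s
      rec$end <- keep_e
      pieces[[k]] <- rec
    }
  }
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  rownames(out) <- NULL
  sort_intervals(out)
}

#' Intersect interval coverage
#'
#' Base-level intersection of two interval sets (records collapsed).
#'
#' @param a,b interval data frames.
#' @return merged interval data frame of shared bases.
#' @export
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(genomic_intervals())
  gr <- GenomicRanges::intersect(.as_granges(merge_intervals(a)),
                                 .as_granges(merge_intervals(b)))
  sort_intervals(.as_intervals(gr))
}

#' Total bases covered by an interval set
#' @param iv interval data frame.
#' @return integer bp after merging.
#' @export
total_coverage <- function(iv) {
  m <- merge_intervals(iv)
  if (nrow(m) == 0L) return(0L)
  sum(m$end - m$start)
}

# all (query, subject) index pairs with >= 1 bp overlap
.overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(data.frame(query = integer(), subject = integer()))
  }
  hits <- GenomicRanges::findOverlaps(.as_granges(query), .as_granges(subject))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

# indices of the subject interval containing each query point (0-based base),
# as a (query, subject) pair table; containment is start <= p < end
.point_in_pairs <- function(chrom, pos, subject) {
  if (length(pos) == 0L || nrow(subject) == 0L) {
    return(data.frame(query = integer(), subject = integer()))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(q, .as_granges(subject))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}
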