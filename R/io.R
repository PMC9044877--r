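# Readers for the plain-text formats the tool consumes.  All of them retain
# duplicate records (collapsing is merge_intervals' job) and report parse
# failures with the offending line number.

.read_tsv_lines <- function(path) {
  lines <- readLines(path)
  lines[nzchar(lines) & !startsWith(lines, "#") &
          !startsWith(lines, "track") & !startsWith(lines, "browser")]
}

.split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

.int_or_stop <- function(x, line_no, path, field) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("%s: line %d: non-integer %s '%s'",
                 path, line_no[bad[1L]], field, x[bad[1L]]))
  }
  v
}

#' Read a BED (or narrowPeak) file
#'
#' Uses the first three columns; further columns are ignored.  Intervals are
#' validated against `sizes`, sorted, and duplicates kept.
#'
#' @param path BED3/BED6/narrowPeak file.
#' @param sizes chromosome sizes from [chrom_sizes()].
#' @return interval data frame.
#' @export
read_bed <- function(path, sizes) {
  lines <- .read_tsv_lines(path)
  if (length(lines) == 0L) return(genomic_intervals())
  fields <- .split_fields(lines)
  n <- lengths(fields)
  if (any(n < 3L)) {
    stop(sprintf("%s: line %d: expected >= 3 tab-separated columns, got %d",
                 path, which(n < 3L)[1L], n[which(n < 3L)[1L]]))
  }
  ln <- seq_along(lines)
  iv <- genomic_intervals(
    chrom = vapply(fields, `[[`, "", 1L),
    start = .int_or_stop(vapply(fields, `[[`, "", 2L), ln, path, "start"),
    end = .int_or_stop(vapply(fields, `[[`, "", 3L), ln, path, "end")
  )
  validate_intervals(iv, sizes, what = paste0(path, ": record"))
  sort_intervals(iv)
}

#' Write intervals as BED3
#' @param iv interval data frame.
#' @param path output file.
#' @export
write_bed <- function(iv, path) {
  utils::write.table(iv[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE file of paired anchors
#'
#' The six coordinate columns are used; an optional score column is ignored.
#' Inter-chromosomal pairs are accepted here (loop-based linking later
#' requires intra-chromosomal spans).
#'
#' @inheritParams read_bed
#' @return data frame `chrom1,start1,end1,chrom2,start2,end2`.
#' @export
read_bedpe <- function(path, sizes) {
  lines <- .read_tsv_lines(path)
  empty <- data.frame(chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer())
  if (length(lines) == 0L) return(empty)
  fields <- .split_fields(lines)
  n <- lengths(fields)
  if (any(n < 6L)) {
    stop(sprintf("%s: line %d: expected >= 6 coordinate columns, got %d",
                 path, which(n < 6L)[1L], n[which(n < 6L)[1L]]))
  }
  ln <- seq_along(lines)
  pe <- data.frame(
    chrom1 = vapply(fields, `[[`, "", 1L),
    start1 = .int_or_stop(vapply(fields, `[[`, "", 2L), ln, path, "start1"),
    end1 = .int_or_stop(vapply(fields, `[[`, "", 3L), ln, path, "end1"),
    chrom2 = vapply(fields, `[[`, "", 4L),
    start2 = .int_or_stop(vapply(fields, `[[`, "", 5L), ln, path, "start2"),
    end2 = .int_or_stop(vapply(fields, `[[`, "", 6L), ln, path, "end2"),
    stringsAsFactors = FALSE
  )
  validate_intervals(
    genomic_intervals(pe$chrom1, pe$start1, pe$end1), sizes,
    what = paste0(path, ": anchor1"))
  validate_intervals(
    genomic_intervals(pe$chrom2, pe$start2, pe$end2), sizes,
    what = paste0(path, ": anchor2"))
  pe
}

#' Write anchor pairs as BEDPE
#' @param pe data frame as returned by [read_bedpe()].
#' @param path output file.
#' @export
write_bedpe <- function(pe, path) {
  utils::write.table(
    pe[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a gene registry
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `tss`, `body_start`, `body_end` (0-based half-open body;
#'   the TSS is supplied explicitly and must lie inside the body).
#' @param sizes chromosome sizes.
#' @return object of class `GeneRegistry`.
#' @export
gene_registry <- function(genes, sizes) {
  need <- c("gene_id", "chrom", "strand", "tss", "body_start", "body_end")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("registry missing column(s): ",
                         paste(miss, collapse = ", "))
  genes <- genes[, need]
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ",
         genes$gene_id[duplicated(genes$gene_id)][1L])
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  bad <- which(genes$tss < genes$body_start | genes$tss >= genes$body_end)
  if (length(bad)) {
    stop("tss outside gene body for gene ", genes$gene_id[bad[1L]])
  }
  validate_intervals(
    genomic_intervals(genes$chrom, genes$body_start, genes$body_end),
    sizes, what = "gene body")
  structure(list(genes = genes, sizes = sizes), class = "GeneRegistry")
}

#' @export
print.GeneRegistry <- function(x, ...) {
  cat(sprintf("GeneRegistry: %d genes on %d chromosome(s) (%s bp)\n",
              nrow(x$genes), length(x$sizes),
              format(sum(as.numeric(x$sizes)), big.mark = ",")))
  invisible(x)
}

#' Read a gene registry from TSV
#'
#' @param path TSV with header
#'   `gene_id chrom strand tss body_start body_end`.
#' @param sizes_path chromosome-sizes TSV (`chrom length`, no header).
#' @return `GeneRegistry`.
#' @export
read_gene_registry <- function(path, sizes_path) {
  sizes <- read_chrom_sizes(sizes_path)
  genes <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  gene_registry(genes, sizes)
}

#' Write a gene registry to TSV
#' @param registry `GeneRegistry`.
#' @param path genes TSV output.
#' @param sizes_path chromosome sizes output.
#' @export
write_gene_registry <- function(registry, path, sizes_path) {
  utils::write.table(registry$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  utils::write.table(
    data.frame(chrom = names(registry$sizes),
               length = as.integer(registry$sizes)),
    sizes_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param terms named list mapping term id to character vector of gene ids.
#' @param dag_parents named list mapping term id to its parent term ids
#'   (may include structure-only terms absent from `terms`).
#' @param namespace label (`BP`, `MF`, `CC`).
#' @return object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(terms, dag_parents = list(),
                                namespace = "BP") {
  stopifnot(is.list(terms))
  .check_dag_acyclic(dag_parents)
  structure(list(terms = terms, dag_parents = dag_parents,
                 namespace = namespace),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection (%s): %d terms, %d DAG edges\n",
              x$namespace, length(x$terms),
              sum(lengths(x$dag_parents))))
  invisible(x)
}

#' Read gene sets from GMT plus an optional parent-child table
#'
#' @param gmt_path GMT file: `term_id<TAB>description<TAB>gene1<TAB>...`.
#' @param dag_path optional 2-column TSV `child<TAB>parent`; `NULL` for a
#'   flat (parentless) collection.
#' @param namespace label stored on the collection.
#' @return `GeneSetCollection`.  DAG terms absent from the GMT are kept as
#'   structure-only nodes with a warning.
#' @export
read_gene_sets <- function(gmt_path, dag_path = NULL, namespace = "BP") {
  lines <- .read_tsv_lines(gmt_path)
  fields <- .split_fields(lines)
  n <- lengths(fields)
  if (length(n) && any(n < 3L)) {
    stop(sprintf("%s: line %d: GMT needs term, description and >= 1 gene",
                 gmt_path, which(n < 3L)[1L]))
  }
  terms <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(terms) <- vapply(fields, `[[`, "", 1L)
  dag <- list()
  if (!is.null(dag_path)) {
    edges <- utils::read.table(dag_path, sep = "\t", header = FALSE,
                               col.names = c("child", "parent"),
                               colClasses = "character")
    dag <- split(edges$parent, edges$child)
    orphans <- setdiff(unique(c(edges$child, edges$parent)), names(terms))
    if (length(orphans)) {
      warning("DAG term(s) absent from GMT kept as structure-only nodes: ",
              paste(utils::head(orphans, 5L), collapse = ", "))
    }
  }
  gene_set_collection(terms, dag, namespace)
}

#' Write gene sets as GMT (+ optional DAG TSV)
#' @param sets `GeneSetCollection`.
#' @param gmt_path output GMT.
#' @param dag_path optional output for parent-child edges.
#' @export
write_gene_sets <- function(sets, gmt_path, dag_path = NULL) {
  lines <- vapply(names(sets$terms), function(id) {
    paste(c(id, id, sets$terms[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, gmt_path)
  if (!is.null(dag_path)) {
    ch <- rep(names(sets$dag_parents), lengths(sets$dag_parents))
    pa <- unlist(sets$dag_parents, use.names = FALSE)
    utils::write.table(data.frame(child = ch, parent = pa), dag_path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(gmt_path)
}

#' Write an EnTDef as TSV
#'
#' Columns: `chrom start end gene_id sources link_methods fallback`.
#' @param entdef `EnTDef` object.
#' @param path output file.
#' @export
write_entdef <- function(entdef, path) {
  utils::write.table(entdef$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an EnTDef from TSV
#' @param path file written by [write_entdef()].
#' @param registry `GeneRegistry` the records refer to.
#' @return `EnTDef` (with a `NULL` config).
#' @export
read_entdef <- function(path, registry) {
  rec <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "character",
                                          "character", "logical"))
  new_entdef(rec, config = NULL, registry = registry)
}

#' Read a labeled benchmark pair table
#'
#' TSV with header `chrom start end gene_id label`; label is `positive` or
#' `negative`.
#' @param path input file.
#' @param sizes chromosome sizes.
#' @return data frame of benchmark pairs.
#' @export
read_benchmark_pairs <- function(path, sizes) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(tab$label %in% c("positive", "negative"))) {
    stop("benchmark labels must be 'positive' or 'negative'")
  }
  validate_intervals(genomic_intervals(tab$chrom, tab$start, tab$end),
                     sizes, what = "benchmark pair")
  tab
}

#' Read an enhancer-gene pair table
#'
#' TSV with header `chrom start end gene_id` (the enhancer interval of the
#' upstream evidence plus its linked gene).
#' @param path input file.
#' @param sizes chromosome sizes.
#' @return data frame of pairs.
#' @export
read_pair_table <- function(path, sizes) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  validate_intervals(genomic_intervals(tab$chrom, tab$start, tab$end),
                     sizes, what = "pair")
  tab
}
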