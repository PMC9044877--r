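# Assembly of enhancer-to-target-gene definitions (EnTDefs): enhancer
# regions from one or more sources are unioned, trimmed away from promoter
# windows, optionally extended to a minimum length, and linked to genes by
# pair-table, paired-anchor or chromatin-loop evidence; optionally every
# remaining distal base falls back to the nearest-TSS gene.

#' Promoter windows of a registry
#'
#' One interval `[tss - window, tss + window)` per gene, clamped to the
#' chromosome; windows of nearby genes may overlap.
#'
#' @param registry `GeneRegistry`.
#' @param window half-width in bp (default 5000).
#' @return interval data frame with a `gene_id` column.
#' @export
promoter_windows <- function(registry, window = 5000L) {
  g <- registry$genes
  genomic_intervals(
    chrom = g$chrom,
    start = pmax(0L, g$tss - as.integer(window)),
    end = pmin(as.integer(registry$sizes[g$chrom]), g$tss + as.integer(window)),
    gene_id = g$gene_id
  )
}

#' Genome-tiling nearest-TSS partition
#'
#' Each chromosome with genes is split at the midpoints between adjacent
#' TSSs; every base belongs to the gene with the nearest TSS.  The boundary
#' between TSSs t1 < t2 sits at `ceiling((t1 + t2) / 2)`, so an exactly
#' equidistant base goes to the downstream (higher-TSS) gene.
#'
#' @param registry `GeneRegistry`.
#' @return interval data frame with `gene_id`, tiling all chromosomes that
#'   carry at least one gene.
#' @export
nearest_tss_partition <- function(registry) {
  out <- list()
  for (chr in names(registry$sizes)) {
    g <- registry$genes[registry$genes$chrom == chr, , drop = FALSE]
    if (nrow(g) == 0L) next
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    L <- as.integer(registry$sizes[[chr]])
    bounds <- if (nrow(g) > 1L) {
      (g$tss[-nrow(g)] + g$tss[-1L] + 1L) %/% 2L
    } else integer()
    s <- c(0L, bounds)
    e <- c(bounds, L)
    keep <- s < e
    out[[chr]] <- genomic_intervals(chr, s[keep], e[keep],
                                    gene_id = g$gene_id[keep])
  }
  res <- do.call(rbind, c(out, list(genomic_intervals(gene_id = character()))))
  rownames(res) <- NULL
  res
}

#' Trim promoter windows out of enhancer regions
#'
#' Subtracts the union of all `[tss - window, tss + window)` windows from
#' the regions; pieces inherit the input records' extra columns.
#'
#' @param regions interval data frame.
#' @param registry `GeneRegistry`.
#' @param window promoter half-width in bp.
#' @return trimmed interval data frame (possibly with split records).
#' @export
trim_promoter_windows <- function(regions, registry, window = 5000L) {
  subtract_intervals(regions, promoter_windows(registry, window))
}

#' Extend short enhancers to a target length
#'
#' Regions shorter than `target_len` are replaced by a `target_len` window
#' centred on their midpoint (clamped to the chromosome); longer regions
#' pass through unchanged.  Promoter trimming is re-applied afterwards so
#' that no extended base invades a promoter window.
#'
#' @param regions interval data frame.
#' @param target_len minimum length in bp (even; default 1000).
#' @param registry `GeneRegistry`.
#' @param window promoter half-width used for the re-trim.
#' @return interval data frame.
#' @export
extend_enhancers <- function(regions, target_len = 1000L, registry,
                             window = 5000L) {
  target_len <- as.integer(target_len)
  if (target_len %% 2L != 0L) stop("target_len must be even")
  if (nrow(regions) == 0L) return(regions)
  len <- regions$end - regions$start
  short <- len < target_len
  if (any(short)) {
    mid <- (regions$start[short] + regions$end[short]) %/% 2L
    half <- target_len %/% 2L
    L <- as.integer(registry$sizes[regions$chrom[short]])
    regions$start[short] <- pmax(0L, mid - half)
    regions$end[short] <- pmin(L, mid + half)
  }
  trim_promoter_windows(regions, registry, window)
}

# links are rows (enh = index into the built enhancer table, gene_id, method)
.empty_links <- function() {
  data.frame(enh = integer(), gene_id = character(), method = character(),
             stringsAsFactors = FALSE)
}

.dedup_links <- function(links) {
  links[!duplicated(links[, c("enh", "gene_id", "method")]), , drop = FALSE]
}

#' Links from a precomputed enhancer-gene pair table
#'
#' A link (E, g) is created for every built enhancer E overlapping a pair's
#' enhancer interval by at least 1 bp; pairs whose gene id is not in the
#' registry are skipped with a warning.
#'
#' @param pairs data frame `chrom,start,end,gene_id` (evidence coordinates).
#' @param enhancers built enhancer interval data frame.
#' @param registry `GeneRegistry`.
#' @param method label recorded on the links.
#' @return link data frame `enh,gene_id,method`.
#' @export
import_pair_links <- function(pairs, enhancers, registry,
                              method = "pair_table") {
  known <- pairs$gene_id %in% registry$genes$gene_id
  if (any(!known)) {
    warning(sum(!known), " pair(s) with unknown gene id skipped")
    pairs <- pairs[known, , drop = FALSE]
  }
  ov <- .overlap_pairs(pairs, enhancers)
  if (nrow(ov) == 0L) return(.empty_links())
  .dedup_links(data.frame(enh = ov$subject,
                          gene_id = pairs$gene_id[ov$query],
                          method = method, stringsAsFactors = FALSE))
}

#' Links from paired-anchor interactions
#'
#' For each anchor pair, if one anchor overlaps a built enhancer (>= 1 bp)
#' and the other overlaps any promoter window, a link is emitted from that
#' enhancer to the promoter's gene.  Both orientations are tested and a
#' promoter anchor covering several genes' windows yields several links.
#' Inter-chromosomal pairs are allowed (each anchor is matched on its own
#' chromosome).
#'
#' @param anchors data frame from [read_bedpe()].
#' @param enhancers built enhancer interval data frame.
#' @param registry `GeneRegistry`.
#' @param promoter_window half-width in bp for the promoter side.
#' @param method label recorded on the links.
#' @return link data frame.
#' @export
map_anchor_pairs_to_links <- function(anchors, enhancers, registry,
                                      promoter_window = 5000L,
                                      method = "anchor_pairs") {
  prom <- promoter_windows(registry, promoter_window)
  a1 <- genomic_intervals(anchors$chrom1, anchors$start1, anchors$end1)
  a2 <- genomic_intervals(anchors$chrom2, anchors$start2, anchors$end2)
  one_way <- function(enh_anchor, prom_anchor) {
    e_ov <- .overlap_pairs(enh_anchor, enhancers)
    p_ov <- .overlap_pairs(prom_anchor, prom)
    m <- merge(e_ov, p_ov, by = "query")
    if (nrow(m) == 0L) return(.empty_links())
    data.frame(enh = m$subject.x, gene_id = prom$gene_id[m$subject.y],
               method = method, stringsAsFactors = FALSE)
  }
  .dedup_links(rbind(one_way(a1, a2), one_way(a2, a1)))
}

#' Links from chromatin-loop spans
#'
#' For each loop span, let G be the genes whose TSS lies inside the span.
#' If `1 <= |G| <= max_genes`, every enhancer overlapping the span by at
#' least 1 bp links to every gene in G; otherwise the loop contributes
#' nothing.  `max_genes` of 1, 2, 3 are the L1/L2/L3 variants.
#'
#' @param loops interval data frame of loop spans (outer boundaries).
#' @param enhancers built enhancer interval data frame.
#' @param registry `GeneRegistry`.
#' @param max_genes maximum number of genes per loop (1, 2 or 3).
#' @param method label recorded on the links.
#' @return link data frame.
#' @export
links_from_loops <- function(loops, enhancers, registry, max_genes = 1L,
                             method = paste0("loop_L", max_genes)) {
  stopifnot(max_genes %in% 1:3)
  g <- registry$genes
  tss_hits <- .point_in_pairs(g$chrom, g$tss, loops)
  # tss_hits: query = gene index, subject = loop index
  per_loop <- split(tss_hits$query, tss_hits$subject)
  links <- .empty_links()
  for (li in names(per_loop)) {
    genes_in <- per_loop[[li]]
    if (length(genes_in) < 1L || length(genes_in) > max_genes) next
    loop <- loops[as.integer(li), , drop = FALSE]
    e_ov <- .overlap_pairs(loop, enhancers)
    if (nrow(e_ov) == 0L) next
    links <- rbind(links, expand.grid(
      enh = e_ov$subject, gene_id = g$gene_id[genes_in],
      method = method, stringsAsFactors = FALSE))
  }
  .dedup_links(links)
}

#' Configuration of one EnTDef
#'
#' @param sources names of the enhancer sources to union.
#' @param links names of the non-loop link-evidence tracks to use.
#' @param loop_variant `NA` (no loop linking) or 1, 2, 3 for the L1/L2/L3
#'   variants (maximum genes per loop).
#' @param extend extend short enhancers to `extension_target` bp?
#' @param nearest_all add the nearest-TSS fallback for uncovered distal
#'   bases?
#' @param promoter_window promoter half-width in bp.
#' @param extension_target minimum enhancer length when extending.
#' @param ct_mode flag recording that the configuration came from the
#'   cell-type-restricted enumeration (link evidence limited to the
#'   interaction track and/or one loop variant).
#' @return object of class `EnTDefConfig`.
#' @export
entdef_config <- function(sources, links = character(), loop_variant = NA,
                          extend = FALSE, nearest_all = FALSE,
                          promoter_window = 5000L, extension_target = 1000L,
                          ct_mode = FALSE) {
  if (length(sources) == 0L) stop("config needs >= 1 enhancer source")
  if (length(links) == 0L && is.na(loop_variant)) {
    stop("config needs >= 1 link method (non-loop and/or loop)")
  }
  structure(list(sources = as.character(sources),
                 links = as.character(links),
                 loop_variant = if (is.na(loop_variant)) NA_integer_
                                else as.integer(loop_variant),
                 extend = isTRUE(extend), nearest_all = isTRUE(nearest_all),
                 promoter_window = as.integer(promoter_window),
                 extension_target = as.integer(extension_target),
                 ct_mode = isTRUE(ct_mode)),
            class = "EnTDefConfig")
}

#' Identifier string of a configuration
#' @param config `EnTDefConfig`.
#' @return single string, unique within an enumeration.
#' @export
config_id <- function(config) {
  paste0("S:", paste(sort(config$sources), collapse = "+"),
         "|L:", paste(sort(config$links), collapse = "+"),
         if (!is.na(config$loop_variant)) paste0("+L", config$loop_variant)
         else "",
         "|ext:", as.integer(config$extend),
         "|na:", as.integer(config$nearest_all))
}

#' @export
print.EnTDefConfig <- function(x, ...) {
  cat("EnTDefConfig", config_id(x), "\n")
  invisible(x)
}

#' Enumerate all definition configurations
#'
#' General mode crosses every non-empty subset of enhancer sources with
#' every non-empty link combination (non-loop subsets, optionally augmented
#' by exactly one loop variant, plus each loop variant alone) and the two
#' binary toggles.  With s sources, k non-loop methods and v loop variants
#' that is `(2^s - 1) * ((2^k - 1)(1 + v) + v) * |extend| * |nearest_all|`
#' configurations.  Cell-type-restricted (`ct_mode`) enumeration limits the
#' link combinations to the first non-loop method and/or one loop variant:
#' `1 + 2v` combinations.
#'
#' @param sources character vector of source names, or a count (names are
#'   generated).
#' @param nonloop_links character vector of non-loop link-method names, or
#'   a count.
#' @param loop_variants number of loop variants (0 for none).
#' @param extend,nearest_all logical vectors of toggle values to cross
#'   (default both `c(FALSE, TRUE)`).
#' @param ct_mode restrict link combinations as described above.
#' @param ... further arguments passed to [entdef_config()].
#' @return list of `EnTDefConfig`.
#' @export
enumerate_definitions <- function(sources, nonloop_links, loop_variants = 3L,
                                  extend = c(FALSE, TRUE),
                                  nearest_all = c(FALSE, TRUE),
                                  ct_mode = FALSE, ...) {
  if (is.numeric(sources)) sources <- paste0("src", seq_len(sources))
  if (is.numeric(nonloop_links)) {
    nonloop_links <- paste0("link", seq_len(nonloop_links))
  }
  nonempty_subsets <- function(x) {
    unlist(lapply(seq_along(x), function(k) {
      asplit(utils::combn(x, k), 2L)
    }), recursive = FALSE)
  }
  src_subsets <- nonempty_subsets(sources)
  loop_vs <- if (loop_variants >= 1L) seq_len(loop_variants) else integer()
  combos <- list()
  if (ct_mode) {
    ia <- nonloop_links[1L]  # the interaction (ChIA-type) track
    combos <- c(list(list(links = ia, loop = NA)),
                lapply(loop_vs, function(v) list(links = character(),
                                                 loop = v)),
                lapply(loop_vs, function(v) list(links = ia, loop = v)))
  } else {
    nl_subsets <- nonempty_subsets(nonloop_links)
    combos <- lapply(nl_subsets, function(s) list(links = s, loop = NA))
    for (v in loop_vs) {
      combos <- c(combos,
                  lapply(nl_subsets, function(s) list(links = s, loop = v)),
                  list(list(links = character(), loop = v)))
    }
  }
  out <- list()
  for (src in src_subsets) {
    for (cmb in combos) {
      for (ext in extend) {
        for (na_ in nearest_all) {
          out[[length(out) + 1L]] <- entdef_config(
            sources = src, links = cmb$links, loop_variant = cmb$loop,
            extend = ext, nearest_all = na_, ct_mode = ct_mode, ...)
        }
      }
    }
  }
  out
}

# records: chrom start end gene_id sources link_methods fallback
new_entdef <- function(records, config, registry) {
  need <- c("chrom", "start", "end", "gene_id", "sources", "link_methods",
            "fallback")
  records <- records[, need]
  rownames(records) <- NULL
  if (!all(records$gene_id %in% registry$genes$gene_id)) {
    stop("EnTDef record refers to gene id absent from the registry")
  }
  structure(list(records = records, config = config), class = "EnTDef")
}

#' @export
print.EnTDef <- function(x, ...) {
  cat(sprintf("EnTDef: %d records (%d fallback), %d genes\n",
              nrow(x$records), sum(x$records$fallback),
              length(unique(x$records$gene_id))))
  if (!is.null(x$config)) cat("  config:", config_id(x$config), "\n")
  invisible(x)
}

#' Add the nearest-TSS fallback to an EnTDef
#'
#' The genomic complement of (promoter windows, existing loci) is
#' partitioned by nearest TSS and appended as records with
#' `fallback = TRUE`.  Chromosomes without genes stay unassigned (warning).
#'
#' @param entdef `EnTDef`.
#' @param registry `GeneRegistry`.
#' @param window promoter half-width in bp.
#' @return `EnTDef` with fallback records appended.
#' @export
add_nearest_all <- function(entdef, registry, window = 5000L) {
  empty_chroms <- setdiff(names(registry$sizes),
                          unique(registry$genes$chrom))
  if (length(empty_chroms)) {
    warning("chromosome(s) without genes left unassigned: ",
            paste(empty_chroms, collapse = ", "))
  }
  part <- nearest_tss_partition(registry)
  occupied <- rbind(promoter_windows(registry, window)[, 1:3],
                    entdef$records[, c("chrom", "start", "end")])
  fb <- subtract_intervals(part, occupied)
  if (nrow(fb)) {
    fb <- genomic_intervals(fb$chrom, fb$start, fb$end,
                            gene_id = fb$gene_id,
                            sources = "nearest_all",
                            link_methods = "nearest_all",
                            fallback = TRUE)
  } else {
    fb <- entdef$records[0, , drop = FALSE]
  }
  rec <- rbind(entdef$records, fb)
  rec <- rec[order(rec$chrom, rec$start, rec$end, rec$gene_id), ]
  new_entdef(rec, entdef$config, registry)
}

#' Assemble an EnTDef from sources and link evidence
#'
#' Pipeline: union and merge the selected source regions (merged enhancers
#' inherit every overlapping source's label); trim promoter windows;
#' optionally extend short enhancers (and re-trim); derive links from each
#' selected evidence track; union links; drop enhancers with no link;
#' optionally add the nearest-TSS fallback.  Deterministic given inputs.
#'
#' @param config `EnTDefConfig`.
#' @param sources named list of enhancer-region interval data frames.
#' @param evidence named list of link evidence; each element is a list with
#'   `method` (`"pair_table"`, `"anchor_pairs"` or `"loops"`) and `payload`
#'   (pair table, BEDPE anchors, or loop-span intervals).  When
#'   `config$loop_variant` is set, every `loops` element in `evidence` is
#'   used with that variant.
#' @param registry `GeneRegistry`.
#' @return `EnTDef`.
#' @export
assemble_entdef <- function(config, sources, evidence, registry) {
  missing_src <- setdiff(config$sources, names(sources))
  if (length(missing_src)) {
    stop("unknown enhancer source(s): ", paste(missing_src, collapse = ", "))
  }
  missing_ev <- setdiff(config$links, names(evidence))
  if (length(missing_ev)) {
    stop("unknown link evidence: ", paste(missing_ev, collapse = ", "))
  }
  w <- config$promoter_window
  pooled <- do.call(rbind, lapply(config$sources, function(s) {
    sources[[s]][, c("chrom", "start", "end")]
  }))
  enh <- merge_intervals(pooled)
  enh <- trim_promoter_windows(enh, registry, w)
  if (config$extend) {
    enh <- extend_enhancers(enh, config$extension_target, registry, w)
    enh <- merge_intervals(enh)  # extension can make fragments touch
  }
  # provenance: which sources overlap each final enhancer
  enh$sources <- ""
  for (s in config$sources) {
    ov <- .overlap_pairs(enh, sources[[s]])
    hit <- unique(ov$query)
    enh$sources[hit] <- ifelse(enh$sources[hit] == "", s,
                               paste(enh$sources[hit], s, sep = ","))
  }
  links <- .empty_links()
  for (ev_name in config$links) {
    ev <- evidence[[ev_name]]
    lk <- switch(ev$method,
      pair_table = import_pair_links(ev$payload, enh, registry,
                                     method = ev_name),
      anchor_pairs = map_anchor_pairs_to_links(ev$payload, enh, registry,
                                               promoter_window = w,
                                               method = ev_name),
      loops = stop("loop evidence '", ev_name,
                   "' must be selected via loop_variant, not links"),
      stop("unknown evidence method: ", ev$method))
    links <- rbind(links, lk)
  }
  if (!is.na(config$loop_variant)) {
    loop_tracks <- names(evidence)[vapply(evidence, function(e)
      identical(e$method, "loops"), logical(1L))]
    if (length(loop_tracks) == 0L) {
      stop("config requests loop linking but no loop evidence supplied")
    }
    for (ev_name in loop_tracks) {
      links <- rbind(links, links_from_loops(
        evidence[[ev_name]]$payload, enh, registry,
        max_genes = config$loop_variant))
    }
  }
  links <- .dedup_links(links)
  if (nrow(links)) {
    key <- paste(links$enh, links$gene_id, sep = "\r")
    methods_by_pair <- vapply(split(links$method, key), function(m)
      paste(sort(unique(m)), collapse = ","), "")
    first <- links[!duplicated(key), , drop = FALSE]
    first_key <- paste(first$enh, first$gene_id, sep = "\r")
    rec <- genomic_intervals(
      chrom = enh$chrom[first$enh],
      start = enh$start[first$enh],
      end = enh$end[first$enh],
      gene_id = first$gene_id,
      sources = enh$sources[first$enh],
      link_methods = unname(methods_by_pair[first_key]),
      fallback = FALSE)
  } else {
    rec <- genomic_intervals(gene_id = character(), sources = character(),
                             link_methods = character(), fallback = logical())
  }
  rec <- rec[order(rec$chrom, rec$start, rec$end, rec$gene_id), ]
  out <- new_entdef(rec, config, registry)
  if (config$nearest_all) out <- add_nearest_all(out, registry, w)
  out
}

#' Summary statistics of an EnTDef
#'
#' @param entdef `EnTDef`.
#' @param registry `GeneRegistry`.
#' @param peaks optional `PeakSet`; enables the distal-peak-catch fraction
#'   (fraction of peaks whose midpoint lies farther than `window` from
#'   every TSS and inside some locus).
#' @param window promoter half-width in bp.
#' @return list of class `EnTDefStats`.
#' @export
entdef_stats <- function(entdef, registry, peaks = NULL, window = 5000L) {
  rec <- entdef$records
  core <- rec[!rec$fallback, , drop = FALSE]
  locus_key <- paste(core$chrom, core$start, core$end)
  genes_per_enh <- if (nrow(core)) as.integer(table(locus_key)) else integer()
  enh_per_gene <- if (nrow(core)) {
    as.integer(table(core$gene_id))
  } else integer()
  coverage <- total_coverage(rec[, c("chrom", "start", "end")]) /
    sum(as.numeric(registry$sizes))
  catch <- NULL
  if (!is.null(peaks)) {
    mids <- (peaks$peaks$start + peaks$peaks$end) %/% 2L
    prom <- promoter_windows(registry, window)
    in_prom <- unique(.point_in_pairs(peaks$peaks$chrom, mids, prom)$query)
    distal <- setdiff(seq_along(mids), in_prom)
    if (length(distal)) {
      hit <- unique(.point_in_pairs(peaks$peaks$chrom[distal], mids[distal],
                                    rec)$query)
      catch <- length(hit) / length(distal)
    } else {
      catch <- NA_real_
    }
  }
  structure(list(
    n_enhancers = length(genes_per_enh),
    genes_per_enhancer_mean = if (length(genes_per_enh))
      mean(genes_per_enh) else NA_real_,
    genes_per_enhancer_median = if (length(genes_per_enh))
      stats::median(genes_per_enh) else NA_real_,
    enhancers_per_gene_mean = if (length(enh_per_gene))
      mean(enh_per_gene) else NA_real_,
    enhancers_per_gene_median = if (length(enh_per_gene))
      stats::median(enh_per_gene) else NA_real_,
    genome_coverage_fraction = coverage,
    distal_peak_catch_fraction = catch
  ), class = "EnTDefStats")
}
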