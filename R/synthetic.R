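# Deterministic generators for toy genomes, ontologies, enhancer/link
# evidence and peak sets with planted signal.  The generator emulates the
# statistical structure the evaluation relies on -- TFs bind enhancers
# linked to genes of the biological processes they are annotated to --
# without modelling chromatin biology.

#' Simulation specification
#'
#' @param chrom_length chromosome length in bp (single toy chromosome).
#' @param n_genes number of genes; TSSs roughly uniform with `min_spacing`.
#' @param min_spacing minimum TSS spacing in bp.
#' @param n_terms ontology size; DAG of depth `dag_depth`.
#' @param dag_depth maximum DAG depth.
#' @param n_sources number of enhancer sources.
#' @param n_enhancers enhancers per source (drawn from a shared pool).
#' @param enhancer_len_range enhancer length range in bp.
#' @param links_per_enhancer range of target genes per pool enhancer.
#' @param n_tfs number of synthetic TFs.
#' @param terms_per_tf range of annotated terms per TF.
#' @param peaks_per_tf peaks per generated ChIP-like peak set.
#' @param peak_width_range peak width range in bp.
#' @param enhancer_signal_fraction probability that a TF peak is planted in
#'   an enhancer linked to one of the TF's annotated-term genes.
#' @param noise_add rate of spurious links added to each evidence track.
#' @param noise_drop rate of true links dropped from each evidence track.
#' @param theta negative-binomial dispersion used by the null-profile
#'   simulator.
#' @param seed base RNG seed; every generator is a pure function of
#'   (spec, seed).
#' @return list of class `SimulationSpec`.
#' @export
simulation_spec <- function(chrom_length = 10e6, n_genes = 300L,
                            min_spacing = 3000L, n_terms = 120L,
                            dag_depth = 4L, n_sources = 3L,
                            n_enhancers = 400L,
                            enhancer_len_range = c(200L, 2000L),
                            links_per_enhancer = c(1L, 2L),
                            n_tfs = 3L, terms_per_tf = c(3L, 8L),
                            peaks_per_tf = 2000L,
                            peak_width_range = c(100L, 500L),
                            enhancer_signal_fraction = 0.6,
                            noise_add = 0.05, noise_drop = 0.10,
                            theta = 5, seed = 1L) {
  spec <- list(chrom_length = as.integer(chrom_length),
               n_genes = as.integer(n_genes),
               min_spacing = as.integer(min_spacing),
               n_terms = as.integer(n_terms),
               dag_depth = as.integer(dag_depth),
               n_sources = as.integer(n_sources),
               n_enhancers = as.integer(n_enhancers),
               enhancer_len_range = as.integer(enhancer_len_range),
               links_per_enhancer = as.integer(links_per_enhancer),
               n_tfs = as.integer(n_tfs),
               terms_per_tf = as.integer(terms_per_tf),
               peaks_per_tf = as.integer(peaks_per_tf),
               peak_width_range = as.integer(peak_width_range),
               enhancer_signal_fraction = enhancer_signal_fraction,
               noise_add = noise_add, noise_drop = noise_drop,
               theta = theta, seed = as.integer(seed))
  stopifnot(all(vapply(spec[1:13], function(x) all(x > 0), logical(1L))),
            enhancer_signal_fraction >= 0, enhancer_signal_fraction <= 1,
            noise_add >= 0, noise_add <= 1, noise_drop >= 0, noise_drop <= 1)
  structure(spec, class = "SimulationSpec")
}

#' Generate a toy gene registry
#'
#' TSSs are placed on a jittered uniform grid (enforcing `min_spacing`);
#' gene bodies are 2-100 kb, run downstream of the TSS on the drawn
#' strand, and are clamped to the chromosome.
#'
#' @param spec `SimulationSpec`.
#' @return `GeneRegistry` on a single chromosome `chr1`.
#' @export
make_toy_genome <- function(spec) {
  L <- spec$chrom_length
  n <- spec$n_genes
  if (as.numeric(n) * spec$min_spacing >= L) {
    stop("cannot place ", n, " genes with min spacing ", spec$min_spacing,
         " on ", L, " bp")
  }
  .with_seed(spec$seed, {
    step <- L / (n + 1)
    tss <- round(step * seq_len(n) +
                   stats::runif(n, -0.3 * step, 0.3 * step))
    tss <- as.integer(pmin(pmax(tss, 1), L - 2))
    tss <- sort(tss)
    # enforce spacing by nudging right where needed
    for (i in seq_len(n - 1L)) {
      if (tss[i + 1L] - tss[i] < spec$min_spacing) {
        tss[i + 1L] <- tss[i] + spec$min_spacing
      }
    }
    if (tss[n] >= L - 1L) stop("min spacing pushed genes off the chromosome")
    strand <- sample(c("+", "-"), n, replace = TRUE)
    body_len <- as.integer(round(stats::runif(n, 2000, 100000)))
    body_start <- ifelse(strand == "+", tss,
                         pmax(0L, tss - body_len + 1L))
    body_end <- ifelse(strand == "+", pmin(L, tss + body_len), tss + 1L)
    genes <- data.frame(
      gene_id = sprintf("g%03d", seq_len(n)), chrom = "chr1",
      strand = strand, tss = tss,
      body_start = as.integer(body_start), body_end = as.integer(body_end),
      stringsAsFactors = FALSE)
    gene_registry(genes, chrom_sizes(L, "chr1"))
  })
}

# ontology with a layered DAG and planted TF annotations
.make_ontology <- function(spec, registry) {
  n <- spec$n_terms
  gene_ids <- registry$genes$gene_id
  # term sizes must stay small relative to the toy universe for set
  # membership to carry contrast (GO-scale sizes assume ~20k genes)
  size_cap <- max(15L, min(400L, as.integer(ceiling(length(gene_ids) / 3))))
  sizes <- pmin(size_cap,
                as.integer(round(exp(stats::runif(n, log(10), log(400))))))
  terms <- lapply(sizes, function(s) sample(gene_ids, s))
  names(terms) <- sprintf("T%03d", seq_len(n))
  levels <- sort(rep_len(seq_len(spec$dag_depth), n))
  dag <- list()
  for (i in seq_len(n)) {
    if (levels[i] == 1L) next
    pool <- which(levels == levels[i] - 1L)
    dag[[names(terms)[i]]] <- names(terms)[sample(pool,
                                                  min(length(pool),
                                                      sample(1:2, 1L)))]
  }
  gene_set_collection(terms, dag, namespace = "BP")
}

#' Generate a toy regulome with a known ground truth
#'
#' Produces enhancer sources with partial overlap, a ground-truth link map
#' (each TF's designated enhancers target genes of its annotated terms),
#' pair-table / paired-anchor / loop evidence consistent with the truth
#' plus configurable noise, a DAG ontology, and TF annotations.  With zero
#' noise, assembling all sources and all evidence reproduces the truth
#' link set exactly (loop evidence is emitted only where the loop implies
#' no extra link).
#'
#' @param spec `SimulationSpec`.
#' @param registry registry from [make_toy_genome()].
#' @return list with `sources` (named list of interval data frames),
#'   `evidence` (named list for [assemble_entdef()]), `sets`
#'   (`GeneSetCollection`), `tf_terms` (named list of annotated term ids),
#'   `annotations` (named list of `TFAnnotation`), and `truth` (`EnTDef`).
#' @export
make_toy_regulome <- function(spec, registry) {
  .with_seed(spec$seed + 1L, {
    sets <- .make_ontology(spec, registry)
    sz <- lengths(sets$terms)
    eligible <- names(sets$terms)[sz >= 15L & sz <= 2000L]
    tfs <- sprintf("TF%d", seq_len(spec$n_tfs))
    tf_terms <- stats::setNames(lapply(tfs, function(tf) {
      k <- sample(seq(spec$terms_per_tf[1L], spec$terms_per_tf[2L]), 1L)
      sample(eligible, min(k, length(eligible)))
    }), tfs)
    annotations <- stats::setNames(lapply(tfs, function(tf) {
      tf_annotation(tf, tf_terms[[tf]])
    }), tfs)

    # distal, mutually disjoint enhancer pool: draw an excess of
    # candidates, drop the ones touching promoters, then greedily keep a
    # non-overlapping subset
    L <- spec$chrom_length
    prom <- promoter_windows(registry, 5000L)
    n_pool <- spec$n_enhancers * 2L
    n_cand <- n_pool * 3L
    lens <- as.integer(round(stats::runif(
      n_cand, spec$enhancer_len_range[1L], spec$enhancer_len_range[2L])))
    starts <- as.integer(floor(stats::runif(n_cand, 0, L - lens)))
    cand <- sort_intervals(genomic_intervals("chr1", starts, starts + lens))
    cand <- cand[!seq_len(nrow(cand)) %in% .overlap_pairs(cand, prom)$query,
                 , drop = FALSE]
    keep <- logical(nrow(cand))
    last_end <- -1L
    for (i in seq_len(nrow(cand))) {
      if (cand$start[i] > last_end) { keep[i] <- TRUE  # gap, so no merge
        last_end <- cand$end[i] }
    }
    pool <- utils::head(cand[keep, , drop = FALSE], n_pool)
    rownames(pool) <- NULL
    n_pool <- nrow(pool)

    # truth links: half the enhancers belong to a TF and target genes of
    # its annotated terms; the rest target nearby genes
    g <- registry$genes
    owner <- sample(c(tfs, NA), n_pool, replace = TRUE,
                    prob = c(rep(0.5 / spec$n_tfs, spec$n_tfs), 0.5))
    truth_links <- list()
    for (i in seq_len(n_pool)) {
      k <- sample(seq(spec$links_per_enhancer[1L],
                      spec$links_per_enhancer[2L]), 1L)
      cand <- if (!is.na(owner[i])) {
        unique(unlist(sets$terms[tf_terms[[owner[i]]]]))
      } else {
        mid <- (pool$start[i] + pool$end[i]) %/% 2L
        g$gene_id[order(abs(g$tss - mid))][1:10]
      }
      truth_links[[i]] <- data.frame(
        enh = i, gene_id = sample(cand, min(k, length(cand))),
        stringsAsFactors = FALSE)
    }
    truth_links <- do.call(rbind, truth_links)

    # sources: each pool enhancer appears in >= 1 source
    sources <- stats::setNames(vector("list", spec$n_sources),
                               sprintf("src%d", seq_len(spec$n_sources)))
    membership <- matrix(stats::runif(n_pool * spec$n_sources) < 0.7,
                         nrow = n_pool)
    none <- rowSums(membership) == 0L
    membership[cbind(which(none),
                     sample(spec$n_sources, sum(none), replace = TRUE))] <-
      TRUE
    for (j in seq_len(spec$n_sources)) {
      sources[[j]] <- pool[membership[, j], , drop = FALSE]
    }

    # evidence; each truth link lands in >= 1 pair/anchor track
    in_a <- stats::runif(nrow(truth_links)) < 0.6
    in_b <- stats::runif(nrow(truth_links)) < 0.6
    in_chia <- stats::runif(nrow(truth_links)) < 0.5
    orphan <- !(in_a | in_b | in_chia)
    in_a[orphan] <- TRUE
    noisy <- function(link_rows) {
      keep <- link_rows[stats::runif(nrow(link_rows)) >= spec$noise_drop, ,
                        drop = FALSE]
      n_false <- stats::rbinom(1L, nrow(link_rows), spec$noise_add)
      if (n_false > 0L) {
        keep <- rbind(keep, data.frame(
          enh = sample(n_pool, n_false, replace = TRUE),
          gene_id = sample(g$gene_id, n_false, replace = TRUE)))
      }
      keep
    }
    pair_payload <- function(link_rows) {
      data.frame(chrom = "chr1", start = pool$start[link_rows$enh],
                 end = pool$end[link_rows$enh],
                 gene_id = link_rows$gene_id, stringsAsFactors = FALSE)
    }
    anchor_payload <- function(link_rows) {
      tssv <- g$tss[match(link_rows$gene_id, g$gene_id)]
      data.frame(chrom1 = "chr1", start1 = pool$start[link_rows$enh],
                 end1 = pool$end[link_rows$enh],
                 chrom2 = "chr1",
                 start2 = pmax(0L, tssv - 1000L),
                 end2 = pmin(L, tssv + 1000L), stringsAsFactors = FALSE)
    }
    # loops only where the span implies no link beyond the truth
    loop_rows <- truth_links[stats::runif(nrow(truth_links)) < 0.3, ,
                             drop = FALSE]
    tssv <- g$tss[match(loop_rows$gene_id, g$gene_id)]
    spans <- genomic_intervals(
      "chr1",
      pmax(0L, pmin(pool$start[loop_rows$enh], tssv - 1000L)),
      pmin(L, pmax(pool$end[loop_rows$enh], tssv + 1000L)))
    tss_in <- .point_in_pairs(g$chrom, g$tss, spans)   # gene x span
    enh_in <- .overlap_pairs(pool, spans)              # enhancer x span
    genes_by_span <- split(g$gene_id[tss_in$query], tss_in$subject)
    enh_by_span <- split(enh_in$query, enh_in$subject)
    links_by_enh <- split(truth_links$gene_id, truth_links$enh)
    ok <- vapply(seq_len(nrow(spans)), function(r) {
      gi <- genes_by_span[[as.character(r)]]
      ei <- enh_by_span[[as.character(r)]]
      length(gi) >= 1L && length(gi) <= 3L &&
        identical(unique(ei), loop_rows$enh[r]) &&
        all(gi %in% links_by_enh[[as.character(loop_rows$enh[r])]])
    }, logical(1L))
    loops <- spans[ok, , drop = FALSE]
    evidence <- list(
      pairsA = list(method = "pair_table",
                    payload = pair_payload(noisy(truth_links[in_a, ]))),
      pairsB = list(method = "pair_table",
                    payload = pair_payload(noisy(truth_links[in_b, ]))),
      chia = list(method = "anchor_pairs",
                  payload = anchor_payload(
                    truth_links[in_chia & stats::runif(nrow(truth_links)) >=
                                  spec$noise_drop, ])),
      loops = list(method = "loops", payload = loops))

    rec <- genomic_intervals(
      chrom = "chr1", start = pool$start[truth_links$enh],
      end = pool$end[truth_links$enh], gene_id = truth_links$gene_id,
      sources = "truth", link_methods = "truth", fallback = FALSE)
    rec <- rec[order(rec$chrom, rec$start, rec$end, rec$gene_id), ]
    truth <- new_entdef(rec, NULL, registry)

    list(sources = sources, evidence = evidence, sets = sets,
         tf_terms = tf_terms, annotations = annotations, truth = truth,
         pool = pool, truth_links = truth_links)
  })
}

#' Zero-noise variant of the evidence tracks
#'
#' Rebuilds the pair-table and anchor evidence of a regulome without the
#' add/drop noise, so that a full assembly reproduces the truth link set.
#'
#' @param spec `SimulationSpec`.
#' @param registry `GeneRegistry`.
#' @return regulome list as from [make_toy_regulome()] (noise-free).
#' @export
make_toy_regulome_noise_free <- function(spec, registry) {
  spec$noise_add <- 0
  spec$noise_drop <- 0
  make_toy_regulome(spec, registry)
}

#' Generate a TF ChIP-like peak set with planted signal
#'
#' With probability `enhancer_signal_fraction` a peak is placed uniformly
#' inside a truth locus linked to a gene of the TF's annotated terms;
#' otherwise uniformly in the genome.  Peak widths are drawn from
#' `peak_width_range`.
#'
#' @param spec `SimulationSpec`.
#' @param registry `GeneRegistry`.
#' @param regulome output of [make_toy_regulome()].
#' @param tf_id one of the regulome's TFs.
#' @return `PeakSet` named after the TF.
#' @export
make_tf_peaks <- function(spec, registry, regulome, tf_id) {
  if (!tf_id %in% names(regulome$tf_terms)) stop("unknown TF: ", tf_id)
  tf_genes <- unique(unlist(regulome$sets$terms[regulome$tf_terms[[tf_id]]]))
  rec <- regulome$truth$records
  loci <- rec[rec$gene_id %in% tf_genes, , drop = FALSE]
  if (nrow(loci) == 0L) stop("TF '", tf_id, "' has no linked enhancers")
  L <- spec$chrom_length
  .with_seed(spec$seed + 100L + .hash_string(tf_id), {
    n <- spec$peaks_per_tf
    w <- as.integer(round(stats::runif(n, spec$peak_width_range[1L],
                                       spec$peak_width_range[2L])))
    planted <- stats::runif(n) < spec$enhancer_signal_fraction
    mid <- integer(n)
    if (any(planted)) {
      li <- sample(nrow(loci), sum(planted), replace = TRUE)
      mid[planted] <- loci$start[li] +
        as.integer(floor(stats::runif(sum(planted)) *
                           (loci$end[li] - loci$start[li])))
    }
    if (any(!planted)) {
      mid[!planted] <- as.integer(floor(stats::runif(sum(!planted), 1, L - 1)))
    }
    half <- pmin(w %/% 2L, mid, L - mid - 1L)
    half <- pmax(half, 1L)
    peak_set(genomic_intervals("chr1", mid - half, mid + half),
             name = tf_id, sizes = registry$sizes)
  })
}

#' Shuffle the gene assignments of a definition
#'
#' Permutes `gene_id` across the non-fallback records, preserving all
#' marginals (loci, per-gene link counts) while destroying the
#' enhancer-gene correspondence.  Used as the decoy in ground-truth
#' recovery checks.
#'
#' @param entdef `EnTDef`.
#' @param registry `GeneRegistry`.
#' @param seed RNG seed.
#' @return `EnTDef` with permuted gene assignments.
#' @export
shuffle_entdef_links <- function(entdef, registry, seed = 1L) {
  rec <- entdef$records
  core <- which(!rec$fallback)
  rec$gene_id[core] <- .with_seed(seed, sample(rec$gene_id[core]))
  new_entdef(rec, entdef$config, registry)
}
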