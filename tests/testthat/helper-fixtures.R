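# Small in-code fixtures shared across test files.

mk_sizes <- function(L = 1000000L) chrom_sizes(L, "chr1")

# registry of plus-strand genes with given TSSs; bodies run downstream
mk_registry <- function(tss, L = 1000000L, body_len = 5000L) {
  n <- length(tss)
  gene_registry(data.frame(
    gene_id = sprintf("g%02d", seq_len(n)), chrom = "chr1", strand = "+",
    tss = as.integer(tss), body_start = as.integer(tss),
    body_end = as.integer(pmin(L, tss + body_len)),
    stringsAsFactors = FALSE), mk_sizes(L))
}

# chain ontology A <- B <- C <- D (A is root) plus extra flat terms
mk_chain_sets <- function(gene_pool = sprintf("g%02d", 1:40)) {
  terms <- list(A = gene_pool[1:30], B = gene_pool[1:25],
                C = gene_pool[1:20], D = gene_pool[1:16],
                X = gene_pool[5:24], Y = gene_pool[11:40],
                Z = gene_pool[1:18])
  gene_set_collection(terms,
                      dag_parents = list(B = "A", C = "B", D = "C",
                                         X = "A", Z = "B"))
}

# simulated assignment profile with length-dependent NB counts; the genes
# in `planted` get their mean multiplied by exp(effect)
mk_profile <- function(n_genes = 200L, theta = 5, effect = 0,
                       planted = character()) {
  gene_id <- sprintf("g%03d", seq_len(n_genes))
  loglen <- runif(n_genes, 3, 5)
  mu <- exp(-2 + 0.9 * log(10^loglen / 1e3))
  mu[gene_id %in% planted] <- mu[gene_id %in% planted] * exp(effect)
  y <- rnbinom(n_genes, mu = mu, size = theta)
  structure(list(
    peakset_name = "sim",
    genes = data.frame(gene_id = gene_id, peak_count = y,
                       weighted_count = as.numeric(y),
                       locus_length = 10^loglen, has_peak = y > 0,
                       stringsAsFactors = FALSE),
    n_assigned_peaks = sum(y), n_unassigned_peaks = 0L,
    peak_gene = NULL), class = "AssignmentProfile")
}

default_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- simulation_spec(seed = 42L)
      registry <- make_toy_genome(spec)
      regulome <- make_toy_regulome(spec, registry)
      cache <<- list(spec = spec, registry = registry, regulome = regulome)
    }
    cache
  }
})
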