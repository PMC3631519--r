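# Shared simulated fixtures, built once per test run (lazy caches).

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

# Five-population reference world with sex chromosomes and lineage trees.
ref_sim <- function() cached("ref_sim", {
  suppressMessages(simulate_reference_panel(
    sim_config(n_populations = 5, n_autosomal = 2000, n_x = 300, n_y = 50,
               n_mt = 50, fst = 0.1),
    n_per_pop = 30, seed = 42))
})

# Frequency-only two-population world for pedigree/kinship work.
kin_sim <- function() cached("kin_sim", {
  simulate_reference_panel(
    sim_config(n_populations = 2, n_autosomal = 20000, n_x = 0, n_y = 0,
               n_mt = 0, fst = 0.1),
    n_per_pop = 2, seed = 3, fit = FALSE)
})

# Large five-population autosome-only world for admixture work; the
# reference size per population is HapMap-scale so that estimated
# reference frequencies do not dominate the admixture error.
big_sim <- function() cached("big_sim", {
  suppressMessages(simulate_reference_panel(
    sim_config(n_populations = 5, n_autosomal = 20000, n_x = 0, n_y = 0,
               n_mt = 0, fst = 0.1),
    n_per_pop = 60, seed = 7))
})

rel_degree <- function(rel) {
  c(parent_offspring = 1, full_sib = 1, half_sib = 2, avuncular = 2,
    grandparent = 2, first_cousin = 3, grand_avuncular = 3,
    cousin_once_removed = 4)[[rel]]
}

# Hudson FST estimator (ratio of averages) between two population samples.
hudson_fst <- function(d1, d2) {
  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) -
    p2 * (1 - p2) / (2 * n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# A minimal hand-built reference panel with known frequencies (no PCA).
manual_freq_panel <- function(freqs) {
  structure(list(
    populations = colnames(freqs),
    marker_ids = rownames(freqs),
    freqs = freqs,
    centers = rep(1, nrow(freqs)),
    scales = rep(1, nrow(freqs)),
    loadings = matrix(0, nrow(freqs), 1,
                      dimnames = list(rownames(freqs), "PC1")),
    eigenvalues = 1,
    centroids = matrix(0, ncol(freqs), 1,
                       dimnames = list(colnames(freqs), "PC1")),
    scores = NULL, n_dropped = 0L
  ), class = "fsnp_reference_panel")
}

# Genotype matrix straight from a dosage matrix of autosomal markers.
auto_genotypes <- function(d, ids = NULL) {
  if (is.null(colnames(d))) colnames(d) <- paste0("auto_", seq_len(ncol(d)))
  if (!is.null(ids)) rownames(d) <- ids
  if (is.null(rownames(d))) rownames(d) <- paste0("S", seq_len(nrow(d)))
  genotype_matrix(d, marker_panel(colnames(d), rep("autosomal", ncol(d))))
}
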