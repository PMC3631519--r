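#' Pairwise identity-by-state sharing
#'
#' For every sample pair, counts the autosomal markers in IBS states 0, 1
#' and 2 over the markers where both samples have calls. The IBS state is
#' `2 - |g_a - g_b|` with the opposite-homozygote adjustment (AA vs BB is
#' state 0, not 1, which plain dosage distance would give only for the
#' het/hom contrast); equivalently, opposite homozygotes are state 0,
#' identical genotypes state 2, everything else state 1. The mean IBS
#' fraction is `(P1 + 2 P2) / (2M)`.
#'
#' @param g A [genotype_matrix()]; typically already passed through
#'   [filter_markers()] (MAF above 1 percent, marker missingness below 5 percent, autosomal).
#' @param min_overlap Minimum overlapping non-missing markers per pair
#'   (default 1000); pairs below it are dropped with a warning.
#' @return A tibble per unordered pair: `id1`, `id2`, `n_used`, `ibs0`,
#'   `ibs1`, `ibs2`, `mean_ibs`.
#' @export
pairwise_sharing <- function(g, min_overlap = 1000) {
  ai <- markers_of_class(g, "autosomal")
  d <- g$dosage[, ai, drop = FALSE]
  n <- nrow(d)
  if (n < 2) stop("need at least two samples")
  I0 <- (!is.na(d) & d == 0) * 1
  I1 <- (!is.na(d) & d == 1) * 1
  I2 <- (!is.na(d) & d == 2) * 1
  NM <- I0 + I1 + I2
  S2 <- tcrossprod(I0) + tcrossprod(I1) + tcrossprod(I2)
  S0 <- I0 %*% t(I2) + I2 %*% t(I0)
  used <- tcrossprod(NM)
  S1 <- used - S0 - S2
  pairs <- which(upper.tri(used), arr.ind = TRUE)
  out <- tibble(
    id1 = rownames(d)[pairs[, 1]],
    id2 = rownames(d)[pairs[, 2]],
    n_used = as.integer(used[pairs]),
    ibs0 = as.integer(S0[pairs]),
    ibs1 = as.integer(S1[pairs]),
    ibs2 = as.integer(S2[pairs])
  )
  low <- out$n_used < min_overlap
  if (any(low)) {
    warning(sum(low), " pair(s) below ", min_overlap,
            " overlapping markers dropped")
    out <- out[!low, ]
    if (nrow(out) == 0) stop("no pair has enough overlapping markers")
  }
  out$mean_ibs <- (out$ibs1 + 2 * out$ibs2) / (2 * out$n_used)
  out
}

# per-marker IBS-state probabilities conditional on IBD state, from known
# allele frequencies (method-of-moments ingredients)
ibs_expectations <- function(p) {
  q <- 1 - p
  list(
    e0_ibs0 = 2 * p^2 * q^2,
    e0_ibs1 = 4 * p^3 * q + 4 * p * q^3,
    e0_ibs2 = p^4 + q^4 + 4 * p^2 * q^2,
    e1_ibs1 = 2 * p * q,
    e1_ibs2 = p^2 + q^2
  )
}

# Same expectations with frequencies estimated from the cohort itself:
# plug-in powers of sample frequencies are biased, so products like p^2 q^2
# are replaced by their unbiased factorial-moment estimators from the
# allele counts (c alternate alleles out of T chromosomes).
ibs_expectations_counts <- function(c_alt, T_chr) {
  ff <- function(x, k) {
    out <- rep(1, length(x))
    for (i in seq_len(k)) out <- out * (x - i + 1)
    out
  }
  c_ref <- T_chr - c_alt
  t2 <- ff(T_chr, 2); t4 <- ff(T_chr, 4)
  pq <- c_alt * c_ref / t2
  p2q2 <- ff(c_alt, 2) * ff(c_ref, 2) / t4
  p3q <- ff(c_alt, 3) * c_ref / t4
  pq3 <- c_alt * ff(c_ref, 3) / t4
  p4 <- ff(c_alt, 4) / t4
  q4 <- ff(c_ref, 4) / t4
  list(
    e0_ibs0 = 2 * p2q2,
    e0_ibs1 = 4 * p3q + 4 * pq3,
    e0_ibs2 = p4 + q4 + 4 * p2q2,
    e1_ibs1 = 2 * pq,
    e1_ibs2 = 1 - 2 * pq
  )
}

#' Method-of-moments pi-hat from IBS sharing
#'
#' Converts observed IBS-state counts into estimated IBD-state proportions:
#' the expected IBS-state probabilities for an unrelated pair are computed
#' from cohort allele frequencies; the observed excess over those
#' expectations is attributed to IBD 1 and IBD 2 in turn, and
#' `pi_hat = P(IBD=2) + P(IBD=1)/2`, clamped to \[0, 1\]. Markers with
#' degenerate frequencies are dropped.
#'
#' @param g The same filtered [genotype_matrix()] used for
#'   [pairwise_sharing()] (the per-pair expectation sums respect each
#'   pair's missingness pattern).
#' @param sharing Optional precomputed [pairwise_sharing()] tibble.
#' @param freqs Optional alternate-allele frequencies (default: estimated
#'   from the cohort itself).
#' @param min_overlap Passed to [pairwise_sharing()] when `sharing` is
#'   `NULL`.
#' @return The sharing tibble with `k0`, `k1`, `k2` and `pi_hat` columns
#'   appended.
#' @export
estimate_pihat <- function(g, sharing = NULL, freqs = NULL,
                           min_overlap = 1000) {
  ai <- markers_of_class(g, "autosomal")
  d <- g$dosage[, ai, drop = FALSE]
  p <- freqs %||% (colMeans(d, na.rm = TRUE) / 2)
  ok <- !is.na(p) & p > 0 & p < 1
  d <- d[, ok, drop = FALSE]
  p <- p[ok]
  sharing <- sharing %||% pairwise_sharing(g, min_overlap = min_overlap)
  ex <- if (is.null(freqs)) {
    T_chr <- 2 * colSums(!is.na(d))
    ibs_expectations_counts(colSums(d, na.rm = TRUE), T_chr)
  } else {
    ibs_expectations(p)
  }
  NM <- (!is.na(d)) * 1
  esum <- function(w) (NM * rep(w, each = nrow(d))) %*% t(NM)
  Se0_0 <- esum(ex$e0_ibs0)
  Se0_1 <- esum(ex$e0_ibs1)
  Se0_2 <- esum(ex$e0_ibs2)
  Se1_1 <- esum(ex$e1_ibs1)
  Se1_2 <- esum(ex$e1_ibs2)
  used <- tcrossprod(NM)
  i <- match(sharing$id1, rownames(d))
  j <- match(sharing$id2, rownames(d))
  idx <- cbind(i, j)
  k0 <- sharing$ibs0 / Se0_0[idx]
  k1 <- (sharing$ibs1 - k0 * Se0_1[idx]) / Se1_1[idx]
  k2 <- (sharing$ibs2 - k0 * Se0_2[idx] - k1 * Se1_2[idx]) / used[idx]
  # k0..k2 are raw moment estimates (noise can push them slightly outside
  # [0, 1]); only the combined pi-hat is clamped, keeping it unbiased for
  # unrelated pairs
  sharing$k0 <- k0
  sharing$k1 <- k1
  sharing$k2 <- k2
  sharing$pi_hat <- clamp(k2 + k1 / 2, 0, 1)
  sharing
}

#' Classify degree of relatedness from pi-hat
#'
#' Bins around the expected genome-sharing of first- to fourth-degree
#' relatives (1/2, 1/4, 1/8, 1/16): a pair is called first degree at or
#' above 0.375, second at or above 0.1875, third at or above 0.09375 (the
#' midpoints between adjacent expectations — so an observed 9 percent share falls
#' in the fourth-degree zone), fourth at or above the lower unrelated
#' cutoff of 0.044, and unrelated below it. Bins are configurable.
#'
#' @param pi_hat Numeric vector in \[0, 1\].
#' @param bins Named descending lower bounds for first..fourth degree.
#' @return Factor with levels `first`, `second`, `third`, `fourth`,
#'   `unrelated`.
#' @export
classify_degree <- function(pi_hat,
                            bins = c(first = 0.375, second = 0.1875,
                                     third = 0.09375, fourth = 0.044)) {
  stopifnot(all(pi_hat >= 0 & pi_hat <= 1, na.rm = TRUE))
  lv <- c(names(bins), "unrelated")
  out <- cut(pi_hat, breaks = c(-Inf, rev(unname(bins)), Inf),
             labels = c("unrelated", rev(names(bins))), right = FALSE)
  factor(as.character(out), levels = lv)
}

#' Genome-wide relatedness for every sample pair
#'
#' End-to-end kinship: filters autosomal markers (MAF > `maf_min`, marker
#' missingness < `max_marker_missing`, no LD pruning by default), computes
#' IBS sharing, converts to pi-hat and classifies the degree of
#' relatedness. Classification is driven by pi-hat (IBD-scale sharing)
#' while the mean IBS fraction is reported alongside.
#'
#' @param g A [genotype_matrix()].
#' @param maf_min,max_marker_missing Marker filters (defaults 0.01 / 0.05).
#' @param min_overlap Minimum overlapping markers per pair (default 1000).
#' @param bins Degree bins for [classify_degree()].
#' @return A tibble of class `fsnp_kinship`: one row per pair with IBS
#'   counts, `mean_ibs`, `k0`..`k2`, `pi_hat` and `degree`.
#' @export
kinship <- function(g, maf_min = 0.01, max_marker_missing = 0.05,
                    min_overlap = 1000,
                    bins = c(first = 0.375, second = 0.1875,
                             third = 0.09375, fourth = 0.044)) {
  gf <- filter_markers(g, maf_min = maf_min,
                       max_marker_missing = max_marker_missing,
                       classes = "autosomal")
  out <- estimate_pihat(gf, min_overlap = min_overlap)
  out$degree <- classify_degree(out$pi_hat, bins = bins)
  class(out) <- c("fsnp_kinship", class(out))
  out
}

#' Square pi-hat matrix from a kinship result
#'
#' @param k An [kinship()] result.
#' @return A symmetric matrix of pi-hat values (diagonal 1).
#' @export
kinship_matrix <- function(k) {
  ids <- sort(unique(c(k$id1, k$id2)))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  m[cbind(k$id1, k$id2)] <- k$pi_hat
  m[cbind(k$id2, k$id1)] <- k$pi_hat
  m
}
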