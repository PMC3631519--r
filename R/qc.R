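#' Per-sample call-rate quality control
#'
#' Computes each sample's missing-genotype fraction over the whole panel and
#' gates it at the platform threshold: a sample fails QC when strictly more
#' than `max_missing` (default 10%) of its genotype calls are missing.
#'
#' @param g A [genotype_matrix()].
#' @param max_missing Maximum tolerated missing fraction (default 0.10).
#' @return A tibble with `sample_id`, `n_markers`, `n_missing`,
#'   `missing_fraction`, `call_rate` and logical `pass`.
#' @export
qc_call_rate <- function(g, max_missing = 0.10) {
  if (ncol(g$dosage) < 1) stop("genotype matrix has no markers")
  n_miss <- rowSums(is.na(g$dosage))
  frac <- n_miss / ncol(g$dosage)
  tibble(
    sample_id = rownames(g$dosage),
    n_markers = ncol(g$dosage),
    n_missing = as.integer(n_miss),
    missing_fraction = frac,
    call_rate = 1 - frac,
    pass = frac <= max_missing
  )
}

#' Marker filtering and subsetting
#'
#' Retains markers passing a minor-allele-frequency gate (frequency computed
#' on the analysis cohort itself), a per-marker missingness gate, an optional
#' chromosome-class restriction, and optional greedy windowed LD pruning
#' (removing one of each marker pair whose squared dosage correlation exceeds
#' `r2_max` within a sliding window).
#'
#' @param g A [genotype_matrix()].
#' @param maf_min Markers are kept when MAF is strictly greater than this
#'   (default 0.01).
#' @param max_marker_missing Markers are kept when their missing fraction is
#'   strictly below this (default 0.05).
#' @param classes Optional chromosome classes to keep (default: all).
#' @param ld_prune Logical; prune by pairwise LD (default `FALSE`).
#' @param r2_max Squared-correlation ceiling for pruning (default 0.2).
#' @param window,step Sliding-window size and step in markers (defaults 50/5).
#' @return A filtered [genotype_matrix()]; errors if nothing survives.
#' @export
filter_markers <- function(g, maf_min = 0.01, max_marker_missing = 0.05,
                           classes = NULL, ld_prune = FALSE, r2_max = 0.2,
                           window = 50, step = 5) {
  keep <- rep(TRUE, ncol(g$dosage))
  if (!is.null(classes)) keep <- keep & g$panel$chromosome_class %in% classes
  miss <- colMeans(is.na(g$dosage))
  keep <- keep & miss < max_marker_missing
  f <- allele_frequencies(g)
  maf <- pmin(f, 1 - f)
  keep <- keep & !is.na(maf) & maf > maf_min
  if (!any(keep)) {
    stop("no markers pass the filters; consider relaxing maf_min or ",
         "max_marker_missing")
  }
  out <- subset_genotypes(g, markers = which(keep))
  if (ld_prune) {
    keep2 <- ld_prune_indices(out, r2_max = r2_max, window = window, step = step)
    if (!any(keep2)) stop("LD pruning removed all markers; relax r2_max")
    out <- subset_genotypes(out, markers = which(keep2))
  }
  out
}

# Greedy windowed pruning: within each window (per chromosome, position
# order) drop the later marker of any remaining pair with r^2 > r2_max.
ld_prune_indices <- function(g, r2_max, window, step) {
  keep <- rep(TRUE, ncol(g$dosage))
  ord <- order(g$panel$chrom, g$panel$position)
  by_chrom <- split(ord, g$panel$chrom[ord])
  for (idx in by_chrom) {
    m <- length(idx)
    starts <- unique(c(seq(1, max(1, m - 1), by = step)))
    for (s in starts) {
      win <- idx[s:min(s + window - 1, m)]
      win <- win[keep[win]]
      if (length(win) < 2) next
      cc <- suppressWarnings(
        stats::cor(g$dosage[, win, drop = FALSE],
                   use = "pairwise.complete.obs"))
      cc[is.na(cc)] <- 0
      for (a in seq_along(win)[-length(win)]) {
        if (!keep[win[a]]) next
        hits <- which(cc[a, ]^2 > r2_max)
        hits <- hits[hits > a & keep[win[hits]]]
        keep[win[hits]] <- FALSE
      }
    }
  }
  keep
}

#' Confusion table of predicted versus observed categories
#'
#' @param predicted,observed Vectors of category labels (predicted rows,
#'   observed columns). `NA` predictions are dropped.
#' @param predicted_levels,observed_levels Optional level orderings.
#' @return A tibble of class `fsnp_confusion`: a `predicted` column plus one
#'   non-negative integer count column per observed category.
#' @export
confusion_table <- function(predicted, observed, predicted_levels = NULL,
                            observed_levels = NULL) {
  ok <- !is.na(predicted) & !is.na(observed)
  predicted <- factor(predicted[ok], levels = predicted_levels %||%
                        sort(unique(as.character(predicted[ok]))))
  observed <- factor(observed[ok], levels = observed_levels %||%
                       sort(unique(as.character(observed[ok]))))
  tab <- table(predicted, observed)
  as_confusion_table(unclass(tab))
}

#' Build a confusion table from a count matrix
#'
#' @param m Matrix of non-negative counts with predicted categories as row
#'   names and observed categories as column names.
#' @return An `fsnp_confusion` tibble.
#' @export
as_confusion_table <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(m >= 0))
  out <- dplyr::bind_cols(tibble(predicted = rownames(m)),
                          as_tibble(m, .name_repair = "minimal"))
  class(out) <- c("fsnp_confusion", class(out))
  out
}

#' Per-row and overall accuracy of a confusion table
#'
#' For each predicted-category row, accuracy is the fraction of its counts
#' falling in the observed columns declared correct for that row, after any
#' column exclusions. Accuracies are reported both as exact fractions and as
#' integer percentages (rounded half up, the convention used in published
#' accuracy tables). A row left empty by exclusions is flagged undefined
#' rather than scored zero.
#'
#' @param ct An `fsnp_confusion` table.
#' @param correct_map Named list: predicted row -> character vector of
#'   observed columns counted as correct. Must cover every row.
#' @param exclude_columns Optional observed columns dropped before scoring
#'   (e.g. excluding self-reported intermediate eye colour).
#' @return A tibble with one row per predicted category plus an `"overall"`
#'   row: `predicted`, `n_total`, `n_correct`, `accuracy`, `accuracy_pct`,
#'   `defined`.
#' @export
confusion_stats <- function(ct, correct_map, exclude_columns = NULL) {
  rows <- ct$predicted
  missing_rows <- setdiff(rows, names(correct_map))
  if (length(missing_rows)) {
    stop("correct_map does not cover rows: ",
         paste(missing_rows, collapse = ", "))
  }
  counts <- as.matrix(ct[, -1, drop = FALSE])
  rownames(counts) <- rows
  keep_cols <- setdiff(colnames(counts), exclude_columns)
  counts <- counts[, keep_cols, drop = FALSE]
  per_row <- purrr::map_dfr(rows, function(r) {
    tot <- sum(counts[r, ])
    corr <- sum(counts[r, intersect(correct_map[[r]], keep_cols)])
    tibble(
      predicted = r, n_total = tot, n_correct = corr,
      accuracy = if (tot > 0) corr / tot else NA_real_,
      defined = tot > 0
    )
  })
  overall <- tibble(
    predicted = "overall",
    n_total = sum(per_row$n_total),
    n_correct = sum(per_row$n_correct),
    accuracy = sum(per_row$n_correct) / sum(per_row$n_total),
    defined = sum(per_row$n_total) > 0
  )
  out <- dplyr::bind_rows(per_row, overall)
  out$accuracy_pct <- round_half_up(100 * out$accuracy)
  out[, c("predicted", "n_total", "n_correct", "accuracy", "accuracy_pct",
          "defined")]
}
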