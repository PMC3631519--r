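#' Marker panel annotation table
#'
#' Builds the marker panel that every genotype matrix carries: one row per
#' marker with its chromosome class (`autosomal`, `X_specific`,
#' `XY_pseudoautosomal`, `Y`, `mt`), position, alleles and optional panel
#' tags (`ancestry_subset`, `eye_snp`, `hair_snp`, `kinship_set`, ...).
#'
#' @param marker_id Character vector of unique marker identifiers.
#' @param chromosome_class Character vector of chromosome classes.
#' @param position Integer 1-based positions (defaults to 1..n within class).
#' @param ref,alt Allele characters (defaults "A"/"G").
#' @param chrom Optional contig names; derived from `chromosome_class` when
#'   absent (all autosomal markers are placed on contig "1" unless told
#'   otherwise).
#' @param tags Optional list of character vectors of panel tags per marker.
#' @return A tibble of class `fsnp_marker_panel`.
#' @export
marker_panel <- function(marker_id, chromosome_class, position = NULL,
                         ref = "A", alt = "G", chrom = NULL, tags = NULL) {
  marker_id <- as.character(marker_id)
  if (anyDuplicated(marker_id)) {
    stop("duplicate marker IDs: ",
         paste(unique(marker_id[duplicated(marker_id)]), collapse = ", "))
  }
  chromosome_class <- as.character(chromosome_class)
  bad <- setdiff(unique(chromosome_class), chromosome_classes)
  if (length(bad)) stop("unknown chromosome class: ", paste(bad, collapse = ", "))
  n <- length(marker_id)
  if (is.null(chrom)) chrom <- unname(default_chrom_for_class(chromosome_class))
  if (is.null(position)) {
    position <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  }
  if (is.null(tags)) tags <- rep(list(character()), n)
  panel <- tibble(
    marker_id = marker_id,
    chrom = as.character(chrom),
    position = as.integer(position),
    chromosome_class = chromosome_class,
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    tags = tags
  )
  class(panel) <- c("fsnp_marker_panel", class(panel))
  panel
}

#' Genotype matrix container
#'
#' The central data object: a samples x markers dosage matrix in
#' \{0, 1, 2, NA\} (haploid classes Y and mt use \{0, 1, NA\}) together with
#' its marker panel and optional per-sample metadata (reported sex, ancestry,
#' eye and hair colour, population labels).
#'
#' @param dosage Integer matrix, samples in rows, markers in columns. Row
#'   names are sample IDs, column names marker IDs. `NA` marks a missing call.
#' @param panel A [marker_panel()] whose `marker_id` matches `colnames(dosage)`.
#' @param samples Optional tibble of per-sample metadata with a `sample_id`
#'   column.
#' @return An object of class `fsnp_genotypes`.
#' @export
genotype_matrix <- function(dosage, panel, samples = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage))) colnames(dosage) <- panel$marker_id
  if (!identical(colnames(dosage), panel$marker_id)) {
    stop("dosage column names do not match panel marker IDs")
  }
  if (is.null(samples)) samples <- tibble(sample_id = rownames(dosage))
  samples <- as_tibble(samples)
  if (!identical(samples$sample_id, rownames(dosage))) {
    stop("sample metadata does not match dosage row names")
  }
  g <- structure(
    list(dosage = dosage, panel = panel, samples = samples),
    class = "fsnp_genotypes"
  )
  validate_genotypes(g)
  g
}

validate_genotypes <- function(g) {
  d <- g$dosage
  rng <- range(d, na.rm = TRUE)
  if (!all(is.na(d)) && (rng[1] < 0 || rng[2] > 2)) {
    bad <- colnames(d)[colSums(d < 0 | d > 2, na.rm = TRUE) > 0][1]
    stop("dosage out of range {0,1,2} at marker ", bad)
  }
  hap <- g$panel$chromosome_class %in% haploid_classes
  if (any(hap)) {
    two <- colSums(d[, hap, drop = FALSE] == 2, na.rm = TRUE) > 0
    if (any(two)) {
      stop("haploid marker carries dosage 2: ",
           paste(g$panel$marker_id[hap][two][1]))
    }
  }
  invisible(g)
}

#' @export
print.fsnp_genotypes <- function(x, ...) {
  cls <- table(x$panel$chromosome_class)
  cat("<fsnp_genotypes> ", nrow(x$dosage), " samples x ", ncol(x$dosage),
      " markers\n", sep = "")
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  cat("  missing:", sprintf("%.2f%%", 100 * mean(is.na(x$dosage))), "\n")
  invisible(x)
}

#' @export
dim.fsnp_genotypes <- function(x) dim(x$dosage)

n_samples <- function(g) nrow(g$dosage)
n_markers <- function(g) ncol(g$dosage)

#' Subset a genotype matrix
#'
#' @param g A [genotype_matrix()].
#' @param samples,markers Character IDs, logical or integer indices; `NULL`
#'   keeps everything.
#' @return A [genotype_matrix()].
#' @export
subset_genotypes <- function(g, samples = NULL, markers = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(g$dosage)) else samples
  mi <- if (is.null(markers)) seq_len(ncol(g$dosage)) else markers
  if (is.character(si)) si <- match(si, rownames(g$dosage))
  if (is.character(mi)) mi <- match(mi, colnames(g$dosage))
  panel <- g$panel[mi, , drop = FALSE]
  genotype_matrix(g$dosage[si, mi, drop = FALSE], panel,
                  g$samples[si, , drop = FALSE])
}

# marker indices for one or more chromosome classes
markers_of_class <- function(g, classes) {
  which(g$panel$chromosome_class %in% classes)
}

# indices of markers carrying a given panel tag
markers_with_tag <- function(g, tag) {
  which(purrr::map_lgl(g$panel$tags, ~ tag %in% .x))
}

#' Alternate-allele frequencies of a genotype matrix
#'
#' Frequencies are computed from non-missing calls; haploid classes divide by
#' one chromosome copy, diploid classes by two.
#'
#' @param g A [genotype_matrix()].
#' @return Named numeric vector of alternate-allele frequencies.
#' @export
allele_frequencies <- function(g) {
  ploidy <- ifelse(g$panel$chromosome_class %in% haploid_classes, 1, 2)
  colMeans(g$dosage, na.rm = TRUE) / ploidy
}

#' Combine genotype matrices over the same marker panel
#'
#' @param ... [genotype_matrix()] objects sharing an identical panel.
#' @return A [genotype_matrix()] with samples stacked in order.
#' @export
bind_genotypes <- function(...) {
  gs <- list(...)
  panel <- gs[[1]]$panel
  for (g in gs[-1]) {
    if (!identical(g$panel$marker_id, panel$marker_id)) {
      stop("genotype matrices have different marker panels")
    }
  }
  genotype_matrix(
    do.call(rbind, lapply(gs, `[[`, "dosage")),
    panel,
    dplyr::bind_rows(lapply(gs, `[[`, "samples"))
  )
}
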