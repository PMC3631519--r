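#' Read a genotype matrix from disk
#'
#' Two dialects are supported. `"tsv"` is the package's internal plain-text
#' dialect: markers as rows with columns `marker_id`, `chrom`, `position`,
#' `chromosome_class`, `ref`, `alt`, `tags` (semicolon-separated, possibly
#' empty) followed by one dosage column per sample; a sidecar
#' `<stem>.samples.tsv`, when present, is read as per-sample metadata.
#' `"vcf"` reads a VCF via \pkg{vcfR}; the chromosome class is derived from
#' the contig name (1-22 autosomal, X, Y, MT, XY) and GT fields are converted
#' to alternate-allele dosages.
#'
#' Y and mitochondrial records coded diploid in a VCF are normalised to
#' haploid dosage (any call carrying the alternate allele becomes dosage 1)
#' with a warning, a tolerance for the common dialect slip rather than an
#' error.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  switch(dialect, tsv = read_genotypes_tsv(path), vcf = read_genotypes_vcf(path))
}

#' Write a genotype matrix to disk
#'
#' Inverse of [read_genotypes()]: `read_genotypes(write_genotypes(g, path))`
#' reproduces `g` exactly, including the missingness mask.
#'
#' @param g A [genotype_matrix()].
#' @param path Output file path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  switch(dialect, tsv = write_genotypes_tsv(g, path), vcf = write_genotypes_vcf(g, path))
  invisible(path)
}

samples_sidecar <- function(path) paste0(sub("\\.tsv$", "", path), ".samples.tsv")

read_genotypes_tsv <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    marker_id = "c", chrom = "c", position = "i", chromosome_class = "c",
    ref = "c", alt = "c", tags = "c", .default = "i"
  ), na = "NA", progress = FALSE)
  meta_cols <- c("marker_id", "chrom", "position", "chromosome_class",
                 "ref", "alt", "tags")
  if (!all(meta_cols %in% names(tb))) {
    stop("not a genotype TSV: missing columns ",
         paste(setdiff(meta_cols, names(tb)), collapse = ", "))
  }
  tags <- purrr::map(tb$tags, ~ if (is.na(.x) || .x == "") character() else
    strsplit(.x, ";", fixed = TRUE)[[1]])
  panel <- marker_panel(tb$marker_id, tb$chromosome_class, tb$position,
                        tb$ref, tb$alt, chrom = tb$chrom, tags = tags)
  dosage <- t(as.matrix(tb[, setdiff(names(tb), meta_cols)]))
  colnames(dosage) <- panel$marker_id
  bad <- dosage[!is.na(dosage) & !(dosage %in% 0:2)]
  if (length(bad)) {
    j <- which(colSums(!is.na(dosage) & !(dosage %in% 0:2)) > 0)[1]
    stop("dosage out of range at marker ", panel$marker_id[j])
  }
  sidecar <- samples_sidecar(path)
  samples <- if (file.exists(sidecar)) {
    readr::read_tsv(sidecar, col_types = readr::cols(.default = "c"),
                    na = "NA", progress = FALSE)
  } else NULL
  genotype_matrix(dosage, panel, samples)
}

write_genotypes_tsv <- function(g, path) {
  tb <- g$panel
  tb$tags <- purrr::map_chr(tb$tags, paste, collapse = ";")
  dos <- as.data.frame(t(g$dosage))
  names(dos) <- rownames(g$dosage)
  readr::write_tsv(dplyr::bind_cols(as_tibble(tb), dos), path, na = "NA",
                   progress = FALSE)
  if (ncol(g$samples) > 1) {
    readr::write_tsv(g$samples, samples_sidecar(path), na = "NA",
                     progress = FALSE)
  }
  invisible(path)
}

write_genotypes_vcf <- function(g, path) {
  p <- g$panel
  hap <- p$chromosome_class %in% haploid_classes
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=forensnp",
    paste0("##contig=<ID=", unique(p$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(g$dosage)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(p)), function(j) {
    d <- g$dosage[, j]
    gt <- if (hap[j]) c("0", "1")[d + 1L] else c("0/0", "0/1", "1/1")[d + 1L]
    gt[is.na(gt)] <- if (hap[j]) "." else "./."
    paste(c(p$chrom[j], p$position[j], p$marker_id[j], p$ref[j], p$alt[j],
            ".", ".", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (anyDuplicated(fix$ID)) {
    stop("duplicate marker IDs: ",
         paste(unique(fix$ID[duplicated(fix$ID)]), collapse = ", "))
  }
  cls <- class_from_chrom(fix$CHROM)
  if (anyNA(cls)) {
    stop("cannot derive chromosome class from contig ",
         paste(unique(fix$CHROM[is.na(cls)]), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(fix$ID, "S1"))
  alleles <- gsub("[|/]", "", gt)
  dosage <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt))
  ok <- !is.na(gt) & !grepl("\\.", gt)
  dosage[ok] <- stringr::str_count(alleles[ok], "1")
  hap <- cls %in% haploid_classes
  if (any(hap)) {
    coded_diploid <- grepl("[|/]", gt[hap, , drop = FALSE])
    over <- !is.na(dosage[hap, , drop = FALSE]) & coded_diploid &
      dosage[hap, , drop = FALSE] > 0
    if (any(over, na.rm = TRUE)) {
      warning("haploid (Y/mt) records coded diploid; ",
              sum(over, na.rm = TRUE),
              " calls normalised to haploid dosage")
    }
    dosage[hap, ] <- pmin(dosage[hap, , drop = FALSE], 1L)
  }
  panel <- marker_panel(fix$ID, cls, as.integer(fix$POS), fix$REF, fix$ALT,
                        chrom = fix$CHROM)
  genotype_matrix(t(dosage), panel)
}

#' Write a true-state sidecar table
#'
#' Serialises the simulator's ground truth (admixture vector, sex,
#' haplogroups, pedigree degrees) as TSV for test harnesses.
#'
#' @param truth A tibble of true states.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(as_tibble(truth), path, na = "NA", progress = FALSE)
  invisible(path)
}
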