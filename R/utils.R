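#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# Round half away from zero, matching the convention used when reporting
# integer percentages (89.5 -> 90).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# log(sum(exp(x))) along rows of a matrix, numerically safe
row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

chromosome_classes <- c("autosomal", "X_specific", "XY_pseudoautosomal", "Y", "mt")
haploid_classes <- c("Y", "mt")

# contig name <-> chromosome class
class_from_chrom <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  dplyr::case_when(
    chrom %in% as.character(1:22) ~ "autosomal",
    chrom == "X" ~ "X_specific",
    chrom == "XY" ~ "XY_pseudoautosomal",
    chrom == "Y" ~ "Y",
    chrom %in% c("MT", "M") ~ "mt",
    TRUE ~ NA_character_
  )
}

default_chrom_for_class <- function(class) {
  c(autosomal = "1", X_specific = "X", XY_pseudoautosomal = "XY",
    Y = "Y", mt = "MT")[class]
}
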