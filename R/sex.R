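#' X-chromosome heterozygosity per sample
#'
#' The fraction of non-missing X-specific calls (markers without a Y
#' homologue; the XY-pseudoautosomal class is excluded) that are
#' heterozygous. Male-derived DNA yields values near zero because the single
#' X is rendered as homozygous diploid calls; a sample with fewer than
#' `min_markers` informative calls is flagged inconclusive-by-data
#' (`x_het = NA`).
#'
#' @param g A [genotype_matrix()].
#' @param min_markers Minimum non-missing X-specific calls (default 100).
#' @return A tibble with `sample_id`, `x_het`, `n_x_used`.
#' @export
x_heterozygosity <- function(g, min_markers = 100) {
  xi <- markers_of_class(g, "X_specific")
  d <- g$dosage[, xi, drop = FALSE]
  n_used <- rowSums(!is.na(d))
  het <- rowSums(d == 1, na.rm = TRUE) / pmax(n_used, 1)
  het[n_used < min_markers] <- NA_real_
  het <- unname(het)
  n_used <- unname(n_used)
  tibble(sample_id = rownames(g$dosage), x_het = het,
         n_x_used = as.integer(n_used))
}

# Y-marker evidence per sample: haplogroup_called / y_present / absent /
# unavailable (no Y markers on the panel)
y_marker_evidence <- function(g, y_presence_min = 0.5, y_calls = NULL) {
  yi <- markers_of_class(g, "Y")
  if (length(yi) == 0) {
    return(tibble(sample_id = rownames(g$dosage),
                  y_call_rate = NA_real_, y_evidence = "unavailable"))
  }
  rate <- rowMeans(!is.na(g$dosage[, yi, drop = FALSE]))
  ev <- ifelse(rate >= y_presence_min, "y_present", "absent")
  if (!is.null(y_calls)) {
    called <- y_calls$sample_id[!y_calls$no_call]
    ev[rownames(g$dosage) %in% called] <- "haplogroup_called"
  }
  tibble(sample_id = rownames(g$dosage), y_call_rate = rate, y_evidence = ev)
}

#' Two-pronged sex inference
#'
#' Combines X-specific heterozygosity with Y-marker evidence. The X side
#' supports a male call below `male_max` (default 0.2) and a female call
#' above `female_min` (default 0.8); intermediate values (closed interval)
#' are inconclusive on their own. The Y side supports male when Y calls are
#' present (call rate at least `y_presence_min`, or a called Y haplogroup)
#' and female when Y data exist but no calls do. When both prongs agree the
#' call is made outright; when only one prong is informative the call is
#' made with a single-evidence caveat; conflicting prongs (a mixture
#' signature) and doubly-uninformative profiles are inconclusive. A conflict
#' flag is set when the call contradicts the reported sex.
#'
#' @param g A [genotype_matrix()].
#' @param reported_sex Optional character vector (or `NULL` to use the
#'   `reported_sex` column of the sample metadata, if present).
#' @param male_max,female_min X-heterozygosity thresholds.
#' @param min_x_markers Minimum informative X calls (see
#'   [x_heterozygosity()]).
#' @param y_presence_min Minimum Y call rate counted as Y presence.
#' @param y_calls Optional [call_haplogroups()] result for the Y tree; a
#'   called haplogroup upgrades the Y evidence.
#' @return A tibble per sample: `x_het`, `n_x_used`, `y_call_rate`,
#'   `y_evidence`, `call` (`male`/`female`/`inconclusive`),
#'   `single_evidence`, `conflict_with_report`.
#' @export
infer_sex <- function(g, reported_sex = NULL, male_max = 0.2,
                      female_min = 0.8, min_x_markers = 100,
                      y_presence_min = 0.5, y_calls = NULL) {
  xh <- x_heterozygosity(g, min_markers = min_x_markers)
  ye <- y_marker_evidence(g, y_presence_min, y_calls)
  tb <- dplyr::left_join(xh, ye, by = "sample_id")
  x_state <- dplyr::case_when(
    is.na(tb$x_het) ~ "unavailable",
    tb$x_het < male_max ~ "male",
    tb$x_het > female_min ~ "female",
    TRUE ~ "intermediate"
  )
  y_state <- dplyr::case_when(
    tb$y_evidence %in% c("haplogroup_called", "y_present") ~ "male",
    tb$y_evidence == "absent" ~ "female",
    TRUE ~ "unavailable"
  )
  # Two-pronged combination. An intermediate X with male Y evidence is a
  # mixture signature and stays inconclusive; an intermediate X with no Y
  # calls at all is compatible only with female (or degraded single-source)
  # DNA, so the Y absence carries the call with a caveat. Directly
  # conflicting prongs are inconclusive.
  tb$call <- dplyr::case_when(
    x_state == "male" & y_state == "male" ~ "male",
    x_state == "female" & y_state == "female" ~ "female",
    x_state == "male" & y_state == "unavailable" ~ "male",
    x_state == "unavailable" & y_state == "male" ~ "male",
    x_state == "female" & y_state == "unavailable" ~ "female",
    x_state %in% c("unavailable", "intermediate") & y_state == "female" ~
      "female",
    TRUE ~ "inconclusive"
  )
  tb$single_evidence <- tb$call != "inconclusive" &
    (x_state != tb$call | y_state != tb$call)
  if (is.null(reported_sex) && "reported_sex" %in% names(g$samples)) {
    reported_sex <- g$samples$reported_sex
  }
  tb$conflict_with_report <- if (is.null(reported_sex)) {
    NA
  } else {
    !is.na(reported_sex) & tb$call != "inconclusive" &
      tb$call != reported_sex
  }
  tb
}
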