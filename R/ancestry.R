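#' Fit the ancestry reference panel
#'
#' Builds the reference space for biparental continental ancestry from a
#' labelled reference cohort: markers are centred by twice their overall
#' alternate-allele frequency and scaled by `sqrt(2p(1-p))`, the
#' standardised matrix is decomposed into its top principal components, and
#' per-population centroids are taken as the mean reference coordinates.
#' Per-population allele frequencies are estimated within each labelled
#' population and clamped to \[0.001, 0.999\] so the admixture likelihood
#' stays finite. Zero-variance markers are dropped with a message.
#'
#' @param g Reference [genotype_matrix()] with population labels.
#' @param population Character vector of labels (default: `population`
#'   column of the sample metadata).
#' @param n_pc Number of principal components (default 3, matching a 3-D
#'   reference plot).
#' @param markers Optional marker IDs; default is the `ancestry_subset` tag
#'   when present, else all autosomal markers.
#' @return An object of class `fsnp_reference_panel`: population labels,
#'   frequencies, centring/scaling vectors, orthonormal loadings,
#'   eigenvalues, reference scores and centroids.
#' @export
fit_reference <- function(g, population = NULL, n_pc = 3, markers = NULL) {
  population <- population %||% g$samples$population
  if (is.null(population)) stop("population labels required")
  population <- as.character(population)
  if (length(unique(population)) < 2) stop("need >= 2 populations")
  if (any(table(population) < 2)) stop("need >= 2 samples per population")
  if (is.null(markers)) {
    idx <- markers_with_tag(g, "ancestry_subset")
    if (!length(idx)) idx <- markers_of_class(g, "autosomal")
  } else {
    idx <- match(markers, g$panel$marker_id)
  }
  d <- g$dosage[, idx, drop = FALSE]
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  n_dropped <- sum(!keep)
  if (n_dropped) message(n_dropped, " zero-variance markers dropped")
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  centers <- 2 * p
  scales <- sqrt(2 * p * (1 - p))
  X <- sweep(sweep(d, 2, centers), 2, scales, "/")
  X[is.na(X)] <- 0
  e <- eigen(tcrossprod(X), symmetric = TRUE)
  n_pc <- min(n_pc, sum(e$values > 1e-8))
  U <- e$vectors[, seq_len(n_pc), drop = FALSE]
  dvals <- sqrt(pmax(e$values[seq_len(n_pc)], 0))
  loadings <- sweep(crossprod(X, U), 2, dvals, "/")
  scores <- X %*% loadings
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  colnames(loadings) <- paste0("PC", seq_len(n_pc))
  rownames(loadings) <- colnames(d)
  pops <- sort(unique(population))
  freqs <- vapply(pops, function(k) {
    clamp(colMeans(d[population == k, , drop = FALSE], na.rm = TRUE) / 2,
          0.001, 0.999)
  }, numeric(ncol(d)))
  centroids <- do.call(rbind, lapply(pops, function(k) {
    colMeans(scores[population == k, , drop = FALSE])
  }))
  rownames(centroids) <- pops
  structure(list(
    populations = pops,
    marker_ids = colnames(d),
    freqs = freqs,
    centers = centers,
    scales = scales,
    loadings = loadings,
    eigenvalues = e$values[seq_len(n_pc)],
    total_variance = sum(pmax(e$values, 0)),
    centroids = centroids,
    scores = dplyr::bind_cols(
      tibble(sample_id = rownames(d), population = population),
      as_tibble(scores)),
    n_dropped = n_dropped
  ), class = "fsnp_reference_panel")
}

#' @export
print.fsnp_reference_panel <- function(x, ...) {
  cat("<fsnp_reference_panel> ", length(x$populations), " populations (",
      paste(x$populations, collapse = ", "), "), ", length(x$marker_ids),
      " markers, ", ncol(x$loadings), " PCs\n", sep = "")
  invisible(x)
}

#' Project samples into the reference PC space and assign by distance
#'
#' Each sample is standardised with the reference centring and scaling,
#' projected onto the reference loadings (missing markers are dropped and
#' the projection renormalised by the retained loadings), and assigned to
#' the population with the nearest (Euclidean) centroid. Ties are broken by
#' label order with a warning. Samples with calls on fewer than
#' `min_overlap` of the panel markers are not projected (their row is `NA`
#' with a warning).
#'
#' @param g A [genotype_matrix()].
#' @param panel An [fit_reference()] panel.
#' @param min_overlap Minimum fraction of panel markers with calls
#'   (default 0.5).
#' @return A tibble per sample: PC coordinates, `nearest_group`, `distance`.
#' @export
project_and_assign <- function(g, panel, min_overlap = 0.5) {
  idx <- match(panel$marker_ids, g$panel$marker_id)
  present <- !is.na(idx)
  purrr::map_dfr(seq_len(nrow(g$dosage)), function(i) {
    x <- rep(NA_real_, length(panel$marker_ids))
    x[present] <- g$dosage[i, idx[present]]
    obs <- !is.na(x)
    out <- tibble(sample_id = rownames(g$dosage)[i])
    if (mean(obs) < min_overlap) {
      warning("sample ", rownames(g$dosage)[i], " has calls on ",
              sprintf("%.0f%%", 100 * mean(obs)),
              " of panel markers; not projected")
      for (c in colnames(panel$loadings)) out[[c]] <- NA_real_
      out$nearest_group <- NA_character_
      out$distance <- NA_real_
      return(out)
    }
    xs <- (x[obs] - panel$centers[obs]) / panel$scales[obs]
    L <- panel$loadings[obs, , drop = FALSE]
    coords <- colSums(xs * L) / colSums(L^2)
    d2 <- rowSums(sweep(panel$centroids, 2, coords)^2)
    best <- which(d2 == min(d2))
    if (length(best) > 1) {
      warning("centroid tie for sample ", rownames(g$dosage)[i],
              "; broken by label order")
      best <- best[1]
    }
    for (c in seq_along(coords)) out[[colnames(panel$loadings)[c]]] <- coords[c]
    out$nearest_group <- panel$populations[best]
    out$distance <- sqrt(d2[best])
    out
  })
}

# One-sample supervised admixture EM. g: dosage vector over panel markers
# (NA allowed); freqs: markers x K. Maximises the binomial mixture
# log-likelihood over the simplex; the EM update is the expected fraction of
# alleles attributed to each ancestry.
admixture_em <- function(g_vec, freqs, tol = 1e-6, max_iter = 500) {
  obs <- !is.na(g_vec)
  g_vec <- g_vec[obs]
  F <- freqs[obs, , drop = FALSE]
  K <- ncol(F)
  m <- length(g_vec)
  if (m == 0) {
    return(list(q = rep(NA_real_, K), loglik = NA_real_, trace = numeric(),
                n_iter = 0L, converged = FALSE))
  }
  q <- rep(1 / K, K)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pi <- as.vector(F %*% q)
    pi <- clamp(pi, 1e-9, 1 - 1e-9)
    ll <- sum(g_vec * log(pi) + (2 - g_vec) * log(1 - pi))
    trace <- c(trace, ll)
    if (it > 1 && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    w_alt <- g_vec / pi
    w_ref <- (2 - g_vec) / (1 - pi)
    num <- q * (crossprod(F, w_alt) + crossprod(1 - F, w_ref))
    q <- as.vector(num / (2 * m))
    q <- q / sum(q)
  }
  list(q = stats::setNames(q, colnames(F)), loglik = ll, trace = trace,
       n_iter = it, converged = converged)
}

#' Quantitative ancestry: supervised admixture proportions by EM
#'
#' Estimates, for each sample, the admixture vector q maximising the
#' binomial mixture log-likelihood
#' `sum_j g_j log(pi_j) + (2 - g_j) log(1 - pi_j)` with
#' `pi_j = sum_k q_k f_kj` over the K reference populations with fixed
#' frequencies `f_kj` (supervised model-based clustering). The EM update
#' attributes each observed allele to an ancestry in expectation; the
#' likelihood is non-decreasing across iterations and the problem is
#' concave in q. Iteration stops when the log-likelihood improves by less
#' than `tol` (default 1e-6) or after `max_iter` (default 500) iterations;
#' non-convergence returns the best q with a warning flag. Missing markers
#' are skipped.
#'
#' @param g A [genotype_matrix()].
#' @param panel An [fit_reference()] panel.
#' @param threshold Single-group assignment threshold passed to
#'   [assign_quantitative()] (default 0.70).
#' @param tol,max_iter EM stopping controls.
#' @return A tibble of class `fsnp_admixture`: `sample_id`, one `q_<pop>`
#'   column per population, `loglik`, `n_iter`, `converged`, `assignment`.
#' @export
estimate_admixture <- function(g, panel, threshold = 0.70, tol = 1e-6,
                               max_iter = 500) {
  idx <- match(panel$marker_ids, g$panel$marker_id)
  present <- !is.na(idx)
  out <- purrr::map_dfr(seq_len(nrow(g$dosage)), function(i) {
    x <- rep(NA_real_, length(panel$marker_ids))
    x[present] <- g$dosage[i, idx[present]]
    fit <- admixture_em(x, panel$freqs, tol = tol, max_iter = max_iter)
    if (!fit$converged && !all(is.na(fit$q))) {
      warning("EM did not converge for sample ", rownames(g$dosage)[i])
    }
    row <- tibble(sample_id = rownames(g$dosage)[i])
    for (k in seq_along(panel$populations)) {
      row[[paste0("q_", panel$populations[k])]] <- fit$q[k]
    }
    row$loglik <- fit$loglik
    row$n_iter <- fit$n_iter
    row$converged <- fit$converged
    row
  })
  out$assignment <- assign_quantitative(
    as.matrix(out[, paste0("q_", panel$populations)]), threshold = threshold,
    labels = panel$populations)
  class(out) <- c("fsnp_admixture", class(out))
  out
}

#' Categorical assignment from admixture proportions
#'
#' A sample is assigned to a single group when its largest admixture
#' proportion strictly exceeds the threshold (default 0.70); otherwise it is
#' assigned to `"multiple groups"`.
#'
#' @param q Simplex vector, or matrix with one row per sample.
#' @param threshold Strict lower bound for a single-group call.
#' @param labels Population labels (default: names/colnames of `q`).
#' @return Character vector of assignments.
#' @export
assign_quantitative <- function(q, threshold = 0.70, labels = NULL) {
  if (is.null(dim(q))) q <- matrix(q, 1, dimnames = list(NULL, names(q)))
  labels <- labels %||% colnames(q)
  apply(q, 1, function(qi) {
    if (anyNA(qi)) return(NA_character_)
    k <- which.max(qi)
    if (qi[k] > threshold) labels[k] else "multiple groups"
  })
}

#' Cohort summaries of admixture components
#'
#' Five-number summaries (box-and-whisker statistics: median, quartiles,
#' whiskers at the most extreme values within 1.5 IQR) of each ancestry
#' component per cohort.
#'
#' @param admixture An [estimate_admixture()] result (or any tibble with
#'   `q_<pop>` columns).
#' @param cohort Character vector of cohort labels, one per row.
#' @return A tibble of class `fsnp_group_summary`: `cohort`, `component`,
#'   `n`, `ymin`, `lower`, `middle`, `upper`, `ymax`.
#' @export
group_summary <- function(admixture, cohort) {
  qcols <- grep("^q_", names(admixture), value = TRUE)
  if (!length(qcols)) stop("no q_ columns found")
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble(cohort = cohort), admixture[, qcols]),
    -"cohort", names_to = "component", values_to = "q")
  long$component <- sub("^q_", "", long$component)
  out <- long |>
    dplyr::group_by(.data$cohort, .data$component) |>
    dplyr::summarise(
      n = dplyr::n(),
      ymin = box_stat(.data$q, 1), lower = box_stat(.data$q, 2),
      middle = box_stat(.data$q, 3), upper = box_stat(.data$q, 4),
      ymax = box_stat(.data$q, 5), .groups = "drop")
  class(out) <- c("fsnp_group_summary", class(out))
  out
}

box_stat <- function(x, i) grDevices::boxplot.stats(x, do.out = FALSE)$stats[i]

#' Serialise a reference panel as a TSV bundle
#'
#' Writes `frequencies.tsv` (marker, centre, scale, per-population
#' frequencies), `loadings.tsv`, `centroids.tsv` and `manifest.json` into a
#' directory.
#'
#' @param panel An [fit_reference()] panel.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  freqs <- dplyr::bind_cols(
    tibble(marker_id = panel$marker_ids, center = panel$centers,
           scale = panel$scales),
    as_tibble(panel$freqs, .name_repair = ~ paste0("f_", colnames(panel$freqs))))
  readr::write_tsv(freqs, file.path(dir, "frequencies.tsv"), progress = FALSE)
  readr::write_tsv(
    dplyr::bind_cols(tibble(marker_id = panel$marker_ids),
                     as_tibble(panel$loadings)),
    file.path(dir, "loadings.tsv"), progress = FALSE)
  readr::write_tsv(
    dplyr::bind_cols(tibble(population = panel$populations),
                     as_tibble(panel$centroids, .name_repair = "minimal")),
    file.path(dir, "centroids.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(populations = panel$populations, n_pc = ncol(panel$loadings),
         eigenvalues = panel$eigenvalues, n_markers = length(panel$marker_ids),
         format_version = "1.0"),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a reference panel written by [write_reference_panel()]
#'
#' @param dir Directory containing the TSV bundle.
#' @return An `fsnp_reference_panel` (without reference scores).
#' @export
read_reference_panel <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  freqs <- readr::read_tsv(file.path(dir, "frequencies.tsv"),
                           col_types = readr::cols(marker_id = "c",
                                                   .default = "d"),
                           progress = FALSE)
  load <- readr::read_tsv(file.path(dir, "loadings.tsv"),
                          col_types = readr::cols(marker_id = "c",
                                                  .default = "d"),
                          progress = FALSE)
  cent <- readr::read_tsv(file.path(dir, "centroids.tsv"),
                          col_types = readr::cols(population = "c",
                                                  .default = "d"),
                          progress = FALSE)
  fmat <- as.matrix(freqs[, paste0("f_", man$populations)])
  colnames(fmat) <- man$populations
  rownames(fmat) <- freqs$marker_id
  lmat <- as.matrix(load[, -1])
  rownames(lmat) <- load$marker_id
  cmat <- as.matrix(cent[, -1])
  rownames(cmat) <- cent$population
  structure(list(
    populations = man$populations, marker_ids = freqs$marker_id,
    freqs = fmat, centers = freqs$center, scales = freqs$scale,
    loadings = lmat, eigenvalues = man$eigenvalues, centroids = cmat,
    scores = NULL, n_dropped = 0L
  ), class = "fsnp_reference_panel")
}
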