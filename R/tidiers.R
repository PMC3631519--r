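#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the centroids of a fitted reference panel
#'
#' @param x An [fit_reference()] panel.
#' @param ... Unused.
#' @return A tibble with one row per population and its PC centroid.
#' @export
tidy.fsnp_reference_panel <- function(x, ...) {
  dplyr::bind_cols(tibble(population = x$populations),
                   as_tibble(x$centroids, .name_repair = "minimal"))
}

#' One-row summary of a fitted reference panel
#'
#' @inheritParams tidy.fsnp_reference_panel
#' @return A one-row tibble: populations, markers, PCs, variance explained
#'   by the retained components (relative to total reference variance).
#' @export
glance.fsnp_reference_panel <- function(x, ...) {
  tibble(
    n_populations = length(x$populations),
    n_markers = length(x$marker_ids),
    n_pc = ncol(x$loadings),
    n_dropped = x$n_dropped,
    prop_variance = if (!is.null(x$total_variance)) {
      sum(x$eigenvalues) / x$total_variance
    } else NA_real_
  )
}

#' Tidy a phenotype model's coefficients
#'
#' @param x An [phenotype_model()].
#' @param ... Unused.
#' @return A long tibble: `category`, `term`, `effect_allele`, `estimate`.
#' @export
tidy.fsnp_phenotype_model <- function(x, ...) {
  purrr::map_dfr(rownames(x$beta), function(cat) {
    tibble(category = cat, term = colnames(x$beta),
           effect_allele = c(NA_character_, unname(x$effect_alleles)),
           estimate = x$beta[cat, ])
  })
}

#' One-row summary of a phenotype model
#'
#' @inheritParams tidy.fsnp_phenotype_model
#' @return A one-row tibble: trait, categories, predictors, log-likelihood.
#' @export
glance.fsnp_phenotype_model <- function(x, ...) {
  tibble(trait = x$trait, n_categories = length(x$categories),
         n_predictors = length(x$predictors), logLik = x$loglik)
}

#' Reference PC space plot
#'
#' Scatter of the reference samples in the first two principal components,
#' coloured by population, with centroids marked.
#'
#' @param object An [fit_reference()] panel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fsnp_reference_panel <- function(object, ...) {
  if (is.null(object$scores)) stop("panel has no stored reference scores")
  cent <- tidy(object)
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2,
                               colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(data = cent, shape = 4, size = 4, stroke = 2,
                        show.legend = FALSE) +
    ggplot2::labs(title = "Reference PCA space",
                  colour = "population") +
    ggplot2::theme_minimal()
}

#' Stacked admixture bar plot
#'
#' @param object An [estimate_admixture()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fsnp_admixture <- function(object, ...) {
  qcols <- grep("^q_", names(object), value = TRUE)
  long <- tidyr::pivot_longer(object[, c("sample_id", qcols)], -"sample_id",
                              names_to = "ancestry", values_to = "q")
  long$ancestry <- sub("^q_", "", long$ancestry)
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$q,
                                     fill = .data$ancestry)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "admixture proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Ancestry-component box plot per cohort
#'
#' Draws the five-number summaries computed by [group_summary()] as
#' box-and-whisker plots.
#'
#' @param object An [group_summary()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fsnp_group_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$component, ymin = .data$ymin, lower = .data$lower,
    middle = .data$middle, upper = .data$upper, ymax = .data$ymax,
    fill = .data$component)) +
    ggplot2::geom_boxplot(stat = "identity") +
    ggplot2::facet_wrap(~cohort) +
    ggplot2::labs(x = "ancestry component", y = "proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Relatedness scatter plot
#'
#' Mean IBS against estimated pi-hat, coloured by the called degree of
#' relatedness.
#'
#' @param object An [kinship()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fsnp_kinship <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$mean_ibs, .data$pi_hat,
                                       colour = .data$degree)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "mean IBS fraction", y = expression(hat(pi)),
                  colour = "degree") +
    ggplot2::theme_minimal()
}
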