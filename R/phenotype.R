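#' Phenotype prediction model (multinomial logistic)
#'
#' Container for a categorical eye- or hair-colour prediction model:
#' a multinomial logistic regression over effect-allele dosages of a fixed
#' predictor SNP list (six SNPs and three categories for eye colour;
#' eighteen SNPs and four categories for the chip-adjusted hair model).
#' The first category is the softmax reference (its coefficients are zero).
#'
#' @param trait `"eye"` or `"hair"`.
#' @param categories Ordered category labels; the first is the reference.
#' @param predictors Predictor SNP IDs.
#' @param effect_alleles Effect allele per predictor (dosage counts this
#'   allele).
#' @param beta Coefficient matrix, `(length(categories) - 1)` rows (named by
#'   non-reference category) by `length(predictors) + 1` columns
#'   (`(Intercept)` first).
#' @param loglik Optional fitted log-likelihood.
#' @return An object of class `fsnp_phenotype_model`.
#' @export
phenotype_model <- function(trait = c("eye", "hair"), categories, predictors,
                            effect_alleles, beta, loglik = NA_real_) {
  trait <- match.arg(trait)
  expected_p <- if (trait == "eye") 6L else 18L
  if (length(predictors) != expected_p) {
    stop(trait, " model requires ", expected_p, " predictor SNPs, got ",
         length(predictors))
  }
  beta <- as.matrix(beta)
  if (!all(is.finite(beta))) stop("beta must be finite")
  stopifnot(nrow(beta) == length(categories) - 1,
            ncol(beta) == length(predictors) + 1)
  rownames(beta) <- categories[-1]
  colnames(beta) <- c("(Intercept)", predictors)
  structure(list(trait = trait, categories = categories,
                 reference = categories[1], predictors = predictors,
                 effect_alleles = stats::setNames(effect_alleles, predictors),
                 beta = beta, loglik = loglik),
            class = "fsnp_phenotype_model")
}

#' @export
print.fsnp_phenotype_model <- function(x, ...) {
  cat("<fsnp_phenotype_model> ", x$trait, ": ",
      paste(x$categories, collapse = "/"), ", ", length(x$predictors),
      " predictor SNPs\n", sep = "")
  invisible(x)
}

# softmax category probabilities for an n x p dosage matrix
model_probs <- function(model, X) {
  X1 <- cbind(1, as.matrix(X))
  eta <- X1 %*% t(model$beta)
  eta <- cbind(0, eta)
  P <- exp(eta - row_logsumexp(eta))
  colnames(P) <- model$categories
  P
}

#' Fit a multinomial logistic phenotype model
#'
#' Maximises the L2-penalised multinomial log-likelihood (ridge penalty
#' `l2` on non-intercept coefficients; the problem is convex, so the fit is
#' deterministic given the data) by quasi-Newton optimisation with analytic
#' gradients.
#'
#' @param x Matrix or data frame of effect-allele dosages (samples x
#'   predictors); must be complete.
#' @param labels Category labels (factor or character); every category must
#'   have at least 3 training samples.
#' @param trait `"eye"` or `"hair"`.
#' @param effect_alleles Optional effect alleles recorded in the model file
#'   (default `"alt"`).
#' @param l2 Ridge penalty (default 1e-4).
#' @return An [phenotype_model()] with fitted coefficients.
#' @export
fit_multinomial <- function(x, labels, trait = c("eye", "hair"),
                            effect_alleles = NULL, l2 = 1e-4) {
  trait <- match.arg(trait)
  X <- as.matrix(x)
  if (anyNA(X)) stop("training genotypes must be complete")
  labels <- factor(labels)
  counts <- table(labels)
  if (any(counts < 3)) {
    stop("every category needs >= 3 samples; short: ",
         paste(names(counts)[counts < 3], collapse = ", "))
  }
  categories <- levels(labels)
  C <- length(categories)
  p <- ncol(X)
  X1 <- cbind(1, X)
  Y <- outer(as.integer(labels), seq_len(C), "==") * 1
  pen_mask <- rep(c(0, rep(1, p)), C - 1)  # no penalty on intercepts
  nll <- function(par) {
    B <- matrix(par, C - 1, p + 1)
    eta <- cbind(0, X1 %*% t(B))
    -sum(eta[Y == 1] - row_logsumexp(eta)) + 0.5 * l2 * sum((par * pen_mask)^2)
  }
  grad <- function(par) {
    B <- matrix(par, C - 1, p + 1)
    eta <- cbind(0, X1 %*% t(B))
    P <- exp(eta - row_logsumexp(eta))
    G <- t(P[, -1, drop = FALSE] - Y[, -1, drop = FALSE]) %*% X1
    as.vector(G) + l2 * par * pen_mask
  }
  fit <- stats::optim(rep(0, (C - 1) * (p + 1)), nll, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  beta <- matrix(fit$par, C - 1, p + 1)
  phenotype_model(
    trait = trait, categories = categories,
    predictors = colnames(X) %||% paste0("snp", seq_len(p)),
    effect_alleles = effect_alleles %||% rep("alt", p),
    beta = beta,
    loglik = -(fit$value - 0.5 * l2 * sum((fit$par * pen_mask)^2))
  )
}

# effect-allele dosages of the model's predictors for each sample;
# NA where the genotype is missing or the marker absent from the panel
effect_dosages <- function(g, model) {
  idx <- match(model$predictors, g$panel$marker_id)
  X <- matrix(NA_real_, nrow(g$dosage), length(model$predictors),
              dimnames = list(rownames(g$dosage), model$predictors))
  for (j in seq_along(idx)) {
    if (is.na(idx[j])) next
    d <- g$dosage[, idx[j]]
    ea <- model$effect_alleles[j]
    ref <- g$panel$ref[idx[j]]
    X[, j] <- if (!is.na(ea) && ea != "alt" && ea == ref) 2 - d else d
  }
  X
}

predict_categorical <- function(g, model) {
  X <- effect_dosages(g, model)
  complete <- rowSums(is.na(X)) == 0
  P <- matrix(NA_real_, nrow(X), length(model$categories),
              dimnames = list(rownames(X), model$categories))
  if (any(complete)) {
    P[complete, ] <- model_probs(model, X[complete, , drop = FALSE])
  }
  list(P = P, complete = complete)
}

#' Predict categorical eye colour
#'
#' Softmax probabilities from the eye model; the call is the highest-
#' probability category when that probability strictly exceeds
#' `p_threshold` (default 0.7), else `"undetermined"`. A prediction
#' requires the full complement of the six predictor SNPs: any missing
#' predictor yields no call and `complete = FALSE`.
#'
#' @param g A [genotype_matrix()].
#' @param model An eye [phenotype_model()].
#' @param p_threshold Probability threshold for a call (default 0.7).
#' @return A tibble per sample: `p_<category>` columns, `call`, `complete`.
#' @export
predict_eye <- function(g, model, p_threshold = 0.7) {
  pr <- predict_categorical(g, model)
  call <- unname(apply(pr$P, 1, function(p) {
    if (anyNA(p)) return(NA_character_)
    k <- which.max(p)
    if (p[k] > p_threshold) model$categories[k] else "undetermined"
  }))
  out <- tibble(sample_id = rownames(g$dosage))
  for (k in seq_along(model$categories)) {
    out[[paste0("p_", model$categories[k])]] <- pr$P[, k]
  }
  out$call <- call
  out$complete <- pr$complete
  out
}

#' Hair prediction guide
#'
#' The guide converting hair-category probabilities into a call is a
#' configurable rule table: by default the highest-probability category is
#' called, and an exact tie is broken toward the lighter shade (with a
#' warning). Lightness ranks order the categories from darkest to lightest;
#' red, whose signal is distinct from the dark-to-light axis, is placed
#' lightest so that a tie never hides a red signal behind a darker call.
#'
#' @param categories Category labels, darkest first.
#' @param lightness Numeric lightness rank per category (higher = lighter).
#' @return A tibble rule table with class `fsnp_hair_guide`.
#' @export
hair_guide <- function(categories = c("black_dark_brown", "brown_light_brown",
                                      "blonde_dark_blonde", "red"),
                       lightness = seq_along(categories)) {
  out <- tibble(category = categories, lightness = lightness)
  class(out) <- c("fsnp_hair_guide", class(out))
  out
}

#' Predict categorical hair colour
#'
#' Softmax probabilities from the 18-SNP hair model with the prediction
#' guide applied (default: argmax with ties broken toward the lighter
#' shade). Requires the full complement of the 18 predictor SNPs.
#'
#' @param g A [genotype_matrix()].
#' @param model A hair [phenotype_model()].
#' @param guide A [hair_guide()] rule table.
#' @return A tibble per sample: `p_<category>` columns, `call`, `complete`.
#' @export
predict_hair <- function(g, model, guide = hair_guide(model$categories)) {
  pr <- predict_categorical(g, model)
  light <- stats::setNames(guide$lightness, guide$category)
  call <- unname(apply(pr$P, 1, function(p) {
    if (anyNA(p)) return(NA_character_)
    top <- which(abs(p - max(p)) < 1e-12)
    if (length(top) > 1) {
      warning("probability tie; broken toward the lighter shade")
      top <- top[which.max(light[model$categories[top]])]
    }
    model$categories[top]
  }))
  out <- tibble(sample_id = rownames(g$dosage))
  for (k in seq_along(model$categories)) {
    out[[paste0("p_", model$categories[k])]] <- pr$P[, k]
  }
  out$call <- call
  out$complete <- pr$complete
  out
}

#' Evaluate phenotype predictions against reported labels
#'
#' Collapses raw reported labels into the observed categories of a
#' confusion table (e.g. reported "blue-gray" into the blue column),
#' tabulates predicted versus reported, and scores it with
#' [confusion_stats()]. Supports excluded columns (e.g. leaving out
#' self-reported intermediate eye colour). Samples without a call are
#' dropped.
#'
#' @param predictions Tibble with `sample_id` and `call` (from
#'   [predict_eye()]/[predict_hair()]).
#' @param reported Character vector of raw reported labels, alongside
#'   `predictions` rows.
#' @param collapse_map Named character vector: raw reported label ->
#'   observed category. Every reported label must be mapped.
#' @param correct_map Named list: predicted category -> observed categories
#'   counted correct (default: the identical label).
#' @param exclude_columns Observed categories excluded from scoring.
#' @return List with `confusion` (an `fsnp_confusion` table) and `stats`
#'   (the [confusion_stats()] tibble).
#' @export
evaluate_phenotypes <- function(predictions, reported, collapse_map,
                                correct_map = NULL, exclude_columns = NULL) {
  unmapped <- setdiff(unique(stats::na.omit(reported)), names(collapse_map))
  if (length(unmapped)) {
    stop("unmapped reported labels: ", paste(unmapped, collapse = ", "))
  }
  observed <- unname(collapse_map[reported])
  keep <- !is.na(predictions$call) & predictions$call != "undetermined" &
    !is.na(observed)
  ct <- confusion_table(predictions$call[keep], observed[keep])
  if (is.null(correct_map)) {
    correct_map <- stats::setNames(as.list(ct$predicted), ct$predicted)
  }
  list(confusion = ct,
       stats = confusion_stats(ct, correct_map, exclude_columns))
}

#' Read / write a phenotype model file
#'
#' The model file is a TSV of `(trait, category, term, effect_allele,
#' beta)` rows; `term` is `(Intercept)` or a predictor SNP ID, and rows for
#' the reference category are implicit (zero). The shipped default model
#' files were fitted on a planted-parameter synthetic cohort — they
#' reproduce the models' structure, not any published coefficient values —
#' and real coefficient sets can be loaded from the same format.
#'
#' @param path TSV path.
#' @return A [phenotype_model()].
#' @export
read_phenotype_model <- function(path) {
  tb <- readr::read_tsv(path, col_types = "ccccd", na = "NA",
                        progress = FALSE)
  trait <- tb$trait[1]
  categories <- unique(tb$category)
  # reference category marked by a single row with term "(reference)"
  ref <- tb$category[tb$term == "(reference)"][1]
  non_ref <- setdiff(categories, ref)
  preds <- unique(tb$term[!tb$term %in% c("(Intercept)", "(reference)")])
  beta <- matrix(0, length(non_ref), length(preds) + 1,
                 dimnames = list(non_ref, c("(Intercept)", preds)))
  rows <- tb[tb$term != "(reference)", ]
  beta[cbind(rows$category, rows$term)] <- rows$beta
  ea <- stats::setNames(rep("alt", length(preds)), preds)
  ea_rows <- rows[!is.na(rows$effect_allele) & rows$term != "(Intercept)", ]
  ea[ea_rows$term] <- ea_rows$effect_allele
  phenotype_model(trait = trait, categories = c(ref, non_ref),
                  predictors = preds, effect_alleles = unname(ea),
                  beta = beta)
}

#' @rdname read_phenotype_model
#' @param model A [phenotype_model()].
#' @export
write_phenotype_model <- function(model, path) {
  rows <- tibble(
    trait = model$trait, category = model$reference, term = "(reference)",
    effect_allele = NA_character_, beta = 0)
  for (cat in rownames(model$beta)) {
    rows <- dplyr::bind_rows(rows, tibble(
      trait = model$trait, category = cat, term = colnames(model$beta),
      effect_allele = c(NA_character_, unname(model$effect_alleles)),
      beta = model$beta[cat, ]))
  }
  readr::write_tsv(rows, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Default synthetic phenotype models
#'
#' Loads the phenotype model shipped with the package. These coefficients
#' were fitted once on a large planted-parameter synthetic cohort (see the
#' methods vignette); they carry the structure of the published
#' eye-/hair-colour models (six-SNP three-category eye; chip-adjusted
#' eighteen-SNP four-category hair) but none of the published coefficient
#' values, which are loadable from the same file format.
#'
#' @param trait `"eye"` or `"hair"`.
#' @return A [phenotype_model()].
#' @export
default_phenotype_model <- function(trait = c("eye", "hair")) {
  trait <- match.arg(trait)
  read_phenotype_model(system.file(
    "extdata", paste0(trait, "_model_synthetic.tsv"), package = "forensnp",
    mustWork = TRUE))
}

#' Simulate a phenotype training cohort from a planted model
#'
#' Draws predictor-SNP dosages binomially from given allele frequencies and
#' labels from the planted model's softmax probabilities.
#'
#' @param model A [phenotype_model()] supplying the planted coefficients.
#' @param n Cohort size.
#' @param freqs Effect-allele frequencies per predictor (recycled;
#'   default 0.4).
#' @param seed Optional integer seed.
#' @return List with `x` (dosage matrix) and `labels` (character).
#' @export
simulate_phenotype_cohort <- function(model, n, freqs = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(model$predictors)
  freqs <- rep_len(freqs, p)
  X <- vapply(freqs, function(f) stats::rbinom(n, 2, f), numeric(n))
  colnames(X) <- model$predictors
  P <- model_probs(model, X)
  labels <- apply(P, 1, function(pr) sample(model$categories, 1, prob = pr))
  list(x = X, labels = labels)
}
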