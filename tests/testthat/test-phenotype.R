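planted_eye_model <- function() {
  beta <- rbind(intermediate = c(-2.0, 1.0, 0.4, 0.3, 0.4, 0.3, 0.3),
                brown        = c(-2.6, 2.2, 0.7, 0.4, 0.8, 0.5, 0.4))
  phenotype_model("eye", c("blue", "intermediate", "brown"),
                  paste0("rs", 1:6), rep("alt", 6), beta)
}

intercept_model <- function(trait, categories, probs, n_pred) {
  # intercept-only model yielding the requested category probabilities
  beta <- matrix(0, length(categories) - 1, n_pred + 1)
  beta[, 1] <- log(probs[-1] / probs[1])
  phenotype_model(trait, categories, paste0("rs", seq_len(n_pred)),
                  rep("alt", n_pred), beta)
}

geno_for <- function(model, dosages) {
  d <- matrix(as.integer(dosages), 1,
              dimnames = list("S1", model$predictors))
  genotype_matrix(d, marker_panel(model$predictors,
                                  rep("autosomal", length(model$predictors))))
}

test_that("model structure invariants are enforced", {
  expect_error(phenotype_model("eye", c("a", "b"), paste0("rs", 1:5),
                               rep("alt", 5), matrix(0, 1, 6)),
               "6 predictor")
  expect_error(phenotype_model("hair", c("a", "b"), paste0("rs", 1:18),
                               rep("alt", 18), matrix(Inf, 1, 19)),
               "finite")
})

test_that("labels independent of genotypes yield a near-null model", {
  set.seed(61)
  n <- 4000
  X <- matrix(rbinom(n * 6, 2, 0.4), n, 6,
              dimnames = list(NULL, paste0("rs", 1:6)))
  labels <- sample(c("blue", "intermediate", "brown"), n, replace = TRUE,
                   prob = c(0.5, 0.2, 0.3))
  fit <- fit_multinomial(X, labels, trait = "eye")
  expect_lt(max(abs(fit$beta[, -1])), 0.15)
  probs <- colMeans(forensnp:::model_probs(fit, X))
  base <- table(factor(labels, levels = fit$categories)) / n
  expect_lt(max(abs(probs - as.numeric(base))), 0.02)
})

test_that("the fit is deterministic and matches an off-the-shelf oracle", {
  skip_if_not_installed("nnet")
  m0 <- planted_eye_model()
  coh <- simulate_phenotype_cohort(m0, 2000, freqs = 0.35, seed = 62)
  labels <- factor(coh$labels, levels = m0$categories)
  fit1 <- fit_multinomial(coh$x, labels, trait = "eye")
  fit2 <- fit_multinomial(coh$x, labels, trait = "eye")
  expect_identical(fit1$beta, fit2$beta)
  df <- data.frame(y = labels, coh$x)
  nn <- nnet::multinom(y ~ ., data = df, trace = FALSE, decay = 1e-4,
                       maxit = 1000, reltol = 1e-12)
  p_oracle <- predict(nn, type = "probs")
  p_fit <- forensnp:::model_probs(fit1, coh$x)
  expect_lt(mean(abs(p_oracle - p_fit)), 1e-3)
})

test_that("training categories must all be present and populated", {
  X <- matrix(rbinom(30, 2, 0.4), 10, 3)
  expect_error(fit_multinomial(X, c(rep("a", 8), "b", "c")), ">= 3 samples")
})

test_that("softmax probabilities normalise exactly", {
  m0 <- planted_eye_model()
  coh <- simulate_phenotype_cohort(m0, 200, seed = 63)
  P <- forensnp:::model_probs(m0, coh$x)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
})

test_that("the eye call obeys the p > 0.7 rule", {
  m <- intercept_model("eye", c("blue", "intermediate", "brown"),
                       c(0.85, 0.10, 0.05), 6)
  out <- predict_eye(geno_for(m, rep(0, 6)), m)
  expect_equal(out$call, "blue")
  expect_equal(out$p_blue, 0.85, tolerance = 1e-9)
  m2 <- intercept_model("eye", c("blue", "intermediate", "brown"),
                        c(0.55, 0.25, 0.20), 6)
  expect_equal(predict_eye(geno_for(m2, rep(0, 6)), m2)$call, "undetermined")
})

test_that("a missing predictor SNP blocks the phenotype call", {
  m <- planted_eye_model()
  g <- geno_for(m, c(NA, 1, 1, 0, 2, 1))
  out <- predict_eye(g, m)
  expect_false(out$complete)
  expect_true(is.na(out$call))
  mh <- intercept_model("hair", c("black_dark_brown", "brown_light_brown",
                                  "blonde_dark_blonde", "red"),
                        c(0.25, 0.25, 0.25, 0.25), 18)
  gh <- geno_for(mh, c(NA, rep(1, 17)))
  expect_true(is.na(predict_hair(gh, mh)$call))
})

test_that("the hair guide picks the argmax and breaks ties to lighter shades", {
  mh <- intercept_model("hair", c("black_dark_brown", "brown_light_brown",
                                  "blonde_dark_blonde", "red"),
                        c(0.1, 0.1, 0.1, 0.7), 18)
  expect_equal(predict_hair(geno_for(mh, rep(0, 18)), mh)$call, "red")
  tie <- intercept_model("hair", c("black_dark_brown", "brown_light_brown",
                                   "blonde_dark_blonde", "red"),
                         c(0.4, 0.4, 0.1, 0.1), 18)
  expect_warning(out <- predict_hair(geno_for(tie, rep(0, 18)), tie),
                 "lighter")
  expect_equal(out$call, "brown_light_brown")
})

test_that("phenotype evaluation collapses reported labels per footnote maps", {
  preds <- tibble::tibble(sample_id = paste0("S", 1:6),
                          call = c("blue", "blue", "brown", "brown",
                                   "blue", "brown"))
  reported <- c("blue-gray", "gray", "hazel", "brown", "blue", "green")
  collapse <- c("blue-gray" = "blue", "gray" = "blue", "blue" = "blue",
                "hazel" = "brown", "brown" = "brown",
                "green" = "intermediate")
  ev <- evaluate_phenotypes(preds, reported, collapse)
  expect_equal(sum(ev$confusion[, -1]), 6)
  expect_equal(ev$stats$accuracy_pct[ev$stats$predicted == "overall"], 83)
  expect_error(evaluate_phenotypes(preds, c(reported[-6], "odd"), collapse),
               "odd")
  # predictions identical to labels score 100% everywhere
  same <- tibble::tibble(sample_id = paste0("S", 1:4),
                         call = c("blue", "brown", "blue", "brown"))
  ev2 <- evaluate_phenotypes(same, c("blue", "brown", "blue", "brown"),
                             c(blue = "blue", brown = "brown"))
  expect_true(all(ev2$stats$accuracy_pct == 100))
})

test_that("an end-to-end planted-model pipeline beats the base rate by 20 points", {
  beta <- rbind(
    intermediate = c(-2.5, 2.0, -1.5, 1.2, -1.0, 1.5, -1.2),
    brown        = c(-3.5, 4.0, 1.5, -1.2, 1.8, -1.4, 1.4))
  m0 <- phenotype_model("eye", c("blue", "intermediate", "brown"),
                        paste0("rs", 1:6), rep("alt", 6), beta)
  coh <- simulate_phenotype_cohort(m0, 5000, freqs = 0.35, seed = 64)
  train <- seq_len(2500)
  fit <- fit_multinomial(coh$x[train, ], coh$labels[train], trait = "eye")
  test_x <- coh$x[-train, ]
  P <- forensnp:::model_probs(fit, test_x)
  call <- fit$categories[max.col(P)]
  acc <- mean(call == coh$labels[-train])
  base <- max(table(coh$labels[-train])) / length(coh$labels[-train])
  expect_gte(acc, base + 0.20)
})

test_that("withholding concentrated red-signal predictors degrades red recall", {
  # plant a 22-variant hair model whose red signal sits in 4 variants that
  # the chip cannot carry; the 18-variant refit must miss more red
  set.seed(65)
  n <- 6000
  p_all <- 22
  X <- matrix(rbinom(n * p_all, 2, rep(c(rep(0.1, 4), rep(0.3, 18)),
                                       each = n)), n, p_all)
  beta_full <- matrix(0, 3, p_all + 1)
  beta_full[, 1] <- c(0.3, -0.6, -2.5)
  beta_full[3, 2:5] <- c(2.2, 2.5, 2.0, 2.3)   # red lives in the 4 withheld
  beta_full[1, 6:23] <- runif(18, -0.2, 0.3)
  beta_full[2, c(6, 7, 8)] <- c(0.8, 0.6, 0.5)
  eta <- cbind(1, X) %*% t(beta_full)
  eta <- cbind(0, eta)
  P <- exp(eta - apply(eta, 1, max))
  P <- P / rowSums(P)
  cats <- c("black_dark_brown", "brown_light_brown", "blonde_dark_blonde",
            "red")
  labels <- apply(P, 1, function(pr) sample(cats, 1, prob = pr))
  full_call <- cats[max.col(P)]
  X18 <- X[, 5:22]
  colnames(X18) <- paste0("rs", 1:18)
  fit18 <- fit_multinomial(X18, factor(labels, levels = cats),
                           trait = "hair")
  call18 <- fit18$categories[max.col(forensnp:::model_probs(fit18, X18))]
  red <- labels == "red"
  recall_full <- mean(full_call[red] == "red")
  recall_18 <- mean(call18[red] == "red")
  expect_lt(recall_18, recall_full)
})

test_that("planted coefficients are recovered without bias", {
  m0 <- planted_eye_model()
  fits <- lapply(1:5, function(s) {
    coh <- simulate_phenotype_cohort(m0, 5000, freqs = 0.35, seed = 70 + s)
    fit_multinomial(coh$x, factor(coh$labels, levels = m0$categories),
                    trait = "eye")$beta
  })
  avg <- Reduce(`+`, fits) / length(fits)
  expect_lt(max(abs(avg - m0$beta)), 0.15)
})

test_that("model files round-trip through the TSV format", {
  m0 <- planted_eye_model()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phenotype_model(m0, path)
  back <- read_phenotype_model(path)
  expect_equal(back$beta, m0$beta)
  expect_equal(back$categories, m0$categories)
  expect_equal(back$predictors, m0$predictors)
  # the shipped synthetic defaults load
  eye <- default_phenotype_model("eye")
  expect_equal(length(eye$predictors), 6L)
  hair <- default_phenotype_model("hair")
  expect_equal(length(hair$predictors), 18L)
  expect_equal(hair$categories[1], "black_dark_brown")
})
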