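test_that("strongly diverged populations separate on PC1", {
  cfg <- sim_config(n_populations = 2, n_autosomal = 1000, n_x = 0, n_y = 0,
                    n_mt = 0, fst = 0.3)
  sim <- suppressMessages(simulate_reference_panel(cfg, n_per_pop = 25,
                                                   seed = 6))
  sc <- sim$reference$scores
  pc1 <- split(sc$PC1, sc$population)
  expect_true(max(pc1$POP1) < min(pc1$POP2) ||
                max(pc1$POP2) < min(pc1$POP1))
})

test_that("projecting a reference sample reproduces its fit coordinates", {
  sim <- ref_sim()
  ref <- sim$reference
  g1 <- subset_genotypes(sim$genotypes, samples = 1:3)
  proj <- project_and_assign(g1, ref)
  fit_coords <- as.matrix(ref$scores[1:3, c("PC1", "PC2", "PC3")])
  expect_lt(max(abs(as.matrix(proj[, c("PC1", "PC2", "PC3")]) - fit_coords)),
            1e-8)
  expect_true(all(proj$distance >= 0))
})

test_that("reference samples sit nearest their own centroid", {
  sim <- ref_sim()
  proj <- project_and_assign(sim$genotypes, sim$reference)
  agree <- proj$nearest_group == sim$genotypes$samples$population
  expect_gte(mean(agree), 0.95)
})

test_that("a 50/50 admixed sample lies between its parental centroids", {
  # with K populations the centroid simplex spans K-1 dimensions; the
  # between-parents geometry needs all of them
  sim <- ref_sim()
  ref4 <- suppressMessages(fit_reference(sim$genotypes, n_pc = 4))
  set.seed(55)
  ok <- vapply(1:10, function(i) {
    ind <- simulate_cohort(sim, matrix(c(0.5, 0.5, 0, 0, 0), 1),
                           sex = "female", ids = "ADM")
    proj <- project_and_assign(ind$genotypes, ref4)
    coords <- as.numeric(proj[, paste0("PC", 1:4)])
    d <- sqrt(rowSums(sweep(ref4$centroids, 2, coords)^2))
    parental <- sort(d[c("AFR", "EUR")])
    all(parental < min(d[c("EAS", "SAS", "AMR")]))
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("samples with insufficient overlap are not projected", {
  sim <- ref_sim()
  g <- subset_genotypes(sim$genotypes, samples = 1)
  g_low <- apply_quality_loss(g, 0.7, seed = 2)
  expect_warning(out <- project_and_assign(g_low, sim$reference),
                 "not projected")
  expect_true(is.na(out$nearest_group))
})

test_that("a degenerate one-marker likelihood pins the admixture vector", {
  freqs <- matrix(c(0.999, 0.001), 1, 2,
                  dimnames = list("auto_1", c("P1", "P2")))
  panel <- manual_freq_panel(freqs)
  g <- auto_genotypes(matrix(2L, 1, 1, dimnames = list("S1", "auto_1")))
  fit <- suppressWarnings(estimate_admixture(g, panel))
  expect_gt(fit$q_P1, 0.98)
  expect_lt(fit$q_P2, 0.02)
})

test_that("EM matches an exhaustive simplex grid search on a small instance", {
  set.seed(42)
  K <- 3; m <- 20
  F <- matrix(runif(K * m, 0.05, 0.95), m, K,
              dimnames = list(paste0("auto_", 1:m), c("P1", "P2", "P3")))
  g_vec <- rbinom(m, 2, as.vector(F %*% c(0.6, 0.3, 0.1)))
  fit <- forensnp:::admixture_em(g_vec, F, tol = 1e-12, max_iter = 5000)
  # independent oracle: brute-force grid at 0.01 resolution
  best <- NULL; best_ll <- -Inf
  for (a in seq(0, 1, 0.01)) for (b in seq(0, 1 - a, 0.01)) {
    q <- c(a, b, 1 - a - b)
    pi <- pmin(pmax(as.vector(F %*% q), 1e-9), 1 - 1e-9)
    ll <- sum(g_vec * log(pi) + (2 - g_vec) * log(1 - pi))
    if (ll > best_ll) { best_ll <- ll; best <- q }
  }
  expect_lt(max(abs(fit$q - best)), 0.02)
  expect_gte(fit$loglik, best_ll - 1e-6)
})

test_that("the EM log-likelihood is non-decreasing at every iteration", {
  sim <- ref_sim()
  set.seed(77)
  for (i in 1:5) {
    q_true <- as.vector(stats::rmultinom(1, 10, rep(0.2, 5))) / 10
    ind <- simulate_cohort(sim, matrix(q_true, 1), sex = "female",
                           ids = "T1")
    ai <- which(sim$panel$chromosome_class == "autosomal")
    x <- ind$genotypes$dosage[1, ai]
    fit <- forensnp:::admixture_em(x[sim$reference$marker_ids],
                                   sim$reference$freqs)
    expect_true(all(diff(fit$trace) >= -1e-9))
  }
})

test_that("admixture q is invariant to marker order and duplication", {
  sim <- ref_sim()
  ind <- simulate_cohort(sim, matrix(c(0.3, 0.7, 0, 0, 0), 1),
                         sex = "female", ids = "A1", seed = 8)
  base <- suppressWarnings(estimate_admixture(ind$genotypes, sim$reference))
  # order
  perm <- sample(ncol(ind$genotypes$dosage))
  g_perm <- subset_genotypes(ind$genotypes, markers = perm)
  out_perm <- suppressWarnings(estimate_admixture(g_perm, sim$reference))
  expect_equal(out_perm[, 1:6], base[, 1:6], tolerance = 1e-6)
  # duplication of the whole marker set
  ref <- sim$reference
  dup <- ref
  dup$marker_ids <- c(ref$marker_ids, paste0(ref$marker_ids, "_b"))
  dup$freqs <- rbind(ref$freqs, ref$freqs)
  rownames(dup$freqs) <- dup$marker_ids
  d <- ind$genotypes$dosage[, ref$marker_ids, drop = FALSE]
  d2 <- cbind(d, d)
  colnames(d2) <- dup$marker_ids
  g_dup <- genotype_matrix(
    d2, marker_panel(dup$marker_ids, rep("autosomal", ncol(d2))))
  out_dup <- suppressWarnings(estimate_admixture(g_dup, dup))
  expect_equal(as.numeric(out_dup[1, 2:6]), as.numeric(base[1, 2:6]),
               tolerance = 1e-6)
})

test_that("the single-group rule is strict at 0.70", {
  q <- c(a = 0.71, b = 0.29, c = 0, d = 0, e = 0)
  expect_equal(assign_quantitative(q), "a")
  expect_equal(assign_quantitative(c(a = 0.70, b = 0.30)), "multiple groups")
  expect_equal(assign_quantitative(rep(0.2, 5),
                                   labels = letters[1:5]),
               "multiple groups")
})

test_that("quantitative and distance assignments agree on pure samples", {
  sim <- big_sim()
  K <- 5
  Q <- diag(K)[rep(1:K, 8), ]
  coh <- simulate_cohort(sim, Q, sex = "female", seed = 12)
  proj <- project_and_assign(coh$genotypes, sim$reference)
  adm <- suppressWarnings(estimate_admixture(coh$genotypes, sim$reference))
  single <- adm$assignment != "multiple groups"
  expect_gte(mean(single), 0.95)   # self-assignment via the 0.70 rule
  expect_gte(mean(proj$nearest_group[single] == adm$assignment[single]),
             0.99)
  truth <- sim$config$pop_labels[rep(1:K, 8)]
  expect_gte(mean(adm$assignment == truth), 0.95)
})

test_that("cohort summaries capture admixed composition", {
  sim <- ref_sim()
  set.seed(91)
  # identical q vectors give zero-width boxes
  n <- 10
  qtb <- tibble::tibble(q_AFR = rep(0.6, n), q_EUR = rep(0.4, n))
  gs <- group_summary(qtb, cohort = rep("fixed", n))
  expect_true(all(gs$lower == gs$upper & gs$ymin == gs$ymax))
  # an admixed cohort drawn around 0.6 African / 0.4 European
  mix <- pmin(pmax(rnorm(40, 0.6, 0.05), 0), 1)
  Q <- cbind(mix, 1 - mix, 0, 0, 0)
  coh <- simulate_cohort(sim, Q, sex = "female")
  adm <- suppressWarnings(estimate_admixture(coh$genotypes, sim$reference))
  gs2 <- group_summary(adm, cohort = rep("ethiopian_like", 40))
  med <- gs2$middle[gs2$component == "AFR"]
  expect_gte(med, 0.5)
  expect_lte(med, 0.7)
})

test_that("an intermediate-origin population mimics a mixed-race cohort", {
  cfg <- sim_config(n_populations = 2, n_autosomal = 4000, n_x = 0, n_y = 0,
                    n_mt = 0, fst = 0.15, pop_labels = c("EUR", "EAS"),
                    regions = c("Western Eurasia", "East Asia"))
  sim <- suppressMessages(simulate_reference_panel(cfg, n_per_pop = 30,
                                                   seed = 14))
  set.seed(15)
  m <- nrow(sim$freqs)
  inter_f <- (sim$freqs[, 1] + sim$freqs[, 2]) / 2
  n <- 30
  d_inter <- matrix(rbinom(n * m, 2, rep(inter_f, each = n)), n, m,
                    dimnames = list(paste0("I", 1:n), rownames(sim$freqs)))
  g_inter <- genotype_matrix(
    d_inter, sim$panel[match(rownames(sim$freqs), sim$panel$marker_id), ])
  mixed <- simulate_cohort(sim, matrix(0.5, n, 2), sex = "female", seed = 16)
  a1 <- suppressWarnings(estimate_admixture(g_inter, sim$reference))
  a2 <- suppressWarnings(estimate_admixture(mixed$genotypes, sim$reference))
  s1 <- group_summary(a1, rep("intermediate", n))
  s2 <- group_summary(a2, rep("mixed", n))
  expect_lt(abs(s1$middle[s1$component == "EUR"] -
                  s2$middle[s2$component == "EUR"]), 0.1)
  expect_true(all(a1$assignment == "multiple groups") ||
                mean(a1$assignment == "multiple groups") > 0.8)
})

test_that("reference panels serialise and reload faithfully", {
  sim <- ref_sim()
  dir <- withr::local_tempdir()
  write_reference_panel(sim$reference, dir)
  back <- read_reference_panel(dir)
  expect_equal(back$populations, sim$reference$populations)
  expect_equal(back$freqs, sim$reference$freqs, tolerance = 1e-12)
  g1 <- subset_genotypes(sim$genotypes, samples = 1:2)
  expect_equal(project_and_assign(g1, back),
               project_and_assign(g1, sim$reference), tolerance = 1e-9)
})
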