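test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_populations = 1), "n_populations")
  expect_error(sim_config(fst = 0), "fst")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(n_autosomal = -1), "counts")
  expect_error(sim_config(ancestral_freq_range = c(0.01, 0.95)),
               "ancestral_freq_range")
  cfg <- sim_config()
  expect_equal(cfg$n_populations, 5L)
  expect_equal(cfg$fst, seq(0.02, 0.15, length.out = 5))
})

test_that("identical seeds give bit-identical panels", {
  cfg <- sim_config(n_autosomal = 200, n_x = 50, n_y = 10, n_mt = 10)
  a <- simulate_reference_panel(cfg, n_per_pop = 3, seed = 11, fit = FALSE)
  b <- simulate_reference_panel(cfg, n_per_pop = 3, seed = 11, fit = FALSE)
  expect_identical(a$freqs, b$freqs)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$truth, b$truth)
})

test_that("drift controls between-population differentiation", {
  # near-zero drift collapses population frequencies onto the ancestral
  cfg0 <- sim_config(n_populations = 2, n_autosomal = 2000, n_x = 0,
                     n_y = 0, n_mt = 0, fst = 0.002)
  s0 <- simulate_reference_panel(cfg0, n_per_pop = 2, seed = 1, fit = FALSE)
  expect_lt(mean(abs(s0$freqs[, 1] - s0$freqs[, 2])), 0.05)
  # FST is monotone in F
  fst_at <- function(F) {
    cfg <- sim_config(n_populations = 2, n_autosomal = 2000, n_x = 0,
                      n_y = 0, n_mt = 0, fst = F)
    s <- simulate_reference_panel(cfg, n_per_pop = 40, seed = 5, fit = FALSE)
    pop <- s$genotypes$samples$population
    hudson_fst(s$genotypes$dosage[pop == "POP1", ],
               s$genotypes$dosage[pop == "POP2", ])
  }
  fsts <- vapply(c(0.02, 0.1, 0.25), fst_at, numeric(1))
  expect_true(all(diff(fsts) > 0))
})

test_that("Hudson FST matches the Balding-Nichols Monte-Carlo oracle", {
  # Oracle: 1e5 replicate markers at F = 0.2, n = 50/pop give Hudson
  # FST 0.201 (scratch Monte-Carlo, frozen)
  cfg <- sim_config(n_populations = 2, n_autosomal = 500, n_x = 0, n_y = 0,
                    n_mt = 0, fst = 0.2)
  s <- simulate_reference_panel(cfg, n_per_pop = 50, seed = 99, fit = FALSE)
  pop <- s$genotypes$samples$population
  fst <- hudson_fst(s$genotypes$dosage[pop == "POP1", ],
                    s$genotypes$dosage[pop == "POP2", ])
  expect_lt(abs(fst - 0.201), 0.05)
})

test_that("frequencies are clamped away from fixation", {
  s <- kin_sim()
  expect_true(all(s$freqs >= 0.001 & s$freqs <= 0.999))
})

test_that("one-hot admixture reproduces the population frequency profile", {
  sim <- ref_sim()
  K <- sim$config$n_populations
  coh <- simulate_cohort(sim, matrix(rep(c(1, rep(0, K - 1)), 200), ncol = K,
                                     byrow = TRUE),
                         sex = "female", seed = 13)
  ai <- which(sim$panel$chromosome_class == "autosomal")
  emp <- colMeans(coh$genotypes$dosage[, ai]) / 2
  expect_lt(mean(abs(emp - sim$freqs[sim$panel$marker_id[ai], 1])), 0.03)
})

test_that("sex-chromosome structure matches the simulated sex", {
  sim <- ref_sim()
  male <- simulate_individual(sim, c(0, 1, 0, 0, 0), sex = "male", seed = 2)
  female <- simulate_individual(sim, c(0, 1, 0, 0, 0), sex = "female",
                                seed = 3)
  yi <- which(sim$panel$chromosome_class == "Y")
  xi <- which(sim$panel$chromosome_class == "X_specific")
  expect_equal(sum(!is.na(female$genotypes$dosage[, yi])), 0)
  expect_true(all(!is.na(male$genotypes$dosage[, yi])))
  expect_true(all(male$genotypes$dosage[, xi] %in% c(0L, 2L)))
  expect_equal(female$truth$x_ploidy, 2L)
  expect_equal(male$truth$x_ploidy, 1L)
  expect_false(is.na(male$truth$y_haplogroup))
})

test_that("off-simplex admixture vectors are rejected", {
  sim <- ref_sim()
  expect_error(simulate_individual(sim, c(0.5, 0.4, 0, 0, 0)), "simplex")
  expect_error(simulate_individual(sim, c(1, 1, 0, 0, 0)), "simplex")
})

test_that("quality loss is the identity at zero rates", {
  sim <- ref_sim()
  g <- sim$genotypes
  expect_identical(apply_quality_loss(g, 0, 0), g)
})

test_that("12% planted missingness fails the QC gate in nearly all replicates", {
  d <- matrix(1L, 1, 2000, dimnames = list("S1", paste0("auto_", 1:2000)))
  g <- auto_genotypes(d)
  set.seed(31)
  fails <- vapply(1:50, function(i) {
    !qc_call_rate(apply_quality_loss(g, 0.12))$pass
  }, logical(1))
  expect_gte(sum(fails), 45)
})

test_that("genotype errors respect chromosome ploidy", {
  sim <- ref_sim()
  g2 <- apply_quality_loss(sim$genotypes, 0.05, 0.1, seed = 8)
  hap <- sim$panel$chromosome_class %in% c("Y", "mt")
  expect_true(all(g2$dosage[, hap] %in% c(0L, 1L, NA)))
  expect_true(all(g2$dosage[, !hap] %in% c(0L, 1L, 2L, NA)))
  expect_gt(mean(is.na(g2$dosage)), mean(is.na(sim$genotypes$dosage)))
})

test_that("parent-offspring pairs share one allele IBD at every marker", {
  pr <- simulate_relative_pair(kin_sim(), "POP1", 1, seed = 21)
  expect_equal(pr$truth$ibd1, 1)
  expect_equal(pr$truth$pihat_true, 0.5)
  expect_equal(pr$truth$relationship, "parent_offspring")
})

test_that("gene-dropped relatives have the expected IBD distributions", {
  sim <- kin_sim()
  for (rel in c("full_sib", "half_sib", "avuncular", "grandparent",
                "first_cousin", "grand_avuncular", "cousin_once_removed")) {
    pr <- simulate_relative_pair(sim, "POP1", rel_degree(rel),
                                 relationship = rel, seed = 100)
    expected <- c(`1` = 0.5, `2` = 0.25, `3` = 0.125, `4` = 0.0625)
    expect_lt(abs(pr$truth$pihat_true - expected[pr$truth$degree]), 0.03,
              label = paste(rel, "realised pi"))
  }
  un <- simulate_relative_pair(sim, "POP1", "unrelated", seed = 5)
  expect_equal(un$truth$pihat_true, 0)
})

test_that("estimated pi-hat of simulated unrelated pairs is centred at zero", {
  sim <- kin_sim()
  set.seed(17)
  m <- 2000
  freq <- sim$freqs[seq_len(m), "POP1"]
  d <- matrix(stats::rbinom(400 * m, 2, rep(freq, each = 400)), 400, m)
  g <- auto_genotypes(d)
  sh <- pairwise_sharing(g, min_overlap = 100)
  est <- estimate_pihat(g, sharing = sh, freqs = freq, min_overlap = 100)
  # 200 disjoint pairs (1,2), (3,4), ...
  pick <- dplyr::semi_join(
    est, tibble::tibble(id1 = paste0("S", seq(1, 399, 2)),
                        id2 = paste0("S", seq(2, 400, 2))),
    by = c("id1", "id2"))
  expect_equal(nrow(pick), 200)
  expect_lt(abs(mean(pick$pi_hat)), 0.02)
})

test_that("first cousins are classified third degree in >=90% of pairs", {
  sim <- kin_sim()
  set.seed(23)
  gs <- lapply(1:100, function(i) {
    pr <- simulate_relative_pair(sim, "POP1", 3)
    gg <- pr$genotypes
    rownames(gg$dosage) <- paste0("P", i, "_", rownames(gg$dosage))
    gg$samples$sample_id <- rownames(gg$dosage)
    gg
  })
  cohort <- do.call(bind_genotypes, gs)
  k <- kinship(cohort, min_overlap = 1000)
  target <- dplyr::semi_join(
    k, tibble::tibble(id1 = paste0("P", 1:100, "_C1"),
                      id2 = paste0("P", 1:100, "_C2")),
    by = c("id1", "id2"))
  expect_equal(nrow(target), 100)
  expect_gte(mean(target$degree == "third"), 0.9)
})

test_that("ancestry assignment survives 30% missingness on pure samples", {
  sim <- big_sim()
  set.seed(37)
  ok <- vapply(1:50, function(i) {
    ind <- simulate_cohort(sim, matrix(c(0, 1, 0, 0, 0), 1), sex = "female",
                           ids = "X1")
    deg <- apply_quality_loss(ind$genotypes, 0.3)
    adm <- suppressWarnings(estimate_admixture(deg, sim$reference))
    identical(adm$assignment, "EUR")
  }, logical(1))
  expect_gte(sum(ok), 45)
})

test_that("the truth sidecar round-trips as TSV", {
  sim <- ref_sim()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$truth, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(sim$truth))
  expect_true(all(abs(rowSums(back[, paste0("q_", sim$config$pop_labels)]) -
                        1) < 1e-9))
})
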