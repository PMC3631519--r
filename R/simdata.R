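#' Simulation configuration
#'
#' Defines the synthetic study conditions: K drifted populations under the
#' Balding-Nichols model (population allele frequencies Beta-distributed
#' around a shared ancestral frequency with per-population drift F), marker
#' counts per chromosome class, and the ancestral-frequency range.
#'
#' Defaults emulate the inference stack's reference setting: five continental
#' populations with drift values spanning within-continent to
#' between-continent differentiation (F from 0.02 to 0.15).
#'
#' @param n_populations Number of populations K (>= 2).
#' @param n_autosomal,n_x,n_y,n_mt Marker counts per class (>= 0).
#' @param fst Per-population drift F, strictly inside (0, 1); recycled to K.
#'   Default: K values evenly spaced on \[0.02, 0.15\].
#' @param ancestral_freq_range Interval for the ancestral allele frequency,
#'   within \[0.05, 0.95\].
#' @param pop_labels Population labels (default AFR/EUR/EAS/SAS/AMR for
#'   K = 5, else POP1..POPK).
#' @param regions Geographic regions per population, used to tie populations
#'   to haplogroup-tree clades.
#' @param seed Default seed used by the generators when none is passed.
#' @return A list of class `fsnp_sim_config`.
#' @export
sim_config <- function(n_populations = 5, n_autosomal = 1000, n_x = 200,
                       n_y = 50, n_mt = 50, fst = NULL,
                       ancestral_freq_range = c(0.05, 0.95),
                       pop_labels = NULL, regions = NULL, seed = NULL) {
  K <- as.integer(n_populations)
  if (K < 2) stop("n_populations must be >= 2")
  counts <- c(n_autosomal, n_x, n_y, n_mt)
  if (any(counts < 0)) stop("marker counts must be >= 0")
  if (is.null(fst)) fst <- seq(0.02, 0.15, length.out = K)
  fst <- rep_len(fst, K)
  if (any(fst <= 0 | fst >= 1)) stop("fst must be strictly inside (0, 1)")
  r <- ancestral_freq_range
  if (length(r) != 2 || r[1] >= r[2] || r[1] < 0.05 || r[2] > 0.95) {
    stop("ancestral_freq_range must be an interval within [0.05, 0.95]")
  }
  region5 <- c("Africa", "Western Eurasia", "East Asia", "South Asia",
               "Americas")
  if (is.null(pop_labels)) {
    pop_labels <- if (K == 5) c("AFR", "EUR", "EAS", "SAS", "AMR")
    else paste0("POP", seq_len(K))
  }
  if (is.null(regions)) regions <- rep_len(region5, K)
  structure(list(
    n_populations = K, n_autosomal = as.integer(n_autosomal),
    n_x = as.integer(n_x), n_y = as.integer(n_y), n_mt = as.integer(n_mt),
    fst = fst, ancestral_freq_range = r, pop_labels = pop_labels,
    regions = rep_len(regions, K), seed = seed
  ), class = "fsnp_sim_config")
}

sim_marker_panel <- function(config) {
  ids <- c(
    if (config$n_autosomal) paste0("auto_", seq_len(config$n_autosomal)),
    if (config$n_x) paste0("x_", seq_len(config$n_x)),
    if (config$n_y) paste0("y_", seq_len(config$n_y)),
    if (config$n_mt) paste0("mt_", seq_len(config$n_mt))
  )
  cls <- rep(c("autosomal", "X_specific", "Y", "mt"),
             c(config$n_autosomal, config$n_x, config$n_y, config$n_mt))
  chrom <- c(
    rep_len(as.character(1:22), config$n_autosomal),
    rep("X", config$n_x), rep("Y", config$n_y), rep("MT", config$n_mt)
  )
  marker_panel(ids, cls, chrom = chrom)
}

# Balding-Nichols frequencies: Beta(p(1-F)/F, (1-p)(1-F)/F) around ancestral
# p, clamped away from fixation.
bn_frequencies <- function(p, fst_k) {
  a <- p * (1 - fst_k) / fst_k
  b <- (1 - p) * (1 - fst_k) / fst_k
  clamp(stats::rbeta(length(p), a, b), 0.001, 0.999)
}

#' Simulate a drifted reference panel
#'
#' Draws ancestral allele frequencies uniformly over the configured range,
#' derives per-population frequencies under the Balding-Nichols model,
#' simulates `n_per_pop` labelled reference individuals per population
#' (autosomal and X genotypes binomial in the population frequency;
#' uniparental markers set by a haplogroup drawn from the population's
#' region of the synthetic Y/mt trees), and fits the ancestry reference
#' (PCA space, centroids, estimated frequencies) from those genotypes.
#'
#' @param config A [sim_config()].
#' @param n_per_pop Reference individuals per population (>= 2).
#' @param seed Integer seed; identical seeds give bit-identical panels.
#' @param fit Fit the ancestry reference with [fit_reference()]
#'   (default `TRUE`; skip for frequency-only uses such as pedigree
#'   simulation).
#' @return A list of class `fsnp_sim` with elements `config`, `panel`
#'   (marker panel), `freqs` (true per-population frequencies for diploid
#'   markers), `y_tree`, `mt_tree`, `geo_map`, `genotypes` (labelled
#'   reference cohort), `truth` and, when `fit = TRUE`, `reference` (a
#'   fitted [fit_reference()] panel).
#' @export
simulate_reference_panel <- function(config, n_per_pop, seed = NULL,
                                     fit = TRUE) {
  if (n_per_pop < 2) {
    stop("n_per_pop must be >= 2 (frequency estimation and PCA undefined)")
  }
  if (!is.null(seed %||% config$seed)) set.seed(seed %||% config$seed)
  K <- config$n_populations
  panel <- sim_marker_panel(config)
  dip <- config$n_autosomal + config$n_x
  p_anc <- stats::runif(dip, config$ancestral_freq_range[1],
                        config$ancestral_freq_range[2])
  freqs <- vapply(seq_len(K), function(k) bn_frequencies(p_anc, config$fst[k]),
                  numeric(dip))
  rownames(freqs) <- panel$marker_id[seq_len(dip)]
  colnames(freqs) <- config$pop_labels
  regions_used <- unique(config$regions)
  y_tree <- if (config$n_y > 0) {
    synthetic_haplogroup_tree("y", config$n_y, regions_used)
  }
  mt_tree <- if (config$n_mt > 0) {
    synthetic_haplogroup_tree("mt", config$n_mt, regions_used)
  }
  geo_map <- stats::setNames(config$regions, config$pop_labels)
  sim <- structure(list(
    config = config, panel = panel, freqs = freqs, y_tree = y_tree,
    mt_tree = mt_tree, geo_map = geo_map
  ), class = "fsnp_sim")

  n <- n_per_pop * K
  Q <- matrix(0, n, K, dimnames = list(NULL, config$pop_labels))
  pop <- rep(config$pop_labels, each = n_per_pop)
  Q[cbind(seq_len(n), match(pop, config$pop_labels))] <- 1
  sex <- rep_len(c("female", "male"), n)
  ids <- paste0(pop, "_", rep(seq_len(n_per_pop), K))
  drawn <- sim_draw(sim, Q, sex, ids, lineage_pop = pop)
  drawn$genotypes$samples$population <- pop
  sim$genotypes <- drawn$genotypes
  sim$truth <- drawn$truth
  if (fit && config$n_autosomal > 0) {
    sim$reference <- fit_reference(sim$genotypes, population = pop)
  }
  sim
}

#' @export
print.fsnp_sim <- function(x, ...) {
  cat("<fsnp_sim> ", x$config$n_populations, " populations (",
      paste(x$config$pop_labels, collapse = ", "), "), ",
      nrow(x$panel), " markers\n", sep = "")
  invisible(x)
}

# Core generator: Q is n x K admixture matrix; sexes, ids, and the
# population whose lineage trees supply each sample's haplogroups.
sim_draw <- function(sim, Q, sex, ids, lineage_pop = NULL,
                     y_haplogroup = NULL, mt_haplogroup = NULL) {
  config <- sim$config
  n <- nrow(Q)
  m <- nrow(sim$panel)
  dosage <- matrix(NA_integer_, n, m,
                   dimnames = list(ids, sim$panel$marker_id))
  male <- sex == "male"
  # expected dosage frequency per individual: mixture over ancestries
  if (config$n_autosomal + config$n_x > 0) {
    P <- sim$freqs %*% t(Q)  # (auto+x) x n
    ai <- seq_len(config$n_autosomal)
    if (config$n_autosomal > 0) {
      dosage[, ai] <- t(matrix(
        stats::rbinom(length(ai) * n, 2, P[ai, , drop = FALSE]),
        nrow = length(ai)))
    }
    if (config$n_x > 0) {
      xi <- config$n_autosomal + seq_len(config$n_x)
      Px <- P[config$n_autosomal + seq_len(config$n_x), , drop = FALSE]
      xdos <- matrix(stats::rbinom(config$n_x * n, 2, Px), nrow = config$n_x)
      if (any(male)) {
        # male X is haploid, rendered as homozygous diploid calls
        xdos[, male] <- 2L * matrix(
          stats::rbinom(config$n_x * sum(male), 1, Px[, male, drop = FALSE]),
          nrow = config$n_x)
      }
      dosage[, xi] <- t(xdos)
    }
  }
  if (is.null(lineage_pop)) {
    # matrilineal/patrilineal population drawn from the admixture vector
    lineage_pop <- apply(Q, 1, function(q) {
      sample(config$pop_labels, 1, prob = q)
    })
  }
  y_nodes <- rep(NA_character_, n)
  mt_nodes <- rep(NA_character_, n)
  fixed <- function(v, i) {
    x <- if (is.null(v)) NULL else v[i]
    if (is.null(x) || is.na(x)) NULL else x
  }
  if (config$n_y > 0 && !is.null(sim$y_tree)) {
    for (i in which(male)) {
      y_nodes[i] <- fixed(y_haplogroup, i) %||%
        sample_region_node(sim$y_tree, sim$geo_map[[lineage_pop[i]]])
      dosage[i, markers_of_class_panel(sim$panel, "Y")] <-
        lineage_states(sim$y_tree, y_nodes[i])
    }
  }
  if (config$n_mt > 0 && !is.null(sim$mt_tree)) {
    for (i in seq_len(n)) {
      mt_nodes[i] <- fixed(mt_haplogroup, i) %||%
        sample_region_node(sim$mt_tree, sim$geo_map[[lineage_pop[i]]])
      dosage[i, markers_of_class_panel(sim$panel, "mt")] <-
        lineage_states(sim$mt_tree, mt_nodes[i])
    }
  }
  samples <- tibble(sample_id = ids, sex = sex)
  truth <- dplyr::bind_cols(
    tibble(sample_id = ids, sex = sex,
           x_ploidy = ifelse(male, 1L, 2L),
           y_haplogroup = y_nodes, mt_haplogroup = mt_nodes),
    as_tibble(Q, .name_repair = ~ paste0("q_", colnames(Q)))
  )
  list(genotypes = genotype_matrix(dosage, sim$panel, samples), truth = truth)
}

markers_of_class_panel <- function(panel, class) {
  which(panel$chromosome_class == class)
}

sample_region_node <- function(tree, region) {
  cand <- tree$nodes$node[!is.na(tree$nodes$geography) &
                            tree$nodes$geography == region]
  if (!length(cand)) cand <- tree$nodes$node[-1]
  if (length(cand) == 1) cand else sample(cand, 1)
}

# haploid states along the tree path to `node`: derived (1) for defining
# variants on the path, ancestral (0) elsewhere
lineage_states <- function(tree, node) {
  path <- path_to(tree, node)
  as.integer(tree$markers$node %in% path)
}

#' Simulate one individual with known admixture and sex
#'
#' Autosomal (and X) genotypes are binomial draws from the admixture-weighted
#' population frequencies; males carry a haploid X rendered as homozygous
#' diploid calls, a Y haplogroup path and no second X dose; females carry no
#' Y calls. The matrilineal (and, for males, patrilineal) haplogroup is drawn
#' from the regional clade of the population sampled from `q`.
#'
#' @param sim An [simulate_reference_panel()] result.
#' @param q Admixture vector on the K-simplex (tolerance 1e-6).
#' @param sex `"female"` or `"male"`.
#' @param id Sample identifier.
#' @param seed Optional integer seed.
#' @param y_haplogroup,mt_haplogroup Optional fixed haplogroup nodes.
#' @return A list with `genotypes` (a one-sample [genotype_matrix()]) and
#'   `truth` (one-row tibble of the true state).
#' @export
simulate_individual <- function(sim, q, sex = c("female", "male"),
                                id = "IND1", seed = NULL,
                                y_haplogroup = NULL, mt_haplogroup = NULL) {
  sex <- match.arg(sex)
  if (!is.null(seed)) set.seed(seed)
  K <- sim$config$n_populations
  if (length(q) != K || any(q < -1e-9) || abs(sum(q) - 1) > 1e-6) {
    stop("q must be a length-", K, " vector on the simplex")
  }
  q <- pmax(q, 0); q <- q / sum(q)
  Q <- matrix(q, 1, K, dimnames = list(NULL, sim$config$pop_labels))
  drawn <- sim_draw(sim, Q, sex, id,
                    y_haplogroup = y_haplogroup %||% NA_character_,
                    mt_haplogroup = mt_haplogroup %||% NA_character_)
  drawn
}

#' Simulate a cohort of individuals
#'
#' Vectorised companion to [simulate_individual()].
#'
#' @param sim An [simulate_reference_panel()] result.
#' @param Q Matrix of admixture vectors, one row per individual.
#' @param sex Character vector (recycled).
#' @param ids Sample IDs (default IND1..INDn).
#' @param seed Optional integer seed.
#' @return A list with `genotypes` and `truth` as in [simulate_individual()].
#' @export
simulate_cohort <- function(sim, Q, sex = "female", ids = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- as.matrix(Q)
  if (any(abs(rowSums(Q) - 1) > 1e-6)) stop("rows of Q must lie on the simplex")
  ids <- ids %||% paste0("IND", seq_len(nrow(Q)))
  colnames(Q) <- sim$config$pop_labels
  sim_draw(sim, Q, rep_len(sex, nrow(Q)), ids)
}

#' Degrade genotype calls (missingness and error)
#'
#' Each call is independently set missing with probability `missing_rate`;
#' each surviving call is flipped to a random other genotype of its class
#' with probability `error_rate` (symmetric category flips; haploid classes
#' flip between 0 and 1).
#'
#' @param g A [genotype_matrix()].
#' @param missing_rate,error_rate Rates in \[0, 1\].
#' @param seed Optional integer seed.
#' @return A degraded [genotype_matrix()].
#' @export
apply_quality_loss <- function(g, missing_rate, error_rate = 0, seed = NULL) {
  if (missing_rate < 0 || missing_rate > 1 || error_rate < 0 || error_rate > 1) {
    stop("rates must be in [0, 1]")
  }
  if (missing_rate == 0 && error_rate == 0) return(g)
  if (!is.null(seed)) set.seed(seed)
  d <- g$dosage
  n <- length(d)
  if (missing_rate > 0) d[stats::runif(n) < missing_rate] <- NA_integer_
  if (error_rate > 0) {
    hap <- matrix(rep(g$panel$chromosome_class %in% haploid_classes,
                      each = nrow(d)), nrow(d))
    err <- !is.na(d) & stats::runif(n) < error_rate
    shift <- matrix(sample(1:2, n, replace = TRUE), nrow(d))
    d[err & !hap] <- (d[err & !hap] + shift[err & !hap]) %% 3L
    d[err & hap] <- 1L - d[err & hap]
  }
  genotype_matrix(d, g$panel, g$samples)
}

# ---- pedigree simulation (gene dropping) -----------------------------------

rel_pedigree <- function(relationship) {
  ped <- function(id, father, mother) tibble(id = id, father = father,
                                             mother = mother)
  switch(relationship,
    parent_offspring = list(
      ped = ped(c("F", "M", "C1"), c(NA, NA, "F"), c(NA, NA, "M")),
      pair = c("F", "C1"), degree = 1L),
    full_sib = list(
      ped = ped(c("F", "M", "C1", "C2"), c(NA, NA, "F", "F"),
                c(NA, NA, "M", "M")),
      pair = c("C1", "C2"), degree = 1L),
    half_sib = list(
      ped = ped(c("F", "M1", "M2", "C1", "C2"), c(NA, NA, NA, "F", "F"),
                c(NA, NA, NA, "M1", "M2")),
      pair = c("C1", "C2"), degree = 2L),
    avuncular = list(
      ped = ped(c("G1", "G2", "S1", "S2", "X1", "N1"),
                c(NA, NA, "G1", "G1", NA, "S1"),
                c(NA, NA, "G2", "G2", NA, "X1")),
      pair = c("S2", "N1"), degree = 2L),
    grandparent = list(
      ped = ped(c("G1", "G2", "S1", "X1", "C1"),
                c(NA, NA, "G1", NA, "S1"), c(NA, NA, "G2", NA, "X1")),
      pair = c("G1", "C1"), degree = 2L),
    first_cousin = list(
      ped = ped(c("G1", "G2", "S1", "S2", "X1", "X2", "C1", "C2"),
                c(NA, NA, "G1", "G1", NA, NA, "S1", "S2"),
                c(NA, NA, "G2", "G2", NA, NA, "X1", "X2")),
      pair = c("C1", "C2"), degree = 3L),
    grand_avuncular = list(
      ped = ped(c("G1", "G2", "S1", "S2", "X1", "N1", "X2", "GN1"),
                c(NA, NA, "G1", "G1", NA, "S1", NA, "N1"),
                c(NA, NA, "G2", "G2", NA, "X1", NA, "X2")),
      pair = c("S2", "GN1"), degree = 3L),
    cousin_once_removed = list(
      ped = ped(c("G1", "G2", "S1", "S2", "X1", "X2", "C1", "C2", "X3", "D1"),
                c(NA, NA, "G1", "G1", NA, NA, "S1", "S2", NA, "C2"),
                c(NA, NA, "G2", "G2", NA, NA, "X1", "X2", NA, "X3")),
      pair = c("C1", "D1"), degree = 4L),
    unrelated = list(
      ped = ped(c("A", "B"), c(NA, NA), c(NA, NA)),
      pair = c("A", "B"), degree = NA_integer_),
    stop("unknown relationship: ", relationship)
  )
}

default_relationship <- function(degree) {
  if (identical(degree, "unrelated")) return("unrelated")
  c("parent_offspring", "half_sib", "first_cousin",
    "cousin_once_removed")[as.integer(degree)]
}

# Drop founder haplotype labels and allele values through a pedigree.
# Returns genotypes and haplotype-label matrices for IBD bookkeeping.
ped_drop <- function(freq, ped) {
  m <- length(freq)
  n <- nrow(ped)
  founder <- is.na(ped$father)
  H <- 2 * sum(founder)
  A <- matrix(stats::rbinom(H * m, 1, rep(freq, each = H)), H, m)
  Lp <- matrix(0L, n, m)
  Lm <- matrix(0L, n, m)
  hap <- 0L
  for (i in seq_len(n)) {
    if (founder[i]) {
      Lp[i, ] <- hap + 1L
      Lm[i, ] <- hap + 2L
      hap <- hap + 2L
    } else {
      fa <- match(ped$father[i], ped$id)
      mo <- match(ped$mother[i], ped$id)
      pickf <- stats::runif(m) < 0.5
      pickm <- stats::runif(m) < 0.5
      Lp[i, ] <- ifelse(pickf, Lp[fa, ], Lm[fa, ])
      Lm[i, ] <- ifelse(pickm, Lp[mo, ], Lm[mo, ])
    }
  }
  G <- matrix(A[cbind(as.vector(Lp), rep(seq_len(m), each = n))] +
                A[cbind(as.vector(Lm), rep(seq_len(m), each = n))],
              n, m)
  rownames(G) <- ped$id
  list(G = G, Lp = Lp, Lm = Lm, ids = ped$id)
}

realized_ibd <- function(drop, a, b) {
  ia <- match(a, drop$ids); ib <- match(b, drop$ids)
  m1 <- (drop$Lp[ia, ] == drop$Lp[ib, ]) + (drop$Lm[ia, ] == drop$Lm[ib, ])
  m2 <- (drop$Lp[ia, ] == drop$Lm[ib, ]) + (drop$Lm[ia, ] == drop$Lp[ib, ])
  ibd <- pmax(m1, m2)
  p <- tabulate(ibd + 1L, 3L) / length(ibd)
  c(p0 = p[1], p1 = p[2], p2 = p[3])
}

#' Simulate genotypes through an arbitrary pedigree
#'
#' Gene-dropping: founders draw haplotypes from the population's
#' Balding-Nichols allele frequencies; descendants inherit one allele per
#' parent per marker (markers independent, no recombination map). Only
#' autosomal markers are generated.
#'
#' @param sim An [simulate_reference_panel()] result.
#' @param population Population label for the founders.
#' @param pedigree Tibble with `id`, `father`, `mother` (`NA` for founders),
#'   parents listed before children.
#' @param observed IDs of genotyped individuals (default: all).
#' @param seed Optional integer seed.
#' @return List with `genotypes` (observed individuals over the autosomal
#'   panel) and `drop` (internal haplotype bookkeeping for realised IBD).
#' @export
simulate_pedigree <- function(sim, population, pedigree, observed = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ai <- markers_of_class_panel(sim$panel, "autosomal")
  freq <- sim$freqs[sim$panel$marker_id[ai], population]
  drop <- ped_drop(freq, pedigree)
  observed <- observed %||% pedigree$id
  G <- drop$G[observed, , drop = FALSE]
  storage.mode(G) <- "integer"
  colnames(G) <- sim$panel$marker_id[ai]
  panel <- sim$panel[ai, , drop = FALSE]
  list(
    genotypes = genotype_matrix(G, panel,
                                tibble(sample_id = observed,
                                       population = population)),
    drop = drop
  )
}

#' Simulate a pair of relatives by gene dropping
#'
#' Builds the minimal pedigree realising the requested degree of
#' relatedness (first: parent-offspring or full sibs; second: half-sib,
#' avuncular or grandparental; third: first cousins or grand-avuncular;
#' fourth: first cousins once removed) and genotypes the two target
#' individuals. Founders are drawn from a single population.
#'
#' @param sim An [simulate_reference_panel()] result.
#' @param population Population label for the founders.
#' @param degree 1, 2, 3, 4 or `"unrelated"`.
#' @param relationship Optional explicit relationship name (see details);
#'   default is the first relationship listed for the degree.
#' @param seed Optional integer seed.
#' @return List with `genotypes` (a two-sample [genotype_matrix()] over the
#'   autosomal panel) and `truth` (one-row tibble: ids, degree,
#'   relationship, realised IBD proportions and realised pi-hat).
#' @export
simulate_relative_pair <- function(sim, population, degree,
                                   relationship = NULL, seed = NULL) {
  if (!identical(degree, "unrelated") &&
      !(is.numeric(degree) && degree %in% 1:4)) {
    stop("degree must be 1, 2, 3, 4 or \"unrelated\"")
  }
  relationship <- relationship %||% default_relationship(degree)
  spec <- rel_pedigree(relationship)
  sim_ped <- simulate_pedigree(sim, population, spec$ped,
                               observed = spec$pair, seed = seed)
  ibd <- realized_ibd(sim_ped$drop, spec$pair[1], spec$pair[2])
  truth <- tibble(
    id1 = spec$pair[1], id2 = spec$pair[2],
    degree = if (is.na(spec$degree)) "unrelated" else as.character(spec$degree),
    relationship = relationship,
    ibd0 = ibd[["p0"]], ibd1 = ibd[["p1"]], ibd2 = ibd[["p2"]],
    pihat_true = ibd[["p2"]] + ibd[["p1"]] / 2
  )
  list(genotypes = sim_ped$genotypes, truth = truth)
}

#' Simulate a relatedness study cohort
#'
#' Builds an 81-sample cohort whose 3,240 pairwise comparisons contain
#' exactly 27 first-degree pairs (three nuclear families of two parents and
#' three children), ten second-degree pairs (five grandparental, four
#' avuncular, one half-sib), three third-degree pairs (two first-cousin
#' pairs, one grand-avuncular), one fourth-degree pair (first cousins once
#' removed) and 3,199 unrelated pairs. All founders are drawn from one
#' population; units are mutually unrelated.
#'
#' @param sim An [simulate_reference_panel()] result.
#' @param population Population label (default: first).
#' @param seed Optional integer seed.
#' @return List with `genotypes` (81 samples over the autosomal panel) and
#'   `pairs` (tibble of the related pairs with true degree and realised
#'   pi-hat).
#' @export
simulate_study_pedigrees <- function(sim, population = NULL, seed = NULL) {
  population <- population %||% sim$config$pop_labels[1]
  if (!is.null(seed)) set.seed(seed)
  family <- list(
    ped = tibble(id = c("F", "M", "C1", "C2", "C3"),
                 father = c(NA, NA, "F", "F", "F"),
                 mother = c(NA, NA, "M", "M", "M")),
    observed = c("F", "M", "C1", "C2", "C3"),
    pairs = rbind(
      cbind(rep(c("F", "M"), each = 3), rep(c("C1", "C2", "C3"), 2)),
      cbind(c("C1", "C1", "C2"), c("C2", "C3", "C3"))),
    degree = "1"
  )
  unit_list <- c(
    rep(list(family), 3),
    rep(list(list(ped = rel_pedigree("grandparent")$ped,
                  observed = c("G1", "C1"),
                  pairs = matrix(c("G1", "C1"), 1), degree = "2")), 5),
    rep(list(list(ped = rel_pedigree("avuncular")$ped,
                  observed = c("S2", "N1"),
                  pairs = matrix(c("S2", "N1"), 1), degree = "2")), 4),
    list(list(ped = rel_pedigree("half_sib")$ped, observed = c("C1", "C2"),
              pairs = matrix(c("C1", "C2"), 1), degree = "2")),
    rep(list(list(ped = rel_pedigree("first_cousin")$ped,
                  observed = c("C1", "C2"),
                  pairs = matrix(c("C1", "C2"), 1), degree = "3")), 2),
    list(list(ped = rel_pedigree("grand_avuncular")$ped,
              observed = c("S2", "GN1"),
              pairs = matrix(c("S2", "GN1"), 1), degree = "3")),
    list(list(ped = rel_pedigree("cousin_once_removed")$ped,
              observed = c("C1", "D1"),
              pairs = matrix(c("C1", "D1"), 1), degree = "4"))
  )
  gts <- list()
  pair_rows <- list()
  for (u in seq_along(unit_list)) {
    unit <- unit_list[[u]]
    tag <- sprintf("U%02d_", u)
    ped <- unit$ped
    sim_ped <- simulate_pedigree(sim, population, ped,
                                 observed = unit$observed)
    gg <- sim_ped$genotypes
    rownames(gg$dosage) <- paste0(tag, rownames(gg$dosage))
    gg$samples$sample_id <- paste0(tag, gg$samples$sample_id)
    gts[[u]] <- gg
    pr <- unit$pairs
    pair_rows[[u]] <- purrr::map_dfr(seq_len(nrow(pr)), function(i) {
      ibd <- realized_ibd(sim_ped$drop, pr[i, 1], pr[i, 2])
      tibble(id1 = paste0(tag, pr[i, 1]), id2 = paste0(tag, pr[i, 2]),
             degree = unit$degree,
             pihat_true = ibd[["p2"]] + ibd[["p1"]] / 2)
    })
  }
  n_related <- sum(vapply(gts, function(g) nrow(g$dosage), numeric(1)))
  n_single <- 81 - n_related
  ai <- markers_of_class_panel(sim$panel, "autosomal")
  freq <- sim$freqs[sim$panel$marker_id[ai], population]
  singles <- matrix(stats::rbinom(n_single * length(ai), 2,
                                  rep(freq, each = n_single)),
                    n_single, length(ai),
                    dimnames = list(sprintf("S%02d", seq_len(n_single)),
                                    sim$panel$marker_id[ai]))
  gts[[length(gts) + 1]] <- genotype_matrix(
    singles, sim$panel[ai, , drop = FALSE],
    tibble(sample_id = rownames(singles), population = population))
  list(
    genotypes = do.call(bind_genotypes, gts),
    pairs = dplyr::bind_rows(pair_rows)
  )
}
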