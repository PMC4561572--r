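test_that("class genotype probabilities follow the gamete model", {
  # fixed-difference parents
  pN <- c(a = 1 - 1e-12, b = 1e-12)  # effectively fixed, strictly positive
  pO <- c(a = 1e-12, b = 1 - 1e-12)
  expect_equal(class_genotype_probability(c("a", "b"), pN, pO, "F1"), 1,
               tolerance = 1e-9)
  expect_equal(class_genotype_probability(c("a", "a"), pN, pO, "pure_natal"),
               1, tolerance = 1e-9)
  expect_equal(class_genotype_probability(c("a", "a"), pN, pO, "backcross_natal"),
               0.5, tolerance = 1e-9)
  expect_equal(class_genotype_probability(c("a", "b"), pN, pO, "backcross_natal"),
               0.5, tolerance = 1e-9)

  # enumerated F1 heterozygote probability
  pA <- c(a = 0.8, b = 0.2); pB <- c(a = 0.1, b = 0.9)
  expect_equal(class_genotype_probability(c("a", "b"), pA, pB, "F1"),
               0.8 * 0.9 + 0.2 * 0.1)

  expect_error(class_genotype_probability(c("zz", "a"), pA, pB, "F1"),
               "union allele set")
})

test_that("class probabilities normalize over the genotype space (enumeration oracle)", {
  set.seed(51)
  alleles <- c("a", "b", "c")
  genotypes <- list()
  for (i in 1:3) for (j in i:3)
    genotypes[[length(genotypes) + 1]] <- c(alleles[i], alleles[j])
  for (rep in 1:5) {
    pN <- prop.table(stats::runif(3) + 0.01); names(pN) <- alleles
    pO <- prop.table(stats::runif(3) + 0.01); names(pO) <- alleles
    for (cl in c("pure_natal", "pure_nonnatal", "F1",
                 "backcross_natal", "backcross_nonnatal")) {
      tot <- sum(vapply(genotypes, class_genotype_probability,
                        numeric(1), pN = pN, pO = pO, class = cl))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("posteriors sum to one, respect priors under no signal, and ignore locus order", {
  # identical reference frequencies for both taxa -> posterior = prior
  a1 <- matrix(rep(c(150L, 152L), each = 8), 8, 2)
  a2 <- matrix(rep(c(152L, 154L), each = 8), 8, 2)
  ind <- data.frame(id = paste0("i", 1:8), site = rep(c("s1", "s2"), each = 4),
                    species = rep(c("A", "B"), each = 4),
                    pair = "P1", stringsAsFactors = FALSE)
  # make both species' calls identical so references coincide
  a1[5:8, ] <- a1[1:4, ]; a2[5:8, ] <- a2[1:4, ]
  d <- genotype_dataset(a1, a2, ind, data.frame(name = c("L1", "L2")))
  nu <- 0.05
  post <- classify(d, nu = nu)
  pmat <- as.matrix(post[, c("pure_natal", "pure_nonnatal", "F1",
                             "backcross_natal", "backcross_nonnatal")])
  expect_equal(rowSums(pmat), rep(1, 8), tolerance = 1e-9)
  expect_equal(unname(pmat[1, ]), c(1 - nu, rep(nu / 4, 4)), tolerance = 1e-9)
  expect_equal(post$class, rep("pure_natal", 8))  # ties resolve to pure natal

  # locus reordering leaves posteriors unchanged
  sim <- simulate_study(sim_config(n_sites = 2, n_per_population = 12,
                                   n_loci = 6, seed = 52))
  p1 <- classify(sim$dataset, nu = 0.01)
  p2 <- classify(sim$dataset[, sample(6)], nu = 0.01)
  expect_equal(p2$pure_natal, p1$pure_natal, tolerance = 1e-9)
})

test_that("clearly pure and F1 individuals are recognized with high confidence", {
  # strong divergence, no cline, no injected hybrids
  cfg <- sim_config(alpha_max = 0, rate_f1 = c(A = 0, B = 0),
                    rate_migrant = c(A = 0, B = 0), missing_rate = 0,
                    n_sites = 2, n_per_population = 40, seed = 53)
  sim <- simulate_study(cfg)
  post <- classify(sim$dataset, nu = 0.01)
  expect_gt(mean(post$pure_natal > 0.99), 0.9)
  expect_true(all(post$class == "pure_natal"))

  # F1 between fixed-difference parents, heterozygous at 10 loci: the pure
  # classes have zero likelihood and the backcross likelihood is 2^-10, so
  # the F1 posterior is 1/(1 + 2 * 2^-10) ~ 0.998 whatever the prior
  L <- 10L
  a1 <- matrix(100L, 21, L); a2 <- matrix(100L, 21, L)
  a1[11:20, ] <- 200L; a2[11:20, ] <- 200L
  a1[21, ] <- 100L; a2[21, ] <- 200L          # the F1
  ind <- data.frame(id = paste0("i", 1:21), site = c(rep("sA", 10), rep("sB", 10), "sA"),
                    species = c(rep("A", 10), rep("B", 10), "A"),
                    pair = "P1", stringsAsFactors = FALSE)
  d <- genotype_dataset(a1, a2, ind, data.frame(name = paste0("L", 1:L)))
  for (nu in c(0.01, 0.05, 0.1)) {
    p <- classify(d, nu = nu, leave_one_out = TRUE, lambda = 1e-9)
    expect_equal(p$class[21], "F1")
    expect_gt(p$F1[21], 0.99)
  }
})

test_that("assignment of clear individuals is insensitive to the migration prior", {
  cfg <- sim_config(n_sites = 3, n_per_population = 25, alpha_max = 0,
                    rate_f1 = c(A = 0, B = 0), rate_migrant = c(A = 0, B = 0),
                    seed = 54)
  sim <- simulate_study(cfg)
  calls <- lapply(c(0.01, 0.05, 0.1), function(nu)
    classify(sim$dataset, nu = nu)$class)
  expect_equal(calls[[1]], calls[[2]])
  expect_equal(calls[[2]], calls[[3]])
})

test_that("individuals with no scored locus are reported unclassified", {
  d <- tiny_dataset()
  d$a1[2, ] <- NA_integer_; d$a2[2, ] <- NA_integer_
  d <- genotype_dataset(d$a1, d$a2, d$ind, d$loci)
  post <- classify(d, nu = 0.05)
  expect_true(is.na(post$class[2]))
  expect_equal(attr(post, "n_unclassified"), 1L)
})

test_that("rate estimators implement the count arithmetic", {
  r <- hybrid_migration_rates(4, 0, 278)
  expect_equal(r$hybridization, 4 / 278)
  expect_equal(r$migration, 2 / 278)
  r2 <- hybrid_migration_rates(0, 1, 327)
  expect_equal(r2$migration, 1 / 327)
  expect_equal(hybrid_migration_rates(0, 0, 50),
               list(hybridization = 0, migration = 0))
  expect_error(hybrid_migration_rates(1, 0, 0), "empty sample")
  expect_error(hybrid_migration_rates(30, 30, 50), "inconsistent")

  # estimate_rates over a classification table, and on planted truth labels
  sim <- simulate_study(sim_config(n_per_population = study_278_sizes,
                                   seed = 55), exact_counts = TRUE)
  truth_post <- data.frame(species = sim$truth$species,
                           class = sim$truth$true_class,
                           stringsAsFactors = FALSE)
  rates <- estimate_rates(truth_post)
  a <- rates[rates$taxon == "A", ]
  expect_equal(a$n, 278L)
  expect_equal(a$n_f1, 4)                 # round(0.015 * 278)
  expect_equal(round(a$hybridization, 4), 0.0144)
  expect_equal(round(a$migration, 4), 0.0072)
  b <- rates[rates$taxon == "B", ]
  expect_equal(b$n_migrant, 1)            # round(0.003 * 278)
  expect_equal(round(b$migration, 4), round(1 / 278, 4))
})
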