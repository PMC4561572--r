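test_that("total-variation frequency difference: oracles and metric properties", {
  expect_equal(freq_difference(c(a = 0.5, b = 0.5), c(a = 0.5, b = 0.5)), 0)
  expect_equal(freq_difference(c(a = 1), c(b = 1)), 1)
  expect_equal(freq_difference(c(a = 0.8, b = 0.2), c(a = 0.1, b = 0.9)), 0.7)

  # symmetry and triangle inequality over random frequency vectors
  set.seed(61)
  rf <- function() {
    k <- sample(2:5, 1)
    stats::setNames(prop.table(stats::runif(k)), sample(letters, k))
  }
  for (i in 1:25) {
    p <- rf(); q <- rf(); r <- rf()
    expect_equal(freq_difference(p, q), freq_difference(q, p))
    expect_lte(freq_difference(p, r),
               freq_difference(p, q) + freq_difference(q, r) + 1e-12)
    expect_gte(freq_difference(p, q), 0)
    expect_lte(freq_difference(p, q), 1)
  }
})

test_that("haversine distance matches closed-form arcs and validates input", {
  expect_equal(geo_distance(10, 20, 10, 20), 0)
  expect_equal(geo_distance(0, 0, 0, 180), pi * 6371.0088, tolerance = 1e-6)
  expect_equal(geo_distance(0, 0, 0, 1), pi * 6371.0088 / 180, tolerance = 1e-4)
  expect_error(geo_distance(91, 0, 0, 0), "out of range")
  expect_error(geo_distance(0, 0, 0, 181), "out of range")
})

test_that("cline regression reproduces closed-form correlations", {
  sim <- simulate_study(sim_config(n_per_population = 10, seed = 62))
  div <- paired_site_divergence(sim$dataset, sim$geo, sim$focal_site)
  expect_true(all(div$per_locus >= 0 & div$per_locus <= 1, na.rm = TRUE))
  cr <- cline_regression(div)
  overall <- cr$r[cr$locus == "all_loci"]
  expect_equal(overall,
               stats::cor(div$summary$mean_difference, div$summary$distance_km))

  # difference exactly linear in distance -> r = 1
  div1 <- div
  div1$summary$mean_difference <- 0.1 + 1e-3 * div1$summary$distance_km
  expect_equal(cline_regression(div1, per_locus = FALSE), 1)
  # constant difference -> undefined
  div1$summary$mean_difference <- rep(0.3, 9)
  expect_true(is.na(cline_regression(div1, per_locus = FALSE)))
})

test_that("covariate correlation equals the closed form and the distance identity", {
  geo <- default_geography(sim_config(seed = 63))
  sim <- simulate_study(sim_config(seed = 63))
  geo$precip_jul_oct <- seq(200, 40, length.out = 9)[match(geo$pair, paste0("P", 1:9))]
  div <- paired_site_divergence(sim$dataset, geo, sim$focal_site)
  r <- covariate_correlation(div, "precip_jul_oct")
  expect_equal(r, stats::cor(div$summary$mean_difference,
                             div$summary$precip_jul_oct))
  # covariate equal to the distance axis reproduces the overall cline r
  geo$fake <- NA_real_
  geo$fake <- div$summary$distance_km[match(geo$pair, div$summary$pair)]
  div2 <- paired_site_divergence(sim$dataset, geo, sim$focal_site)
  expect_equal(covariate_correlation(div2, "fake"),
               cline_regression(div2, per_locus = FALSE))
  expect_error(covariate_correlation(div, "nope"), "not present")
})

test_that("permutation p-values respect the add-one bounds and the fixed seed", {
  sim <- simulate_study(sim_config(n_loci = 5, n_per_population = 12, seed = 64))
  ct <- cline_permutation_test(sim$dataset, sim$geo, sim$focal_site,
                               n_perm = 99, seed = 7)
  ok <- !is.na(ct$p)
  expect_true(all(ct$p[ok] >= 1 / 100 & ct$p[ok] <= 1))
  ct2 <- cline_permutation_test(sim$dataset, sim$geo, sim$focal_site,
                                n_perm = 99, seed = 7)
  expect_identical(as.data.frame(ct), as.data.frame(ct2))
  expect_error(cline_permutation_test(sim$dataset, sim$geo, sim$focal_site,
                                      n_perm = 10), ">= 99")
})

test_that("a cline in the generator is detected against the permutation null", {
  sim <- simulate_study(sim_config(seed = 65))
  ct <- as.data.frame(cline_permutation_test(sim$dataset, sim$geo,
                                             sim$focal_site,
                                             n_perm = 499, seed = 66))
  expect_lte(ct$p[ct$locus == "all_loci"], 0.05)
  # introgressed loci carry larger observed r on average than clean loci
  intro <- names(which(sim$freq_truth$introgressed))
  r_int <- mean(ct$r[ct$locus %in% intro], na.rm = TRUE)
  r_cln <- mean(ct$r[!(ct$locus %in% c(intro, "all_loci"))], na.rm = TRUE)
  expect_gt(r_int, r_cln)
})

test_that("Mantel and partial Mantel: exact cases and vegan cross-check", {
  set.seed(67)
  n <- 12
  mk <- function() {
    m <- matrix(stats::runif(n * n), n)
    m <- m + t(m); diag(m) <- 0
    dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
    m
  }
  A <- mk(); B <- mk(); C <- mk()
  expect_equal(mantel_test(A, A, n_perm = 99, seed = 1)$r, 1)
  mt <- mantel_test(A, B, n_perm = 999, seed = 2)
  expect_gte(mt$p, 1 / 1000)

  # r agrees with the reference implementation
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(stats::as.dist(A), stats::as.dist(B), permutations = 99)
  expect_equal(mt$r, unname(vg$statistic), tolerance = 1e-12)

  pm <- partial_mantel_test(A, B, C, n_perm = 999, seed = 3)
  vgp <- vegan::mantel.partial(stats::as.dist(A), stats::as.dist(B),
                               stats::as.dist(C), permutations = 99)
  # residual-based partial r equals the standard partial correlation
  expect_equal(pm$r, unname(vgp$statistic), tolerance = 1e-10)

  # conditioning matrix identical to dmB: self-residual r reported as 0
  expect_equal(partial_mantel_test(A, B, B, n_perm = 99, seed = 4)$r, 0)
  expect_error(mantel_test(A, B[n:1, n:1], n_perm = 99), "mismatched")
})

test_that("species and geographic distance matrices feed the Mantel tests", {
  geo <- default_geography(sim_config(seed = 68))
  gdm <- geo_distance_matrix(geo)
  expect_equal(gdm, t(gdm))
  expect_true(all(diag(gdm) == 0))
  # co-located pair members are 0 km apart; transect ends ~320 km
  expect_equal(gdm["A1", "B1"], 0)
  expect_equal(gdm["A1", "A9"], 320, tolerance = 1)
  sdm <- species_distance_matrix(stats::setNames(geo$species, geo$site))
  expect_equal(sdm["A1", "B1"], 1)
  expect_equal(sdm["A1", "A2"], 0)
})
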