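#' Configuration for the two-taxon paired-site simulator
#'
#' Defaults emulate the study design the package targets: two sibling taxa
#' sampled at nine paired field sites on a west-east transect, 19
#' microsatellites on five linkage groups, strong divergence without fixed
#' differences, a subset of loci with introgression clines in taxon A
#' toward a focal site at one end of the transect, and hybrid/migrant
#' individuals injected at roughly the empirically observed rates.
#'
#' @param n_loci Number of loci (default 19).
#' @param alleles_per_locus Alleles in the ancestral pool per locus (8).
#' @param divergence_F Balding-Nichols divergence parameter between the two
#'   taxa, interpretable as FST (default 0.15).
#' @param n_sites Number of paired sites (default 9).
#' @param n_per_population Diploids per (site x taxon) population; scalar
#'   or vector of length `n_sites` (default 30).
#' @param introgressed_fraction Fraction of loci given a cline (7/19).
#' @param alpha_max Mixing weight of taxon-B frequencies into taxon-A site
#'   frequencies at the focal site, in [0, 1] (default 0.4).
#' @param lambda_km Exponential decay length of the cline with distance to
#'   the focal site (default 150 km).
#' @param rate_f1,rate_migrant,rate_backcross Injection rates per taxon
#'   sample, named vectors over the two taxa. Defaults: F1 at 0.015 in
#'   taxon A's host sample, migrants at 0.003 in taxon B's, no backcrosses.
#' @param missing_rate Per-call missing-data rate (default 0.02).
#' @param site_drift Within-taxon site-level drift parameter (second-level
#'   Balding-Nichols F; 0 = sites share their taxon's frequencies,
#'   default 0).
#' @param taxa Labels of the two taxa (default `c("A", "B")`; taxon A is
#'   the cline-bearing, introduced-like taxon).
#' @param seed Integer seed fixed into the config; `NULL` = use the
#'   current RNG state.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 19L, alleles_per_locus = 8L,
                       divergence_F = 0.15, n_sites = 9L,
                       n_per_population = 30L,
                       introgressed_fraction = 7 / 19,
                       alpha_max = 0.4, lambda_km = 150,
                       rate_f1 = c(A = 0.015, B = 0),
                       rate_migrant = c(A = 0, B = 0.003),
                       rate_backcross = c(A = 0, B = 0),
                       missing_rate = 0.02, site_drift = 0,
                       taxa = c("A", "B"), seed = NULL) {
  stopifnot(divergence_F > 0, divergence_F < 1,
            alpha_max >= 0, alpha_max <= 1, lambda_km > 0,
            length(taxa) == 2, n_sites >= 1, n_loci >= 1)
  fix_rate <- function(r) {
    if (is.null(names(r))) names(r) <- taxa
    r <- r[taxa]; r[is.na(r)] <- 0
    names(r) <- taxa
    r
  }
  rate_f1 <- fix_rate(rate_f1); rate_migrant <- fix_rate(rate_migrant)
  rate_backcross <- fix_rate(rate_backcross)
  tot <- rate_f1 + rate_migrant + rate_backcross
  if (any(c(rate_f1, rate_migrant, rate_backcross) < 0) || any(tot >= 1))
    stop("class rates must be in [0,1) and sum to < 1 per taxon")
  if (length(n_per_population) == 1L)
    n_per_population <- rep(n_per_population, n_sites)
  if (length(n_per_population) != n_sites)
    stop("n_per_population must be scalar or length n_sites")
  structure(list(
    n_loci = as.integer(n_loci), alleles_per_locus = as.integer(alleles_per_locus),
    divergence_F = divergence_F, n_sites = as.integer(n_sites),
    n_per_population = as.integer(n_per_population),
    introgressed_fraction = introgressed_fraction,
    alpha_max = alpha_max, lambda_km = lambda_km,
    rate_f1 = rate_f1, rate_migrant = rate_migrant,
    rate_backcross = rate_backcross,
    missing_rate = missing_rate, site_drift = site_drift,
    taxa = taxa, seed = seed
  ), class = "sim_config")
}

#' Default transect geography for the simulator
#'
#' Nine (or `n_sites`) paired sites on an east-west line at ~40 km spacing
#' (about the study's inter-site scale), both members of a pair co-located;
#' the focal site is the taxon-A site of the last pair.
#'
#' @param config A [sim_config()].
#' @return Site-geography data frame (site, lat, lon, pair, species) with
#'   the focal site id in `attr(, "focal_site")`.
#' @export
default_geography <- function(config) {
  lat <- 46
  # ~40 km spacing: 1 deg lon at lat 46 is ~77.2 km
  lons <- -122.4 + (seq_len(config$n_sites) - 1L) * (40 / (111.195 * cospi(lat / 180)))
  geo <- do.call(rbind, lapply(seq_len(config$n_sites), function(i) {
    data.frame(
      site = paste0(config$taxa, i),
      lat = lat, lon = lons[i],
      pair = paste0("P", i),
      species = config$taxa,
      stringsAsFactors = FALSE
    )
  }))
  attr(geo, "focal_site") <- paste0(config$taxa[1], config$n_sites)
  geo
}

# internal: one Dirichlet draw
rdirichlet1 <- function(alpha) {
  if (any(alpha <= 0)) stop("Dirichlet parameters must be positive")
  g <- stats::rgamma(length(alpha), shape = alpha)
  s <- sum(g)
  if (s == 0) { g[which.max(alpha)] <- 1; s <- 1 }  # extreme underflow guard
  stats::setNames(g / s, names(alpha))
}

#' Simulate per-site allele frequencies under Balding-Nichols divergence
#'
#' Per locus: ancestral frequencies ~ symmetric Dirichlet(1); each taxon's
#' base frequencies ~ Dirichlet(p (1-F)/F) independently (Balding-Nichols,
#' F = `divergence_F`). A random subset of loci (fraction
#' `introgressed_fraction`) carries a cline: taxon-A site frequencies are
#' (1 - alpha_s) pA + alpha_s pB with alpha_s = alpha_max exp(-d_s /
#' lambda_km), d_s the site's distance to the focal site. Other loci, and
#' all taxon-B sites, use the taxon base frequencies, optionally perturbed
#' by site-level drift (`site_drift` > 0).
#'
#' @param config A [sim_config()].
#' @param geo Site geography (default [default_geography()]).
#' @param focal_site Focal site id (default the geography's attribute).
#' @return List with `site_freqs` (site -> locus -> named frequency
#'   vector), `taxon_freqs` (taxon base frequencies), `loci` (locus table
#'   with linkage groups), `truth` (introgressed flags, per-site alpha),
#'   `geo`, `focal_site`.
#' @export
simulate_frequencies <- function(config, geo = default_geography(config),
                                 focal_site = attr(geo, "focal_site")) {
  if (!is.null(config$seed)) set.seed(config$seed)
  K <- config$alleles_per_locus
  allele_labels <- as.character(100L + 2L * seq_len(K))  # fragment lengths
  L <- config$n_loci
  loci <- data.frame(
    name = paste0("p", seq_len(L)),
    linkage_group = ((seq_len(L) - 1L) %% 5L) + 1L,
    stringsAsFactors = FALSE
  )
  F <- config$divergence_F
  n_intro <- round(config$introgressed_fraction * L)
  introgressed <- seq_len(L) %in% sample.int(L, n_intro)
  taxon_freqs <- list()
  ancestral <- vector("list", L)
  for (l in seq_len(L)) {
    ancestral[[l]] <- rdirichlet1(stats::setNames(rep(1, K), allele_labels))
  }
  for (t in config$taxa) {
    taxon_freqs[[t]] <- lapply(seq_len(L), function(l)
      rdirichlet1(ancestral[[l]] * (1 - F) / F))
    names(taxon_freqs[[t]]) <- loci$name
  }
  f_row <- match(focal_site, geo$site)
  if (is.na(f_row)) stop("focal site '", focal_site, "' not in geography")
  site_freqs <- list()
  alpha_s <- stats::setNames(numeric(config$n_sites), unique(geo$pair))
  for (i in seq_len(nrow(geo))) {
    s <- geo$site[i]; t <- geo$species[i]
    d <- geo_distance(geo$lat[i], geo$lon[i], geo$lat[f_row], geo$lon[f_row])
    alpha <- config$alpha_max * exp(-d / config$lambda_km)
    if (t == config$taxa[1]) alpha_s[geo$pair[i]] <- alpha
    fl <- vector("list", L); names(fl) <- loci$name
    for (l in seq_len(L)) {
      base <- if (t == config$taxa[1] && introgressed[l]) {
        (1 - alpha) * taxon_freqs[[config$taxa[1]]][[l]] +
          alpha * taxon_freqs[[config$taxa[2]]][[l]]
      } else {
        taxon_freqs[[t]][[l]]
      }
      if (config$site_drift > 0) {
        d2 <- config$site_drift
        base <- rdirichlet1(pmax(base, 1e-12) * (1 - d2) / d2)
      }
      fl[[l]] <- base
    }
    site_freqs[[s]] <- fl
  }
  list(
    site_freqs = site_freqs, taxon_freqs = taxon_freqs, loci = loci,
    truth = list(introgressed = stats::setNames(introgressed, loci$name),
                 alpha = alpha_s),
    geo = geo, focal_site = focal_site
  )
}

# internal: draw one gamete (allele label) from a frequency vector
rgamete <- function(freq, n = 1L) {
  as.integer(sample(names(freq), n, replace = TRUE, prob = freq))
}

#' Sample a genotype dataset from simulated frequencies
#'
#' Draws `n_per_population` diploids per (site x taxon) population. Each
#' individual's true ancestry class is drawn from the config's injection
#' rates (or fixed to exact counts with `exact_counts = TRUE`, which plants
#' `round(rate * N)` individuals of each non-pure class per taxon): pure
#' residents are Hardy-Weinberg draws from their site x taxon frequencies;
#' F1s take one gamete from each taxon's frequencies at the site's pair;
#' migrants are pure draws from the opposite taxon's frequencies but keep
#' the natal host (species) label; backcrosses draw gametes from
#' (natal, (natal + other)/2). Calls are masked missing independently at
#' `missing_rate`.
#'
#' @param sim Result of [simulate_frequencies()].
#' @param config The same [sim_config()].
#' @param exact_counts Plant deterministic class counts instead of
#'   per-individual multinomial draws.
#' @return List with `dataset` (a [genotype_dataset()] with species and
#'   pair labels set) and `truth` (data frame: id, site, species, pair,
#'   true_class).
#' @export
sample_dataset <- function(sim, config, exact_counts = FALSE) {
  geo <- sim$geo
  L <- config$n_loci
  taxa <- config$taxa
  ind <- list(); a1 <- list(); a2 <- list(); true_class <- list()
  # per taxon: flatten individuals across sites, then assign classes
  for (t in taxa) {
    sites <- geo$site[geo$species == t]
    pairs <- geo$pair[geo$species == t]
    ns <- config$n_per_population
    N <- sum(ns)
    cls <- rep("pure_natal", N)
    rates <- c(F1 = unname(config$rate_f1[t]),
               pure_nonnatal = unname(config$rate_migrant[t]),
               backcross_natal = unname(config$rate_backcross[t]))
    if (exact_counts) {
      counts <- round(rates * N)
      if (sum(counts) > N) stop("requested hybrid counts exceed sample size")
      slots <- sample.int(N, sum(counts))
      cls[slots] <- rep(names(counts), counts)
    } else {
      probs <- c(1 - sum(rates), rates)
      cls <- sample(c("pure_natal", names(rates)), N, replace = TRUE,
                    prob = probs)
    }
    site_vec <- rep(sites, ns)
    pair_vec <- rep(pairs, ns)
    A1 <- matrix(NA_integer_, N, L); A2 <- matrix(NA_integer_, N, L)
    other <- setdiff(taxa, t)
    for (i in seq_len(N)) {
      s_nat <- site_vec[i]
      s_oth <- geo$site[geo$pair == pair_vec[i] & geo$species == other]
      for (l in seq_len(L)) {
        fN <- sim$site_freqs[[s_nat]][[l]]
        fO <- sim$site_freqs[[s_oth]][[l]]
        g <- switch(cls[i],
          pure_natal = rgamete(fN, 2L),
          pure_nonnatal = rgamete(fO, 2L),
          F1 = c(rgamete(fN), rgamete(fO)),
          backcross_natal = c(rgamete(fN), rgamete((fN + fO) / 2))
        )
        A1[i, l] <- g[1]; A2[i, l] <- g[2]
      }
    }
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(N * L) < config$missing_rate, N, L)
      A1[mask] <- NA_integer_; A2[mask] <- NA_integer_
    }
    ord <- order(match(site_vec, sites))  # group by site for tidy output
    ids <- paste0(site_vec[ord], "_",
                  stats::ave(seq_len(N), site_vec[ord], FUN = seq_along))
    ind[[t]] <- data.frame(id = ids, site = site_vec[ord], species = t,
                           pair = pair_vec[ord], stringsAsFactors = FALSE)
    a1[[t]] <- A1[ord, , drop = FALSE]
    a2[[t]] <- A2[ord, , drop = FALSE]
    true_class[[t]] <- cls[ord]
  }
  ind_all <- do.call(rbind, ind)
  dataset <- genotype_dataset(do.call(rbind, a1), do.call(rbind, a2),
                              ind_all, sim$loci)
  truth <- cbind(ind_all, data.frame(true_class = unlist(true_class),
                                     stringsAsFactors = FALSE))
  rownames(truth) <- NULL
  list(dataset = dataset, truth = truth)
}

#' Simulate a complete two-taxon paired-site study
#'
#' Convenience wrapper: [simulate_frequencies()] then [sample_dataset()].
#' Fixing `config$seed` makes the whole result — and any files written from
#' it — fully reproducible.
#'
#' @param config A [sim_config()].
#' @param exact_counts See [sample_dataset()].
#' @return List: `dataset`, `truth` (per-individual true classes),
#'   `freq_truth` (introgressed loci, per-site alpha), `site_freqs`,
#'   `taxon_freqs`, `geo`, `focal_site`.
#' @export
simulate_study <- function(config = sim_config(), exact_counts = FALSE) {
  sim <- simulate_frequencies(config)
  samp <- sample_dataset(sim, config, exact_counts = exact_counts)
  list(dataset = samp$dataset, truth = samp$truth,
       freq_truth = sim$truth, site_freqs = sim$site_freqs,
       taxon_freqs = sim$taxon_freqs, geo = sim$geo,
       focal_site = sim$focal_site)
}

#' Hudson-type FST between the two taxa from their base frequencies
#'
#' Ratio-of-averages estimator over loci: 1 - mean(Hw) / mean(Hb), with
#' Hw the average within-taxon gene diversity and Hb the between-taxon
#' heterozygosity at each locus. Used to check that the realized divergence
#' of a simulation matches the Balding-Nichols target.
#'
#' @param taxon_freqs Two-element list of per-locus frequency vectors
#'   (e.g. `simulate_study(...)$taxon_freqs`).
#' @return FST estimate.
#' @export
realized_fst <- function(taxon_freqs) {
  stopifnot(length(taxon_freqs) == 2)
  fa <- taxon_freqs[[1]]; fb <- taxon_freqs[[2]]
  hw <- hb <- numeric(length(fa))
  for (l in seq_along(fa)) {
    pa <- fa[[l]]; pb <- fb[[l]]
    hw[l] <- 1 - (sum(pa^2) + sum(pb^2)) / 2
    hb[l] <- 1 - sum(pa * pb)
  }
  1 - mean(hw) / mean(hb)
}
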