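#' Total-variation distance between two allele frequency vectors
#'
#' The per-locus "allele frequency difference" between co-occurring
#' populations of the two taxa: half the sum of absolute frequency
#' differences over the union allele set. Bounded in [0, 1]; 0 for
#' identical frequencies, 1 for disjoint allele sets.
#'
#' @param pA,pB Named numeric frequency vectors (names = allele labels).
#' @return Real in [0, 1].
#' @export
freq_difference <- function(pA, pB) {
  union <- union(names(pA), names(pB))
  fA <- stats::setNames(numeric(length(union)), union)
  fB <- fA
  fA[names(pA)] <- pA
  fB[names(pB)] <- pB
  0.5 * sum(abs(fA - fB))
}

#' Great-circle distance between two points, in km
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance in km.
#' @export
geo_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of range: |lat| <= 90, |lon| <= 180")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088) # km
}

#' Per-paired-site divergence between the two taxa
#'
#' For each paired site, computes the per-locus total-variation allele
#' frequency difference between the taxon-A and taxon-B samples, the mean
#' over the loci scored in both samples at that pair, and the great-circle
#' distance (km) from the pair (midpoint of its two sites) to the focal
#' site. Climate covariate columns present in `geo` are averaged over the
#' pair's sites and carried along.
#'
#' @param dataset A `genotype_dataset` with species labels.
#' @param geo Site-geography table ([read_site_table()]).
#' @param focal_site Site id of the focal site toward which introgression
#'   is hypothesized; defines the distance axis of the cline.
#' @return List with `per_locus` (pairs x loci matrix of differences, `NA`
#'   where a locus is unscored in either member), `summary` (data frame:
#'   pair, mean_difference, n_loci, distance_km, covariates...).
#' @export
paired_site_divergence <- function(dataset, geo, focal_site) {
  dataset <- attach_geography(dataset, geo)
  require_species(dataset)
  taxa <- two_taxa(dataset)
  if (!(focal_site %in% geo$site))
    stop("focal site '", focal_site, "' not in geography table")
  freqs <- allele_frequencies(dataset, "site")
  site_of <- function(pr, tx) {
    s <- geo$site[geo$pair == pr & geo$species == tx]
    if (length(s) != 1L)
      stop("pair '", pr, "' does not have exactly one site of taxon '", tx, "'")
    s
  }
  pairs <- unique(geo$pair[geo$site %in% dataset$ind$site])
  loci <- dataset$loci$name
  per_locus <- matrix(NA_real_, length(pairs), length(loci),
                      dimnames = list(pairs, loci))
  f_row <- match(focal_site, geo$site)
  covars <- setdiff(names(geo), c("site", "lat", "lon", "pair", "species"))
  summary <- data.frame(pair = pairs, mean_difference = NA_real_,
                        n_loci = 0L, distance_km = NA_real_,
                        stringsAsFactors = FALSE)
  for (cv in covars) summary[[cv]] <- NA_real_
  for (k in seq_along(pairs)) {
    sA <- site_of(pairs[k], taxa[1])
    sB <- site_of(pairs[k], taxa[2])
    for (l in loci) {
      fA <- freqs$freq[[sA]][[l]]
      fB <- freqs$freq[[sB]][[l]]
      if (!length(fA) || !length(fB)) next
      per_locus[k, l] <- freq_difference(fA, fB)
    }
    scored <- !is.na(per_locus[k, ])
    summary$n_loci[k] <- sum(scored)
    summary$mean_difference[k] <- mean(per_locus[k, scored])
    rows <- match(c(sA, sB), geo$site)
    summary$distance_km[k] <- geo_distance(
      mean(geo$lat[rows]), mean(geo$lon[rows]),
      geo$lat[f_row], geo$lon[f_row])
    for (cv in covars) summary[[cv]][k] <- mean(geo[[cv]][rows], na.rm = TRUE)
  }
  list(per_locus = per_locus, summary = summary, taxa = taxa)
}

#' Pearson correlation of divergence on distance to the focal site
#'
#' @param divergence Result of [paired_site_divergence()].
#' @param per_locus Also return per-locus correlations.
#' @return If `per_locus`, a data frame (locus, r) with a final row
#'   `"all_loci"` for the mean-difference statistic; otherwise the overall
#'   r alone. Zero variance in either variable yields `NA`.
#' @export
cline_regression <- function(divergence, per_locus = TRUE) {
  s <- divergence$summary
  if (nrow(s) < 3) stop("cline regression needs >= 3 paired sites")
  safe_cor <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) return(NA_real_)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }
  overall <- safe_cor(s$mean_difference, s$distance_km)
  if (!per_locus) return(overall)
  loci <- colnames(divergence$per_locus)
  r <- vapply(loci, function(l)
    safe_cor(divergence$per_locus[, l], s$distance_km), numeric(1))
  rbind(data.frame(locus = loci, r = unname(r), stringsAsFactors = FALSE),
        data.frame(locus = "all_loci", r = overall, stringsAsFactors = FALSE))
}

# internal: fast permutation machinery. Encodes each species' individuals as
# a dosage matrix over all (locus, allele) columns so per-site frequencies
# under any site relabeling are a single rowsum.
build_perm_data <- function(dataset, geo, focal_site) {
  dataset <- attach_geography(dataset, geo)
  require_species(dataset)
  taxa <- two_taxa(dataset)
  loci <- dataset$loci$name
  union <- lapply(seq_along(loci), function(l) {
    u <- sort(unique(c(dataset$a1[, l], dataset$a2[, l])))
    u[!is.na(u)]
  })
  ncols <- vapply(union, length, integer(1))
  col_locus <- rep(seq_along(loci), ncols)
  offset <- c(0L, cumsum(ncols))
  enc <- function(rows) {
    M <- matrix(0, length(rows), sum(ncols))
    S <- matrix(0, length(rows), length(loci))
    for (l in seq_along(loci)) {
      a1 <- dataset$a1[rows, l]; a2 <- dataset$a2[rows, l]
      ok <- !is.na(a1)
      S[ok, l] <- 1
      if (!any(ok)) next
      i1 <- match(a1[ok], union[[l]]) + offset[l]
      i2 <- match(a2[ok], union[[l]]) + offset[l]
      idx <- which(ok)
      M[cbind(idx, i1)] <- M[cbind(idx, i1)] + 1
      M[cbind(idx, i2)] <- M[cbind(idx, i2)] + 1
    }
    list(M = M, S = S)
  }
  per_taxon <- list()
  for (t in taxa) {
    rows <- which(dataset$ind$species == t)
    e <- enc(rows)
    per_taxon[[t]] <- list(M = e$M, S = e$S,
                           pair = dataset$ind$pair[rows])
  }
  pairs <- sort(unique(dataset$ind$pair))
  # distance of each pair to the focal site (midpoint of its two sites)
  f_row <- match(focal_site, geo$site)
  dist_km <- vapply(pairs, function(pr) {
    rows <- which(geo$pair == pr & geo$site %in% dataset$ind$site)
    geo_distance(mean(geo$lat[rows]), mean(geo$lon[rows]),
                 geo$lat[f_row], geo$lon[f_row])
  }, numeric(1))
  list(per_taxon = per_taxon, taxa = taxa, pairs = pairs,
       dist_km = dist_km, col_locus = col_locus, n_loci = length(loci),
       loci = loci)
}

# internal: per-locus and overall cline r for given pair assignments
perm_stat <- function(pd, pairA, pairB) {
  tA <- pd$per_taxon[[pd$taxa[1]]]; tB <- pd$per_taxon[[pd$taxa[2]]]
  fA <- rowsum(tA$M, pairA)[pd$pairs, , drop = FALSE]
  fB <- rowsum(tB$M, pairB)[pd$pairs, , drop = FALSE]
  nA <- rowsum(tA$S, pairA)[pd$pairs, , drop = FALSE]
  nB <- rowsum(tB$S, pairB)[pd$pairs, , drop = FALSE]
  # frequencies: divide each (pair, allele) count by 2 * scored at its locus
  fA <- fA / (2 * nA[, pd$col_locus, drop = FALSE])
  fB <- fB / (2 * nB[, pd$col_locus, drop = FALSE])
  adiff <- abs(fA - fB)
  tv <- matrix(NA_real_, length(pd$pairs), pd$n_loci)
  for (l in seq_len(pd$n_loci)) {
    cols <- which(pd$col_locus == l)
    tv[, l] <- 0.5 * rowSums(adiff[, cols, drop = FALSE])
  }
  mean_tv <- rowMeans(tv, na.rm = TRUE)
  safe_cor <- function(y) {
    ok <- is.finite(y)
    if (sum(ok) < 3 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(y[ok], pd$dist_km[ok])
  }
  c(vapply(seq_len(pd$n_loci), function(l) safe_cor(tv[, l]), numeric(1)),
    safe_cor(mean_tv))
}

#' Permutation test for clinal convergence toward the focal site
#'
#' Tests, per locus and for the across-loci mean, whether the between-taxon
#' allele frequency difference at paired sites declines with proximity to
#' the focal site more strongly than chance allows. The observed statistic
#' is the Pearson r of difference on distance-to-focal. The null is built by
#' randomly reassigning individuals among the paired sites within each
#' species (preserving per-site sample sizes) and recomputing frequencies,
#' differences and r. One-tailed p for a positive r:
#' p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm).
#'
#' @param dataset A `genotype_dataset`.
#' @param geo Site-geography table.
#' @param focal_site Focal site id.
#' @param n_perm Number of permutations (>= 99); default 9999.
#' @param seed Optional integer seed.
#' @return Data frame of class `cline_test` (locus, linkage_group, r, p,
#'   final row `all_loci`), with `n_perm` and `seed` attributes.
#' @export
cline_permutation_test <- function(dataset, geo, focal_site, n_perm = 9999L,
                                   seed = NULL) {
  if (n_perm < 99L) stop("use n_perm >= 99")
  if (!is.null(seed)) set.seed(seed)
  pd <- build_perm_data(dataset, geo, focal_site)
  pairA0 <- pd$per_taxon[[pd$taxa[1]]]$pair
  pairB0 <- pd$per_taxon[[pd$taxa[2]]]$pair
  obs <- perm_stat(pd, pairA0, pairB0)
  count <- integer(length(obs))
  for (b in seq_len(n_perm)) {
    rb <- perm_stat(pd, sample(pairA0), sample(pairB0))
    count <- count + (!is.na(rb) & !is.na(obs) & rb >= obs)
  }
  p <- (1 + count) / (1 + n_perm)
  p[is.na(obs)] <- NA_real_
  lg <- c(dataset$loci$linkage_group, NA_integer_)
  out <- data.frame(
    locus = c(pd$loci, "all_loci"),
    linkage_group = lg,
    r = obs, p = p,
    stringsAsFactors = FALSE
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("cline_test", "data.frame")
  out
}

#' Correlation of mean divergence with a climate covariate
#'
#' @param divergence Result of [paired_site_divergence()] built from a
#'   geography table that carries the covariate column.
#' @param covariate Covariate column name (e.g. `"precip_jul_oct"`).
#' @return Pearson r (NA if either variable has zero variance).
#' @export
covariate_correlation <- function(divergence, covariate) {
  s <- divergence$summary
  if (!covariate %in% names(s))
    stop("covariate '", covariate, "' not present for these sites")
  if (anyNA(s[[covariate]]))
    stop("covariate '", covariate, "' missing for some sites")
  if (stats::sd(s[[covariate]]) == 0 || stats::sd(s$mean_difference) == 0)
    return(NA_real_)
  stats::cor(s$mean_difference, s[[covariate]])
}
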