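# internal: checks + lower-triangle vector of a labelled distance matrix
check_dm <- function(dm, name) {
  dm <- as.matrix(dm)
  if (is.null(rownames(dm))) stop(name, " needs dimnames")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-10)))
    stop(name, " is not symmetric")
  if (any(abs(diag(dm)) > 1e-12)) stop(name, " has a nonzero diagonal")
  dm
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal (lower-triangle) entries, with a
#' one-tailed permutation p-value: rows and columns of `dmA` are permuted
#' jointly and p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm).
#'
#' @param dmA,dmB Symmetric distance matrices with identical labels in
#'   identical order.
#' @param n_perm Number of permutations; default 9999.
#' @param seed Optional integer seed.
#' @return List with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(dmA, dmB, n_perm = 9999L, seed = NULL) {
  dmA <- check_dm(dmA, "dmA"); dmB <- check_dm(dmB, "dmB")
  if (!identical(rownames(dmA), rownames(dmB)))
    stop("dmA and dmB have mismatched labels")
  if (!is.null(seed)) set.seed(seed)
  lt <- lower.tri(dmA)
  b <- dmB[lt]
  r_obs <- stats::cor(dmA[lt], b)
  count <- 0L
  n <- nrow(dmA)
  for (k in seq_len(n_perm)) {
    idx <- sample(n)
    rp <- stats::cor(dmA[idx, idx][lt], b)
    if (!is.na(rp) && rp >= r_obs) count <- count + 1L
  }
  list(r = r_obs, p = (1 + count) / (1 + n_perm), n_perm = n_perm)
}

#' Partial Mantel test
#'
#' Correlates the residuals of `dmA` and `dmB` after linear regression of
#' each on `dmC` (Smouse-Long-Sokal). The permutation null permutes the
#' labels of the residual matrix of `dmA`; p is one-tailed on r >= r_obs
#' with the add-one convention. When `dmC` explains `dmB` exactly (zero
#' residual variance) the partial correlation is reported as 0.
#'
#' @inheritParams mantel_test
#' @param dmC Conditioning distance matrix.
#' @return List with `r`, `p`, `n_perm`.
#' @export
partial_mantel_test <- function(dmA, dmB, dmC, n_perm = 9999L, seed = NULL) {
  dmA <- check_dm(dmA, "dmA"); dmB <- check_dm(dmB, "dmB")
  dmC <- check_dm(dmC, "dmC")
  if (!identical(rownames(dmA), rownames(dmB)) ||
      !identical(rownames(dmA), rownames(dmC)))
    stop("matrices have mismatched labels")
  if (!is.null(seed)) set.seed(seed)
  lt <- lower.tri(dmA)
  a <- dmA[lt]; b <- dmB[lt]; cc <- dmC[lt]
  res_a <- stats::resid(stats::lm(a ~ cc))
  res_b <- stats::resid(stats::lm(b ~ cc))
  tol <- 1e-12
  if (stats::sd(res_b) < tol || stats::sd(res_a) < tol)
    return(list(r = 0, p = 1, n_perm = n_perm))
  r_obs <- stats::cor(res_a, res_b)
  # residuals of dmA put back in matrix form for label permutation
  RA <- matrix(0, nrow(dmA), nrow(dmA))
  RA[lt] <- res_a
  RA <- RA + t(RA)
  count <- 0L
  n <- nrow(dmA)
  for (k in seq_len(n_perm)) {
    idx <- sample(n)
    rp <- stats::cor(RA[idx, idx][lt], res_b)
    if (!is.na(rp) && rp >= r_obs) count <- count + 1L
  }
  list(r = r_obs, p = (1 + count) / (1 + n_perm), n_perm = n_perm)
}

#' Binary species-identity distance matrix
#'
#' 0 within a species, 1 between species — the conditioning matrix of the
#' partial Mantel isolation-by-distance analysis.
#'
#' @param species Named character vector: population label -> species.
#' @return Symmetric 0/1 matrix with zero diagonal.
#' @export
species_distance_matrix <- function(species) {
  dm <- outer(species, species, FUN = function(a, b) as.numeric(a != b))
  dimnames(dm) <- list(names(species), names(species))
  dm
}

#' Geographic distance matrix between sites, in km
#'
#' @param geo Site-geography table; rows define the label order.
#' @param sites Optional subset/order of site ids.
#' @return Symmetric haversine distance matrix (km).
#' @export
geo_distance_matrix <- function(geo, sites = NULL) {
  if (is.null(sites)) sites <- geo$site
  idx <- match(sites, geo$site)
  if (anyNA(idx)) stop("unknown site(s): ", paste(sites[is.na(idx)], collapse = ", "))
  n <- length(sites)
  dm <- matrix(0, n, n, dimnames = list(sites, sites))
  for (i in seq_len(n)) {
    dm[i, ] <- geo_distance(geo$lat[idx[i]], geo$lon[idx[i]],
                            geo$lat[idx], geo$lon[idx])
  }
  dm[abs(dm) < 1e-9] <- 0
  (dm + t(dm)) / 2
}
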