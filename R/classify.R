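ANCESTRY_CLASSES <- c("pure_natal", "pure_nonnatal", "F1",
                      "backcross_natal", "backcross_nonnatal")

#' Genotype probability under a hybrid ancestry class
#'
#' Each ancestry class corresponds to a pair of gamete allele distributions
#' built from the natal-taxon (`pN`) and non-natal-taxon (`pO`) reference
#' frequencies at a locus:
#' pure natal (pN, pN); pure non-natal (pO, pO); F1 (pN, pO);
#' backcross into natal (pN, (pN+pO)/2); backcross into non-natal
#' (pO, (pN+pO)/2). The probability of an unordered genotype \{x, y\} is
#' q1(x) q2(y) + q1(y) q2(x) for x != y and q1(x) q2(x) for x == y.
#'
#' @param genotype Integer vector of length 2 (unordered allele pair).
#' @param pN,pO Named numeric vectors: strictly positive (smoothed)
#'   frequencies over the same union allele set.
#' @param class One of `"pure_natal"`, `"pure_nonnatal"`, `"F1"`,
#'   `"backcross_natal"`, `"backcross_nonnatal"`.
#' @return Probability of the genotype under the class.
#' @export
class_genotype_probability <- function(genotype, pN, pO, class) {
  class <- match.arg(class, ANCESTRY_CLASSES)
  x <- as.character(genotype[1]); y <- as.character(genotype[2])
  if (!(x %in% names(pN)) || !(y %in% names(pN)) ||
      !(x %in% names(pO)) || !(y %in% names(pO)))
    stop("allele absent from the union allele set; apply Dirichlet ",
         "smoothing over the dataset-wide union before classifying")
  mix <- (pN + pO) / 2
  q <- switch(class,
    pure_natal = list(pN, pN),
    pure_nonnatal = list(pO, pO),
    F1 = list(pN, pO),
    backcross_natal = list(pN, mix),
    backcross_nonnatal = list(pO, mix)
  )
  p <- if (x == y) q[[1]][x] * q[[2]][x]
  else q[[1]][x] * q[[2]][y] + q[[1]][y] * q[[2]][x]
  unname(p)
}

# internal: smoothed reference frequencies from count tables.
# counts: named integer vector (may miss alleles); union: character vector.
smooth_freqs <- function(counts, union, lambda = NULL) {
  K <- length(union)
  lam <- if (is.null(lambda)) 1 / K else lambda
  full <- stats::setNames(numeric(K), union)
  full[names(counts)] <- as.numeric(counts)
  (full + lam) / (sum(full) + lam * K)
}

#' Supervised genotype-class classification of individuals
#'
#' Assigns each individual a posterior probability over the five ancestry
#' classes (pure natal, pure non-natal, F1, backcross into natal, backcross
#' into non-natal), treating its sampling host as the natal taxon.
#' Reference allele frequencies for the two taxa are estimated from the
#' sampled individuals — per paired site by default, or pooled across all
#' sites of a taxon — with Dirichlet smoothing over the dataset-wide union
#' allele set so all class likelihoods are positive. Per-locus class
#' likelihoods are multiplied across non-missing loci (in log space) and
#' combined with the prior P(pure natal) = 1 - nu, the remaining nu split
#' equally over the four non-resident classes.
#'
#' With `leave_one_out = TRUE` an individual's own two alleles are removed
#' from its natal reference counts before smoothing, which removes the
#' self-assignment bias of small reference samples.
#'
#' @param dataset A `genotype_dataset` with species (and, unless
#'   `pool = TRUE`, pair) labels attached.
#' @param nu Prior migration rate in (0, 1); default 0.01.
#' @param lambda Dirichlet pseudo-count per allele; `NULL` = 1/K.
#' @param pool If `TRUE`, references are pooled across all populations of a
#'   taxon instead of per paired site.
#' @param leave_one_out Remove each individual's alleles from its natal
#'   reference before classifying it.
#' @return Data frame of class `class_posterior`: one row per individual
#'   with id, site, species, pair, the five posterior columns, `class`
#'   (argmax; ties resolved to pure natal), `n_loci_used`,
#'   `n_loci_missing`. Individuals with no scored locus get `NA` posteriors
#'   and class `NA`; their count is in `attr(, "n_unclassified")`.
#' @export
classify <- function(dataset, nu = 0.01, lambda = NULL, pool = FALSE,
                     leave_one_out = FALSE) {
  stopifnot(nu > 0, nu < 1)
  require_species(dataset)
  taxa <- two_taxa(dataset)
  if (!pool && anyNA(dataset$ind$pair))
    stop("per-pair references need pair labels; attach_geography() or use pool = TRUE")

  L <- n_loci(dataset)
  groups <- if (pool) dataset$ind$species else
    paste(dataset$ind$pair, dataset$ind$species, sep = ":")
  ct <- allele_count_tables(dataset, groups)
  union <- lapply(ct$union, as.character)

  prior <- c(1 - nu, rep(nu / 4, 4))
  log_prior <- log(prior)

  n_ind <- n_individuals(dataset)
  post <- matrix(NA_real_, n_ind, 5L, dimnames = list(NULL, ANCESTRY_CLASSES))
  n_used <- integer(n_ind); n_missing <- integer(n_ind)

  for (i in seq_len(n_ind)) {
    natal <- dataset$ind$species[i]
    other <- setdiff(taxa, natal)
    gN <- if (pool) natal else paste(dataset$ind$pair[i], natal, sep = ":")
    gO <- if (pool) other else paste(dataset$ind$pair[i], other, sep = ":")
    if (!(gO %in% names(ct$counts)))
      stop("no reference sample for taxon '", other, "' at pair '",
           dataset$ind$pair[i], "'")
    ll <- numeric(5)
    used <- 0L
    for (l in seq_len(L)) {
      x <- dataset$a1[i, l]
      if (is.na(x)) next
      y <- dataset$a2[i, l]
      cN <- ct$counts[[gN]][[l]]
      if (leave_one_out) {
        cN <- cN - (names(cN) == as.character(x)) - (names(cN) == as.character(y))
        if (any(cN < 0)) stop("internal error: negative leave-one-out count")
      }
      pN <- smooth_freqs(cN, union[[l]], lambda)
      pO <- smooth_freqs(ct$counts[[gO]][[l]], union[[l]], lambda)
      for (k in seq_along(ANCESTRY_CLASSES)) {
        ll[k] <- ll[k] + log(class_genotype_probability(
          c(x, y), pN, pO, ANCESTRY_CLASSES[k]))
      }
      used <- used + 1L
    }
    n_used[i] <- used
    n_missing[i] <- L - used
    if (used == 0L) next
    lp <- log_prior + ll
    lp <- lp - max(lp)
    post[i, ] <- exp(lp) / sum(exp(lp))
  }

  cls <- rep(NA_character_, n_ind)
  scored <- n_used > 0L
  # argmax with ties resolved to pure_natal (column 1 wins ties by order)
  cls[scored] <- ANCESTRY_CLASSES[apply(post[scored, , drop = FALSE], 1, which.max)]

  out <- data.frame(
    id = dataset$ind$id, site = dataset$ind$site,
    species = dataset$ind$species, pair = dataset$ind$pair,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(post))
  out$class <- cls
  out$n_loci_used <- n_used
  out$n_loci_missing <- n_missing
  attr(out, "n_unclassified") <- sum(!scored)
  attr(out, "nu") <- nu
  class(out) <- c("class_posterior", "data.frame")
  out
}

#' Per-generation hybridization and migration rates from class counts
#'
#' For a sample of N flies from one host: the hybridization rate is
#' (number of F1 hybrids) / N and the migration rate into that host's taxon
#' is (number of pure non-natal migrant genotypes + half the number of F1
#' hybrids) / N.
#'
#' @param n_f1 Number of F1-classified individuals in the sample.
#' @param n_migrant Number of pure non-natal (migrant) genotypes.
#' @param n_total Total individuals scored (> 0).
#' @return List with `hybridization` and `migration` (per generation).
#' @export
hybrid_migration_rates <- function(n_f1, n_migrant, n_total) {
  if (n_total <= 0) stop("empty sample: rates undefined")
  if (n_f1 < 0 || n_migrant < 0 || n_f1 + n_migrant > n_total)
    stop("inconsistent class counts")
  list(hybridization = n_f1 / n_total,
       migration = (n_migrant + n_f1 / 2) / n_total)
}

#' Hybridization and migration rates per taxon sample
#'
#' Applies [hybrid_migration_rates()] to the argmax class calls of a
#' [classify()] result, separately for each taxon's host sample. The
#' migration rate reported for a taxon's sample is gene flow *into* that
#' taxon (from the other host).
#'
#' @param posteriors A `class_posterior` data frame from [classify()].
#' @return Data frame: taxon, n, n_f1, n_migrant, hybridization, migration.
#' @export
estimate_rates <- function(posteriors) {
  taxa <- sort(unique(posteriors$species))
  do.call(rbind, lapply(taxa, function(t) {
    s <- posteriors[posteriors$species == t & !is.na(posteriors$class), ]
    if (nrow(s) == 0L) stop("empty sample for taxon '", t, "'")
    n_f1 <- sum(s$class == "F1")
    n_mig <- sum(s$class == "pure_nonnatal")
    r <- hybrid_migration_rates(n_f1, n_mig, nrow(s))
    data.frame(taxon = t, n = nrow(s), n_f1 = n_f1, n_migrant = n_mig,
               hybridization = r$hybridization, migration = r$migration,
               stringsAsFactors = FALSE)
  }))
}
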