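#' Private-allele accounting between two taxa
#'
#' Tabulates, for every (locus, allele) observed in the frequency table,
#' the populations carrying it (frequency > 0), how many populations that
#' is (k), whether the allele is private to one taxon (observed in at least
#' one of its populations and none of the other's) or shared, and — for
#' alleles carried by exactly two populations — whether those two
#' populations form a designated sympatric cross-taxon pair.
#'
#' @param freqs An [allele_frequencies()] table built per site (unsmoothed;
#'   presence/absence uses observed frequency > 0, no minimum-frequency
#'   filter).
#' @param taxon_of Named character vector mapping population label ->
#'   taxon; both taxa must have >= 1 population.
#' @param pair_of Optional named character vector mapping population label
#'   -> pair id (for the sympatric flag on k = 2 alleles).
#' @return List of class `private_allele_report`: `alleles` (data frame:
#'   locus, allele, k, carriers, status, sympatric_pair), `counts` (list:
#'   total_private, private per taxon, k tallies, two-population alleles
#'   and sympatric hits).
#' @export
find_private_alleles <- function(freqs, taxon_of, pair_of = NULL) {
  taxa <- sort(unique(taxon_of))
  if (length(taxa) != 2)
    stop("taxon_of must map populations onto exactly two taxa")
  unknown <- setdiff(freqs$pops, names(taxon_of))
  if (length(unknown))
    stop("populations without a taxon: ", paste(unknown, collapse = ", "))
  rows <- list()
  for (l in freqs$loci$name) {
    carriers <- list()
    for (g in freqs$pops) {
      f <- freqs$freq[[g]][[l]]
      f <- f[f > 0]
      for (a in names(f)) carriers[[a]] <- c(carriers[[a]], g)
    }
    for (a in names(carriers)) {
      pops <- carriers[[a]]
      in_taxon <- vapply(taxa, function(t) any(taxon_of[pops] == t), logical(1))
      status <- if (all(in_taxon)) "shared" else
        paste0("private_", taxa[in_taxon])
      symp <- FALSE
      if (length(pops) == 2L && !is.null(pair_of) && status == "shared")
        symp <- pair_of[pops[1]] == pair_of[pops[2]]
      rows[[length(rows) + 1L]] <- data.frame(
        locus = l, allele = as.integer(a), k = length(pops),
        carriers = paste(sort(pops), collapse = ","),
        status = status, sympatric_pair = symp,
        stringsAsFactors = FALSE
      )
    }
  }
  alleles <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(), allele = integer(), k = integer(),
               carriers = character(), status = character(),
               sympatric_pair = logical(), stringsAsFactors = FALSE)
  priv <- alleles$status != "shared"
  counts <- list(
    total_private = sum(priv),
    private_by_taxon = stats::setNames(
      vapply(taxa, function(t) sum(alleles$status == paste0("private_", t)),
             integer(1)), taxa),
    k_tally = if (nrow(alleles)) table(alleles$k) else table(integer(0)),
    n_two_pop = sum(alleles$k == 2L),
    n_two_pop_sympatric = sum(alleles$k == 2L & alleles$sympatric_pair)
  )
  structure(list(alleles = alleles, counts = counts, taxa = taxa),
            class = "private_allele_report")
}

#' @export
print.private_allele_report <- function(x, ...) {
  cat("private_allele_report\n")
  cat("  total private alleles:", x$counts$total_private, "\n")
  for (t in x$taxa)
    cat(sprintf("    private to %s: %d\n", t, x$counts$private_by_taxon[[t]]))
  cat("  alleles in exactly 1 population:",
      sum(x$alleles$k == 1L), "\n")
  cat("  alleles in exactly 2 populations:", x$counts$n_two_pop,
      "( sympatric cross-taxon pairs:", x$counts$n_two_pop_sympatric, ")\n")
  invisible(x)
}

#' Chi-squared test of equal private-allele proportions
#'
#' Goodness-of-fit chi-squared of the two taxa's private-allele counts
#' against an equal split (df = 1, no continuity correction).
#'
#' @param countA,countB Private-allele counts for the two taxa.
#' @return List with `chi2`, `df`, `p`, `proportionA` (countA's share).
#' @export
private_proportion_chisq <- function(countA, countB) {
  if (countA + countB <= 0) stop("both counts are zero")
  ht <- stats::chisq.test(c(countA, countB), p = c(0.5, 0.5))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, proportionA = countA / (countA + countB))
}

#' Null expectation for sympatric sharing of two-population alleles
#'
#' Expected number of alleles — among those observed in exactly two of the
#' surveyed populations — whose two carrier populations form a sympatric
#' cross-taxon pair, if carrier pairs were random. Three modes:
#' \describe{
#'   \item{`paper`}{`(n_sympatric_pairs / (n_pops (n_pops - 1))) *
#'     n_two_pop_alleles` — a denominator of ordered population pairs.}
#'   \item{`combinatorial`}{`(n_sympatric_pairs / choose(n_pops, 2)) *
#'     n_two_pop_alleles` — unordered pairs; exactly twice the `paper`
#'     value.}
#'   \item{`montecarlo`}{places each allele on a uniform random unordered
#'     population pair and counts sympatric hits; converges to the
#'     combinatorial value.}
#' }
#'
#' @param n_two_pop_alleles Number of two-population alleles.
#' @param n_pops Number of surveyed populations (>= 2).
#' @param n_sympatric_pairs Number of designated sympatric cross-taxon
#'   pairs (<= n_pops / 2).
#' @param mode `"paper"`, `"combinatorial"` or `"montecarlo"`.
#' @param reps,seed Monte Carlo settings.
#' @return Expected count (real). For `montecarlo`, the mean over reps with
#'   its standard error in `attr(, "se")`.
#' @export
rare_shared_expectation <- function(n_two_pop_alleles, n_pops,
                                    n_sympatric_pairs,
                                    mode = c("paper", "combinatorial", "montecarlo"),
                                    reps = 1e5, seed = NULL) {
  mode <- match.arg(mode)
  if (n_pops < 2) stop("need n_pops >= 2")
  if (n_two_pop_alleles < 0 || n_sympatric_pairs < 0)
    stop("counts must be nonnegative")
  if (n_sympatric_pairs > n_pops / 2)
    stop("more sympatric pairs than n_pops/2")
  switch(mode,
    paper = n_sympatric_pairs / (n_pops * (n_pops - 1)) * n_two_pop_alleles,
    combinatorial = n_sympatric_pairs / choose(n_pops, 2) * n_two_pop_alleles,
    montecarlo = {
      if (!is.null(seed)) set.seed(seed)
      if (n_two_pop_alleles == 0) return(structure(0, se = 0))
      # designate pairs (1,2), (3,4), ... as the sympatric ones
      symp <- matrix(seq_len(2 * n_sympatric_pairs), ncol = 2, byrow = TRUE)
      keys <- symp[, 1] * (n_pops + 1) + symp[, 2]
      hits <- vapply(seq_len(reps), function(i) {
        p1 <- sample.int(n_pops, n_two_pop_alleles, replace = TRUE)
        p2 <- sample.int(n_pops - 1L, n_two_pop_alleles, replace = TRUE)
        p2 <- p2 + (p2 >= p1)  # uniform over pairs p1 != p2
        lo <- pmin(p1, p2); hi <- pmax(p1, p2)
        sum((lo * (n_pops + 1) + hi) %in% keys)
      }, numeric(1))
      structure(mean(hits), se = stats::sd(hits) / sqrt(reps))
    }
  )
}
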