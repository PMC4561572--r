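#' Nei's (1972) standard genetic distance between two populations
#'
#' D = -ln( Jxy / sqrt(Jx Jy) ), where Jxy, Jx, Jy are arithmetic means over
#' loci of the gene identities sum_a pA(a) pB(a), sum_a pA(a)^2 and
#' sum_a pB(a)^2. Only loci scored (n > 0) in both populations enter the
#' means (pairwise locus deletion); D = +Inf when the mean cross-identity is
#' zero (completely disjoint allele sets).
#'
#' @param freqs An [allele_frequencies()] table.
#' @param popA,popB Population labels.
#' @param loci Optional subset of locus names; default all.
#' @return Nonnegative real (possibly `Inf`).
#' @export
nei_standard_distance <- function(freqs, popA, popB, loci = NULL) {
  if (is.null(loci)) loci <- freqs$loci$name
  bad <- setdiff(c(popA, popB), freqs$pops)
  if (length(bad)) stop("unknown population(s): ", paste(bad, collapse = ", "))
  jxy <- jx <- jy <- numeric(0)
  for (l in loci) {
    fA <- freqs$freq[[popA]][[l]]
    fB <- freqs$freq[[popB]][[l]]
    if (!length(fA) || !length(fB)) next
    shared <- intersect(names(fA), names(fB))
    jxy <- c(jxy, sum(fA[shared] * fB[shared]))
    jx <- c(jx, sum(fA^2))
    jy <- c(jy, sum(fB^2))
  }
  if (!length(jxy))
    stop("populations '", popA, "' and '", popB,
         "' share no scored locus in the requested set")
  m_xy <- mean(jxy)
  if (m_xy == 0) return(Inf)
  -log(m_xy / sqrt(mean(jx) * mean(jy)))
}

#' All-pairs Nei distance matrix
#'
#' @inheritParams nei_standard_distance
#' @return Symmetric matrix with zero diagonal, labelled by population.
#' @export
nei_distance_matrix <- function(freqs, loci = NULL) {
  pops <- freqs$pops
  dm <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  if (length(pops) < 2) return(dm)
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in (i + 1):length(pops)) {
      d <- nei_standard_distance(freqs, pops[i], pops[j], loci)
      dm[i, j] <- dm[j, i] <- d
    }
  }
  dm
}
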