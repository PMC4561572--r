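# internal: grouping label per individual
group_labels <- function(dataset, grouping = c("site", "species", "site_species")) {
  grouping <- match.arg(grouping)
  if (grouping != "site") require_species(dataset)
  switch(grouping,
    site = dataset$ind$site,
    species = dataset$ind$species,
    site_species = paste(dataset$ind$site, dataset$ind$species, sep = ":")
  )
}

# internal: per (group, locus) allele count tables over the observed calls.
# Returns list(counts = counts[[group]][[locus]] named integer vector,
#              n = groups x loci matrix of genotyped diploids,
#              union = per-locus union allele set over the whole dataset)
allele_count_tables <- function(dataset, groups) {
  gl <- sort(unique(groups))
  L <- n_loci(dataset)
  counts <- vector("list", length(gl)); names(counts) <- gl
  n <- matrix(0L, length(gl), L, dimnames = list(gl, dataset$loci$name))
  union_set <- vector("list", L); names(union_set) <- dataset$loci$name
  for (l in seq_len(L)) {
    union_set[[l]] <- sort(unique(c(dataset$a1[, l], dataset$a2[, l])))
    union_set[[l]] <- union_set[[l]][!is.na(union_set[[l]])]
  }
  for (g in gl) {
    rows <- which(groups == g)
    counts[[g]] <- vector("list", L)
    names(counts[[g]]) <- dataset$loci$name
    for (l in seq_len(L)) {
      alleles <- c(dataset$a1[rows, l], dataset$a2[rows, l])
      alleles <- alleles[!is.na(alleles)]
      n[g, l] <- length(alleles) %/% 2L
      counts[[g]][[l]] <- if (length(alleles)) table(alleles) else
        structure(integer(0), names = character(0))
    }
  }
  list(counts = counts, n = n, union = union_set)
}

#' Allele frequencies per population
#'
#' Computes per-(population, locus) allele frequency tables from the
#' observed calls. With `smoothing = "none"` these are the maximum-likelihood
#' frequencies count / (2 n); with `smoothing = "dirichlet"` they are
#' posterior means (count + lambda) / (2 n + lambda K) over the union allele
#' set of the whole dataset at that locus (K alleles), so every union allele
#' gets strictly positive mass — the form required by the genotype-class
#' classifier. `lambda = NULL` uses 1/K.
#'
#' A (population, locus) cell with zero genotyped individuals is flagged
#' empty (`NULL` entry, `n = 0`), never zero-filled.
#'
#' @param dataset A `genotype_dataset`.
#' @param grouping `"site"`, `"species"`, or `"site_species"`.
#' @param smoothing `"none"` (default) or `"dirichlet"`.
#' @param lambda Dirichlet pseudo-count per allele; `NULL` = 1/K.
#' @return An object of class `allele_freq_table`: list with `freq` (nested
#'   list population -> locus -> named numeric vector), `n` (populations x
#'   loci matrix of genotyped diploids), `pops`, `loci`, `smoothing`.
#' @export
allele_frequencies <- function(dataset, grouping = c("site", "species", "site_species"),
                               smoothing = c("none", "dirichlet"),
                               lambda = NULL) {
  smoothing <- match.arg(smoothing)
  groups <- group_labels(dataset, grouping)
  ct <- allele_count_tables(dataset, groups)
  freq <- ct$counts
  for (g in names(freq)) {
    for (l in seq_along(freq[[g]])) {
      cnt <- freq[[g]][[l]]
      n2 <- 2L * ct$n[g, l]
      if (n2 == 0L) { freq[[g]][[l]] <- NULL2(); next }
      if (smoothing == "none") {
        freq[[g]][[l]] <- stats::setNames(as.numeric(cnt) / n2, names(cnt))
      } else {
        uni <- as.character(ct$union[[l]])
        K <- length(uni)
        lam <- if (is.null(lambda)) 1 / K else lambda
        full <- stats::setNames(numeric(K), uni)
        full[names(cnt)] <- as.numeric(cnt)
        freq[[g]][[l]] <- (full + lam) / (n2 + lam * K)
      }
    }
  }
  structure(
    list(freq = freq, n = ct$n, pops = rownames(ct$n),
         loci = dataset$loci, smoothing = smoothing),
    class = "allele_freq_table"
  )
}

# marker for an empty (unscored) population x locus cell
NULL2 <- function() structure(numeric(0), empty = TRUE)

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d populations x %d loci (smoothing: %s)\n",
              length(x$pops), nrow(x$loci), x$smoothing))
  invisible(x)
}

#' Export an allele frequency table as a long data frame
#'
#' @param x An `allele_freq_table`.
#' @param ... Unused.
#' @return Data frame with columns population, locus, allele, frequency, n.
#' @export
as.data.frame.allele_freq_table <- function(x, ...) {
  out <- list()
  for (g in x$pops) {
    for (l in x$loci$name) {
      f <- x$freq[[g]][[l]]
      if (!length(f)) next
      out[[length(out) + 1L]] <- data.frame(
        population = g, locus = l, allele = as.integer(names(f)),
        frequency = as.numeric(f), n = x$n[g, l],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    return(data.frame(population = character(), locus = character(),
                      allele = integer(), frequency = numeric(), n = integer()))
  do.call(rbind, out)
}

#' Observed and expected heterozygosity with inbreeding coefficients
#'
#' Per (population, locus): observed heterozygosity `Ho` = het count / n;
#' unbiased expected heterozygosity `He` = (2n/(2n-1)) (1 - sum p^2);
#' inbreeding coefficient `f` = 1 - Ho/He, reported missing where `He` = 0
#' (monomorphic locus). The per-population summary gives the mean and
#' standard deviation of `f` over the loci where it is defined.
#'
#' @param dataset A `genotype_dataset`.
#' @param grouping As in [allele_frequencies()].
#' @return List with `per_locus` (data frame: population, locus, n, Ho, He,
#'   f) and `summary` (data frame: population, n_loci, mean_f, sd_f).
#' @export
heterozygosity_and_f <- function(dataset, grouping = c("site", "species", "site_species")) {
  groups <- group_labels(dataset, grouping)
  gl <- sort(unique(groups))
  rows <- list()
  for (g in gl) {
    sel <- which(groups == g)
    for (l in seq_len(n_loci(dataset))) {
      a1 <- dataset$a1[sel, l]; a2 <- dataset$a2[sel, l]
      ok <- !is.na(a1)
      n <- sum(ok)
      if (n == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          population = g, locus = dataset$loci$name[l], n = 0L,
          Ho = NA_real_, He = NA_real_, f = NA_real_)
        next
      }
      ho <- sum(a1[ok] != a2[ok]) / n
      p <- as.numeric(table(c(a1[ok], a2[ok]))) / (2 * n)
      he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
      f <- if (he > 0) 1 - ho / he else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        population = g, locus = dataset$loci$name[l], n = n,
        Ho = ho, He = he, f = f)
    }
  }
  per_locus <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(gl, function(g) {
    f <- per_locus$f[per_locus$population == g]
    f <- f[!is.na(f)]
    data.frame(population = g, n_loci = length(f),
               mean_f = if (length(f)) mean(f) else NA_real_,
               sd_f = if (length(f) > 1) stats::sd(f) else NA_real_)
  }))
  list(per_locus = per_locus, summary = summary)
}
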