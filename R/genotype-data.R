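#' Construct a diploid multilocus genotype dataset
#'
#' The central container of the package: diploid microsatellite calls for a
#' set of individuals at a set of loci, with per-individual site and species
#' labels. Allele labels are fragment lengths (positive integers) and are
#' never recoded to indices at this layer, so a call can always be compared
#' with published allele tables (e.g. "allele 226 at locus p7").
#'
#' @param a1,a2 Integer matrices (individuals x loci) holding the two allele
#'   labels of each call. A missing call has `NA` in both matrices. The pair
#'   is unordered; it is stored with `a1 <= a2`.
#' @param ind Data frame with one row per individual and columns `id`,
#'   `site`, `species` and optionally `pair`. `species`/`pair` may be `NA`
#'   (e.g. straight after reading a Genepop file) and can be filled in later
#'   with [attach_geography()].
#' @param loci Data frame with columns `name` (unique locus labels) and
#'   optionally `linkage_group` (integer 1-6 or `NA`).
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(a1, a2, ind, loci) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices must have identical dimensions")
  ind <- as.data.frame(ind, stringsAsFactors = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (is.null(ind$pair)) ind$pair <- NA_character_
  if (is.null(ind$species)) ind$species <- NA_character_
  if (is.null(loci$linkage_group)) loci$linkage_group <- NA_integer_
  if (nrow(ind) != nrow(a1))
    stop("individual table and allele matrices disagree on row count")
  if (nrow(loci) != ncol(a1))
    stop("locus table and allele matrices disagree on locus count")
  if (anyDuplicated(loci$name))
    stop("duplicate locus names: ", paste(loci$name[duplicated(loci$name)], collapse = ", "))
  miss1 <- is.na(a1); miss2 <- is.na(a2)
  if (any(miss1 != miss2))
    stop("half-missing calls: both alleles of a call must be present or absent")
  if (any(a1[!miss1] <= 0) || any(a2[!miss2] <= 0))
    stop("allele labels must be positive integers")
  if (any(is.na(ind$site)) || any(!nzchar(ind$site)))
    stop("every individual needs a site label")
  # store the unordered pair canonically
  swap <- !miss1 & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  colnames(a1) <- colnames(a2) <- loci$name
  structure(
    list(a1 = a1, a2 = a2, ind = ind, loci = loci),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf(
    "genotype_dataset: %d individuals x %d loci, %d sites, species: %s\n",
    nrow(x$ind), nrow(x$loci), length(unique(x$ind$site)),
    paste(unique(stats::na.omit(x$ind$species)), collapse = "/")
  ))
  nm <- sum(is.na(x$a1))
  cat(sprintf("  missing calls: %d (%.1f%%)\n", nm, 100 * nm / length(x$a1)))
  invisible(x)
}

#' Number of individuals / loci
#' @param x A `genotype_dataset`.
#' @export
n_individuals <- function(x) nrow(x$ind)

#' @rdname n_individuals
#' @export
n_loci <- function(x) nrow(x$loci)

#' Subset a genotype dataset by individuals and/or loci
#' @param x A `genotype_dataset`.
#' @param i Individual index (integer/logical).
#' @param j Locus index (integer/logical or locus names).
#' @param ... Unused.
#' @export
`[.genotype_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$ind))
  if (missing(j)) j <- seq_len(nrow(x$loci))
  if (is.character(j)) j <- match(j, x$loci$name)
  genotype_dataset(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                   x$ind[i, , drop = FALSE], x$loci[j, , drop = FALSE])
}

#' Read a site-geography (and optional climate covariate) table
#'
#' Expects a delimited text file with a header and columns `site`, `lat`,
#' `lon`, `pair`, `species`, optionally followed by covariate columns such as
#' `precip_jul_oct` (mm), `tmax_jul` (deg C), `tmin_jan` (deg C). The
#' delimiter (tab, comma or whitespace) is detected from the header line.
#'
#' @param path Path to the table.
#' @return A data frame with one row per site.
#' @export
read_site_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  geo <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("site", "lat", "lon", "pair", "species")
  missing_cols <- setdiff(need, names(geo))
  if (length(missing_cols))
    stop("site table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(geo$site))
    stop("duplicate site ids in site table")
  geo$site <- as.character(geo$site)
  geo$pair <- as.character(geo$pair)
  geo$species <- as.character(geo$species)
  geo
}

#' Fill species and pair labels of a dataset from a site-geography table
#'
#' Genepop and STRUCTURE files carry only a population (site) label per
#' individual; the species and paired-site assignment live in the
#' site-geography table. This helper joins them onto the dataset.
#'
#' @param dataset A `genotype_dataset`.
#' @param geo Site table as returned by [read_site_table()].
#' @return The dataset with `species` and `pair` filled in.
#' @export
attach_geography <- function(dataset, geo) {
  idx <- match(dataset$ind$site, geo$site)
  if (anyNA(idx)) {
    bad <- unique(dataset$ind$site[is.na(idx)])
    stop("site(s) absent from geography table: ", paste(bad, collapse = ", "))
  }
  dataset$ind$species <- geo$species[idx]
  dataset$ind$pair <- geo$pair[idx]
  dataset
}

# internal: species labels must be present for species-aware analyses
require_species <- function(dataset) {
  if (anyNA(dataset$ind$species))
    stop("dataset has individuals without a species label; ",
         "use attach_geography() first")
  invisible(dataset)
}

# internal: the two taxa of a two-species dataset, sorted for determinism
two_taxa <- function(dataset) {
  sp <- sort(unique(dataset$ind$species))
  if (length(sp) != 2L)
    stop("expected exactly two species labels, found: ",
         paste(sp, collapse = ", "))
  sp
}
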