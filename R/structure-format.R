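#' Read a STRUCTURE-format genotype table
#'
#' Whitespace-delimited, headerless table with columns: individual id,
#' population code, then the genotypes. In two-row mode (the default, one
#' row per gamete) each individual occupies two consecutive rows with one
#' column per locus; in one-row mode each individual is a single row with
#' two adjacent columns per locus. Missing alleles are coded `-9`. The
#' population code is stored as the `site` label.
#'
#' @param path Path to the file.
#' @param rows_per_individual 2 (default) or 1.
#' @param locus_names Optional character vector of locus names; defaults to
#'   `L1`, `L2`, ...
#' @return A [genotype_dataset()] (species labels unset).
#' @export
read_structure_table <- function(path, rows_per_individual = 2L,
                                 locus_names = NULL) {
  stopifnot(rows_per_individual %in% c(1L, 2L))
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 3L) stop("STRUCTURE table needs id, pop and >=1 genotype column")
  geno <- as.matrix(tab[, -(1:2), drop = FALSE])
  if (any(!grepl("^-?[0-9]+$", geno)))
    stop("non-integer allele field in STRUCTURE table")
  geno <- matrix(as.integer(geno), nrow = nrow(tab))

  if (rows_per_individual == 2L) {
    if (nrow(tab) %% 2L != 0L)
      stop("two-row STRUCTURE file has an odd number of rows")
    r1 <- seq(1L, nrow(tab), by = 2L)
    r2 <- r1 + 1L
    if (any(tab[[1]][r1] != tab[[1]][r2]))
      stop("two-row STRUCTURE file: paired rows carry different individual ids")
    ids <- tab[[1]][r1]; pops <- tab[[2]][r1]
    a1 <- geno[r1, , drop = FALSE]
    a2 <- geno[r2, , drop = FALSE]
  } else {
    if (ncol(geno) %% 2L != 0L)
      stop("one-row STRUCTURE file needs an even number of genotype columns")
    ids <- tab[[1]]; pops <- tab[[2]]
    odd <- seq(1L, ncol(geno), by = 2L)
    a1 <- geno[, odd, drop = FALSE]
    a2 <- geno[, odd + 1L, drop = FALSE]
  }
  miss <- a1 == -9L | a2 == -9L
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  L <- ncol(a1)
  if (is.null(locus_names)) locus_names <- paste0("L", seq_len(L))
  if (length(locus_names) != L)
    stop("locus_names length (", length(locus_names), ") != locus count (", L, ")")
  genotype_dataset(
    a1, a2,
    data.frame(id = ids, site = pops, species = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(name = locus_names, stringsAsFactors = FALSE)
  )
}

#' Write a dataset as a STRUCTURE-format table
#'
#' @param dataset A `genotype_dataset`.
#' @param path Output path.
#' @param rows_per_individual 2 (default) or 1.
#' @return `path`, invisibly.
#' @export
write_structure_table <- function(dataset, path, rows_per_individual = 2L) {
  stopifnot(rows_per_individual %in% c(1L, 2L))
  a1 <- dataset$a1; a2 <- dataset$a2
  a1[is.na(a1)] <- -9L; a2[is.na(a2)] <- -9L
  con <- file(path, "w"); on.exit(close(con))
  for (r in seq_len(nrow(dataset$ind))) {
    id <- dataset$ind$id[r]; site <- dataset$ind$site[r]
    if (rows_per_individual == 2L) {
      writeLines(paste(c(id, site, a1[r, ]), collapse = " "), con)
      writeLines(paste(c(id, site, a2[r, ]), collapse = " "), con)
    } else {
      inter <- as.vector(rbind(a1[r, ], a2[r, ]))
      writeLines(paste(c(id, site, inter), collapse = " "), con)
    }
  }
  invisible(path)
}
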