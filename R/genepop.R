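#' Read a Genepop file
#'
#' Parses the classic Genepop text dialect: a title line, one locus name per
#' line (or a single comma-separated line), then `POP` blocks of individuals
#' written as `id , a1a2 a1a2 ...` with fixed-width 2- or 3-digit allele
#' codes. Code `00`/`000` denotes a missing allele; a call with either allele
#' missing is treated as a missing call. The digit width is auto-detected
#' from the genotype field width (4 = 2-digit, 6 = 3-digit); any other or
#' mixed width is an error.
#'
#' Populations are mapped to `site` labels, taken from the id of the last
#' individual of each `POP` block (the Genepop convention); individuals with
#' empty ids get autogenerated ids `<site>_<ordinal>`.
#'
#' @param path Path to the Genepop file.
#' @return A [genotype_dataset()] (species labels unset; see
#'   [attach_geography()]).
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[cumsum(nzchar(trimws(lines))) > 0L]  # keep leading title even if later blanks
  if (length(lines) < 2L) stop("not a Genepop file: fewer than two lines")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a Genepop file: no POP line found")
  locus_lines <- trimws(lines[2:(first_pop - 1L)])
  locus_lines <- locus_lines[nzchar(locus_lines)]
  locus_names <- trimws(unlist(strsplit(locus_lines, ",")))
  locus_names <- locus_names[nzchar(locus_names)]
  if (!length(locus_names)) stop("no locus names before first POP")
  if (anyDuplicated(locus_names))
    stop("duplicate locus names: ",
         paste(unique(locus_names[duplicated(locus_names)]), collapse = ", "))
  L <- length(locus_names)

  pop_id <- cumsum(is_pop)
  body <- which(!is_pop & seq_along(lines) > first_pop - 1L)
  body <- body[pop_id[body] >= 1L & nzchar(trimws(lines[body]))]
  if (!length(body)) {
    return(genotype_dataset(
      matrix(NA_integer_, 0, L), matrix(NA_integer_, 0, L),
      data.frame(id = character(), site = character(),
                 species = character(), stringsAsFactors = FALSE),
      data.frame(name = locus_names, stringsAsFactors = FALSE)
    ))
  }

  ids <- character(length(body))
  geno_fields <- vector("list", length(body))
  for (k in seq_along(body)) {
    ln <- lines[body[k]]
    comma <- regexpr(",", ln, fixed = TRUE)
    if (comma < 0)
      stop("line ", body[k], ": no ',' separating id from genotypes")
    ids[k] <- trimws(substr(ln, 1L, comma - 1L))
    fields <- strsplit(trimws(substr(ln, comma + 1L, nchar(ln))), "[ \t]+")[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) != L)
      stop("line ", body[k], ": expected ", L, " genotype fields, found ",
           length(fields))
    geno_fields[[k]] <- fields
  }
  fields_all <- unlist(geno_fields)
  if (any(grepl("[^0-9]", fields_all)))
    stop("non-numeric allele code in genotype fields")
  widths <- unique(nchar(fields_all))
  if (length(widths) != 1L || !(widths %in% c(4L, 6L)))
    stop("ambiguous allele code width (need uniform 4- or 2-digit, 6- or ",
         "3-digit fields); widths seen: ", paste(widths, collapse = ", "))
  w <- widths / 2L
  a1 <- matrix(as.integer(substr(fields_all, 1L, w)),
               nrow = length(body), ncol = L, byrow = TRUE)
  a2 <- matrix(as.integer(substr(fields_all, w + 1L, 2L * w)),
               nrow = length(body), ncol = L, byrow = TRUE)
  miss <- a1 == 0L | a2 == 0L
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_

  # Site label per POP block. Genepop convention names a population after
  # its last individual; ids written as "<site>_<ordinal>" (this package's
  # writer and the common field convention) are recognised and reduced to
  # the shared site prefix, otherwise the last id is used verbatim.
  popn <- pop_id[body]
  site <- character(length(body))
  for (p in unique(popn)) {
    members <- which(popn == p)
    block_ids <- ids[members]
    prefixes <- sub("_[0-9]+$", "", block_ids)
    has_ord <- grepl("_[0-9]+$", block_ids)
    label <- if (all(has_ord) && length(unique(prefixes)) == 1L && nzchar(prefixes[1]))
      prefixes[1]
    else
      block_ids[length(block_ids)]
    if (!nzchar(label)) label <- paste0("pop", p)
    site[members] <- label
  }
  blank <- !nzchar(ids)
  if (any(blank))
    ids[blank] <- paste0(site[blank], "_", ave(seq_along(ids), popn, FUN = seq_along)[blank])

  genotype_dataset(
    a1, a2,
    data.frame(id = ids, site = site, species = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(name = locus_names, stringsAsFactors = FALSE)
  )
}

#' Write a dataset in Genepop format
#'
#' Alleles are encoded at fixed width (default 3 digits, the common
#' microsatellite convention); a missing call becomes `000000`. Individuals
#' are grouped into `POP` blocks by site, in order of first appearance.
#' Ids that do not already carry the `<site>_<ordinal>` form are rewritten
#' to it so that [read_genepop()] recovers the site label exactly (Genepop
#' itself only encodes population identity through individual ids).
#'
#' @param dataset A `genotype_dataset`.
#' @param path Output path.
#' @param title Title line (first line of the file).
#' @param digits Allele code width, 2 or 3.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(dataset, path, title = "hybridtrace export",
                          digits = 3L) {
  stopifnot(digits %in% c(2L, 3L))
  maxcode <- 10^digits - 1
  a1 <- dataset$a1; a2 <- dataset$a2
  if (any(a1 > maxcode, na.rm = TRUE) || any(a2 > maxcode, na.rm = TRUE))
    stop("allele label exceeds ", maxcode, " and cannot be Genepop-encoded; ",
         "use write_structure_table() instead")
  fmt <- function(a) {
    out <- sprintf(paste0("%0", digits, "d"), a)
    out[is.na(a)] <- strrep("0", digits)
    out
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(dataset$loci$name, con)
  sites <- unique(dataset$ind$site)
  for (s in sites) {
    writeLines("POP", con)
    rows <- which(dataset$ind$site == s)
    ids <- dataset$ind$id[rows]
    conforms <- grepl("_[0-9]+$", ids) & sub("_[0-9]+$", "", ids) == s
    if (!all(conforms)) ids <- paste0(s, "_", seq_along(rows))
    for (k in seq_along(rows)) {
      r <- rows[k]
      g <- paste0(fmt(dataset$a1[r, ]), fmt(dataset$a2[r, ]))
      writeLines(paste(ids[k], ",", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}
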