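#' Run the full analysis pipeline on a genotype dataset
#'
#' Orchestrates the stages end-to-end: Nei distance matrix and NJ tree with
#' locus bootstrap; genotype-class posteriors and per-taxon
#' hybridization/migration rates; the clinal permutation test toward the
#' focal site; Mantel / partial Mantel isolation-by-distance tests; and the
#' private-allele report. All outputs are written as delimited text (plus
#' newick for the tree) into `outdir`, together with a run manifest
#' recording the seed and every threshold, so a rerun with the same inputs
#' and seed reproduces every file byte-for-byte.
#'
#' @param dataset A `genotype_dataset`, or a path to a Genepop file.
#' @param geo Site-geography table or path ([read_site_table()]).
#' @param focal_site Focal site id for the cline axis.
#' @param outdir Output directory (created if needed).
#' @param nu Prior migration rate for [classify()].
#' @param n_perm Permutations for the cline and Mantel tests.
#' @param n_bootstrap Bootstrap replicates for the NJ tree.
#' @param seed Integer seed governing every stochastic stage.
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(dataset, geo, focal_site, outdir,
                         nu = 0.01, n_perm = 999L, n_bootstrap = 100L,
                         seed = 1L) {
  if (is.character(dataset)) dataset <- read_genepop(dataset)
  if (is.character(geo)) geo <- read_site_table(geo)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dataset <- attach_geography(dataset, geo)
  require_species(dataset)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  out <- function(f) file.path(outdir, f)
  wtsv <- function(x, f) utils::write.table(
    x, out(f), sep = "\t", quote = FALSE, row.names = FALSE)

  freqs <- stage("allele_frequencies", allele_frequencies(dataset, "site"))
  wtsv(as.data.frame(freqs), "allele_frequencies.tsv")

  hetf <- stage("heterozygosity", heterozygosity_and_f(dataset, "site"))
  wtsv(hetf$per_locus, "heterozygosity.tsv")
  wtsv(hetf$summary, "inbreeding_summary.tsv")

  dm <- stage("nei_distances", nei_distance_matrix(freqs))
  utils::write.table(dm, out("nei_distances.tsv"), sep = "\t", quote = FALSE)

  boot <- stage("nj_bootstrap",
                bootstrap_support(dataset, "site", n_reps = n_bootstrap,
                                  seed = seed))
  write_tree_newick(boot$tree, out("nj_tree.nwk"))

  post <- stage("classify", classify(dataset, nu = nu))
  wtsv(as.data.frame(post), "posteriors.tsv")
  rates <- stage("rates", estimate_rates(post))
  wtsv(rates, "rates.tsv")

  cline <- stage("cline_test",
                 cline_permutation_test(dataset, geo, focal_site,
                                        n_perm = n_perm, seed = seed + 1L))
  wtsv(as.data.frame(cline), "cline.tsv")

  gdm <- stage("geo_distances", geo_distance_matrix(geo))
  sp <- stats::setNames(geo$species, geo$site)
  sdm <- species_distance_matrix(sp)
  mt <- stage("partial_mantel",
              partial_mantel_test(dm, gdm[rownames(dm), rownames(dm)],
                                  sdm[rownames(dm), rownames(dm)],
                                  n_perm = n_perm, seed = seed + 2L))

  taxon_of <- stats::setNames(geo$species, geo$site)
  pair_of <- stats::setNames(geo$pair, geo$site)
  priv <- stage("private_alleles",
                find_private_alleles(freqs, taxon_of, pair_of))
  wtsv(priv$alleles, "private_alleles.tsv")

  manifest <- c(
    sprintf("hybridtrace %s", as.character(utils::packageVersion("hybridtrace"))),
    sprintf("seed: %d", seed),
    sprintf("nu: %g", nu),
    sprintf("n_perm: %d", n_perm),
    sprintf("n_bootstrap: %d", n_bootstrap),
    sprintf("focal_site: %s", focal_site),
    sprintf("individuals: %d", n_individuals(dataset)),
    sprintf("loci: %d", n_loci(dataset)),
    sprintf("partial_mantel_r: %.6f", mt$r),
    sprintf("partial_mantel_p: %.6f", mt$p)
  )
  writeLines(manifest, out("manifest.txt"))

  invisible(list(freqs = freqs, het = hetf, distances = dm, bootstrap = boot,
                 posteriors = post, rates = rates, cline = cline,
                 partial_mantel = mt, private = priv))
}
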