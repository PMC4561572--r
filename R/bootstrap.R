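#' Locus-resampling bootstrap supports for the NJ population tree
#'
#' Builds the NJ tree from Nei distances over all loci, then resamples loci
#' with replacement `n_reps` times, recomputing distances and the NJ tree
#' each time. The support of each internal edge (bipartition) of the
#' original tree is the fraction of replicate trees containing that
#' bipartition. A replicate whose resampled loci yield a non-finite
#' distance for some population pair is dropped and counted; a warning is
#' issued if more than 1% of replicates are dropped.
#'
#' @param dataset A `genotype_dataset`.
#' @param grouping Population grouping, as in [allele_frequencies()].
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `tree` (the original NJ `phylo`, with bipartition
#'   supports as `node.label`, root blank), `supports` (named vector,
#'   bipartition key -> support in [0,1]), `n_used`, `n_dropped`.
#' @export
bootstrap_support <- function(dataset, grouping = "site", n_reps = 100L,
                              seed = NULL) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  freqs <- allele_frequencies(dataset, grouping)
  loci <- freqs$loci$name
  dm <- nei_distance_matrix(freqs)
  if (any(!is.finite(dm)))
    stop("non-finite Nei distance on the full locus set")
  tree <- nj_tree(dm)
  ref <- sort(tree$tip.label)[1]
  obs_splits <- tree_splits(tree, ref)
  tally <- stats::setNames(numeric(length(obs_splits)), obs_splits)
  n_used <- 0L; n_dropped <- 0L
  for (b in seq_len(n_reps)) {
    samp <- sample(loci, length(loci), replace = TRUE)
    dmb <- try(nei_distance_matrix(freqs, loci = samp), silent = TRUE)
    if (inherits(dmb, "try-error") || any(!is.finite(dmb))) {
      n_dropped <- n_dropped + 1L
      next
    }
    n_used <- n_used + 1L
    sp <- tree_splits(nj_tree(dmb), ref)
    hit <- obs_splits %in% sp
    tally[hit] <- tally[hit] + 1
  }
  if (n_used == 0L) stop("all bootstrap replicates dropped")
  if (n_dropped > 0.01 * n_reps)
    warning(sprintf("%d of %d bootstrap replicates dropped (non-finite distances)",
                    n_dropped, n_reps))
  supports <- tally / n_used

  # attach supports as internal node labels of the original tree
  tips <- tree$tip.label
  parts <- ape::prop.part(tree)
  labs <- character(length(parts))
  for (k in seq_along(parts)) {
    side <- tips[parts[[k]]]
    if (ref %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    labs[k] <- if (key %in% names(supports)) sprintf("%.4g", supports[key]) else ""
  }
  tree$node.label <- labs
  list(tree = tree, supports = supports, n_used = n_used, n_dropped = n_dropped)
}

#' Write a tree in newick format (supports as internal node labels)
#'
#' @param tree An `ape::phylo` (e.g. `bootstrap_support(...)$tree`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Nei distance in resampled locus sets: helper for nei distances on a
#' multiset of loci is provided by `nei_distance_matrix(freqs, loci = ...)`,
#' which accepts repeated locus names (resampling with replacement).
#' @name bootstrap-details
#' @keywords internal
NULL
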