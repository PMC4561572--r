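# Small fixtures built in code, shared across test files.

# a 2-population, 3-locus dataset with known calls and one missing call
tiny_dataset <- function() {
  a1 <- rbind(c(150L, 226L, 101L),
              c(150L, 224L, NA),
              c(152L, 226L, 103L),
              c(154L, 224L, 101L))
  a2 <- rbind(c(152L, 226L, 103L),
              c(150L, 226L, NA),
              c(152L, 228L, 103L),
              c(156L, 226L, 105L))
  ind <- data.frame(
    id = c("north_1", "north_2", "south_1", "south_2"),
    site = c("north", "north", "south", "south"),
    species = c("A", "A", "B", "B"),
    pair = c("P1", "P1", "P1", "P1"),
    stringsAsFactors = FALSE
  )
  loci <- data.frame(name = c("p7", "p27", "p3"),
                     linkage_group = c(3L, 5L, 1L),
                     stringsAsFactors = FALSE)
  genotype_dataset(a1, a2, ind, loci)
}

# frequency table built directly from named lists, for distance oracles
freq_table_from_lists <- function(freq, n) {
  pops <- names(freq)
  loci <- names(freq[[1]])
  structure(
    list(freq = freq,
         n = matrix(n, length(pops), length(loci),
                    dimnames = list(pops, loci)),
         pops = pops,
         loci = data.frame(name = loci, linkage_group = NA_integer_,
                           stringsAsFactors = FALSE),
         smoothing = "none"),
    class = "allele_freq_table"
  )
}

# default-sized study whose taxon-A sample totals 278 (study sample size)
study_278_sizes <- c(31L, 31L, 31L, 31L, 31L, 31L, 31L, 31L, 30L)

# random additive distance matrix from a random unrooted binary tree;
# returns list(dm, tree)
random_additive_matrix <- function(n_leaves) {
  tree <- ape::rtree(n_leaves, rooted = FALSE,
                     br = function(n) stats::runif(n, 0.1, 1))
  tree$tip.label <- paste0("t", seq_len(n_leaves))
  dm <- ape::cophenetic.phylo(tree)
  ord <- sort(rownames(dm))
  list(dm = dm[ord, ord], tree = tree)
}

# unrooted topology equality via bipartition sets
same_unrooted_topology <- function(t1, t2) {
  setequal(hybridtrace:::tree_splits(t1), hybridtrace:::tree_splits(t2))
}
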