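#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with two determinism rules: (i) ties in the
#' Q-criterion minimum are broken toward the lowest (row, column) index pair;
#' (ii) a negative branch length produced by the three-point estimates is
#' clamped to zero with the excess transferred to its sister branch, so the
#' path length between the joined pair is preserved. On an additive distance
#' matrix the generating tree (topology and branch lengths) is recovered
#' exactly.
#'
#' @param dm Symmetric numeric matrix with zero diagonal, finite entries and
#'   population labels as dimnames; at least 3 populations.
#' @return An unrooted `ape::phylo` tree (internal nodes of degree 3).
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  labels <- rownames(dm)
  if (is.null(labels)) stop("distance matrix needs dimnames")
  n <- nrow(dm)
  if (n < 3) stop("neighbor-joining needs at least 3 populations")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-10)))
    stop("distance matrix is not symmetric")
  if (any(!is.finite(dm)))
    stop("infinite distances; exclude unscorable loci pairwise upstream")
  if (any(grepl("[(),:;\\[\\]]", labels)))
    stop("population labels may not contain newick metacharacters")

  fmt <- function(x) sprintf("%.12g", x)
  reps <- labels                     # newick subtree per active node
  D <- dm
  while (nrow(D) > 3L) {
    m <- nrow(D)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    # lowest (row, col) pair among ties, i < j
    qmin <- min(Q)
    hits <- which(Q == qmin, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    vi <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newrep <- paste0("(", reps[i], ":", fmt(vi), ",", reps[j], ":", fmt(vj), ")")
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    reps <- c(reps[keep], newrep)
    rownames(D2) <- colnames(D2) <- as.character(seq_len(m - 1L))
    D <- D2
  }
  # final trifurcation via the three-point formulas
  v1 <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  v2 <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  v3 <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  v <- c(v1, v2, v3)
  for (k in 1:3) {
    if (v[k] < 0) {
      others <- setdiff(1:3, k)
      v[others] <- v[others] + v[k] / 2
      v[k] <- 0
    }
  }
  v <- pmax(v, 0)
  txt <- paste0("(", reps[1], ":", fmt(v[1]), ",", reps[2], ":", fmt(v[2]),
                ",", reps[3], ":", fmt(v[3]), ");")
  ape::read.tree(text = txt)
}

# internal: nontrivial bipartitions of an unrooted tree, canonicalized as the
# sorted tip-label set of the side not containing `ref`.
tree_splits <- function(tree, ref = NULL) {
  tips <- tree$tip.label
  if (is.null(ref)) ref <- sort(tips)[1]
  parts <- ape::prop.part(tree)
  out <- character(0)
  for (p in parts) {
    side <- tips[p]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > length(tips) - 2L) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}
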