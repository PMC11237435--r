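# Saitou-Nei neighbor-joining and bootstrap support.
#
# The NJ agglomeration is implemented here (Q-criterion, standard
# branch-length and matrix-reduction formulas); the resulting tree is
# returned as an ape "phylo" object so downstream tooling (Newick export,
# bipartition counting, plotting) uses the field-standard container.

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei neighbor joining: iteratively joins the pair
#' `(i, j)` minimising `Q(i, j) = (r - 2) d(i, j) - R_i - R_j` (with `R`
#' the row sums over the `r` active nodes), assigns branch lengths by the
#' standard formulas, and reduces the matrix with
#' `d(u, k) = (d(i, k) + d(j, k) - d(i, j)) / 2`. A negative branch length
#' is clamped to zero and the deficit moved to its sister edge, preserving
#' the pair's summed length. The result is unrooted (basal trifurcation).
#'
#' @param D Symmetric non-negative distance matrix with zero diagonal and
#'   taxon labels as dimnames; at least 3 taxa.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("nj_tree: need at least 3 taxa")
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("nj_tree: distance matrix must be symmetric")
  if (any(D < 0)) stop("nj_tree: distances must be non-negative")
  if (any(abs(diag(D)) > 1e-12)) stop("nj_tree: diagonal must be zero")
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  if (anyDuplicated(labs)) stop("nj_tree: taxon labels must be unique")

  # subtree Newick fragments, grown as nodes are joined
  sub <- labs
  active <- seq_len(n)
  fmt <- function(x) sprintf("%.17g", max(x, 0))
  while (length(active) > 3L) {
    r <- length(active)
    d <- D[active, active, drop = FALSE]
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    ij <- arrayInd(which.min(Q), dim(Q))
    i <- ij[1]; j <- ij[2]
    dij <- d[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    ai <- active[i]; aj <- active[j]
    new_sub <- sprintf("(%s:%s,%s:%s)", sub[ai], fmt(li), sub[aj], fmt(lj))
    dnew <- (d[i, ] + d[j, ] - dij) / 2
    D[ai, active] <- dnew
    D[active, ai] <- dnew
    D[ai, ai] <- 0
    sub[ai] <- new_sub
    active <- active[-j]
  }
  a <- active
  d12 <- D[a[1], a[2]]; d13 <- D[a[1], a[3]]; d23 <- D[a[2], a[3]]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 sub[a[1]], fmt(l1), sub[a[2]], fmt(l2), sub[a[3]], fmt(l3))
  ape::read.tree(text = nwk)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the full-data NJ tree from JC69 distances, then resamples
#' alignment columns with replacement `n_reps` times under `seed`; each
#' replicate is rebuilt with the same distance/NJ pipeline, and the support
#' of every internal edge of the full-data tree is the percentage of
#' replicate trees containing the same leaf bipartition. Replicates in
#' which any pairwise distance saturates (p >= 3/4) are skipped; their
#' count is reported.
#'
#' @param aln Nucleotide alignment matrix ([read_alignment()], type
#'   `"dna"`).
#' @param n_reps Number of bootstrap replicates (0 = no supports).
#' @param seed RNG seed; same seed gives identical supports.
#' @param model Distance model passed to [alignment_distances()].
#' @return The full-data `phylo` tree. If `n_reps > 0`, internal-node
#'   labels carry support percentages and attributes `n_valid` /
#'   `n_skipped` record replicate bookkeeping.
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 1,
                              model = "JC69") {
  full <- nj_tree(alignment_distances(aln, model = model))
  if (n_reps == 0) return(full)
  set.seed(seed)
  ncol_aln <- ncol(aln)
  reps <- vector("list", n_reps)
  skipped <- 0L
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    tr <- tryCatch(nj_tree(alignment_distances(aln[, cols, drop = FALSE],
                                               model = model)),
                   error = function(e) NULL)
    if (is.null(tr)) skipped <- skipped + 1L else reps[[r]] <- tr
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  n_valid <- length(reps)
  if (n_valid == 0) stop("bootstrap_support: every replicate saturated")
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_valid, 1)
  full$node.label <- as.character(support)
  # the basal trifurcation is not a real bipartition; blank its label
  full$node.label[1] <- ""
  attr(full, "n_valid") <- n_valid
  attr(full, "n_skipped") <- skipped
  full
}

#' Leaf bipartitions induced by a tree's internal edges
#'
#' Utility for comparing trees at the split level: each internal edge is
#' represented as the lexicographically smaller side of its leaf
#' bipartition, serialised as a sorted, comma-joined label string.
#'
#' @param tree A `phylo` object.
#' @return Character vector of canonical split keys (may be empty).
#' @export
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- sort(tips[p])
    other <- sort(setdiff(tips, side))
    if (length(side) < 2L || length(other) < 2L) next  # trivial split
    a <- paste(side, collapse = ",")
    b <- paste(other, collapse = ",")
    keys <- c(keys, if (a < b) a else b)
  }
  unique(keys)
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` object (node labels, e.g. bootstrap supports, are
#'   written as internal-node labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
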