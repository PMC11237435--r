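# Pairwise distances on multiple alignments.
#
# Alignments are plain character matrices (rows = taxa, columns = aligned
# positions, rownames = identifiers). Gaps and ambiguity codes are removed
# pairwise: a column is compared only where both rows carry an unambiguous
# residue.

VALID_NT <- c("A", "C", "G", "T")
VALID_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read a multiple alignment from aligned FASTA
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @param type `"dna"` or `"protein"`.
#' @return Uppercase character matrix, rows named by sequence identifiers.
#' @export
read_alignment <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  s <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(s))
  if (length(unique(nchar(rows))) != 1L)
    stop("aligned FASTA rows differ in length")
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- names(s)
  attr(m, "type") <- type
  m
}

#' Proportion of differing sites between two aligned rows
#'
#' Pairwise deletion: columns where either row carries a gap or an
#' ambiguous character are excluded from both numerator and denominator.
#'
#' @param a,b Aligned sequences: equal-length character vectors or single
#'   strings.
#' @param valid Characters counted as comparable (default: the four
#'   nucleotides). Use [VALID_AA] via `type` helpers for proteins.
#' @return Proportion of differences among compared positions.
#' @export
p_distance <- function(a, b, valid = VALID_NT) {
  a <- as_residues(a); b <- as_residues(b)
  if (length(a) != length(b))
    stop("p_distance: sequences must be aligned to equal length")
  ok <- a %in% valid & b %in% valid
  n <- sum(ok)
  if (n == 0L) stop("p_distance: no comparable positions after pairwise deletion")
  sum(a[ok] != b[ok]) / n
}

as_residues <- function(x) {
  if (is.character(x) && length(x) == 1L && nchar(x) > 1L)
    x <- strsplit(x, "")[[1]]
  toupper(x)
}

#' Jukes-Cantor (JC69) distance from a proportion of differences
#'
#' `d = -(3/4) * ln(1 - (4/3) * p)`, defined for `p` in `[0, 3/4)`.
#'
#' @param p Proportion(s) of differing sites.
#' @return Corrected distance(s), substitutions per site.
#' @export
jc69_distance <- function(p) {
  if (any(p < 0)) stop("jc69_distance: p must be >= 0")
  if (any(p >= 0.75))
    stop("jc69_distance: p >= 3/4, distance saturated (undefined under JC69)")
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise JC69 distance matrix of a nucleotide alignment
#'
#' @param aln Character matrix from [read_alignment()] (type `"dna"`).
#' @param model `"JC69"` (corrected) or `"raw"` (p-distances).
#' @return Symmetric numeric matrix with taxon labels.
#' @export
alignment_distances <- function(aln, model = c("JC69", "raw")) {
  model <- match.arg(model)
  n <- nrow(aln)
  labs <- rownames(aln)
  if (is.null(labs)) labs <- paste0("seq", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- p_distance(aln[i, ], aln[j, ])
    D[i, j] <- D[j, i] <- if (model == "JC69") jc69_distance(p) else p
  }
  D
}
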