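#' Reference genome from concatenated contigs
#'
#' @param name Reference name (used as the SAM/VCF sequence name).
#' @param sequence Single uppercase A/C/G/T/N string, or a character vector
#'   of contig sequences to concatenate.
#' @param contig_names Optional contig names (defaults to `contig_1`, ...).
#' @return An object of class `reference_genome` with fields `name`, `seq`,
#'   `length` and `contigs` (name, offset, length; offsets 0-based).
#' @export
reference_genome <- function(name, sequence, contig_names = NULL) {
  sequence <- toupper(sequence)
  lens <- nchar(sequence)
  if (is.null(contig_names))
    contig_names <- if (length(sequence) == 1L) name else
      sprintf("contig_%d", seq_along(sequence))
  seq <- paste(sequence, collapse = "")
  if (grepl("[^ACGTN]", seq))
    stop("reference_genome: sequence must contain only A/C/G/T/N")
  structure(list(
    name = name, seq = seq, length = nchar(seq),
    contigs = data.frame(name = contig_names,
                         offset = cumsum(c(0L, lens[-length(lens)])),
                         length = lens)),
    class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome> %s: %d bp in %d contig(s)\n",
              x$name, x$length, nrow(x$contigs)))
  invisible(x)
}

#' Read a reference genome from FASTA, concatenating contigs
#'
#' @param path FASTA file.
#' @param name Name for the concatenated reference (default: file stem).
#' @return A [reference_genome()].
#' @export
read_reference_fasta <- function(path, name = NULL) {
  s <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*", "", names(s))
  if (is.null(name))
    name <- if (length(s) == 1L) ids else
      sub("\\.(fa|fasta|fna)$", "", basename(path))
  reference_genome(name, as.character(s), contig_names = ids)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences, or a
#'   [reference_genome()] (written as one concatenated record).
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (inherits(seqs, "reference_genome"))
    seqs <- stats::setNames(seqs$seq, seqs$name)
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(seqs), path, width = width)
  invisible(path)
}
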