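# Plain-text SAM reading/writing. Alignments are inputs to the pipeline
# (mapping itself is external); only the fields the pileup needs are kept.

#' Read alignments from a plain-text SAM file
#'
#' Parses the mandatory SAM columns and keeps `qname, flag, rname, pos,
#' mapq, cigar, seq`. `@SQ` header lines, when present, are validated
#' against `ref` (name and length).
#'
#' @param path SAM file (uncompressed text).
#' @param ref Optional [reference_genome()] to validate `@SQ` headers and
#'   record names against.
#' @return A data frame of class `sam_records`.
#' @export
read_sam <- function(path, ref = NULL) {
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  if (!is.null(ref)) {
    sq <- lines[hdr & grepl("^@SQ", lines)]
    for (l in sq) {
      sn <- sub(".*\tSN:([^\t]+).*", "\\1", l)
      ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", l))
      if (sn != ref$name || ln != ref$length)
        stop(sprintf("SAM @SQ (%s, %d bp) does not match reference (%s, %d bp)",
                     sn, ln, ref$name, ref$length))
    }
  }
  body <- lines[!hdr]
  if (length(body) == 0L)
    return(structure(
      data.frame(qname = character(), flag = integer(), rname = character(),
                 pos = integer(), mapq = integer(), cigar = character(),
                 seq = character()),
      class = c("sam_records", "data.frame")))
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) < 11L))
    stop("malformed SAM: a record has fewer than 11 fields")
  get <- function(i) vapply(f, `[[`, character(1), i)
  rec <- data.frame(
    qname = get(1), flag = as.integer(get(2)), rname = get(3),
    pos = as.integer(get(4)), mapq = as.integer(get(5)), cigar = get(6),
    seq = toupper(get(10)))
  if (!is.null(ref)) {
    mapped <- bitwAnd(rec$flag, 4L) == 0L
    bad <- mapped & rec$rname != ref$name
    if (any(bad))
      stop(sprintf("SAM record %s aligned to unknown reference '%s'",
                   rec$qname[which(bad)[1]], rec$rname[which(bad)[1]]))
  }
  class(rec) <- c("sam_records", "data.frame")
  rec
}

#' Write alignments as a plain-text SAM file
#'
#' @param records A `sam_records` data frame (columns `qname, flag, rname,
#'   pos, mapq, cigar, seq`).
#' @param ref A [reference_genome()] for the `@SQ` header.
#' @param path Output path.
#' @param pg Optional one-line provenance comment (written as `@CO`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, ref, path, pg = NULL) {
  records <- as.data.frame(records)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", ref$name, ref$length))
  if (!is.null(pg)) hdr <- c(hdr, paste0("@CO\t", pg))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar, records$seq)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# parse a CIGAR string into (lengths, ops); "*" -> zero ops
parse_cigar <- function(cigar) {
  if (cigar == "*") return(list(len = integer(), op = character()))
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (length(toks) == 0L || sum(attr(m, "match.length")) != nchar(cigar))
    stop(sprintf("malformed CIGAR '%s'", cigar))
  list(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}
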