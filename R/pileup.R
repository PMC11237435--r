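# Pileup construction and fixed-difference SNP calling.
#
# Coordinates are 0-based half-open internally; SAM's 1-based positions are
# converted at the boundary and written back as 1-based in VCF output.

BASES <- c("A", "C", "G", "T")

# map ASCII codes to base codes 1..4 (A,C,G,T), 0 otherwise
base_code_table <- local({
  tab <- integer(256)
  tab[utf8ToInt("A")] <- 1L; tab[utf8ToInt("C")] <- 2L
  tab[utf8ToInt("G")] <- 3L; tab[utf8ToInt("T")] <- 4L
  tab[utf8ToInt("a")] <- 1L; tab[utf8ToInt("c")] <- 2L
  tab[utf8ToInt("g")] <- 3L; tab[utf8ToInt("t")] <- 4L
  tab
})

#' Build a per-position base-count pileup from alignments
#'
#' Walks each aligned record's CIGAR: `M`, `=` and `X` consume reference and
#' read and increment the base count at the reference position; `D` and `N`
#' consume reference only; `I` and `S` consume read only; `H` and `P`
#' consume neither. Unmapped, secondary and supplementary records are
#' skipped. A record whose read-consuming CIGAR length disagrees with its
#' sequence length raises an error naming the read.
#'
#' @param ref A [reference_genome()].
#' @param alignments A `sam_records` data frame from [read_sam()] /
#'   [simulate_reads()], or a path to a SAM file.
#' @return An object of class `pileup`: list with `counts` (4 x L integer
#'   matrix, rows A/C/G/T), `depth` (length-L integer), `ref_code`
#'   (length-L base codes, 0 for N) and `length`.
#' @export
build_pileup <- function(ref, alignments) {
  stopifnot(inherits(ref, "reference_genome"))
  if (is.character(alignments) && length(alignments) == 1L)
    alignments <- read_sam(alignments, ref = ref)
  aln <- as.data.frame(alignments)
  L <- ref$length
  keep <- bitwAnd(aln$flag, 4L) == 0L &
    bitwAnd(aln$flag, 256L) == 0L &
    bitwAnd(aln$flag, 2048L) == 0L
  aln <- aln[keep, , drop = FALSE]
  tab <- integer(4L * L)

  add_counts <- function(refpos, codes) {
    ok <- codes > 0L & refpos >= 1L & refpos <= L
    idx <- (refpos[ok] - 1L) * 4L + codes[ok]
    t2 <- tabulate(idx, nbins = 4L * L)
    tab <<- tab + t2
  }

  simple <- grepl("^[0-9]+M$", aln$cigar)
  if (any(simple)) {
    s <- aln[simple, , drop = FALSE]
    lens <- as.integer(sub("M$", "", s$cigar))
    bad <- lens != nchar(s$seq)
    if (any(bad))
      stop(sprintf("read %s: CIGAR consumes %d read bases but sequence has %d",
                   s$qname[which(bad)[1]], lens[which(bad)[1]],
                   nchar(s$seq[which(bad)[1]])))
    # chunked so the expanded position vector stays bounded in memory
    chunk <- max(1L, 2e6 %/% max(lens, 1L))
    starts <- seq(1L, nrow(s), by = chunk)
    for (b in starts) {
      e <- min(b + chunk - 1L, nrow(s))
      refpos <- sequence(lens[b:e], from = s$pos[b:e])
      codes <- base_code_table[utf8ToInt(paste(s$seq[b:e], collapse = ""))]
      add_counts(refpos, codes)
    }
  }

  complex_idx <- which(!simple)
  for (k in complex_idx) {
    cig <- parse_cigar(aln$cigar[k])
    read_consumed <- sum(cig$len[cig$op %in% c("M", "I", "S", "=", "X")])
    if (read_consumed != nchar(aln$seq[k]))
      stop(sprintf("read %s: CIGAR consumes %d read bases but sequence has %d",
                   aln$qname[k], read_consumed, nchar(aln$seq[k])))
    codes_all <- base_code_table[utf8ToInt(aln$seq[k])]
    rp <- aln$pos[k]; qp <- 1L
    refpos <- integer(0); codes <- integer(0)
    for (j in seq_along(cig$op)) {
      len <- cig$len[j]; op <- cig$op[j]
      if (op %in% c("M", "=", "X")) {
        refpos <- c(refpos, rp + seq_len(len) - 1L)
        codes <- c(codes, codes_all[qp + seq_len(len) - 1L])
        rp <- rp + len; qp <- qp + len
      } else if (op %in% c("D", "N")) {
        rp <- rp + len
      } else if (op %in% c("I", "S")) {
        qp <- qp + len
      } # H, P: consume neither
    }
    add_counts(refpos, codes)
  }

  counts <- matrix(tab, nrow = 4L,
                   dimnames = list(BASES, NULL))
  structure(list(counts = counts, depth = colSums(counts),
                 ref_code = base_code_table[utf8ToInt(ref$seq)],
                 length = L, ref_name = ref$name),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d positions, mean depth %.2f\n",
              x$length, mean(x$depth)))
  invisible(x)
}

#' Call fixed-difference SNPs from a pileup
#'
#' Emits biallelic substitution calls at positions where depth is at least
#' `min_depth` and the most frequent non-reference base reaches frequency
#' `min_alt_freq`. The defaults target fixed differences between
#' time-separated populations rather than within-sample polymorphism.
#' Positions whose reference base is N are excluded; indels are ignored.
#'
#' @param pileup A [build_pileup()] result.
#' @param min_depth Minimum depth (>= 1).
#' @param min_alt_freq Minimum alternate-allele frequency, in (0, 1].
#' @return A data frame of class `snp_calls` with columns `pos` (0-based),
#'   `ref`, `alt`, `freq`, `depth`.
#' @export
call_snps <- function(pileup, min_depth = 5, min_alt_freq = 0.9) {
  stopifnot(inherits(pileup, "pileup"),
            min_depth >= 1, min_alt_freq > 0, min_alt_freq <= 1)
  cand <- which(pileup$depth >= min_depth & pileup$ref_code > 0L)
  if (length(cand) == 0L)
    return(empty_snp_calls())
  cnt <- pileup$counts[, cand, drop = FALSE]
  # mask the reference base so the column max is the top alternate allele
  cnt[cbind(pileup$ref_code[cand], seq_along(cand))] <- -1L
  alt_code <- max.col(t(cnt), ties.method = "first")
  alt_count <- cnt[cbind(alt_code, seq_along(cand))]
  freq <- alt_count / pileup$depth[cand]
  hit <- freq >= min_alt_freq & alt_count > 0L
  out <- data.frame(pos = cand[hit] - 1L,
                    ref = BASES[pileup$ref_code[cand[hit]]],
                    alt = BASES[alt_code[hit]],
                    freq = freq[hit],
                    depth = pileup$depth[cand[hit]])
  class(out) <- c("snp_calls", "data.frame")
  out
}

empty_snp_calls <- function() {
  out <- data.frame(pos = integer(), ref = character(), alt = character(),
                    freq = numeric(), depth = integer())
  class(out) <- c("snp_calls", "data.frame")
  out
}

#' Length and fraction of the reference covered at a minimum depth
#'
#' @param pileup A [build_pileup()] result.
#' @param min_depth Depth threshold.
#' @return Named numeric `c(mapped_length, fraction)`.
#' @export
mapped_region_length <- function(pileup, min_depth = 5) {
  ml <- sum(pileup$depth >= min_depth)
  c(mapped_length = ml, fraction = ml / pileup$length)
}

#' SNP accumulation rate and read-based nucleotide identity
#'
#' Converts a fixed-difference SNP count over a mapped reference length and
#' a known elapsed time into the calibration statistic: SNPs per Mb per
#' century. Also reports the read-based average nucleotide identity
#' `ANI = 100 * (1 - snp_count / mapped_length)`.
#'
#' @param snp_count Number of fixed-difference SNPs.
#' @param mapped_length Reference length the rate is normalised by (bp);
#'   by convention the mapped (covered) length, not the full genome length.
#' @param elapsed Elapsed time between the two samples (yr).
#' @return An object of class `rate_estimate` with fields `snp_count`,
#'   `mapped_length`, `elapsed`, `rate` (SNPs/Mb/century) and `ani` (%).
#' @export
snp_rate <- function(snp_count, mapped_length, elapsed) {
  if (!(mapped_length > 0)) stop("snp_rate: mapped_length must be > 0")
  if (!(elapsed > 0)) stop("snp_rate: elapsed must be > 0")
  structure(list(
    snp_count = snp_count, mapped_length = mapped_length, elapsed = elapsed,
    rate = snp_count / (mapped_length / 1e6) / (elapsed / 100),
    ani = 100 * (1 - snp_count / mapped_length)),
    class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> %d SNPs over %d bp in %.1f yr\n  rate = %.1f SNPs/Mb/century, ANI = %.3f%%\n",
    x$snp_count, as.integer(x$mapped_length), x$elapsed, x$rate, x$ani))
  invisible(x)
}

#' Write SNP calls as minimal VCF
#'
#' @param calls A `snp_calls` data frame (0-based positions; written 1-based).
#' @param ref A [reference_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, ref, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", ref$name, ref$length),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt frequency\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f",
                  ref$name, calls$pos + 1L, calls$ref, calls$alt,
                  calls$depth, calls$freq)
  writeLines(c(hdr, body), path)
  invisible(path)
}
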