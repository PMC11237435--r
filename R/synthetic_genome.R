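# Synthetic genomes, time-evolved descendants with planted substitutions,
# and read simulation with truth alignments.

#' Generate a random reference genome with optional coding regions
#'
#' Bases are drawn i.i.d. with the requested GC content. Coding regions are
#' laid out as non-overlapping, in-frame genes (default 900 bp) whose
#' codons are resampled to exclude stop codons, so a coding mask with
#' enforced dN/dS behaviour can be used by [evolve_genome()].
#'
#' @param L Genome length (bp, >= 1).
#' @param gc GC fraction in `[0, 1]`.
#' @param coding_fraction Target fraction of the genome inside genes.
#' @param gene_len Gene length (bp, multiple of 3).
#' @param seed RNG seed; the same seed reproduces the genome exactly.
#' @param name Reference name.
#' @return A [reference_genome()] with attribute `coding`: data frame of
#'   1-based, in-frame gene `start`/`end` coordinates (possibly empty).
#' @export
make_genome <- function(L, gc = 0.5, coding_fraction = 0, gene_len = 900,
                        seed = 1, name = "synthetic_genome") {
  stopifnot(L >= 1, gc >= 0, gc <= 1, gene_len %% 3 == 0)
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- sample(VALID_NT, L, replace = TRUE, prob = p)
  coding <- data.frame(start = integer(), end = integer())
  n_genes <- floor(L * coding_fraction / gene_len)
  if (n_genes > 0) {
    stride <- L %/% n_genes
    starts <- (seq_len(n_genes) - 1L) * stride + 1L
    starts <- starts[starts + gene_len - 1L <= L]
    codons <- non_stop_codons()
    cw <- codon_weights(codons, p)
    for (s in starts) {
      gene <- sample(codons, gene_len / 3, replace = TRUE, prob = cw)
      chars[s:(s + gene_len - 1L)] <- unlist(strsplit(gene, ""))
    }
    coding <- data.frame(start = starts, end = starts + gene_len - 1L)
  }
  g <- reference_genome(name, paste(chars, collapse = ""))
  attr(g, "coding") <- coding
  g
}

non_stop_codons <- function() {
  code <- genetic_code()
  names(code)[code != "*"]
}

codon_weights <- function(codons, p) {
  vapply(codons, function(cd) {
    ch <- strsplit(cd, "")[[1]]
    prod(p[ch])
  }, numeric(1))
}

#' Evolve a genome by planting substitutions at a known per-site rate
#'
#' Each site mutates independently with probability `r * t` (enforced
#' `< 0.05` so multiple hits are negligible and the planted count is the
#' exact divergence). Transitions are favoured over each transversion by
#' `kappa`. Inside coding regions the substitution class is chosen
#' Bernoulli(`omega`) non-synonymous vs synonymous, then a base change of
#' that class (never creating a stop codon) is drawn; if the class has no
#' available change at the site, the other class is used.
#'
#' @param genome A [reference_genome()] (e.g. from [make_genome()]); its
#'   `coding` attribute, if present, provides the coding mask.
#' @param r Per-site substitution rate (1/yr).
#' @param t Elapsed time (yr).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param omega Target non-synonymous fraction among coding substitutions.
#' @param seed RNG seed.
#' @return An object of class `evolution_truth`: list with `ancestral`,
#'   `descendant` (both [reference_genome()]), `positions` (1-based),
#'   `ref`, `alt`, and the parameters. Planted positions are exactly the
#'   ancestral/descendant mismatches.
#' @export
evolve_genome <- function(genome, r, t, kappa = 2, omega = 0.5, seed = 1) {
  stopifnot(inherits(genome, "reference_genome"), r >= 0, t >= 0)
  mu <- r * t
  if (mu >= 0.05)
    stop("evolve_genome: r * t >= 0.05 risks multiple hits; lower the rate or time")
  set.seed(seed)
  L <- genome$length
  chars <- strsplit(genome$seq, "")[[1]]
  sites <- which(stats::runif(L) < mu & chars %in% VALID_NT)
  coding <- attr(genome, "coding")
  in_coding <- rep(FALSE, L)
  gene_start <- integer(L)
  if (!is.null(coding) && nrow(coding) > 0) {
    for (k in seq_len(nrow(coding))) {
      idx <- coding$start[k]:coding$end[k]
      in_coding[idx] <- TRUE
      gene_start[idx] <- coding$start[k]
    }
  }
  code <- genetic_code()
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  desc <- chars
  ref_al <- character(length(sites)); alt_al <- character(length(sites))
  classify_alts <- function(pos) {
    off <- pos - gene_start[pos]             # 0-based offset within gene
    cstart <- pos - off %% 3
    codon <- desc[cstart:(cstart + 2L)]
    cpos <- pos - cstart + 1L
    aa0 <- unname(code[paste(codon, collapse = "")])
    alts <- setdiff(VALID_NT, desc[pos])
    cls <- vapply(alts, function(b) {
      mutc <- codon; mutc[cpos] <- b
      aa <- unname(code[paste(mutc, collapse = "")])
      if (aa == "*") "stop" else if (aa == aa0) "syn" else "nonsyn"
    }, character(1))
    list(alts = alts, cls = cls, cstart = cstart)
  }
  for (m in seq_along(sites)) {
    pos <- sites[m]
    refb <- desc[pos]
    alts <- setdiff(VALID_NT, refb)
    w <- ifelse(alts == transition[[refb]], kappa, 1)
    if (in_coding[pos]) {
      cc <- classify_alts(pos)
      want <- if (stats::runif(1) < omega) "nonsyn" else "syn"
      pool <- cc$alts[cc$cls == want]
      if (length(pool) == 0L) {
        # the wanted class is unavailable at this position (e.g. no
        # synonymous change off a 1st/2nd codon position): relocate the
        # substitution within the same codon if an untouched position
        # offers it, otherwise fall back to the other class here
        for (p2 in setdiff(cc$cstart + 0:2, pos)) {
          if (desc[p2] != chars[p2] || p2 %in% sites) next
          c2 <- classify_alts(p2)
          pool2 <- c2$alts[c2$cls == want]
          if (length(pool2) > 0L) {
            pos <- p2
            refb <- desc[pos]
            alts <- c2$alts
            w <- ifelse(alts == transition[[refb]], kappa, 1)
            pool <- pool2
            break
          }
        }
      }
      if (length(pool) == 0L) pool <- cc$alts[cc$cls != "stop"]
      if (length(pool) == 0L) pool <- alts   # unreachable for table 1
      wp <- w[match(pool, alts)]
      alt <- if (length(pool) == 1L) pool else sample(pool, 1L, prob = wp)
      sites[m] <- pos
    } else {
      alt <- sample(alts, 1L, prob = w)
    }
    desc[pos] <- alt
    ref_al[m] <- refb; alt_al[m] <- alt
  }
  ord <- order(sites)
  sites <- sites[ord]; ref_al <- ref_al[ord]; alt_al <- alt_al[ord]
  descendant <- reference_genome(paste0(genome$name, "_desc"),
                                 paste(desc, collapse = ""))
  attr(descendant, "coding") <- coding
  structure(list(ancestral = genome, descendant = descendant,
                 positions = sites, ref = ref_al, alt = alt_al,
                 r = r, t = t, kappa = kappa, omega = omega, seed = seed),
            class = "evolution_truth")
}

#' @export
print.evolution_truth <- function(x, ...) {
  cat(sprintf(
    "<evolution_truth> %d substitutions planted on %d bp (r*t = %.3g)\n",
    length(x$positions), x$ancestral$length, x$r * x$t))
  invisible(x)
}

#' Simulate shotgun reads with a truth alignment
#'
#' Reads start uniformly on the genome; per-base errors occur independently
#' at `err_rate` and always change the base. Base qualities are uniform
#' (downstream SNP calling is frequency/depth-based). The returned records
#' double as the truth SAM: positions are exact and CIGARs are all-match,
#' with `seq` stored in reference orientation. With `paired = TRUE`,
#' proper-pair mates are generated from opposite ends of
#' `insert_size`-length fragments.
#'
#' @param genome A [reference_genome()] (typically the evolved descendant).
#' @param coverage Target mean depth (> 0).
#' @param read_len Read length (bp, default 150).
#' @param paired Generate paired-end reads (default FALSE).
#' @param err_rate Per-base sequencing error rate.
#' @param insert_size Mean fragment length for paired mode.
#' @param seed RNG seed; the same seed gives byte-identical output.
#' @return A `sam_records` data frame (class also `read_set`) with
#'   attributes `errors` (data frame `read`, `offset`) and `params`.
#' @export
simulate_reads <- function(genome, coverage, read_len = 150, paired = FALSE,
                           err_rate = 0, insert_size = 400, seed = 1) {
  stopifnot(inherits(genome, "reference_genome"),
            coverage > 0, read_len <= genome$length)
  set.seed(seed)
  L <- genome$length
  n_reads <- ceiling(coverage * L / read_len)
  if (paired) {
    n_pairs <- ceiling(n_reads / 2)
    frag <- pmax(2L * read_len,
                 round(stats::rnorm(n_pairs, insert_size, insert_size / 10)))
    frag <- as.integer(pmin(frag, L))
    fstart <- 1L + as.integer(floor(stats::runif(n_pairs) * (L - frag + 1L)))
    pos <- c(fstart, fstart + frag - read_len)
    flag <- c(rep(99L, n_pairs), rep(147L, n_pairs))
    qname <- c(sprintf("read_%d", seq_len(n_pairs)),
               sprintf("read_%d", seq_len(n_pairs)))
  } else {
    pos <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
    strand <- sample(c(0L, 16L), n_reads, replace = TRUE)
    flag <- strand
    qname <- sprintf("read_%d", seq_len(n_reads))
  }
  n <- length(pos)
  seqs <- substring(genome$seq, pos, pos + read_len - 1L)
  errors <- data.frame(read = integer(), offset = integer())
  if (err_rate > 0) {
    hits <- which(stats::runif(n * read_len) < err_rate)
    if (length(hits) > 0) {
      er <- (hits - 1L) %/% read_len + 1L
      eo <- (hits - 1L) %% read_len + 1L
      for (j in seq_along(hits)) {
        old <- substr(seqs[er[j]], eo[j], eo[j])
        new <- sample(setdiff(VALID_NT, old), 1L)
        substr(seqs[er[j]], eo[j], eo[j]) <- new
      }
      errors <- data.frame(read = er, offset = eo)
    }
  }
  rec <- data.frame(qname = qname, flag = flag, rname = genome$name,
                    pos = as.integer(pos), mapq = 60L,
                    cigar = sprintf("%dM", read_len), seq = seqs)
  class(rec) <- c("read_set", "sam_records", "data.frame")
  attr(rec, "errors") <- errors
  attr(rec, "params") <- list(coverage = coverage, read_len = read_len,
                              paired = paired, err_rate = err_rate,
                              seed = seed)
  rec
}

revcomp <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' Write simulated reads as FASTQ
#'
#' Reverse-strand reads are reverse-complemented into read orientation;
#' qualities are uniform `I` (Q40).
#'
#' @param reads A `read_set` from [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- reads$seq
  rev <- bitwAnd(reads$flag, 16L) != 0L
  if (any(rev)) seqs[rev] <- revcomp(seqs[rev])
  qual <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@", reads$qname), seqs, "+", qual)),
             path)
  invisible(path)
}
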