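# Nei-Gojobori (1986-style, equal pathway weighting) synonymous /
# non-synonymous analysis and the amino-acid substitution-rate statistic.

genetic_code <- function() Biostrings::GENETIC_CODE  # standard table 1

translate_codon <- function(codon, code = genetic_code()) {
  aa <- unname(code[codon])
  if (is.na(aa)) stop(sprintf("untranslatable codon '%s'", codon))
  aa
}

# fraction of non-stop single-base changes of `codon` that are synonymous,
# per position; sites s_i = fraction, n_i = 1 - s_i, so S + N = 3 exactly
codon_site_fractions <- function(codon, code = genetic_code()) {
  aa0 <- translate_codon(codon, code)
  ch <- strsplit(codon, "")[[1]]
  s <- numeric(3)
  for (i in 1:3) {
    syn <- 0L; tot <- 0L
    for (b in setdiff(VALID_NT, ch[i])) {
      mut <- ch; mut[i] <- b
      aa <- unname(code[paste(mut, collapse = "")])
      if (aa == "*") next  # mutations to stop codons are disregarded
      tot <- tot + 1L
      if (aa == aa0) syn <- syn + 1L
    }
    s[i] <- if (tot > 0L) syn / tot else 0
  }
  s
}

# Sd/Nd for one codon pair: average over equal-weight orderings of the
# single-base steps; pathways passing through a stop codon are discarded.
# If every pathway is blocked by a stop, all pathways are used and
# stop-involving steps count as non-synonymous (degenerate fallback).
codon_pair_differences <- function(a, b, code = genetic_code()) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  dpos <- which(ca != cb)
  d <- length(dpos)
  if (d == 0L) return(c(Sd = 0, Nd = 0))
  perms <- permutations_of(dpos)
  walk <- function(ord, allow_stops) {
    cur <- ca; syn <- 0; non <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- cb[p]
      aa1 <- unname(code[paste(cur, collapse = "")])
      aa2 <- unname(code[paste(nxt, collapse = "")])
      if (!allow_stops && (aa1 == "*" || aa2 == "*")) return(NULL)
      if (aa1 == aa2 && aa1 != "*") syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    c(syn, non)
  }
  res <- lapply(perms, walk, allow_stops = FALSE)
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) res <- lapply(perms, walk, allow_stops = TRUE)
  m <- do.call(rbind, res)
  c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
}

permutations_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutations_of(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

split_codons <- function(seq) {
  s <- as_residues(seq)
  if (length(s) %% 3 != 0)
    stop("nei_gojobori: sequence length must be divisible by 3 (codon-aligned)")
  apply(matrix(s, nrow = 3), 2, paste, collapse = "")
}

#' Nei-Gojobori synonymous / non-synonymous analysis of two coding sequences
#'
#' Counts synonymous and non-synonymous differences and potential sites for
#' a pair of codon-aligned nucleotide sequences under the standard genetic
#' code. Potential sites per codon are the per-position fractions of
#' non-stop single-base changes that are synonymous, averaged between the
#' two sequences; multi-step codon differences are averaged over all
#' orderings of single-base pathways with equal weight, discarding pathways
#' through stop codons. `pS = Sd/S` and `pN = Nd/N` are corrected to `dS`,
#' `dN` with [jc69_distance()].
#'
#' Codons containing a gap or ambiguity in either sequence are skipped
#' whole; an internal stop codon in either input frame is an error.
#'
#' @param a,b Codon-aligned nucleotide sequences (strings or character
#'   vectors) of equal length divisible by 3.
#' @return An object of class `dnds_result`: list with `Sd`, `Nd`, `S`,
#'   `N`, `codons` (compared), `pS`, `pN`, `dS`, `dN` and `dnds`
#'   (`NA` if `dS` is 0).
#' @export
nei_gojobori <- function(a, b) {
  code <- genetic_code()
  ca <- split_codons(a); cb <- split_codons(b)
  if (length(ca) != length(cb))
    stop("nei_gojobori: sequences must be aligned to equal codon length")
  ok_codon <- function(x) !grepl("[^ACGT]", x)
  usable <- ok_codon(ca) & ok_codon(cb)
  for (k in which(usable)) {
    if (translate_codon(ca[k], code) == "*" ||
        translate_codon(cb[k], code) == "*")
      stop(sprintf("internal stop codon at codon index %d", k))
  }
  Sa <- 0; Sb <- 0; Sd <- 0; Nd <- 0; ncod <- 0L
  for (k in which(usable)) {
    Sa <- Sa + sum(codon_site_fractions(ca[k], code))
    Sb <- Sb + sum(codon_site_fractions(cb[k], code))
    dd <- codon_pair_differences(ca[k], cb[k], code)
    Sd <- Sd + dd[["Sd"]]; Nd <- Nd + dd[["Nd"]]
    ncod <- ncod + 1L
  }
  if (ncod == 0L) stop("nei_gojobori: no comparable codons")
  S <- (Sa + Sb) / 2
  N <- 3 * ncod - S
  # S can be 0 (e.g. Met/Trp-only comparisons have no synonymous sites);
  # then Sd is necessarily 0 too and the proportion is taken as 0
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  # JC69 correction saturates at p >= 3/4 (possible on very short inputs);
  # report NA for the affected corrected quantity rather than failing
  jc_or_na <- function(p) if (p < 0.75) jc69_distance(p) else NA_real_
  dS <- jc_or_na(pS); dN <- jc_or_na(pN)
  structure(list(Sd = Sd, Nd = Nd, S = S, N = N, codons = ncod,
                 pS = pS, pN = pN, dS = dS, dN = dN,
                 dnds = if (!is.na(dS) && !is.na(dN) && dS > 0)
                   dN / dS else NA_real_),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf(
    "<dnds_result> %d codons: Sd=%.3f Nd=%.3f S=%.2f N=%.2f dS=%.5f dN=%.5f dN/dS=%s\n",
    x$codons, x$Sd, x$Nd, x$S, x$N, x$dS, x$dN,
    ifelse(is.na(x$dnds), "NA", sprintf("%.4f", x$dnds))))
  invisible(x)
}

#' Amino-acid substitution rate between two aligned proteins
#'
#' Counts differences with pairwise gap/ambiguity deletion and scales to
#' substitutions per 100 residues per century:
#' `rate = (differences / positions * 100) / (elapsed / 100)`.
#'
#' @param a,b Aligned protein sequences (strings or character vectors).
#' @param elapsed Time separating the two sequences (yr, > 0).
#' @return An object of class `subst_rate_estimate` with fields
#'   `differences`, `positions`, `elapsed` and `rate`.
#' @export
aa_substitution_rate <- function(a, b, elapsed) {
  if (!(elapsed > 0)) stop("aa_substitution_rate: elapsed must be > 0")
  a <- as_residues(a); b <- as_residues(b)
  if (length(a) != length(b))
    stop("aa_substitution_rate: sequences must be aligned to equal length")
  ok <- a %in% VALID_AA & b %in% VALID_AA
  n <- sum(ok)
  if (n == 0L)
    stop("aa_substitution_rate: no comparable positions after pairwise deletion")
  diffs <- sum(a[ok] != b[ok])
  structure(list(differences = diffs, positions = n, elapsed = elapsed,
                 rate = (diffs / n * 100) / (elapsed / 100)),
            class = "subst_rate_estimate")
}

#' @export
print.subst_rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<subst_rate_estimate> %d differences / %d positions over %.1f yr\n  rate = %.4f substitutions per 100 aa per century\n",
    x$differences, x$positions, x$elapsed, x$rate))
  invisible(x)
}
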