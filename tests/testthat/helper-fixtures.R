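# Shared fixtures and independent oracles for the test suite.

NT <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(NT, n, replace = TRUE), collapse = "")

mutate_dna <- function(s, n_mut) {
  ch <- strsplit(s, "")[[1]]
  idx <- sample(length(ch), n_mut)
  ch[idx] <- vapply(ch[idx],
                    function(b) sample(setdiff(NT, b), 1), character(1))
  paste(ch, collapse = "")
}

# alignment matrix from a character vector of equal-length sequences
aln_matrix <- function(seqs, ids = paste0("t", seq_along(seqs))) {
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- ids
  m
}

# uniform velocity field whose domain comfortably contains [0, 10 km]
uniform_field <- function(u0 = 250, v0 = 0) {
  make_velocity_field("uniform", u0 = u0, v0 = v0,
                      x = seq(-2000, 14000, 500),
                      y = seq(-4000, 4000, 500))
}

constant_basal <- function(field, ab = -0.5, sigma = 0) {
  scalar_field(field$x, field$y,
               matrix(ab, length(field$y), length(field$x)),
               matrix(sigma, length(field$y), length(field$x)))
}

# ---- independent Nei-Gojobori oracle -------------------------------------
# Exhaustive enumeration, written against the genetic-code table directly
# and independently of the package's pathway walker.

GC1 <- Biostrings::GENETIC_CODE

oracle_site_fractions <- function(codon) {
  aa0 <- GC1[[codon]]
  out <- 0
  for (i in 1:3) {
    muts <- character(0)
    for (b in NT) {
      if (substr(codon, i, i) == b) next
      m <- codon
      substr(m, i, i) <- b
      muts <- c(muts, m)
    }
    aas <- GC1[muts]
    aas <- aas[aas != "*"]
    if (length(aas) > 0) out <- out + sum(aas == aa0) / length(aas)
  }
  out
}

all_orderings <- function(x) {
  if (length(x) <= 1) return(list(x))
  do.call(c, lapply(seq_along(x), function(i)
    lapply(all_orderings(x[-i]), function(r) c(x[i], r))))
}

oracle_pair_differences <- function(a, b) {
  dpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(dpos) == 0) return(c(Sd = 0, Nd = 0))
  paths <- list(); blocked <- list()
  for (ord in all_orderings(dpos)) {
    cur <- a; syn <- 0; non <- 0; hits_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (GC1[[cur]] == "*" || GC1[[nxt]] == "*") hits_stop <- TRUE
      if (GC1[[cur]] == GC1[[nxt]] && GC1[[cur]] != "*") syn <- syn + 1
      else non <- non + 1
      cur <- nxt
    }
    rec <- c(syn, non)
    if (hits_stop) blocked[[length(blocked) + 1]] <- rec
    else paths[[length(paths) + 1]] <- rec
  }
  use <- if (length(paths) > 0) paths else blocked
  m <- do.call(rbind, use)
  c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
}

random_sense_codon <- function() {
  repeat {
    cd <- random_dna(3)
    if (GC1[[cd]] != "*") return(cd)
  }
}

# ---- brute-force 4-taxon topology oracle ---------------------------------
# Fits edge lengths of each of the three unrooted 4-taxon topologies by
# least squares; the generating topology is the one with zero residual.

brute_force_quartet <- function(D) {
  labs <- rownames(D)
  pairings <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  best <- NULL
  for (pg in pairings) {
    # edges: e1..e4 terminal (taxa pg), e5 internal; rows = 6 pairs
    A <- matrix(0, 6, 5); y <- numeric(6); r <- 1
    for (i in 1:3) for (j in (i + 1):4) {
      ti <- pg[i]; tj <- pg[j]
      A[r, i] <- 1; A[r, j] <- 1
      same_side <- (i <= 2 && j <= 2) || (i >= 3 && j >= 3)
      if (!same_side) A[r, 5] <- 1
      y[r] <- D[ti, tj]
      r <- r + 1
    }
    fit <- qr.solve(crossprod(A), crossprod(A, y))
    resid <- sum((A %*% fit - y)^2)
    if (is.null(best) || resid < best$resid)
      best <- list(pg = pg, edges = drop(fit), resid = resid)
  }
  split <- sort(labs[best$pg[1:2]])
  other <- sort(labs[best$pg[3:4]])
  key <- if (paste(split, collapse = ",") < paste(other, collapse = ","))
    paste(split, collapse = ",") else paste(other, collapse = ",")
  list(split = key, edges = best$edges, resid = best$resid)
}

# random unrooted binary tree with strictly positive branch lengths and its
# additive distance matrix (oracle inputs for NJ consistency)
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 1)
  D <- ape::cophenetic.phylo(tr)
  list(tree = tr, D = D[tr$tip.label, tr$tip.label])
}
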