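# SAM parsing, pileup construction, SNP calling and the rate statistic.

ref10 <- function() reference_genome("ref", "ACGTACGTAC")

rec <- function(qname, pos, cigar, seq, flag = 0L) {
  data.frame(qname = qname, flag = flag, rname = "ref", pos = pos,
             mapq = 60L, cigar = cigar, seq = seq)
}

test_that("pileup walks simple and complex CIGARs correctly", {
  ref <- ref10()
  p <- build_pileup(ref, rec("r1", 1L, "10M", "ACGTACGTAC"))
  expect_equal(p$depth, rep(1, 10))
  expect_equal(p$counts["A", c(1, 5, 9)], c(1, 1, 1))
  expect_equal(sum(p$counts), 10)

  # overlapping reads, one mismatch in the overlap
  two <- rbind(rec("r1", 1L, "6M", "ACGTAC"),
               rec("r2", 4L, "6M", "TGCGTA"))  # mismatch at ref pos 5 (A->G)
  p2 <- build_pileup(ref, two)
  expect_equal(p2$depth[5], 2)
  expect_equal(unname(p2$counts["A", 5]), 1)
  expect_equal(unname(p2$counts["G", 5]), 1)

  # 5M2D5M consumes 12 reference positions; deleted columns gain no counts
  p3 <- build_pileup(reference_genome("ref", strrep("A", 15)),
                     rec("r1", 1L, "5M2D5M", strrep("A", 10)))
  expect_equal(p3$depth[1:12], c(rep(1, 5), 0, 0, rep(1, 5)))
  expect_equal(sum(p3$depth), 10)

  # insertions and soft clips consume read only
  p4 <- build_pileup(ref10(), rec("r1", 2L, "2S3M2I3M", "GGCGTAAACG"))
  expect_equal(sum(p4$depth), 6)
  expect_equal(p4$depth[2:7], rep(1, 6))

  # unmapped and secondary records are skipped
  p5 <- build_pileup(ref, rbind(rec("r1", 1L, "10M", "ACGTACGTAC"),
                                rec("r2", 1L, "10M", "ACGTACGTAC", flag = 4L),
                                rec("r3", 1L, "10M", "ACGTACGTAC", flag = 256L)))
  expect_equal(sum(p5$depth), 10)

  expect_error(build_pileup(ref, rec("bad", 1L, "9M", "ACGTACGTAC")), "bad")
})

test_that("pileup depth equals aligned base-bearing bases (conservation)", {
  set.seed(42)
  ref <- reference_genome("ref", random_dna(500))
  reads <- simulate_reads(ref, coverage = 8, read_len = 50, err_rate = 0.01,
                          seed = 7)
  p <- build_pileup(ref, reads)
  expect_equal(sum(p$depth), nrow(reads) * 50)
  expect_equal(sum(p$counts), sum(p$depth))
})

test_that("pileup matches the Rsamtools oracle on a mixed fixture", {
  skip_if_not_installed("Rsamtools")
  set.seed(11)
  ref <- reference_genome("ref", random_dna(300))
  reads <- simulate_reads(ref, coverage = 6, read_len = 40, err_rate = 0.02,
                          seed = 3)
  dir <- tempfile(); dir.create(dir)
  sam <- file.path(dir, "aln.sam")
  write_sam(reads, ref, sam)
  mine <- build_pileup(ref, read_sam(sam, ref = ref))

  bam <- Rsamtools::asBam(sam, file.path(dir, "aln"), overwrite = TRUE)
  pp <- Rsamtools::PileupParam(max_depth = 10000, min_base_quality = 0,
                               min_mapq = 0, distinguish_strands = FALSE,
                               include_insertions = FALSE)
  oracle <- Rsamtools::pileup(bam, pileupParam = pp)
  counts <- matrix(0L, 4, ref$length, dimnames = list(c("A", "C", "G", "T"),
                                                      NULL))
  keep <- oracle$nucleotide %in% rownames(counts)
  counts[cbind(match(as.character(oracle$nucleotide[keep]), rownames(counts)),
               oracle$pos[keep])] <- oracle$count[keep]
  expect_equal(unname(mine$counts), unname(counts))
  unlink(dir, recursive = TRUE)
})

test_that("SAM text round-trips through write_sam/read_sam", {
  set.seed(2)
  ref <- reference_genome("ref", random_dna(200))
  reads <- simulate_reads(ref, coverage = 3, read_len = 30, seed = 5)
  f <- tempfile(fileext = ".sam")
  write_sam(reads, ref, f)
  back <- read_sam(f, ref = ref)
  expect_equal(back$pos, reads$pos)
  expect_equal(back$cigar, reads$cigar)
  expect_equal(back$seq, reads$seq)
  # @SQ validation catches a mismatched reference
  expect_error(read_sam(f, ref = reference_genome("other", "ACGT")),
               "does not match")
  unlink(f)
})

test_that("call_snps applies depth and frequency thresholds", {
  ref <- reference_genome("ref", "AAAAAAAAAA")
  mk_reads <- function(n_alt, n_ref, pos = 5L) {
    alt <- if (n_alt > 0) rec(sprintf("a%d", 1:n_alt), pos, "1M", "G")
    else NULL
    rf <- if (n_ref > 0) rec(sprintf("r%d", 1:n_ref), pos, "1M", "A")
    else NULL
    rbind(alt, rf)
  }
  # depth 10, all alternate -> call at frequency 1
  calls <- call_snps(build_pileup(ref, mk_reads(10, 0)))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$pos, 4)  # 0-based
  expect_equal(calls$ref, "A")
  expect_equal(calls$alt, "G")
  expect_equal(calls$freq, 1)
  # depth 4 < min_depth -> no call
  expect_equal(nrow(call_snps(build_pileup(ref, mk_reads(4, 0)))), 0)
  # 50% alternate below min_alt_freq 0.9 -> no call
  expect_equal(nrow(call_snps(build_pileup(ref, mk_reads(5, 5)))), 0)
})

test_that("mapped_region_length counts covered positions", {
  ref <- reference_genome("ref", random_dna(1000))
  empty <- build_pileup(ref, rec("r", 1L, "10M", "ACGTACGTAC")[0, ])
  expect_equal(unname(mapped_region_length(empty)), c(0, 0))
  one <- build_pileup(ref, rec("r1", 101L, "100M",
                               substr(ref$seq, 101, 200)))
  expect_equal(unname(mapped_region_length(one, min_depth = 1)),
               c(100, 0.1))
})

test_that("snp_rate computes the calibration statistic and ANI", {
  r <- snp_rate(2500, 1e6, 100)
  expect_equal(r$rate, 2500)
  expect_equal(r$ani, 100 * (1 - 2500 / 1e6))

  expect_equal(snp_rate(0, 1e6, 100)$rate, 0)
  expect_equal(snp_rate(0, 1e6, 100)$ani, 100)
  expect_equal(snp_rate(1000, 2e6, 200)$rate, 250)
  expect_error(snp_rate(10, 0, 100), "mapped_length")
  expect_error(snp_rate(10, 1e6, 0), "elapsed")

  # linear in count, inversely linear in length and time
  set.seed(1)
  for (k in 1:20) {
    n <- sample(1:5000, 1); L <- runif(1, 1e5, 5e6); t <- runif(1, 10, 500)
    base <- snp_rate(n, L, t)$rate
    expect_equal(snp_rate(3 * n, L, t)$rate, 3 * base)
    expect_equal(snp_rate(n, 2 * L, t)$rate, base / 2)
    expect_equal(snp_rate(n, L, 4 * t)$rate, base / 4)
  }
})

test_that("VCF output is 1-based and carries depth/frequency", {
  ref <- reference_genome("ref", "AAAAAAAAAA")
  reads <- rec(sprintf("a%d", 1:10), 5L, "1M", "G")
  calls <- call_snps(build_pileup(ref, reads))
  f <- tempfile(fileext = ".vcf")
  write_vcf(calls, ref, f)
  lines <- readLines(f)
  body <- lines[!grepl("^#", lines)]
  expect_length(body, 1)
  expect_match(body, "^ref\t5\t\\.\tA\tG\t.*DP=10;AF=1")
  unlink(f)
})
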