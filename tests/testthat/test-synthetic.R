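# Synthetic-data generators: fields, scenarios, genomes, reads.

test_that("make_velocity_field attaches exact strain oracles", {
  u <- make_velocity_field("uniform")
  expect_equal(attr(u, "ezz_fn")(0, 0), 0)
  expect_equal(vertical_strain_rate(u, c(12, 34)), 0)

  d <- make_velocity_field("divergent", k = 0.004)
  expect_equal(attr(d, "ezz_fn")(99, 1), -0.004)
  expect_equal(vertical_strain_rate(d, c(99, 1)), -0.004)

  r <- make_velocity_field("rotational", k = 2)
  expect_equal(vertical_strain_rate(r, c(50, -70)), 0)
  expect_error(make_velocity_field("vortex"))
})

test_that("make_segments attaches closed forms and seeded noise", {
  seg <- make_segments(ice_scenario("constant_accretion", a = 0.5,
                                    n_segments = 100, dt = 1))
  cf <- attr(seg, "closed_form")
  expect_equal(cf(100), 50)

  ss <- make_segments(ice_scenario("steady_strain", a = 0.5, eps = 0.005,
                                   n_segments = 100, dt = 1))
  cf2 <- attr(ss, "closed_form")
  expect_equal(cf2(100), (0.5 / 0.005) * (1 - exp(-0.5)))

  # melt episode bookkeeping by hand: 5 segments accrete 1 m each; the
  # 2-segment episode melts 1.5 m total, removing layer 5 (0.25 m left
  # after step 6) and 0.5 m of layer 4 -> [1, 1, 1, 0.5]
  sc <- ice_scenario("accretion_with_melt_episode", a = 1, n_segments = 7,
                     dt = 1, melt_rate = 0.75, episode = c(6, 7))
  run <- run_flowline(make_segments(sc))
  expect_equal(run$stack$h, c(1, 1, 1, 0.5))
  expect_equal(total_thickness(run$stack), 3.5)

  p1 <- make_segments(ice_scenario("paper_like", n_segments = 50, seed = 4))
  p2 <- make_segments(ice_scenario("paper_like", n_segments = 50, seed = 4))
  expect_identical(p1$ab, p2$ab)  # deterministic under seed
  expect_lt(mean(p1$ab[1:25]), 0)   # accretion early
  expect_gt(mean(p1$ab[46:50]), 0)  # melting late

  # degenerate uncertainty
  s0 <- make_segments(ice_scenario("constant_accretion", sigma_ab = 0))
  a <- age_with_uncertainty(s0, 10)
  expect_equal(unname(a[1]), unname(a[3]))
})

test_that("make_genome honours GC, determinism and the coding mask", {
  g <- make_genome(1e5, gc = 0.5, seed = 42)
  gc_obs <- mean(strsplit(g$seq, "")[[1]] %in% c("G", "C"))
  se <- sqrt(0.25 / 1e5)
  expect_lt(abs(gc_obs - 0.5), 3 * se)

  g2 <- make_genome(1e5, gc = 0.5, seed = 42)
  expect_identical(g$seq, g2$seq)

  expect_equal(nrow(attr(make_genome(1000, coding_fraction = 0), "coding")), 0)

  gc3 <- make_genome(3e4, coding_fraction = 0.5, seed = 7)
  coding <- attr(gc3, "coding")
  expect_gt(nrow(coding), 0)
  # genes are in frame with no internal stop codons
  code <- Biostrings::GENETIC_CODE
  for (k in seq_len(nrow(coding))) {
    gene <- substr(gc3$seq, coding$start[k], coding$end[k])
    codons <- substring(gene, seq(1, nchar(gene), 3), seq(3, nchar(gene), 3))
    expect_false(any(code[codons] == "*"))
  }
})

test_that("evolve_genome plants the stated divergence", {
  g <- make_genome(1e5, seed = 1)
  ev0 <- evolve_genome(g, r = 0, t = 100, seed = 2)
  expect_identical(ev0$descendant$seq, g$seq)
  expect_length(ev0$positions, 0)

  ev <- evolve_genome(g, r = 2.5e-5, t = 100, seed = 3)  # r*t = 2.5e-3
  n_exp <- 1e5 * 2.5e-3
  expect_lt(abs(length(ev$positions) - n_exp), 3 * sqrt(n_exp))
  # planted positions are exactly the ancestral/descendant mismatches
  anc <- strsplit(ev$ancestral$seq, "")[[1]]
  des <- strsplit(ev$descendant$seq, "")[[1]]
  expect_identical(which(anc != des), as.integer(ev$positions))
  expect_identical(anc[ev$positions], ev$ref)
  expect_identical(des[ev$positions], ev$alt)

  # kappa -> infinity: every planted change is a transition
  evk <- evolve_genome(make_genome(5e4, seed = 5), r = 2e-4, t = 100,
                       kappa = 1e9, seed = 6)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  expect_true(all(evk$alt == ts_map[evk$ref]))

  expect_error(evolve_genome(g, r = 1e-3, t = 100), "multiple hits")
})

test_that("evolve_genome steers the non-synonymous fraction with omega", {
  g <- make_genome(9e4, coding_fraction = 0.9, seed = 9)
  frac_nonsyn <- function(omega) {
    ev <- evolve_genome(g, r = 3e-4, t = 100, omega = omega, seed = 10)
    coding <- attr(g, "coding")
    in_cd <- rep(FALSE, g$length)
    for (k in seq_len(nrow(coding)))
      in_cd[coding$start[k]:coding$end[k]] <- TRUE
    sel <- ev$positions[in_cd[ev$positions]]
    code <- Biostrings::GENETIC_CODE
    anc <- strsplit(ev$ancestral$seq, "")[[1]]
    des <- strsplit(ev$descendant$seq, "")[[1]]
    nonsyn <- vapply(sel, function(pos) {
      gs <- coding$start[findInterval(pos, coding$start)]
      cstart <- pos - (pos - gs) %% 3
      code[paste(anc[cstart:(cstart + 2)], collapse = "")] !=
        code[paste(des[cstart:(cstart + 2)], collapse = "")]
    }, logical(1))
    mean(nonsyn)
  }
  lo <- frac_nonsyn(0.1)
  hi <- frac_nonsyn(0.9)
  expect_lt(lo, 0.35)
  expect_gt(hi, 0.65)
})

test_that("simulate_reads produces exact truth alignments", {
  g <- make_genome(5000, seed = 30)
  one <- simulate_reads(g, coverage = 150 / 5000, read_len = 150,
                        err_rate = 0, seed = 31)
  expect_equal(nrow(one), 1)
  expect_identical(one$seq, substr(g$seq, one$pos, one$pos + 149))

  reads <- simulate_reads(g, coverage = 20, read_len = 150,
                          err_rate = 0, seed = 32)
  expect_equal(nrow(reads), ceiling(20 * 5000 / 150))

  r1 <- simulate_reads(g, coverage = 5, err_rate = 1e-3, seed = 33)
  r2 <- simulate_reads(g, coverage = 5, err_rate = 1e-3, seed = 33)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(r1, f1); write_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical under seed
  unlink(c(f1, f2))

  # every truth record round-trips through the SAM reader
  sam <- tempfile(fileext = ".sam")
  write_sam(r1, g, sam)
  back <- read_sam(sam, ref = g)
  expect_identical(back$pos, r1$pos)
  expect_identical(back$cigar, r1$cigar)
  expect_identical(back$seq, r1$seq)
  unlink(sam)
})

test_that("paired reads form proper fragments", {
  g <- make_genome(20000, seed = 40)
  reads <- simulate_reads(g, coverage = 4, paired = TRUE,
                          insert_size = 400, seed = 41)
  n_pairs <- nrow(reads) / 2
  first <- reads[seq_len(n_pairs), ]
  second <- reads[n_pairs + seq_len(n_pairs), ]
  expect_identical(first$qname, second$qname)
  expect_true(all(second$pos >= first$pos))
  expect_true(all(second$pos + 150 - first$pos <= 20000))
})

test_that("planted SNPs are recovered end-to-end at desk scale", {
  g <- make_genome(1e5, gc = 0.45, seed = 50)
  ev <- evolve_genome(g, r = 2.5e-5, t = 100, seed = 51)
  reads <- simulate_reads(ev$descendant, coverage = 20, err_rate = 1e-3,
                          seed = 52)
  sam <- tempfile(fileext = ".sam")
  write_sam(reads, ev$descendant, sam)
  pil <- build_pileup(g, read_sam(sam))
  calls <- call_snps(pil, min_depth = 5, min_alt_freq = 0.9)
  ml <- mapped_region_length(pil, min_depth = 5)
  est <- snp_rate(nrow(calls), ml[["mapped_length"]], elapsed = 100)
  planted_rate <- length(ev$positions) / (g$length / 1e6) / 1
  expect_lt(abs(est$rate - planted_rate) / planted_rate, 0.05)
  # false positives per Mb stay small with 0.1% errors at freq 0.9
  fp <- sum(!(calls$pos %in% (ev$positions - 1L)))
  expect_lt(fp / (ml[["mapped_length"]] / 1e6), 5)
  unlink(sam)
})
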