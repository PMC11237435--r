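# iceclock

Marine ice accreted beneath Antarctic ice shelves preserves seawater — and
the microbes in it — for centuries. If a dated layer of that ice yields
sequenceable DNA, comparing it with present-day relatives of the same
lineage turns the ice core into a molecular-clock calibration: two samples
of one population separated by a known span of time. `iceclock` implements
both halves of that calculation for R users:

1. **Dating the ice.** A Lagrangian layer-tracking model follows a column
   of shelf ice from the grounding line along its flowline. For each
   segment of the journey the basal mass balance adds marine ice
   (`ΔH_m = −a_b Δt`, with `a_b > 0` for melting) as a new bottom layer or
   melts existing layers newest-first, and every layer is thinned by the
   vertical strain rate (`h ← h·exp(ε̇_zz Δt)`, with
   `ε̇_zz = −(∂u/∂x + ∂v/∂y)` from the horizontal velocity field). The
   result is an age–depth profile of the marine column, with uncertainty
   bounds propagated from the melt-rate uncertainties.

2. **Calibrating the clock.** Reads from the dated sample are piled up
   against a modern reference genome; positions where the reads
   near-unanimously carry a non-reference allele are counted as fixed
   differences, and the count becomes a rate in SNPs·Mb⁻¹·century⁻¹
   (plus a read-based average nucleotide identity). For single genes, the
   package provides Jukes–Cantor distances
   (`d = −¾·ln(1 − 4p/3)`), Saitou–Nei neighbor joining with bootstrap
   supports, Nei–Gojobori dN/dS, and the amino-acid substitution rate in
   substitutions per 100 residues per century.

A synthetic-data module generates every input — analytic velocity fields
with exact strain-rate oracles, forcing scenarios with closed-form
thickness solutions, genomes diverged at a known planted rate with
controlled Ts/Tv and non-synonymous fractions, and simulated reads with
exact truth alignments — so the entire pipeline is testable offline.

## Worked example

Date a synthetic ice column (steady accretion 0.5 m/yr thinned at
0.005 /yr for 1,000 yr), then recover a planted substitution rate:

```r
library(iceclock)

seg <- make_segments(ice_scenario("steady_strain", a = 0.5, eps = 0.005,
                                  n_segments = 2000, dt = 0.5))
run <- run_flowline(seg)
run
#> <flowline_run> 2000 segments over 1000.0 yr; final Hm = 99.20 m in 2000 layers
prof <- age_depth_profile(run$stack, run$total_time)
age_at_depth(prof, 50)
#> [1] 135.7057
```

The modeled thickness (99.20 m) sits 0.12% from the closed form
`(a/ε)(1 − e^{−εT}) = 99.33 m`; ice 50 m below the meteoric interface was
accreted ~136 yr before arrival.

```r
g     <- make_genome(1e5, coding_fraction = 0.8, seed = 7)
ev    <- evolve_genome(g, r = 2.5e-5, t = 100, seed = 8)   # r·t = 2.5e-3
reads <- simulate_reads(ev$descendant, coverage = 15, err_rate = 1e-3,
                        seed = 9)
pil   <- build_pileup(g, reads)
calls <- call_snps(pil, min_depth = 5, min_alt_freq = 0.9)
ml    <- mapped_region_length(pil, min_depth = 5)
snp_rate(nrow(calls), ml[["mapped_length"]], elapsed = 100)
#> <rate_estimate> 257 SNPs over 99857 bp in 100.0 yr
#>   rate = 2573.7 SNPs/Mb/century, ANI = 99.743%
```

257 of 259 planted substitutions are recovered with no false positives;
the rate lands in the planted ~2,500 SNPs·Mb⁻¹·century⁻¹ regime. The
protein-level statistic:

```r
aa_substitution_rate(strrep("A", 100), paste0("C", strrep("A", 99)),
                     elapsed = 100)$rate
#> [1] 1   # one substitution per 100 residues per century
```

## Command-line use

Thin wrappers live in `inst/cli/` (locate with
`system.file("cli", package = "iceclock")`):

```sh
Rscript $CLI/simulate.R ice  --scenario steady_strain --n-segments 2000 --dt 0.5 --out seg.tsv
Rscript $CLI/age_depth.R     --segments seg.tsv --depth 50 --out profile.tsv
Rscript $CLI/simulate.R reads --length 1e6 --rate 2.5e-3 --coverage 20 --seed 7 --out-prefix sim
Rscript $CLI/snp_rate.R      --ref sim_ancestral.fasta --sam sim_truth.sam --elapsed-years 100
Rscript $CLI/nj.R            --aln aln.fasta --bootstrap 1000 --seed 42 --out tree.nwk
Rscript $CLI/subst_rate.R    --aln aa.fasta --pair SAG22,IceCore --elapsed-years 326.5
Rscript $CLI/trace_flowline.R --velocity vel.csv --basal melt.csv --start 0,0 --out seg.tsv
```

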