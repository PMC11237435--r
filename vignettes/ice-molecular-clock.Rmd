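---
title: "Dating marine ice and calibrating microbial evolutionary rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating marine ice and calibrating microbial evolutionary rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iceclock)
```

## The problem

Ice shelves carry two archives at once. Below the meteoric ice (compacted
snowfall), seawater freezes onto the shelf base as *marine ice* wherever
the basal mass balance favours accretion; because new ice is always added
at the ice–ocean interface, the **oldest marine ice lies at the top** of
the marine column (against the meteoric ice) and the youngest at the
bottom. Dating a depth in that column therefore requires following the
ice column along its flowline from the grounding line and bookkeeping the
accretion, melting and strain thinning it experiences — a Lagrangian
layer-tracking computation. If a dated layer yields DNA of a lineage that
is still alive nearby today, the pair of samples separated by a known
time span calibrates that lineage's molecular clock: substitutions
accumulated per unit genome per unit time.

`iceclock` implements both computations and the synthetic world needed to
test them without external downloads.

## The layer model

For each flowline segment `i` (250 m of arc length by default) with
duration `Δt = length / speed`, the marine-ice thickness change is

```
ΔH_m = −a_b Δt
```

with `a_b` the basal melt/accretion rate, **positive for melting**. A
positive `ΔH_m` is appended as a new layer at the bottom of the stack
with its accretion timestamp; a negative `ΔH_m` melts ice from the newest
layer downward in last-in-first-out order, deleting exhausted layers and
their ages. After the mass step, every layer is thinned by the vertical
strain rate, which incompressibility ties to the horizontal velocity
divergence:

```
ε̇_zz = −(∂u/∂x + ∂v/∂y),     h ← h · exp(ε̇_zz Δt)
```

The exponential is the exact solution of `dh/dt = ε̇_zz h` over the
segment; the first-order factor `1 + ε̇_zz Δt` agrees to `O(Δt²)` and is
available via `apply_thinning(..., method = "linear")`. The source
recursions this model was rebuilt from print the thinning step as a bare
product of thickness and `ε̇_zz Δt`, which would annihilate the column;
the exponential reading is the only dimensionally consistent one and is
the package's fixed choice.

Ages: layer `j`'s accretion timestamp `τ_j` is the cumulative transit
time at the **end** of its accreting segment (the upper boundary of the
layer is dated by the segment start, so the top of the column carries the
full transit time). `age_depth_profile()` converts timestamps to years
before drilling, `total_transit_time − τ_j + drill_lag`, and
interpolates linearly between layer boundaries. `drill_lag` (time between
the column reaching the core site and the drilling) defaults to 0 and is
exposed because the source record is silent about it.

Three behaviours worth knowing:

* **Stack exhaustion.** A melt demand exceeding the marine column is
  clamped at `H_m = 0`; the shortfall is recorded per step as
  `melt_deficit` and warned about, never silently dropped and never
  allowed to eat into meteoric ice.
* **Partial melt** of a layer keeps the layer's timestamps; the
  within-layer age interpolation of a partially melted layer is therefore
  slightly stretched. The model reports layer-boundary ages exactly.
* **Uncertainty.** `age_with_uncertainty()` reruns the whole model with
  all basal rates shifted by ±1σ (`mode = "systematic"`, the default and
  the more conservative envelope) or with independent per-segment
  Gaussian perturbations (`mode = "mc"`, seeded). Whether a real
  uncertainty product should be treated as systematic or independent is
  genuinely open; both are provided and the choice is the caller's.

### Flowline tracing

`trace_flowline()` integrates the streamline with classical RK4
parameterised by arc length (fixed 50 m step by default; verified to
reproduce an analytic circular streamline to 10⁻³ relative radius at
step/radius = 0.01). Flow slower than 1 m/yr terminates the trace —
transit time diverges as speed → 0, so treating near-stagnant ice as a
boundary is safer than integrating through it. Strain rates use central
finite differences at the grid nodes of the cell containing the query
point, interpolated bilinearly (exact for fields linear in x and y);
queries within one cell of the grid boundary **error** rather than
degrade to one-sided differences. Forcing values (`a_b`, σ, speed,
`ε̇_zz`) are sampled at segment midpoints — the simplest consistent
reading of per-segment forcing; a trailing remainder shorter than the
segment length is kept as a final truncated segment so transit time is
conserved.

## The rate calibration

`build_pileup()` walks SAM records' CIGAR strings (`M/=/X` consume
reference and read, `D/N` reference only, `I/S` read only, `H/P`
neither; unmapped/secondary/supplementary records skipped) into
per-position A/C/G/T counts. `call_snps()` emits a fixed-difference call
where depth ≥ 5 and the top non-reference base reaches frequency ≥ 0.9 —
thresholds chosen to detect substitutions *between* time-separated
populations rather than within-sample polymorphism, and both exposed as
parameters since the original analysis ran in a commercial package whose
thresholds are unpublished. The calibration statistic is

```
rate = snp_count / (mapped_length / 10⁶) / (elapsed / 100)     [SNPs·Mb⁻¹·century⁻¹]
ANI  = 100 · (1 − snp_count / mapped_length)                    [%]
```

normalised by **mapped** length (positions at calling depth) by default;
the full genome length is available behind a flag. `elapsed` is always an
explicit argument: for a core drilled in 1992 whose sampled layers date
275–328 yr before drilling, compared against seawater sampled in 2017, a
natural choice is `(2017 − 1992) + 301.5 ≈ 326.5` yr — but published
rate statements of this kind cannot always be inverted to a unique
divisor, so no default is hard-wired.

For single genes the package provides the classical machinery:
`jc69_distance()` (`d = −¾ ln(1 − 4p/3)`, errors at `p ≥ ¾`),
`nj_tree()` (Saitou–Nei agglomeration on the Q-criterion; negative branch
lengths clamped to 0 with the deficit moved to the sister edge),
`bootstrap_support()` (column resampling; replicates hitting JC
saturation are skipped and counted, never imputed), `nei_gojobori()` and
`aa_substitution_rate()` (differences per 100 residues per century, with
pairwise gap deletion).

Nei–Gojobori conventions, fixed here because the original tool left them
unstated: gaps/ambiguities are deleted pairwise by whole codons;
potential sites per position are the fraction of **non-stop** single-base
changes that are synonymous (so `S + N = 3 ×` codons exactly); multi-step
codon differences are averaged over all orderings of single-base pathways
with equal weight, pathways through stop codons discarded (with an
all-blocked fallback counting stop steps as non-synonymous); `pN`, `pS`
are JC-corrected. Two small-input edge cases are defined rather than
fatal: `pS` (or `pN`) beyond the JC domain yields `dS = NA`, and `S = 0`
(comparisons involving only Met/Trp codons) yields `pS = 0`.

## The synthetic world

The generators state a world once and the tests measure the pipeline
against it; none of their defaults were tuned to test outcomes.

* `make_velocity_field()` samples uniform, divergent (`u = kx`) or
  rotational (`u = −ky, v = kx`) fields and attaches the exact strain
  function, giving the tracer and strain code analytic oracles.
* `make_segments()` builds forcing scenarios: `constant_accretion`
  (`H = aT`, linear ages), `steady_strain`
  (`H(t) = (a/ε)(1 − e^{−εt})`, attached as a closed form),
  `accretion_with_melt_episode`, and `paper_like` — accretion over the
  early flowline and a melt episode near the end, magnitudes of order
  1 m/yr as in the ice-shelf literature. The defaults `a = 0.5` m/yr and
  `ε = 0.005`/yr give a century-to-millennium column of O(100 m),
  the regime of interest. `paper_like` is a qualitative synthetic
  stand-in, never a reconstruction of a real shelf.
* `make_genome()` draws i.i.d. bases at a target GC and carves in-frame,
  stop-free genes covering a coding fraction (default gene length
  900 bp ≈ a typical prokaryotic CDS).
* `evolve_genome()` mutates each site independently with probability
  `r·t` (enforced `< 0.05`, so multiple hits are negligible and the
  mismatch list *is* the truth set), favours transitions by `κ`
  (default 2), and steers the non-synonymous fraction of coding changes
  to `ω`. Because most 1st/2nd codon positions offer no synonymous
  change, a plain accept/reject cannot reach low `ω`; the generator
  instead relocates the change within the codon to a position where the
  chosen class exists, falling back to the other class for codons that
  have none (Met, Trp). Planted counts stay Binomial(L, r·t).
* `simulate_reads()` places reads uniformly, plants independent base
  errors that always change the base, and returns records that double as
  an exact truth SAM (all-match CIGARs, reference-orientation
  sequences, uniform qualities — the caller is frequency/depth-based and
  ignores qualities). The default emulation is 150 bp reads at 20×
  with 0.1% error, the stated sequencing regime. Because the divergence
  model is substitution-only, descendant coordinates coincide with the
  ancestral reference and the truth SAM is valid against it directly.

What a green test establishes — and what it does not: recovery of a
planted rate through pileup → calling → normalisation shows the counting
machinery is unbiased under uniform coverage and independent errors. Real
metagenomic read sets add amplification bias, indels, contamination and
mapping ambiguity, none of which are simulated; the acceptance suite
makes claims only about the stated world.

## Numerical choices

* RK4 step 50 m; stagnation threshold 1 m/yr; segment forcing at
  midpoints; partial trailing segments kept.
* Thinning factor `exp(ε̇_zz Δt)`; the accretion discretisation is first
  order in `Δt` (the steady-strain check shows ~0.12% error at
  `Δt = 0.5` yr against the ODE solution, shrinking with `Δt`).
* Layer bookkeeping tolerances: thickness identity to 10⁻⁹ m; a layer
  melted to within 10⁻¹⁵ m is removed.
* NJ ties on the Q-criterion break to the first minimum in column-major
  order; branch lengths are serialised at 17 significant digits so path
  lengths round-trip to 10⁻⁸.
* Coordinates are 0-based half-open internally; SAM/VCF positions are
  converted at the format boundary.
* All stochastic generators take explicit seeds and are reproducible to
  the byte.

## Known limitations

* The ice model is mass bookkeeping, not thermodynamics: no frazil-ice
  physics, meteoric accumulation, firn densification, or time-varying
  forcing. Forcing fields observed today are assumed representative of
  the whole transit — an assumption inherited from the method itself and
  not quantifiable within it.
* The SNP caller targets fixed differences only; within-sample allele
  spectra, indels and base qualities are out of scope.
* JC69 is the only substitution model wired into distances and tree
  building; the dN/dS implementation is the equal-pathway-weight
  counting method, not a codon model.
* Velocity/forcing grids are read from long-format CSV only; no NetCDF
  reader is bundled (none is available in the supported dependency set)
  and no map reprojection is attempted — grids must arrive in a common
  projected coordinate system in metres.
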