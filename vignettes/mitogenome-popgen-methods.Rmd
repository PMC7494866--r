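---
title: "Methods: mitogenome population genetics in porpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome population genetics in porpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

porpopgen analyses whole-mitogenome alignments of closely related cetacean
lineages: typically one ~16.3-kb circular genome per individual, a few to a
few dozen individuals per lineage, lineages nested within species. This
vignette records the statistical models the package implements, the
assumptions behind them, and the numerical and design choices a maintainer
would want spelled out. Nothing here reports an empirical result; all
quantitative claims about the implementation are the ones the test suite
and `scripts/acceptance.R` recompute.

## Data model and partitions

An alignment is a `MitoAlignment`: equal-width sequences plus a per-column
map to *original* coordinates. Masking (e.g. an unalignable control-region
repeat) removes columns but keeps the map, so annotations stated on
original coordinates stay resolvable afterwards. Coordinates are 1-based
inclusive throughout (GenBank/GFF convention); BED masks are converted on
read from 0-based half-open. Because interval ends quoted in the
literature are sometimes inclusive and sometimes half-open, the
`maskIntervals()` constructor takes an `inclusive` flag; the inclusive
reading is the default. A quoted repeat interval of 15,508–15,734 spans
227 columns inclusive but 226 half-open — both are one call away, and the
analysis downstream is insensitive to one column either way.

Three partitions drive the comparative tables:

* **whole** — the masked alignment as-is;
* **noncoding** — columns covered by no CDS/tRNA/rRNA/origin feature, in
  genomic order (intergenic spacers plus the control region);
* **cds_concat** — protein-coding genes concatenated in annotation order.
  Minus-strand genes are reverse-complemented so codon positions are
  assignable; columns inside gene overlaps are emitted once *per gene*, so
  the concatenation length is the sum of gene lengths, not the union —
  with the mitochondrial ND5/ND6 17-bp overlap this makes the CDS
  partition 17 bp longer than the union, and each gene keeps its own
  reading frame. A terminal codon left incomplete (mitochondrial CDSs
  often end on an incomplete stop completed by polyadenylation) is
  dropped with a warning rather than an error.

**Missing data.** All statistics use complete deletion: a column with any
gap, `N`, or IUPAC ambiguity in any sequence is removed for every
sequence. The per-pair alternative would retain more sites for some pairs
but makes *S* depend on which pair you ask about; complete deletion keeps
*S*, *π*, and the haplotype partition mutually consistent and is the
default of the desktop tools this package's outputs are meant to be
comparable with. Haplotype identity is likewise evaluated on usable
columns only, so sequences differing solely at excluded columns collapse.

## Diversity statistics

For usable sites *L* and *n* sequences: *S* counts columns with ≥ 2
states; a segregating site is a *singleton* when every non-major state is
carried by exactly one sequence, otherwise a *shared polymorphism*; η sums
(states − 1) per column and η_s counts variants whose minority lineage is
one sequence (so both frequency-1 and frequency-(n−1) derived classes,
as appropriate without an outgroup). π is the mean pairwise difference
count over all C(n,2) pairs — computed from per-column state counts,
which the test suite verifies equals both the explicit pair loop and the
site-frequency-spectrum form Σ 2c(n−c)/(n(n−1)). Standard deviations for
π and haplotype diversity follow Nei (1987, eqs. 10.7 and 8.12), which is
what desktop tools print, making cross-checks possible. θ_W = S/(a₁L).

**Rarefaction.** Lineages with n from 3 to ~27 are not comparable on raw
π, so `rarefiedPi()` draws k distinct sequences without replacement
(default k = 3, the smallest informative pool, matching the smallest
lineages), B = 2,500 times, recomputing usable columns inside each
subsample, and summarises the replicate distribution by median, mean and
the 2.5/97.5 percentiles. Percentile intervals were chosen over normal
approximations because the replicate distribution is discrete and skewed
at these pool sizes; with n = k the interval width is exactly zero by
construction. The resampler is seed-deterministic.

## Codon analyses and the McDonald–Kreitman test

All codon work uses NCBI translation table 2 (vertebrate mitochondrial:
ATA = Met, TGA = Trp, AGA/AGG = stop). The code table is configurable,
but table 2 is the only defensible choice for vertebrate mitochondrial
CDSs — under the standard code the ATA↔ATG contrast would flip from
synonymous to nonsynonymous, and AGA/AGG would translate as arginine.

Site counting is Nei–Gojobori: each codon position contributes, for each
of its three possible changes, 1/3 of a site classified by whether the
change is silent; changes that would create a stop are excluded from the
denominator, so per codon syn + nonsyn + stop-excluded = 3 exactly (the
test suite asserts this over all 64 codons). Differences between codons
differing at several positions are averaged over all minimal mutational
pathways, excluding pathways through stop codons; if every pathway is
blocked the pair is skipped with a warning. π_N and π_S divide mean
pairwise nonsynonymous/synonymous differences by the corresponding site
counts; π_N/π_S is flagged undefined when π_S = 0 rather than erroring,
because small lineages genuinely produce zero synonymous polymorphism.

The MK test classifies each codon column: segregating within the ingroup
→ polymorphism (counted as a star from the majority codon to each minor
codon); ingroup-monomorphic and different from the outgroup consensus →
fixed difference. Codons simultaneously polymorphic and divergent count
as polymorphism only — the conservative resolution, and the one that
keeps the 2×2 margins interpretable when ancestral states are unknown.
The outgroup state is the majority consensus when several outgroup
sequences are supplied. NI = (Pn/Ps)/(Dn/Ds) is computed on the
fractional pathway-averaged counts; the G and Fisher tests need integer
cells, so the table is rounded half-to-even for testing only, and both
tables are reported. The G-test is uncorrected by default (the primary
output of the desktop tools); the Williams correction is behind a flag.
No pseudocounts are added when a cell is zero — NI is flagged undefined
instead — with an optional Haldane +0.5 behind a flag, because silent
pseudocounts change NI materially at mitogenome-scale counts.

Group comparisons of NI distributions use a permutation one-way F-type
test (default 9,999 permutations, p = (1 + #{perm ≥ obs})/(B + 1)) with
pairwise contrasts adjusted by Benjamini–Hochberg; groups with fewer than
two observations are excluded with a warning rather than failing the run.

## Neutrality tests and their p-values

Tajima's D uses the 1989 normalization. Fu & Li's D* and F* (the
no-outgroup "starred" versions) use the corrected variance constants of
Simonsen, Churchill & Aquadro (1995); the originally printed constants
contain typos, and the corrected forms are what standard implementations
agree on — the test suite locks both statistics to independently coded
oracles at 1e-10 on random alignments.

P-values come from coalescent simulation under the standard neutral
constant-size model, *conditioned on the observed S* (exactly S mutations
placed uniformly on the genealogy). Fixed-S conditioning rather than
fixed-θ matches the simulation convention of the desktop tools whose
two-tailed test this reproduces: p = 2·min(P(stat ≤ obs), P(stat ≥ obs)),
capped at 1, with the +1-corrected empirical proportions so p ∈ (0, 1].
The acceptance suite verifies test size: under neutral data (n = 20,
θ = 10) the rejection rate at 0.05 falls in [0.03, 0.07] over 2,000
replicates, with null distributions of 600 simulations per observed S.

## Mismatch distributions

The expected pairwise-difference distribution under constant size is
geometric, F(k) = θ^k/(θ+1)^(k+1). Under a sudden size change — diversity
θ₀ until τ mutational units ago, θ₁ since (τ = 2µt, µ per sequence per
generation) — the transient law is the two-epoch pair-coalescent closed
form: the θ₁ equilibrium plus an exponentially damped convolution of the
equilibrium difference, implemented as a polynomial product via FFT. Both
limit cases (τ = 0 → constant at θ₀; τ → ∞ → constant at θ₁) are asserted
in the tests, as is normalization to 1e-9 tail tolerance.

Fitting minimizes the sum of squared deviations between observed and
expected mismatch frequencies with bounded `nlminb` from eight
deterministic starts spanning several decades of (θ₀, θ₁, τ), ties broken
by lowest SSD then lowest τ. θ₁ ≥ θ₀ is *not* imposed by default — decline
is as admissible as growth — with a constrained mode available. The
parametric bootstrap (default B = 10,000) resimulates coalescent data of
the same sample size under the fitted model, refits each replicate
(warm-started at the point estimate plus one coarse start; the full
8-start sweep adds nothing on resimulated histograms and quadruples the
cost), and reports 95% percentile CIs and p_SSD = P(SSD_boot ≥ SSD_obs).
Monomorphic data collapse to the τ = 0 boundary with a degenerate-fit
flag rather than an optimizer failure. Observed histograms use the same
complete-deletion columns as the diversity module, so S, π and the
mismatch histogram stay internally consistent.

Unit conversions assume a maternally inherited, effectively haploid
genome: t = τ/(2µ_seq) generations with µ_seq = rate·L·generation time
(defaults 5×10⁻⁸ substitutions/site/year and 10-year generations, the
standard values for cetacean mitogenomes), and N_e = θ_total/(2µ_seq).

## The synthetic-data generator

`synthMitogenomeSet()` emulates the *shape* of a porpoise mitogenome
study: a ~16.3-kb genome with 13 CDSs (one minus-strand gene overlapping
its neighbour by 17 bp), 22 tRNAs, 2 rRNAs, an origin feature and a
control region; lineages of n = 1–27 sequences; per-lineage Kingman
genealogies under constant-size or sudden-expansion demographies;
infinite-sites mutations mapped to distinct genome positions (collisions
resampled — effectively infinite sites at mitogenome scale); and CDS
mutations forced nonsynonymous with a configurable probability by
rejection-sampling target positions (bounded retries, then an
unconstrained fallback that is counted and warned about). Ancestral CDS
frames are generated stop-free, including across the strand-overlap
constraint. Time inside the simulator is in coalescent units; τ is
converted once via θ₁ (t_change = τ/θ₁), since users state expansion ages
in mutational units. A single seeded RNG stream makes output files
byte-identical across runs.

What the generator does *not* emulate — and therefore what passing tests
do not certify about real data: substitution-model complexity (no
transition/transversion bias, no rate heterogeneity, no multiple hits),
alignment and assembly error, heteroplasmy, selection (the simulator is
neutral by construction; the nonsynonymous fraction is a composition
dial, not a fitness model), recombination (absent in mtDNA anyway), and
shared genealogy between lineages (groups are independent coalescents
hung off a common ancestral sequence via Poisson divergence mutations).
Calibration results on synthetic data bound implementation correctness,
not robustness to those real-data features.

Default demographic parameters follow the study conditions the package
is aimed at: lineage sizes of 3–27, per-sequence θ chosen to put π in
the 0.02–1% per-site range observed across porpoise lineages (θ ≈ 49
targets π = 0.3% at 16.3 kb), and expansion scenarios like
(θ₀ = 1, θ₁ = 100, τ = 5) whose τ/θ ratios match recent post-glacial
expansions.

## Problem sizes in the test suite

The suite runs the statistical checks at the sizes the methods are meant
for, chosen once: 200 random alignments (n ≤ 6, L ≤ 60) against
brute-force oracles; 2,000 neutral replicates at n = 20, θ = 10 for the
Tajima/Watterson calibrations; 500 neutral ingroup/outgroup pairs of
3,800 codons (n = 8, θ = 40, 100 expected divergence mutations —
mitogenome-CDS scale, large enough that the ratio bias of NI stays well
inside its band) for the MK calibration; and 100 expansion replicates
(n = 30) with B = 200 bootstrap refits for mismatch recovery and CI
coverage. Bootstrap defaults in production use remain B = 10,000.

## Known limitations

* The MK polymorphism count uses a majority-codon star, which can
  undercount within-codon mutations when three or more codon states
  segregate at once; at mitogenome polymorphism densities this is rare.
* NI is a ratio of ratios and is biased upward at small counts even
  under neutrality; the package reports the raw counts alongside so
  users can apply their preferred correction.
* Fixed-S null distributions condition on S but not on the mutation
  frequency spectrum; this is the standard convention but is known to be
  slightly conservative for extreme S.
* The sudden-expansion model is a single instantaneous size change;
  ragged multi-modal mismatch distributions (old structure, admixture)
  will fit poorly, which the SSD p-value is there to flag.
* `regionDiversity()` assigns overlap columns to every class that covers
  them; the two coding strands of an overlap are not disentangled.
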