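---
title: "Methods: bin-map QTL mapping and salt-specific expression integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bin-map QTL mapping and salt-specific expression integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the models, their assumptions, the tunable parameters and why
their defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices a maintainer would otherwise
have to reverse-engineer from the code.

# The analysis chain

The package targets one recurring study design: a bi-parental rice RIL
population (donor parent P1, recurrent parent P2, single-seed descent to
roughly F10), whole-genome resequenced at low coverage; salt-injury SES
phenotypes scored across environments, years and replicates; and an
eight-library bulked-segregant RNA-seq design — both parents and a
most-tolerant / most-sensitive bulk, each under salt stress and control.
The pipeline turns those three inputs into a candidate-gene list in five
stages, each usable on its own.

## Bin-map construction

Per-call depth and per-site quality filters come first (defaults: depth ≥ 3
per line per site, site quality ≥ 30; failing calls become missing, failing
sites are dropped). A sliding window of `window_size = 15` SNPs, stepping
one SNP, is genotyped by the ratio of parental calls among non-missing ones:
A or B when the majority fraction reaches `homo_fraction = 0.7`, otherwise
heterozygous (H); all-missing windows are U. The window caller is what makes
bin maps robust to genotyping error: with a per-call error rate of 0.5%, a
15-SNP window essentially never miscalls a homozygous tract, because ≥ 5
simultaneous miscalls would be needed to cross the 0.7 threshold.

Two numerical points deserve emphasis:

* **Breakpoint refinement.** A window that straddles a crossover mixes
  calls from both parents and comes out H, so every A→B junction reads
  A…A H…H B…B along the windows. If those transition tracts were kept, the
  line that recombined would be heterozygous in one of the two bins
  flanking every junction — and since heterozygous lines are excluded from
  two-point recombination estimates, *every* adjacent-bin recombinant
  fraction would be zero and the linkage map would collapse. The caller
  therefore splits any H (or missing) run whose homozygous flanks differ at
  its midpoint, recovering a point breakpoint. Internal H runs with
  *identical* homozygous flanks are genuine residual heterozygous tracts
  and are kept as H.
* **Bin formation.** Per line, runs of identical refined window calls form
  tracts; a breakpoint sits at the midpoint between the centers of the
  flanking windows. Population bins are the union of all lines'
  breakpoints, so bins tile each chromosome exactly (1-based inclusive
  coordinates) and every line is constant within a bin; adjacent bins
  identical in every line are merged. Bins informative in fewer than
  `min_line_frac = 0.8` of lines stay in the physical tiling but are left
  out of the linkage map, mirroring the distinction between bins created
  and bins mapped in high-density rice maps.

Genetic distances per adjacent mapped pair use the observed recombinant
fraction R among lines homozygous at both bins, the selfed-RIL correction
r = R / (2(1 − R)) — the exact inverse of the expansion R = 2r/(1 + 2r)
that repeated selfing produces — and the Kosambi map function
d = 25·ln((1+2r)/(1−2r)) cM. R is clamped at 0.49999; a pair with no
informative lines contributes distance 0 with a warning. Marker *order* is
physical: this assumes the reference-genome order agrees with the genetic
order, which is the normal situation for rice bin maps and avoids
re-implementing de novo ordering; users mapping structurally rearranged
material should not rely on that assumption.

The genome summary follows the conventions of published bin-map tables:
average bin length is chromosome length over *created* bins; the average
adjacent gap is linkage-group length over *mapped* bin count (not count−1 —
this is the convention that reproduces the worked example's per-chromosome
column, e.g. 165.63/349 = 0.47); the genome average bin length weights
chromosomes by created-bin counts.

## Phenotype model

Plot-level SES in the greenhouse is the injury-weighted mean
SES = Σ(plants at level × level score)/total plants over the 1/3/5/7/9
grades (`plotSes`); field plots are scored directly on the same scale. Both
enter one phenotype table.

`fitBlup` fits Y_ijk = μ + L_k + E_i + R(E)_ij + (L×E)_ik + e_ijk with all
factors random by REML (lme4). The environment index i is whatever grouping
column the caller supplies; the pipeline uses environment-by-year
combinations, so "environment" and "year" are absorbed into one factor,
while per-environment line means are used for the condition-specific scans
that the stability rule needs. Line BLUPs are the shrunken random-effect
predictions; broad-sense heritability on an entry-mean basis is
H² = σ²g / (σ²g + σ²ge/n + σ²e/(nr)) × 100 with n environments and r
replicates. lme4 never returns negative components, so the truncation the
formula requires is only relevant to moment estimators; the
`VarianceComponents` container still validates non-negativity and records
any truncation.

Numerical choices: the lme4 optimizer is bobyqa with `rhoend = 1e-13`, so
that on balanced designs the REML estimates match the analytic balanced-
ANOVA expected-mean-squares estimators to ~1e-6 absolute (the test suite
verifies this equivalence against an independently coded oracle). The
degenerate noise-free case — phenotype depending on the line alone — makes
the REML surface flat in the zero variance components, so it is solved
exactly instead: unshrunken line deviations, σ²g = the variance of line
means. Kurtosis is reported as *excess* kurtosis, matching descriptive
tables whose values sit in (−1, 1).

## QTL scanning

At each mapped bin the trait is regressed on genotype coded A = +1,
B = −1 (H and U lines dropped at that bin — at F10 their frequency is ~2⁻⁹,
too small to justify imputation), giving LOD = (n/2)·log₁₀(RSS₀/RSS₁),
per-bin PVE = 1 − RSS₁/RSS₀, and additive effect a = (mean_A − mean_B)/2,
positive when the P1 allele raises the trait. The regression identity
PVE = 1 − 10^(−2·LOD/n) is enforced by construction and tested to 1e-9.

Genome-wide thresholds come from permuting the trait across lines
(default `n_perm = 1000`, α = 0.05): the threshold is the k-th largest of
the per-permutation genome-wide maximum LODs with k = ⌈(1−α)·n_perm⌉,
deterministic given the seed. The test suite calibrates the resulting
genome-wide type-I error at ≈ 5% over 200 outer replicates (desk scale:
200 permutations per replicate, ~500 bins over 12 chromosomes, 200 lines).

Multiple-QTL structure is handled by forward cofactor selection: the
strongest genome-wide-significant bin becomes a regression cofactor, the
genome is rescanned conditional on the cofactor set, and the cycle repeats.
Two rules keep this stable: a cofactor within `window_cm = 10` cM of the
tested bin is excluded from that bin's model (otherwise the QTL's own
neighborhood would be conditioned away), and a *new* cofactor must sit at
least `window_cm` from every existing one — one cofactor per QTL region.
Without the separation rule, cofactors pile up shoulder-to-shoulder around
a strong peak, their exclusion windows overlap, and the conditional profile
degenerates into a chromosome-wide plateau. For the same reason, once a QTL
is extracted, bins within `window_cm` of its 2-LOD interval are masked
before looking for further peaks: those bins were tested without the
cofactor representing the extracted QTL and are not independent evidence.

Support intervals walk left and right from the peak while LOD stays within
2 of the peak value, in both cM and bp; an interval that reaches a
chromosome end without dropping is truncated and flagged. Overlapping
physical intervals (≥ 1 bp, transitively) merge to their union, keeping the
max-LOD member's statistics. Ties at equal LOD resolve to the lower
chromosome, then lower position. Finally the stability rule: intervals from
all condition × trait scans are clustered by physical overlap; a region is
*stable* iff, for at least one trait, it is supported under every condition
(greenhouse, field, BLUP), and flagged separately when every
condition × trait cell is hit. Region bounds are unions over supporting
QTLs — whether to re-estimate per condition instead is genuinely open, and
union was chosen as the more conservative (wider) report.

## Salt-specific expression classes

TMM normalization is implemented as specified for the trimmed mean of
M-values: reference = library whose upper quartile of library-size-scaled
counts is closest to the mean upper quartile; per library, M- and A-values
over genes expressed in both; 30% two-sided trim on M and 5% on A;
precision-weighted (inverse delta-method variance) mean of the surviving
M-values; factors rescaled to geometric mean 1. The implementation is
cross-checked in the test suite against edgeR's `calcNormFactors`, which
it matches exactly on shared inputs.

With one library per side, dispersion cannot be estimated from the data, so
contrasts use an exact conditional negative-binomial test at a fixed
dispersion (default 0.1, a typical gene-level value for bulk rice tissue):
conditional on the pair sum s, the probability of each split k/(s−k) is
enumerated under equal normalized expression, and the two-sided p is the
sum of outcome probabilities ≤ that of the observed split. Dispersion 0
reduces exactly to the binomial (Poisson) exact test, which the tests
verify, alongside brute-force enumeration at dispersion 0.1. LFC uses a
symmetric 0.5 pseudocount over TMM-adjusted effective library sizes. DE
requires |LFC| ≥ 1 *and* BH FDR ≤ 0.05.

The six-class rule compares each salt contrast with its normal-condition
counterpart: DE only under salt → SalOnly_up/down by sign; DE only under
normal → NorOnly_up/down; DE under both → ΔLFC = LFC_salt − LFC_normal,
class ΔLFC>1 or ΔLFC<−1, with the band in between (and non-DE genes)
labelled none — the classes partition the gene universe. Classes
{SalOnly_up, NorOnly_down, ΔLFC>1} are up-regulated specifically under
salt; {SalOnly_down, NorOnly_up, ΔLFC<−1} down. The ΔLFC classes require
the DE flag in *both* contrasts. The parent and bulk salt-specific sets are
intersected direction-consistently (up with up, down with down), which is
what makes the bulk comparison a noise filter rather than a second
discovery arm.

## Colocalization

Shared salt-specific DEGs qualify as candidates when their gene model
overlaps a stable region by ≥ 1 bp (`rule = "overlap"`, the default;
`"within"` demands full containment — on the packaged worked example both
rules admit the same fifteen genes, so the more permissive one is default
and the choice is exposed). Mb-precision region bounds convert to bp as
round(Mb·10⁶); coordinates are 1-based inclusive throughout; genes touching
several regions are listed once with all region labels and counted once per
region in the per-region tallies.

# The synthetic-data generator

`simulateStudy` emulates the study conditions so that every stage can be
validated against truth. Its defaults *are* the study design: 253 lines,
F10 (nine selfing rounds from the F1), 12 chromosomes of 117.3 cM / 31.1 Mb
(a rice-sized 1408 cM / 373 Mb genome), 2 environments × 3 years × 3
replicates, variance components σ²g = 1, σ²ge = 0.5, σ²e = 1 on the SES
scale around a grand mean of 4.5, and an 8-library expression design of
2000 genes.

Meioses draw crossover counts per chromosome as Poisson with mean equal to
the map length in Morgans and positions uniform in cM — no interference;
the Kosambi function used downstream differs from Haldane only at the
larger recombination fractions that adjacent dense bins never reach.
Single-seed descent resamples two gametes from the current plant each
generation; residual heterozygous tracts are retained and labelled, never
forced out, and parents are assumed fully inbred. Observed SNPs are placed
uniformly at `snp_density = 60` per Mb; each call is miscalled (to a random
homozygote) with probability 0.005, masked with probability 0.05, and
annotated with Poisson(8) depth and a per-site quality score so the filters
have something to act on. The density default is a resolution choice: the
bin caller cannot resolve recombinant tracts shorter than about one window
span, so windows must stay well under ~1 cM for map-length recovery; 60
SNPs/Mb with a 15-SNP window gives ~0.25 Mb ≈ 1 cM spans on the default
chromosome, and the test suite requires the estimated chromosome length to
land within 15% of the simulated truth.

Phenotypes follow the fitted model exactly: line genetic value = Σ ±a over
planted QTLs (+a for the P1 allele, matching the convention that published
salt-QTL additive effects are donor-contributed) plus a polygenic normal
draw scaled so the total line variance is σ²g. `qtlEffectForPve` sizes a
planted effect against the phenotypic variance of a *per-environment line
mean*, σ²g + σ²ge + σ²e/r. This definition — rather than PVE against the
(less noisy) BLUP — is deliberate: the stability rule demands detection in
every single-environment scan, so a "15% QTL" must be a 15% QTL in the
scans that gate stability, not only in the combined analysis. On the BLUP
scale the same QTL explains more variance, which is why recovered BLUP-scan
PVEs exceed the planted per-environment figure.

Expression counts are negative binomial with lognormal baseline means,
configured dispersion (0.1) and library sizes, one library per sample as in
the real design. All six classes are planted for both the parent and bulk
contrasts, plus parent-only and bulk-only genes that the intersection must
remove. Planted effect sizes default to |LFC| = 4 (4.5/3 for the ΔLFC
classes) and planted genes draw their baseline from lognormal(log 400,
0.5): with one library per side at dispersion 0.1 the LFC sampling sd is
≈ 0.65, so effects less than ~3 sd above the |LFC| ≥ 1 cut-off are simply
not detectable by this design, and planting them would turn every recovery
rate into a statement about the generator instead of the analysis. A
configurable number of shared salt-specific DEGs is placed within
±250 kb of planted QTL positions; all other genes are kept ≥ 1 Mb clear of
them so "inside" and "outside" are unambiguous.

What the generator does **not** emulate: crossover interference, segregation
distortion, read-level sequencing (alignment and variant calling are out of
scope — error and missingness are injected at the call level), linkage
disequilibrium between the polygenic background and markers (the polygenic
term is drawn independently of the genome, so background QTLs cannot
inflate the scan), spatial field trends beyond the replicate effect,
isoform-level expression, and correlated gene-gene expression. Passing
recovery tests therefore demonstrate the pipeline's correctness under its
own model assumptions, not robustness to the full messiness of field data.

# Problem sizes and reproducibility

All validation runs at desk scale, chosen as the smallest sizes at which
the quantities of interest are statistically meaningful: recovery studies
use 250 lines on a 2 × 120 cM genome over the spec-style seed panel 1–20
with 200 permutations per threshold; map-length recovery uses 253 lines on
one chromosome over 10 seeds; heterozygosity decay uses 800–3000 lines on a
short chromosome; permutation calibration uses 200 outer replicates × 200
permutations; the two-locus recombination check uses 8000 lines against an
exhaustive transition-matrix oracle. One global seed fixes every artifact
byte-for-byte; per-stage seeds derive deterministically from it
((seed mod 20000)·100000 + stage·101), so any stage is independently
reproducible.

# Known limitations

* **Interval resolution vs planted windows.** 2-LOD support intervals of a
  strong QTL on a dense bin map can be narrower (~0.3 Mb) than the
  generator's ±250 kb planting window, so a planted DEG near the window
  edge can be correctly detected as a shared DEG yet fall outside the
  detected stable region. End-to-end planted-DEG recall consequently sits
  near, not far above, the 90% mark; the shortfall is a resolution
  property, not missed detection.
* **Map-length undercount.** Recombinant tracts shorter than one window
  span are invisible, so estimated map lengths run a few percent short of
  truth, more at low SNP density.
* **Physical marker order is assumed correct**; no de novo ordering or
  inversion detection.
* **Fixed-dispersion exact tests** trade power calibration for honesty
  about an unreplicated design; single-library contrasts cannot separate
  biological from technical variation, which is precisely why the
  parent × bulk intersection and the QTL overlay are part of the design.
* The replicate factor is crossed within environment labels as recorded;
  incomplete-block (α-lattice) spatial adjustment is out of scope.
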