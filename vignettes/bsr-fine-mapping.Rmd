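---
title: "Methods: BSR-seq scanning and fine mapping of a dominant locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BSR-seq scanning and fine mapping of a dominant locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsrmap)
```

# The problem and the model

A qualitative trait — here modelled on a stably variegated leaf phenotype
in ornamental kale — segregates in an F2 population derived from two
inbred parents. Under a one-locus dominant model, the F1 is uniformly
mutant, the F2 splits 3 mutant : 1 wildtype, and a backcross to the
recessive parent splits 1:1. `bsrmap` implements the full downstream
analysis chain for such a design: inheritance tests, bulked-segregant
RNA-seq (BSR-seq) scanning, recessive-class linkage mapping, and
candidate-allele annotation, together with a simulator that generates
every input with known ground truth.

This vignette records the modelling choices, parameter meanings and
defaults, numerical conventions, and the limits of what a passing test
establishes. It states no empirical result that the test suite or the
acceptance script does not itself compute.

# Segregation tests

`chi_square_gof()` computes the uncorrected goodness-of-fit statistic
$\chi^2 = \sum_i (O_i - E_i)^2 / E_i$ against user-supplied ratio
weights; the critical value is always computed from the
$\chi^2_{k-1}$ distribution (3.84 emerges at $k = 2$, $\alpha = 0.05$)
rather than hard-coded. Yates' continuity correction is available via a
flag but **off by default**: two-class Mendelian ratio tests in the
mapping literature are conventionally reported uncorrected, and the
canonical worked examples in this package (90:27 vs 3:1 → 0.23; 11:13 vs
1:1 → 0.17 at 2 dp) are reproduced only without correction.
`infer_inheritance()` combines the F1-uniformity check, the F2 3:1 test
and the optional backcross tests into a dominance call.

# The F2 simulator as a stated world

`simulate_f2()` implements meiosis with **no crossover interference**:
the crossover count per chromosome per gamete is Poisson with mean equal
to the chromosome's genetic length in Morgans, crossover positions are
uniform, and the parental origin of the leftmost segment is a fair coin.
The Haldane model is the standard null and makes the recombination
fraction between two positions available in closed form
($r = (1 - e^{-2d})/2$), which the property tests use as an independent
oracle. The Kosambi function used on the estimation side assumes partial
interference; at the distances relevant to fine mapping (< 5 cM) the
Haldane–Kosambi discrepancy is far below sampling error, which is why
the parameter-recovery test can compare the two directly.

Key defaults, all configurable:

* `bp_per_cM = 5e5` (0.5 Mb/cM) — a realistic genome-wide figure for a
  *Brassica*-sized genome (~600 Mb, ~1200 cM).
* `default_genome_spec()` — three chromosomes (60/50/55 Mb), 5000
  parent-diagnostic SNVs by default, the causal locus at C03:2,000,000
  with a diagnostic SNV placed exactly at the locus, and a six-marker
  panel at ±0.5, ±1 and ±2 cM.
* `bulk_design()` — 50 + 50 individuals per bulk and mean depth 100.
  The emulated study describes both a 50/50 and a 50/20 bulk design in
  different places; 50/50 (the BSR-seq methods description) is the
  default and 50/20 remains a one-argument preset. Neither is asserted
  as "the" design anywhere in the tests.
* `depth_dispersion = 10` — per-site total depth is negative-binomial
  with this size parameter (mean `mean_depth`); `Inf` recovers Poisson.
  RNA-seq coverage is overdispersed, so a finite default is the
  realistic choice; tests that need exact binomial arithmetic use the
  Poisson limit explicitly.

Reads are assigned to alleles by binomial sampling from the bulk's true
allele pool, i.e. the simulator models *pool-construction* sampling
(which of the 2N alleles a read comes from) and *sequencing* sampling,
but **not** allele-specific expression bias, mapping bias, base-calling
error, or shared-read structure along the chromosome. A green end-to-end
test therefore establishes that the scoring and calling logic recovers a
locus under faithful Mendelian sampling noise — not that the pipeline is
robust to alignment artefacts.

The candidate-gene fixture (`make_candidate_gene_fixture()`) is a
**synthetic** two-exon gene, 972 bp in total, whose mutant allele
carries exactly two exon-2 substitutions (one engineered missense
AGG→AAG at codon 132, CDS position 395; one synonymous) and a 1-bp
insertion causing a frameshift and a premature stop. The consequence of
the second substitution is never specified in the motivating study, so
the fixture plants it as synonymous by explicit choice, documented in
its truth record. The truncated protein length in the truth record is
computed by translation, not assumed.

# ED^k scanning

`ed_statistic()` uses the standard BSA definition: the Euclidean
distance between the two bulks' allele-frequency vectors over the four
nucleotides, raised to the k-th power with `k = 5` by default. The
exponent is configurable; 5 is the conventional noise-suppressing
choice. At a dominant causal locus the mutant bulk's expected mutant
allele frequency is 2/3 (1 VV : 2 Vv) and the recessive bulk's is 0, so
the expected ED is $\sqrt{(2/3)^2 + (2/3)^2} = \sqrt{8/9} \approx
0.9428$ — the quantity the stochastic acceptance test checks.

Numerical conventions, each covered by a direct test:

* **Thresholding is genome-wide on per-SNV ED^k** with no sliding-window
  smoothing, matching a direct "top 1% of SNVs" rule. The threshold is
  the nearest-rank $(1-f)$ quantile: sorted value at rank
  $n - \lfloor nf \rfloor$ + 1. Ties at the threshold are significant.
  When $\lfloor nf \rfloor = 0$ the threshold is the maximum value.
* **A configurable min-depth filter (default 10 per bulk)** runs before
  thresholding; whether the emulated study used such a filter is
  unstated, so it is explicit and reported rather than silent.
* **Region merging**: significant SNVs on one chromosome separated by
  ≤ `max_gap` (default 1 Mb) merge; regions with < `min_snvs`
  (default 3) are dropped. The merge rule is this package's own — the
  motivating study reports regions without stating one. The defaults
  keep sparse isolated false positives out of the region table while a
  `min_snvs = 1` setting makes them visible again.
* **Coordinates are 1-based inclusive**, and region length is
  `stop − start`: that convention exactly reproduces all three published
  interval lengths used as acceptance targets, so it is applied
  uniformly (also to the physical span between flanking markers).

# Recessive-class linkage mapping

With only homozygous-recessive individuals genotyped, every
mutant-parent allele at a marker records one recombinant gamete, so
`r = (AB + 2·BB) / 2n`. Gamete counting is adopted because it is the
only convention under which ~1300 recessive individuals yield the
0.04/0.08 cM granularity seen in fine-mapping reports (1 and 2 events
among 2n gametes). Distances use Kosambi
$d = 25\ln\frac{1+2r}{1-2r}$ and are reported to 2 decimals.

Side assignment uses recombinant-individual sharing: two markers are on
the same side iff the overlap of their recombinant sets reaches a
configurable fraction (default 0.5) of the smaller set — on the same
side the nearer marker's recombinants are (nearly) a subset of the
farther marker's, while opposite sides share only double recombinants.
Groups are ordered left/right by physical coordinate; markers with zero
recombinants cannot separate and stay unassigned (they also cannot
flank). If more than two groups form, only the outermost two are
oriented; the middle groups stay unassigned rather than being guessed.
`flanking_interval()` takes the minimum-distance marker per side,
breaking ties toward the physically closer marker.

Missing genotypes are excluded marker-wise (pairwise-complete `n`).
Estimates above r = 0.5 are capped at 0.5 with a warning; the Kosambi
function itself refuses r ≥ 0.5, where the distance is unbounded.

The parameter-recovery property test simulates recombinant gametes
directly as Bernoulli(r) draws — the exact generative model of the
estimator — rather than running full meiosis 200 times; meiosis itself
is validated separately against the Haldane closed form. This keeps the
suite fast without weakening either check.

# Variant effects

`diff_alleles()` is built on global pairwise alignment (match 1,
mismatch −1, gap −2 by default) and then **left-aligns indels** in
repeat runs, the common variant-normalization convention, so planted
fixture coordinates are deterministic. An insertion at position *p*
inserts before reference base *p*. `classify_effects()` translates
substituted codons under the standard genetic code (the first ATG of
the supplied CDS is taken as the start; the inputs are gene-level
sequences without ORF annotation); frameshifts re-translate the mutant
CDS from the start codon to the first stop and report the truncated
protein length. The oracle test re-translates the entire mutant CDS
naively and compares consequences on 1000 random fixtures.

One deliberate non-check: the motivating study's stated protein length
for its 972-bp candidate gene (679 aa) is arithmetically impossible
(972 bp can encode at most 324 aa), so no test asserts it; truncation
logic is validated on synthetic fixtures whose truth is computed.

# Assay calculators

`pigment_content()` implements the 13.95/6.88, 24.96/7.32 and
carotenoid formulas and converts extract concentration (mg/L) to
dry-weight content as $C \cdot V / m$ — with the 20 mg / 10 mL defaults
of the emulated protocol, but parameterized, since the conversion is
standard dilution accounting rather than something the formulas fix.
Negative formula outputs (possible outside the valid absorbance range)
are flagged, never clipped. `relative_expression()` averages replicate
Cts arithmetically on the Ct scale before ΔCt (the common convention),
then applies $2^{-\Delta\Delta C_t}$. Published figure-level pigment
values are not machine-readable and are not asserted anywhere; formula
correctness is checked analytically, and fixture round-trips recover
planted fold changes (including a planted 2158.85-fold contrast) to
1e−9.

# Determinism and the CLI

Every stochastic function takes a `seed` argument and restores the
caller's RNG state; stage seeds in `run-all` are derived from the
top-level seed (kept below $2^{31}$). No output file carries a
timestamp, so `run-all` with a fixed seed is byte-identical across
runs — asserted by checksum in the acceptance suite. The CLI returns
exit status 0/1/2 (success / runtime error / usage) with a one-line
cause on stderr.

# Known limitations

* The simulator does not model allele-specific expression, sequencing
  error, or linkage disequilibrium in the founder parents; published
  region tables from real RNA-seq data are therefore not reproducible at
  desk scale, and the end-to-end criteria are property checks on the
  stated synthetic world instead.
* Side assignment needs at least one recombinant on each side; very
  tight panels on small populations legitimately return "locus not
  flanked".
* Multi-locus ratios (9:7, 13:3, …) are supported only as user-supplied
  weight vectors; no epistasis model selection is attempted.
* VCF input is a convenience dialect; the canonical interchange format
  is the plain allele-depth TSV.
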