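---
title: "Methods: LDR probe design, simulation and fingerprint analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LDR probe design, simulation and fingerprint analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldrua)
```

## The assay being modeled

A Ligase Detection Reaction / Universal Array (LDR-UA) experiment types a
complex 16S rRNA amplicon pool against a panel of taxon-specific probe
pairs. Each pair consists of a Discriminating Probe (DS), carrying a 5'
fluorescent label and ending on the discriminating base of the target, and
a Common Probe (CP) that anneals immediately 3'-downstream and carries a
cZipCode tail. A thermostable ligase seals the DS/CP junction only when the
template matches perfectly at the junction, so a single 3'-terminal
mismatch suppresses the product. Products are captured on a Universal
Array, a generic grid of ZipCode address oligos, and read out as spot
fluorescence. Because the array content is decoupled from the assay
chemistry, panels can grow without re-optimizing hybridization.

`ldrua` implements the complete computational side of this platform:
consensus extraction from aligned target groups, probe-pair design,
layout modeling, an experiment simulator, presence calling, and
community-fingerprint analysis.

## Consensus extraction

Target groups arrive as gapped multiple alignments. Per column, the
dominant base is emitted when its frequency reaches the calling cutoff
(default 0.75); otherwise the column is coded with the IUPAC symbol
covering every base at or above a minor-frequency floor. Two parameters
deserve comment:

* **`cutoff` (default 0.75).** The majority threshold for calling a plain
  base. Values in (0.5, 1] are allowed; 1.0 reproduces a strict consensus.
* **`minor_floor` (default 0.05).** Bases rarer than this are treated as
  alignment noise and left out of the ambiguity code. The threshold for
  minority bases is genuinely open — we expose it rather than fix it, and
  chose 5% as the conventional point below which singleton sequencing
  errors dominate real polymorphism in curated 16S alignments.
* **Gap policy.** Columns whose gap frequency reaches the cutoff are
  dropped (probes are designed on ungapped consensi); elsewhere gaps are
  ignored and frequencies renormalized over real characters. Ties at the
  cutoff resolve to the ambiguity code of all tied bases, which makes the
  output independent of input order.

Degenerate consensus symbols contribute fractionally to each of their
bases, so a column of `R`s counts half `A`, half `G`.

## Melting temperature

Probe Tm uses the unified nearest-neighbor parameter set (Allawi &
SantaLucia 1997) with the entropic monovalent-salt correction
`0.368 (L-1) ln[Na+]`. Defaults are 50 mM Na+ and 0.25 uM total strand
concentration, with the CT/4 approximation for non-self-complementary
duplexes and CT plus the symmetry entropy for self-complementary ones.
These defaults are stated in `melting_temperature()` and configurable; the
design criterion (68 +/- 1 degrees C) is enforced with whatever model is
configured, so internal consistency — not reproduction of any particular
published probe list — is the contract. Degenerate probes report the
arithmetic mean Tm over all concrete expansions (capped at 256), a
deterministic and symmetric choice.

Candidate enumeration scans every (position, DS length, CP length) triple.
Because that touches tens of thousands of windows per consensus, window
Tm is computed from cumulative dimer enthalpy/entropy sums in O(1) per
concrete window, with a fallback to full expansion-averaged evaluation for
windows containing ambiguity codes. The scorer is checked against the
direct implementation to 1e-9 in the test suite.

## Probe design and specificity

A designed pair must satisfy: DS and CP each 25-60 nt, Tm within 68 +/- 1
degrees C, at most 4 degenerate bases per probe, CP abutting the DS 3' end
with junction gap 0. Candidates are ranked by |mean(DS Tm, CP Tm) - 68|,
then fewer degenerate bases, then leftmost position — a total order, so
design is deterministic.

Specificity follows the ligase logic: every positive-set sequence must
match the full DS+CP footprint exactly (degenerate positions match by
IUPAC intersection; Biostrings ambiguity matching does the scanning, and
an exhaustive expand-and-compare oracle confirms it in tests), while every
negative-set sequence must carry at least one mismatch inside the
discrimination window at the DS 3' end wherever the rest of the footprint
matches. The window defaults to 1 nt — the 3'-terminal base, which is what
the ligase actually proofreads — and can be widened. Positive sequences
whose footprint region is gapped are reported separately rather than
counted as design failures, since alignment gaps there are artifacts of
the input alignment, not biology.

Negative sets respect the taxonomic hierarchy: family/phylum-level groups
are discriminated against the consensus sequences of the other
family-level groups, while genus/species-level groups (sub-probes) are
discriminated only against sequences from *other* families — a sub-probe
is allowed to match its own parent clade.

## Array model

The layout builder places each subarray as a deterministic grid:
hybridization controls (type flag 1), ligation controls (2), probe
ZipCodes in replicate (3/4), blanks (5). Defaults — 8 subarrays, 47
probe-addressable ZipCodes in quadruplicate, 8/6/6
hybridization/ligation/blank control spots, 13-column grid — give 208
spots per subarray. Published descriptions of this platform quote "49
ZipCodes" alongside "208 spots with quadruplicates and 8/6/6 controls";
those totals only reconcile if 47 codes are spotted in quadruplicate, so
every count is a parameter and 208 is never hard-coded. ZipCode
assignment is ordered and injective, hence stable across re-runs.

## The simulator and what it does (not) emulate

`simulate_experiment()` renders one template mixture per subarray. For
each probe the ligation yield is `amount_fmol x yield_per_fmol` summed
over templates carrying a matching footprint (junction rule enforced),
zero otherwise — LDR cycling is linear per cycle, so the cycled
amplification collapses into the single calibration constant
`yield_per_fmol`. Spot intensities draw from a lognormal with expectation
(background + yield) and a multiplicative coefficient of variation; blanks
and unused ZipCodes draw around the background; hybridization and ligation
controls draw at fixed high levels. Each spot also emits a pixel SD as a
fixed fraction of its intensity so the conservative-null calling rule has
something to work with.

Default calibration, chosen once as the package's operating point:
background 100 a.u., spot CV 0.15, pixel SD fraction 0.10,
`yield_per_fmol` 400. Under these defaults the standard 50 fmol input
yields specific SNR near 200 and non-specific SNR near 1 — the same order
as the platform's published specificity figures — and the 0.7 fmol
sensitivity limit sits a few replicate-SDs above the adjusted blank null,
i.e. detectable but near the edge, which is exactly how the platform
describes its lowest tested concentration.

The generator emulates: group-specific single-site recognition, replicate
spotting, per-subarray hybridizations, multiplicative scanner noise, an
inert genomic-DNA diluent (bookkeeping only). It does **not** emulate:
PCR amplification bias, 16S copy-number variation, cross-hybridization
free energies, or image-level artifacts. Passing simulation-based tests
therefore demonstrates that the calling statistics behave as designed
under the stated noise model, not that the wet-lab platform is free of
those upstream biases.

## Presence calling

Per sample and subarray:

1. **Null construction.** The blanks (>= 2 required; 6 by default) each
   contribute `IF + 2 x pixel SD` — a conservative upward-shifted null.
2. **Outlier exclusion.** Replicates below 2.5x the adjusted null mean are
   discarded, provided at least one replicate clears the threshold and at
   least `min_replicates` (2) remain; if all replicates are low, none are
   excluded and the probe simply fails the test. The reference intensity
   for the 2.5x rule is the adjusted null mean — the only distribution
   defined in the calling procedure — and is switchable to the raw blank
   mean.
3. **Presence test.** One-sided two-sample t-test of retained replicates
   against the adjusted null values, Welch by default (the blank and
   signal populations have very different spreads; pooling is available
   via `var_equal`). Present means p < alpha, with alpha 0.01 by default
   and 0.05 in sensitivity mode for very low template amounts.
4. **SNR.** Probe mean intensity over the *raw* (unadjusted) blank mean;
   the +2SD shift belongs to the test's null only. Specific/non-specific
   summary means mirror the platform's published validation metric.

No multiple-testing correction is applied by default — the per-probe alpha
with a conservative null is the platform's own convention — but a
Bonferroni switch exists.

## Fingerprints

Presence/absence vectors over the probe panel are the unit of comparison
across samples. Relative fluorescence contributions average each probe's
mean intensity over one or two technical replicates, drop sub-probes
(finer probes nested inside a broader group probe, which would
double-count their parent's signal; the shipped 30-probe annotation marks
10 of them), and scale to percent of total. Clustering uses Euclidean
distance with Ward agglomeration — specifically the squared-Euclidean Ward
criterion as implemented by `hclust(method = "ward.D2")`, named in the
output because the two common Ward variants differ. Binary profiles are
clustered by default; contribution vectors are an option. Replicate
reproducibility is the percentage of probes agreeing between two technical
replicates.

## Numerical choices and degenerate inputs

* Degenerate expansion is capped (default 256) everywhere it occurs; a
  probe exceeding the cap is scored inadmissible rather than expanded.
* Consensus columns with no countable characters raise an error rather
  than emit an arbitrary base.
* A presence test with both sides at zero variance falls back to a sign
  rule (present iff the replicate mean exceeds the null mean).
* Layout, design, assignment and simulation are deterministic given their
  inputs and seeds; seeded internals restore the caller's RNG state.
* Ties in candidate ranking are broken by degeneracy then position, so
  re-runs are bit-identical.

## Problem sizes used in the shipped checks

The test-suite panels are deliberately small: 3-8 random 200-300 nt
templates with one designed pair each, 1-8 subarrays, 200-run null and
power ensembles. These sizes exercise every code path while keeping the
whole suite fast; nothing in the methods depends on the panel being
large, and all sizes are ordinary function arguments.

## Known limitations

* The thermodynamic model is a single unified NN parameter set; probes
  designed under other salt corrections will differ near the Tm
  boundaries.
* Specificity is exact-match logic over IUPAC sets: near-matches outside
  the discrimination window with nonzero tolerance are supported, but no
  free-energy model of cross-hybridization is attempted.
* The simulator's noise is stationary per spot; spatial artifacts,
  gradients and saturation are out of scope.
* Relative contributions approximate relative abundance only up to the
  platform's upstream biases (PCR, copy number), which are not modeled.
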