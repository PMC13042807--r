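---
title: "Methods: IDR grammar, condensate imaging metrics, and accessibility transitions"
author: "idrcond"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IDR grammar, condensate imaging metrics, and accessibility transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrcond)
```

This vignette is the package's own account of the science it
implements: the models and procedures, their assumptions, the tunable
parameters and why their defaults are what they are, what the
synthetic-data generators do and do not emulate, and the numerical
choices made where the design was genuinely open.

## 1. The scientific setting

Many chromatin regulators carry very long intrinsically disordered
regions (IDRs). When such a region is an internal linker — flanked by
folded domains on both sides and more than a thousand residues long —
its sequence "grammar" (composition, charge patterning, residue runs)
can encode both drivers and brakes of liquid–liquid phase separation
(LLPS): a basic platform segment can nucleate condensation while a
nearby acidic "charge block" electrostatically masks it in *cis*.
Truncation mutations that delete the acidic brake unleash condensate
formation, and the resulting condensates can redistribute chromatin
readers and open chromatin at ectopic sites. The package quantifies
each link of that chain: sequence → features, image → condensation
burden, matched statistics → construct comparisons, peaks → state
transitions.

## 2. IDR calling, llIDR selection, segmentation

Disorder tracks are *inputs* (one score in [0, 1] per residue from a
consensus disorder predictor); the package deliberately does not
re-implement or smooth the predictor. `callIDRs()` takes maximal runs
of scores ≥ 0.5 that are strictly longer than 30 residues. There is no
gap tolerance: any smoothing belongs to the predictor that produced
the track.

Coordinates are 1-based closed `IRanges`, the native R/Bioconductor
convention. The long-linker criteria in that convention:
`start > 1`, `end < protein length`, `width > 1000` — i.e. the region
touches neither terminus and is strictly longer than 1000 residues
(`selectLLIDRs()`). A region of exactly 1000 residues does not qualify.

`segmentRegion()` tiles a region with consecutive 200-residue blocks;
a final remainder shorter than 30 residues is merged into the
preceding block (1050 → five 200-mers + one 50-mer; 1020 → four
200-mers + one 220-mer). The 30-residue floor keeps every segment long
enough for composition features to be meaningful.

## 3. The 90-feature grammar vector

`featureVector()` concatenates, in a fixed column order
(`featureNames90()`):

1. **36 binary-patterning z-scores.** Classes: pol = {S,T,N,Q,C,H},
   hyd = {A,I,L,M,V}, pos = {R,K}, neg = {D,E}, aro = {F,W,Y},
   ala = {A}, pro = {P}, gly = {G}; all unordered pairs including
   self-pairs (28 + 8 = 36 — the count itself is what implies
   self-pairs are included). Overlapping classes (A is both `hyd` and
   `ala`) are permitted because each pair is evaluated independently.
   For a pair (X, Y) residues are labeled +1/−1/0, and the blockiness
   statistic is the variance of the windowed class asymmetry
   σ = (f⁺ − f⁻)²/(f⁺ + f⁻) around the whole-sequence asymmetry,
   averaged over window sizes 5 and 6 — a member of the kappa family
   of patterning parameters. Only the z-score of the observed
   statistic against `nShuffles` within-sequence permutations is
   reported, so the statistic's constant factors cancel under the
   null; positive z = blocky, negative z = well-mixed. Default 1000
   shuffles with a mandatory seed; pairs with fewer than two residues
   of either class (or zero shuffle variance, e.g. homopolymers) are
   reported as 0 and flagged.
2. **20 amino-acid fractions** (alphabetical A..Y).
3. **5 grouped fractions**: K+R, D+E, polar {S,T,N,Q,C,H,Y}, aliphatic
   {A,I,L,M,V}, aromatic {F,W,Y}. Grouped fractions are computed from
   integer count sums so that the identities below hold bitwise.
4. **2 pseudocounted log-ratios**: log10((nK+1)/(nR+1)) and
   log10((nE+1)/(nD+1)); the +1 pseudocount makes absent residues give
   a ratio of exactly 0.
5. **7 charge/global properties**: FCR = frac(K+R) + frac(D+E);
   NCPR = frac(K+R) − frac(D+E); mean Kyte–Doolittle hydrophobicity
   rescaled to [0,1] as (x + 4.5)/9; disorder-promoting fraction over
   {A,R,G,Q,S,P,E,K}; isoelectric point; chain-expanding fraction over
   {E,D,R,K,P}; mean polyproline-II propensity from a fixed
   experimental per-residue scale. All scales are package constants
   (`KYTE_DOOLITTLE`, `PPII_SCALE`, `PKA_EMBOSS`, …) rather than
   hidden magic numbers.
6. **19 residue-block fractions** (A..Y excluding W) and the
   **RG-stretch fraction**. A residue patch is a span between
   occurrences of one residue with at most 2 interrupting residues
   between consecutive occurrences, qualifying with ≥ 4 occurrences;
   the feature is the fraction of sequence covered by qualifying
   spans. The RG analogue chains non-overlapping "RG" dimers (left to
   right) separated by ≤ 2 residues and qualifies at ≥ 2 dimers. Both
   rules are verified in the test suite against brute-force span
   enumeration — exhaustively for all 4096 length-12 {E,S} sequences.

The isoelectric point is solved by bisection of the
Henderson–Hasselbalch net charge over pH ∈ [0, 14] with the EMBOSS pKa
table (free termini included), stopping at |net charge| < 1e-4. The
net charge is strictly decreasing in pH and the termini guarantee a
sign change, so the root is unique; for a neutral backbone the
solution is the terminal-pKa midpoint (8.6 + 3.6)/2 = 6.1, which the
tests use as a closed-form check.

`featureVariability()` reports the population standard deviation
(divisor *n*) of every feature across a region's segments — the
segments are the entire population of interest, not a sample — and
excludes features flagged in all segments. `zScoreColumns()` provides
the column-wise z-scoring used for heatmap display.

### Charge rewiring

`rewireCharges()` implements the five construct designs: D→R/E→K
(acidic→basic), K→E/R→D (basic→acidic), either set → serine
(neutral), and the balanced substitution `BS`, which converts the
minimal number of acidic residues (left to right) to basic so that
|NCPR| is minimized. The acidic→basic pairing (D→R, E→K) and serine as
the neutral substitute are package choices — the original constructs
were synthesized commercially and the exact substitution table is not
public; serine is small, polar and disorder-compatible, which keeps
the variants disordered while removing charge. Likewise, `BS`'s
minimal-|NCPR| left-to-right rule is one consistent reading of
"partial substitution to charge balance"; an exhaustive minimization
oracle in the tests confirms the rule attains the optimum.

## 4. Imaging metrics

**Line scans.** Traces are smoothed with a 5-point running average;
at the edges the window is clipped to the trace and the mean taken
over the covered samples (length-preserving). The condensation index
is CI = (I_peak − I_baseline)/σ with I_baseline the linearly
interpolated (type-7) 20th percentile and σ = 1.4826 × MAD; the MAD is
kept unscaled internally and the consistency factor applied exactly
once. A flat trace has CI = 0 by definition; a positive peak with zero
MAD indicates a degenerate line placement (e.g. a line through uniform
signal ending on one bright pixel) and raises an error rather than
returning infinity. PVR = (I_peak − I_valley)/(I_peak + I_valley) lies
in [0, 1] for nonnegative traces and is 0 exactly when the smoothed
trace is constant. Line placement is an input, not an algorithm — in
practice lines are drawn through 2–3 puncta by the experimenter, and
the synthetic generator mimics that by placing puncta on the path.

**Foci and fractions.** `segmentFoci()` keeps pixels inside the
nuclear mask whose intensity falls in a window (default 10–50, always
interpreted on the image's native scale — the same physical window is
a different number on a different detector scale), groups them
8-connected, and drops components below 4 px. The window is the only
published parameter of this procedure; 8-connectivity and the minimum
area are its conventional companions and both are arguments. Condensed
area fraction = Σ foci areas / mask area; condensed intensity
fraction = Σ foci integrated intensity / total nuclear intensity.
Connected-component labeling is an iterative minimum-label propagation
written in the package (validated against plateau fixtures); it is
exact for any foreground, with convergence bounded by the longest
label path.

**FRAP.** Three ROIs per cell: bleached region, cell-free background,
total fluorescence area; ≥ 5 pre-bleach frames. After background
subtraction, double normalization
I_norm(t) = (T_pre/T(t)) · (I(t)/I_pre) corrects acquisition
photobleaching and sets the pre-bleach mean to 1; full-scale rescaling
then maps the first post-bleach point to 0, and
I(t) = M·(1 − exp(−t/τ)) is fitted on the post-bleach samples
(Levenberg–Marquardt, bounded M ∈ [0, 2]), giving the mobile fraction
and half-time τ·log 2. The single-exponential model assumes one
dominant recovery timescale; traces with two well-separated timescales
will be summarized by an effective τ. A trace with no measurable
recovery short-circuits to M = 0 with undefined τ.

**pbFRET.** With background-subtracted donor intensities in the
bleached ROI (D_pre, D_post) and an unbleached control ROI
(DN_pre, DN_post), the drift factor is b = DN_post/DN_pre and
E = 1 − D_pre·b/D_post. E may legitimately be negative — a construct
whose donor is slightly dimmer after bleach than drift predicts — and
the implementation does not clamp it. The inversion is exact on
noiseless synthetic ROIs for any E < 1 and b > 0, which the tests
verify over E ∈ {−0.06, 0, 0.02, 0.10} × b ∈ {0.8, 1.0, 1.25}.

## 5. Expression-matched condensation testing

Condensate formation scales with expression level, so a naive
between-construct comparison confounds construct with abundance.
`propensityMatch()` fits a logistic regression of group on intensity,
then greedily 1:1 matches cells across groups on the logit propensity,
nearest neighbor without replacement, within a caliper. The default
caliper is 0.2 × SD of the logit propensity — the conventional reading
of "a caliper of 0.2" in the propensity-matching literature;
`caliperScale = "raw"` interprets 0.2 as an absolute logit width
instead (the behavior of some statistics packages' PSM procedures,
which matches nearly all cells when the propensity model is null).
The processing order is randomized by a mandatory seed, which makes
the pairing reproducible and breaks distance ties deterministically.
Greedy matching without replacement is deliberately simple; it is not
optimal bipartite matching, and under the SD-scaled caliper it
typically pairs 70–90% of cells from overlapping distributions.

`fisherCondensateTest()` builds the 2×2 group × condensate table over
matched cells and computes the two-sided exact p-value by
hypergeometric enumeration: the sum of probabilities of all tables
with the observed margins that are no more probable than the observed
table (with the standard 1 + 1e-7 relative guard against
floating-point ties). The odds ratio uses the Haldane 0.5 correction
when any cell is zero; a table with an empty margin carries no
information and returns p = 1, flagged. The suite verifies the p-value
against an independent log-factorial enumeration (agreement 1e-12 over
every non-degenerate table with n ≤ 40) and against
`stats::fisher.test`, and — by simulation over 500 seeded cohorts —
that matching removes intensity confounding: when condensation depends
only on intensity and groups differ in intensity, the unmatched test
rejects essentially always while the matched test stays near the
nominal level, and under the full null the matched rejection rate is
within the exact test's conservative neighborhood of α = 0.05.

`classifyState()` encodes the morphology/dynamics classification:
no foci → diffuse; foci with circularity ≥ 0.8 and mobile fraction
≥ 0.5 → LLPS; otherwise aggregate. The thresholds have no published
values; they are explicit, config-exposed defaults chosen so that
round, fast-recovering puncta count as liquid-like.

## 6. Accessibility transitions

`mergePeaks()` fuses intervals whose gap is ≤ 100 bp (bedtools
`merge -d 100` semantics) via `GenomicRanges::reduce`; the brute-force
pairwise-fusion oracle in the tests pins the semantics, including
idempotence. The unified reference is the merge of all conditions'
merged peak files with the same 100-bp gap — whether the reference
merge reused the gap is not published; reusing it is the
self-consistent choice and the gap is an argument. A reference peak is
open in a condition iff it overlaps any of that condition's peaks by
≥ 1 bp. `encodePatterns()` emits per-peak C/O strings in an explicit,
logged condition order (default EV → FL → TR → LTR; the order is a
required parameter precisely because condition labels vary between
figures and files). Pattern counts always sum to the number of
reference peaks. `queryTransition()` computes conditional fractions
such as "of the FL-closed ∧ TR-open peaks, the fraction open in LTR",
and `samplePeaks()` draws the seeded 5000-peak subset used for
alluvial displays, exporting a long-format table rather than a figure.

## 7. What the generators emulate — and what they do not

Each generator produces inputs with exactly the statistical structure
the consuming stage assumes, plus programmed ground truth:

* `simulateSequence()` — block architectures (e.g. a basic platform
  followed by an acidic block) as residue draws from per-block
  composition weights. It emulates composition and charge sign per
  block, not real positional conservation or motif structure.
* `simulateNucleusImage()` — a circular nucleus, uniform background,
  isotropic Gaussian puncta, additive Gaussian noise clipped at zero.
  The ground-truth focus mask is the 2σ disk around each center
  (≥ 95% of the punctum's mass), and the ground-truth condensed
  fractions are computed on the noiseless image. No PSF, no
  z-sectioning, no chromatin texture: passing the round trip shows the
  measurement chain is faithful, not that segmentation is robust to
  real optics.
* `simulateFrapTrace()` / `simulatePbfretRois()` — exact forward
  models of the two normalization schemes (instantaneous bleach,
  single-exponential recovery; multiplicative drift b with
  D_post = D_pre·b/(1 − E)), plus background and optional noise, so
  the analysis functions are tested as exact inverses.
* `simulatePopulation()` — two groups with normal intensities (clipped
  at zero; means far from zero so clipping is negligible) and a
  logistic condensation model in group and intensity. Defaults are
  100 cells per group, the scale of the per-construct imaging cohorts
  in this kind of experiment.
* `simulatePeakSets()` — reference peaks laid out with inter-peak gaps
  strictly greater than the merge gap, so merging can never fuse two
  ground-truth units and pattern recovery is exact by construction;
  all-closed patterns correctly vanish from every file. Peak
  coordinates are synthetic; there is no sequence, no mappability, no
  replicate noise.

Determinism is part of each generator's contract: fixed seed, byte
identical output.

## 8. Numerical choices and degenerate inputs

* Percentiles: linear interpolation (R type 7) everywhere, stated to
  avoid quantile-dialect drift.
* CI: flat trace → 0; positive peak with zero MAD → error.
* PVR: all-zero trace → error (undefined ratio).
* Patterning z: windows shorter than the sequence are required;
  shuffle SD of 0 → z flagged to 0; `nShuffles < 50` is rejected.
* pI bisection: 200 iterations maximum, tolerance 1e-4 on the net
  charge (not on pH), so compositions with flat titration curves
  around neutrality return a point on the plateau.
* Fisher: enumeration via `dhyper` over the hypergeometric support;
  p capped at 1.
* Merging: strictly half-open BED arithmetic on disk, 1-based closed
  GRanges in memory; a gap of exactly 100 bp fuses, 101 does not.
* FRAP fit: bounded Levenberg–Marquardt with data-driven starts
  (plateau from the trace tail, τ from the half-recovery time).

## 9. Problem sizes used in validation

The shipped validation uses desk-scale sizes chosen to make every
property check exhaustive or tightly converged: 1000 random sequences
for the composition identities; all 4096 length-12 two-letter
sequences plus 2000 random length-30 sequences for the block-feature
enumeration; 200 null sequences × 1000 shuffles for the patterning
calibration; 500 simulated cohorts of 2 × 100 cells for the matching
calibration; every non-degenerate 2×2 table with n ≤ 40 for the exact
test; 1000 random interval sets (n ≤ 50) plus a 2000-peak round trip
for the accessibility encoding.

## 10. Known limitations

* Proteome-scale IDR scans are supported but not validated against any
  proteome-wide census; disorder prediction itself is out of scope.
* The foci segmenter assumes a provided nuclear mask; nucleus
  segmentation from raw images is out of scope.
* The imaging metrics are single-plane (2-D); no deconvolution or 3-D
  analysis.
* The matched test conditions on the realized matching; it does not
  propagate propensity-model uncertainty.
* The patterning statistic's absolute value is not comparable across
  window-size conventions — only the z-scores are meaningful, which is
  the only thing the package reports.
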