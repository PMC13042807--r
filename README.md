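# idrcond

Quantitative analysis of intrinsically disordered region (IDR) sequence
grammar, biomolecular-condensate imaging, and downstream chromatin
accessibility changes — one tested R pipeline, exercised entirely on
seeded synthetic inputs.

## Who this is for

Labs studying proteins whose long disordered linkers drive (or
restrain) liquid–liquid phase separation (LLPS), and what ectopic
condensates do to chromatin. The package covers the quantitative steps
such a study needs after the wet-lab and read-level processing are
done:

* **IDR grammar** — call IDRs from per-residue disorder scores
  (threshold 0.5, regions > 30 residues), flag *long linker IDRs*
  (llIDRs: internal IDRs > 1000 residues flanked by structured
  sequence), split them into 200-residue segments, and compute a
  90-feature vector per segment: 36 NARDINI-style binary-patterning
  z-scores over residue-class pairs (pol, hyd, pos, neg, aro, ala, pro,
  gly), 20 amino-acid fractions, 5 grouped fractions, log10(K/R) and
  log10(E/D) with +1 pseudocounts, FCR, NCPR, hydrophobicity,
  disorder-promoting fraction, pI, chain-expanding fraction, PPII
  propensity, 19 residue-block (run/patch) fractions and the RG-stretch
  fraction. Charge-rewired construct variants (acidic→basic,
  acidic→neutral, basic→acidic, basic→neutral, balanced substitution)
  are generated with `rewireCharges()`.
* **Condensate imaging metrics** — line-scan condensation index
  `CI = (I_peak − I_baseline) / (1.4826 · MAD)` (baseline = 20th
  percentile of the 5-point-smoothed trace) and peak-to-valley ratio
  `PVR = (I_peak − I_valley)/(I_peak + I_valley)`; condensed area and
  intensity fractions from intensity-window foci segmentation
  (8-connected, minimum area 4 px); puncta counts; Pearson
  colocalization; double-normalized FRAP with the mobile fraction from
  a single-exponential fit; and drift-corrected acceptor-photobleach
  FRET efficiency `E = 1 − D_pre·b / D_post` with `b = DN_post/DN_pre`.
* **Expression-matched statistics** — per-cell condensation states,
  propensity-score matching of cells on fluorescence intensity
  (caliper 0.2), and Fisher's exact test on the matched sets, so
  condensation differences are not artifacts of expression level.
* **Accessibility transitions** — merge ATAC-seq peak sets (maximum gap
  100 bp), build a unified reference, label each reference peak
  open/closed per condition (≥ 1 bp overlap), encode four-letter
  patterns such as `"CCOC"` in a fixed condition order, count them,
  and answer transition queries ("of the peaks that opened
  specifically in TR, what fraction stays open in LTR?").
* **Synthetic-data generators** — every input above can be simulated
  with programmed ground truth (charge-block sequences, Gaussian-punctum
  nuclear images, FRAP/pbFRET traces, two-group cell populations,
  four-condition peak sets), so each stage is testable by round trip.

Sequences, intervals and matrices live in the standard Bioconductor
containers (`IRanges`, `GRanges`, a `RangedSummarizedExperiment`
subclass for the occupancy matrix).

## Worked example

```r
library(idrcond)

## 1. an internal 1100-residue disordered linker in a 1500-residue protein
scores <- rep(0.1, 1500); scores[101:1200] <- 0.9
regions <- selectLLIDRs(callIDRs(scores), proteinLength = 1500)
regions
#> IRanges object with 1 range and 1 metadata column:
#>           start       end     width |  is_llidr
#>   [1]       101      1200      1100 |      TRUE
IRanges::width(segmentRegion(regions[1]))
#> [1] 200 200 200 200 200 100

## 2. a 50/50 charge diblock is maximally "blocky" for the (pos, neg) pair
z <- patterningZScores(paste0(strrep("E", 50), strrep("K", 50)),
                       nShuffles = 1000, seed = 1, pairs = "z_pos_neg")
z[["z_pos_neg"]]
#> [1] 25.2

## 3. pbFRET: programmed E = 0.10 under 10% acquisition drift, recovered
rois <- simulatePbfretRois(efficiency = 0.10, drift = 0.9, n = 3,
                           background = 12)
pbfretEfficiency(rois)
#> [1] 0.1 0.1 0.1

## 4. FRAP: mobile fraction from a noisy synthetic trace
fit <- frapNormalize(simulateFrapTrace(mobileFraction = 0.8, tau = 5,
                                       noiseSd = 1, seed = 2))
c(fit$mobile_fraction, fit$half_time)
#> [1] 0.798 3.39

## 5. accessibility transitions over EV -> FL -> TR -> LTR
sim <- simulatePeakSets(n = 500, seed = 3,
  patternFreq = c(OOOO = 0.3, CCOC = 0.4, CCOO = 0.2, CCCC = 0.1))
occ <- labelOccupancy(buildReference(sim$peakSets), sim$peakSets)
encodePatterns(occ, c("EV", "FL", "TR", "LTR"))$counts
#> CCOC CCOO OOOO
#>  198   84  165
queryTransition(occ, function(st) !st[, "FL"] & st[, "TR"],
                fractionOpenIn = "LTR")$fraction
#> [1] 0.298
```

Reading the numbers: the linker qualifies as an llIDR (internal, longer
than 1000 residues) and tiles into five 200-mers plus a 100-residue
tail; the diblock's z-score of ~25 says its charge arrangement is ~25
shuffle-null standard deviations blockier than its composition alone
predicts; the FRET inversion recovers the programmed efficiency exactly
because the unbleached-ROI correction removes the drift; the FRAP fit
recovers the programmed mobile fraction within 1% at this noise level;
and of the 282 peaks that opened specifically in TR (closed in FL, open
in TR), 29.8% remain open in LTR — the generator's programmed mix,
recovered by the encoding.

A command-line wrapper with the same functionality is installed at
`system.file("scripts", "idrcond.R", package = "idrcond")`; every
subcommand writes a `manifest.json` with the tool version, full
configuration and input checksums.

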