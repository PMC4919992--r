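---
title: "Detecting isotope-labelled taxa from density-gradient fractions"
author: "SIPshift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting isotope-labelled taxa from density-gradient fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SIPshift)
```

## The inference problem

DNA stable-isotope probing (DNA-SIP) identifies which community members
assimilate carbon from a ^13^C-labelled substrate. DNA built from ^13^C is
denser than its ^12^C counterpart, so after isopycnic centrifugation in a
CsCl gradient the DNA of substrate assimilators equilibrates at a higher
buoyant density (BD). The gradient is fractionated bottom-to-top into a
small number of fractions — twelve here, with fraction 1 the heaviest —
and each fraction is profiled (amplicon sequencing or TRFLP) and its 16S
rRNA gene copies quantified by qPCR.

The catch is that BD also rises with GC content: an unlabelled high-GC
organism bands where a labelled low-GC organism does. SIP experiments
therefore always run *paired* gradients — soil spiked with the ^13^C
substrate versus soil spiked with the identical ^12^C substrate — and ask,
per taxon, whether its band sits measurably heavier in the labelled
gradient than in its own unlabelled control. `SIPshift` implements that
comparison quantitatively, together with the fraction-level bookkeeping
around it and a forward simulator that provides ground truth.

## Data model

A `GradientRun` (an extension of `SummarizedExperiment`) holds one
fractionated gradient: a taxon × fraction relative-abundance assay whose
columns each sum to 1 (optionally the raw read counts), per-fraction
metadata (`fraction` index, `density` in g/ml strictly decreasing with
index, qPCR `copies`), and the run identity (soil, treatment, replicate,
incubation day). Validity checks enforce the fraction conventions so that
downstream code can align fractions positionally across runs.

## The detection procedure

`detectLabelled()` takes replicate sets of ^13^C and ^12^C runs and, for
every taxon shared by both arms:

1. **Difference profile.** The per-fraction mean relative abundance over
   the ^13^C replicates minus the same over the ^12^C replicates
   (`differenceProfile()`). A labelled taxon loses relative abundance in
   light fractions and gains it in heavy ones.
2. **Centre-of-mass shift.** Each arm's abundance-weighted mean BD,
   $\mathrm{com} = \sum_f d_f m_{tf} / \sum_f m_{tf}$, and the shift
   $\Delta\mathrm{com} = \mathrm{com}_{13C} - \mathrm{com}_{12C}$. This is
   the quantitative form of "shifted toward heavier fractions".
3. **Call.** Labelled when $\Delta\mathrm{com} \ge$ `comThreshold` *and*
   the difference profile is positive in at least `heavyK` heavy-side
   fractions where the taxon is detected. The two conditions encode the
   expectation that a genuine shift is both large on the density scale and
   built up gradually over at least two of the heavier fractions, rather
   than a single-fraction spike.

"Heavy side" is defined per experiment as the fractions denser than the
copy-weighted median density of the ^12^C arm — i.e. the half of the DNA
pool's density distribution that unlabelled DNA mostly avoids.

### Why centres of mass are copy-weighted

With `weighting = "copies"` (the default) the mass term is
$m_{tf} = a_{tf} \cdot c_f$: the taxon's relative abundance times the
fraction's 16S copies, which is proportional to the taxon's absolute DNA
in that fraction. The purely relative alternative
(`weighting = "relative"`, $m_{tf} = a_{tf}$) mirrors the bar-plot
difference profiles exactly, but has a known artifact: heavy fractions of
an unlabelled gradient contain almost no DNA, yet sequencing them still
returns reads — drawn from whatever trace DNA tails into that region,
which is disproportionately the highest-GC organisms. Those near-empty
fractions then dominate the relative centre of mass of high-GC taxa,
inflating $\mathrm{com}_{12C}$ and compressing the apparent shift. The
copy-weighted estimator down-weights empty fractions by exactly how empty
they are and is therefore the default; in simulations it recovers the
configured density gain to within a fraction width at 12 fractions and to
$<0.005$ g/ml at 120.

### Thresholds

* `comThreshold = 0.010` g/ml — about one fraction width of a 12-fraction
  window spanning 0.110 g/ml. A fully ^13^C-labelled genome gains
  ~0.036 g/ml, so the threshold sits at roughly a third of the maximal
  effect while exceeding the null spread of the centre-of-mass estimate by
  an order of magnitude at typical depths.
* `heavyK = 2` — shifts should span at least two heavy fractions.
* `minAbund = 0.001` — taxa below 0.1 % of the reconstructed total
  community are reported but never called; their fraction profiles carry
  too few reads for a stable centre of mass.
* The permutation test (`nPerm > 0`) shuffles treatment labels across
  replicate gradients and recomputes the shift; it is **off by default**
  because the baseline procedure is a deterministic threshold screen, and
  with three replicates per arm only 20 relabellings exist (minimum
  attainable p = 0.05).

Taxa present in only one treatment arm are flagged (`absent_12C` /
`absent_13C`) and never auto-called: with no control band there is no
shift to measure.

## Whole-community shift and timepoint selection

Before any per-taxon analysis, `totalShiftCheck()` asks whether the
^13^C treatment moved the *entire* 16S pool: the copy-weighted mean
density per run, averaged within arms and differenced. Early in an
incubation the label has not yet propagated into biomass and the check is
negative; once it turns positive (beyond `tolerance`, default
0.002 g/ml — set near three standard deviations of the null difference
under the default qPCR noise) the timepoint is informative for per-taxon
screening. The demo configuration reproduces this logic with a weakly
labelled early timepoint and a strongly labelled late one.

## Fraction-table conventions and filtering

`normalizeProfile()` divides each profile by its total signal.
`filterTRFs()` applies the two standard TRFLP exclusions — fragments
shorter than 50 bp, and peaks contributing less than 1 % of a profile's
total height. The 1 % rule is evaluated **per profile** against the
**pre-filter** total (a flag switches to the post-length-filter total);
entries below threshold are zeroed and rows that vanish everywhere are
dropped, then columns are renormalized. `rarefy()` subsamples count
columns without replacement to a common depth (default 3240 reads, a
typical minimum per-sample yield) via `vegan::rrarefy`, seeded and
RNG-stream-preserving. OTU tables are kept as counts until after
rarefaction; TRFLP tables are intrinsically relative.

Refractometer-to-density conversion is deliberately not implemented:
fraction densities are measured quantities and enter as an input column.

## The gradient simulator

`simulateGradient()` forward-models the data-generating process so that
every inference step can be validated against known ground truth:

* **Banding.** $BD = a + b\,GC + \Delta_{max}(x - x_0)/(1 - x_0)$ with
  defaults $a = 1.660$, $b = 0.098$ g/ml (the classical linear CsCl
  GC–density relation) and $\Delta_{max} = 0.036$ g/ml for full ^13^C
  substitution. Each taxon's DNA is a Gaussian band of width
  `bandSigma` (default 0.006 g/ml, giving realistic 3–5-fraction bands)
  centred at its BD.
* **Fractionation.** Twelve equal-width windows spanning 1.665–1.775
  g/ml, centred near the 1.72 g/ml average density of a typical gradient;
  band mass is the Gaussian integral over each window. Mass outside the
  window is reported as pellet/top, never silently renormalized, so
  per-taxon mass conservation is auditable to machine precision.
* **Noise.** qPCR copy totals get mean-preserving lognormal noise
  (CV 0.1, a typical inter-replicate qPCR spread); read counts are
  Dirichlet-multinomial draws (concentration 200 × proportions, moderate
  overdispersion) at 3240 reads per fraction. Both are seeded;
  `simulateExperiment()` derives independent per-run seeds
  deterministically from one master seed.
* **Community.** `makeCommunity()` draws 50 taxa with GC uniform on
  0.30–0.70, symmetric-Dirichlet (concentration 2) base abundances, and
  MspI-style TRF lengths on 53–802 bp with collisions allowed. The first
  ten taxon ids are guild slots guaranteed ≥ 1 % abundance, so labelled
  guilds are always resolvable — mirroring the fact that detected
  assimilators in fraction-level screens are invariably the reasonably
  abundant ones.

What the simulator does **not** emulate: relic/extracellular DNA,
cross-feeding of label through the food web, partial genome replication
(a taxon's DNA is a single band, not a labelled/unlabelled mixture),
chimeras and sequencing error at the read level, and between-run density
miscalibration. Passing tests therefore demonstrate the inference is
correct *given* clean paired gradients; they do not certify robustness to
those real-data pathologies, of which cross-feeding (label flowing into
secondary consumers during long incubations) is the one the procedure
inherently cannot distinguish from primary assimilation.

## Numerical choices and degenerate inputs

* Fraction alignment across runs is positional (by index), matching how
  heavier fractions are compared across gradients in practice; densities
  are averaged per index for the density scale.
* Fractions whose simulated band mass underflows to zero get a flat read
  profile (their copies are ~0, so they carry no weight downstream).
* Empty fraction profiles, all-zero copy vectors, non-monotone densities,
  duplicate (run, fraction) pairs and sub-depth samples all raise
  descriptive errors rather than propagating NaN.
* TSV writers emit full-precision (`%.17g`) numbers; a written run
  re-reads bit-identically, and a rewrite is byte-identical.
* The demo sizes (50 taxa, 12 fractions, 3 replicates, 3240 reads, 200
  calibration seeds, 50 demo seeds) were chosen as the smallest design at
  which the calibration statements (null call rate ≤ 5 %, sensitivity
  ≥ 0.90, specificity ≥ 0.95) are meaningfully testable.

## Isotope arithmetic

The chloroform-fumigation mixing balance
$\delta^{13}C_{mic} = (\delta_{fum} C_{fum} - \delta_{nfum} C_{nfum}) /
(C_{fum} - C_{nfum})$ treats the fumigated extract as the sum of the
non-fumigated background pool and the microbial biomass released by
fumigation; no extraction-efficiency correction factor is applied, the
biomass carbon being taken as the raw concentration difference.
`summarizeDeltaCmic()` propagates replicates as per-replicate values
summarized to mean ± sd per treatment × timepoint. qPCR standard-curve
efficiency is $10^{-1/slope} - 1$. Delta-notation ↔ atom-fraction
conversion uses the V-PDB reference ratio 0.0111802 (configurable); the
round trip closes to $10^{-12}$ relative over the range from natural
abundance to fully labelled substrates.

## A worked example

```{r example, eval = FALSE}
taxa <- makeCommunity(50, seed = 3)
runs <- simulateExperiment(taxa, gradientConfig(), soils = "D",
                           replicates = 3,
                           labelledBySoil = list(D = sprintf("T%02d", 1:5)),
                           masterSeed = 11)
st <- detectLabelled(runs[grepl("_13C_", names(runs))],
                     runs[grepl("_12C_", names(runs))])
labelledTaxa(st)
renderDeltaPlot(st)
```

The packaged demo configuration (`demoConfig()`) extends this to three
soils with two labelled guilds and two timepoints; `runPipeline()` runs
it end to end and writes a deterministic report bundle.

## Known limitations

* Binary calls only: no per-taxon atom-fraction-excess estimation
  (qSIP-style inversion of the density shift) — the screen answers
  "labelled or not", not "how labelled".
* Positional fraction alignment assumes comparable gradients; strongly
  discrepant density ranges between runs should be interpolated onto a
  common density grid before detection.
* With very uneven communities the guild-slot guarantee of
  `makeCommunity()` can fail (fewer than `guildSlots` taxa above 1 %),
  which raises an error rather than silently relaxing the design.
* The permutation test's resolution is limited by the replicate count;
  it is a reproducibility aid, not a substitute for replication.
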