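# SIPshift

Detection of isotope-labelled taxa from DNA-SIP density-gradient fractions.

## What it is for

DNA stable-isotope probing (DNA-SIP) asks which members of a microbial
community assimilate carbon from a ¹³C-labelled substrate: their DNA becomes
denser and, after isopycnic centrifugation in a CsCl gradient, bands in
heavier gradient fractions. Because buoyant density (BD) also rises with GC
content, the analysis always compares *paired* gradients — ¹³C-spiked versus
¹²C-spiked microcosms — fraction by fraction.

`SIPshift` is an R package for the fraction-level analysis of such
experiments: it normalizes and filters fraction profiles (TRFLP or OTU
tables), reconstructs whole communities from their fractions, computes
labelled-vs-unlabelled difference profiles, scores each taxon's
buoyant-density shift, classifies taxa as labelled, checks for
whole-community qPCR shifts across incubation timepoints, and handles the
stable-isotope arithmetic (fumigation-extraction biomass δ¹³C, qPCR
efficiency, δ-notation ↔ atom fraction). A seeded forward simulator of
isopycnic gradients provides ground truth for validating every step.

## The statistic at its core

For taxon *t* with relative abundance *a*<sub>tf</sub> in fraction *f*
(density *d*<sub>f</sub>, 16S copies *c*<sub>f</sub>), each treatment arm
gets a copy-weighted centre of mass

> com = Σ<sub>f</sub> d<sub>f</sub> · a<sub>tf</sub> c<sub>f</sub> / Σ<sub>f</sub> a<sub>tf</sub> c<sub>f</sub>

and the shift score is Δcom = com(¹³C) − com(¹²C). A taxon is called
labelled when Δcom ≥ 0.010 g/ml (≈ one fraction width) **and** its mean
difference profile (¹³C − ¹²C relative abundance per fraction, averaged over
replicates) is positive in at least two heavy-side fractions. An optional
permutation test over treatment relabellings makes the screen inferential.

Fraction conventions: gradients are fractionated bottom-to-top into 12 equal
fractions; fraction 1 is the heaviest, densities strictly decrease with
fraction index. TRFLP filtering follows the standard rules (fragments
< 50 bp excluded; peaks contributing < 1 % of a profile's total signal
excluded, then renormalized); OTU counts are rarefied without replacement
(default 3240 reads) before conversion to relative abundance.

## Worked example

```r
library(SIPshift)

taxa <- makeCommunity(50, seed = 3)                 # 50 taxa, guild slots T01..T10
runs <- simulateExperiment(taxa, gradientConfig(), soils = "D", replicates = 3,
                           labelledBySoil = list(D = sprintf("T%02d", 1:5)),
                           masterSeed = 11)
st <- detectLabelled(runs[grepl("_13C_", names(runs))],
                     runs[grepl("_12C_", names(runs))])
st
#> ShiftTable: 50 taxa over 12 fractions; 5 called labelled
#>   labelled: T01, T02, T03, T04, T05
#>   com_threshold 0.01 g/ml | heavy_k 2 | min_abund 0.001
totalShiftCheck(runs[grepl("_13C_", names(runs))],
                runs[grepl("_12C_", names(runs))])$shift
#> [1] 0.004564228
```

The five taxa simulated as fully ¹³C-labelled are exactly the five called;
their centre-of-mass shifts (0.035–0.037 g/ml) bracket the 0.036 g/ml
density gain of fully labelled DNA, and the whole 16S pool moves by
+0.0046 g/ml — the community-level signature used to pick the right
sampling timepoint.

The packaged three-soil demo (two soils sharing one labelled guild, a third
with a disjoint guild, plus a weakly labelled early timepoint) runs end to
end with:

```r
res <- runPipeline(demoConfig(), outDir = "demo_out")
res$labelled
#> $D: "T01" "T02" "T03" "T04" "T05"
#> $F: "T01" "T02" "T03" "T04" "T05"
#> $W: "T06" "T07" "T08" "T09" "T10"
```

writing per-soil shift tables, difference-profile matrices, total-shift
checks and a manifest; the same config and seed give a byte-identical
bundle.

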