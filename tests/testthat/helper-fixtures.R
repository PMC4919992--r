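# Shared fixtures: tiny hand-built runs and small simulated experiments.

suppressPackageStartupMessages(library(SummarizedExperiment))

# A GradientRun from explicit per-fraction abundance columns (each sums to 1).
toyRun <- function(abundance, density = NULL, copies = NULL, runId = "toy",
                   soil = "X", treatment = "12C", replicate = 1L) {
  n <- ncol(abundance)
  if (is.null(density)) density <- seq(1.76, by = -0.01, length.out = n)
  if (is.null(copies)) copies <- rep(100, n)
  GradientRun(abundance = abundance, density = density, copies = copies,
              runId = runId, soil = soil, treatment = treatment,
              replicate = replicate, timepointDays = 32L)
}

# Paired 13C/12C replicate sets simulated from one community.
simPair <- function(nTaxa = 50, labelled = character(), replicates = 3,
                    cfg = gradientConfig(), communitySeed = 1,
                    masterSeed = 100, labelAtomFraction = 1.0) {
  taxa <- makeCommunity(nTaxa, seed = communitySeed)
  runs <- simulateExperiment(taxa, cfg, soils = "X", replicates = replicates,
                             labelledBySoil = if (length(labelled))
                               list(X = labelled) else list(),
                             labelAtomFraction = labelAtomFraction,
                             masterSeed = masterSeed)
  list(taxa = taxa,
       r13 = runs[grepl("_13C_", names(runs))],
       r12 = runs[grepl("_12C_", names(runs))])
}
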