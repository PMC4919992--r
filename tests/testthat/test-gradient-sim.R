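afNat <- deltaToAtomFraction(0)

test_that("buoyant density is linear in GC and 13C enrichment", {
  cfg <- gradientConfig()
  expect_equal(taxonBuoyantDensity(0, afNat, cfg), 1.660, tolerance = 1e-12)
  expect_equal(taxonBuoyantDensity(0.5, afNat, cfg), 1.709, tolerance = 1e-12)
  # full labelling adds exactly the configured density gain
  expect_equal(taxonBuoyantDensity(0.5, 1.0, cfg), 1.709 + 0.036,
               tolerance = 1e-12)
  expect_error(taxonBuoyantDensity(1.2, afNat), "gc")
  expect_error(taxonBuoyantDensity(0.5, -0.1), "atom13c")
})

test_that("band centre increases strictly with 13C atom fraction", {
  af <- seq(afNat, 1, length.out = 25)
  bd <- taxonBuoyantDensity(0.5, af)
  expect_true(all(diff(bd) > 0))
})

test_that("fractionation conserves per-taxon mass exactly", {
  set.seed(7)
  for (i in 1:20) {
    taxa <- makeCommunity(sample(5:60, 1), seed = i)
    fr <- fractionate(taxa, gradientConfig())
    expect_equal(unname(rowSums(fr$mass) + fr$pellet + fr$top),
                 taxa$base_abundance, tolerance = 1e-9)
  }
})

test_that("a narrow band centred on a fraction midpoint stays in that fraction", {
  cfg <- gradientConfig(bandSigma = 0.0005)
  win_width <- (cfg$densityMax - cfg$densityMin) / cfg$nFractions
  # place the band exactly at fraction 5's midpoint via the GC dial
  target <- cfg$densityMax - 4.5 * win_width
  gc <- (target - cfg$bdIntercept) / cfg$bdGcSlope
  taxa <- data.frame(taxon_id = "t", gc = gc, atom13c = afNat,
                     base_abundance = 1)
  fr <- fractionate(taxa, cfg)
  # Gaussian integral oracle over +/- half a window
  oracle <- 1 - 2 * pnorm(-win_width / 2 / cfg$bandSigma)
  expect_equal(unname(fr$mass["t", "F5"]), oracle, tolerance = 1e-9)
  expect_gte(fr$mass["t", "F5"], 0.997)
})

test_that("mirrored communities produce mirrored mass matrices", {
  cfg <- gradientConfig()
  centre <- (cfg$densityMin + cfg$densityMax) / 2
  off <- 0.02
  gcs <- ((centre + c(-off, off)) - cfg$bdIntercept) / cfg$bdGcSlope
  taxa <- data.frame(taxon_id = c("lo", "hi"), gc = gcs, atom13c = afNat,
                     base_abundance = 0.5)
  fr <- fractionate(taxa, cfg)
  expect_equal(unname(fr$mass["lo", ]), unname(rev(fr$mass["hi", ])),
               tolerance = 1e-12)
})

test_that("simulated gradients are reproducible and noise-free in the limit", {
  taxa <- makeCommunity(20, seed = 5)
  cfg <- gradientConfig(seed = 11)
  r1 <- simulateGradient(taxa, cfg, "12C")
  r2 <- simulateGradient(taxa, cfg, "12C")
  expect_identical(assay(r1, "counts"), assay(r2, "counts"))
  expect_identical(copyNumbers(r1), copyNumbers(r2))
  # zero-noise / infinite-depth limit: abundances equal mass proportions
  cfg0 <- gradientConfig(seqDepth = Inf, qpcrCv = 0)
  r0 <- simulateGradient(taxa, cfg0, "12C", seed = 1)
  fr <- fractionate(transform(taxa, atom13c = afNat), cfg0)
  expect_equal(abundances(r0),
               sweep(fr$mass, 2, colSums(fr$mass), "/"), tolerance = 1e-12)
  expect_equal(unname(copyNumbers(r0)), unname(colSums(fr$mass) * cfg0$copyScale),
               tolerance = 1e-12)
})

test_that("densities decrease with fraction index and copies are positive", {
  taxa <- makeCommunity(10, seed = 2)
  run <- simulateGradient(taxa, gradientConfig(), "13C", seed = 3)
  expect_true(all(diff(densities(run)) < 0))
  expect_true(all(copyNumbers(run) >= 0))
  expect_equal(colSums(abundances(run)), setNames(rep(1, 12), colnames(run)),
               tolerance = 1e-9)
})

test_that("labelling moves the copy-weighted band centre by the full gain", {
  # one fully labelled taxon, fine fractionation, no sampling noise
  taxa <- data.frame(taxon_id = "t", gc = 0.5, atom13c = 1.0,
                     base_abundance = 1, labelled = TRUE, trf_length = 100L)
  cfg <- gradientConfig(nFractions = 120, seqDepth = Inf, qpcrCv = 0)
  r12 <- simulateGradient(taxa, cfg, "12C", seed = 1)
  r13 <- simulateGradient(taxa, cfg, "13C", seed = 1)
  wm <- function(r) sum(densities(r) * copyNumbers(r)) / sum(copyNumbers(r))
  expect_equal(wm(r13) - wm(r12), cfg$bdDeltaMax, tolerance = 1e-3)
})

test_that("band-centre estimate converges to the configured buoyant density", {
  taxa <- data.frame(taxon_id = "t", gc = 0.42, atom13c = afNat,
                     base_abundance = 1)
  cfg <- gradientConfig(nFractions = 120, bandSigma = 0.002)
  fr <- fractionate(taxa, cfg)
  est <- sum(fr$densities * fr$mass["t", ]) / sum(fr$mass["t", ])
  expect_equal(est, taxonBuoyantDensity(0.42, afNat, cfg), tolerance = 1e-3)
})

test_that("Dirichlet-multinomial sampling preserves expected proportions", {
  taxa <- data.frame(taxon_id = paste0("t", 1:5),
                     gc = c(0.35, 0.4, 0.45, 0.5, 0.55),
                     atom13c = afNat,
                     base_abundance = c(0.4, 0.25, 0.2, 0.1, 0.05),
                     labelled = FALSE, trf_length = 60L)
  cfg <- gradientConfig(nFractions = 2, densityMin = 1.66, densityMax = 1.76,
                        bandSigma = 0.05, seqDepth = 500)
  fr <- fractionate(taxa, cfg)
  expProp <- fr$mass[, 1] / sum(fr$mass[, 1])
  draws <- vapply(seq_len(1000), function(s)
    abundances(simulateGradient(taxa, cfg, "12C", seed = s))[, 1],
    numeric(5))
  obs <- rowMeans(draws)
  se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(obs - expProp) <= 3 * se + 1e-12))
})

test_that("in-silico TRFLP merges taxa sharing a fragment length", {
  m <- matrix(c(0.3, 0.2, 0.5, 0.1, 0.4, 0.5), 3, 2,
              dimnames = list(c("a", "b", "c"), c("F1", "F2")))
  # shared TRF: rows a and b sum
  out <- insilicoTRFLP(m, c(a = 56L, b = 56L, c = 120L))
  expect_equal(out["56", ], c(F1 = 0.5, F2 = 0.5), tolerance = 1e-12)
  expect_equal(out["120", ], c(F1 = 0.5, F2 = 0.5), tolerance = 1e-12)
  # injective map: row-relabelled copy of the input
  inj <- insilicoTRFLP(m, c(a = 70L, b = 56L, c = 120L))
  expect_equal(unname(inj[c("70", "56", "120"), ]), unname(m), tolerance = 1e-12)
  # empty column preserved
  m0 <- cbind(m, F3 = c(0, 0, 0))
  expect_equal(unname(insilicoTRFLP(m0, c(a = 56L, b = 56L, c = 120L))[, "F3"]),
               c(0, 0), tolerance = 1e-12)
  expect_error(insilicoTRFLP(m, c(a = 56L, b = 56L)), "c")
  expect_error(insilicoTRFLP(m, c(a = 10L, b = 56L, c = 120L)), "50")
})

test_that("simulated TRF lengths span a realistic range", {
  taxa <- makeCommunity(200, seed = 31)
  expect_true(all(taxa$trf_length >= 53 & taxa$trf_length <= 802))
  expect_gt(diff(range(taxa$trf_length)), 400)
})

test_that("a full experiment produces the designed run grid, reproducibly", {
  taxa <- makeCommunity(30, seed = 8)
  cfg <- gradientConfig()
  lab <- list(D = c("T01", "T02"), F = c("T01", "T02"), W = c("T03", "T04"))
  runs <- simulateExperiment(taxa, cfg, soils = c("D", "F", "W"),
                             replicates = 3, labelledBySoil = lab,
                             masterSeed = 77)
  expect_length(runs, 18)
  expect_true(all(vapply(runs, ncol, integer(1)) == 12))
  expect_equal(sort(unique(vapply(runs, soil, character(1)))),
               c("D", "F", "W"))
  # labelled flags follow the per-soil design in the 13C arms
  wRun <- runs[["W_13C_r1_d32"]]
  expect_equal(rownames(wRun)[rowData(wRun)$labelled], c("T03", "T04"))
  expect_false(any(rowData(runs[["W_12C_r1_d32"]])$atom13c > 0.5))
  # same master seed: identical outputs
  runs2 <- simulateExperiment(taxa, cfg, soils = c("D", "F", "W"),
                              replicates = 3, labelledBySoil = lab,
                              masterSeed = 77)
  expect_identical(lapply(runs, abundances), lapply(runs2, abundances))
  expect_error(simulateExperiment(taxa, cfg, labelledBySoil = list(D = "nope")),
               "unknown taxa")
})

test_that("guild slots of a generated community are resolvably abundant", {
  for (s in 1:5) {
    taxa <- makeCommunity(50, guildSlots = 10, seed = s)
    expect_equal(sum(taxa$base_abundance), 1, tolerance = 1e-9)
    expect_true(all(taxa$base_abundance[1:10] >= 0.01))
  }
})
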