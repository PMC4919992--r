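#' Configuration of a simulated isopycnic gradient
#'
#' Bundles the physical and noise parameters of the forward simulator.
#' Defaults emulate a 12-fraction CsCl gradient fractionated bottom-to-top
#' with the fraction window centred near a mean density of 1.72 g/ml.
#'
#' @param nFractions number of equal-width density fractions (default 12).
#' @param densityMin,densityMax bounds of the fraction window (g/ml).
#' @param bandSigma within-gradient banding standard deviation (g/ml); a
#'   taxon's DNA forms a Gaussian band of this width around its buoyant
#'   density. Default 0.006 gives realistic 3-5-fraction bands.
#' @param seqDepth reads sequenced per fraction (default 3240). \code{Inf}
#'   switches sampling off: abundances equal the underlying mass proportions.
#' @param qpcrCv coefficient of variation of the lognormal noise on
#'   per-fraction 16S copy totals (default 0.1).
#' @param overdispersion Dirichlet concentration scaler of the
#'   Dirichlet-multinomial read sampler (larger = closer to multinomial;
#'   \code{Inf} = pure multinomial). Default 200.
#' @param copyScale 16S copies recovered from a whole gradient at unit DNA
#'   mass (default 1e8).
#' @param bdIntercept,bdGcSlope linear GC-to-buoyant-density relation (g/ml):
#'   BD = intercept + slope * GC at natural 13C abundance.
#' @param bdDeltaMax buoyant-density gain of fully 13C-labelled DNA (g/ml).
#' @param seed integer seed making a simulation reproducible.
#' @return A validated list of class \code{"GradientConfig"}.
#' @export
#' @examples
#' cfg <- gradientConfig(seed = 1)
#' cfg$nFractions
gradientConfig <- function(nFractions = 12L, densityMin = 1.665,
                           densityMax = 1.775, bandSigma = 0.006,
                           seqDepth = 3240, qpcrCv = 0.1,
                           overdispersion = 200, copyScale = 1e8,
                           bdIntercept = 1.660, bdGcSlope = 0.098,
                           bdDeltaMax = 0.036, seed = NULL) {
  cfg <- list(nFractions = as.integer(nFractions), densityMin = densityMin,
              densityMax = densityMax, bandSigma = bandSigma,
              seqDepth = seqDepth, qpcrCv = qpcrCv,
              overdispersion = overdispersion, copyScale = copyScale,
              bdIntercept = bdIntercept, bdGcSlope = bdGcSlope,
              bdDeltaMax = bdDeltaMax, seed = seed)
  if (cfg$nFractions < 2L) stop("nFractions must be >= 2")
  if (cfg$densityMin >= cfg$densityMax) stop("densityMin must be < densityMax")
  if (cfg$bandSigma <= 0) stop("bandSigma must be positive")
  if (cfg$seqDepth < 1) stop("seqDepth must be >= 1")
  if (cfg$qpcrCv < 0) stop("qpcrCv must be >= 0")
  class(cfg) <- "GradientConfig"
  cfg
}

## fraction f covers [densityMax - f*w, densityMax - (f-1)*w]: fraction 1 is
## the bottom (heaviest) fraction, densities decrease with increasing index
.fractionWindows <- function(cfg) {
  w <- (cfg$densityMax - cfg$densityMin) / cfg$nFractions
  f <- seq_len(cfg$nFractions)
  list(upper = cfg$densityMax - (f - 1) * w, lower = cfg$densityMax - f * w,
       mid = cfg$densityMax - (f - 0.5) * w, width = w)
}

#' Buoyant density of a taxon's DNA
#'
#' Linear banding model: in CsCl the equilibrium buoyant density of DNA rises
#' linearly with GC content, and full 13C substitution adds a fixed density
#' gain. With atom fraction \eqn{x} and natural abundance \eqn{x_0},
#' \deqn{BD = a + b \cdot GC + \Delta_{max} (x - x_0) / (1 - x_0).}
#'
#' @param gc GC content fraction in [0, 1]; vectorized.
#' @param atom13c 13C atom fraction of the DNA in [0, 1]; vectorized.
#' @param cfg a \code{\link{gradientConfig}} supplying \code{bdIntercept},
#'   \code{bdGcSlope}, \code{bdDeltaMax}.
#' @param ratio reference isotope ratio defining natural abundance.
#' @return Buoyant density in g/ml.
#' @export
#' @examples
#' taxonBuoyantDensity(0.5, deltaToAtomFraction(0))   # unlabelled: 1.709
#' taxonBuoyantDensity(0.5, 1.0)                      # fully labelled: 1.745
taxonBuoyantDensity <- function(gc, atom13c, cfg = gradientConfig(),
                                ratio = vpdbRatio()) {
  if (any(gc < 0 | gc > 1)) stop("gc must lie in [0, 1]")
  if (any(atom13c < 0 | atom13c > 1)) stop("atom13c must lie in [0, 1]")
  x0 <- .afNatural(ratio)
  cfg$bdIntercept + cfg$bdGcSlope * gc +
    cfg$bdDeltaMax * (atom13c - x0) / (1 - x0)
}

#' Generate a synthetic soil community
#'
#' Draws a community of \code{nTaxa} members with GC contents uniform on
#' \code{gcRange}, base relative abundances from a symmetric Dirichlet
#' (\code{evenness} concentration), and MspI-like terminal restriction
#' fragment lengths sampled from 53-802 bp (distinct taxa may share a TRF).
#' The first \code{guildSlots} taxon ids are reserved for label-assignable
#' guild members and are guaranteed a base abundance of at least
#' \code{minGuildAbund}, mirroring the fact that substrate-assimilating taxa
#' must be reasonably abundant to be resolvable in fraction profiles.
#'
#' All taxa start at natural 13C abundance; labelling is assigned by
#' \code{\link{simulateExperiment}} or by setting \code{atom13c}/\code{labelled}
#' directly.
#'
#' @param nTaxa community size (default 50).
#' @param guildSlots number of leading taxon ids eligible for labelling.
#' @param minGuildAbund minimum base abundance of guild slots (default 0.01).
#' @param gcRange range of GC content fractions.
#' @param evenness Dirichlet concentration of base abundances (default 2).
#' @param seed integer seed.
#' @return data.frame with columns \code{taxon_id}, \code{gc}, \code{atom13c},
#'   \code{base_abundance}, \code{labelled}, \code{trf_length}; abundances
#'   sum to 1.
#' @export
makeCommunity <- function(nTaxa = 50L, guildSlots = min(10L, nTaxa),
                          minGuildAbund = 0.01, gcRange = c(0.3, 0.7),
                          evenness = 2, seed = NULL) {
  if (guildSlots > nTaxa) stop("guildSlots cannot exceed nTaxa")
  withSeed(seed, {
    gc <- runif(nTaxa, gcRange[1], gcRange[2])
    ab <- rgamma(nTaxa, shape = evenness)
    ab <- ab / sum(ab)
    trf <- sample(53:802, nTaxa, replace = TRUE)
    ## move abundant taxa into the guild slots so labelling a slot always
    ## labels a taxon resolvable above ~1% of the community
    if (guildSlots > 0L) {
      eligible <- which(ab >= minGuildAbund)
      if (length(eligible) < guildSlots)
        stop("community too uneven: fewer than ", guildSlots,
             " taxa at base abundance >= ", minGuildAbund)
      pick <- sample(eligible, guildSlots)
      ord <- c(pick, setdiff(seq_len(nTaxa), pick))
      gc <- gc[ord]; ab <- ab[ord]; trf <- trf[ord]
    }
    data.frame(taxon_id = sprintf("T%02d", seq_len(nTaxa)), gc = gc,
               atom13c = .afNatural(), base_abundance = ab,
               labelled = FALSE, trf_length = trf,
               stringsAsFactors = FALSE)
  })
}

#' Distribute taxon bands over gradient fractions
#'
#' Each taxon's DNA forms a Gaussian band centred at its buoyant density
#' (\code{\link{taxonBuoyantDensity}}) with standard deviation
#' \code{bandSigma}; the mass landing in a fraction is the Gaussian integral
#' over that fraction's density window. Band mass outside the window is
#' reported as \code{pellet} (denser than the bottom fraction) and \code{top}
#' (lighter than the top fraction), never silently renormalized, so
#' per-taxon mass is conserved exactly:
#' \code{rowSums(mass) + pellet + top == base_abundance}.
#'
#' @param taxa data.frame with \code{taxon_id}, \code{gc}, \code{atom13c},
#'   \code{base_abundance} (see \code{\link{makeCommunity}}).
#' @param cfg a \code{\link{gradientConfig}}.
#' @return List with \code{mass} (taxon x fraction matrix), \code{pellet},
#'   \code{top} (named numeric vectors), \code{densities} (fraction
#'   midpoints, decreasing), \code{width} (fraction width, g/ml) and
#'   \code{bd} (per-taxon band centres).
#' @export
fractionate <- function(taxa, cfg = gradientConfig()) {
  if (nrow(taxa) == 0L) stop("empty community")
  if (cfg$bandSigma <= 0) stop("bandSigma must be positive")
  win <- .fractionWindows(cfg)
  bd <- taxonBuoyantDensity(taxa$gc, taxa$atom13c, cfg)
  ## P(band in window f) via the Gaussian CDF, telescoping so mass conserves
  up <- outer(bd, win$upper, function(b, u) pnorm(u, mean = b, sd = cfg$bandSigma))
  lo <- outer(bd, win$lower, function(b, l) pnorm(l, mean = b, sd = cfg$bandSigma))
  mass <- (up - lo) * taxa$base_abundance
  pellet <- (1 - pnorm(cfg$densityMax, bd, cfg$bandSigma)) * taxa$base_abundance
  top <- pnorm(cfg$densityMin, bd, cfg$bandSigma) * taxa$base_abundance
  dimnames(mass) <- list(taxa$taxon_id, paste0("F", seq_len(cfg$nFractions)))
  list(mass = mass, pellet = setNames(pellet, taxa$taxon_id),
       top = setNames(top, taxa$taxon_id), densities = win$mid,
       width = win$width, bd = setNames(bd, taxa$taxon_id))
}

## Dirichlet-multinomial draw of `depth` reads from proportions p
.sampleReads <- function(p, depth, overdispersion) {
  if (is.finite(overdispersion)) {
    g <- rgamma(length(p), shape = overdispersion * p)
    if (sum(g) > 0) p <- g / sum(g)
  }
  as.vector(rmultinom(1, size = depth, prob = p))
}

#' Simulate one fractionated gradient
#'
#' Runs the banding model (\code{\link{fractionate}}) for one treatment arm
#' and overlays measurement noise: per-fraction 16S copy totals are the
#' fraction's DNA mass times \code{copyScale} with mean-preserving lognormal
#' noise of coefficient of variation \code{qpcrCv}; per-fraction read counts
#' are Dirichlet-multinomial draws of \code{seqDepth} reads from the
#' fraction's mass proportions. Under treatment \code{"12C"} every taxon is
#' forced to natural 13C abundance; under \code{"13C"} only taxa flagged
#' \code{labelled} keep their elevated \code{atom13c}.
#'
#' With \code{seqDepth = Inf} the abundance assay equals the exact mass
#' proportions and no counts assay is produced (the noise-free limit).
#'
#' @param taxa community data.frame (see \code{\link{makeCommunity}}).
#' @param cfg a \code{\link{gradientConfig}}; \code{cfg$seed} (or the
#'   \code{seed} argument) makes the run reproducible.
#' @param treatment \code{"12C"} or \code{"13C"}.
#' @param runId,soilId,replicate,timepointDays run identity metadata.
#' @param seed overrides \code{cfg$seed}.
#' @return A \code{\link{GradientRun}} whose \code{rowData} carries the
#'   realized \code{gc}, \code{atom13c} and \code{labelled} flags and whose
#'   metadata records the untruncated \code{pellet}/\code{top} band mass.
#' @export
#' @examples
#' taxa <- makeCommunity(20, seed = 7)
#' run <- simulateGradient(taxa, gradientConfig(seed = 7), "12C")
#' run
simulateGradient <- function(taxa, cfg = gradientConfig(),
                             treatment = c("12C", "13C"), runId = NULL,
                             soilId = NA_character_, replicate = 1L,
                             timepointDays = NA_integer_, seed = cfg$seed) {
  treatment <- match.arg(treatment)
  if (nrow(taxa) == 0L) stop("empty community")
  taxa$labelled <- taxa$labelled %||% rep(FALSE, nrow(taxa))
  taxa$atom13c <- if (treatment == "12C") .afNatural()
                  else ifelse(taxa$labelled, taxa$atom13c, .afNatural())
  fr <- fractionate(taxa, cfg)
  if (is.null(runId))
    runId <- sprintf("%s_%s_r%d", ifelse(is.na(soilId), "sim", soilId),
                     treatment, replicate)
  withSeed(seed, {
    total <- colSums(fr$mass)
    sdlog <- sqrt(log(1 + cfg$qpcrCv^2))
    noise <- exp(rnorm(cfg$nFractions, 0, sdlog)) / exp(sdlog^2 / 2)
    copies <- total * cfg$copyScale * noise
    ## fractions where every band has underflowed to zero mass carry no
    ## information; give them a flat profile (their copies are ~zero anyway)
    prop <- fr$mass
    nz <- total > 0
    prop[, nz] <- sweep(fr$mass[, nz, drop = FALSE], 2, total[nz], "/")
    prop[, !nz] <- 1 / nrow(taxa)
    if (is.finite(cfg$seqDepth)) {
      counts <- vapply(seq_len(cfg$nFractions), function(f)
        .sampleReads(prop[, f], cfg$seqDepth, cfg$overdispersion),
        numeric(nrow(taxa)))
      dimnames(counts) <- dimnames(fr$mass)
      abundance <- sweep(counts, 2, colSums(counts), "/")
    } else {
      counts <- NULL
      abundance <- prop
    }
    GradientRun(abundance = abundance, counts = counts,
                density = fr$densities, copies = copies, runId = runId,
                soil = soilId, treatment = treatment, replicate = replicate,
                timepointDays = timepointDays,
                rowData = DataFrame(gc = taxa$gc, atom13c = taxa$atom13c,
                                    labelled = taxa$labelled %||% FALSE,
                                    trf_length = taxa$trf_length %||% NA_integer_,
                                    row.names = taxa$taxon_id),
                metadata = list(pellet = fr$pellet, top = fr$top,
                                config = unclass(cfg)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collapse an OTU-level fraction matrix to TRF level
#'
#' In-silico TRFLP: after restriction digestion only the terminal fragment is
#' detected, so distinct taxa sharing a fragment length merge into one TRF.
#' Abundances of taxa mapping to the same length are summed per fraction.
#'
#' @param mat taxon x fraction abundance (or count) matrix with taxon ids as
#'   rownames.
#' @param trfMap named integer vector mapping taxon_id to TRF length (bp) in
#'   [50, 1000].
#' @return TRF x fraction matrix; rownames are TRF lengths (bp) as characters,
#'   sorted numerically, with the lengths repeated in attribute
#'   \code{"trf_length"}.
#' @export
#' @examples
#' m <- matrix(c(0.3, 0.2, 0.5), 3, 1, dimnames = list(c("a", "b", "c"), "F1"))
#' insilicoTRFLP(m, c(a = 56, b = 56, c = 120))
insilicoTRFLP <- function(mat, trfMap) {
  unmapped <- setdiff(rownames(mat), names(trfMap))
  if (length(unmapped))
    stop("taxa without a TRF length: ", paste(unmapped, collapse = ", "))
  len <- as.integer(trfMap[rownames(mat)])
  if (any(len < 50 | len > 1000))
    stop("TRF lengths must lie in [50, 1000] bp")
  out <- rowsum(mat, group = len)
  ord <- order(as.integer(rownames(out)))
  out <- out[ord, , drop = FALSE]
  attr(out, "trf_length") <- as.integer(rownames(out))
  out
}

#' Simulate a full multi-soil SIP experiment
#'
#' Generates paired 12C/13C gradient runs for each soil and replicate, with
#' per-soil labelled-taxon sets (e.g. one guild shared by two soils and a
#' disjoint guild in the third). Each run receives its own RNG seed derived
#' deterministically from \code{masterSeed}, so any single run can be
#' regenerated in isolation and the whole experiment is byte-reproducible.
#'
#' @param taxa community data.frame (see \code{\link{makeCommunity}}).
#' @param cfg a \code{\link{gradientConfig}}.
#' @param soils character vector of soil ids (default \code{c("D","F","W")}).
#' @param replicates replicate gradients per soil x treatment (default 3).
#' @param labelledBySoil named list: soil id -> character vector of taxon ids
#'   labelled in that soil's 13C microcosms.
#' @param labelAtomFraction 13C atom fraction reached by labelled taxa
#'   (default 1, fully labelled).
#' @param timepointDays incubation day stamped on the runs.
#' @param masterSeed integer master seed.
#' @return Named list of \code{\link{GradientRun}} (one per
#'   soil x treatment x replicate), names are run ids
#'   \code{<soil>_<treatment>_r<rep>_d<day>}.
#' @export
simulateExperiment <- function(taxa, cfg = gradientConfig(),
                               soils = c("D", "F", "W"), replicates = 3L,
                               labelledBySoil = list(),
                               labelAtomFraction = 1.0,
                               timepointDays = 32L, masterSeed = 1L) {
  bad <- setdiff(unlist(labelledBySoil), taxa$taxon_id)
  if (length(bad))
    stop("labelledBySoil names unknown taxa: ", paste(bad, collapse = ", "))
  grid <- expand.grid(replicate = seq_len(replicates),
                      treatment = c("12C", "13C"), soil = soils,
                      stringsAsFactors = FALSE)
  seeds <- withSeed(masterSeed, sample.int(.Machine$integer.max, nrow(grid)))
  runs <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    tx <- taxa
    lab <- labelledBySoil[[g$soil]] %||% character()
    tx$labelled <- tx$taxon_id %in% lab
    tx$atom13c <- ifelse(tx$labelled, labelAtomFraction, .afNatural())
    simulateGradient(tx, cfg, treatment = g$treatment,
                     runId = sprintf("%s_%s_r%d_d%d", g$soil, g$treatment,
                                     g$replicate, timepointDays),
                     soilId = g$soil, replicate = g$replicate,
                     timepointDays = timepointDays, seed = seeds[i])
  })
  names(runs) <- vapply(runs, runId, character(1))
  runs
}
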