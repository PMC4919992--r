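## shared argument checks for replicate sets of runs
.checkArms <- function(runs13C, runs12C) {
  if (!length(runs13C) || !length(runs12C))
    stop("need at least one replicate run per treatment arm")
  nf <- unique(vapply(c(runs13C, runs12C), ncol, integer(1)))
  if (length(nf) != 1L)
    stop("runs disagree on fraction count: ", paste(nf, collapse = " vs "))
  taxa <- rownames(runs13C[[1]])
  ok <- vapply(c(runs13C, runs12C), function(r) identical(rownames(r), taxa),
               logical(1))
  if (!all(ok)) stop("runs disagree on taxon rows; intersect/reorder first")
  invisible(nf)
}

## element-wise mean abundance matrix of a replicate set
.meanAbundance <- function(runs) {
  Reduce(`+`, lapply(runs, abundances)) / length(runs)
}

## index-aligned mean fraction densities of a replicate set
.meanDensities <- function(runs) {
  Reduce(`+`, lapply(runs, densities)) / length(runs)
}

## weighted median of x with non-negative weights w
.weightedMedian <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

#' Reconstruct the unfractionated community from its gradient fractions
#'
#' Summarizes per-fraction relative abundances into one whole-community
#' profile. With \code{weighting = "copies"} each fraction contributes in
#' proportion to its 16S copy number (its share of the total DNA pool); with
#' \code{"uniform"} all fractions weigh equally.
#'
#' @param run a \code{\link{GradientRun}}.
#' @param weighting \code{"copies"} (default) or \code{"uniform"}.
#' @return Named numeric vector over taxa, summing to 1.
#' @export
reconstructTotalCommunity <- function(run, weighting = c("copies", "uniform")) {
  weighting <- match.arg(weighting)
  a <- abundances(run)
  w <- if (weighting == "copies") {
    cp <- copyNumbers(run)
    if (all(cp == 0) || all(is.na(cp)))
      stop("weighting = 'copies' needs non-zero per-fraction copy numbers")
    cp / sum(cp)
  } else rep(1 / ncol(a), ncol(a))
  drop(a %*% w)
}

#' Mean per-fraction abundance difference between treatment arms
#'
#' The fraction-resolved screen for isotope labelling: for each taxon and
#' fraction index, the mean relative abundance over the 13C replicate
#' gradients minus the mean over the 12C replicates. Fractions are aligned
#' positionally (fraction 1 = heaviest in every run). A labelled taxon shows
#' a characteristic negative-light / positive-heavy difference profile.
#'
#' @param runs13C,runs12C lists of \code{\link{GradientRun}} replicates.
#' @param taxon optional taxon id; when given a single profile vector is
#'   returned instead of the full matrix.
#' @return taxon x fraction matrix (or vector) of mean differences in
#'   [-1, 1].
#' @export
differenceProfile <- function(runs13C, runs12C, taxon = NULL) {
  .checkArms(runs13C, runs12C)
  delta <- .meanAbundance(runs13C) - .meanAbundance(runs12C)
  if (!is.null(taxon)) {
    if (!taxon %in% rownames(delta)) stop("unknown taxon: ", taxon)
    return(delta[taxon, ])
  }
  delta
}

#' Buoyant-density centre of mass of a taxon within one gradient
#'
#' The abundance-weighted mean fraction density,
#' \eqn{\sum_f d_f m_{tf} / \sum_f m_{tf}}, where \eqn{m_{tf}} is the
#' taxon's relative abundance in fraction f (\code{weighting = "relative"})
#' or that abundance scaled by the fraction's 16S copies
#' (\code{weighting = "copies"}). This turns "shifted toward heavier
#' fractions" into a number on the density scale.
#'
#' @param run a \code{\link{GradientRun}}.
#' @param taxon taxon id.
#' @param weighting \code{"relative"} (default) or \code{"copies"}.
#' @return Density in g/ml, or \code{NA} (with a warning) for a taxon absent
#'   from every fraction (not evaluable).
#' @export
bdCenterOfMass <- function(run, taxon, weighting = c("relative", "copies")) {
  weighting <- match.arg(weighting)
  if (!taxon %in% rownames(run)) stop("unknown taxon: ", taxon)
  m <- abundances(run)[taxon, ]
  if (weighting == "copies") m <- m * copyNumbers(run)
  if (sum(m) <= 0) {
    warning("taxon ", taxon, " absent from all fractions: centre of mass not evaluable")
    return(NA_real_)
  }
  sum(densities(run) * m) / sum(m)
}

## centre-of-mass densities for all taxa from a mean abundance matrix
.comAll <- function(meanAb, dens, copies = NULL) {
  m <- if (is.null(copies)) meanAb else sweep(meanAb, 2, copies, "*")
  tot <- rowSums(m)
  out <- as.vector(m %*% dens) / tot
  out[tot <= 0] <- NA_real_
  names(out) <- rownames(meanAb)
  out
}

#' Classify taxa as isotope-labelled from paired gradient sets
#'
#' The core SIP call. For every taxon shared by the two arms it computes the
#' mean difference profile (\code{\link{differenceProfile}}), the
#' centre-of-mass buoyant density in each arm, and the shift
#' \code{com_shift = com_13C - com_12C}. A taxon is called labelled when
#' (i) \code{com_shift >= comThreshold} and (ii) its difference profile is
#' positive in at least \code{heavyK} heavy-side fractions where the taxon is
#' detected — encoding the expectation that a genuine shift builds up
#' gradually over at least two of the heavier fractions rather than in a
#' single spike. "Heavy side" means fractions denser than the copy-weighted
#' median density of the 12C arm.
#'
#' Centres of mass are copy-weighted by default (\code{weighting = "copies"}):
#' each fraction's contribution is the taxon's relative abundance there times
#' the fraction's 16S copies, i.e. the taxon's absolute DNA mass. The purely
#' relative alternative (\code{"relative"}) mirrors the difference-profile
#' figures exactly but lets near-empty fractions — whose sequenced reads
#' reflect trace DNA — dominate the centre of mass of high-GC taxa.
#'
#' Taxa below \code{minAbund} in the copy-weighted reconstructed total
#' community, or present in only one arm, are never called; their
#' \code{status} column says why. An optional permutation test shuffles
#' treatment labels across replicate gradients and recomputes
#' \code{com_shift}; with \code{nPerm > 0} a call additionally requires
#' \code{p_value <= alpha}. The default procedure (\code{nPerm = 0}) is the
#' plain threshold screen.
#'
#' @param runs13C,runs12C lists of replicate \code{\link{GradientRun}}.
#' @param comThreshold minimum centre-of-mass shift (g/ml) for a call;
#'   default 0.010, about one fraction width of a 12-fraction gradient.
#' @param heavyK minimum number of heavy-side fractions with positive
#'   difference (default 2).
#' @param minAbund minimum whole-community relative abundance for a taxon to
#'   be evaluated (default 0.001).
#' @param weighting abundance weighting for centres of mass
#'   (\code{"relative"} or \code{"copies"}).
#' @param nPerm permutation count for the optional significance test
#'   (default 0 = off).
#' @param alpha significance level used when \code{nPerm > 0}.
#' @param seed RNG seed for the permutation test.
#' @return A \code{\link{ShiftTable}}.
#' @export
detectLabelled <- function(runs13C, runs12C, comThreshold = 0.010,
                           heavyK = 2L, minAbund = 0.001,
                           weighting = c("copies", "relative"),
                           nPerm = 0L, alpha = 0.05, seed = NULL) {
  weighting <- match.arg(weighting)
  .checkArms(runs13C, runs12C)
  a13 <- .meanAbundance(runs13C)
  a12 <- .meanAbundance(runs12C)
  d13 <- .meanDensities(runs13C)
  d12 <- .meanDensities(runs12C)
  delta <- a13 - a12
  taxa <- rownames(delta)

  total <- rowMeans(vapply(c(runs13C, runs12C),
                           reconstructTotalCommunity,
                           numeric(length(taxa))))
  cp12 <- if (weighting == "copies") Reduce(`+`, lapply(runs12C, copyNumbers)) / length(runs12C) else NULL
  cp13 <- if (weighting == "copies") Reduce(`+`, lapply(runs13C, copyNumbers)) / length(runs13C) else NULL
  com12 <- .comAll(a12, d12, cp12)
  com13 <- .comAll(a13, d13, cp13)
  comShift <- com13 - com12

  ## heavy side: fractions denser than the 12C arm's copy-weighted median
  medCopies <- Reduce(`+`, lapply(runs12C, copyNumbers)) / length(runs12C)
  heavyMedian <- .weightedMedian(d12, medCopies)
  heavy <- which(d12 > heavyMedian)
  detected <- (a13 > 0) | (a12 > 0)
  nHeavyPos <- rowSums((delta[, heavy, drop = FALSE] > 0) &
                       detected[, heavy, drop = FALSE])
  heavyGain <- rowSums(pmax(delta[, heavy, drop = FALSE], 0))

  status <- rep("ok", length(taxa))
  status[rowSums(a13) == 0] <- "absent_13C"
  status[rowSums(a12) == 0] <- "absent_12C"
  status[status == "ok" & total < minAbund] <- "below_min_abund"

  pval <- rep(NA_real_, length(taxa))
  if (nPerm > 0L) {
    if (length(runs13C) < 2L || length(runs12C) < 2L) {
      warning("permutation test needs >= 2 replicates per arm; skipped")
    } else {
      pool <- c(runs13C, runs12C)
      n13 <- length(runs13C)
      exceed <- integer(length(taxa))
      withSeed(seed, for (i in seq_len(nPerm)) {
        idx <- sample(length(pool), n13)
        p13 <- pool[idx]; p12 <- pool[-idx]
        pa13 <- .meanAbundance(p13); pa12 <- .meanAbundance(p12)
        pc <- .comAll(pa13, .meanDensities(p13),
                      if (weighting == "copies") Reduce(`+`, lapply(p13, copyNumbers)) / n13 else NULL) -
              .comAll(pa12, .meanDensities(p12),
                      if (weighting == "copies") Reduce(`+`, lapply(p12, copyNumbers)) / length(p12) else NULL)
        exceed <- exceed + as.integer(!is.na(pc) & !is.na(comShift) & pc >= comShift)
      })
      pval <- (1 + exceed) / (1 + nPerm)
    }
  }

  labelled <- status == "ok" &
    !is.na(comShift) & comShift >= comThreshold &
    nHeavyPos >= heavyK
  if (nPerm > 0L && !all(is.na(pval)))
    labelled <- labelled & !is.na(pval) & pval <= alpha

  res <- DataFrame(row.names = taxa, taxon_id = taxa, total_abundance = total,
                   com_12C = com12, com_13C = com13, com_shift = comShift,
                   heavy_gain = heavyGain, n_heavy_pos = as.integer(nHeavyPos),
                   status = status, p_value = pval, labelled = labelled)
  new("ShiftTable", results = res, deltaProfiles = delta,
      params = list(comThreshold = comThreshold, heavyK = as.integer(heavyK),
                    minAbund = minAbund, weighting = weighting,
                    nPerm = as.integer(nPerm), alpha = alpha,
                    heavyFractions = heavy, heavyMedian = heavyMedian,
                    densities12C = d12, densities13C = d13,
                    n13 = length(runs13C), n12 = length(runs12C)))
}

#' Whole-community buoyant-density shift from qPCR copy profiles
#'
#' Detects isotope incorporation at the level of the entire 16S pool: for
#' each run the copy-weighted mean fraction density
#' \eqn{\sum_f d_f c_f / \sum_f c_f} is computed, and the statistic is the
#' mean over 13C replicates minus the mean over 12C replicates. This is the
#' screen used to decide at which incubation timepoint labelling has become
#' strong enough for community-level analysis.
#'
#' @param runs13C,runs12C lists of replicate \code{\link{GradientRun}} with
#'   per-fraction copy numbers.
#' @param tolerance minimum positive density difference (g/ml) counted as a
#'   detected shift; default 0.002.
#' @return List with \code{shift} (g/ml), \code{detected} (logical),
#'   \code{perRun13C}, \code{perRun12C} (named per-run weighted mean
#'   densities) and \code{tolerance}.
#' @export
totalShiftCheck <- function(runs13C, runs12C, tolerance = 0.002) {
  .checkArms(runs13C, runs12C)
  wmd <- function(r) {
    cp <- copyNumbers(r)
    if (is.null(cp) || all(is.na(cp)) || sum(cp) == 0)
      stop("run ", runId(r), " lacks per-fraction copy numbers")
    sum(densities(r) * cp) / sum(cp)
  }
  w13 <- vapply(runs13C, wmd, numeric(1))
  w12 <- vapply(runs12C, wmd, numeric(1))
  shift <- mean(w13) - mean(w12)
  list(shift = shift, detected = shift > tolerance,
       perRun13C = w13, perRun12C = w12, tolerance = tolerance)
}
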