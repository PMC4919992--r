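#' Microbial biomass delta-13C from fumigation-extraction pairs
#'
#' Chloroform fumigation lyses microbial cells, so the carbon flushed out by a
#' fumigated extraction contains the biomass pool on top of the extractable
#' background measured in the non-fumigated extraction. The biomass carbon is
#' \eqn{C_{mic} = C_{fum} - C_{nfum}} and its isotopic signature follows from
#' the two-pool mixing balance
#' \deqn{\delta^{13}C_{mic} = \frac{\delta^{13}C_{fum} C_{fum} -
#'   \delta^{13}C_{nfum} C_{nfum}}{C_{mic}}.}
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param deltaFum delta-13C of the fumigated extract (permil V-PDB).
#' @param cFum carbon concentration of the fumigated extract (mg/L), > 0.
#' @param deltaNfum delta-13C of the non-fumigated extract (permil V-PDB).
#' @param cNfum carbon concentration of the non-fumigated extract (mg/L),
#'   >= 0 and < \code{cFum}.
#' @return delta-13C of microbial biomass (permil V-PDB).
#' @export
#' @examples
#' deltaCmic(-10, 30, -25, 20)   # ((-300) - (-500)) / 10 = 20
deltaCmic <- function(deltaFum, cFum, deltaNfum, cNfum) {
  n <- max(length(deltaFum), length(cFum), length(deltaNfum), length(cNfum))
  deltaFum <- rep_len(deltaFum, n); cFum <- rep_len(cFum, n)
  deltaNfum <- rep_len(deltaNfum, n); cNfum <- rep_len(cNfum, n)
  if (any(cFum <= 0) || any(cNfum < 0))
    stop("carbon concentrations must satisfy cFum > 0 and cNfum >= 0")
  if (any(cFum <= cNfum))
    stop("cFum must exceed cNfum: biomass carbon Cmic = cFum - cNfum must be positive")
  (deltaFum * cFum - deltaNfum * cNfum) / (cFum - cNfum)
}

#' qPCR amplification efficiency from a standard-curve slope
#'
#' For a standard curve of Ct against log10(template copies) with slope
#' \eqn{s < 0}, the per-cycle amplification efficiency is
#' \eqn{Eff = 10^{-1/s} - 1}; a perfect doubling corresponds to
#' \eqn{s = -1/\log_{10} 2 \approx -3.32} and \eqn{Eff = 1}.
#'
#' @param slope regression slope of Ct vs log10(copies); must be negative.
#' @return Efficiency as a fraction (0.94 means 94\%). Vectorized.
#' @export
#' @examples
#' qpcrEfficiency(-3.4748)
qpcrEfficiency <- function(slope) {
  if (any(slope >= 0)) stop("a qPCR standard curve must have negative slope")
  10^(-1 / slope) - 1
}

#' Convert between delta-13C and 13C atom fraction
#'
#' delta values (permil) are relative deviations of the 13C/12C ratio from a
#' reference standard: \eqn{R = R_{ref}(\delta/1000 + 1)} and the atom
#' fraction is \eqn{R/(1+R)}. The inverse maps an atom fraction back to delta
#' notation. Defaults use the V-PDB ratio (\code{\link{vpdbRatio}}).
#'
#' @param delta delta-13C (permil); must exceed -1000.
#' @param af 13C atom fraction in (0, 1).
#' @param ratio reference 13C/12C isotope ratio.
#' @return \code{deltaToAtomFraction}: atom fraction;
#'   \code{atomFractionToDelta}: delta-13C (permil).
#' @export
#' @examples
#' deltaToAtomFraction(0)                 # natural abundance, ~0.011056
#' atomFractionToDelta(0.99)              # heavily labelled substrate
#' atomFractionToDelta(deltaToAtomFraction(70.5))
deltaToAtomFraction <- function(delta, ratio = vpdbRatio()) {
  if (any(delta <= -1000)) stop("delta <= -1000 permil is unphysical")
  R <- ratio * (delta / 1000 + 1)
  R / (1 + R)
}

#' @rdname deltaToAtomFraction
#' @export
atomFractionToDelta <- function(af, ratio = vpdbRatio()) {
  if (any(af <= 0 | af >= 1)) stop("atom fraction must lie in (0, 1)")
  R <- af / (1 - af)
  (R / ratio - 1) * 1000
}

#' Read isotope measurements from a tab-separated file
#'
#' Expected columns: \code{sample_id}, \code{timepoint_days},
#' \code{treatment}, \code{delta_fum}, \code{c_fum}, \code{delta_nfum},
#' \code{c_nfum}.
#'
#' @param path path to the TSV file.
#' @return A data.frame with the input columns plus \code{delta13c_mic}.
#' @export
readIsotopeMeasurements <- function(path) {
  m <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "timepoint_days", "treatment",
            "delta_fum", "c_fum", "delta_nfum", "c_nfum")
  miss <- setdiff(need, colnames(m))
  if (length(miss))
    stop("isotope table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  m$delta13c_mic <- deltaCmic(m$delta_fum, m$c_fum, m$delta_nfum, m$c_nfum)
  m
}

#' Summarize biomass delta-13C over measurement replicates
#'
#' Computes per-replicate delta-13C of microbial biomass and reports
#' mean and standard deviation per (treatment, timepoint) group — the form
#' in which fumigation-extraction results are conventionally tabulated
#' (n replicates, mean +/- sd).
#'
#' @param measurements data.frame as returned by
#'   \code{\link{readIsotopeMeasurements}} (the \code{delta13c_mic} column is
#'   recomputed if absent).
#' @param by character vector of grouping columns.
#' @return data.frame with columns \code{by}, \code{n}, \code{mean_delta13c_mic},
#'   \code{sd_delta13c_mic}.
#' @export
summarizeDeltaCmic <- function(measurements,
                               by = c("treatment", "timepoint_days")) {
  if (!"delta13c_mic" %in% colnames(measurements))
    measurements$delta13c_mic <- deltaCmic(measurements$delta_fum,
                                           measurements$c_fum,
                                           measurements$delta_nfum,
                                           measurements$c_nfum)
  miss <- setdiff(by, colnames(measurements))
  if (length(miss)) stop("missing grouping column(s): ", paste(miss, collapse = ", "))
  key <- interaction(measurements[by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    rows <- measurements[key == k, , drop = FALSE]
    cbind(rows[1, by, drop = FALSE],
          data.frame(n = nrow(rows),
                     mean_delta13c_mic = mean(rows$delta13c_mic),
                     sd_delta13c_mic = if (nrow(rows) > 1) sd(rows$delta13c_mic) else NA_real_))
  }))
  rownames(out) <- NULL
  out
}
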