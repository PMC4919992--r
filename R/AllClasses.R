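#' GradientRun: one fractionated isopycnic gradient
#'
#' A \code{GradientRun} extends \link[SummarizedExperiment]{SummarizedExperiment}.
#' Rows are taxa (TRFs or OTUs), columns are density-gradient fractions ordered
#' bottom-to-top, so fraction 1 is the heaviest (highest buoyant density).
#' \code{colData} carries \code{fraction} (1..n), \code{density} (g/ml,
#' strictly decreasing with fraction index) and \code{copies} (per-fraction 16S
#' rRNA gene copy numbers from qPCR). \code{metadata} identifies the run:
#' \code{run_id}, \code{soil}, \code{treatment} (\code{"12C"}, \code{"13C"} or
#' \code{"control"}), \code{replicate} and \code{timepoint_days}.
#'
#' The \code{"abundance"} assay holds per-fraction relative abundances (columns
#' sum to 1); a \code{"counts"} assay with raw read counts may be present as
#' well.
#'
#' @aliases GradientRun-class
#' @export
setClass("GradientRun", contains = "SummarizedExperiment")

setValidity("GradientRun", function(object) {
  msg <- character()
  cd <- colData(object)
  need <- c("fraction", "density", "copies")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("colData lacks column(s):", paste(miss, collapse = ", ")))
  d <- cd$density
  if (anyNA(d) || any(d <= 1.60) || any(d >= 1.85))
    msg <- c(msg, "fraction densities must lie in (1.60, 1.85) g/ml")
  if (ncol(object) > 1 && any(diff(d) >= 0))
    msg <- c(msg, "densities must strictly decrease with fraction index (fraction 1 is heaviest)")
  if (any(cd$copies < 0, na.rm = TRUE))
    msg <- c(msg, "copies must be non-negative")
  if ("abundance" %in% assayNames(object)) {
    a <- assay(object, "abundance")
    if (any(a < 0)) msg <- c(msg, "abundances must be non-negative")
    cs <- colSums(a)
    if (any(abs(cs - 1) > 1e-9))
      msg <- c(msg, "abundance columns must each sum to 1 (tolerance 1e-9)")
  }
  tr <- metadata(object)$treatment
  if (!is.null(tr) && !tr %in% c("12C", "13C", "control"))
    msg <- c(msg, "treatment must be one of '12C', '13C', 'control'")
  if (length(msg)) msg else TRUE
})

#' Construct a GradientRun
#'
#' @param abundance taxon x fraction matrix of per-fraction relative abundances
#'   (each column sums to 1). Either this or \code{counts} must be given; when
#'   only \code{counts} is supplied the abundance assay is derived by
#'   column-normalization.
#' @param counts optional taxon x fraction matrix of read counts.
#' @param density numeric vector of fraction buoyant densities (g/ml), strictly
#'   decreasing (fraction 1 = bottom = heaviest).
#' @param copies per-fraction 16S copy numbers (qPCR); non-negative.
#' @param runId,soil,treatment,replicate,timepointDays run identity metadata.
#' @param rowData optional \code{DataFrame}/data.frame of per-taxon annotation
#'   (e.g. \code{gc}, \code{atom13c}, \code{labelled}, \code{trf_length}).
#' @param metadata optional extra metadata list entries.
#'
#' @return A validated \code{GradientRun}.
#' @export
#' @examples
#' a <- matrix(c(.2, .8, .5, .5), 2, dimnames = list(c("t1", "t2"), NULL))
#' GradientRun(abundance = a, density = c(1.74, 1.70), copies = c(10, 20),
#'             runId = "demo", soil = "D", treatment = "12C")
GradientRun <- function(abundance = NULL, counts = NULL, density, copies,
                        runId = "run", soil = NA_character_,
                        treatment = c("12C", "13C", "control"),
                        replicate = 1L, timepointDays = NA_integer_,
                        rowData = NULL, metadata = list()) {
  treatment <- match.arg(treatment)
  if (is.null(abundance) && is.null(counts))
    stop("supply at least one of 'abundance' or 'counts'")
  if (is.null(abundance)) {
    cs <- colSums(counts)
    if (any(cs <= 0)) stop("cannot derive abundances: fraction(s) with zero total counts")
    abundance <- sweep(counts, 2, cs, "/")
  }
  n <- ncol(abundance)
  assays <- list(abundance = abundance)
  if (!is.null(counts)) assays$counts <- counts
  cd <- DataFrame(fraction = seq_len(n), density = as.numeric(density),
                  copies = as.numeric(copies))
  md <- c(list(run_id = runId, soil = soil, treatment = treatment,
               replicate = as.integer(replicate),
               timepoint_days = as.integer(timepointDays)), metadata)
  se <- SummarizedExperiment(assays = assays, colData = cd)
  if (!is.null(rowData)) rowData(se) <- rowData
  colnames(se) <- paste0("F", seq_len(n))
  out <- as(se, "GradientRun")
  metadata(out) <- md
  validObject(out)
  out
}

#' ShiftTable: per-taxon buoyant-density shift results
#'
#' Result container returned by \code{\link{detectLabelled}}. The
#' \code{results} slot is a \code{DataFrame} with one row per taxon
#' (\code{taxon_id}, \code{total_abundance}, \code{com_12C}, \code{com_13C},
#' \code{com_shift}, \code{heavy_gain}, \code{n_heavy_pos}, \code{status},
#' \code{p_value}, \code{labelled}); \code{deltaProfiles} is the taxon x
#' fraction matrix of mean 13C-minus-12C relative-abundance differences;
#' \code{params} records thresholds, the heavy-fraction set and fraction
#' densities used.
#'
#' @aliases ShiftTable-class
#' @export
setClass("ShiftTable",
         representation(results = "DataFrame", deltaProfiles = "matrix",
                        params = "list"))

setValidity("ShiftTable", function(object) {
  r <- object@results
  dp <- object@deltaProfiles
  if (nrow(r) != nrow(dp))
    return("results and deltaProfiles disagree on taxon count")
  if (nrow(dp) && (max(dp) > 1 + 1e-12 || min(dp) < -1 - 1e-12))
    return("delta profiles must lie in [-1, 1]")
  TRUE
})
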