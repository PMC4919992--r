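#' Accessors for GradientRun and ShiftTable
#'
#' Small accessors so user code never touches slots: \code{runId},
#' \code{soil}, \code{treatment}, \code{replicateId}, \code{timepointDays}
#' return run identity; \code{densities}, \code{copyNumbers},
#' \code{fractionIndex} return fraction metadata; \code{abundances} returns
#' the relative-abundance assay. For \code{ShiftTable}: \code{shiftResults},
#' \code{deltaProfiles} and \code{labelledTaxa}.
#'
#' @param x a \code{GradientRun} or \code{ShiftTable}.
#' @return The corresponding metadata vector, matrix or \code{DataFrame}.
#' @name accessors
#' @examples
#' a <- matrix(c(.2, .8, .5, .5), 2, dimnames = list(c("t1", "t2"), NULL))
#' run <- GradientRun(abundance = a, density = c(1.74, 1.70),
#'                    copies = c(10, 20), treatment = "13C")
#' densities(run)
#' treatment(run)
NULL

#' @rdname accessors
#' @export
setGeneric("runId", function(x) standardGeneric("runId"))
#' @rdname accessors
#' @export
setMethod("runId", "GradientRun", function(x) metadata(x)$run_id)

#' @rdname accessors
#' @export
setGeneric("soil", function(x) standardGeneric("soil"))
#' @rdname accessors
#' @export
setMethod("soil", "GradientRun", function(x) metadata(x)$soil)

#' @rdname accessors
#' @export
setGeneric("treatment", function(x) standardGeneric("treatment"))
#' @rdname accessors
#' @export
setMethod("treatment", "GradientRun", function(x) metadata(x)$treatment)

#' @rdname accessors
#' @export
setGeneric("replicateId", function(x) standardGeneric("replicateId"))
#' @rdname accessors
#' @export
setMethod("replicateId", "GradientRun", function(x) metadata(x)$replicate)

#' @rdname accessors
#' @export
setGeneric("timepointDays", function(x) standardGeneric("timepointDays"))
#' @rdname accessors
#' @export
setMethod("timepointDays", "GradientRun", function(x) metadata(x)$timepoint_days)

#' @rdname accessors
#' @export
setGeneric("densities", function(x) standardGeneric("densities"))
#' @rdname accessors
#' @export
setMethod("densities", "GradientRun", function(x) colData(x)$density)

#' @rdname accessors
#' @export
setGeneric("copyNumbers", function(x) standardGeneric("copyNumbers"))
#' @rdname accessors
#' @export
setMethod("copyNumbers", "GradientRun", function(x) colData(x)$copies)

#' @rdname accessors
#' @export
setGeneric("fractionIndex", function(x) standardGeneric("fractionIndex"))
#' @rdname accessors
#' @export
setMethod("fractionIndex", "GradientRun", function(x) colData(x)$fraction)

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setMethod("abundances", "GradientRun", function(x) assay(x, "abundance"))

#' @rdname accessors
#' @export
setGeneric("shiftResults", function(x) standardGeneric("shiftResults"))
#' @rdname accessors
#' @export
setMethod("shiftResults", "ShiftTable", function(x) x@results)

#' @rdname accessors
#' @export
setGeneric("deltaProfiles", function(x) standardGeneric("deltaProfiles"))
#' @rdname accessors
#' @export
setMethod("deltaProfiles", "ShiftTable", function(x) x@deltaProfiles)

#' @rdname accessors
#' @export
setGeneric("labelledTaxa", function(x) standardGeneric("labelledTaxa"))
#' @rdname accessors
#' @export
setMethod("labelledTaxa", "ShiftTable", function(x)
  as.character(x@results$taxon_id[x@results$labelled]))

#' @rdname accessors
#' @export
setGeneric("detectionParams", function(x) standardGeneric("detectionParams"))
#' @rdname accessors
#' @export
setMethod("detectionParams", "ShiftTable", function(x) x@params)

setMethod("show", "GradientRun", function(object) {
  cat(sprintf("GradientRun '%s': %d taxa x %d fractions\n",
              runId(object), nrow(object), ncol(object)))
  cat(sprintf("  soil %s | treatment %s | replicate %s | day %s\n",
              soil(object), treatment(object), replicateId(object),
              timepointDays(object)))
  d <- densities(object)
  cat(sprintf("  density %.4f (fraction 1, heaviest) .. %.4f g/ml\n",
              d[1], d[length(d)]))
  cat(sprintf("  assays: %s\n", paste(assayNames(object), collapse = ", ")))
})

setMethod("show", "ShiftTable", function(object) {
  r <- object@results
  cat(sprintf("ShiftTable: %d taxa over %d fractions; %d called labelled\n",
              nrow(r), ncol(object@deltaProfiles), sum(r$labelled)))
  if (any(r$labelled))
    cat("  labelled:", paste(head(labelledTaxa(object), 10), collapse = ", "),
        if (sum(r$labelled) > 10) "..." else "", "\n")
  p <- object@params
  cat(sprintf("  com_threshold %.4g g/ml | heavy_k %d | min_abund %.4g\n",
              p$comThreshold, p$heavyK, p$minAbund))
})
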