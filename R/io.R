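#' Normalize fraction profiles to relative abundance
#'
#' TRFLP convention: the relative abundance of each peak is its signal
#' divided by the total signal height of the profile. Applied per column
#' (one profile = one gradient fraction).
#'
#' @param mat non-negative taxon x fraction matrix of raw signal (peak
#'   heights or read counts).
#' @return Matrix whose columns each sum to 1.
#' @export
#' @examples
#' normalizeProfile(matrix(c(2, 3, 5), 3, 1))
normalizeProfile <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("raw signals must be non-negative")
  cs <- colSums(mat)
  if (any(cs == 0)) {
    bad <- which(cs == 0)
    stop("empty fraction profile(s): column ",
         paste(colnames(mat)[bad] %||% bad, collapse = ", "))
  }
  sweep(mat, 2, cs, "/")
}

#' Filter TRF profiles by fragment length and relative contribution
#'
#' Applies the two standard TRFLP exclusion rules: terminal fragments shorter
#' than \code{minLen} bases are removed, and peaks contributing less than
#' \code{minAbund} of a profile's total height are removed from that profile.
#' The contribution threshold is evaluated per profile (column); entries
#' below it are zeroed and rows that become zero everywhere are dropped.
#' Surviving columns are renormalized to sum to 1.
#'
#' @param mat TRF x fraction matrix (signal or relative abundance).
#' @param lengths integer TRF lengths (bp), one per row; defaults to the
#'   \code{"trf_length"} attribute or to rownames parsed as integers.
#' @param minLen minimum fragment length retained (default 50 bp).
#' @param minAbund minimum per-profile relative contribution (default 0.01).
#' @param preFilter if \code{TRUE} (default) the contribution of a peak is
#'   measured against the raw profile total before any exclusion; if
#'   \code{FALSE}, against the total remaining after the length filter.
#' @return Filtered matrix, columns renormalized to 1, with the surviving
#'   lengths in attribute \code{"trf_length"}.
#' @export
filterTRFs <- function(mat, lengths = NULL, minLen = 50, minAbund = 0.01,
                       preFilter = TRUE) {
  mat <- as.matrix(mat)
  if (is.null(lengths))
    lengths <- attr(mat, "trf_length") %||% suppressWarnings(as.integer(rownames(mat)))
  if (is.null(lengths) || anyNA(lengths) || length(lengths) != nrow(mat))
    stop("every TRF row needs an integer length (bp)")
  keepLen <- lengths >= minLen
  base <- if (preFilter) mat else mat[keepLen, , drop = FALSE]
  totals <- colSums(base)
  if (any(totals == 0)) stop("empty fraction profile(s) before filtering")
  out <- mat[keepLen, , drop = FALSE]
  rel <- sweep(out, 2, totals, "/")
  out[rel < minAbund] <- 0
  keepRow <- rowSums(out) > 0
  out <- out[keepRow, , drop = FALSE]
  if (nrow(out) == 0L) stop("filtering removed every TRF")
  cs <- colSums(out)
  if (any(cs == 0)) stop("filtering emptied fraction profile(s): column ",
                         paste(which(cs == 0), collapse = ", "))
  out <- sweep(out, 2, cs, "/")
  attr(out, "trf_length") <- lengths[keepLen][keepRow]
  out
}

#' Rarefy count profiles to a common depth
#'
#' Subsamples each sample column without replacement to exactly \code{depth}
#' reads (the conventional guard against unequal sequencing effort before
#' comparing diversity). Wraps \code{\link[vegan]{rrarefy}}; the draw is
#' reproducible when \code{seed} is given and leaves the caller's RNG stream
#' untouched.
#'
#' @param counts non-negative integer taxon x sample matrix.
#' @param depth target reads per sample (default 3240).
#' @param seed integer seed, or \code{NULL} to use the current RNG stream.
#' @return Integer matrix of the same shape with every column summing to
#'   \code{depth}.
#' @export
rarefy <- function(counts, depth = 3240, seed = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  tot <- colSums(counts)
  shallow <- tot < depth
  if (any(shallow))
    stop("sample(s) shallower than depth ", depth, ": ",
         paste(colnames(counts)[shallow] %||% which(shallow), collapse = ", "))
  withSeed(seed, {
    ## vegan nags when the smallest count exceeds 1; irrelevant here
    withCallingHandlers(
      out <- t(vegan::rrarefy(t(counts), sample = depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  })
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(counts)
  out
}

#' Write a set of gradient runs as tab-separated tables
#'
#' Writes four files to \code{dir}: \code{runs.tsv} (run identity),
#' \code{fractions.tsv} (\code{run_id}, \code{fraction}, \code{density_g_ml},
#' \code{copies_16s}), \code{abundance.tsv} (taxon x \code{run_id:fraction}
#' relative-abundance matrix) and, when the runs carry simulator annotation,
#' \code{taxa.tsv} (\code{taxon_id}, \code{gc}, \code{atom13c},
#' \code{labelled}, \code{trf_length}). Numbers are written at full precision
#' so \code{\link{readFractionTables}} restores them exactly.
#'
#' @param runs list of \code{\link{GradientRun}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeFractionTables <- function(runs, dir) {
  if (!length(runs)) stop("no runs to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  runsTab <- data.frame(
    run_id = vapply(runs, runId, character(1)),
    soil = vapply(runs, soil, character(1)),
    treatment = vapply(runs, treatment, character(1)),
    replicate = vapply(runs, replicateId, integer(1)),
    timepoint_days = vapply(runs, timepointDays, integer(1)))
  fracTab <- do.call(rbind, lapply(runs, function(r)
    data.frame(run_id = runId(r), fraction = fractionIndex(r),
               density_g_ml = .fmtNum(densities(r)),
               copies_16s = .fmtNum(copyNumbers(r)))))
  taxa <- rownames(runs[[1]])
  ab <- do.call(cbind, lapply(runs, function(r) {
    if (!identical(rownames(r), taxa))
      stop("runs disagree on taxon rows; cannot write one abundance table")
    m <- abundances(r)
    colnames(m) <- paste0(runId(r), ":", fractionIndex(r))
    m
  }))
  abTab <- data.frame(taxon_id = taxa,
                      apply(ab, 2, .fmtNum), check.names = FALSE)
  paths <- file.path(dir, c("runs.tsv", "fractions.tsv", "abundance.tsv"))
  write.table(runsTab, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fracTab, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(abTab, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  rd <- rowData(runs[[1]])
  if (all(c("gc", "atom13c", "labelled") %in% colnames(rd))) {
    taxaTab <- data.frame(taxon_id = taxa, gc = .fmtNum(rd$gc),
                          atom13c = .fmtNum(rd$atom13c),
                          labelled = rd$labelled,
                          trf_length = rd$trf_length)
    p <- file.path(dir, "taxa.tsv")
    write.table(taxaTab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  cfg <- metadata(runs[[1]])$config
  if (!is.null(cfg)) {
    p <- file.path(dir, "config.yaml")
    yaml::write_yaml(cfg, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

.requireCols <- function(df, need, file) {
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(file, " lacks column(s): ", paste(miss, collapse = ", "))
}

#' Read gradient runs from tab-separated tables
#'
#' Reads the schema written by \code{\link{writeFractionTables}} and rebuilds
#' the \code{\link{GradientRun}} list, enforcing the fraction invariants:
#' densities must strictly decrease with fraction index within every run,
#' (run, fraction) pairs must be unique, and all files must agree on run ids.
#' Violations raise errors naming the offending run or line.
#'
#' @param dir directory containing \code{runs.tsv}, \code{fractions.tsv} and
#'   \code{abundance.tsv} (optionally \code{taxa.tsv}).
#' @return Named list of \code{\link{GradientRun}}.
#' @export
readFractionTables <- function(dir) {
  pr <- file.path(dir, "runs.tsv"); pf <- file.path(dir, "fractions.tsv")
  pa <- file.path(dir, "abundance.tsv")
  for (p in c(pr, pf, pa)) if (!file.exists(p)) stop("missing file: ", p)
  runsTab <- read.delim(pr, stringsAsFactors = FALSE)
  fracTab <- read.delim(pf, stringsAsFactors = FALSE)
  abTab <- read.delim(pa, check.names = FALSE, stringsAsFactors = FALSE)
  .requireCols(runsTab, c("run_id", "soil", "treatment", "replicate",
                          "timepoint_days"), pr)
  .requireCols(fracTab, c("run_id", "fraction", "density_g_ml", "copies_16s"), pf)
  .requireCols(abTab, "taxon_id", pa)
  if (anyDuplicated(runsTab$run_id))
    stop(pr, ": duplicate run_id ",
         paste(unique(runsTab$run_id[duplicated(runsTab$run_id)]), collapse = ", "))
  key <- paste(fracTab$run_id, fracTab$fraction)
  if (anyDuplicated(key))
    stop(pf, ": duplicate (run_id, fraction) at line(s) ",
         paste(which(duplicated(key)) + 1L, collapse = ", "))
  bad <- which(is.na(fracTab$density_g_ml) | is.na(fracTab$fraction))
  if (length(bad))
    stop(pf, ": malformed row(s) at line(s) ", paste(bad + 1L, collapse = ", "))
  taxa <- abTab$taxon_id
  rdata <- NULL
  pt <- file.path(dir, "taxa.tsv")
  if (file.exists(pt)) {
    taxaTab <- read.delim(pt, stringsAsFactors = FALSE)
    .requireCols(taxaTab, c("taxon_id", "gc", "atom13c", "labelled"), pt)
    taxaTab <- taxaTab[match(taxa, taxaTab$taxon_id), ]
    rdata <- DataFrame(gc = taxaTab$gc, atom13c = taxaTab$atom13c,
                       labelled = taxaTab$labelled,
                       trf_length = taxaTab$trf_length %||% NA_integer_,
                       row.names = taxa)
  }
  runs <- lapply(seq_len(nrow(runsTab)), function(i) {
    r <- runsTab[i, ]
    fr <- fracTab[fracTab$run_id == r$run_id, , drop = FALSE]
    if (!nrow(fr)) stop("run ", r$run_id, " has no rows in ", pf)
    fr <- fr[order(fr$fraction), , drop = FALSE]
    if (any(diff(fr$density_g_ml) >= 0))
      stop("run ", r$run_id,
           ": density must strictly decrease with fraction index")
    cols <- paste0(r$run_id, ":", fr$fraction)
    miss <- setdiff(cols, colnames(abTab))
    if (length(miss))
      stop(pa, " lacks column(s): ", paste(miss, collapse = ", "))
    a <- as.matrix(abTab[, cols, drop = FALSE])
    rownames(a) <- taxa
    GradientRun(abundance = a, density = fr$density_g_ml,
                copies = fr$copies_16s, runId = r$run_id, soil = r$soil,
                treatment = r$treatment, replicate = r$replicate,
                timepointDays = r$timepoint_days, rowData = rdata)
  })
  names(runs) <- runsTab$run_id
  runs
}
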