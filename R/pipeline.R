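#' Path to the packaged demo pipeline configuration
#'
#' A three-soil simulated SIP experiment: soils D and F share one labelled
#' guild of five taxa, soil W carries a disjoint guild of five, mirroring the
#' common design where two related soils recruit the same substrate
#' assimilators while a third recruits a different set. Two incubation
#' timepoints are simulated: an early one with weak labelling (atom fraction
#' 0.05) and a late one with strong labelling (0.90).
#'
#' @return Path to \code{demo_config.yaml} inside the installed package.
#' @export
demoConfig <- function() {
  system.file("extdata", "demo_config.yaml", package = "SIPshift",
              mustWork = TRUE)
}

.validatePipelineConfig <- function(config) {
  if (!xor(is.null(config$simulate), is.null(config$inputs)))
    stop("config must contain exactly one of 'simulate' or 'inputs'")
  if (is.null(config$master_seed) && !is.null(config$simulate))
    stop("simulation configs must set 'master_seed'")
  invisible(config)
}

.logLine <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

.writeTsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], .fmtNum)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full SIP analysis pipeline
#'
#' Orchestrates one reproducible run: either simulates a multi-soil
#' experiment (config section \code{simulate}) or loads gradient runs from
#' TSV tables (\code{inputs}), then per soil and timepoint reconstructs the
#' total community, screens for buoyant-density shifts
#' (\code{\link{detectLabelled}}), checks the whole-community qPCR shift
#' (\code{\link{totalShiftCheck}}), and, when isotope measurements are
#' supplied, summarizes biomass delta-13C. All seeds derive from
#' \code{master_seed}; the same config and seed produce a byte-identical
#' report bundle.
#'
#' Outputs written to \code{outDir}: per soil/timepoint
#' \code{total_community_*.tsv}, \code{shifts_*.tsv},
#' \code{delta_profiles_*.tsv}; \code{total_shift.tsv};
#' \code{labelled_taxa.tsv}; optional \code{isotope_summary.tsv};
#' \code{manifest.json} (config, seeds, package version) and \code{run.log}.
#'
#' @param config path to a YAML configuration or an equivalent list (see
#'   \code{\link{demoConfig}} for the schema).
#' @param outDir output directory; overrides \code{config$output_dir}.
#' @param plots also render difference-profile figures (PNG); off by default
#'   because image encoding is not byte-stable across platforms.
#' @return Invisibly, a list with elements \code{runs} (per timepoint),
#'   \code{shifts} (per soil/timepoint \code{\link{ShiftTable}}),
#'   \code{labelled} (per soil character vectors at the detection timepoint),
#'   \code{totalShift}, \code{totals}, \code{isotope}, \code{files}.
#' @export
runPipeline <- function(config, outDir = NULL, plots = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validatePipelineConfig(config)
  outDir <- outDir %||% config$output_dir
  if (is.null(outDir)) stop("no output directory: set outDir or config$output_dir")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logCon <- file(file.path(outDir, "run.log"), open = "wt")
  on.exit(close(logCon), add = TRUE)
  files <- character()

  ## ---- obtain runs, grouped by timepoint ----
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    cfg <- gradientConfig(
      nFractions = sim$n_fractions %||% 12L,
      densityMin = sim$density_min %||% 1.665,
      densityMax = sim$density_max %||% 1.775,
      bandSigma = sim$band_sigma %||% 0.006,
      seqDepth = sim$seq_depth %||% 3240,
      qpcrCv = sim$qpcr_cv %||% 0.1,
      overdispersion = sim$overdispersion %||% 200,
      copyScale = as.numeric(sim$copy_scale %||% 1e8))
    seeds <- withSeed(config$master_seed,
                      sample.int(.Machine$integer.max,
                                 1L + length(sim$timepoints)))
    taxa <- makeCommunity(nTaxa = sim$n_taxa %||% 50L,
                          guildSlots = sim$guild_slots %||% 10L,
                          seed = seeds[1])
    .logLine(logCon, "simulated community: ", nrow(taxa), " taxa, seed ", seeds[1])
    runsByTp <- lapply(seq_along(sim$timepoints), function(i) {
      tp <- sim$timepoints[[i]]
      simulateExperiment(taxa, cfg, soils = unlist(sim$soils),
                         replicates = sim$replicates %||% 3L,
                         labelledBySoil = lapply(sim$labelled, unlist),
                         labelAtomFraction = tp$label_atom_fraction,
                         timepointDays = tp$days, masterSeed = seeds[1L + i])
    })
    names(runsByTp) <- vapply(sim$timepoints, function(tp)
      as.character(tp$days), character(1))
    groundTruth <- lapply(sim$labelled, unlist)
  } else {
    allRuns <- readFractionTables(config$inputs$dir)
    tps <- vapply(allRuns, timepointDays, integer(1))
    runsByTp <- split(allRuns, tps)
    groundTruth <- NULL
    .logLine(logCon, "loaded ", length(allRuns), " runs from ",
             config$inputs$dir)
  }
  soils <- unique(unlist(lapply(runsByTp, function(rs)
    vapply(rs, soil, character(1)))))

  ## ---- whole-community qPCR shift per soil and timepoint ----
  shiftRows <- list()
  tol <- config$total_shift_tolerance %||% 0.002
  for (tp in names(runsByTp)) {
    rs <- runsByTp[[tp]]
    for (s in soils) {
      r13 <- Filter(function(r) soil(r) == s && treatment(r) == "13C", rs)
      r12 <- Filter(function(r) soil(r) == s && treatment(r) == "12C", rs)
      if (!length(r13) || !length(r12)) next
      ts <- totalShiftCheck(r13, r12, tolerance = tol)
      shiftRows[[paste(s, tp)]] <- data.frame(
        soil = s, timepoint_days = as.integer(tp), shift_g_ml = ts$shift,
        detected = ts$detected, tolerance = tol)
      .logLine(logCon, sprintf("total 16S shift %s day %s: %+.5f g/ml (%s)",
                               s, tp, ts$shift,
                               if (ts$detected) "detected" else "not detected"))
    }
  }
  totalShift <- do.call(rbind, shiftRows)
  if (!is.null(totalShift)) {
    rownames(totalShift) <- NULL
    files <- c(files, .writeTsv(totalShift, file.path(outDir, "total_shift.tsv")))
  }

  ## ---- detection at the requested timepoint(s) ----
  det <- config$detect %||% list()
  detTp <- as.character(det$timepoint %||% names(runsByTp)[length(runsByTp)])
  shifts <- list(); totals <- list(); labelled <- list()
  rs <- runsByTp[[detTp]]
  for (s in soils) {
    r13 <- Filter(function(r) soil(r) == s && treatment(r) == "13C", rs)
    r12 <- Filter(function(r) soil(r) == s && treatment(r) == "12C", rs)
    if (!length(r13) || !length(r12)) {
      .logLine(logCon, "soil ", s, ": missing a treatment arm, no detection performed")
      next
    }
    st <- detectLabelled(r13, r12,
                         comThreshold = det$com_threshold %||% 0.010,
                         heavyK = det$heavy_k %||% 2L,
                         minAbund = det$min_abund %||% 0.001,
                         nPerm = det$permutations %||% 0L,
                         alpha = det$alpha %||% 0.05,
                         seed = det$seed %||% NULL)
    shifts[[s]] <- st
    labelled[[s]] <- labelledTaxa(st)
    tot <- rowMeans(vapply(c(r13, r12), reconstructTotalCommunity,
                           numeric(nrow(r13[[1]]))))
    totals[[s]] <- tot
    .logLine(logCon, "soil ", s, " day ", detTp, ": ",
             length(labelled[[s]]), " taxa called labelled (",
             paste(labelled[[s]], collapse = ", "), ")")
    files <- c(files,
      .writeTsv(data.frame(taxon_id = names(tot), relative_abundance = tot),
                file.path(outDir, sprintf("total_community_%s_d%s.tsv", s, detTp))),
      .writeTsv(as.data.frame(shiftResults(st)),
                file.path(outDir, sprintf("shifts_%s_d%s.tsv", s, detTp))),
      .writeTsv(data.frame(taxon_id = rownames(deltaProfiles(st)),
                           as.data.frame(deltaProfiles(st))),
                file.path(outDir, sprintf("delta_profiles_%s_d%s.tsv", s, detTp))))
    if (plots) {
      pf <- file.path(outDir, sprintf("delta_profiles_%s_d%s.png", s, detTp))
      renderDeltaPlot(st, file = pf, title = paste("soil", s))
      files <- c(files, pf)
    }
  }
  if (length(labelled)) {
    lab <- do.call(rbind, lapply(names(labelled), function(s)
      if (length(labelled[[s]]))
        data.frame(soil = s, taxon_id = labelled[[s]]) else NULL))
    if (is.null(lab)) lab <- data.frame(soil = character(), taxon_id = character())
    files <- c(files, .writeTsv(lab, file.path(outDir, "labelled_taxa.tsv")))
  } else {
    .logLine(logCon, "no paired 13C/12C arms anywhere: no detection performed")
  }

  ## ---- isotope summaries ----
  isotope <- NULL
  if (!is.null(config$isotope)) {
    m <- readIsotopeMeasurements(config$isotope$path)
    isotope <- summarizeDeltaCmic(m, by = config$isotope$by %||%
                                    c("treatment", "timepoint_days"))
    files <- c(files, .writeTsv(isotope, file.path(outDir, "isotope_summary.tsv")))
  }

  manifest <- list(package = "SIPshift",
                   version = as.character(packageVersion("SIPshift")),
                   master_seed = config$master_seed, config = config)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  files <- c(files, file.path(outDir, "manifest.json"))
  invisible(list(runs = runsByTp, shifts = shifts, labelled = labelled,
                 groundTruth = groundTruth, totalShift = totalShift,
                 totals = totals, isotope = isotope, files = files))
}
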