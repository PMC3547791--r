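## End-to-end orchestration: simulate bound/free cohorts, run every
## analysis stage, write a deterministic report bundle with a manifest.

.pipelineDefaults <- function() {
  list(
    cohorts = list(
      free = list(runs = 12L, bound = FALSE, seedBase = 1000L),
      bound = list(runs = 12L, bound = TRUE, seedBase = 2000L)),
    sim = list(),                    # SimParams overrides
    peakThreshold = 100,             # pN; "auto" selects from the force
    minProminence = 30,              #     distribution's deviation maximum
    smooth = 5L,
    persistence = 3.8,
    contourBinWidth = 5,
    rmsdThreshold = 10,
    kdeBandwidthNs = 1.6,
    workBandwidthKbt = 50,
    trajFrameInterval = 20,
    trajJitter = 0.3,
    nContactRuns = 3L,               # bound runs used for binding analysis
    fullExtensionFrac = 0.8)         # measure work at this fraction of the
}                                    # run, once stretching is complete

#' Run the full simulate-analyze-report pipeline
#'
#' Simulates seeded cohorts of ligand-bound and free pulling runs at the
#' configured conditions, then runs every analysis stage: transferred work
#' and per-repeat components with bound-versus-free Welch comparisons,
#' force-peak detection and WLC contour-length fits with periodicity
#' analysis, RMSD unfolding midpoints and order statistics from
#' synthesized coordinate trajectories with an exact Fisher test on the
#' order contingency, kernel density summaries, and (for a subset of bound
#' runs) ligand-binding lifetimes.  All tables are written
#' deterministically and a manifest records the configuration, seeds and
#' output checksums, so re-running with the same manifest reproduces the
#' bundle byte for byte.
#'
#' @param config A named list of settings, or a path to a JSON file with
#'   the same structure.  Any subset may be given; the rest takes the
#'   defaults.  Must contain a `cohorts` entry (named list with `runs`,
#'   `bound`, `seedBase` per cohort) — supplied by default.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a list of in-memory summaries: per-run works, peak
#'   sets, WLC fits, periodicity, unfolding events, test results, and the
#'   manifest.
#' @export
runPipeline <- function(config = list(), outDir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config error: file not found: ", config, call. = FALSE)
    config <- jsonlite::fromJSON(config, simplifyVector = FALSE)
  }
  cfg <- utils::modifyList(.pipelineDefaults(), config)
  ## an explicit cohorts entry replaces (not merges into) the default
  if (!is.null(config$cohorts)) cfg$cohorts <- config$cohorts
  if (is.null(cfg$cohorts) || !length(cfg$cohorts))
    stop("config error: no cohorts defined", call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  ## ---- simulate ----------------------------------------------------------
  runs <- list()
  for (cohortName in names(cfg$cohorts)) {
    co <- cfg$cohorts[[cohortName]]
    simArgs <- c(list(bound = isTRUE(co$bound)), cfg$sim)
    params <- do.call(SimParams, simArgs)
    for (i in seq_len(co$runs)) {
      seed <- co$seedBase + i
      id <- sprintf("%s%02d", cohortName, i)
      sim <- simulatePull(params, seed = seed, runId = id)
      runs[[id]] <- list(cohort = cohortName, seed = seed, sim = sim,
                         params = params)
    }
  }
  cohortOf <- vapply(runs, `[[`, character(1), "cohort")

  ## ---- work --------------------------------------------------------------
  workRows <- lapply(names(runs), function(id) {
    sim <- runs[[id]]$sim
    wp <- repeatWorkComponents(sim$trace)
    tcut <- cfg$fullExtensionFrac * max(frameTimes(sim$trace))
    fIdx <- max(which(frameTimes(sim$trace) <= tcut))
    tot <- workTotal(wp, "kbt")[fIdx]
    comps <- workComponents(wp, "kbt")[fIdx, ]
    c(list(run = id, cohort = runs[[id]]$cohort, W_total_kbt = tot),
      stats::setNames(as.list(comps),
                      paste0("W_r", seq_along(comps), "_kbt")))
  })
  workTab <- do.call(rbind, lapply(workRows, function(r)
    as.data.frame(r, check.names = FALSE)))
  writeResultsTable(workTab, file.path(outDir, "work_summary.tsv"))

  nRep <- length(grep("^W_r", names(workTab)))
  comparisons <- list()
  wf <- workTab$W_total_kbt[workTab$cohort == "free"]
  wb <- workTab$W_total_kbt[workTab$cohort == "bound"]
  if (length(wf) >= 3L && length(wb) >= 3L) {
    comparisons$total <- compareWork(wb, wf)
    for (r in seq_len(nRep)) {
      col <- paste0("W_r", r, "_kbt")
      comparisons[[paste0("r", r)]] <-
        compareWork(workTab[[col]][workTab$cohort == "bound"],
                    workTab[[col]][workTab$cohort == "free"])
    }
    jsonlite::write_json(comparisons, file.path(outDir,
                                                "work_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  ## ---- peaks and WLC -----------------------------------------------------
  peakSets <- list(); fitList <- list()
  for (id in names(runs)) {
    trace <- runs[[id]]$sim$trace
    thr <- cfg$peakThreshold
    if (identical(thr, "auto")) {
      fit <- fitForceDistribution(forceMagnitudes(trace))
      thr <- selectForceThreshold(fit)$threshold
    }
    ps <- detectPeaks(trace, threshold = thr,
                      minProminence = cfg$minProminence,
                      smooth = cfg$smooth)
    peakSets[[id]] <- ps
    if (nrow(peaks(ps)) >= 2L)
      fitList[[id]] <- fitPeakContours(trace, ps, p = cfg$persistence)
  }
  allPeaks <- do.call(rbind, lapply(peakSets, peaks))
  writeResultsTable(allPeaks, file.path(outDir, "peaks.tsv"))
  allFits <- do.call(rbind, fitList)
  writeResultsTable(allFits, file.path(outDir, "wlc_fits.tsv"))

  periodicity <- list()
  for (cohortName in unique(cohortOf)) {
    ids <- names(runs)[cohortOf == cohortName]
    fits <- do.call(rbind, fitList[names(fitList) %in% ids])
    if (!is.null(fits) && nrow(fits) >= 2L) {
      ch <- contourLengthDifferences(fits, binWidth = cfg$contourBinWidth)
      if (length(ch@diffs) >= 10L) {
        ch <- estimatePeriodicity(ch)
        periodicity[[cohortName]] <- list(period = ch@period,
                                          score = ch@score)
      }
      writeResultsTable(data.frame(mid_A = ch@mids, count = ch@counts),
                        file.path(outDir,
                                  sprintf("contour_hist_%s.tsv",
                                          cohortName)))
    }
  }

  ## ---- unfolding order from synthesized trajectories ---------------------
  template <- makeNativeTemplate(
    nRepeats = runs[[1L]]$params@nRepeats,
    ligandRepeats = integer(0))
  eventTabs <- list()
  for (id in names(runs)) {
    sim <- runs[[id]]$sim
    traj <- synthesizeTrajectory(sim$truth, template,
                                 frameInterval = cfg$trajFrameInterval,
                                 jitter = cfg$trajJitter,
                                 seed = runs[[id]]$seed + 500000L)
    rs <- repeatRMSD(traj, template$repeatMap, template$coords)
    eventTabs[[id]] <- unfoldingMidpoints(rs, cfg$rmsdThreshold, run = id)
  }
  eventsAll <- do.call(rbind, eventTabs)
  writeResultsTable(eventsAll, file.path(outDir, "unfolding_events.tsv"))

  fisher <- NULL
  orderTabs <- list()
  for (cohortName in unique(cohortOf)) {
    ev <- eventsAll[eventsAll$run %in% names(runs)[cohortOf == cohortName], ]
    orderTabs[[cohortName]] <- orderContingency(ev)
    writeOrderTable(orderTabs[[cohortName]],
                    file.path(outDir, sprintf("order_table_%s.tsv",
                                              cohortName)))
  }
  if (all(c("free", "bound") %in% names(orderTabs))) {
    evF <- eventsAll[eventsAll$run %in% names(runs)[cohortOf == "free"], ]
    evB <- eventsAll[eventsAll$run %in% names(runs)[cohortOf == "bound"], ]
    ct <- conditionContingency(evB, evF, repeatId = 1L)
    fisher <- fisherExactRxC(ct, seed = 424242L)
    jsonlite::write_json(list(repeat1Table = ct, p = fisher$p,
                              method = fisher$method),
                         file.path(outDir, "fisher.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  ## successive unfolding-time densities (per event index)
  evOk <- eventsAll[!is.na(eventsAll$rank), ]
  kdeRows <- list()
  for (k in sort(unique(evOk$rank))) {
    tv <- evOk$midpoint[evOk$rank == k] / 1000       # ns
    if (length(tv) >= 2L) {
      kd <- kde1d(tv, cfg$kdeBandwidthNs)
      kdeRows[[k]] <- data.frame(event = k, t_ns = kd$x,
                                 density = kd$density)
    }
  }
  if (length(kdeRows))
    writeResultsTable(do.call(rbind, kdeRows),
                      file.path(outDir, "unfolding_time_kde.tsv"))

  ## ---- binding lifetimes on a subset of bound runs -----------------------
  binding <- NULL
  boundIds <- names(runs)[cohortOf == "bound"]
  if (length(boundIds) && cfg$nContactRuns > 0L) {
    use <- utils::head(boundIds, cfg$nContactRuns)
    ligTemplate <- makeNativeTemplate(
      nRepeats = runs[[1L]]$params@nRepeats,
      ligandRepeats = seq_len(min(6L, runs[[1L]]$params@nRepeats - 1L)))
    trajs <- lapply(use, function(id)
      synthesizeTrajectory(runs[[id]]$sim$truth, ligTemplate,
                           frameInterval = cfg$trajFrameInterval,
                           jitter = cfg$trajJitter,
                           seed = runs[[id]]$seed + 600000L))
    binding <- bindingAnalysis(trajs)
    writeResultsTable(binding, file.path(outDir, "binding.tsv"))
  }

  ## ---- manifest ----------------------------------------------------------
  outFiles <- sort(list.files(outDir, full.names = FALSE))
  outFiles <- setdiff(outFiles, "manifest.json")
  sums <- as.list(tools::md5sum(file.path(outDir, outFiles)))
  names(sums) <- outFiles
  manifest <- list(config = cfg,
                   seeds = lapply(runs, `[[`, "seed"),
                   checksums = sums)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(work = workTab, comparisons = comparisons,
                 peaks = peakSets, fits = allFits,
                 periodicity = periodicity, events = eventsAll,
                 orderTables = orderTabs, fisher = fisher,
                 binding = binding, manifest = manifest))
}
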