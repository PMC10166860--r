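#' @include AllClasses.R traceprep.R behavior.R ringdetect.R rpcspace.R phasedyn.R headnav.R
NULL

#' Default pipeline configuration
#'
#' Nested list of every tunable stage parameter, addressable by dotted keys
#' in [runPipeline()]. Unknown keys are rejected before any computation.
#'
#' @return named nested list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1,
    preprocess = list(baseline_window_s = 900, median_kernel_frames = 3),
    behavior = list(vigor_threshold = 0.1, min_gap_ms = 100,
                    trimodal_bins = 61, fallback_threshold = DEFAULT_SWIM_THRESHOLD),
    ring = list(threshold = -0.6, scan = FALSE, template_min_corr = 0.5),
    phase = list(clip_low = 0.02, clip_high = 0.98, profile_bins = 100,
                 tuning_bins = 36),
    coupling = list(window_s = 300, window_step_s = 30,
                    delta_window_s = c(15, 20)),
    anatomy = list(n_shuffles = 200)
  )
}

.mergeConfig <- function(base, override, path = character()) {
  for (nm in names(override)) {
    key <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(base)) stop("unknown config key: ", key)
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]], c(path, nm))
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Validate and merge a pipeline configuration
#'
#' @param config partial nested list of overrides.
#' @return full configuration with defaults filled in.
#' @export
pipelineConfig <- function(config = list()) {
  .mergeConfig(defaultPipelineConfig(), config)
}

#' Write a session bundle to a directory of CSV/JSON files
#'
#' Layout: traces.csv (ROIs x frames, first column roi_id), rois.csv,
#' tail.csv, gaze.csv (optional), swims.csv (optional), conditions.csv
#' (optional), truth_phase.csv / truth_heading.csv (synthetic only) and
#' metadata.json (rates, seed, provenance). All angles are radians, all
#' times seconds.
#'
#' @param session a [SyntheticSession-class], or a list with elements
#'   `traces` ([RoiTraces-class]), `tail` ([TailTrace-class]) and optionally
#'   `gaze`, `swims`, `conditions`, `truth`, `metadata`.
#' @param dir output directory (created).
#' @return invisibly, `dir`.
#' @export
writeSessionBundle <- function(session, dir) {
  if (methods::is(session, "SyntheticSession")) {
    session <- list(traces = session@traces, tail = session@tail,
                    gaze = session@gaze,
                    swims = session@truth@swimEvents,
                    truth = session@truth,
                    metadata = list(seed = session@params@seed,
                                    synthetic = TRUE))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- session$traces
  utils::write.csv(cbind(data.frame(roi_id = rownames(tr)),
                         as.data.frame(traceValues(tr))),
                   file.path(dir, "traces.csv"), row.names = FALSE)
  utils::write.csv(cbind(data.frame(roi_id = rownames(tr)), roiInfo(tr)),
                   file.path(dir, "rois.csv"), row.names = FALSE)
  utils::write.csv(data.frame(angle = session$tail@angle),
                   file.path(dir, "tail.csv"), row.names = FALSE)
  meta <- c(session$metadata,
            list(imaging_rate_hz = samplingRate(tr),
                 behavior_rate_hz = session$tail@rate,
                 preprocessed = isPreprocessed(tr),
                 package = "ringcompass",
                 version = as.character(utils::packageVersion("ringcompass"))))
  if (!is.null(session$gaze)) {
    utils::write.csv(data.frame(angle = session$gaze@angle),
                     file.path(dir, "gaze.csv"), row.names = FALSE)
    meta$gaze_rate_hz <- session$gaze@rate
    meta$saccade_times_s <- session$gaze@saccadeTimes
  }
  if (!is.null(session$swims) && nrow(session$swims) > 0) {
    utils::write.csv(session$swims, file.path(dir, "swims.csv"),
                     row.names = FALSE)
  }
  if (!is.null(session$conditions)) {
    utils::write.csv(session$conditions, file.path(dir, "conditions.csv"),
                     row.names = FALSE)
  }
  if (!is.null(session$truth)) {
    utils::write.csv(data.frame(true_phase = session$truth@truePhase),
                     file.path(dir, "truth_phase.csv"), row.names = FALSE)
    utils::write.csv(data.frame(true_heading = session$truth@trueHeading),
                     file.path(dir, "truth_heading.csv"), row.names = FALSE)
  }
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a session bundle from a directory
#'
#' @param dir bundle directory written by [writeSessionBundle()].
#' @param centerPoint optional length-3 numeric (lr, rc, dv): ROI
#'   coordinates are re-centered on this aHB reference point.
#' @return list with traces, tail, gaze, swims, conditions, truth, metadata.
#' @export
loadSessionBundle <- function(dir, centerPoint = NULL) {
  need <- c("traces.csv", "rois.csv", "tail.csv", "metadata.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("session bundle is missing required component(s): ",
         paste(missing, collapse = ", "))
  }
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  trTab <- utils::read.csv(file.path(dir, "traces.csv"), check.names = FALSE)
  roi <- utils::read.csv(file.path(dir, "rois.csv"))
  roi$roi_id <- NULL
  if (!is.null(centerPoint)) {
    roi$lr <- roi$lr - centerPoint[1]
    roi$rc <- roi$rc - centerPoint[2]
    roi$dv <- roi$dv - centerPoint[3]
  }
  values <- as.matrix(trTab[, -1, drop = FALSE])
  dimnames(values) <- NULL
  traces <- RoiTraces(values, rate = meta$imaging_rate_hz, roi = roi,
                      roiIds = trTab$roi_id,
                      preprocessed = isTRUE(meta$preprocessed))
  tail <- TailTrace(utils::read.csv(file.path(dir, "tail.csv"))$angle,
                    rate = meta$behavior_rate_hz)
  gaze <- NULL
  if (file.exists(file.path(dir, "gaze.csv"))) {
    gaze <- GazeTrace(utils::read.csv(file.path(dir, "gaze.csv"))$angle,
                      rate = meta$gaze_rate_hz,
                      saccadeTimes = as.numeric(meta$saccade_times_s))
  }
  swims <- if (file.exists(file.path(dir, "swims.csv"))) {
    utils::read.csv(file.path(dir, "swims.csv"))
  } else NULL
  conditions <- if (file.exists(file.path(dir, "conditions.csv"))) {
    utils::read.csv(file.path(dir, "conditions.csv"))
  } else NULL
  truth <- NULL
  if (file.exists(file.path(dir, "truth_phase.csv"))) {
    truth <- list(
      true_phase = utils::read.csv(file.path(dir, "truth_phase.csv"))$true_phase,
      true_heading = utils::read.csv(file.path(dir, "truth_heading.csv"))$true_heading)
  }
  list(traces = traces, tail = tail, gaze = gaze, swims = swims,
       conditions = conditions, truth = truth, metadata = meta)
}

#' Run the full analysis pipeline on a session
#'
#' preprocess -> swim detection/classification -> ring selection ->
#' rotated-PC embedding (with sorted-matrix exclusion and re-embedding) ->
#' phase decoding -> bump profile and tuning curves -> heading integration
#' and phase-heading coupling. Deterministic given `config$seed`.
#'
#' @param session a [SyntheticSession-class] or a bundle list from
#'   [loadSessionBundle()].
#' @param config overrides merged by [pipelineConfig()].
#' @return named result list (stages as elements plus a `summary`).
#' @export
runPipeline <- function(session, config = list()) {
  cfg <- pipelineConfig(config)
  if (methods::is(session, "SyntheticSession")) {
    session <- list(traces = session@traces, tail = session@tail,
                    gaze = session@gaze, truth = session@truth)
  }
  set.seed(cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  traces <- stage("preprocess", {
    if (isPreprocessed(session$traces)) session$traces else
      preprocessTraces(session$traces,
                       baselineWindowS = cfg$preprocess$baseline_window_s,
                       medianKernelFrames = cfg$preprocess$median_kernel_frames)
  })
  behavior <- stage("behavior", {
    ev <- detectSwims(session$tail, threshold = cfg$behavior$vigor_threshold,
                      minGapMs = cfg$behavior$min_gap_ms)
    fit <- tryCatch(fitTrimodal(ev$laterality, nBins = cfg$behavior$trimodal_bins),
                    error = function(e) NULL, warning = function(w) NULL)
    thr <- if (is.null(fit)) cfg$behavior$fallback_threshold else fit$threshold
    list(events = classifySwims(ev, thr), trimodal = fit, threshold = thr)
  })
  selection <- stage("ring-detection", {
    sel <- selectAnticorrelated(traces, threshold = cfg$ring$threshold,
                                scan = cfg$ring$scan)
    if (length(sel@selectedIds) < 8) {
      stop("fewer than 8 ring candidates selected")
    }
    sel
  })
  embStage <- stage("embedding", {
    emb <- buildEmbedding(traces[selection@selectedIds, ])
    sel2 <- excludeBySortedMatrix(traces, selection, ringAlpha(emb),
                                  templateMinCorr = cfg$ring$template_min_corr)
    if (length(sel2@selectedIds) < length(selection@selectedIds)) {
      emb <- buildEmbedding(traces[sel2@selectedIds, ])
    }
    list(embedding = emb, selection = sel2)
  })
  embedding <- embStage$embedding
  selection <- embStage$selection
  ringTraces <- traces[selection@selectedIds, ]
  statePca <- stage("state-pca", pcaStateSpace(ringTraces, k = 2))
  phase <- stage("phase", {
    computePhase(ringTraces, embedding,
                 clipQuantiles = c(cfg$phase$clip_low, cfg$phase$clip_high))
  })
  profile <- stage("bump-profile", {
    phaseZeroedProfile(ringTraces, embedding, phase,
                       nBins = cfg$phase$profile_bins)
  })
  tuning <- stage("tuning-curves", {
    suppressWarnings(tuningCurves(ringTraces, phase,
                                  nBins = cfg$phase$tuning_bins))
  })
  heading <- stage("heading", {
    integrateHeading(behavior$events, rate = session$tail@rate,
                     durationS = length(session$tail@angle) / session$tail@rate)
  })
  coupling <- stage("coupling", {
    phaseHeadingCoupling(phase, heading, windowS = cfg$coupling$window_s,
                         windowStepS = cfg$coupling$window_step_s)
  })
  anatomy <- stage("anatomy", {
    tryCatch(anatomyStats(embedding, roiInfo(ringTraces),
                          nShuffles = cfg$anatomy$n_shuffles),
             error = function(e) NULL)
  })
  summary <- list(
    n_ring_rois = length(selection@selectedIds),
    variance_fraction_pc12 = sum(statePca$varianceFraction),
    bump_fwhm_rad = profile@fwhm,
    median_tuning_fwhm_rad = stats::median(tuning$fwhm, na.rm = TRUE),
    n_swims = nrow(behavior$events),
    coupling_median_correlation = stats::median(coupling$window_correlations),
    coupling_p_value = coupling$p_value,
    phase_heading_slope = coupling$slope,
    rho_t = if (!is.null(anatomy)) anatomy$rho_t else NA_real_,
    config = cfg)
  list(traces = traces, behavior = behavior, selection = selection,
       embedding = embedding, statePca = statePca, phase = phase,
       profile = profile, tuning = tuning, heading = heading,
       coupling = coupling, anatomy = anatomy, summary = summary)
}

#' Write a pipeline report
#'
#' Writes `summary.json` (all scalar statistics with provenance) plus, when
#' `figures = TRUE`, diagnostic figures: phase vs heading overlay, the
#' alpha-sorted trace raster, the bump profile and the sorted correlation
#' matrix.
#'
#' @param results result list from [runPipeline()].
#' @param dir output directory.
#' @param figures write PNG figures.
#' @return invisibly, the path to summary.json.
#' @export
writeReport <- function(results, dir, figures = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(dir, "summary.json")
  jsonlite::write_json(results$summary, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  utils::write.csv(
    data.frame(time_s = (seq_along(results$phase@wrapped) - 1) /
                 results$phase@rate,
               wrapped = results$phase@wrapped,
               unwrapped = results$phase@unwrapped,
               vector_norm = results$phase@vectorNorm),
    file.path(dir, "phase.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(bin_rad = results$profile@bins, mean = results$profile@mean,
               sd = results$profile@sd),
    file.path(dir, "bump_profile.csv"), row.names = FALSE)
  utils::write.csv(results$behavior$events, file.path(dir, "swims.csv"),
                   row.names = FALSE)
  if (figures) {
    grDevices::png(file.path(dir, "phase_heading.png"), 900, 500)
    rate <- results$phase@rate
    t <- (seq_along(results$phase@unwrapped) - 1) / rate
    h <- .resampleZoh(results$heading@heading, results$heading@rate, rate,
                      length(t))
    graphics::par(mar = c(4, 4, 2, 4))
    graphics::plot(t, results$phase@unwrapped, type = "l", col = "darkgreen",
                   xlab = "time (s)", ylab = "network phase (rad)",
                   main = "network phase vs estimated heading")
    graphics::par(new = TRUE)
    graphics::plot(t, -h, type = "l", col = "goldenrod", axes = FALSE,
                   xlab = "", ylab = "")
    graphics::axis(4)
    graphics::mtext("-heading (rad)", side = 4, line = 2.5)
    grDevices::dev.off()
    grDevices::png(file.path(dir, "raster_sorted.png"), 900, 500)
    ord <- order(results$embedding@alpha)
    graphics::image(t, seq_along(ord),
                    t(traceValues(results$traces)[results$embedding@roiIds[ord], ]),
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "time (s)", ylab = "ROI (sorted by alpha)")
    grDevices::dev.off()
    grDevices::png(file.path(dir, "bump_profile.png"), 600, 450)
    graphics::plot(results$profile@bins, results$profile@mean, type = "l",
                   lwd = 2, xlab = "angle from bump peak (rad)",
                   ylab = "mean activity (z)",
                   main = sprintf("bump profile, FWHM = %.2f rad",
                                  results$profile@fwhm))
    grDevices::dev.off()
  }
  invisible(out)
}
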