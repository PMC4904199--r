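#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run: generator parameters,
#' schedule, screening thresholds, band and window settings, contrast
#' adjustment and mediation options.  All randomness flows from the
#' single `seed` (per-session and per-stage seeds are derived from it).
#'
#' @param seed master integer seed.
#' @param n_participants participants in the simulated study.
#' @param params a [generatorParams()].
#' @param schedule a [scheduleConfig()].
#' @param rt_bounds RT screening bounds, ms.
#' @param artifact_uv artifact screen threshold, microvolts.
#' @param outlier_k conditional-mean outlier criterion, SDs.
#' @param band alpha band, Hz.
#' @param pretarget_window_ms pre-target summary window.
#' @param desync_window_ms post-target desynchronisation window.
#' @param filter_method `"spectral"` or `"filtfilt"` (see
#'   [bandpassAlpha()]).
#' @param contrast_adjustment p adjustment for follow-up contrasts.
#' @param prune run [pruneRandomStructure()] on the RT model instead of
#'   fitting the retained structure directly.
#' @param mediation_random random terms of the mediation path models.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L, n_participants = 24L,
                           params = generatorParams(),
                           schedule = scheduleConfig(),
                           rt_bounds = c(200, 1000), artifact_uv = 100,
                           outlier_k = 3, band = c(8, 13),
                           pretarget_window_ms = c(-500, 0),
                           desync_window_ms = c(50, 600),
                           filter_method = "spectral",
                           contrast_adjustment = "single-step",
                           prune = FALSE,
                           mediation_random = "(1 | participant_id)") {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields override [pipelineConfig()] defaults; `params` and
#' `schedule` subsections override the corresponding constructor
#' arguments.
#'
#' @param path YAML file.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  params <- do.call(generatorParams, y$params %||% list())
  schedule <- do.call(scheduleConfig, y$schedule %||% list())
  y$params <- NULL; y$schedule <- NULL
  do.call(pipelineConfig, c(y, list(params = params,
                                    schedule = schedule)))
}

#' Hash of a pipeline configuration
#'
#' MD5 of the deparsed configuration (excluding nothing): stage outputs
#' carry this hash so that outputs of different runs cannot be mixed.
#'
#' @param config a `PipelineConfig`.
#' @return A hex string.
#' @export
configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[order(names(config))]), tf)
  unname(tools::md5sum(tf))
}

## refuse to combine stage outputs from different configurations
checkStageHash <- function(found, expected, what) {
  if (!is.null(found) && !is.null(expected) &&
      !identical(found, expected))
    stop("config hash mismatch for ", what,
         ": stage output comes from a different run (found ", found,
         ", expected ", expected, ")")
  invisible(TRUE)
}

## ---- per-session processing ---------------------------------------

subsetAlphaTrials <- function(series, idx) {
  out <- new("AlphaSeries",
             values = series@values[idx, , , drop = FALSE],
             gridTimesMs = series@gridTimesMs, bandHz = series@bandHz,
             channelLabels = series@channelLabels)
  attr(out, "winMs") <- attr(series, "winMs")
  out
}

## Simulate one session, inject artifacts, extract alpha measures and
## per-session selection.  Returns the augmented trial table, the
## selection result and per-channel condition topography means.
processSession <- function(sspec, config, schedSeed, artSeed) {
  params <- config$params
  sch <- makeSchedule(config$schedule, seed = schedSeed)
  ses <- simulateSession(sspec, params, sch, render_eeg = TRUE)
  inj <- injectArtifacts(ses$epochs, params$artifact_rate,
                         params$artifact_amplitude_uv, seed = artSeed)
  epochs <- inj$epochs
  trials <- ses$trials

  ## broad-band artifact screens (before narrow-band filtering)
  scrPre <- filterTrials(trials, epochs, "pretarget",
                         rt_bounds = config$rt_bounds,
                         artifact_uv = config$artifact_uv)
  scrDes <- filterTrials(trials, epochs, "desync",
                         rt_bounds = config$rt_bounds,
                         artifact_uv = config$artifact_uv)

  ## alpha path: candidates only, baseline -> band-pass -> envelope
  cand <- unlist(candidatePools())
  sub <- epochs[, cand]
  sub <- baselineEpochs(sub, c(-100, 0))
  filt <- bandpassAlpha(sub, config$band, method = config$filter_method)
  series <- alphaEnvelope(filt)

  ## per-session electrode selection from desync-screened trials
  keepD <- which(scrDes$kept)
  if (!length(keepD))
    stop("selection stage: no trials survive the desync screen in ",
         trials$session_id[1L])
  des <- posttargetDesync(subsetAlphaTrials(series, keepD),
                          trials[keepD, ],
                          window_ms = config$desync_window_ms)
  sel <- selectElectrodes(des, session_id = trials$session_id[1L])

  ## pre-target alpha at the selected electrodes
  al <- pretargetAlpha(series,
                       list(left = sel$left$chosen,
                            right = sel$right$chosen),
                       window_ms = config$pretarget_window_ms)
  trials <- cbind(trials, al)
  trials$kept_pretarget <- scrPre$kept
  trials$kept_desync <- scrDes$kept

  ## per-channel pre-target means (pretarget-screened trials) for the
  ## cumulative topography
  wi <- gridWindowsWithin(series, config$pretarget_window_ms)
  keepP <- which(scrPre$kept)
  topo <- if (length(keepP)) {
    v <- series@values[keepP, , wi, drop = FALSE]
    setNames(colMeans(matrix(aperm(v, c(1L, 3L, 2L)),
                             ncol = dim(v)[2L])), series@channelLabels)
  } else setNames(rep(NA_real_, length(cand)), series@channelLabels)

  list(trials = trials, selection = sel, topography = topo,
       reports = list(pretarget = scrPre$report,
                      desync = scrDes$report),
       contaminated = inj$contaminated)
}

## ---- full pipeline -------------------------------------------------

#' Run the full analysis pipeline
#'
#' Executes synth -> alpha -> selection -> screening -> models ->
#' mediation on a simulated study, one session at a time (epochs are
#' rendered, processed and released, so memory stays flat).  Writes
#' per-stage outputs and a `report.json` under `out` when given.
#'
#' @param config a [pipelineConfig()].
#' @param out optional output directory.
#' @param verbose print stage progress.
#' @return A list of class `PipelineReport`: screened study table,
#'   selections, filter counts, topography, LRT table, contrasts,
#'   coupling slopes, mediation result and the config hash.
#' @export
runPipeline <- function(config = pipelineConfig(), out = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  hash <- configHash(config)
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(sprintf(...))
  stageSeeds <- deriveSeeds(config$seed, 4L)

  ## --- synth + alpha + selection + screening, per session ----------
  plan <- studyPlan(config$params, config$n_participants, stageSeeds[1L])
  schedSeeds <- deriveSeeds(stageSeeds[2L], length(plan))
  artSeeds <- deriveSeeds(stageSeeds[3L], length(plan))
  say("synth+alpha: %d sessions", length(plan))
  sessions <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    sessions[[i]] <- tryCatch(
      processSession(plan[[i]], config, schedSeeds[i], artSeeds[i]),
      error = function(e) stop("stage synth/alpha failed in session ",
                               i, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  study <- do.call(rbind, lapply(sessions, `[[`, "trials"))
  study$tnorm <- (study$trial_number - 1) / (max(study$trial_number) - 1)
  study$hemi_left <- as.numeric(study$hemifield == "left")
  selections <- lapply(sessions, `[[`, "selection")
  filterCounts <- Reduce(`+`, lapply(sessions, function(s)
    s$reports$pretarget$removed))
  say("synth+alpha done (%.1f s)", proc.time()[["elapsed"]] - t0)

  ## cumulative topography of pre-target alpha across light conditions
  topo <- do.call(rbind, lapply(sessions, `[[`, "topography"))
  cond <- vapply(plan, `[[`, "", "light_condition")
  condMean <- function(l) colMeans(topo[cond == l, , drop = FALSE],
                                   na.rm = TRUE)
  topography <- cumulativeLightTopography(condMean("low"),
                                          condMean("medium"),
                                          condMean("high"))

  ## --- screening: RT/artifact flags + conditional-mean outliers ----
  rtData <- study[study$kept_pretarget, , drop = FALSE]
  if (!nrow(rtData))
    stop("stage screen failed: no surviving trials after the ",
         "pre-target artifact and RT screens")
  og <- interaction(rtData$participant_id, rtData$light_condition)
  outRT <- removeOutliers(rtData$rt_ms, og, k = config$outlier_k)
  rtData <- rtData[outRT$kept, , drop = FALSE]
  nOutRT <- length(outRT$removed)

  ## long format for the alpha model (hemisphere nested in participant)
  alphaLong <- rbind(
    transform(rtData, hemisphere = "left", log_alpha = log_alpha_left),
    transform(rtData, hemisphere = "right", log_alpha = log_alpha_right))
  ga <- interaction(alphaLong$participant_id, alphaLong$light_condition,
                    alphaLong$hemisphere)
  outA <- removeOutliers(alphaLong$log_alpha, ga, k = config$outlier_k)
  alphaLong <- alphaLong[outA$kept, , drop = FALSE]

  ## --- models ------------------------------------------------------
  ## pin the RNG for the model stage: the single-step contrast
  ## adjustment integrates a multivariate normal by quasi-Monte-Carlo
  rngM <- localRNG(stageSeeds[4L])
  on.exit(rngM(), add = TRUE)
  say("models: RT (n = %d), alpha (n = %d)", nrow(rtData),
      nrow(alphaLong))
  if (!nrow(rtData)) stop("stage model failed: no surviving trials")
  randRT <- c("(1 | condition_order/participant_id)",
              "(0 + hemi_left | participant_id)")
  if (config$prune) {
    pr <- pruneRandomStructure(
      modelSpec("rt_ms", c("light_condition * hemifield", "tnorm"),
                "(1 | condition_order/participant_id)"),
      rtData,
      candidates = c("(0 + hemi_left | participant_id)",
                     "(0 + log_alpha_pooled | participant_id)",
                     "(0 + tnorm | participant_id)"))
    randRT <- pr$spec$random
  }
  fitF <- fitMixed(modelSpec("rt_ms",
                             c("light_condition * hemifield", "tnorm"),
                             randRT), rtData)
  fitNoInt <- fitMixed(modelSpec("rt_ms",
                                 c("light_condition + hemifield", "tnorm"),
                                 randRT), rtData)
  fitNoLight <- fitMixed(modelSpec("rt_ms", c("hemifield", "tnorm"),
                                   randRT), rtData)
  lrts <- list(
    light_x_hemifield = lrTest(fitF, fitNoInt, "Light x Target-hemifield"),
    light_main = lrTest(fitNoInt, fitNoLight, "Light"))

  ## follow-up: light contrasts for each hemifield separately
  leftFit <- fitMixed(modelSpec("rt_ms", c("light_condition", "tnorm"),
                                "(1 | condition_order/participant_id)"),
                      rtData[rtData$hemifield == "left", ])
  rightFit <- fitMixed(modelSpec("rt_ms", c("light_condition", "tnorm"),
                                 "(1 | condition_order/participant_id)"),
                       rtData[rtData$hemifield == "right", ])
  contrasts <- list(
    rt_left = pairwiseContrasts(leftFit, "light_condition",
                                config$contrast_adjustment),
    rt_right = pairwiseContrasts(rightFit, "light_condition",
                                 config$contrast_adjustment))

  ## alpha model: Light x Hemisphere on log alpha
  randA <- "(1 | condition_order/participant_id/hemisphere)"
  fitAF <- fitMixed(modelSpec("log_alpha",
                              c("light_condition * hemisphere", "tnorm"),
                              randA), alphaLong)
  fitANoInt <- fitMixed(modelSpec("log_alpha",
                                  c("light_condition + hemisphere",
                                    "tnorm"), randA), alphaLong)
  fitANoLight <- fitMixed(modelSpec("log_alpha",
                                    c("hemisphere", "tnorm"), randA),
                          alphaLong)
  lrts$light_x_hemisphere <- lrTest(fitAF, fitANoInt,
                                    "Light x Hemisphere (log alpha)")
  lrts$light_on_alpha <- lrTest(fitANoInt, fitANoLight,
                                "Light (log alpha)")
  for (h in c("left", "right")) {
    hf <- fitMixed(modelSpec("log_alpha", c("light_condition", "tnorm"),
                             "(1 | condition_order/participant_id)"),
                   alphaLong[alphaLong$hemisphere == h, ])
    contrasts[[paste0("alpha_", h)]] <-
      pairwiseContrasts(hf, "light_condition",
                        config$contrast_adjustment)
  }

  ## alpha x RT coupling: light-specific slopes of pooled log alpha
  rtData$la_c <- rtData$log_alpha_pooled -
    mean(rtData$log_alpha_pooled)
  randC <- c(randRT, "(0 + la_c | participant_id)")
  fitCF <- fitMixed(modelSpec("rt_ms",
                              c("light_condition * hemifield",
                                "light_condition * la_c", "tnorm"),
                              randC), rtData)
  fitCR <- fitMixed(modelSpec("rt_ms",
                              c("light_condition * hemifield", "la_c",
                                "tnorm"), randC), rtData)
  fitC0 <- fitMixed(modelSpec("rt_ms",
                              c("light_condition * hemifield", "tnorm"),
                              randC), rtData)
  lrts$light_x_alpha <- lrTest(fitCF, fitCR, "Light x alpha (RT)")
  lrts$alpha_main <- lrTest(fitCR, fitC0, "alpha (RT)")
  cf <- setNames(fitCF$coefficients$estimate, fitCF$coefficients$term)
  slopes <- c(low = unname(cf["la_c"]),
              medium = unname(cf["la_c"] +
                                cf["light_conditionmedium:la_c"]),
              high = unname(cf["la_c"] + cf["light_conditionhigh:la_c"]))

  ## --- mediation ---------------------------------------------------
  say("mediation")
  med <- mediationSobel(
    rtData[rtData$hemifield == "left" &
             rtData$light_condition %in% c("low", "high"), ],
    treatment = "light_condition", mediator = "log_alpha_right",
    outcome = "rt_ms", random = config$mediation_random)

  report <- list(
    config_hash = hash, seed = config$seed,
    n_sessions = length(plan),
    filter_counts = as.list(filterCounts),
    n_rt_outliers = nOutRT,
    n_alpha_outliers = length(outA$removed),
    n_analysis_trials = nrow(rtData),
    selections = selections,
    topography = topography,
    lrts = lrts, contrasts = contrasts,
    coupling_slopes = slopes,
    condition_means_left = tapply(
      rtData$rt_ms[rtData$hemifield == "left"],
      rtData$light_condition[rtData$hemifield == "left"], mean),
    condition_means_right = tapply(
      rtData$rt_ms[rtData$hemifield == "right"],
      rtData$light_condition[rtData$hemifield == "right"], mean),
    mediation = med,
    trials = rtData,
    elapsed_s = proc.time()[["elapsed"]] - t0)
  class(report) <- "PipelineReport"

  if (!is.null(out)) writeReport(report, config, out)
  report
}

## serialise the report bundle (report.json + screened trials CSV +
## selection JSON) under `out`
writeReport <- function(report, config, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  writeTrialTable(report$trials, file.path(out, "trials_screened.csv"))
  jsonlite::write_json(
    lapply(report$selections, function(s)
      list(session_id = s$session_id,
           left = list(chosen = s$left$chosen,
                       metric = as.list(s$left$metric)),
           right = list(chosen = s$right$chosen,
                        metric = as.list(s$right$metric)))),
    file.path(out, "selection.json"), auto_unbox = TRUE, digits = NA)
  lt <- lapply(report$lrts, function(x)
    list(term = x$term, chi_square = x$chi_square, df = x$df,
         p_value = x$p_value))
  med <- report$mediation
  jsonlite::write_json(list(
    config_hash = report$config_hash,
    seed = report$seed,
    n_sessions = report$n_sessions,
    filter_counts = report$filter_counts,
    n_rt_outliers = report$n_rt_outliers,
    n_alpha_outliers = report$n_alpha_outliers,
    n_analysis_trials = report$n_analysis_trials,
    condition_means_left = as.list(report$condition_means_left),
    condition_means_right = as.list(report$condition_means_right),
    lrts = lt,
    contrasts = report$contrasts,
    coupling_slopes = as.list(report$coupling_slopes),
    topography = as.list(report$topography),
    mediation = list(paths = as.list(med@paths),
                     indirect = med@indirect, sobel_se = med@sobelSe,
                     sobel_z = med@sobelZ, sobel_p = med@sobelP,
                     consistency = med@consistency)),
    file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("Pipeline report (", x$n_sessions, " sessions, ",
      x$n_analysis_trials, " analysis trials, hash ",
      substr(x$config_hash, 1, 8), ")\n", sep = "")
  cat("Left-hemifield RT means (ms):\n")
  print(round(x$condition_means_left, 1))
  cat("LRTs:\n")
  for (l in x$lrts) print(l)
  cat("Coupling slopes (ms per log-unit alpha):\n")
  print(round(x$coupling_slopes, 2))
  show(x$mediation)
  invisible(x)
}
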