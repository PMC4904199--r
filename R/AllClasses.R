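#' EpochSet: epoched multi-channel EEG voltages
#'
#' Container for event-locked EEG epochs: a trials x channels x samples
#' voltage array (microvolts) together with its sampling rate, the time
#' of the first sample relative to target onset, channel labels on the
#' 10-10 system, and a record of any baseline window already applied.
#'
#' @slot voltages numeric array, trials x channels x samples, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot tStartMs time of the first sample relative to target onset (ms).
#' @slot channelLabels unique 10-10 channel labels, one per channel.
#' @slot baselineWindowMs length-0 numeric if no baseline has been
#'   subtracted, otherwise the `c(from, to)` window in ms.
#'
#' @seealso [epochSet()], [baselineEpochs()], [bandpassAlpha()]
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    voltages = "array",
    fs = "numeric",
    tStartMs = "numeric",
    channelLabels = "character",
    baselineWindowMs = "numeric"
  )
)

setValidity("EpochSet", function(object) {
  v <- object@voltages
  msg <- character()
  if (length(dim(v)) != 3L)
    msg <- c(msg, "voltages must be a trials x channels x samples array")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@tStartMs) != 1L)
    msg <- c(msg, "tStartMs must be a single number")
  if (length(dim(v)) == 3L && dim(v)[2L] != length(object@channelLabels))
    msg <- c(msg, "channelLabels length must equal the channel dimension")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (!length(object@baselineWindowMs) %in% c(0L, 2L))
    msg <- c(msg, "baselineWindowMs must be length 0 or 2")
  if (length(msg)) msg else TRUE
})

#' Construct an EpochSet
#'
#' @param voltages trials x channels x samples numeric array (microvolts).
#' @param fs sampling rate (Hz).
#' @param tStartMs time of the first sample relative to target onset (ms).
#' @param channelLabels character vector of unique channel labels.
#' @param baselineWindowMs `c(from, to)` in ms if a baseline has already
#'   been subtracted, otherwise `numeric(0)`.
#' @return An [EpochSet-class] object.
#' @examples
#' es <- epochSet(array(0, c(2, 1, 100)), fs = 500, tStartMs = -100, "Oz")
#' nTrials(es)
#' @export
epochSet <- function(voltages, fs, tStartMs, channelLabels,
                     baselineWindowMs = numeric(0)) {
  new("EpochSet", voltages = voltages, fs = fs, tStartMs = tStartMs,
      channelLabels = as.character(channelLabels),
      baselineWindowMs = baselineWindowMs)
}

#' @describeIn epochSet number of trials
#' @param x an `EpochSet` or `AlphaSeries`
#' @export
nTrials <- function(x) dim(slot(x, dataSlot(x)))[1L]

#' @describeIn epochSet number of channels
#' @export
nChannels <- function(x) dim(slot(x, dataSlot(x)))[2L]

#' @describeIn epochSet number of samples per epoch
#' @export
nSamples <- function(x) dim(x@voltages)[3L]

dataSlot <- function(x) if (is(x, "AlphaSeries")) "values" else "voltages"

#' @describeIn epochSet channel labels
#' @export
channelLabels <- function(x) slot(x, "channelLabels")

#' @describeIn epochSet sample times in ms relative to target onset
#' @export
sampleTimes <- function(x)
  x@tStartMs + (seq_len(nSamples(x)) - 1L) * 1000 / x@fs

setMethod("show", "EpochSet", function(object) {
  cat("EpochSet:", nTrials(object), "trials x", nChannels(object),
      "channels x", nSamples(object), "samples\n")
  tt <- sampleTimes(object)
  cat(sprintf("  fs = %g Hz, t = %g..%g ms\n", object@fs, tt[1L],
              tt[length(tt)]))
  cat("  baseline:",
      if (length(object@baselineWindowMs))
        sprintf("[%g, %g) ms", object@baselineWindowMs[1L],
                object@baselineWindowMs[2L]) else "none", "\n")
})

#' Subset an EpochSet by trial and/or channel
#'
#' @param x an `EpochSet`
#' @param i trial indices
#' @param j channel indices or labels
#' @param ... ignored
#' @param drop ignored (dimensions are always kept)
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nTrials(x))
  if (missing(j)) j <- seq_len(nChannels(x))
  if (is.character(j)) {
    jj <- match(j, x@channelLabels)
    if (anyNA(jj)) stop("unknown channel label(s): ",
                        paste(j[is.na(jj)], collapse = ", "))
    j <- jj
  }
  epochSet(x@voltages[i, j, , drop = FALSE], fs = x@fs,
           tStartMs = x@tStartMs, channelLabels = x@channelLabels[j],
           baselineWindowMs = x@baselineWindowMs)
})

#' AlphaSeries: smoothed rectified alpha-band envelope
#'
#' Single-trial alpha envelope on a trimmed, coarse time grid: the
#' band-passed signal is rectified and averaged inside 100 ms windows
#' advancing in 50 ms steps, after discarding 200 ms of filter warm-up
#' at each epoch edge.  Values are non-negative amplitudes (microvolts).
#'
#' @slot values trials x channels x grid array of envelope amplitudes.
#' @slot gridTimesMs window centres (ms relative to target onset).
#' @slot bandHz `c(low, high)` pass band in Hz.
#' @slot channelLabels channel labels matching the channel dimension.
#'
#' @seealso [alphaEnvelope()], [pretargetAlpha()], [posttargetDesync()]
#' @exportClass AlphaSeries
setClass("AlphaSeries",
  representation(
    values = "array",
    gridTimesMs = "numeric",
    bandHz = "numeric",
    channelLabels = "character"
  )
)

setValidity("AlphaSeries", function(object) {
  v <- object@values
  msg <- character()
  if (length(dim(v)) != 3L)
    msg <- c(msg, "values must be a trials x channels x grid array")
  if (length(dim(v)) == 3L && dim(v)[3L] != length(object@gridTimesMs))
    msg <- c(msg, "gridTimesMs length must equal the grid dimension")
  if (length(dim(v)) == 3L && dim(v)[2L] != length(object@channelLabels))
    msg <- c(msg, "channelLabels length must equal the channel dimension")
  if (length(object@bandHz) != 2L || object@bandHz[1L] >= object@bandHz[2L])
    msg <- c(msg, "bandHz must be c(low, high) with low < high")
  if (any(v < 0))
    msg <- c(msg, "envelope values must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AlphaSeries", function(object) {
  g <- object@gridTimesMs
  cat("AlphaSeries:", nTrials(object), "trials x", nChannels(object),
      "channels x", length(g), "windows\n")
  cat(sprintf("  band %g-%g Hz, grid %g..%g ms (step %g ms)\n",
              object@bandHz[1L], object@bandHz[2L], g[1L], g[length(g)],
              if (length(g) > 1L) g[2L] - g[1L] else NA_real_))
})

#' MediationResult: paths and Sobel test of an indirect effect
#'
#' Result of a treatment -> mediator -> outcome mediation analysis:
#' path a (treatment to mediator), path b (mediator to outcome adjusted
#' for treatment), total effect c, direct effect c', the indirect effect
#' a*b with its first-order Sobel standard error, z and two-sided p, and
#' the consistency classification ("inconsistent" when the direct and
#' indirect effects have opposite signs).
#'
#' @slot paths named numeric: a, b, c, c_prime and their SEs
#'   (se_a, se_b, se_c, se_c_prime), on the analysis (standardised
#'   mediator) scale.
#' @slot indirect a * b.
#' @slot sobelSe Sobel standard error of the indirect effect.
#' @slot sobelZ z statistic.
#' @slot sobelP two-sided normal p value.
#' @slot consistency "consistent" or "inconsistent".
#' @slot mediatorSd standard deviation used to standardise the mediator
#'   (1 if not standardised); divide a by it and multiply b by it to
#'   recover the raw-mediator scale.
#' @exportClass MediationResult
setClass("MediationResult",
  representation(
    paths = "numeric",
    indirect = "numeric",
    sobelSe = "numeric",
    sobelZ = "numeric",
    sobelP = "numeric",
    consistency = "character",
    mediatorSd = "numeric"
  )
)

setValidity("MediationResult", function(object) {
  msg <- character()
  need <- c("a", "se_a", "b", "se_b", "c", "se_c", "c_prime", "se_c_prime")
  if (!all(need %in% names(object@paths)))
    msg <- c(msg, "paths must contain a, b, c, c_prime and their SEs")
  if (!object@consistency %in% c("consistent", "inconsistent"))
    msg <- c(msg, "consistency must be 'consistent' or 'inconsistent'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MediationResult", function(object) {
  p <- object@paths
  cat("Mediation (treatment -> mediator -> outcome)\n")
  cat(sprintf("  a       = %8.4f (SE %.4f)\n", p["a"], p["se_a"]))
  cat(sprintf("  b       = %8.4f (SE %.4f)\n", p["b"], p["se_b"]))
  cat(sprintf("  c       = %8.4f (SE %.4f)   total\n", p["c"], p["se_c"]))
  cat(sprintf("  c'      = %8.4f (SE %.4f)   direct\n",
              p["c_prime"], p["se_c_prime"]))
  cat(sprintf("  a*b     = %8.4f (Sobel SE %.4f, z = %.2f, p = %.4g)\n",
              object@indirect, object@sobelSe, object@sobelZ, object@sobelP))
  cat("  classification:", object@consistency, "mediation\n")
})
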