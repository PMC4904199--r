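## ---- preprocessing -------------------------------------------------

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean voltage over the baseline
#' window (default the 100 ms immediately before target onset,
#' half-open at 0).  Applying the same window twice is a no-op on the
#' values since the window mean is already zero.
#'
#' @param epochs an [EpochSet-class].
#' @param window_ms `c(from, to)` baseline window, ms relative to
#'   target onset; samples with `from <= t < to` are used.
#' @return A baselined [EpochSet-class] with `baselineWindowMs` set.
#' @export
baselineEpochs <- function(epochs, window_ms = c(-100, 0)) {
  stopifnot(is(epochs, "EpochSet"), length(window_ms) == 2L)
  tt <- sampleTimes(epochs)
  idx <- which(tt >= window_ms[1L] & tt < window_ms[2L])
  if (!length(idx) || window_ms[1L] < tt[1L] ||
      window_ms[2L] > tt[length(tt)] + 1000 / epochs@fs)
    stop("baseline window lies outside the epoch")
  arr <- epochs@voltages
  mu <- rowMeans(arr[, , idx, drop = FALSE], dims = 2L)
  arr <- arr - as.vector(mu)      # (trial, channel) means recycle over samples
  epochSet(arr, fs = epochs@fs, tStartMs = epochs@tStartMs,
           channelLabels = epochs@channelLabels,
           baselineWindowMs = as.numeric(window_ms))
}

#' Broad-band low-pass filter
#'
#' Optional preprocessing for real recordings: 4th-order Butterworth
#' low-pass (default 35 Hz) applied forward and backward (zero net
#' phase).  The synthetic generator produces band-limited data, so the
#' pipeline leaves this off by default.
#'
#' @param epochs an [EpochSet-class].
#' @param cutoff_hz low-pass edge in Hz.
#' @return A filtered [EpochSet-class].
#' @export
lowpassBroadband <- function(epochs, cutoff_hz = 35) {
  stopifnot(is(epochs, "EpochSet"))
  if (cutoff_hz <= 0 || cutoff_hz >= epochs@fs / 2)
    stop("cutoff must lie strictly inside (0, Nyquist)")
  bf <- signal::butter(4, cutoff_hz / (epochs@fs / 2), type = "low")
  applyZeroPhase(epochs, bf, method = "filtfilt")
}

#' Average re-reference
#'
#' Optional preprocessing for real recordings: subtracts the
#' instantaneous mean over channels from every channel.  Synthetic data
#' are generated referenced, so the pipeline leaves this off by default.
#'
#' @param epochs an [EpochSet-class].
#' @return A re-referenced [EpochSet-class].
#' @export
rereferenceAverage <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  arr <- epochs@voltages
  mu <- apply(arr, c(1L, 3L), mean)                 # trial x sample
  arr <- arr - aperm(array(mu, c(dim(arr)[1L], dim(arr)[3L],
                                 dim(arr)[2L])), c(1L, 3L, 2L))
  epochSet(arr, fs = epochs@fs, tStartMs = epochs@tStartMs,
           channelLabels = epochs@channelLabels,
           baselineWindowMs = epochs@baselineWindowMs)
}

## Apply a zero-phase (forward-backward) IIR filter to all traces.
## method "filtfilt" loops signal::filtfilt over trials x channels;
## method "spectral" multiplies each trace's DFT by |H(f)|^2 -- the
## same forward-backward response applied circularly, vectorised over
## all traces.  The two agree away from the epoch edges, which the
## envelope step trims.
applyZeroPhase <- function(epochs, bf, method = c("spectral", "filtfilt")) {
  method <- match.arg(method)
  arr <- epochs@voltages
  d <- dim(arr)
  if (method == "filtfilt") {
    for (i in seq_len(d[1L]))
      for (j in seq_len(d[2L]))
        arr[i, j, ] <- signal::filtfilt(bf, arr[i, j, ])
  } else {
    n <- d[3L]
    fbins <- 2 * pi * (seq_len(n) - 1) / n          # rad/sample
    h <- signal::freqz(bf, Fs = 2 * pi, n = fbins)$h
    gain2 <- Mod(h)^2
    m <- t(matrix(arr, d[1L] * d[2L], n))           # samples x traces
    m <- Re(mvfft(mvfft(m) * gain2, inverse = TRUE)) / n
    arr <- array(t(m), d)
  }
  epochSet(arr, fs = epochs@fs, tStartMs = epochs@tStartMs,
           channelLabels = epochs@channelLabels,
           baselineWindowMs = epochs@baselineWindowMs)
}

#' Band-pass filter epochs to the alpha range
#'
#' 4th-order Butterworth band-pass (default 8-13 Hz) applied forward
#' and backward so the net phase shift is zero.  `method = "spectral"`
#' (default) applies the identical forward-backward magnitude response
#' through the DFT, which vectorises over all trials and channels;
#' `method = "filtfilt"` runs `signal::filtfilt` trace by trace.  The
#' two differ only near the epoch edges, which [alphaEnvelope()] trims.
#'
#' @param epochs an [EpochSet-class].
#' @param band `c(low, high)` pass band in Hz; the high edge must lie
#'   below Nyquist.
#' @param method `"spectral"` or `"filtfilt"`.
#' @return A filtered [EpochSet-class].
#' @export
bandpassAlpha <- function(epochs, band = c(8, 13),
                          method = c("spectral", "filtfilt")) {
  stopifnot(is(epochs, "EpochSet"))
  if (length(band) != 2L || band[1L] >= band[2L])
    stop("band must be c(low, high) with low < high")
  if (band[2L] >= epochs@fs / 2)
    stop("band high edge must lie below the Nyquist frequency")
  bf <- signal::butter(4, band / (epochs@fs / 2), type = "pass")
  out <- applyZeroPhase(epochs, bf, method = match.arg(method))
  attr(out, "bandHz") <- band
  out
}

## ---- envelope ------------------------------------------------------

#' Rectified, smoothed alpha envelope
#'
#' Converts band-passed epochs to single-trial amplitude envelopes:
#' absolute value sample-wise, discard `trim_ms` at each epoch edge
#' (filter warm-up), then average inside `win_ms` windows advancing in
#' `step_ms` increments.  A window contributes only if it lies fully
#' inside the trimmed support (half-open `[t, t + win_ms)`); grid times
#' are window centres.
#'
#' @param filtered a band-passed [EpochSet-class] (see
#'   [bandpassAlpha()]).
#' @param trim_ms trim at each end, ms.
#' @param win_ms smoothing window length, ms.
#' @param step_ms window step, ms.
#' @param band_hz pass band recorded in the result (taken from the
#'   input's `bandHz` attribute when present).
#' @return An [AlphaSeries-class].
#' @examples
#' tt <- seq(-700, 1198, by = 2)
#' v <- array(sin(2 * pi * 10 * tt / 1000), c(1, 1, length(tt)))
#' es <- epochSet(v, 500, -700, "Oz")
#' as <- alphaEnvelope(es)
#' range(as@values)       # ~ 2/pi everywhere
#' @export
alphaEnvelope <- function(filtered, trim_ms = 200, win_ms = 100,
                          step_ms = 50, band_hz = NULL) {
  stopifnot(is(filtered, "EpochSet"))
  tt <- sampleTimes(filtered)
  span <- tt[length(tt)] - tt[1L]
  if (span <= 2 * trim_ms + win_ms)
    stop("epoch too short for the requested trim and window")
  lo <- tt[1L] + trim_ms
  hi <- tt[length(tt)] + 1000 / filtered@fs - trim_ms  # half-open end
  keep <- which(tt >= lo & tt < hi)
  rect <- abs(filtered@voltages[, , keep, drop = FALSE])
  tk <- tt[keep]
  starts <- seq(lo, hi - win_ms, by = step_ms)
  vals <- vapply(starts, function(s) {
    idx <- which(tk >= s & tk < s + win_ms)
    rowMeans(rect[, , idx, drop = FALSE], dims = 2L)
  }, matrix(0, dim(rect)[1L], dim(rect)[2L]))
  if (is.null(dim(vals)))   # single trial x single channel
    vals <- array(vals, c(1L, 1L, length(starts)))
  if (is.null(band_hz))
    band_hz <- attr(filtered, "bandHz") %||% c(8, 13)
  out <- new("AlphaSeries", values = vals,
             gridTimesMs = starts + win_ms / 2,
             bandHz = as.numeric(band_hz),
             channelLabels = filtered@channelLabels)
  attr(out, "winMs") <- win_ms
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- summaries -----------------------------------------------------

## grid windows (by centre) whose full smoothing window lies inside the
## half-open interval [from, to)
gridWindowsWithin <- function(series, window_ms) {
  g <- series@gridTimesMs
  win <- attr(series, "winMs") %||% 100
  which(g - win / 2 >= window_ms[1L] & g + win / 2 <= window_ms[2L])
}

#' Per-trial pre-target alpha summary
#'
#' Averages the envelope over the pre-target window (default the 500 ms
#' immediately before target onset, half-open at 0) and over each
#' hemisphere's electrode pool, yielding one value per trial per
#' hemisphere plus a combined pool of all listed electrodes (used by
#' the alpha x RT model).
#'
#' @param series an [AlphaSeries-class].
#' @param electrodes a list with character vectors `left` and `right`.
#' @param window_ms pre-target window `c(from, to)`, half-open at `to`.
#' @return A data.frame with `alpha_left`, `alpha_right`,
#'   `alpha_pooled` (microvolts) and their natural logs.
#' @export
pretargetAlpha <- function(series, electrodes,
                           window_ms = c(-500, 0)) {
  stopifnot(is(series, "AlphaSeries"))
  labs <- c(electrodes$left, electrodes$right)
  miss <- setdiff(labs, series@channelLabels)
  if (length(miss))
    stop("unknown electrode label(s): ", paste(miss, collapse = ", "))
  wi <- gridWindowsWithin(series, window_ms)
  if (!length(wi)) stop("window outside the envelope grid support")
  poolMean <- function(chs) {
    j <- match(chs, series@channelLabels)
    v <- series@values[, j, wi, drop = FALSE]
    rowMeans(matrix(v, nrow = dim(v)[1L]))
  }
  aL <- poolMean(electrodes$left)
  aR <- poolMean(electrodes$right)
  aP <- poolMean(labs)
  data.frame(alpha_left = aL, alpha_right = aR, alpha_pooled = aP,
             log_alpha_left = log(aL), log_alpha_right = log(aR),
             log_alpha_pooled = log(aP))
}

#' Post-target alpha desynchronisation per electrode
#'
#' For each lateral electrode, averages the envelope waveform over
#' trials whose target fell contralateral to the electrode's
#' hemisphere, and separately over ipsilateral-target trials.
#' Desynchronisation is the mean envelope inside the post-target window
#' (default 50-600 ms) minus the same trial set's mean pre-target
#' (-500..0 ms) envelope.  The contralateral-minus-ipsilateral
#' difference is the electrode-selection metric.
#'
#' @param series an [AlphaSeries-class].
#' @param trials trial table aligned with `series` by row (needs a
#'   `hemifield` column).
#' @param window_ms post-target window, half-open.
#' @param electrodes electrode labels to evaluate (default: all lateral
#'   candidates present in the series).  Midline labels error.
#' @param pre_window_ms pre-target reference window.
#' @return A data.frame with `electrode`, `hemisphere`, `desync_contra`,
#'   `desync_ipsi`, `diff` (contra minus ipsi).
#' @export
posttargetDesync <- function(series, trials, window_ms = c(50, 600),
                             electrodes = NULL,
                             pre_window_ms = c(-500, 0)) {
  stopifnot(is(series, "AlphaSeries"))
  if (nrow(trials) != nTrials(series))
    stop("trials and series are not aligned (row counts differ)")
  if (is.null(electrodes))
    electrodes <- intersect(unlist(candidatePools()),
                            series@channelLabels)
  hemi <- electrodeHemisphere(electrodes)
  wiPost <- gridWindowsWithin(series, window_ms)
  wiPre <- gridWindowsWithin(series, pre_window_ms)
  if (!length(wiPost) || !length(wiPre))
    stop("window outside the envelope grid support")
  out <- lapply(seq_along(electrodes), function(k) {
    j <- match(electrodes[k], series@channelLabels)
    if (is.na(j)) stop("unknown electrode label: ", electrodes[k])
    contra <- if (hemi[k] == "left") trials$hemifield == "right"
              else trials$hemifield == "left"
    des <- function(sel) {
      wave <- colMeans(series@values[sel, j, , drop = FALSE])
      mean(wave[wiPost]) - mean(wave[wiPre])
    }
    data.frame(electrode = electrodes[k], hemisphere = hemi[k],
               desync_contra = des(contra), desync_ipsi = des(!contra),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$diff <- out$desync_contra - out$desync_ipsi
  out
}
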