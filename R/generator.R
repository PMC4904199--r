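#' Generator parameters for synthetic sessions
#'
#' Houses the generative counterparts of the study's reported effects.
#' Light levels are always indexed in the fixed order low < medium <
#' high.  Defaults are calibrated so that the printed condition-level
#' results are the generator's fixed point:
#' left-hemifield response-time means of 499/497/490 ms for
#' low/medium/high light (right-hemifield flat), right-hemisphere
#' log-alpha light gains of 0/0.04/0.07 (left 0/0.01/0.03), and
#' alpha-to-RT coupling slopes of 12.0/9.2/7.0 ms per log-unit whose
#' pairwise differences reproduce the printed slope contrasts
#' (medium-low -2.8, high-medium -2.2, high-low -5.0).
#'
#' @param alpha_base baseline alpha sinusoid amplitude (microvolts) at a
#'   full-weight source electrode.
#' @param light_gain_left,light_gain_right multiplicative alpha gain per
#'   light level (length 3, low/medium/high, each > 0 and
#'   non-decreasing; right steeper than left).
#' @param desync_depth fractional post-target envelope reduction
#'   contralateral to the target.
#' @param tot_alpha_slope log-amplitude drift over the session (alpha
#'   grows with time-on-task).
#' @param alpha_trial_sdlog lognormal sd of trial-to-trial alpha
#'   amplitude fluctuations, per hemisphere.
#' @param alpha_trial_cor correlation of the two hemispheres' log
#'   amplitude fluctuations (bilateral arousal co-fluctuation).
#' @param subject_alpha_sdlog between-subject sd of log alpha amplitude.
#' @param alpha_freq_hz frequency of the alpha oscillation.
#' @param rt_intercept_ms mean RT (ms) for left-hemifield targets under
#'   low light.
#' @param hemifield_offset_ms additive RT offset for right-hemifield
#'   targets (time-averaged).
#' @param light_left_rt_effect_ms additive RT effect of each light level
#'   for left-hemifield targets only (length 3; low is the reference 0).
#' @param alpha_rt_slope_ms RT change (ms) per log-unit of pre-target
#'   pooled alpha, one value per light level; magnitudes decrease with
#'   light intensity.
#' @param tot_rt_interaction_ms size of the hemifield-specific RT drift:
#'   right-hemifield responses start this much slower than their mean
#'   and end as much faster (the early right-hemifield disadvantage
#'   wanes with time-on-task).
#' @param subject_sd named sds of by-subject random effects
#'   (`intercept`, `hemifield`, `alpha` slope), all in ms.
#' @param resid_sd_ms residual RT standard deviation.
#' @param miss_rate probability a trial has no response (ceiling
#'   accuracy: default 2.6%).
#' @param artifact_rate fraction of trials receiving an injected
#'   voltage transient (see [injectArtifacts()]).
#' @param artifact_amplitude_uv peak amplitude of injected transients.
#' @param noise_exponent spectral slope of the 1/f background (power
#'   proportional to f^-exponent).
#' @param noise_sd_uv broadband background-noise sd per channel.
#' @param n_noise_sources number of independent 1/f sources mixed into
#'   the channels (spatially correlated background).
#' @return A list of class `GeneratorParams`.
#' @export
generatorParams <- function(alpha_base = 12,
                            light_gain_left = exp(c(0, 0.01, 0.03)),
                            light_gain_right = exp(c(0, 0.04, 0.07)),
                            desync_depth = 0.5,
                            tot_alpha_slope = 0.10,
                            alpha_trial_sdlog = 0.5,
                            alpha_trial_cor = 0.64,
                            subject_alpha_sdlog = 0.2,
                            alpha_freq_hz = 10,
                            rt_intercept_ms = 499,
                            hemifield_offset_ms = 0,
                            light_left_rt_effect_ms = c(0, -2, -9),
                            alpha_rt_slope_ms = c(12.0, 9.2, 7.0),
                            tot_rt_interaction_ms = 10,
                            subject_sd = c(intercept = 25, hemifield = 10,
                                           alpha = 3),
                            resid_sd_ms = 90,
                            miss_rate = 0.026,
                            artifact_rate = 0.02,
                            artifact_amplitude_uv = 150,
                            noise_exponent = 1,
                            noise_sd_uv = 12,
                            n_noise_sources = 16L) {
  p <- as.list(environment())
  if (any(c(p$light_gain_left, p$light_gain_right) <= 0))
    stop("light gains must be positive")
  if (length(p$light_gain_left) != 3L || length(p$light_gain_right) != 3L ||
      length(p$light_left_rt_effect_ms) != 3L ||
      length(p$alpha_rt_slope_ms) != 3L)
    stop("per-light parameters must have length 3 (low, medium, high)")
  if (any(p$subject_sd < 0) || p$resid_sd_ms < 0 ||
      p$alpha_trial_sdlog < 0 || p$subject_alpha_sdlog < 0)
    stop("standard deviations must be non-negative")
  if (p$artifact_rate < 0 || p$artifact_rate > 1)
    stop("artifact_rate must lie in [0, 1]")
  if (p$alpha_trial_cor < 0 || p$alpha_trial_cor > 1)
    stop("alpha_trial_cor must lie in [0, 1]")
  if (p$miss_rate < 0 || p$miss_rate > 1)
    stop("miss_rate must lie in [0, 1]")
  if (!all(c("intercept", "hemifield", "alpha") %in% names(p$subject_sd)))
    stop("subject_sd must name intercept, hemifield and alpha components")
  class(p) <- "GeneratorParams"
  p
}

LIGHT_LEVELS <- c("low", "medium", "high")

## Raised-cosine post-target desynchronisation profile: amplitude drops
## from 1 to (1 - depth) over 50..150 ms, holds until 600 ms, recovers
## over 600..700 ms.  Applied contralaterally to the target hemifield.
desyncProfile <- function(t_ms, depth) {
  ramp <- function(x) 0.5 * (1 - cos(pi * pmin(pmax(x, 0), 1)))
  drop <- ramp((t_ms - 50) / 100) - ramp((t_ms - 600) / 100)
  1 - depth * drop
}

## Synthesize spatially-correlated 1/f background noise for one session:
## n_src independent 1/f streams (frequency-domain shaping of white
## noise, unit variance) mixed through a fixed unit-row-norm matrix.
## Returns a (trials x channels x samples) array scaled to sd_uv.
synthNoise <- function(n_trials, n_channels, n_samples, fs, exponent,
                       sd_uv, n_src) {
  if (sd_uv <= 0)
    return(array(0, c(n_trials, n_channels, n_samples)))
  mix <- matrix(rnorm(n_channels * n_src), n_channels, n_src)
  mix <- mix / sqrt(rowSums(mix^2))
  w <- matrix(rnorm(n_samples * n_src * n_trials), n_samples)
  f <- seq_len(n_samples) - 1
  f <- pmin(f, n_samples - f) * fs / n_samples
  shape <- ifelse(f < 0.5, 0, f^(-exponent / 2))
  shape <- shape / sqrt(mean(shape^2))   # unit output variance
  src <- Re(mvfft(mvfft(w) * shape, inverse = TRUE)) / n_samples
  ## columns ordered source-fastest: reshape to samples x src x trial
  src <- array(src, c(n_samples, n_src, n_trials))
  big <- matrix(aperm(src, c(2L, 1L, 3L)), n_src)   # src x (samples*trials)
  chan <- mix %*% big                               # ch x (samples*trials)
  aperm(array(chan, c(n_channels, n_samples, n_trials)),
        c(3L, 1L, 2L)) * sd_uv
}

#' Simulate one testing session
#'
#' Generates the behavioural outcomes and (optionally) raw-like EEG
#' epochs of a single session, carrying the statistical structure the
#' downstream inference assumes: light-dose-dependent alpha amplitude
#' that is larger over the right hemisphere, post-target alpha
#' desynchronisation contralateral to the target hemifield, response
#' times coupled to the trial's realised pre-target log alpha envelope
#' with a light-specific slope, a left-hemifield-specific RT benefit of
#' higher light, and time-on-task drifts in both alpha and the
#' hemifield RT asymmetry.
#'
#' The realised per-trial envelope targets (`env_left_true`,
#' `env_right_true`, in microvolts, and `log_alpha_pooled_true`) are
#' recorded in the trial table as ground truth for recovery tests.  RT
#' is coupled to the deviation of `log_alpha_pooled_true` from its
#' session mean, so condition-level mean RTs equal the calibrated
#' values exactly in expectation.
#'
#' The synthetic scalp projects each hemisphere's alpha source with
#' weight 1.0 onto four "true" parieto-occipital electrodes, 0.5 onto
#' the remaining candidates of that hemisphere, and 0 elsewhere, on top
#' of spatially correlated 1/f background noise on all 64 channels.
#'
#' @param spec a list with `participant_id`, `light_condition`
#'   (`"low"`, `"medium"` or `"high"`), `condition_order`, `seed`, and
#'   optionally `subject_effects` (as produced by [studyPlan()]); when
#'   absent, subject effects are drawn from the session seed.
#' @param params a [generatorParams()] object.
#' @param schedule a schedule from [makeSchedule()].
#' @param render_eeg if `FALSE`, only the behavioural trial table is
#'   generated (fast path for model-level simulations).
#' @param channels channel labels of the rendered montage; must contain
#'   all 16 candidate electrodes.
#' @return A list with `trials` (data.frame) and `epochs` (an
#'   [EpochSet-class], or `NULL` when `render_eeg = FALSE`).
#' @examples
#' sch <- makeSchedule(scheduleConfig(n_blocks = 1), seed = 1)
#' ses <- simulateSession(list(participant_id = 1, light_condition = "low",
#'                             condition_order = 1, seed = 7),
#'                        generatorParams(), sch, render_eeg = FALSE)
#' head(ses$trials)
#' @export
simulateSession <- function(spec, params = generatorParams(),
                            schedule = makeSchedule(),
                            render_eeg = TRUE, channels = MONTAGE64) {
  stopifnot(inherits(params, "GeneratorParams"))
  if (!spec$light_condition %in% LIGHT_LEVELS)
    stop("unknown light condition: ", spec$light_condition)
  need <- c("trial_number", "delay_s", "quadrant", "hemifield",
            "vertical_field", "direction")
  if (!all(need %in% names(schedule)))
    stop("schedule is missing columns: ",
         paste(setdiff(need, names(schedule)), collapse = ", "))
  rng <- localRNG(spec$seed)
  on.exit(rng())

  n <- nrow(schedule)
  li <- match(spec$light_condition, LIGHT_LEVELS)
  tnorm <- (schedule$trial_number - 1) / max(n - 1, 1)
  right <- schedule$hemifield == "right"

  subj <- spec$subject_effects
  if (is.null(subj)) {
    subj <- list(
      rt_intercept = rnorm(1, 0, params$subject_sd[["intercept"]]),
      rt_hemifield = rnorm(1, 0, params$subject_sd[["hemifield"]]),
      rt_alpha = rnorm(1, 0, params$subject_sd[["alpha"]]),
      alpha_log = rnorm(1, 0, params$subject_alpha_sdlog)
    )
  }

  ## realised per-trial alpha amplitudes (sinusoid peak, microvolts):
  ## lognormal trial fluctuation with a common (bilateral) component
  ## and a hemisphere-specific remainder
  drift <- exp(params$tot_alpha_slope * tnorm)
  sdC <- params$alpha_trial_sdlog * sqrt(params$alpha_trial_cor)
  sdH <- params$alpha_trial_sdlog * sqrt(1 - params$alpha_trial_cor)
  zC <- rnorm(n, 0, sdC)
  ampL <- params$alpha_base * params$light_gain_left[li] *
    exp(subj$alpha_log + zC + rnorm(n, 0, sdH)) * drift
  ampR <- params$alpha_base * params$light_gain_right[li] *
    exp(subj$alpha_log + zC + rnorm(n, 0, sdH)) * drift
  envL <- 2 * ampL / pi      # mean of |A sin| over whole cycles
  envR <- 2 * ampR / pi
  laPooled <- log((envL + envR) / 2)
  laDev <- laPooled - mean(laPooled)

  slope <- params$alpha_rt_slope_ms[li] + subj$rt_alpha
  rt <- params$rt_intercept_ms +
    params$light_left_rt_effect_ms[li] * (!right) +
    (params$hemifield_offset_ms +
       params$tot_rt_interaction_ms * (0.5 - tnorm) +
       subj$rt_hemifield) * right +
    subj$rt_intercept + slope * laDev +
    rnorm(n, 0, params$resid_sd_ms)
  responded <- runif(n) >= params$miss_rate
  rt[!responded] <- NA_real_

  trials <- data.frame(
    session_id = sprintf("P%02d_%s", spec$participant_id,
                         spec$light_condition),
    participant_id = spec$participant_id,
    condition_order = spec$condition_order,
    light_condition = spec$light_condition,
    trial_number = schedule$trial_number,
    delay_s = schedule$delay_s,
    quadrant = schedule$quadrant,
    hemifield = schedule$hemifield,
    vertical_field = schedule$vertical_field,
    direction = schedule$direction,
    responded = responded,
    rt_ms = rt,
    env_left_true = envL,
    env_right_true = envR,
    log_alpha_pooled_true = laPooled,
    stringsAsFactors = FALSE
  )

  epochs <- NULL
  if (render_eeg) {
    pools <- candidatePools()
    if (!all(unlist(pools) %in% channels))
      stop("channel montage must include all 16 candidate electrodes")
    fs <- 500
    nSmp <- 950L
    tMs <- -700 + (seq_len(nSmp) - 1) * 1000 / fs
    arr <- synthNoise(n, length(channels), nSmp, fs, params$noise_exponent,
                      params$noise_sd_uv, params$n_noise_sources)
    ## hemisphere alpha sources: amplitude x desync profile x sinusoid
    phase <- matrix(runif(2L * n, 0, 2 * pi), n)
    wt <- 2 * pi * params$alpha_freq_hz / 1000
    prof <- desyncProfile(tMs, params$desync_depth)
    ones <- rep(1, nSmp)
    sinL <- sin(outer(phase[, 1L], ones) +
                  outer(rep(1, n), wt * tMs))
    sinR <- sin(outer(phase[, 2L], ones) +
                  outer(rep(1, n), wt * tMs))
    ## desync applies to the hemisphere contralateral to the target:
    ## left hemisphere for right-hemifield targets and vice versa
    profM <- outer(rep(1, n), prof)
    srcL <- ampL * ifelse(matrix(right, n, nSmp), profM, 1) * sinL
    srcR <- ampR * ifelse(matrix(!right, n, nSmp), profM, 1) * sinR
    weights <- setNames(numeric(length(channels)), channels)
    tr <- trueElectrodes()
    weights[unlist(pools)] <- 0.5
    weights[unlist(tr)] <- 1.0
    hemi <- setNames(rep(NA_character_, length(channels)), channels)
    hemi[pools$left] <- "left"
    hemi[pools$right] <- "right"
    for (ch in unlist(pools)) {
      k <- match(ch, channels)
      src <- if (hemi[ch] == "left") srcL else srcR
      arr[, k, ] <- arr[, k, ] + weights[ch] * src
    }
    epochs <- epochSet(arr, fs = fs, tStartMs = -700,
                       channelLabels = channels)
  }
  list(trials = trials, epochs = epochs)
}

#' Plan a full study (counterbalanced sessions and subject effects)
#'
#' Builds the per-session specifications of a study: counterbalanced
#' light-condition orders, per-session seeds derived from the master
#' seed, and by-subject random effects drawn once per participant.
#' Subject effects are centred across the participants of the study so
#' the calibrated condition means are the simulated grand truth (a
#' balanced-panel simulation choice; see the methods vignette).
#'
#' @param params a [generatorParams()].
#' @param n_participants number of participants (study default 24).
#' @param seed master integer seed.
#' @return A list of session specs, each suitable for
#'   [simulateSession()].
#' @export
studyPlan <- function(params = generatorParams(), n_participants = 24L,
                      seed = 1L) {
  specs <- sessionSpecs(n_participants)
  seeds <- deriveSeeds(seed, nrow(specs) + 4L)
  rng <- localRNG(seeds[length(seeds)])
  on.exit(rng())
  ctr <- function(x) x - mean(x)
  eff <- list(
    rt_intercept = ctr(rnorm(n_participants, 0,
                             params$subject_sd[["intercept"]])),
    rt_hemifield = ctr(rnorm(n_participants, 0,
                             params$subject_sd[["hemifield"]])),
    rt_alpha = ctr(rnorm(n_participants, 0, params$subject_sd[["alpha"]])),
    alpha_log = ctr(rnorm(n_participants, 0, params$subject_alpha_sdlog))
  )
  lapply(seq_len(nrow(specs)), function(i) {
    p <- specs$participant_id[i]
    list(participant_id = p,
         light_condition = specs$light_condition[i],
         condition_order = specs$condition_order[i],
         seed = seeds[i],
         subject_effects = list(rt_intercept = eff$rt_intercept[p],
                                rt_hemifield = eff$rt_hemifield[p],
                                rt_alpha = eff$rt_alpha[p],
                                alpha_log = eff$alpha_log[p]))
  })
}

#' Simulate the behavioural tables of a whole study
#'
#' Convenience wrapper running [simulateSession()] without EEG rendering
#' for every session of a counterbalanced study and binding the trial
#' tables.  For the full EEG path use [runPipeline()], which renders and
#' processes epochs one session at a time.
#'
#' @inheritParams studyPlan
#' @param config a [scheduleConfig()].
#' @return A data.frame of all trials (with ground-truth alpha columns).
#' @export
simulateStudy <- function(params = generatorParams(), n_participants = 24L,
                          seed = 1L, config = scheduleConfig()) {
  plan <- studyPlan(params, n_participants, seed)
  schedSeeds <- deriveSeeds(seed + 1L, length(plan))
  out <- lapply(seq_along(plan), function(i) {
    sch <- makeSchedule(config, seed = schedSeeds[i])
    simulateSession(plan[[i]], params, sch, render_eeg = FALSE)$trials
  })
  do.call(rbind, out)
}

#' Inject high-voltage artifacts into epochs
#'
#' Adds a 100 ms half-sine voltage transient with the given peak
#' amplitude to a seeded random fraction of trials, on one random
#' channel, at a random onset inside the pre-target -500..0 ms window.
#' Used to exercise the +/-100 microvolt artifact screen.
#'
#' @param epochs an [EpochSet-class].
#' @param rate fraction of trials to contaminate, in [0, 1].
#' @param amplitude_uv peak amplitude of the transient; values at or
#'   below 100 trigger a warning because the screen would not catch
#'   them.
#' @param seed integer seed.
#' @return A list with `epochs` (contaminated copy) and `contaminated`
#'   (sorted trial indices).
#' @export
injectArtifacts <- function(epochs, rate, amplitude_uv = 150, seed = 1L) {
  stopifnot(is(epochs, "EpochSet"), rate >= 0, rate <= 1)
  if (amplitude_uv <= 100)
    warning("artifact amplitude <= 100 microvolts would evade the ",
            "+/-100 microvolt screen")
  if (rate == 0)
    return(list(epochs = epochs, contaminated = integer(0)))
  rng <- localRNG(seed)
  on.exit(rng())
  n <- nTrials(epochs)
  hit <- which(runif(n) < rate)
  tt <- sampleTimes(epochs)
  durSmp <- round(0.1 * epochs@fs)          # 100 ms
  startable <- which(tt >= -500 & tt <= -100)
  arr <- epochs@voltages
  for (i in hit) {
    ch <- sample.int(nChannels(epochs), 1L)
    s0 <- sample(startable, 1L)
    idx <- s0:(s0 + durSmp - 1L)
    arr[i, ch, idx] <- arr[i, ch, idx] +
      amplitude_uv * sin(pi * seq(0, 1, length.out = durSmp))
  }
  list(epochs = epochSet(arr, fs = epochs@fs, tStartMs = epochs@tStartMs,
                         channelLabels = epochs@channelLabels,
                         baselineWindowMs = epochs@baselineWindowMs),
       contaminated = sort(hit))
}
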