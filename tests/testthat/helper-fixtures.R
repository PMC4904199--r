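## shared fixture builders (all data generated in code)

## generator with every stochastic nuisance switched off: pure alpha
## oscillation at fixed amplitude on the synthetic scalp
quietParams <- function(...) {
  args <- list(noise_sd_uv = 0, alpha_trial_sdlog = 0,
               subject_alpha_sdlog = 0, tot_alpha_slope = 0,
               desync_depth = 0,
               subject_sd = c(intercept = 0, hemifield = 0, alpha = 0),
               resid_sd_ms = 0, miss_rate = 0, artifact_rate = 0,
               light_gain_left = c(1, 1, 1),
               light_gain_right = c(1, 1, 1))
  do.call(generatorParams, utils::modifyList(args, list(...)))
}

## 16-channel montage (candidates only) keeps EEG rendering cheap
CAND16 <- unname(unlist(candidatePools()))

tinySession <- function(seed = 1, n_blocks = 1, params = quietParams(),
                        light = "low", channels = CAND16) {
  sch <- makeSchedule(scheduleConfig(n_blocks = n_blocks), seed = seed)
  simulateSession(list(participant_id = 1, light_condition = light,
                       condition_order = 1, seed = seed),
                  params, sch, channels = channels)
}

## epoch set with externally supplied voltages on a -700..1198 ms grid
rawEpochs <- function(voltages, labels = "O1") {
  epochSet(voltages, fs = 500, tStartMs = -700, channelLabels = labels)
}

## hand-built AlphaSeries on the standard -450..950 ms grid
handSeries <- function(values, labels) {
  out <- new("AlphaSeries", values = values,
             gridTimesMs = seq(-450, 950, by = 50),
             bandHz = c(8, 13), channelLabels = labels)
  attr(out, "winMs") <- 100
  out
}

## screened behavioural study table (no EEG): RT bounds + conditional
## outlier pass, mirroring the pipeline's screening for model tests
screenedStudy <- function(params = generatorParams(), n = 24, seed = 1) {
  d <- simulateStudy(params, n_participants = n, seed = seed)
  d$tnorm <- (d$trial_number - 1) / (max(d$trial_number) - 1)
  d <- d[d$responded & !is.na(d$rt_ms) & d$rt_ms >= 200 &
           d$rt_ms <= 1000, ]
  keep <- removeOutliers(d$rt_ms,
                         interaction(d$participant_id,
                                     d$light_condition))$kept
  d <- d[keep, ]
  d$hemi_left <- as.numeric(d$hemifield == "left")
  d$log_alpha_pooled <- d$log_alpha_pooled_true
  d$log_alpha_right <- log(d$env_right_true)
  d$log_alpha_left <- log(d$env_left_true)
  d
}
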