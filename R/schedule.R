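#' Trial-schedule configuration
#'
#' Describes the factorial trial structure of one session of the
#' lateralised random-dot-motion task: each trial type is a combination
#' of a pre-target incoherent-motion duration, a target quadrant and a
#' coherent-motion direction, and every type occurs a fixed number of
#' times inside every block.
#'
#' Defaults reproduce the study design: 3 delays x 4 quadrants x 2
#' directions = 24 trial types, each twice per 48-trial block, 7 blocks,
#' 336 trials per session.
#'
#' @param delays_s pre-target incoherent-motion durations in seconds.
#' @param quadrants target quadrant codes (upper/lower x left/right).
#' @param directions coherent-motion directions.
#' @param reps_per_block occurrences of each trial type per block.
#' @param n_blocks blocks per session.
#' @return A list of class `ScheduleConfig`.
#' @examples
#' cfg <- scheduleConfig()
#' cfg$block_length   # 48
#' @export
scheduleConfig <- function(delays_s = c(1.8, 2.8, 3.8),
                           quadrants = c("UL", "UR", "LL", "LR"),
                           directions = c("up", "down"),
                           reps_per_block = 2L,
                           n_blocks = 7L) {
  if (length(delays_s) != 3L) stop("exactly 3 delay durations required")
  if (length(quadrants) != 4L) stop("exactly 4 quadrants required")
  if (length(directions) != 2L) stop("exactly 2 motion directions required")
  if (reps_per_block != as.integer(reps_per_block) || reps_per_block < 1L)
    stop("reps_per_block must be a positive integer")
  if (n_blocks != as.integer(n_blocks) || n_blocks < 1L)
    stop("n_blocks must be a positive integer")
  structure(list(
    delays_s = delays_s, quadrants = quadrants, directions = directions,
    reps_per_block = as.integer(reps_per_block),
    n_blocks = as.integer(n_blocks),
    block_length = length(delays_s) * length(quadrants) *
      length(directions) * as.integer(reps_per_block)
  ), class = "ScheduleConfig")
}

#' Build a pseudorandom session schedule
#'
#' Generates the ordered trial list of one session under the design
#' constraint that every trial type occurs exactly `reps_per_block`
#' times in every consecutive block: types are replicated within each
#' block and the block order is a seeded permutation.
#'
#' @param config a [scheduleConfig()].
#' @param seed integer seed for the within-block permutations.
#' @return A data.frame with one row per trial: `trial_number`,
#'   `block`, `delay_s`, `quadrant`, `hemifield`, `vertical_field`,
#'   `direction`.  Hemifield and vertical field are derived from the
#'   quadrant (UL/LL -> left, UR/LR -> right; UL/UR -> upper).
#' @examples
#' sch <- makeSchedule(scheduleConfig(), seed = 1)
#' nrow(sch)                       # 336
#' table(sch$delay_s[1:48])        # 16 each within a block
#' @export
makeSchedule <- function(config = scheduleConfig(), seed = 1L) {
  stopifnot(inherits(config, "ScheduleConfig"))
  types <- expand.grid(delay_s = config$delays_s,
                       quadrant = config$quadrants,
                       direction = config$directions,
                       stringsAsFactors = FALSE)
  block <- types[rep(seq_len(nrow(types)), each = config$reps_per_block), ]
  rng <- localRNG(seed)
  on.exit(rng())
  out <- do.call(rbind, lapply(seq_len(config$n_blocks), function(b) {
    perm <- block[sample.int(nrow(block)), ]
    perm$block <- b
    perm
  }))
  rownames(out) <- NULL
  out$trial_number <- seq_len(nrow(out))
  out$hemifield <- ifelse(substr(out$quadrant, 2L, 2L) == "L",
                          "left", "right")
  out$vertical_field <- ifelse(substr(out$quadrant, 1L, 1L) == "U",
                               "upper", "lower")
  out[, c("trial_number", "block", "delay_s", "quadrant", "hemifield",
          "vertical_field", "direction")]
}

#' Dot-motion speed from per-frame displacement
#'
#' Coherently moving dots are displaced by a fixed angular distance each
#' frame; the resulting speed is displacement times frame rate.  At the
#' study's kinematics (0.282 degrees at 21.25 frames/s) this gives
#' 5.9925, reported rounded as 6 degrees/s.
#'
#' @param displacement_deg per-frame displacement, degrees of visual angle.
#' @param frame_rate frames per second.
#' @return Speed in degrees per second.
#' @examples
#' dotMotionSpeed(0.282, 21.25)
#' @export
dotMotionSpeed <- function(displacement_deg, frame_rate) {
  if (any(displacement_deg < 0) || any(frame_rate < 0))
    stop("displacement and frame rate must be non-negative")
  displacement_deg * frame_rate
}

#' Counterbalanced session specifications for a study
#'
#' Assigns each participant the three light conditions (low, medium,
#' high) in one of the six possible orders, cycling through the orders
#' so they are balanced across participants as evenly as divisibility
#' allows (exactly balanced at the study's 24 participants: 4 per
#' order).
#'
#' @param n_participants number of participants.
#' @return A data.frame with one row per session (participant x light
#'   condition): `participant_id`, `condition_order` (1..6),
#'   `session_index` (1..3, position within the participant's order),
#'   `light_condition`.
#' @examples
#' ss <- sessionSpecs(24)
#' nrow(ss)                      # 72 sessions
#' table(ss$condition_order) / 3 # 4 participants per order
#' @export
sessionSpecs <- function(n_participants = 24L) {
  orders <- list(c("low", "medium", "high"), c("low", "high", "medium"),
                 c("medium", "low", "high"), c("medium", "high", "low"),
                 c("high", "low", "medium"), c("high", "medium", "low"))
  out <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
    ord <- ((p - 1L) %% 6L) + 1L
    data.frame(participant_id = p, condition_order = ord,
               session_index = 1:3, light_condition = orders[[ord]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

## Run code under a private RNG state, restoring the caller's state.
localRNG <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

## Derive a stream of stage/session seeds (< 2^31) from one master seed.
deriveSeeds <- function(seed, n) {
  rng <- localRNG(seed)
  on.exit(rng())
  sample.int(.Machine$integer.max - 1L, n)
}
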