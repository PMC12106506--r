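#' Specify a simultaneity-judgment experimental design
#'
#' An SJ design presents audiovisual stimulus pairs at a fixed set of signed
#' stimulus onset asynchronies (SOAs). Each SOA is realized by delaying both
#' the auditory and the visual stimulus relative to a common event onset;
#' the signed SOA is the difference `audio_delay - video_delay`, so a
#' negative SOA means the auditory stimulus leads.
#'
#' @param soa_levels_ms Signed SOA levels in milliseconds. The default is the
#'   standard 14-level audiovisual schedule: +/-67, 100, 167, 200, 267, 334
#'   and 400 ms.
#' @param blocks_per_condition Number of blocks per condition (default 4).
#' @param trials_per_soa_per_block Trials at each SOA level within one block
#'   (default 4), giving `blocks * trials_per_soa_per_block` trials per level.
#' @param delay_min_ms,delay_max_ms Feasible range for each per-trial stimulus
#'   delay, in ms (defaults 200 and 600). Every `|SOA|` must fit inside
#'   `delay_max_ms - delay_min_ms`.
#' @param conditions Ordered condition labels, default `c("active", "passive")`.
#' @param rng_seed Integer seed controlling trial-order randomization and the
#'   per-trial leading-delay draws in [build_design()].
#'
#' @return An object of class `sj_design_spec` (a validated list).
#' @seealso [build_design()], [delays_for_soa()]
#' @export
#' @examples
#' spec <- design_spec()
#' design_summary(spec)
design_spec <- function(soa_levels_ms = c(-400L, -334L, -267L, -200L, -167L,
                                          -100L, -67L, 67L, 100L, 167L, 200L,
                                          267L, 334L, 400L),
                        blocks_per_condition = 4L,
                        trials_per_soa_per_block = 4L,
                        delay_min_ms = 200L,
                        delay_max_ms = 600L,
                        conditions = c("active", "passive"),
                        rng_seed = 1L) {
  soa_levels_ms <- as.integer(soa_levels_ms)
  if (anyDuplicated(soa_levels_ms)) {
    stop("SOA levels must be distinct", call. = FALSE)
  }
  if (blocks_per_condition < 1L || trials_per_soa_per_block < 1L) {
    stop("block and trial counts must be positive", call. = FALSE)
  }
  if (delay_min_ms < 0L || delay_max_ms <= delay_min_ms) {
    stop("need 0 <= delay_min_ms < delay_max_ms", call. = FALSE)
  }
  span <- delay_max_ms - delay_min_ms
  bad <- abs(soa_levels_ms) > span
  if (any(bad)) {
    stop(sprintf("infeasible SOA level(s) %s: |SOA| exceeds the delay span %d ms",
                 paste(soa_levels_ms[bad], collapse = ", "), span),
         call. = FALSE)
  }
  if (length(conditions) < 1L || anyDuplicated(conditions)) {
    stop("conditions must be distinct labels", call. = FALSE)
  }
  structure(
    list(soa_levels_ms = soa_levels_ms,
         blocks_per_condition = as.integer(blocks_per_condition),
         trials_per_soa_per_block = as.integer(trials_per_soa_per_block),
         delay_min_ms = as.integer(delay_min_ms),
         delay_max_ms = as.integer(delay_max_ms),
         conditions = as.character(conditions),
         rng_seed = as.integer(rng_seed)),
    class = "sj_design_spec"
  )
}

#' Apparatus delay calibration
#'
#' Constant reproduction delays of the playback chain, measured once per
#' apparatus, plus their trial-to-trial jitter. Commanded delays are assumed
#' to be compensated for the constants at design time; the calibration is
#' used only by the simulator's effective-onset path ([effective_onsets()]).
#'
#' @param audio_const_ms Constant auditory reproduction delay (default 170 ms).
#' @param audio_jitter_ms Auditory jitter half-width (default 5 ms).
#' @param video_const_ms Constant visual reproduction delay (default 150 ms).
#' @param video_jitter_ms Visual jitter half-width (default 8 ms).
#' @return An object of class `sj_calibration`.
#' @export
device_calibration <- function(audio_const_ms = 170, audio_jitter_ms = 5,
                               video_const_ms = 150, video_jitter_ms = 8) {
  vals <- c(audio_const_ms, audio_jitter_ms, video_const_ms, video_jitter_ms)
  if (any(vals < 0)) stop("calibration constants and jitters must be nonnegative",
                          call. = FALSE)
  structure(
    list(audio_const_ms = audio_const_ms, audio_jitter_ms = audio_jitter_ms,
         video_const_ms = video_const_ms, video_jitter_ms = video_jitter_ms),
    class = "sj_calibration"
  )
}

#' Audio/video delays realizing a target SOA
#'
#' The leading modality (audio when `target_soa_ms < 0`, video when positive)
#' receives `leading_delay_ms`; the lagging modality receives
#' `leading_delay_ms + |SOA|`. The returned pair always satisfies
#' `audio - video == target_soa_ms`. For example, a -200 ms SOA with a 200 ms
#' leading delay is realized as audio 200 ms, video 400 ms.
#'
#' @param target_soa_ms Signed SOA in ms (negative = auditory first).
#' @param leading_delay_ms Delay assigned to the leading modality, in ms. Must
#'   lie in `[delay_min_ms, delay_max_ms - |target_soa_ms|]`.
#' @param spec An [design_spec()] object supplying the feasible delay range.
#' @return Named numeric vector `c(audio_delay_ms, video_delay_ms)`.
#' @export
#' @examples
#' delays_for_soa(-200, 200)  # audio 200, video 400
delays_for_soa <- function(target_soa_ms, leading_delay_ms, spec = design_spec()) {
  stopifnot(inherits(spec, "sj_design_spec"))
  span <- spec$delay_max_ms - spec$delay_min_ms
  if (abs(target_soa_ms) > span) {
    stop(sprintf("SOA %d ms infeasible: |SOA| may not exceed delay span %d ms",
                 target_soa_ms, span), call. = FALSE)
  }
  lo <- spec$delay_min_ms
  hi <- spec$delay_max_ms - abs(target_soa_ms)
  if (leading_delay_ms < lo || leading_delay_ms > hi) {
    stop(sprintf("leading delay %s ms out of range: feasible interval is [%d, %d] ms for SOA %d ms",
                 format(leading_delay_ms), lo, hi, target_soa_ms), call. = FALSE)
  }
  if (target_soa_ms < 0) {
    audio <- leading_delay_ms
    video <- leading_delay_ms + abs(target_soa_ms)
  } else {
    video <- leading_delay_ms
    audio <- leading_delay_ms + abs(target_soa_ms)
  }
  c(audio_delay_ms = audio, video_delay_ms = video)
}

#' Build the trial list for one participant
#'
#' Generates `blocks_per_condition * trials_per_soa_per_block` trials per SOA
#' level per condition. Within each block every level appears
#' `trials_per_soa_per_block` times and the order is randomized, reproducibly
#' from `spec$rng_seed`. The per-trial leading delay is drawn uniformly on
#' the feasible integer interval `[delay_min, delay_max - |SOA|]`. Records
#' carry no responses (`response = NA`) and are not yet rejected.
#'
#' @param spec A [design_spec()].
#' @param participant_id Identifier stored in the `participant` column.
#' @return A `data.frame` of trial records with columns `participant`,
#'   `condition`, `block`, `trial`, `soa_ms`, `audio_delay_ms`,
#'   `video_delay_ms`, `response`, `rejected`.
#' @export
#' @examples
#' d <- build_design(design_spec())
#' nrow(d)  # 448 = 224 per condition
build_design <- function(spec = design_spec(), participant_id = "P01") {
  stopifnot(inherits(spec, "sj_design_spec"))
  withr::with_seed(spec$rng_seed, {
    out <- lapply(spec$conditions, function(cond) {
      blocks <- lapply(seq_len(spec$blocks_per_condition), function(b) {
        soas <- rep(spec$soa_levels_ms, each = spec$trials_per_soa_per_block)
        soas <- soas[sample.int(length(soas))]  # randomized order within block
        lead <- vapply(soas, function(s) {
          lo <- spec$delay_min_ms
          hi <- spec$delay_max_ms - abs(s)
          if (hi > lo) lo + sample.int(hi - lo + 1L, 1L) - 1L else lo
        }, integer(1))
        del <- t(mapply(delays_for_soa, soas, lead, MoreArgs = list(spec = spec)))
        data.frame(condition = cond, block = b, soa_ms = soas,
                   audio_delay_ms = del[, 1], video_delay_ms = del[, 2])
      })
      do.call(rbind, blocks)
    })
    out <- do.call(rbind, out)
  })
  out$trial <- stats::ave(seq_len(nrow(out)), out$condition, FUN = seq_along)
  data.frame(participant = participant_id,
             condition = out$condition,
             block = out$block,
             trial = out$trial,
             soa_ms = out$soa_ms,
             audio_delay_ms = out$audio_delay_ms,
             video_delay_ms = out$video_delay_ms,
             response = NA_integer_,
             rejected = FALSE)
}

#' Effective stimulus onsets under the apparatus calibration
#'
#' Adds the device's constant reproduction delay and a uniform jitter draw on
#' `[-jitter, +jitter]` (rounded to 0.1 ms) to each commanded delay. Used by
#' the simulator to perturb the effective SOA around the nominal level;
#' estimation always works on nominal SOA levels.
#'
#' @param trials Trial data frame from [build_design()].
#' @param calibration A [device_calibration()].
#' @param rng_seed Seed for the jitter draws.
#' @return `trials` with added columns `audio_onset_ms`, `video_onset_ms` and
#'   `effective_soa_ms` (= audio onset - video onset).
#' @export
effective_onsets <- function(trials, calibration = device_calibration(),
                             rng_seed = 1L) {
  stopifnot(inherits(calibration, "sj_calibration"))
  n <- nrow(trials)
  withr::with_seed(rng_seed, {
    ja <- round(stats::runif(n, -calibration$audio_jitter_ms,
                             calibration$audio_jitter_ms), 1)
    jv <- round(stats::runif(n, -calibration$video_jitter_ms,
                             calibration$video_jitter_ms), 1)
  })
  trials$audio_onset_ms <- trials$audio_delay_ms + calibration$audio_const_ms + ja
  trials$video_onset_ms <- trials$video_delay_ms + calibration$video_const_ms + jv
  trials$effective_soa_ms <- trials$audio_onset_ms - trials$video_onset_ms
  trials
}

#' Trial-count summary of a design
#'
#' @param spec A [design_spec()].
#' @return A list with the number of SOA levels, trials per SOA, trials per
#'   condition, and total trials in the session (all conditions).
#' @export
design_summary <- function(spec = design_spec()) {
  per_soa <- spec$blocks_per_condition * spec$trials_per_soa_per_block
  n_levels <- length(spec$soa_levels_ms)
  list(n_soa_levels = n_levels,
       trials_per_soa = per_soa,
       trials_per_condition = n_levels * per_soa,
       trials_total = n_levels * per_soa * length(spec$conditions))
}
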