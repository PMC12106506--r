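# Shared fixtures, built in code.

default_soas <- c(-400, -334, -267, -200, -167, -100, -67,
                  67, 100, 167, 200, 267, 334, 400)

# Minimal trial frame: n trials per SOA, k of them "simultaneous", in the
# trial-log dialect (delays filled with a feasible constant-lead realization).
trials_from_counts <- function(soa, k, n, participant = "P01",
                               condition = "active") {
  stopifnot(length(soa) == length(k), length(soa) == length(n), all(k <= n))
  rows <- do.call(rbind, lapply(seq_along(soa), function(i) {
    del <- delays_for_soa(soa[i], 200)
    data.frame(soa_ms = soa[i],
               audio_delay_ms = del[[1]], video_delay_ms = del[[2]],
               response = c(rep(1L, k[i]), rep(0L, n[i] - k[i])))
  }))
  data.frame(participant = participant, condition = condition,
             block = 1L, trial = seq_len(nrow(rows)),
             soa_ms = rows$soa_ms,
             audio_delay_ms = rows$audio_delay_ms,
             video_delay_ms = rows$video_delay_ms,
             response = rows$response, rejected = FALSE)
}

# Unanswered design-like frame with n_per trials at each SOA level.
design_frame <- function(soa_levels = default_soas, n_per = 16,
                         participant = "P01", condition = "active") {
  rows <- do.call(rbind, lapply(soa_levels, function(s) {
    del <- delays_for_soa(s, 200)
    data.frame(soa_ms = rep(s, n_per),
               audio_delay_ms = del[[1]], video_delay_ms = del[[2]])
  }))
  data.frame(participant = participant, condition = condition,
             block = 1L, trial = seq_len(nrow(rows)),
             soa_ms = rows$soa_ms,
             audio_delay_ms = rows$audio_delay_ms,
             video_delay_ms = rows$video_delay_ms,
             response = NA_integer_, rejected = FALSE)
}

# Simulate one session from an exact two-sided logistic observer.
synth_session <- function(c_av = 240.76, c_va = 119.53,
                          slope_av = 0.015, slope_va = 0.015,
                          n_per_soa = 16, seed = 1,
                          soa_levels = default_soas,
                          participant = "P01", condition = "active", ...) {
  obs <- observer_params(c_av, c_va, slope_av, slope_va, ...)
  simulate_session(design_frame(soa_levels, n_per_soa, participant, condition),
                   obs, rng_seed = seed)
}
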