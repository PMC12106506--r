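#' Run configuration for the full analysis pipeline
#'
#' Bundles the design, population, fitting, and statistics options with a
#' master seed. The defaults reproduce the reference study setup: 17
#' participants, active/passive conditions, 14 SOA levels x 16 trials,
#' one-tailed power protocol at dz = 0.95.
#'
#' @param design A [design_spec()].
#' @param calibration A [device_calibration()].
#' @param population A [population_spec()].
#' @param link Psychometric link (`"logit"` default).
#' @param min_slope Minimum usable fitted slope, per ms.
#' @param soa_range Measured SOA magnitude range for extrapolation flags.
#' @param tails Tails of the power protocol (`"one"` default).
#' @param power_d,power_alpha,power_target Power-protocol inputs.
#' @param seed Master seed for simulation.
#' @return An object of class `sj_run_config`.
#' @export
run_config <- function(design = design_spec(),
                       calibration = device_calibration(),
                       population = population_spec(),
                       link = "logit",
                       min_slope = 1e-4,
                       soa_range = c(67, 400),
                       tails = "one",
                       power_d = 0.95, power_alpha = 0.05, power_target = 0.95,
                       seed = 1L) {
  structure(list(design = design, calibration = calibration,
                 population = population, link = link, min_slope = min_slope,
                 soa_range = soa_range, tails = tails,
                 power_d = power_d, power_alpha = power_alpha,
                 power_target = power_target, seed = as.integer(seed)),
            class = "sj_run_config")
}

config_hash <- function(config) {
  # stable content digest over the deparsed config, no external deps
  txt <- paste(deparse(config, control = "all"), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %% 4294967291)
}

#' Group-level inference on a cohort's TBW estimates
#'
#' Runs the standard SJ inferential battery on a two-condition estimates
#' table: paired t-tests (first vs second condition) on the AV side, VA side,
#' total width, and peak amplitude; the auditory-shift test (AV vs VA side)
#' within each condition; and the 2x2 within-subject ANOVA
#' (condition x side). Participants lacking a usable estimate in either
#' condition are dropped listwise, with the count reported.
#'
#' @param estimates Output of [estimate_cohort()] with exactly two conditions.
#' @return A list with `tests` (data frame of paired tests), `anova`
#'   (an [rm_anova_2x2()] result), `n_used`, `n_dropped`.
#' @export
analyze_cohort <- function(estimates) {
  conds <- unique(estimates$condition)
  if (length(conds) != 2L) stop("need exactly two conditions", call. = FALSE)
  wide <- merge(estimates[estimates$condition == conds[1], ],
                estimates[estimates$condition == conds[2], ],
                by = "participant", suffixes = c("_1", "_2"))
  ok <- wide$usable_1 %in% TRUE & wide$usable_2 %in% TRUE
  n_dropped <- sum(!ok) + length(setdiff(unique(estimates$participant),
                                         wide$participant))
  wide <- wide[ok, ]
  if (nrow(wide) < 2L) stop("fewer than 2 participants with usable estimates in both conditions",
                            call. = FALSE)

  row_of <- function(label, res) {
    data.frame(comparison = label, t = res$t, df = res$df, p = res$p,
               cohens_d = res$d, n = res$n,
               mean_diff = res$mean_diff, sd_diff = res$sd_diff)
  }
  tests <- rbind(
    row_of(sprintf("av: %s - %s", conds[1], conds[2]),
           paired_t(wide$av_ms_1, wide$av_ms_2)),
    row_of(sprintf("va: %s - %s", conds[1], conds[2]),
           paired_t(wide$va_ms_1, wide$va_ms_2)),
    row_of(sprintf("width: %s - %s", conds[1], conds[2]),
           paired_t(wide$width_ms_1, wide$width_ms_2)),
    row_of(sprintf("peak: %s - %s", conds[1], conds[2]),
           paired_t(wide$peak_1, wide$peak_2)),
    row_of(sprintf("shift %s: av - va", conds[1]),
           paired_t(wide$av_ms_1, wide$va_ms_1)),
    row_of(sprintf("shift %s: av - va", conds[2]),
           paired_t(wide$av_ms_2, wide$va_ms_2))
  )
  long <- rbind(
    data.frame(subject = wide$participant, a = conds[1], b = "av", value = wide$av_ms_1),
    data.frame(subject = wide$participant, a = conds[1], b = "va", value = wide$va_ms_1),
    data.frame(subject = wide$participant, a = conds[2], b = "av", value = wide$av_ms_2),
    data.frame(subject = wide$participant, a = conds[2], b = "va", value = wide$va_ms_2)
  )
  aov2 <- rm_anova_2x2(long)
  list(tests = tests, anova = aov2, n_used = nrow(wide), n_dropped = n_dropped)
}

#' Run the full pipeline: simulate, fit, analyze, report
#'
#' Simulates a cohort from the configured population (or ingests an existing
#' trial log), estimates every participant's TBW, computes group summaries
#' and the inferential battery, and writes all tables plus a run log to
#' `outdir`. The whole bundle is a pure function of `(config, seed)`.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @param trials Optional pre-existing trial data frame; when supplied, the
#'   simulation stage is skipped and `config$population` is ignored.
#' @return Invisibly, a list with `trials`, `estimates`, `group`, `analysis`,
#'   `power_n`, `paths`.
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("sj_run_"),
                         trials = NULL) {
  stopifnot(inherits(config, "sj_run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  paths <- list(trials = file.path(outdir, "trials.csv"),
                estimates = file.path(outdir, "estimates.tsv"),
                group = file.path(outdir, "group_summary.tsv"),
                tests = file.path(outdir, "stats_tests.tsv"),
                anova = file.path(outdir, "stats_anova.tsv"),
                log = file.path(outdir, "run_log.txt"))
  log_lines <- c(sprintf("config_hash: %s", hash),
                 sprintf("seed: %d", config$seed))

  if (is.null(trials)) {
    sim <- simulate_cohort(config$population, config$design,
                           rng_seed = config$seed)
    trials <- sim$trials
    log_lines <- c(log_lines, sprintf("simulated participants: %d",
                                      config$population$n_participants))
  }
  write_trials(trials, paths$trials)
  log_lines <- c(log_lines,
                 sprintf("trials: %d (%d rejected)", nrow(trials),
                         sum(trials$rejected)))

  estimates <- estimate_cohort(trials, link = config$link,
                               min_slope = config$min_slope,
                               soa_range = config$soa_range)
  estimates$config_hash <- hash
  write_tsv(estimates, paths$estimates)
  log_lines <- c(log_lines,
                 sprintf("estimates: %d usable of %d sessions",
                         sum(estimates$usable), nrow(estimates)))

  group <- group_tbw(estimates)
  group$config_hash <- hash
  write_tsv(group, paths$group)

  analysis <- analyze_cohort(estimates)
  analysis$tests$config_hash <- hash
  write_tsv(analysis$tests, paths$tests)
  av <- as.data.frame(analysis$anova)
  av$config_hash <- hash
  write_tsv(av, paths$anova)
  log_lines <- c(log_lines,
                 sprintf("analysis: n_used %d, n_dropped %d",
                         analysis$n_used, analysis$n_dropped))

  power_n <- required_n(config$power_d, config$power_alpha,
                        config$power_target, config$tails)
  log_lines <- c(log_lines,
                 sprintf("power protocol (%s-tailed, dz = %g, alpha = %g, target %g): N = %d",
                         config$tails, config$power_d, config$power_alpha,
                         config$power_target, power_n))
  writeLines(log_lines, paths$log)
  invisible(list(trials = trials, estimates = estimates, group = group,
                 analysis = analysis, power_n = power_n, paths = paths))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
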