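#' Psychometric parameters of one synthetic observer
#'
#' A two-sided observer for the SJ task: the probability of reporting
#' "simultaneous" rises logistically toward synchrony on the audio-leading
#' (AV, negative SOA) side and falls logistically on the visual-leading
#' (VA, positive SOA) side. `c_av_ms` and `c_va_ms` are the magnitudes of the
#' 50% crossings of the two sides; `guess` and `lapse` are stimulus-
#' independent floor/ceiling rates that compress the curve into
#' `[guess, 1 - lapse]`.
#'
#' @param c_av_ms,c_va_ms Positive crossing magnitudes in ms.
#' @param slope_av,slope_va Positive logistic slopes per ms.
#' @param lapse,guess Rates in `[0, 0.5)` with `1 - guess - lapse > 0`.
#' @return An object of class `sj_observer`.
#' @export
observer_params <- function(c_av_ms, c_va_ms, slope_av, slope_va,
                            lapse = 0, guess = 0) {
  if (c_av_ms <= 0 || c_va_ms <= 0) stop("crossings must be positive", call. = FALSE)
  if (slope_av <= 0 || slope_va <= 0) stop("slopes must be positive", call. = FALSE)
  if (lapse < 0 || lapse >= 0.5 || guess < 0 || guess >= 0.5) {
    stop("lapse and guess must lie in [0, 0.5)", call. = FALSE)
  }
  structure(list(c_av_ms = c_av_ms, c_va_ms = c_va_ms,
                 slope_av = slope_av, slope_va = slope_va,
                 lapse = lapse, guess = guess),
            class = "sj_observer")
}

#' Probability of a "simultaneous" response
#'
#' Piecewise-logistic psychometric function:
#' `p = guess + (1 - guess - lapse) * core`, where for `soa < 0` (audio leads)
#' `core = plogis(slope_av * (soa + c_av))` and for `soa >= 0` (visual leads)
#' `core = plogis(-slope_va * (soa - c_va))`. With `guess = lapse = 0` the
#' function equals 0.5 exactly at `soa = -c_av` and `soa = +c_va`, so the
#' generative crossings coincide with the 50% estimation criterion.
#'
#' @param soa_ms Signed SOA(s) in ms.
#' @param params An [observer_params()] object.
#' @return Probabilities in (0, 1), same length as `soa_ms`.
#' @export
#' @examples
#' obs <- observer_params(240, 120, 0.02, 0.02)
#' p_synchronous(c(-240, 120), obs)  # both 0.5
p_synchronous <- function(soa_ms, params) {
  stopifnot(inherits(params, "sj_observer"))
  core <- ifelse(soa_ms < 0,
                 stats::plogis(params$slope_av * (soa_ms + params$c_av_ms)),
                 stats::plogis(-params$slope_va * (soa_ms - params$c_va_ms)))
  params$guess + (1 - params$guess - params$lapse) * core
}

#' Population of synthetic observers
#'
#' Defines, per condition, the population mean and SD of the AV and VA
#' crossing magnitudes, plus shared slope/lapse/guess distributions and the
#' trial-rejection regime. The defaults are the group statistics of a
#' published talk-versus-listen SJ study (17 participants; active AV
#' 240.76/100.71, active VA 119.53/91.45, passive AV 259/79.13, passive VA
#' 222.41/82.97 ms; 7 participants losing 1-26 active trials), so a cohort
#' simulated from the default spec emulates that study's conditions.
#'
#' Crossings are drawn from zero-truncated normal distributions whose
#' realized (post-truncation) mean and SD equal the stated values; the parent
#' parameters are solved by moment matching. Across conditions, a
#' participant's crossings are coupled through a Gaussian copula with
#' correlation `rho`.
#'
#' @param mean_c Named list per condition, each a vector `c(av = , va = )` of
#'   crossing means in ms.
#' @param sd_c Same shape, crossing SDs in ms.
#' @param n_participants Cohort size (default 17).
#' @param rho Within-participant cross-condition correlation of crossings
#'   (default 0.5).
#' @param slope_meanlog,slope_sdlog Lognormal parameters of the per-
#'   participant-side logistic slope, per ms (defaults `log(0.015)` and 0.3).
#' @param lapse,guess Shared rates for all observers (defaults 0, so the
#'   generative 50% crossings equal `c_av`/`c_va` exactly).
#' @param rejected_participants Number of participants with rejected active-
#'   condition trials; defaults to `min(7, n_participants)`, matching
#'   reference cohorts of 17 in which 7 participants lose trials.
#' @param rejected_range Integer range of rejected trial counts for those
#'   participants (default `c(1, 26)`).
#' @param rng_seed Integer seed.
#' @return An object of class `sj_population`.
#' @export
population_spec <- function(mean_c = list(active  = c(av = 240.76, va = 119.53),
                                          passive = c(av = 259.00, va = 222.41)),
                            sd_c   = list(active  = c(av = 100.71, va = 91.45),
                                          passive = c(av = 79.13,  va = 82.97)),
                            n_participants = 17L,
                            rho = 0.5,
                            slope_meanlog = log(0.015),
                            slope_sdlog = 0.3,
                            lapse = 0, guess = 0,
                            rejected_participants = NULL,
                            rejected_range = c(1L, 26L),
                            rng_seed = 1L) {
  conds <- names(mean_c)
  if (is.null(conds) || !identical(conds, names(sd_c))) {
    stop("mean_c and sd_c must be named lists over the same conditions",
         call. = FALSE)
  }
  for (cn in conds) {
    if (any(mean_c[[cn]] <= 0)) stop("crossing means must be positive", call. = FALSE)
    if (any(sd_c[[cn]] < 0)) stop("crossing SDs must be nonnegative", call. = FALSE)
    # a zero-truncated normal cannot have SD >= mean (its CV is below 1)
    pos <- sd_c[[cn]] > 0
    if (any(sd_c[[cn]][pos] >= mean_c[[cn]][pos])) {
      stop(sprintf("condition '%s': crossing SD must be smaller than the mean for a zero-truncated normal",
                   cn), call. = FALSE)
    }
  }
  if (n_participants < 1L) stop("n_participants must be positive", call. = FALSE)
  if (is.null(rejected_participants)) {
    rejected_participants <- min(7L, n_participants)
  }
  if (rho < -1 || rho > 1) stop("rho must lie in [-1, 1]", call. = FALSE)
  if (rejected_participants > n_participants) {
    stop("rejected_participants cannot exceed n_participants", call. = FALSE)
  }
  structure(list(mean_c = mean_c, sd_c = sd_c,
                 conditions = conds,
                 n_participants = as.integer(n_participants),
                 rho = rho,
                 slope_meanlog = slope_meanlog, slope_sdlog = slope_sdlog,
                 lapse = lapse, guess = guess,
                 rejected_participants = as.integer(rejected_participants),
                 rejected_range = as.integer(rejected_range),
                 rng_seed = as.integer(rng_seed)),
            class = "sj_population")
}

# Moments of a normal(mu, sigma) truncated to (0, Inf).
truncnorm0_moments <- function(mu, sigma) {
  a <- -mu / sigma
  lam <- exp(stats::dnorm(a, log = TRUE) -
             stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + a * lam - lam^2)
  c(mean = m, sd = sqrt(v))
}

# Parent (mu, sigma) whose zero-truncated normal has the target mean/sd.
truncnorm0_parent <- function(target_mean, target_sd) {
  if (target_sd == 0) return(c(mu = target_mean, sigma = 0))
  obj <- function(p) {
    mm <- truncnorm0_moments(p[1], exp(p[2]))
    sum(((mm - c(target_mean, target_sd)) / c(target_mean, target_sd))^2)
  }
  o <- stats::optim(c(target_mean, log(target_sd)), obj,
                    control = list(reltol = 1e-15, maxit = 10000))
  if (o$value > 1e-8) {
    stop(sprintf("cannot moment-match a zero-truncated normal to mean %.3g, sd %.3g",
                 target_mean, target_sd), call. = FALSE)
  }
  c(mu = o$par[1], sigma = exp(o$par[2]))
}

# Inverse CDF of the zero-truncated normal, u in (0,1).
qtruncnorm0 <- function(u, mu, sigma) {
  if (sigma == 0) return(rep(mu, length(u)))
  p0 <- stats::pnorm(0, mu, sigma)
  stats::qnorm(p0 + u * (1 - p0), mu, sigma)
}

#' Draw a cohort of observer parameters
#'
#' For each side (AV, VA), the per-participant crossings across conditions
#' are a Gaussian copula with correlation `rho` over exact zero-truncated-
#' normal margins whose realized moments equal the spec's means/SDs. Slopes
#' are independent lognormal draws per participant, condition, and side.
#'
#' @param pop A [population_spec()].
#' @param rng_seed Seed; defaults to the spec's.
#' @return A data frame with one row per participant x condition and columns
#'   `participant`, `condition`, `c_av_ms`, `c_va_ms`, `slope_av`,
#'   `slope_va`, `lapse`, `guess`.
#' @export
sample_population <- function(pop = population_spec(), rng_seed = pop$rng_seed) {
  stopifnot(inherits(pop, "sj_population"))
  n <- pop$n_participants
  conds <- pop$conditions
  k <- length(conds)
  # copula correlation matrix across conditions
  R <- matrix(pop$rho, k, k); diag(R) <- 1
  L <- chol(R)
  draw_side <- function(side) {
    z <- matrix(stats::rnorm(n * k), n, k) %*% L
    u <- stats::pnorm(z)
    out <- matrix(NA_real_, n, k)
    for (j in seq_len(k)) {
      par <- truncnorm0_parent(pop$mean_c[[conds[j]]][[side]],
                               pop$sd_c[[conds[j]]][[side]])
      out[, j] <- qtruncnorm0(u[, j], par[["mu"]], par[["sigma"]])
    }
    out
  }
  withr::with_seed(rng_seed, {
    c_av <- draw_side("av")
    c_va <- draw_side("va")
    s_av <- matrix(stats::rlnorm(n * k, pop$slope_meanlog, pop$slope_sdlog), n, k)
    s_va <- matrix(stats::rlnorm(n * k, pop$slope_meanlog, pop$slope_sdlog), n, k)
  })
  ids <- sprintf("P%02d", seq_len(n))
  do.call(rbind, lapply(seq_len(k), function(j) {
    data.frame(participant = ids, condition = conds[j],
               c_av_ms = c_av[, j], c_va_ms = c_va[, j],
               slope_av = s_av[, j], slope_va = s_va[, j],
               lapse = pop$lapse, guess = pop$guess)
  }))
}

#' Simulate responses for one session
#'
#' Each unanswered trial gets a Bernoulli response with success probability
#' [p_synchronous()] at its nominal SOA; `rejection_count` trials are then
#' flagged rejected, chosen uniformly at random (emulating microphone
#' failures). Responses on rejected trials are retained in the record but
#' excluded from all downstream rate and fit computations.
#'
#' @param design Trial data frame for one participant x condition
#'   ([build_design()] subset), responses absent.
#' @param params An [observer_params()] object (or one row of
#'   [sample_population()]).
#' @param rejection_count Number of trials to flag rejected (default 0).
#' @param rng_seed Seed for the response and rejection draws.
#' @param use_effective_soa If `TRUE`, responses are generated at the
#'   calibration-perturbed effective SOA instead of the nominal level.
#' @param calibration Calibration used when `use_effective_soa = TRUE`.
#' @return The design with `response` filled and `rejected` set.
#' @export
simulate_session <- function(design, params, rejection_count = 0L,
                             rng_seed = 1L, use_effective_soa = FALSE,
                             calibration = device_calibration()) {
  if (is.data.frame(params)) {
    stopifnot(nrow(params) == 1L)
    params <- observer_params(params$c_av_ms, params$c_va_ms,
                              params$slope_av, params$slope_va,
                              params$lapse, params$guess)
  }
  n <- nrow(design)
  if (rejection_count >= n) {
    stop("rejection_count must be smaller than the number of trials", call. = FALSE)
  }
  if (any(!is.na(design$response))) {
    stop("design already carries responses", call. = FALSE)
  }
  soa <- design$soa_ms
  if (use_effective_soa) {
    design2 <- effective_onsets(design, calibration, rng_seed = rng_seed + 1L)
    soa <- design2$effective_soa_ms
  }
  p <- p_synchronous(soa, params)
  withr::with_seed(rng_seed, {
    design$response <- stats::rbinom(n, 1L, p)
    if (rejection_count > 0L) {
      design$rejected[sample.int(n, rejection_count)] <- TRUE
    }
  })
  design
}

#' Simulate a full cohort
#'
#' Draws observer parameters from the population spec, builds one design per
#' participant (trial order re-randomized per participant), and simulates
#' every session. `rejected_participants` participants, chosen at random,
#' lose a uniform number of trials in `rejected_range` from the first
#' condition (the active one by default), mirroring apparatus losses.
#'
#' @param pop A [population_spec()].
#' @param spec A [design_spec()].
#' @param rng_seed Master seed; all per-participant seeds derive from it.
#' @return A list with `trials` (long trial data frame across the cohort) and
#'   `truth` (the generative parameter table from [sample_population()]).
#' @export
simulate_cohort <- function(pop = population_spec(), spec = design_spec(),
                            rng_seed = pop$rng_seed) {
  stopifnot(inherits(pop, "sj_population"), inherits(spec, "sj_design_spec"))
  truth <- sample_population(pop, rng_seed = rng_seed)
  n <- pop$n_participants
  ids <- sprintf("P%02d", seq_len(n))
  withr::with_seed(rng_seed + 1L, {
    rej_ids <- if (pop$rejected_participants > 0L)
      sample(ids, pop$rejected_participants) else character(0)
    rej_counts <- stats::setNames(integer(n), ids)
    if (length(rej_ids)) {
      rej_counts[rej_ids] <- sample(seq(pop$rejected_range[1], pop$rejected_range[2]),
                                    length(rej_ids), replace = TRUE)
    }
  })
  rejected_condition <- pop$conditions[1]
  sessions <- list()
  for (i in seq_len(n)) {
    dspec <- spec
    dspec$rng_seed <- (spec$rng_seed + 7919L * i) %% 2147483647L
    des <- build_design(dspec, participant_id = ids[i])
    for (cond in pop$conditions) {
      prow <- truth[truth$participant == ids[i] & truth$condition == cond, ]
      rc <- if (cond == rejected_condition) rej_counts[[ids[i]]] else 0L
      ses <- simulate_session(des[des$condition == cond, ], prow,
                              rejection_count = rc,
                              rng_seed = (rng_seed + 104729L * i +
                                          match(cond, pop$conditions)) %% 2147483647L)
      sessions[[length(sessions) + 1L]] <- ses
    }
  }
  trials <- do.call(rbind, sessions)
  rownames(trials) <- NULL
  list(trials = trials, truth = truth)
}
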