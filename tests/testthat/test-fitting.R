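test_that("compute_rates counts valid trials only", {
  tr <- trials_from_counts(-200, k = 8, n = 16)
  r <- compute_rates(tr)
  expect_equal(r$rate, 0.5)
  expect_equal(r$n_valid, 16)

  # two rejected, 7 of the remaining 14 synchronous -> rate 0.5 at n_valid 14
  tr2 <- trials_from_counts(-200, k = 7, n = 16)
  tr2$rejected[tr2$response == 0][1:2] <- TRUE
  r2 <- compute_rates(tr2)
  expect_equal(r2$n_valid, 14)
  expect_equal(r2$rate, 0.5)

  # saturation
  tr3 <- trials_from_counts(c(-100, 100), k = c(16, 16), n = c(16, 16))
  expect_true(all(compute_rates(tr3)$rate == 1))

  # rates are invariant to trial order
  set.seed(2)
  ses <- synth_session(seed = 4)
  shuffled <- ses[sample(nrow(ses)), ]
  expect_equal(compute_rates(shuffled), compute_rates(ses),
               ignore_attr = "row.names")

  expect_error(compute_rates(ses[0, ]), "no trials")
  lost <- trials_from_counts(c(-100, 100, 200), k = c(4, 4, 4), n = c(8, 8, 8))
  lost$rejected[lost$soa_ms == 200] <- TRUE
  expect_warning(r4 <- compute_rates(lost), "all trials rejected")
  expect_false(200 %in% r4$soa_ms)
})

test_that("fit_side recovers generative logit coefficients on big samples", {
  # truth: AV side, b1 = 0.02, b0 = 4.8152 (crossing at -240.76 ms)
  ses <- synth_session(c_av = 240.76, c_va = 119.53,
                       slope_av = 0.02, slope_va = 0.02,
                       n_per_soa = 10000, seed = 21)
  f <- fit_side(ses, "av")
  # independent SE oracle from a direct glm on the same aggregated data
  av <- ses[ses$soa_ms < 0, ]
  rt <- compute_rates(av)
  g <- glm(cbind(n_synchronous, n_valid - n_synchronous) ~ soa_ms,
           family = binomial, data = rt)
  se <- sqrt(diag(vcov(g)))
  expect_lt(abs(f$b0 - 4.8152), 3 * se[1])
  expect_lt(abs(f$b1 - 0.02), 3 * se[2])
  expect_false(f$penalized)
  expect_gt(f$b1, 0)             # AV side rises toward synchrony
  expect_lt(fit_side(ses, "va")$b1, 0)  # VA side falls away from it
})

test_that("side fits on aggregated counts equal trial-level binomial fits", {
  ses <- synth_session(n_per_soa = 16, seed = 31)
  for (side in c("av", "va")) {
    sub <- ses[if (side == "av") ses$soa_ms < 0 else ses$soa_ms > 0, ]
    g <- glm(response ~ soa_ms, family = binomial, data = sub)
    f <- fit_side(ses, side)
    expect_equal(f$b0, unname(coef(g)[1]), tolerance = 1e-8)
    expect_equal(f$b1, unname(coef(g)[2]), tolerance = 1e-8)
  }
})

test_that("both-side comparison fits and the probit link are available", {
  ses <- synth_session(n_per_soa = 32, seed = 77)
  f <- fit_side(ses, "va", include_other_side = TRUE)
  expect_true(f$both_sides)
  expect_equal(f$n_trials, nrow(ses))
  fp <- fit_side(ses, "va", link = "probit")
  expect_equal(fp$link, "probit")
  # same crossing estimate to within a few ms across links
  expect_lt(abs(as.numeric(crossing_ms(fp)) -
                  as.numeric(crossing_ms(fit_side(ses, "va")))), 10)
})

test_that("flat data give a near-zero slope and no usable crossing", {
  soas <- default_soas[default_soas < 0]
  tr <- trials_from_counts(soas, k = rep(8, 7), n = rep(16, 7))
  f <- fit_side(tr, "av")
  expect_lt(abs(f$b1), 1e-8)
  expect_error(crossing_ms(f), class = "tbw_no_crossing")
})

test_that("separated sides get a finite Jeffreys-penalized fit", {
  soas <- default_soas[default_soas < 0]
  all_one <- trials_from_counts(soas, k = rep(16, 7), n = rep(16, 7))
  f <- fit_side(all_one, "av")
  expect_true(f$penalized)
  expect_true(is.finite(f$b0) && is.finite(f$b1))

  # perfectly separated step data
  step <- trials_from_counts(soas, k = c(0, 0, 0, 16, 16, 16, 16),
                             n = rep(16, 7))
  fs <- fit_side(step, "av")
  expect_true(fs$penalized)
  expect_true(is.finite(fs$b0) && is.finite(fs$b1))
  # the penalized crossing sits inside the separating gap
  cr <- crossing_ms(fs)
  expect_gt(as.numeric(cr), 167)
  expect_lt(as.numeric(cr), 267)
})

test_that("fit_side requires two SOA levels per side", {
  one <- trials_from_counts(-100, 8, 16)
  expect_error(fit_side(one, "av"), ">= 2 distinct SOA levels")
  expect_error(fit_side(one, "va"), "no valid trials")
})

test_that("crossing_ms equals the closed form and flags extrapolation", {
  mkfit <- function(b0, b1, side = "va") {
    structure(list(side = side, b0 = b0, b1 = b1, n_trials = 100,
                   n_levels = 7, converged = TRUE, penalized = FALSE,
                   link = "logit"), class = "sigmoid_fit")
  }
  c0 <- crossing_ms(mkfit(0, 0.01, "av"))
  expect_equal(as.numeric(c0), 0)
  expect_true(attr(c0, "extrapolated"))
  c200 <- crossing_ms(mkfit(2, -0.01))
  expect_equal(as.numeric(c200), 200)
  expect_false(attr(c200, "extrapolated"))
  expect_true(attr(crossing_ms(mkfit(5, -0.01)), "extrapolated"))  # 500 ms
})

test_that("estimate_tbw assembles width, asymmetry, and peak coherently", {
  ses <- synth_session(c_av = 240, c_va = 120, n_per_soa = 400, seed = 17)
  est <- estimate_tbw(ses)
  expect_equal(est$width_ms, est$av_ms + est$va_ms)
  expect_equal(est$asymmetry_ms, est$av_ms - est$va_ms)
  expect_equal(est$peak, max(plogis(est$fits$av$b0), plogis(est$fits$va$b0)))
  expect_true(est$peak >= 0 && est$peak <= 1)
  # recovery of the generative crossings at 400 trials/SOA
  expect_lt(abs(est$av_ms - 240), 15)
  expect_lt(abs(est$va_ms - 120), 15)

  # symmetric observer: asymmetry ~ 0
  sym <- synth_session(c_av = 200, c_va = 200, n_per_soa = 1000, seed = 18)
  expect_lt(abs(estimate_tbw(sym)$asymmetry_ms), 12)

  # flat data on one side -> TBW unavailable
  soas <- default_soas
  flat <- trials_from_counts(soas, k = rep(8, 14), n = rep(16, 14))
  expect_error(estimate_tbw(flat), class = "tbw_unavailable")
})

test_that("mirroring the SOA axis swaps the window sides exactly", {
  ses <- synth_session(c_av = 260, c_va = 110, n_per_soa = 64, seed = 23)
  est <- estimate_tbw(ses)
  mir <- ses
  mir$soa_ms <- -mir$soa_ms
  est_m <- estimate_tbw(mir)
  expect_equal(est_m$av_ms, est$va_ms, tolerance = 1e-10)
  expect_equal(est_m$va_ms, est$av_ms, tolerance = 1e-10)
  expect_equal(est_m$asymmetry_ms, -est$asymmetry_ms, tolerance = 1e-10)
})

test_that("adding synchronous trials beyond the crossing widens that side", {
  soas <- default_soas[default_soas < 0]
  base <- trials_from_counts(soas, k = c(1, 2, 4, 8, 12, 15, 16), n = rep(16, 7))
  cr_base <- as.numeric(crossing_ms(fit_side(base, "av")))
  widened <- rbind(base, trials_from_counts(-334, k = 16, n = 16))
  cr_wide <- as.numeric(crossing_ms(fit_side(widened, "av")))
  expect_gte(cr_wide, cr_base)
})

test_that("group_tbw averages usable estimates with sample SDs", {
  est <- data.frame(participant = c("P01", "P02"), condition = "active",
                    av_ms = c(200, 250), va_ms = c(100, 150),
                    width_ms = c(300, 400), asymmetry_ms = c(100, 100),
                    peak = c(0.9, 0.8), extrapolated = FALSE,
                    penalized = FALSE, usable = TRUE)
  g <- group_tbw(est)
  expect_equal(g$width_mean, 350)
  expect_equal(g$width_sd, 70.71068, tolerance = 1e-6)
  expect_equal(g$av_mean + g$va_mean, g$width_mean)

  est2 <- est
  est2$width_ms <- 333
  expect_equal(group_tbw(est2)$width_sd, 0)

  expect_error(group_tbw(est[1, ]), ">= 2 usable")
})

test_that("estimate_cohort marks unusable sessions instead of dropping them", {
  good <- synth_session(n_per_soa = 16, seed = 41, participant = "P01")
  flat <- trials_from_counts(default_soas, k = rep(8, 14), n = rep(16, 14),
                             participant = "P02")
  est <- estimate_cohort(rbind(good, flat))
  expect_equal(nrow(est), 2)
  expect_true(est$usable[est$participant == "P01"])
  expect_false(est$usable[est$participant == "P02"])
  expect_true(is.na(est$width_ms[est$participant == "P02"]))
})
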