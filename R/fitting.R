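#' Per-SOA simultaneity rates
#'
#' Computes, over the non-rejected trials of one participant x condition, the
#' number of valid trials, the number of "simultaneous" responses, and their
#' ratio at each SOA level. SOA levels whose trials were all rejected are
#' dropped with a warning.
#'
#' @param trials Trial data frame for one participant x condition, responses
#'   present.
#' @return A data frame with columns `soa_ms`, `n_valid`, `n_synchronous`,
#'   `rate`, ordered by SOA.
#' @export
compute_rates <- function(trials) {
  if (nrow(trials) == 0L) stop("no trials supplied", call. = FALSE)
  if (any(is.na(trials$response) & !trials$rejected)) {
    stop("trials carry missing responses; simulate or ingest responses first",
         call. = FALSE)
  }
  valid <- trials[!trials$rejected, , drop = FALSE]
  lost <- setdiff(unique(trials$soa_ms), unique(valid$soa_ms))
  if (length(lost)) {
    warning(sprintf("SOA level(s) %s dropped: all trials rejected",
                    paste(sort(lost), collapse = ", ")), call. = FALSE)
  }
  if (nrow(valid) == 0L) stop("all trials rejected", call. = FALSE)
  agg <- stats::aggregate(cbind(n_valid = 1L, n_synchronous = valid$response),
                          by = list(soa_ms = valid$soa_ms), FUN = sum)
  agg$rate <- agg$n_synchronous / agg$n_valid
  agg[order(agg$soa_ms), c("soa_ms", "n_valid", "n_synchronous", "rate")]
}

# Jeffreys-prior (Firth) penalized binomial regression, logit link.
# Newton iterations on the modified score U* = X'(k - n p) + X' h (1/2 - p),
# h the hat diagonals of the weighted fit. Keeps coefficients finite under
# complete or quasi-separation.
firth_logit <- function(x, k, n, max_iter = 200L, tol = 1e-10) {
  X <- cbind(1, x)
  beta <- c(stats::qlogis(pmin(pmax(sum(k) / sum(n), 0.05), 0.95)), 0)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- n * p * (1 - p)
    XtWX <- crossprod(X, X * w)
    XtWXinv <- solve(XtWX)
    h <- rowSums((X %*% XtWXinv) * X) * w
    U <- drop(crossprod(X, (k - n * p) + h * (0.5 - p)))
    step <- drop(XtWXinv %*% U)
    # step halving for stability
    s <- 1
    while (max(abs(s * step)) > 5) s <- s / 2
    beta <- beta + s * step
    if (max(abs(U)) < tol) break
  }
  list(coefficients = stats::setNames(beta, c("(Intercept)", "soa")),
       converged = max(abs(U)) < 1e-4, iterations = it)
}

#' Fit one side of the psychometric curve
#'
#' Splits the trials by SOA sign (AV side: `soa < 0`, audio leading; VA side:
#' `soa > 0`, visual leading; a zero-SOA level, if present, enters both
#' sides) and fits a maximum-likelihood binomial regression of the response
#' on the signed SOA. Trials are aggregated to per-SOA counts first — the
#' binomial likelihood, and hence the fit, is identical to the trial-level
#' fit. Under complete or quasi-separation (or non-convergence) the fit is
#' redone with a Jeffreys-prior penalty and flagged `penalized`.
#'
#' @param trials Trial data frame for one participant x condition.
#' @param side `"av"` or `"va"`.
#' @param link `"logit"` (default, the tested path) or `"probit"`.
#' @param include_other_side For sensitivity comparison only: fit the side's
#'   monotone sigmoid to the trials of *both* sides. Default `FALSE` (the
#'   per-side split is the supported analysis); results are labeled via the
#'   fit's `both_sides` field.
#' @return An object of class `sigmoid_fit`: list with `side`, `b0`
#'   (intercept), `b1` (slope per ms on signed SOA), `n_trials`, `n_levels`,
#'   `converged`, `penalized`, `link`, `both_sides`.
#' @export
fit_side <- function(trials, side = c("av", "va"), link = c("logit", "probit"),
                     include_other_side = FALSE) {
  side <- match.arg(side)
  link <- match.arg(link)
  sel <- if (include_other_side) rep(TRUE, nrow(trials))
         else if (side == "av") trials$soa_ms <= 0 else trials$soa_ms >= 0
  sub <- trials[sel & !trials$rejected, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("no valid trials on the %s side", toupper(side)), call. = FALSE)
  }
  rates <- suppressWarnings(compute_rates(sub))
  if (nrow(rates) < 2L) {
    stop(sprintf("need >= 2 distinct SOA levels on the %s side, got %d",
                 toupper(side), nrow(rates)), call. = FALSE)
  }
  k <- rates$n_synchronous
  n <- rates$n_valid
  x <- rates$soa_ms
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(cbind(k, n - k) ~ x, family = stats::binomial(link = link)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  b <- stats::coef(fit)
  penalized <- FALSE
  # |b0| > 15 means a fitted boundary probability within 3e-7 of 0/1 —
  # unattainable from binomial data at these trial counts except under
  # (quasi-)separation, where the ML intercept diverges
  degenerate <- sep_warn || !fit$converged || any(!is.finite(b)) ||
    abs(b[2]) > 0.5 || abs(b[1]) > 15 || all(k == n) || all(k == 0)
  if (degenerate) {
    if (link != "logit") {
      stop("penalized refit is only implemented for the logit link", call. = FALSE)
    }
    pf <- firth_logit(x, k, n)
    if (!pf$converged) {
      stop(sprintf("side %s: penalized fit failed to converge (last coefficients %s)",
                   toupper(side), paste(signif(pf$coefficients, 4), collapse = ", ")),
           call. = FALSE)
    }
    b <- pf$coefficients
    penalized <- TRUE
  }
  structure(list(side = side,
                 b0 = unname(b[1]), b1 = unname(b[2]),
                 n_trials = sum(n), n_levels = nrow(rates),
                 converged = TRUE, penalized = penalized, link = link,
                 both_sides = include_other_side),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> side %s (%s link): b0 = %.4f, b1 = %.6f /ms, %d trials over %d SOAs%s\n",
              toupper(x$side), x$link, x$b0, x$b1, x$n_trials, x$n_levels,
              if (x$penalized) " [Jeffreys-penalized]" else ""))
  invisible(x)
}

#' 50%-criterion crossing of a fitted side
#'
#' The SOA at which the fitted sigmoid equals an absolute 0.5 probability of
#' a "simultaneous" response is `-b0/b1`; its magnitude in ms is the side's
#' contribution to the TBW. Slopes with `|b1|` below `min_slope` give wildly
#' extrapolated crossings, so the side is declared unusable instead
#' (condition class `tbw_no_crossing`).
#'
#' @param fit A `sigmoid_fit`.
#' @param min_slope Minimum usable `|b1|` per ms (default 1e-4).
#' @param soa_range Measured SOA magnitude range; crossings outside it are
#'   returned but flagged (default `c(67, 400)`).
#' @return Crossing magnitude in ms, with attribute `extrapolated`.
#' @export
crossing_ms <- function(fit, min_slope = 1e-4, soa_range = c(67, 400)) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (abs(fit$b1) < min_slope) {
    stop(errorCondition(
      sprintf("side %s: |slope| %.2e below the minimum %.0e /ms; no usable 50%% crossing",
              toupper(fit$side), abs(fit$b1), min_slope),
      class = "tbw_no_crossing"))
  }
  cr <- abs(-fit$b0 / fit$b1)
  attr(cr, "extrapolated") <- cr < soa_range[1] || cr > soa_range[2]
  cr
}

#' Estimate the temporal binding window for one session
#'
#' Fits both sides, extracts the two 50% crossings, and assembles the window:
#' `width = av + va`, `asymmetry = av - va` (positive = auditory-shifted
#' window), and the peak amplitude — the maximum of the two fitted sigmoids
#' at SOA = 0, each side's supremum over its own domain, used as a
#' response-confidence proxy.
#'
#' @param trials Trial data frame for one participant x condition.
#' @param link Link function passed to [fit_side()].
#' @param min_slope,soa_range Passed to [crossing_ms()].
#' @return An object of class `tbw_estimate`: `av_ms`, `va_ms`, `width_ms`,
#'   `asymmetry_ms`, `peak`, logical flags `extrapolated` and `penalized`,
#'   and the two fits.
#' @export
estimate_tbw <- function(trials, link = "logit", min_slope = 1e-4,
                         soa_range = c(67, 400)) {
  fits <- tryCatch(
    list(av = fit_side(trials, "av", link), va = fit_side(trials, "va", link)),
    error = function(e) {
      stop(errorCondition(paste("TBW unavailable:", conditionMessage(e)),
                          class = "tbw_unavailable"))
    })
  cr <- tryCatch(
    list(av = crossing_ms(fits$av, min_slope, soa_range),
         va = crossing_ms(fits$va, min_slope, soa_range)),
    tbw_no_crossing = function(e) {
      stop(errorCondition(paste("TBW unavailable:", conditionMessage(e)),
                          class = "tbw_unavailable"))
    })
  av <- as.numeric(cr$av); va <- as.numeric(cr$va)
  peak <- max(stats::plogis(fits$av$b0), stats::plogis(fits$va$b0))
  structure(list(av_ms = av, va_ms = va,
                 width_ms = av + va, asymmetry_ms = av - va,
                 peak = peak,
                 extrapolated = attr(cr$av, "extrapolated") ||
                   attr(cr$va, "extrapolated"),
                 penalized = fits$av$penalized || fits$va$penalized,
                 fits = fits),
            class = "tbw_estimate")
}

#' @export
print.tbw_estimate <- function(x, ...) {
  cat(sprintf("<tbw_estimate> AV %.1f ms + VA %.1f ms = %.1f ms (asymmetry %+.1f ms), peak %.3f%s%s\n",
              x$av_ms, x$va_ms, x$width_ms, x$asymmetry_ms, x$peak,
              if (x$extrapolated) " [extrapolated]" else "",
              if (x$penalized) " [penalized]" else ""))
  invisible(x)
}

#' Estimate TBWs for every participant x condition in a trial log
#'
#' Sessions whose fits are unusable are reported as `NA` rows with the
#' `usable` flag unset rather than dropped silently.
#'
#' @param trials Long trial data frame across a cohort.
#' @param ... Passed to [estimate_tbw()].
#' @return Data frame with one row per participant x condition: `participant`,
#'   `condition`, `av_ms`, `va_ms`, `width_ms`, `asymmetry_ms`, `peak`,
#'   `extrapolated`, `penalized`, `usable`.
#' @export
estimate_cohort <- function(trials, ...) {
  cells <- unique(trials[, c("participant", "condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- trials[trials$participant == cells$participant[i] &
                    trials$condition == cells$condition[i], , drop = FALSE]
    est <- tryCatch(estimate_tbw(sub, ...), tbw_unavailable = function(e) NULL)
    if (is.null(est)) {
      data.frame(participant = cells$participant[i], condition = cells$condition[i],
                 av_ms = NA_real_, va_ms = NA_real_, width_ms = NA_real_,
                 asymmetry_ms = NA_real_, peak = NA_real_,
                 extrapolated = NA, penalized = NA, usable = FALSE)
    } else {
      data.frame(participant = cells$participant[i], condition = cells$condition[i],
                 av_ms = est$av_ms, va_ms = est$va_ms, width_ms = est$width_ms,
                 asymmetry_ms = est$asymmetry_ms, peak = est$peak,
                 extrapolated = est$extrapolated, penalized = est$penalized,
                 usable = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-level TBW summary
#'
#' Arithmetic means and sample SDs (n - 1 denominator) of the AV side, VA
#' side, total width, and peak amplitude per condition, over participants
#' with usable estimates.
#'
#' @param estimates Output of [estimate_cohort()].
#' @return Data frame with one row per condition and mean/SD columns, plus
#'   `n` (usable participants) and `n_dropped`.
#' @export
group_tbw <- function(estimates) {
  out <- lapply(split(estimates, estimates$condition), function(d) {
    use <- d[d$usable %in% TRUE, , drop = FALSE]
    if (nrow(use) < 2L) {
      stop(sprintf("condition '%s': need >= 2 usable estimates, got %d",
                   d$condition[1], nrow(use)), call. = FALSE)
    }
    data.frame(condition = d$condition[1], n = nrow(use),
               n_dropped = nrow(d) - nrow(use),
               av_mean = mean(use$av_ms), av_sd = stats::sd(use$av_ms),
               va_mean = mean(use$va_ms), va_sd = stats::sd(use$va_ms),
               width_mean = mean(use$width_ms), width_sd = stats::sd(use$width_ms),
               peak_mean = mean(use$peak), peak_sd = stats::sd(use$peak))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
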