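#' Paired-samples t-test with Cohen's d (dz)
#'
#' Classical paired t on the within-subject differences `x - y`, with a
#' two-tailed p from the central t distribution and the paired effect size
#' `d = mean(diff) / sd(diff)` (so `t = d * sqrt(n)` identically). Subjects
#' missing either value are dropped pairwise and counted in `n_dropped`.
#'
#' @param x,y Per-subject paired values, equal length.
#' @return An object of class `paired_t_result`: `t`, `df`, `p`, `d`, `n`,
#'   `mean_diff`, `sd_diff`, `n_dropped`.
#' @export
#' @examples
#' paired_t(c(3, 5, 7), c(2, 3, 4))  # differences 1, 2, 3
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  d_i <- x - y
  m <- mean(d_i)
  s <- stats::sd(d_i)
  if (s == 0) {
    if (m != 0) {
      stop("differences have zero variance but nonzero mean: t is infinite",
           call. = FALSE)
    }
    t <- 0; d <- 0; p <- 1
  } else {
    t <- m / (s / sqrt(n))
    d <- m / s
    p <- 2 * stats::pt(-abs(t), n - 1)
  }
  structure(list(t = t, df = n - 1L, p = p, d = d, n = n,
                 mean_diff = m, sd_diff = s, n_dropped = n_dropped),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.4f, p = %.4g, Cohen's d = %.4f (n = %d%s)\n",
              x$df, x$t, x$p, x$d, x$n,
              if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else ""))
  invisible(x)
}

#' Cohen's d for a paired design from t and n
#'
#' The paired (dz) standardizer: `d = t / sqrt(n)`, the inverse of the
#' identity `t = d * sqrt(n)` that holds when d is the mean within-subject
#' difference over the SD of the differences.
#'
#' @param t Paired t statistic.
#' @param n Number of pairs (so `df = n - 1`).
#' @return Cohen's d.
#' @export
#' @examples
#' cohens_d_from_t(6.046, 17)  # 1.466
cohens_d_from_t <- function(t, n) {
  if (any(n < 2)) stop("n must be >= 2", call. = FALSE)
  t / sqrt(n)
}

#' Fully within-subject 2x2 ANOVA
#'
#' Repeated-measures ANOVA for two crossed within-subject factors with two
#' levels each (e.g. condition: active/passive and side: AV/VA). Each effect
#' is tested against its own subject-by-effect interaction error term
#' (df_effect = 1, df_error = n - 1); with 2-level factors sphericity holds
#' trivially. Partial eta squared is `SS_effect / (SS_effect + SS_error)`.
#' Subjects with incomplete cells are dropped with a warning.
#'
#' @param data Long data frame with columns `subject`, `a`, `b`, `value`,
#'   where `a` and `b` each have exactly two levels and every retained
#'   subject has all four cells.
#' @return An object of class `rm_anova_result`: a data frame with rows
#'   `a`, `b`, `a:b` and columns `effect`, `F`, `df1`, `df2`, `p`,
#'   `partial_eta_sq`, plus attribute `n` (subjects used).
#' @export
rm_anova_2x2 <- function(data) {
  stopifnot(all(c("subject", "a", "b", "value") %in% names(data)))
  if (length(unique(data$a)) != 2L || length(unique(data$b)) != 2L) {
    stop("both factors must have exactly 2 levels", call. = FALSE)
  }
  counts <- table(data$subject)
  complete <- names(counts)[counts == 4L]
  if (length(complete) < length(counts)) {
    warning(sprintf("%d subject(s) dropped for incomplete cells",
                    length(counts) - length(complete)), call. = FALSE)
  }
  data <- data[data$subject %in% complete & stats::complete.cases(data$value), ]
  counts <- table(data$subject)
  data <- data[data$subject %in% names(counts)[counts == 4L], ]
  n <- length(unique(data$subject))
  if (n < 2L) stop("need >= 2 subjects with complete cells", call. = FALSE)

  y <- data$value
  s <- factor(data$subject); a <- factor(data$a); b <- factor(data$b)
  grand <- mean(y)
  m_a <- tapply(y, a, mean); m_b <- tapply(y, b, mean)
  m_ab <- tapply(y, list(a, b), mean)
  m_sa <- tapply(y, list(s, a), mean); m_sb <- tapply(y, list(s, b), mean)
  m_s <- tapply(y, s, mean)

  ss_a <- 2 * n * sum((m_a - grand)^2)
  ss_b <- 2 * n * sum((m_b - grand)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + grand)^2)
  ss_sa <- 2 * sum((m_sa - outer(m_s, rep(1, 2)) -
                      outer(rep(1, n), m_a) + grand)^2)
  ss_sb <- 2 * sum((m_sb - outer(m_s, rep(1, 2)) -
                      outer(rep(1, n), m_b) + grand)^2)
  # residual = subject x a x b interaction
  fitted_cell <- m_sa[cbind(as.character(s), as.character(a))] +
    m_sb[cbind(as.character(s), as.character(b))] +
    m_ab[cbind(as.character(a), as.character(b))] -
    m_s[as.character(s)] - m_a[as.character(a)] - m_b[as.character(b)] + grand
  ss_sab <- sum((y - fitted_cell)^2)

  ss_tot <- sum((y - grand)^2)
  eff <- function(name, ss_eff, ss_err) {
    # degenerate strata: a sum of squares that is zero up to rounding
    tiny <- 1e-12 * max(ss_tot, 1)
    if (ss_eff < tiny) {
      Fv <- 0; peta <- 0
    } else if (ss_err < tiny) {
      Fv <- Inf; peta <- 1
    } else {
      Fv <- ss_eff / (ss_err / (n - 1))
      peta <- ss_eff / (ss_eff + ss_err)
    }
    data.frame(effect = name, F = Fv, df1 = 1L, df2 = n - 1L,
               p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE),
               partial_eta_sq = peta)
  }
  out <- rbind(eff("a", ss_a, ss_sa), eff("b", ss_b, ss_sb),
               eff("a:b", ss_ab, ss_sab))
  attr(out, "n") <- n
  class(out) <- c("rm_anova_result", "data.frame")
  out
}

#' Partial eta squared from F and degrees of freedom
#'
#' `F * df1 / (F * df1 + df2)`, the effect-size measure conventionally
#' reported alongside repeated-measures ANOVA effects.
#'
#' @param F F statistic (nonnegative).
#' @param df1,df2 Effect and error degrees of freedom.
#' @return Partial eta squared in `[0, 1)`.
#' @export
#' @examples
#' partial_eta_sq(30.005, 1, 16)  # 0.652
partial_eta_sq <- function(F, df1, df2) {
  if (any(F < 0) || any(df1 <= 0) || any(df2 <= 0)) {
    stop("F must be >= 0 and degrees of freedom positive", call. = FALSE)
  }
  F * df1 / (F * df1 + df2)
}

#' Exact power of a paired t-test
#'
#' Noncentral-t power: under effect size `d` (mean difference over SD of
#' differences) the t statistic is noncentral t with noncentrality
#' `d * sqrt(n)` and `n - 1` degrees of freedom; power is the probability of
#' exceeding the central-t critical value at `alpha` (split across both tails
#' for `tails = "two"`).
#'
#' @param d Paired effect size (dz).
#' @param n Number of pairs.
#' @param alpha Significance level (default 0.05).
#' @param tails `"one"` or `"two"`.
#' @return Power in (0, 1). Vectorized over `n`.
#' @export
#' @examples
#' power_paired_t(0.95, 14)  # ~ 0.957
power_paired_t <- function(d, n, alpha = 0.05, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (any(n < 2)) stop("n must be >= 2", call. = FALSE)
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == "one") {
    stats::pt(stats::qt(1 - alpha, df), df, ncp, lower.tail = FALSE)
  } else {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tc, df, ncp) + stats::pt(tc, df, ncp, lower.tail = FALSE)
  }
}

#' Smallest sample size reaching a target power
#'
#' Deterministic scan (with doubling then bisection) for the smallest
#' `n >= 2` whose exact noncentral-t power reaches `target_power`. One-tailed
#' by default; the choice of tails is always echoed in printed reports
#' because it changes the answer (e.g. d = 0.95, alpha = .05, power = .95
#' needs 14 pairs one-tailed but 17 two-tailed).
#'
#' @param d Paired effect size (must be positive).
#' @param alpha Significance level.
#' @param target_power Target power in (0, 1).
#' @param tails `"one"` or `"two"`.
#' @param n_max Search ceiling (default 1e6).
#' @return Integer sample size.
#' @export
#' @examples
#' required_n(0.95, 0.05, 0.95, "one")  # 14
required_n <- function(d, alpha = 0.05, target_power = 0.95,
                       tails = c("one", "two"), n_max = 1e6) {
  tails <- match.arg(tails)
  if (d <= 0) stop("effect size must be positive to reach any power target",
                   call. = FALSE)
  if (target_power <= 0 || target_power >= 1) {
    stop("target_power must lie in (0, 1)", call. = FALSE)
  }
  pow <- function(n) power_paired_t(d, n, alpha, tails)
  lo <- 2L
  if (pow(lo) >= target_power) return(lo)
  hi <- 4L
  while (pow(hi) < target_power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > n_max) stop("target power unreachable below n_max", call. = FALSE)
  }
  # invariant: pow(lo) < target <= pow(hi)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pow(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}

#' G*Power-style protocol block for a paired-design power analysis
#'
#' @param d,alpha,target_power,tails As in [required_n()].
#' @return Invisibly, the computed n; prints the protocol to the console.
#' @export
power_protocol <- function(d, alpha = 0.05, target_power = 0.95,
                           tails = c("one", "two")) {
  tails <- match.arg(tails)
  n <- required_n(d, alpha, target_power, tails)
  achieved <- power_paired_t(d, n, alpha, tails)
  cat("t test: difference between two dependent means (matched pairs)\n",
      "Analysis: a priori (required sample size)\n",
      sprintf("  Tails                 : %s\n", tails),
      sprintf("  Effect size dz        : %g\n", d),
      sprintf("  alpha                 : %g\n", alpha),
      sprintf("  Target power          : %g\n", target_power),
      sprintf("  Noncentrality (at N)  : %.6f\n", d * sqrt(n)),
      sprintf("  Critical t (df = %d)  : %.6f\n", n - 1,
              stats::qt(1 - if (tails == "one") alpha else alpha / 2, n - 1)),
      sprintf("  Required N            : %d\n", n),
      sprintf("  Achieved power        : %.6f\n", achieved), sep = "")
  invisible(n)
}
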