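#' Plot group mean TBW curves
#'
#' Draws, per condition, the mean fitted sigmoid of each side over the SOA
#' range together with the observed mean simultaneity rates and the 50%
#' criterion line, with vertical lines at the group-mean crossings. The
#' group curve uses the arithmetic means of the per-participant crossings and
#' slopes, matching how group TBWs are conventionally displayed.
#'
#' @param trials Cohort trial data frame.
#' @param estimates Output of [estimate_cohort()].
#' @param link Link used for the per-participant fits.
#' @return A ggplot object (requires the `ggplot2` package).
#' @export
plot_tbw_curves <- function(trials, estimates, link = "logit") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_tbw_curves needs the ggplot2 package", call. = FALSE)
  }
  conds <- unique(estimates$condition)
  # observed mean rates per condition x SOA
  obs <- do.call(rbind, lapply(conds, function(cn) {
    sub <- trials[trials$condition == cn & !trials$rejected, ]
    r <- stats::aggregate(response ~ soa_ms + participant, sub, mean)
    m <- stats::aggregate(response ~ soa_ms, r, mean)
    data.frame(condition = cn, soa_ms = m$soa_ms, rate = m$response)
  }))
  # mean fitted curves from per-participant fits
  grid <- seq(min(obs$soa_ms), max(obs$soa_ms), length.out = 400)
  curves <- do.call(rbind, lapply(conds, function(cn) {
    sub <- trials[trials$condition == cn, ]
    fits <- lapply(split(sub, sub$participant), function(d) {
      tryCatch(list(av = fit_side(d, "av", link), va = fit_side(d, "va", link)),
               error = function(e) NULL)
    })
    fits <- Filter(Negate(is.null), fits)
    p <- sapply(fits, function(f) {
      ifelse(grid < 0,
             stats::plogis(f$av$b0 + f$av$b1 * grid),
             stats::plogis(f$va$b0 + f$va$b1 * grid))
    })
    data.frame(condition = cn, soa_ms = grid, p = rowMeans(p))
  }))
  gm <- group_tbw(estimates)
  vlines <- rbind(data.frame(condition = gm$condition, x = -gm$av_mean),
                  data.frame(condition = gm$condition, x = gm$va_mean))
  ggplot2::ggplot() +
    ggplot2::geom_col(data = obs,
                      ggplot2::aes(x = .data$soa_ms, y = .data$rate,
                                   fill = .data$condition),
                      position = "dodge", width = 18, alpha = 0.4) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$soa_ms, y = .data$p,
                                    colour = .data$condition),
                       linewidth = 0.9) +
    ggplot2::geom_vline(data = vlines,
                        ggplot2::aes(xintercept = .data$x,
                                     colour = .data$condition),
                        linetype = 2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = "SOA (ms; negative = auditory first)",
                  y = "P(judged simultaneous)",
                  colour = "condition", fill = "condition") +
    ggplot2::theme_minimal()
}
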