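#' @export
print.tl_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Robust linear fit (%s outcome), n = %d%s\n",
              x$outcome_type, x$n,
              if (x$converged) "" else " [NOT converged]"))
  est <- x$estimates
  est[c("beta", "se", "pct_change", "ci_low", "ci_high")] <-
    lapply(est[c("beta", "se", "pct_change", "ci_low", "ci_high")],
           round, digits)
  est$p_value <- signif(est$p_value, 2)
  print(est, row.names = FALSE)
  invisible(x)
}

#' @export
print.tl_assoc <- function(x, digits = 3, ...) {
  unit <- if (x$outcome_type == "log10_tl") "% change in TL"
          else "percentage points of ranking"
  cat(sprintf("Association model %s: %s ~ %s tertile (n = %d)\n",
              x$model, x$outcome, x$exposure, x$n))
  cat(sprintf("  tertile cut-points: %.2f, %.2f h/day; reference = low\n",
              x$cutpoints[1], x$cutpoints[2]))
  eff <- x$effects
  for (i in seq_len(nrow(eff)))
    cat(sprintf("  %-7s %+6.*f (%s %+.*f, %+.*f), p = %.3g\n",
                eff$tertile[i], digits, eff$pct_change[i], "95% CI",
                digits, eff$ci_low[i], digits, eff$ci_high[i],
                eff$p_value[i]))
  cat(sprintf("  estimates are %s vs the lowest tertile\n", unit))
  if (!is.null(x$interaction))
    cat(sprintf("  exposure x sex interaction: Wald chi2 = %.2f, p = %.3g\n",
                x$interaction$statistic, x$interaction$p_value))
  invisible(x)
}

#' @export
summary.tl_fit <- function(object, ...) {
  structure(list(object = object, rlm_summary = summary(object$fit)),
            class = "summary.tl_fit")
}

#' @export
print.summary.tl_fit <- function(x, ...) {
  print(x$object)
  cat("\nUnderlying M-estimation fit:\n")
  print(x$rlm_summary)
  invisible(x)
}

#' @export
coef.tl_fit <- function(object, ...) stats::coef(object$fit)

#' @export
confint.tl_fit <- function(object, parm, level = NULL, ...) {
  level <- level %||% object$conf_level
  b <- stats::coef(object$fit)
  se <- summary(object$fit)$coefficients[, "Std. Error"]
  crit <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(b - crit * se, b + crit * se)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.tl_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$fit, ...)
  else stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.tl_fit <- function(object, ...) stats::residuals(object$fit)

#' Plot tertile effect estimates with confidence intervals
#'
#' Horizontal interval plot of the percent-change estimates of a fitted
#' association model (middle and high tertile vs the lowest).
#'
#' @param x a \code{tl_assoc} fit.
#' @param ... passed to \code{plot}.
#' @export
plot.tl_assoc <- function(x, ...) {
  eff <- x$effects
  unit <- if (x$outcome_type == "log10_tl") "% change in TL"
          else "delta-R (percentage points)"
  xlim <- range(0, eff$ci_low, eff$ci_high)
  plot(eff$pct_change, seq_len(nrow(eff)), xlim = xlim,
       ylim = c(0.5, nrow(eff) + 0.5), yaxt = "n", pch = 16,
       xlab = unit, ylab = "",
       main = sprintf("%s ~ %s tertile (%s)", x$outcome, x$exposure,
                      x$model), ...)
  segments(eff$ci_low, seq_len(nrow(eff)), eff$ci_high)
  abline(v = 0, lty = 2, col = "grey50")
  axis(2, at = seq_len(nrow(eff)), labels = eff$tertile, las = 1)
  invisible(x)
}
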