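#' @keywords internal
#' @importFrom MASS rlm psi.bisquare
#' @importFrom graphics abline axis segments
#' @importFrom stats quantile coef qnorm pnorm pchisq pf qf rnorm rlnorm
#'   rbinom rgamma lm aov kruskal.test chisq.test ks.test cor.test
"_PACKAGE"

# geometric mean on the log scale; x must be positive
gmean <- function(x) exp(mean(log(x)))

# group means for a numeric vector, returned in the order of `levels(f)`
group_mean <- function(x, f) {
  f <- factor(f)
  as.vector(rowsum(x, f) / as.vector(table(f)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tt <- function(...) stop(sprintf(...), call. = FALSE)

# Wald covariance of an rlm fit (asymptotic, from the M-estimation sandwich
# summary); stats::vcov has no rlm method.
rlm_vcov <- function(fit) {
  s <- summary(fit, method = "XtWX")
  s$cov.unscaled * s$stddev^2
}

# joint Wald chi-square test on a subset of coefficients
wald_joint <- function(fit, terms) {
  b <- stats::coef(fit)[terms]
  V <- rlm_vcov(fit)[terms, terms, drop = FALSE]
  stat <- drop(t(b) %*% solve(V) %*% b)
  list(statistic = stat, df = length(b),
       p_value = stats::pchisq(stat, df = length(b), lower.tail = FALSE))
}
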