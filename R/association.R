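#' Percent-change transform of a regression coefficient
#'
#' For a log10-level outcome the coefficient converts to a percent change
#' as \code{(10^beta - 1) x 100}; for the rank-tracking outcome (already
#' in percentage points) the coefficient is reported as is. The transform
#' is strictly increasing and maps 0 to 0.
#'
#' @param beta coefficient(s) on the model scale.
#' @param outcome_type \code{"log10_tl"} or \code{"delta_r"}.
#' @return Percent change.
#' @examples
#' pct_change(-0.0173) # about -3.9
#' @export
pct_change <- function(beta, outcome_type = c("log10_tl", "delta_r")) {
  outcome_type <- match.arg(outcome_type)
  if (outcome_type == "log10_tl") (10^beta - 1) * 100 else beta
}

#' Robust linear fit with percent-change effect estimates
#'
#' M-type robust regression (iteratively reweighted least squares with a
#' bisquare bounded-influence loss tuned to about 95\% Gaussian
#' efficiency, via \code{\link[MASS]{rlm}}), with asymptotic Wald
#' standard errors, normal-approximation confidence intervals and the
#' percent-change transform appropriate to the outcome. Complete cases
#' only; refuses rank-deficient designs and fits with fewer than
#' (number of coefficients + 10) observations.
#'
#' @param formula model formula.
#' @param data data frame (complete cases are taken).
#' @param outcome_type \code{"log10_tl"} (coefficients transformed with
#'   \code{(10^b - 1) x 100}) or \code{"delta_r"} (reported as is).
#' @param conf_level confidence level.
#' @return Object of class \code{tl_fit}: the underlying \code{rlm} fit
#'   plus an \code{estimates} data frame (term, beta, se, pct_change,
#'   ci_low, ci_high, p_value, n).
#' @export
fit_robust_model <- function(formula, data,
                             outcome_type = c("log10_tl", "delta_r"),
                             conf_level = 0.95) {
  outcome_type <- match.arg(outcome_type)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  n <- nrow(mf)
  mm <- stats::model.matrix(formula, mf)
  p <- ncol(mm)
  if (qr(mm)$rank < p)
    stop_tt("rank-deficient design: %s", paste(deparse(formula), collapse = ""))
  if (n < p + 10L)
    stop_tt("too few observations for a stable fit (n = %d, %d coefficients)",
            n, p)
  fit <- MASS::rlm(formula, data = mf, psi = MASS::psi.bisquare,
                   method = "M", maxit = 100)
  s <- summary(fit)
  cf <- s$coefficients
  z <- cf[, "Value"] / cf[, "Std. Error"]
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- data.frame(
    term = rownames(cf),
    beta = unname(cf[, "Value"]),
    se = unname(cf[, "Std. Error"]),
    pct_change = pct_change(unname(cf[, "Value"]), outcome_type),
    ci_low = pct_change(unname(cf[, "Value"] - crit * cf[, "Std. Error"]),
                        outcome_type),
    ci_high = pct_change(unname(cf[, "Value"] + crit * cf[, "Std. Error"]),
                         outcome_type),
    p_value = 2 * stats::pnorm(-abs(unname(z))),
    n = n,
    stringsAsFactors = FALSE)
  rownames(est) <- NULL
  structure(list(fit = fit, estimates = est, formula = formula,
                 outcome_type = outcome_type, n = n,
                 converged = isTRUE(fit$converged),
                 conf_level = conf_level),
            class = "tl_fit")
}

# covariate ladder of the association models
ladder_covariates <- function(model, outcome) {
  sets <- list(
    M1 = c("storage_days", "cohort"),
    M2 = c("storage_days", "cohort", "energy_kcal", "upf_g", "age4"),
    M3 = c("storage_days", "cohort", "energy_kcal", "upf_g", "age4", "sex"),
    M4 = c("storage_days", "cohort", "energy_kcal", "upf_g", "age4", "sex",
           "followup_years", "log10_tl4"))
  if (!model %in% names(sets)) stop_tt("unknown model label '%s'", model)
  if (model == "M4" && outcome != "delta_r")
    stop_tt("Model 4 is only defined for the delta_r outcome")
  sets[[model]]
}

# assemble the complete-case analysis set for one association model;
# tertiles are assigned on that analysis sample
prepare_assoc <- function(data, outcome, exposure, model, covariates = NULL,
                          extra = NULL, subset = NULL) {
  outcome_var <- if (outcome == "tl4") "tl4" else "delta_r"
  outcome_type <- if (outcome == "tl4") "log10_tl" else "delta_r"
  covs <- covariates %||% ladder_covariates(model, outcome)
  covs <- union(covs, extra %||% character(0))
  # resolve derived columns
  derived <- character(0)
  for (cv in covs) {
    if (cv == "log10_tl4") derived <- c(derived, "tl4")
    if (grepl("_tertile$", cv) && !cv %in% names(data))
      derived <- c(derived, sub("_tertile$", "_daily", cv))
  }
  expo_col <- paste0(exposure, "_daily")
  need <- unique(c(outcome_var, expo_col,
                   setdiff(covs, c("log10_tl4", grep("_tertile$", covs,
                                                     value = TRUE))),
                   intersect(covs, names(data)), derived))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_tt("missing columns: %s", paste(miss, collapse = ", "))
  d <- data[, unique(c(need, intersect(c("child_id", "cohort", "sex"),
                                       names(data)))), drop = FALSE]
  if (!is.null(subset)) d <- d[which(subset), , drop = FALSE]
  d <- d[stats::complete.cases(d[, need, drop = FALSE]), , drop = FALSE]
  if (outcome == "tl4" && any(d$tl4 <= 0)) stop_tt("non-positive TL values")
  d$.y <- if (outcome == "tl4") log10(d$tl4) else d$delta_r
  d$.tert <- assign_tertiles(d[[expo_col]])
  if ("log10_tl4" %in% covs) d$log10_tl4 <- log10(d$tl4)
  for (cv in grep("_tertile$", covs, value = TRUE))
    if (!cv %in% names(d))
      d[[cv]] <- assign_tertiles(d[[sub("_tertile$", "_daily", cv)]])
  # factors with a single observed level cannot enter the design
  covs_use <- covs[vapply(covs, function(cv) {
    v <- d[[cv]]
    !(is.factor(v) && length(unique(v[!is.na(v)])) < 2L)
  }, logical(1))]
  list(data = d, covariates = covs_use, outcome_type = outcome_type,
       exposure_col = expo_col)
}

#' Association between a sedentary-behaviour tertile and telomere outcome
#'
#' Fits one model of the association ladder by robust linear regression:
#' outcome \code{"tl4"} regresses log10 baseline TL (estimates reported
#' as percent change in TL), outcome \code{"delta_r"} regresses the
#' rank-tracking statistic (estimates in percentage points of ranking).
#' The exposure enters as a tertile factor with the lowest tertile as
#' reference; tertiles are assigned on the model's complete-case analysis
#' sample. Ladder: M1 adjusts for blood storage time and cohort; M2 adds
#' energy intake, ultra-processed food intake and baseline age; M3 adds
#' sex; M4 (tracking outcome only) adds follow-up time and log10 baseline
#' TL.
#'
#' @param data analysis table, e.g. from \code{\link{build_analysis}}:
#'   one row per child with tl4/delta_r, \code{<exposure>_daily} hours
#'   and the covariates.
#' @param outcome \code{"tl4"} or \code{"delta_r"}.
#' @param exposure \code{"screen"}, \code{"other"} or \code{"total"}.
#' @param model ladder label "M1".."M4"; default M3 for tl4 and M4 for
#'   delta_r.
#' @param covariates optional character vector replacing the ladder set.
#' @param extra covariate names added on top (an entry like
#'   \code{"other_tertile"} is derived from \code{other_daily} on the
#'   analysis sample).
#' @param subset optional logical vector selecting rows of \code{data}.
#' @param interaction_sex add an exposure-by-sex interaction; its joint
#'   Wald test is stored as \code{$interaction}.
#' @param conf_level confidence level for the intervals.
#' @return Object of class \code{c("tl_assoc", "tl_fit")}; the
#'   \code{estimates} element of interest is in \code{$effects} (middle
#'   and high tertile rows).
#' @examples
#' \donttest{
#' sim <- simulate_study(sim_config(seed = 1, n_per_cohort = 120))
#' ana <- build_analysis(sim$cohort, sim$sb, quantify_all(sim$plates))
#' fit <- tl_assoc(ana, outcome = "tl4", exposure = "screen", model = "M3")
#' fit
#' }
#' @export
tl_assoc <- function(data, outcome = c("tl4", "delta_r"),
                     exposure = c("screen", "other", "total"),
                     model = NULL, covariates = NULL, extra = NULL,
                     subset = NULL, interaction_sex = FALSE,
                     conf_level = 0.95) {
  outcome <- match.arg(outcome)
  exposure <- match.arg(exposure)
  model <- model %||% if (outcome == "tl4") "M3" else "M4"
  prep <- prepare_assoc(data, outcome, exposure, model,
                        covariates = covariates, extra = extra,
                        subset = subset)
  rhs <- c(".tert", prep$covariates)
  if (interaction_sex) {
    if (!"sex" %in% names(prep$data)) stop_tt("no sex column for interaction")
    rhs <- c(rhs, ".tert:sex")
  }
  fml <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  tf <- fit_robust_model(fml, prep$data, outcome_type = prep$outcome_type,
                         conf_level = conf_level)
  est <- tf$estimates
  est$term <- sub("^\\.tert", paste0(exposure, "_tertile_"), est$term)
  tf$estimates <- est
  eff <- est[grepl(paste0("^", exposure, "_tertile_(middle|high)$"),
                   est$term), , drop = FALSE]
  eff$tertile <- sub(paste0("^", exposure, "_tertile_"), "", eff$term)
  tf$effects <- eff
  tf$outcome <- outcome
  tf$exposure <- exposure
  tf$model <- model
  tf$cutpoints <- attr(prep$data$.tert, "cutpoints")
  tf$group_sizes <- attr(prep$data$.tert, "group_sizes")
  if (interaction_sex) {
    iterms <- grep(":", rownames(summary(tf$fit)$coefficients), value = TRUE)
    tf$interaction <- wald_joint(tf$fit, iterms)
  }
  tf$call <- match.call()
  class(tf) <- c("tl_assoc", "tl_fit")
  tf
}

#' Change-in-estimate covariate selection
#'
#' Two-stage procedure around an exposure-outcome model: stage 1 keeps
#' candidate covariates with bivariate p < \code{p_enter} against the
#' outcome (univariable robust regression; joint Wald test for factors);
#' stage 2 runs a backward-forward elimination on the survivors, at each
#' backward step dropping the covariate whose removal changes the
#' high-vs-low exposure coefficient the least, provided that relative
#' change is below \code{change_threshold}, and at each forward step
#' re-adding a removed covariate whose re-entry changes it by at least
#' the threshold. Every decision is recorded in an audit trail.
#'
#' @inheritParams tl_assoc
#' @param candidates character vector of candidate covariate names.
#' @param forced covariates always kept in the model (never screened).
#' @param p_enter stage-1 bivariate p threshold.
#' @param change_threshold relative change-in-estimate threshold.
#' @return List: \code{selected} (character), \code{trail} (data frame
#'   step/phase/covariate/value/decision), \code{fit} (final
#'   \code{tl_fit}), \code{exposure_beta}.
#' @export
select_covariates <- function(data, outcome = c("tl4", "delta_r"),
                              exposure = c("screen", "other", "total"),
                              candidates, forced = character(0),
                              p_enter = 0.2, change_threshold = 0.10) {
  outcome <- match.arg(outcome)
  exposure <- match.arg(exposure)
  trail <- data.frame(step = integer(0), phase = character(0),
                      covariate = character(0), value = numeric(0),
                      decision = character(0), stringsAsFactors = FALSE)
  if (length(candidates) == 0L)
    return(list(selected = character(0), trail = trail, fit = NULL,
                exposure_beta = NA_real_))
  prep <- prepare_assoc(data, outcome, exposure, model = "M1",
                        covariates = union(forced, candidates))
  d <- prep$data
  step <- 0L
  note <- function(phase, covariate, value, decision) {
    trail[nrow(trail) + 1L, ] <<- list(step <<- step + 1L, phase, covariate,
                                       value, decision)
  }
  # stage 1: bivariate screen against the outcome
  survivors <- character(0)
  for (cv in candidates) {
    f1 <- fit_robust_model(stats::as.formula(paste(".y ~", cv)), d,
                           outcome_type = prep$outcome_type)
    terms <- setdiff(rownames(summary(f1$fit)$coefficients), "(Intercept)")
    pv <- if (length(terms) > 1L) wald_joint(f1$fit, terms)$p_value
          else f1$estimates$p_value[f1$estimates$term == terms]
    keep <- pv < p_enter
    note("bivariate", cv, pv, if (keep) "keep" else "drop")
    if (keep) survivors <- c(survivors, cv)
  }
  ref_fit <- function(covs) {
    rhs <- c(".tert", forced, covs)
    fit_robust_model(stats::as.formula(paste(".y ~",
                                             paste(rhs, collapse = " + "))),
                     d, outcome_type = prep$outcome_type)
  }
  high_beta <- function(f) f$estimates$beta[f$estimates$term == ".terthigh"]
  current <- survivors
  fit_cur <- ref_fit(current)
  b_cur <- high_beta(fit_cur)
  rel <- function(b) abs(b - b_cur) / max(abs(b_cur), 1e-8)
  # stage 2: backward-forward change-in-estimate elimination
  for (cycle in 1:10) {
    changed <- FALSE
    repeat { # backward
      if (!length(current)) break
      ch <- vapply(current, function(cv)
        rel(high_beta(ref_fit(setdiff(current, cv)))), numeric(1))
      j <- which.min(ch)
      if (ch[j] < change_threshold) {
        note("backward", current[j], ch[j], "drop")
        current <- setdiff(current, current[j])
        fit_cur <- ref_fit(current)
        b_cur <- high_beta(fit_cur)
        changed <- TRUE
      } else {
        note("backward", current[j], ch[j], "keep")
        break
      }
    }
    out_set <- setdiff(survivors, current)
    repeat { # forward
      if (!length(out_set)) break
      ch <- vapply(out_set, function(cv)
        rel(high_beta(ref_fit(c(current, cv)))), numeric(1))
      j <- which.max(ch)
      if (ch[j] >= change_threshold) {
        note("forward", out_set[j], ch[j], "add")
        current <- c(current, out_set[j])
        out_set <- out_set[-j]
        fit_cur <- ref_fit(current)
        b_cur <- high_beta(fit_cur)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  list(selected = current, trail = trail, fit = fit_cur,
       exposure_beta = b_cur)
}

#' Fixed-effect pooling and heterogeneity of per-cohort estimates
#'
#' Inverse-variance fixed-effect pool of per-cohort coefficients with
#' Cochran's Q and the I-squared statistic
#' \code{I2 = max(0, (Q - df)/Q) x 100}. When I-squared is below 50\%,
#' the recommendation flag \code{pool_with_cohort_covariate} is set: the
#' cohorts are then analysed jointly with cohort as a covariate.
#'
#' @param beta per-cohort coefficients.
#' @param se their standard errors (all > 0).
#' @param labels optional cohort labels.
#' @return Object of class \code{tl_het}: Q, df, i_squared, beta_pooled,
#'   se_pooled, pool_with_cohort_covariate.
#' @examples
#' heterogeneity(c(0, 1), c(0.5, 0.5)) # Q = 2, I2 = 50
#' @export
heterogeneity <- function(beta, se, labels = NULL) {
  if (length(beta) < 2L) stop_tt("need estimates from at least 2 cohorts")
  if (length(beta) != length(se)) stop_tt("beta and se lengths differ")
  if (any(!is.finite(se)) || any(se <= 0)) stop_tt("all SEs must be positive")
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - pooled)^2)
  df <- length(beta) - 1L
  i2 <- if (q > df) (q - df) / q * 100 else 0
  structure(list(Q = q, df = df, i_squared = i2, beta_pooled = pooled,
                 se_pooled = sqrt(1 / sum(w)),
                 pool_with_cohort_covariate = i2 < 50,
                 labels = labels, beta = beta, se = se),
            class = "tl_het")
}

#' @export
print.tl_het <- function(x, ...) {
  cat(sprintf("Fixed-effect pool: beta = %.4f (SE %.4f); Q = %.3f on %d df; I2 = %.1f%%\n",
              x$beta_pooled, x$se_pooled, x$Q, x$df, x$i_squared))
  cat(if (x$pool_with_cohort_covariate)
    "  I2 < 50%: pool cohorts with a cohort covariate\n"
    else "  I2 >= 50%: report cohort-stratified estimates\n")
  invisible(x)
}

#' Per-cohort fits and heterogeneity for one association model
#'
#' Fits the chosen model separately within each cohort (dropping the
#' cohort covariate; exposure tertiles are assigned on the pooled
#' analysis sample, so groups are comparable across cohorts) and pools
#' the high-vs-low coefficients with \code{\link{heterogeneity}}.
#'
#' @inheritParams tl_assoc
#' @return A \code{\link{heterogeneity}} result with the per-cohort fits
#'   attached as attribute \code{fits}.
#' @export
cohort_heterogeneity <- function(data, outcome = c("tl4", "delta_r"),
                                 exposure = c("screen", "other", "total"),
                                 model = NULL) {
  outcome <- match.arg(outcome)
  exposure <- match.arg(exposure)
  model <- model %||% if (outcome == "tl4") "M3" else "M4"
  prep <- prepare_assoc(data, outcome, exposure, model)
  d <- prep$data
  covs <- setdiff(prep$covariates, "cohort")
  fml <- stats::as.formula(paste(".y ~",
                                 paste(c(".tert", covs), collapse = " + ")))
  cohorts <- unique(d$cohort)
  if (length(cohorts) < 2L) stop_tt("need at least 2 cohorts")
  fits <- lapply(cohorts, function(co)
    fit_robust_model(fml, d[d$cohort == co, , drop = FALSE],
                     outcome_type = prep$outcome_type))
  beta <- vapply(fits, function(f)
    f$estimates$beta[f$estimates$term == ".terthigh"], numeric(1))
  se <- vapply(fits, function(f)
    f$estimates$se[f$estimates$term == ".terthigh"], numeric(1))
  het <- heterogeneity(beta, se, labels = cohorts)
  attr(het, "fits") <- stats::setNames(fits, cohorts)
  het
}

#' Descriptive comparison of characteristics across tertiles
#'
#' For each variable, normality is checked with a Kolmogorov-Smirnov test
#' against a normal with the sample moments; normal-looking variables are
#' summarised as mean (SD) and compared with one-way ANOVA, others as
#' median (IQR) with a Kruskal-Wallis test; categorical variables get
#' counts (\%) and a chi-square test. Constant variables are skipped with
#' a flag.
#'
#' @param data data frame of characteristics.
#' @param tertile factor splitting the sample (e.g. a tertile from
#'   \code{\link{assign_tertiles}}).
#' @param vars variables to describe (default: all except the tertile).
#' @param normal_alpha KS significance level below which a variable is
#'   treated as non-normal.
#' @return Data frame: variable, type, one summary column per group,
#'   test, p_value, flag.
#' @export
describe_by_tertile <- function(data, tertile, vars = NULL,
                                normal_alpha = 0.05) {
  g <- factor(tertile)
  if (nlevels(droplevels(g[!is.na(g)])) < 2L) stop_tt("need at least 2 groups")
  vars <- vars %||% names(data)
  rows <- list()
  for (v in vars) {
    x <- data[[v]]
    ok <- !is.na(x) & !is.na(g)
    xo <- x[ok]; go <- droplevels(g[ok])
    if (any(table(go) == 0L)) stop_tt("empty group for variable %s", v)
    if (is.numeric(xo)) {
      if (stats::sd(xo) == 0) {
        rows[[v]] <- desc_row(v, "numeric", levels(g),
                              rep(sprintf("%.2f (constant)", xo[1]),
                                  nlevels(g)),
                              test = "none", p = NA_real_, flag = "constant")
        next
      }
      ks <- suppressWarnings(stats::ks.test(xo, "pnorm", mean(xo),
                                            stats::sd(xo)))
      if (ks$p.value > normal_alpha) {
        summ <- vapply(levels(g), function(l) {
          z <- xo[go == l]
          sprintf("%.2f (%.2f)", mean(z), stats::sd(z))
        }, character(1))
        p <- summary(stats::aov(xo ~ go))[[1]][["Pr(>F)"]][1]
        rows[[v]] <- desc_row(v, "numeric mean (SD)", levels(g), summ,
                              "ANOVA", p, "")
      } else {
        summ <- vapply(levels(g), function(l) {
          z <- xo[go == l]
          q <- stats::quantile(z, c(0.25, 0.5, 0.75))
          sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
        }, character(1))
        p <- stats::kruskal.test(xo, go)$p.value
        rows[[v]] <- desc_row(v, "numeric median (IQR)", levels(g), summ,
                              "Kruskal-Wallis", p, "")
      }
    } else {
      xf <- droplevels(factor(xo))
      if (nlevels(xf) < 2L) {
        rows[[v]] <- desc_row(v, "categorical", levels(g),
                              rep("all one level", nlevels(g)),
                              "none", NA_real_, "constant")
        next
      }
      tab <- table(xf, go)
      p <- suppressWarnings(stats::chisq.test(tab)$p.value)
      summ <- vapply(levels(g), function(l) {
        ct <- table(xf[go == l])
        paste(sprintf("%s %d (%.0f%%)", names(ct), ct,
                      100 * ct / sum(ct)), collapse = "; ")
      }, character(1))
      rows[[v]] <- desc_row(v, "categorical n (%)", levels(g), summ,
                            "Chi-square", p, "")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

desc_row <- function(variable, type, groups, summaries, test, p, flag) {
  row <- data.frame(variable = variable, type = type,
                    stringsAsFactors = FALSE)
  for (i in seq_along(groups)) row[[groups[i]]] <- summaries[i]
  row$test <- test
  row$p_value <- p
  row$flag <- flag
  row
}

#' Sensitivity-analysis suite around a main association model
#'
#' Re-fits the main model under a fixed set of perturbations: separately
#' adding the other sedentary-behaviour variable (as a tertile),
#' Mediterranean-diet score, BMI, season of blood extraction and
#' extracurricular physical activity; adding the maternal block
#' (periconceptional BMI, smoking, education) jointly; restricting to
#' boys or to girls; excluding preterm children; and an exposure-by-sex
#' interaction (joint Wald p reported). A variant whose subgroup is too
#' small to fit is skipped with a flag.
#'
#' @inheritParams tl_assoc
#' @param variants optional named list overriding the default variant
#'   specifications; each element may carry \code{extra},
#'   \code{subset_expr} (an expression evaluated in \code{data}) and
#'   \code{interaction_sex}.
#' @return Data frame of tertile effect estimates per variant (columns
#'   variant, tertile, beta, se, pct_change, ci_low, ci_high, p_value, n,
#'   interaction_p, flag), with the fits attached as attribute
#'   \code{fits}.
#' @export
sensitivity_suite <- function(data, outcome = c("tl4", "delta_r"),
                              exposure = c("screen", "other", "total"),
                              model = NULL, variants = NULL,
                              conf_level = 0.95) {
  outcome <- match.arg(outcome)
  exposure <- match.arg(exposure)
  model <- model %||% if (outcome == "tl4") "M3" else "M4"
  other_sb <- paste0(setdiff(c("screen", "other"),
                             if (exposure == "other") "other" else "screen")[1],
                     "_tertile")
  if (exposure == "total") other_sb <- NULL
  variants <- variants %||% c(
    list(main = list()),
    if (!is.null(other_sb)) list(add_other_sb = list(extra = other_sb)),
    list(
      add_rmed = list(extra = "rmed"),
      add_bmi = list(extra = "bmi"),
      add_season = list(extra = "season"),
      add_pa = list(extra = "pa_met"),
      add_mother = list(extra = c("mother_bmi", "mother_smoking",
                                  "mother_education")),
      boys_only = list(subset_expr = quote(sex == "male")),
      girls_only = list(subset_expr = quote(sex == "female")),
      exclude_preterm = list(subset_expr = quote(!preterm)),
      sex_interaction = list(interaction_sex = TRUE)))
  rows <- list()
  fits <- list()
  for (nm in names(variants)) {
    sp <- variants[[nm]]
    subs <- if (!is.null(sp$subset_expr))
      eval(sp$subset_expr, envir = data) else NULL
    res <- tryCatch(
      tl_assoc(data, outcome = outcome, exposure = exposure, model = model,
               extra = sp$extra, subset = subs,
               interaction_sex = isTRUE(sp$interaction_sex),
               conf_level = conf_level),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[nm]] <- data.frame(variant = nm, tertile = NA_character_,
                               beta = NA_real_, se = NA_real_,
                               pct_change = NA_real_, ci_low = NA_real_,
                               ci_high = NA_real_, p_value = NA_real_,
                               n = NA_integer_, interaction_p = NA_real_,
                               flag = paste("skipped:",
                                            conditionMessage(res)),
                               stringsAsFactors = FALSE)
      next
    }
    fits[[nm]] <- res
    eff <- res$effects
    rows[[nm]] <- data.frame(
      variant = nm, tertile = eff$tertile, beta = eff$beta, se = eff$se,
      pct_change = eff$pct_change, ci_low = eff$ci_low,
      ci_high = eff$ci_high, p_value = eff$p_value, n = eff$n,
      interaction_p = if (is.null(res$interaction)) NA_real_
                      else res$interaction$p_value,
      flag = "", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
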