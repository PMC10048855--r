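#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the synthetic multi-cohort child study: sample
#' sizes, the planted exposure effects, telomere-length distributions,
#' qPCR noise structure and plate layout, and the strength of the
#' confounding linking sedentary behaviour to dietary covariates.
#'
#' The defaults describe a three-cohort study of roughly 670 children with
#' about 79% follow-up, a baseline relative telomere length (T/S ratio)
#' that is lognormal with sdlog 0.25, multiplicative attrition between the
#' two visits (median factor 0.9, sdlog 0.35, which yields a baseline to
#' follow-up rank correlation near 0.6), triplicate qPCR wells with
#' 0.075-cycle replicate noise and 0.5-cycle run-to-run shifts, target
#' amplification efficiencies of 2.07 (telomere) and 2.0 (single-copy
#' gene), 8 inter-run calibrators and a 6-point two-fold dilution series
#' per run.
#'
#' @param seed integer master seed; every output table draws from its own
#'   stream derived from it, so generated tables are reproducible and
#'   adding a table does not shift the draws of another.
#' @param n_per_cohort children per cohort (3 cohorts).
#' @param effect_tl4_high_screen fractional difference in true baseline TL
#'   for the highest vs lowest screen-time tertile (e.g. -0.04 for 4%
#'   shorter); the middle tertile receives half the effect.
#' @param effect_rank_high_screen planted high-vs-low contrast on the
#'   rank-tracking statistic delta-R, in percentage points (e.g. -2).
#'   Implemented as a displacement in within-cohort quantile space of
#'   follow-up TL (high tertile displaced by \code{effect/100}, middle by
#'   half), so the expected regression contrast equals the parameter.
#' @param tl4_lognormal_mu,tl4_lognormal_sigma meanlog/sdlog of true
#'   baseline TL (arbitrary T/S units).
#' @param attrition_mean median multiplicative TL change between visits.
#' @param attrition_sd sdlog of the multiplicative attrition factor.
#' @param cq_noise_sd replicate-level Cq noise, cycles.
#' @param run_shift_sd per-(run, target) additive Cq offset SD, cycles.
#' @param efficiency_T,efficiency_S amplification factors per cycle.
#' @param n_irc inter-run calibrators measured on every run (>= 2).
#' @param samples_per_run study samples per qPCR run.
#' @param followup_rate probability a child attends the follow-up visit.
#' @param conf_strength multiplier on the exposure-covariate confounding
#'   paths (0 removes the association between screen time and diet).
#' @param beta_upf_tl4 log-scale effect of ultra-processed food intake on
#'   true baseline TL, per 100 g/day (the planted confounder effect).
#' @param screen_mu,screen_sigma,other_mu,other_sigma meanlog/sdlog of the
#'   latent daily screen-time and other-sedentary-time distributions
#'   (hours/day).
#' @param cohorts character vector of three cohort labels.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(seed = 7, n_per_cohort = 50)
#' cfg$effect_tl4_high_screen
#' @export
sim_config <- function(seed = 1L,
                       n_per_cohort = 223L,
                       effect_tl4_high_screen = -0.04,
                       effect_rank_high_screen = -2,
                       tl4_lognormal_mu = 0,
                       tl4_lognormal_sigma = 0.25,
                       attrition_mean = 0.9,
                       attrition_sd = 0.35,
                       cq_noise_sd = 0.075,
                       run_shift_sd = 0.5,
                       efficiency_T = 2.07,
                       efficiency_S = 2.0,
                       n_irc = 8L,
                       samples_per_run = 40L,
                       followup_rate = 530 / 669,
                       conf_strength = 1,
                       beta_upf_tl4 = -0.015,
                       screen_mu = log(1.2), screen_sigma = 0.45,
                       other_mu = log(1.3), other_sigma = 0.40,
                       cohorts = c("cohort_A", "cohort_B", "cohort_C")) {
  cfg <- list(seed = as.integer(seed), n_per_cohort = as.integer(n_per_cohort),
              effect_tl4_high_screen = effect_tl4_high_screen,
              effect_rank_high_screen = effect_rank_high_screen,
              tl4_lognormal_mu = tl4_lognormal_mu,
              tl4_lognormal_sigma = tl4_lognormal_sigma,
              attrition_mean = attrition_mean, attrition_sd = attrition_sd,
              cq_noise_sd = cq_noise_sd, run_shift_sd = run_shift_sd,
              efficiency_T = efficiency_T, efficiency_S = efficiency_S,
              n_irc = as.integer(n_irc),
              samples_per_run = as.integer(samples_per_run),
              followup_rate = followup_rate, conf_strength = conf_strength,
              beta_upf_tl4 = beta_upf_tl4,
              screen_mu = screen_mu, screen_sigma = screen_sigma,
              other_mu = other_mu, other_sigma = other_sigma,
              cohorts = cohorts)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_per_cohort <= 0L) stop_tt("n_per_cohort must be positive")
  if (cfg$effect_tl4_high_screen <= -1)
    stop_tt("effect_tl4_high_screen <= -1 would force non-positive TL")
  if (cfg$n_irc < 2L) stop_tt("at least 2 inter-run calibrators are required")
  if (cfg$efficiency_T <= 1 || cfg$efficiency_S <= 1)
    stop_tt("amplification efficiencies must exceed 1")
  for (nm in c("tl4_lognormal_sigma", "attrition_sd", "cq_noise_sd",
               "run_shift_sd", "screen_sigma", "other_sigma"))
    if (cfg[[nm]] < 0) stop_tt("%s must be >= 0", nm)
  if (cfg$followup_rate <= 0 || cfg$followup_rate > 1)
    stop_tt("followup_rate must be in (0, 1]")
  if (length(cfg$cohorts) != 3L) stop_tt("exactly 3 cohort labels expected")
  if (cfg$samples_per_run < 1L) stop_tt("samples_per_run must be >= 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d cohorts x %d children (seed %d)\n",
              length(x$cohorts), x$n_per_cohort, x$seed))
  cat(sprintf("  planted effects: TL4 high-screen %+.1f%%, delta-R high-screen %+.1f pts\n",
              100 * x$effect_tl4_high_screen, x$effect_rank_high_screen))
  cat(sprintf("  qPCR: E_T=%.2f E_S=%.2f, Cq noise %.3f, run shift %.2f, %d IRCs\n",
              x$efficiency_T, x$efficiency_S, x$cq_noise_sd,
              x$run_shift_sd, x$n_irc))
  invisible(x)
}

# seed offsets for the per-table RNG streams
.seed_covariates <- 101L
.seed_sb <- 202L
.seed_tl <- 303L
.seed_qpcr <- 404L

#' Simulate a multi-cohort child study with known ground truth
#'
#' Generates the child-level tables of a synthetic telomere study: a truth
#' table carrying true baseline and follow-up relative telomere length and
#' the true exposure tertile, a cohort/covariate table, and a
#' sedentary-behaviour questionnaire table with weekday and weekend hours.
#'
#' The exposure effect on baseline TL is multiplicative by true
#' screen-time tertile (full effect in the top tertile, half in the
#' middle). Dietary covariates (energy and ultra-processed food intake)
#' are generated correlated with screen time, and ultra-processed food
#' intake additionally shortens true baseline TL, so the generator plants
#' a genuine confounder for covariate-selection checks. The follow-up
#' effect on rank tracking is a quantile-space displacement of follow-up
#' TL (see \code{\link{sim_config}}). Questionnaire hours are rounded to
#' 0.1 h to mimic parent-report granularity.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list with data frames \code{truth} (child_id, cohort,
#'   tl4_true, tl8_true, screen_tertile_true, followed), \code{cohort}
#'   (covariates) and \code{sb} (questionnaire hours).
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 1, n_per_cohort = 40))
#' head(sim$truth)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  n <- config$n_per_cohort
  N <- 3L * n
  cohort <- rep(config$cohorts, each = n)
  child_id <- sprintf("C%04d", seq_len(N))

  # -- sedentary-behaviour questionnaire stream ------------------------------
  set.seed(config$seed + .seed_sb)
  screen_lat <- pmin(stats::rlnorm(N, config$screen_mu, config$screen_sigma), 5)
  other_lat <- pmin(stats::rlnorm(N, config$other_mu, config$other_sigma), 8)
  # weekends carry somewhat more screen time than weekdays
  we_ratio_s <- exp(stats::rnorm(N, 0.15, 0.20))
  we_ratio_o <- exp(stats::rnorm(N, 0.05, 0.20))
  sb <- data.frame(
    child_id = child_id,
    screen_wd = pmin(round(screen_lat, 1), 24),
    screen_we = pmin(round(screen_lat * we_ratio_s, 1), 24),
    other_wd = pmin(round(other_lat, 1), 24),
    other_we = pmin(round(other_lat * we_ratio_o, 1), 24),
    stringsAsFactors = FALSE)

  # the exposure the analysis will see: daily mean of the rounded hours
  screen_daily <- daily_mean(sb$screen_wd, sb$screen_we)
  tert <- assign_tertiles(screen_daily)
  score <- c(low = 0, middle = 0.5, high = 1)[as.character(tert)]

  # -- covariate stream ------------------------------------------------------
  set.seed(config$seed + .seed_covariates)
  z <- as.vector(scale(log(screen_daily + 0.25)))
  cs <- config$conf_strength
  energy_kcal <- round(1500 * exp(0.10 * cs * z + stats::rnorm(N, 0, 0.12)))
  upf_g <- round(380 * exp(0.30 * cs * z + stats::rnorm(N, 0, 0.40)))
  sex <- factor(ifelse(stats::rbinom(N, 1, 0.523) == 1, "male", "female"),
                levels = c("female", "male"))
  age4 <- round(stats::rnorm(N, 4.4, 0.2), 2)
  followup_years <- round(pmax(stats::rnorm(N, 4.1, 0.5), 2), 2)
  cohort_df <- data.frame(
    child_id = child_id, cohort = cohort, sex = sex, age4 = age4,
    age8 = age4 + followup_years, followup_years = followup_years,
    storage_days = sample.int(400, N, replace = TRUE) + 30,
    energy_kcal = energy_kcal, upf_g = upf_g,
    bmi = round(stats::rlnorm(N, log(16), 0.07), 1),
    rmed = pmin(pmax(round(stats::rnorm(N, 9, 2.5)), 0), 18),
    season = factor(sample(c("spring", "summer", "autumn", "winter"),
                           N, replace = TRUE)),
    pa_met = round(stats::rgamma(N, shape = 2.2, scale = 4.5), 1),
    preterm = stats::rbinom(N, 1, 0.06) == 1,
    mother_age = round(stats::rnorm(N, 37.1, 4.2), 1),
    mother_bmi = round(stats::rlnorm(N, log(22.9), 0.12), 1),
    mother_smoking = factor(ifelse(stats::rbinom(N, 1, 0.25) == 1,
                                   "yes", "no"), levels = c("no", "yes")),
    mother_education = factor(sample(c("primary", "secondary", "university"),
                                     N, replace = TRUE,
                                     prob = c(0.23, 0.37, 0.40)),
                              levels = c("primary", "secondary", "university")),
    stringsAsFactors = FALSE)

  # -- telomere stream -------------------------------------------------------
  set.seed(config$seed + .seed_tl)
  tl4 <- stats::rlnorm(N, config$tl4_lognormal_mu, config$tl4_lognormal_sigma)
  tl4 <- tl4 * (1 + config$effect_tl4_high_screen * score)
  tl4 <- tl4 * exp(config$beta_upf_tl4 * (upf_g - 380) / 100)
  attr_fac <- exp(stats::rnorm(N, log(config$attrition_mean),
                               config$attrition_sd))
  tl8 <- tl4 * attr_fac
  # exposure-dependent attrition: displacement in within-cohort quantile
  # space so the planted delta-R contrast is the regression estimand
  if (config$effect_rank_high_screen != 0) {
    d <- (config$effect_rank_high_screen / 100) * score
    for (co in config$cohorts) {
      i <- cohort == co
      ni <- sum(i)
      p <- (rank(tl8[i], ties.method = "average") - 0.5) / ni
      # sub-grid jitter: a displacement that is an exact multiple of the
      # rank spacing would land on occupied grid points and the resulting
      # ties would be averaged away, shrinking the planted contrast
      jit <- (stats::runif(ni) - 0.5) / (5 * ni)
      p2 <- pmin(pmax(p + d[i] + jit, 1 / (2 * ni)), 1 - 1 / (2 * ni))
      tl8[i] <- as.vector(stats::quantile(tl8[i], probs = p2, type = 7))
    }
  }
  followed <- stats::rbinom(N, 1, config$followup_rate) == 1

  truth <- data.frame(
    child_id = child_id, cohort = cohort,
    tl4_true = tl4, tl8_true = tl8,
    screen_tertile_true = tert, followed = followed,
    stringsAsFactors = FALSE)
  list(truth = truth, cohort = cohort_df, sb = sb)
}

#' Simulate raw qPCR plate data for a truth table
#'
#' Emits well-level Cq values for the telomere (T) and single-copy gene
#' (S) assays of each cohort and visit: triplicate study-sample wells,
#' triplicate wells for the inter-run calibrators re-measured on every
#' run, and a 6-point two-fold serial dilution of a pooled DNA per run and
#' target. Cq is generated as
#' \code{base - log_E(quantity) + run_shift + noise}; the single-copy gene
#' quantity varies per sample (DNA input), and the telomere quantity is
#' that input times the child's true T/S ratio, so a noise-free
#' configuration round-trips exactly through the CNRQ chain.
#'
#' Each (cohort, visit) combination is an independent assay block with its
#' own runs, calibrator aliquots and dilution series; follow-up plates are
#' only generated for children seen at follow-up.
#'
#' @param truth truth table from \code{\link{simulate_cohort}}.
#' @param config the same \code{\link{sim_config}}.
#' @return A data frame of wells: cohort, age (4 or 8), sample_id, run_id,
#'   target ("T"/"S"), replicate, cq, well_class
#'   ("sample"/"irc"/"dilution"), dilution_factor (NA except dilution
#'   wells).
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 1, n_per_cohort = 30))
#' plates <- simulate_qpcr(sim$truth, sim_config(seed = 1, n_per_cohort = 30))
#' table(plates$well_class)
#' @export
simulate_qpcr <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(truth) == 0L) stop_tt("truth table is empty")
  set.seed(config$seed + .seed_qpcr)
  base_cq <- c(T = 20, S = 24)
  E <- c(T = config$efficiency_T, S = config$efficiency_S)
  blocks <- list()
  for (co in unique(truth$cohort)) {
    for (age in c(4L, 8L)) {
      tt <- truth[truth$cohort == co, , drop = FALSE]
      if (age == 8L) tt <- tt[tt$followed, , drop = FALSE]
      if (nrow(tt) == 0L) next
      tl <- if (age == 4L) tt$tl4_true else tt$tl8_true
      blocks[[paste(co, age)]] <-
        simulate_assay_block(co, age, tt$child_id, tl, config, base_cq, E)
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

# one (cohort, age) assay: runs, IRC aliquots, dilution series
simulate_assay_block <- function(cohort, age, ids, tl, config, base_cq, E) {
  n <- length(ids)
  n_runs <- max(1L, ceiling(n / config$samples_per_run))
  run_of <- rep(seq_len(n_runs), each = config$samples_per_run)[seq_len(n)]
  run_ids <- sprintf("%s_y%d_r%02d", cohort, age, seq_len(n_runs))

  # DNA input varies per sample; T quantity = input x true T/S ratio
  q_s <- stats::rlnorm(n, 0, 0.2)
  q_t <- q_s * tl
  # IRC aliquots: fixed true quantities re-measured on every run
  irc_ids <- sprintf("IRC%02d", seq_len(config$n_irc))
  irc_qs <- stats::rlnorm(config$n_irc, 0, 0.1)
  irc_qt <- irc_qs * stats::rlnorm(config$n_irc, config$tl4_lognormal_mu,
                                   config$tl4_lognormal_sigma)
  # pooled-DNA dilution series: 6 points, 2-fold, top concentration 4x
  dil_fac <- 2^(0:5)
  pool_qs <- 4
  pool_qt <- pool_qs * exp(config$tl4_lognormal_mu)

  wells <- list()
  for (tgt in c("T", "S")) {
    q_sample <- if (tgt == "T") q_t else q_s
    q_irc <- if (tgt == "T") irc_qt else irc_qs
    q_pool <- if (tgt == "T") pool_qt else pool_qs
    shift <- stats::rnorm(n_runs, 0, config$run_shift_sd)
    # study samples, triplicate
    idx <- rep(seq_len(n), each = 3L)
    w_s <- data.frame(
      cohort = cohort, age = age, sample_id = ids[idx],
      run_id = run_ids[run_of[idx]], target = tgt,
      replicate = rep(1:3, n),
      cq = base_cq[[tgt]] - log(q_sample[idx]) / log(E[[tgt]]) +
        shift[run_of[idx]] +
        stats::rnorm(3L * n, 0, config$cq_noise_sd),
      well_class = "sample", dilution_factor = NA_real_,
      stringsAsFactors = FALSE)
    # IRCs on every run, triplicate
    g <- expand.grid(replicate = 1:3, irc = seq_len(config$n_irc),
                     run = seq_len(n_runs))
    w_i <- data.frame(
      cohort = cohort, age = age, sample_id = irc_ids[g$irc],
      run_id = run_ids[g$run], target = tgt, replicate = g$replicate,
      cq = base_cq[[tgt]] - log(q_irc[g$irc]) / log(E[[tgt]]) +
        shift[g$run] + stats::rnorm(nrow(g), 0, config$cq_noise_sd),
      well_class = "irc", dilution_factor = NA_real_,
      stringsAsFactors = FALSE)
    # dilution series, one well per point per run
    gd <- expand.grid(dil = dil_fac, run = seq_len(n_runs))
    w_d <- data.frame(
      cohort = cohort, age = age, sample_id = "POOL",
      run_id = run_ids[gd$run], target = tgt, replicate = 1L,
      cq = base_cq[[tgt]] - log(q_pool / gd$dil) / log(E[[tgt]]) +
        shift[gd$run] + stats::rnorm(nrow(gd), 0, config$cq_noise_sd),
      well_class = "dilution", dilution_factor = gd$dil,
      stringsAsFactors = FALSE)
    wells[[tgt]] <- rbind(w_s, w_i, w_d)
  }
  do.call(rbind, wells)
}

#' Simulate a complete synthetic study (tables plus qPCR plates)
#'
#' Convenience wrapper running \code{\link{simulate_cohort}} and
#' \code{\link{simulate_qpcr}} under one configuration.
#'
#' @param config a \code{\link{sim_config}}.
#' @return List with \code{config}, \code{truth}, \code{cohort},
#'   \code{sb} and \code{plates}.
#' @export
simulate_study <- function(config) {
  sim <- simulate_cohort(config)
  sim$plates <- simulate_qpcr(sim$truth, config)
  sim$config <- config
  sim
}
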