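#' Assemble the child-level analysis table
#'
#' Joins the cohort/covariate table, the sedentary-behaviour exposures
#' derived from the questionnaire, the baseline and follow-up CNRQ
#' values, and the rank-tracking statistic into one row per child.
#' Exposure tertiles are deliberately not frozen here: each association
#' model assigns tertiles on its own complete-case analysis sample (see
#' \code{\link{tl_assoc}}), so the groups match the sample actually
#' modelled.
#'
#' @param cohort cohort table (child_id, cohort, covariates).
#' @param sb questionnaire table for \code{\link{build_exposures}}.
#' @param quant a \code{\link{quantify_all}} result, or a data frame with
#'   columns cohort, age, sample_id, cnrq.
#' @param rank_on_full_baseline passed to \code{\link{track_telomeres}}.
#' @return Data frame: one row per child with covariates, daily
#'   sedentary-behaviour hours, tl4, tl8 (CNRQ), r1, r2, n_rank and
#'   delta_r (NA for children without both measurements).
#' @examples
#' \donttest{
#' sim <- simulate_study(sim_config(seed = 2, n_per_cohort = 80))
#' ana <- build_analysis(sim$cohort, sim$sb, quantify_all(sim$plates))
#' summary(ana$delta_r)
#' }
#' @export
build_analysis <- function(cohort, sb, quant,
                           rank_on_full_baseline = FALSE) {
  cnrq <- if (inherits(quant, "tl_quant_set")) quant$cnrq else quant
  need <- c("cohort", "age", "sample_id", "cnrq")
  if (!all(need %in% names(cnrq)))
    stop_tt("quant must provide columns: %s", paste(need, collapse = ", "))
  expo <- build_exposures(sb)
  d <- merge(cohort, expo[, c("child_id", "screen_daily", "other_daily",
                              "total_daily")],
             by = "child_id", all.x = TRUE)
  tl4 <- cnrq[cnrq$age == 4, c("sample_id", "cnrq")]
  names(tl4) <- c("child_id", "tl4")
  tl8 <- cnrq[cnrq$age == 8, c("sample_id", "cnrq")]
  names(tl8) <- c("child_id", "tl8")
  d <- merge(merge(d, tl4, by = "child_id", all.x = TRUE),
             tl8, by = "child_id", all.x = TRUE)
  trk <- track_telomeres(d$tl4, d$tl8, d$cohort, d$child_id,
                         rank_on_full_baseline = rank_on_full_baseline)
  names(trk)[names(trk) == "n"] <- "n_rank"
  d <- merge(d, trk[, c("child_id", "r1", "r2", "n_rank", "delta_r")],
             by = "child_id", all.x = TRUE)
  d[order(d$child_id), ]
}

#' Run the full synthetic-study pipeline
#'
#' Simulates a study, quantifies every assay block, and assembles the
#' analysis table — the one-call entry point used throughout the examples
#' and validation code.
#'
#' @param config a \code{\link{sim_config}}.
#' @param efficiency passed to \code{\link{quantify_all}}.
#' @return List: \code{sim} (the \code{\link{simulate_study}} output),
#'   \code{quant} (the \code{tl_quant_set}) and \code{analysis} (the
#'   table from \code{\link{build_analysis}}).
#' @export
run_study <- function(config, efficiency = "estimated") {
  sim <- simulate_study(config)
  quant <- quantify_all(sim$plates, efficiency = efficiency)
  analysis <- build_analysis(sim$cohort, sim$sb, quant)
  list(sim = sim, quant = quant, analysis = analysis)
}
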