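#' Amplification efficiency from a serial dilution standard curve
#'
#' Least-squares fit of mean Cq against log10 relative input quantity
#' (quantity = 1/dilution_factor). The slope gives the amplification
#' factor per cycle \code{E = 10^(-1/slope)} and the efficiency percent
#' \code{(E - 1) x 100}; perfect doubling chemistry has slope
#' \code{-1/log10(2) = -3.3219} and efficiency 100\%.
#'
#' Replicate wells and wells from different runs are first averaged per
#' dilution point; with every run carrying the full series, additive
#' run shifts cancel out of the slope.
#'
#' @param dilution_wells data frame with columns \code{dilution_factor}
#'   and \code{cq} (and optionally \code{target} when \code{target} is
#'   given).
#' @param target optional target ("T" or "S") to subset on.
#' @return List (class \code{tl_efficiency}): target, slope, E,
#'   efficiency_pct, r_squared, n_points.
#' @examples
#' dil <- data.frame(dilution_factor = 2^(0:5),
#'                   cq = 20 + log2(2^(0:5)))
#' estimate_efficiency(dil)$efficiency_pct # 100
#' @export
estimate_efficiency <- function(dilution_wells, target = NULL) {
  d <- dilution_wells
  if (!is.null(target) && "target" %in% names(d))
    d <- d[d$target == target, , drop = FALSE]
  if (!all(c("dilution_factor", "cq") %in% names(d)))
    stop_tt("dilution wells need columns dilution_factor and cq")
  d <- d[!is.na(d$cq) & !is.na(d$dilution_factor), , drop = FALSE]
  if (any(d$dilution_factor <= 0)) stop_tt("dilution factors must be positive")
  pts <- unique(d$dilution_factor)
  if (length(pts) < 3L)
    stop_tt("at least 3 distinct dilution points required (got %d)",
            length(pts))
  logq <- -log10(d$dilution_factor)
  mcq <- group_mean(d$cq, logq)
  x <- sort(unique(logq))
  fit <- stats::lm(mcq ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope == 0) stop_tt("degenerate standard curve")
  E <- 10^(-1 / slope)
  r2 <- if (length(x) > 2) suppressWarnings(summary(fit)$r.squared) else 1
  structure(list(target = target %||% NA_character_, slope = slope, E = E,
                 efficiency_pct = (E - 1) * 100, r_squared = r2,
                 n_points = length(pts)),
            class = "tl_efficiency")
}

#' @export
print.tl_efficiency <- function(x, ...) {
  cat(sprintf("Standard curve%s: slope %.4f, E = %.4f (%.1f%%), R2 = %.4f, %d points\n",
              if (is.na(x$target)) "" else paste0(" [", x$target, "]"),
              x$slope, x$E, x$efficiency_pct, x$r_squared, x$n_points))
  invisible(x)
}

#' Aggregate replicate Cq wells
#'
#' Arithmetic mean of the retained replicates for one (sample, run,
#' target) group, with non-blocking QC flags: fewer than 2 replicates, or
#' a replicate spread above \code{max_spread} cycles. No automatic
#' replicate rejection is applied.
#'
#' @param cq numeric vector of 1-3 replicate Cq values.
#' @param max_spread spread (max - min, cycles) above which the group is
#'   flagged.
#' @return List: mean_cq, n, flag_low_rep, flag_spread.
#' @examples
#' aggregate_replicates(c(20.0, 20.2))$mean_cq # 20.1
#' @export
aggregate_replicates <- function(cq, max_spread = 0.5) {
  cq <- cq[!is.na(cq)]
  if (length(cq) == 0L) stop_tt("no replicate Cq values")
  if (length(cq) > 3L) stop_tt("more than 3 replicates in one group")
  list(mean_cq = mean(cq), n = length(cq),
       flag_low_rep = length(cq) < 2L,
       flag_spread = (max(cq) - min(cq)) > max_spread)
}

#' Relative quantity from the delta-Cq method
#'
#' \code{RQ = E^(reference_cq - mean_cq)} with a target-specific
#' amplification efficiency. The reference Cq is the arithmetic mean Cq
#' over all analysed study samples of that target within the run and
#' cohort, not a designated calibrator sample.
#'
#' @param mean_cq replicate-averaged Cq of the sample (vectorised).
#' @param reference_cq arithmetic mean Cq of the analysed samples.
#' @param E amplification factor per cycle (> 1).
#' @return Relative quantity (1 at the reference mean).
#' @examples
#' compute_rq(19, 20, E = 2) # one cycle below reference = 2
#' @export
compute_rq <- function(mean_cq, reference_cq, E) {
  if (!is.finite(E) || E <= 1) stop_tt("E must be a finite value > 1")
  E^(reference_cq - mean_cq)
}

#' Normalised relative quantity (T/S ratio)
#'
#' @param rq_T,rq_S positive relative quantities of the telomere and
#'   single-copy gene targets.
#' @return NRQ = rq_T / rq_S.
#' @export
compute_nrq <- function(rq_T, rq_S) {
  if (any(rq_T <= 0, na.rm = TRUE) || any(rq_S <= 0, na.rm = TRUE))
    stop_tt("relative quantities must be positive")
  rq_T / rq_S
}

#' Inter-run correction factors from calibrator samples
#'
#' For each run, the correction factor is the geometric mean over
#' inter-run calibrators (IRCs) of that calibrator's NRQ on the run
#' divided by its geometric-mean NRQ over all runs; dividing a sample's
#' NRQ by its run's CF yields the calibrated NRQ (CNRQ). By construction
#' the geometric mean of the CFs across runs is exactly 1. A single-run
#' input gets CF = 1.
#'
#' An IRC not measured on every run is flagged and excluded (keeping the
#' construction balanced); with two or more runs, at least 2 complete
#' IRCs must remain.
#'
#' @param irc_nrq data frame with columns sample_id (IRC identity),
#'   run_id, nrq (replicate-aggregated NRQ of the calibrator on the run).
#' @return Data frame (run_id, cf) with attribute \code{excluded_ircs}.
#' @export
compute_inter_run_cf <- function(irc_nrq) {
  need <- c("sample_id", "run_id", "nrq")
  if (!all(need %in% names(irc_nrq)))
    stop_tt("irc_nrq needs columns: %s", paste(need, collapse = ", "))
  runs <- unique(irc_nrq$run_id)
  if (length(runs) == 1L) {
    out <- data.frame(run_id = runs, cf = 1, stringsAsFactors = FALSE)
    attr(out, "excluded_ircs") <- character(0)
    return(out)
  }
  if (any(irc_nrq$nrq <= 0, na.rm = TRUE)) stop_tt("IRC NRQs must be positive")
  # average (log scale) duplicates within (irc, run), then check coverage
  key <- interaction(irc_nrq$sample_id, irc_nrq$run_id, drop = TRUE)
  lg <- tapply(log(irc_nrq$nrq), key, mean)
  ids <- do.call(rbind, strsplit(names(lg), ".", fixed = TRUE))
  tab <- table(ids[, 1])
  complete <- names(tab)[tab == length(runs)]
  excluded <- setdiff(unique(irc_nrq$sample_id), complete)
  if (length(complete) < 2L)
    stop_tt("fewer than 2 IRCs measured on every run (%d excluded)",
            length(excluded))
  keep <- ids[, 1] %in% complete
  m <- tapply(lg[keep], list(ids[keep, 1], ids[keep, 2]), mean)
  m <- m[, as.character(runs), drop = FALSE]
  # CF_r = gmean_i( NRQ_ir / gmean_r' NRQ_ir' )
  centred <- m - rowMeans(m)
  cf <- exp(colMeans(centred))
  out <- data.frame(run_id = runs, cf = unname(cf[as.character(runs)]),
                    stringsAsFactors = FALSE)
  if (length(excluded))
    warning(sprintf("IRC(s) missing from some runs, excluded: %s",
                    paste(excluded, collapse = ", ")), call. = FALSE)
  attr(out, "excluded_ircs") <- excluded
  out
}

#' Intraclass correlation coefficient (one-way random effects)
#'
#' ICC(1) from one-way ANOVA mean squares: with between-subject mean
#' square MSB, within-subject mean square MSW and (average) group size k,
#' \code{ICC = (MSB - MSW) / (MSB + (k - 1) MSW)}. The confidence
#' interval and p-value come from the F distribution of MSB/MSW.
#' Unbalanced groups use the standard k0 adjustment. Negative estimates
#' are reported as computed.
#'
#' @param values numeric measurements.
#' @param subjects grouping factor (one level per subject/sample).
#' @param kind label carried through, e.g. "intra_T", "intra_S",
#'   "intra_TS", "inter_assay".
#' @param conf_level confidence level for the interval.
#' @return List (class \code{tl_icc}): kind, icc, ci_low, ci_high,
#'   p_value, n_subjects, n_obs, msb, msw.
#' @examples
#' compute_icc(c(1, 1, 2, 2, 3, 3), rep(1:3, each = 2))$icc # 1
#' @export
compute_icc <- function(values, subjects, kind = "intra", conf_level = 0.95) {
  ok <- !is.na(values) & !is.na(subjects)
  values <- values[ok]
  subjects <- factor(subjects[ok])
  ni <- as.vector(table(subjects))
  if (length(ni) < 2L) stop_tt("at least 2 subjects required")
  if (all(ni < 2L)) stop_tt("all subjects have a single measure")
  n <- length(ni)
  N <- length(values)
  gm <- group_mean(values, subjects)
  grand <- mean(values)
  ssb <- sum(ni * (gm - grand)^2)
  ssw <- sum((values - gm[as.integer(subjects)])^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (N - n)
  k0 <- (N - sum(ni^2) / N) / (n - 1)
  if (msw == 0) {
    res <- list(kind = kind, icc = 1, ci_low = 1, ci_high = 1, p_value = 0,
                n_subjects = n, n_obs = N, msb = msb, msw = msw)
    class(res) <- "tl_icc"
    return(res)
  }
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  f <- msb / msw
  df1 <- n - 1
  df2 <- N - n
  alpha <- 1 - conf_level
  fl <- f / stats::qf(1 - alpha / 2, df1, df2)
  fu <- f * stats::qf(1 - alpha / 2, df2, df1)
  res <- list(kind = kind, icc = icc,
              ci_low = (fl - 1) / (fl + k0 - 1),
              ci_high = (fu - 1) / (fu + k0 - 1),
              p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
              n_subjects = n, n_obs = N, msb = msb, msw = msw)
  class(res) <- "tl_icc"
  res
}

#' @export
print.tl_icc <- function(x, ...) {
  cat(sprintf("ICC [%s] = %.3f (95%% CI %.3f-%.3f), p = %.3g; %d subjects, %d measures\n",
              x$kind, x$icc, x$ci_low, x$ci_high, x$p_value,
              x$n_subjects, x$n_obs))
  invisible(x)
}

#' Relative telomere length (CNRQ) for one cohort assay
#'
#' Runs the full calibrated-normalised-relative-quantity chain on the
#' plate table of a single cohort (and, when present, a single visit):
#' standard-curve efficiency per target, replicate aggregation, delta-Cq
#' relative quantities against the per-run all-sample arithmetic mean Cq,
#' the T/S ratio (NRQ), inter-run calibrator correction (CNRQ), and
#' reliability ICCs (triplicate T, S and T/S; inter-assay on the IRC
#' CNRQs across runs). Normalisation never mixes cohorts: process each
#' cohort separately or use \code{\link{quantify_all}}.
#'
#' @param plates well-level plate table (see \code{\link{simulate_qpcr}}
#'   for the column contract).
#' @param cohort,age optional filters when the table carries those
#'   columns; after filtering the table must contain exactly one assay
#'   block.
#' @param efficiency "estimated" (default: applied from the dilution
#'   series) or a named numeric vector \code{c(T = ..., S = ...)} of
#'   assumed amplification factors.
#' @param max_spread replicate-spread QC threshold in cycles
#'   (non-blocking flag).
#' @return Object of class \code{tl_quant}: \code{quantities} data frame
#'   (sample_id, run_id, well_class, rq_T, rq_S, nrq, cnrq, QC flags),
#'   \code{cf}, \code{efficiency}, \code{icc}, \code{excluded}.
#' @export
quantify_cohort <- function(plates, cohort = NULL, age = NULL,
                            efficiency = "estimated", max_spread = 0.5) {
  p <- plates
  if (!is.null(cohort) && "cohort" %in% names(p))
    p <- p[p$cohort == cohort, , drop = FALSE]
  if (!is.null(age) && "age" %in% names(p))
    p <- p[p$age == age, , drop = FALSE]
  if (nrow(p) == 0L) stop_tt("no wells after filtering")
  for (col in c("cohort", "age"))
    if (col %in% names(p) && length(unique(p[[col]])) > 1L)
      stop_tt("plate table spans multiple %ss; use quantify_all()", col)
  need <- c("sample_id", "run_id", "target", "replicate", "cq", "well_class")
  if (!all(need %in% names(p)))
    stop_tt("plate table needs columns: %s", paste(need, collapse = ", "))
  if (any(p$cq <= 0, na.rm = TRUE)) stop_tt("Cq values must be positive")

  # efficiencies
  if (identical(efficiency, "estimated")) {
    dil <- p[p$well_class == "dilution", , drop = FALSE]
    if (nrow(dil) == 0L)
      stop_tt("no dilution wells; supply efficiency = c(T=, S=) instead")
    eff <- list(T = estimate_efficiency(dil, target = "T"),
                S = estimate_efficiency(dil, target = "S"))
  } else {
    if (!all(c("T", "S") %in% names(efficiency)))
      stop_tt("efficiency must be 'estimated' or a named c(T=, S=) vector")
    eff <- list(
      T = structure(list(target = "T", slope = -1 / log10(efficiency[["T"]]),
                         E = efficiency[["T"]],
                         efficiency_pct = (efficiency[["T"]] - 1) * 100,
                         r_squared = NA_real_, n_points = 0L),
                    class = "tl_efficiency"),
      S = structure(list(target = "S", slope = -1 / log10(efficiency[["S"]]),
                         E = efficiency[["S"]],
                         efficiency_pct = (efficiency[["S"]] - 1) * 100,
                         r_squared = NA_real_, n_points = 0L),
                    class = "tl_efficiency"))
  }
  E <- c(T = eff$T$E, S = eff$S$E)

  w <- p[p$well_class %in% c("sample", "irc"), , drop = FALSE]
  w <- w[!is.na(w$cq), , drop = FALSE]
  # replicate aggregation per (sample, run, target)
  key <- paste(w$sample_id, w$run_id, w$target, sep = "\r")
  kf <- factor(key, levels = unique(key))
  nrep <- as.vector(table(kf))
  if (any(nrep > 3L)) stop_tt("more than 3 replicates for some wells")
  agg <- data.frame(do.call(rbind, strsplit(levels(kf), "\r", fixed = TRUE)),
                    stringsAsFactors = FALSE)
  names(agg) <- c("sample_id", "run_id", "target")
  agg$mean_cq <- group_mean(w$cq, kf)
  agg$n_rep <- nrep
  rng <- tapply(w$cq, kf, function(z) max(z) - min(z))
  agg$flag_low_rep <- agg$n_rep < 2L
  agg$flag_spread <- as.vector(rng[levels(kf)]) > max_spread
  cls <- tapply(w$well_class, kf, function(z) z[1])
  agg$well_class <- as.vector(cls[levels(kf)])

  # per-(run, target) reference: arithmetic mean Cq of analysed samples
  refkey <- paste(agg$run_id, agg$target, sep = "\r")
  samp <- agg$well_class == "sample"
  if (!any(samp)) stop_tt("no study-sample wells present")
  ref <- tapply(agg$mean_cq[samp], refkey[samp], mean)
  # a run measured only for IRCs falls back to its own mean
  missing_ref <- setdiff(unique(refkey), names(ref))
  if (length(missing_ref)) {
    extra <- tapply(agg$mean_cq[refkey %in% missing_ref],
                    refkey[refkey %in% missing_ref], mean)
    ref <- c(ref, extra)
  }
  agg$rq <- NA_real_
  for (tgt in c("T", "S")) {
    i <- agg$target == tgt
    agg$rq[i] <- compute_rq(agg$mean_cq[i], as.vector(ref[refkey[i]]),
                            E = E[[tgt]])
  }

  # pair targets per (sample, run)
  at <- agg[agg$target == "T", ]
  as_ <- agg[agg$target == "S", ]
  m <- merge(at[, c("sample_id", "run_id", "well_class", "rq",
                    "flag_low_rep", "flag_spread")],
             as_[, c("sample_id", "run_id", "rq",
                     "flag_low_rep", "flag_spread")],
             by = c("sample_id", "run_id"), all = TRUE,
             suffixes = c("_T", "_S"))
  excluded <- m[is.na(m$rq_T) | is.na(m$rq_S), , drop = FALSE]
  if (nrow(excluded))
    warning(sprintf("%d sample(s) missing a target; excluded",
                    nrow(excluded)), call. = FALSE)
  m <- m[!is.na(m$rq_T) & !is.na(m$rq_S), , drop = FALSE]
  m$nrq <- compute_nrq(m$rq_T, m$rq_S)

  # inter-run calibration
  irc <- m[m$well_class == "irc", c("sample_id", "run_id", "nrq")]
  cf <- if (nrow(irc) && length(unique(m$run_id)) > 1L) {
    compute_inter_run_cf(irc)
  } else {
    data.frame(run_id = unique(m$run_id), cf = 1, stringsAsFactors = FALSE)
  }
  m$cnrq <- m$nrq / cf$cf[match(m$run_id, cf$run_id)]
  m$flag_low_rep <- m$flag_low_rep_T | m$flag_low_rep_S
  m$flag_spread <- m$flag_spread_T | m$flag_spread_S

  icc <- quant_iccs(w, agg, m, ref, refkey_by = refkey, E = E)

  quantities <- m[order(m$well_class != "sample", m$sample_id, m$run_id),
                  c("sample_id", "run_id", "well_class", "rq_T", "rq_S",
                    "nrq", "cnrq", "flag_low_rep", "flag_spread")]
  rownames(quantities) <- NULL
  structure(list(quantities = quantities, cf = cf, efficiency = eff,
                 icc = icc, excluded = excluded,
                 cohort = if ("cohort" %in% names(p)) p$cohort[1] else NA,
                 age = if ("age" %in% names(p)) p$age[1] else NA),
            class = "tl_quant")
}

# reliability ICCs for one quantified block
quant_iccs <- function(w, agg, m, ref, refkey_by, E) {
  ws <- w[w$well_class == "sample", , drop = FALSE]
  rk <- paste(ws$run_id, ws$target, sep = "\r")
  rq_rep <- ifelse(ws$target == "T",
                   E[["T"]]^(as.vector(ref[rk]) - ws$cq),
                   E[["S"]]^(as.vector(ref[rk]) - ws$cq))
  subj <- paste(ws$sample_id, ws$run_id, sep = "\r")
  icc <- list()
  for (tgt in c("T", "S")) {
    i <- ws$target == tgt
    icc[[paste0("intra_", tgt)]] <-
      try_icc(rq_rep[i], subj[i], paste0("intra_", tgt))
  }
  # replicate-wise T/S ratio: pair T and S wells by replicate index
  tw <- ws[ws$target == "T", c("sample_id", "run_id", "replicate")]
  tw$rq <- rq_rep[ws$target == "T"]
  sw <- ws[ws$target == "S", c("sample_id", "run_id", "replicate")]
  sw$rq <- rq_rep[ws$target == "S"]
  ts <- merge(tw, sw, by = c("sample_id", "run_id", "replicate"),
              suffixes = c("_T", "_S"))
  icc$intra_TS <- try_icc(ts$rq_T / ts$rq_S,
                          paste(ts$sample_id, ts$run_id), "intra_TS")
  irc_c <- m[m$well_class == "irc", , drop = FALSE]
  icc$inter_assay <- if (length(unique(irc_c$run_id)) > 1L)
    try_icc(irc_c$cnrq, irc_c$sample_id, "inter_assay") else NULL
  icc
}

try_icc <- function(values, subjects, kind) {
  tryCatch(compute_icc(values, subjects, kind = kind),
           error = function(e) NULL)
}

#' @export
print.tl_quant <- function(x, ...) {
  ns <- sum(x$quantities$well_class == "sample")
  cat(sprintf("CNRQ quantification%s%s: %d samples, %d runs\n",
              if (is.na(x$cohort)) "" else paste0(" [", x$cohort, "]"),
              if (is.na(x$age)) "" else paste0(" (age ", x$age, ")"),
              ns, nrow(x$cf)))
  cat(sprintf("  efficiency: T %.1f%%, S %.1f%%\n",
              x$efficiency$T$efficiency_pct, x$efficiency$S$efficiency_pct))
  for (ic in x$icc) if (!is.null(ic))
    cat(sprintf("  ICC %s = %.3f\n", ic$kind, ic$icc))
  invisible(x)
}

#' Quantify every cohort/visit assay block of a plate table
#'
#' Splits the plate table by cohort (and visit, when an \code{age} column
#' is present), runs \code{\link{quantify_cohort}} on each block
#' independently — normalisation and inter-run calibration never mix
#' cohorts — and binds the study-sample CNRQs.
#'
#' @inheritParams quantify_cohort
#' @return List (class \code{tl_quant_set}): \code{blocks} (named list of
#'   \code{tl_quant}) and \code{cnrq} (data frame cohort, age, sample_id,
#'   nrq, cnrq, flags).
#' @export
quantify_all <- function(plates, efficiency = "estimated", max_spread = 0.5) {
  co <- if ("cohort" %in% names(plates)) plates$cohort else "all"
  ag <- if ("age" %in% names(plates)) plates$age else NA
  keys <- unique(data.frame(cohort = co, age = ag, stringsAsFactors = FALSE))
  blocks <- list()
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- co == keys$cohort[i] & (is.na(keys$age[i]) | ag == keys$age[i])
    q <- quantify_cohort(plates[sel, , drop = FALSE],
                         efficiency = efficiency, max_spread = max_spread)
    nm <- paste(keys$cohort[i], keys$age[i], sep = "_y")
    blocks[[nm]] <- q
    s <- q$quantities[q$quantities$well_class == "sample", , drop = FALSE]
    if (nrow(s))
      rows[[nm]] <- data.frame(cohort = keys$cohort[i], age = keys$age[i],
                               s[, c("sample_id", "nrq", "cnrq",
                                     "flag_low_rep", "flag_spread")],
                               stringsAsFactors = FALSE)
  }
  cnrq <- do.call(rbind, rows)
  rownames(cnrq) <- NULL
  structure(list(blocks = blocks, cnrq = cnrq), class = "tl_quant_set")
}

#' @export
print.tl_quant_set <- function(x, ...) {
  cat(sprintf("CNRQ quantification: %d assay blocks, %d sample quantities\n",
              length(x$blocks), nrow(x$cnrq)))
  invisible(x)
}
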