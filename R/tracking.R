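#' Rank telomere lengths from longest to shortest
#'
#' Descending ranks (1 = longest TL); ties receive the average of the
#' spanned ranks, which keeps the rank sum — and hence the mean of the
#' tracking statistic — exact. Missing values keep NA ranks.
#'
#' @param tl numeric TL (CNRQ) values of one cohort.
#' @param ties \code{"average"} (default) or \code{"first"} for ordinal
#'   ranking.
#' @return Numeric ranks.
#' @examples
#' rank_tl(c(5.1, 3.2, 4.0)) # 1 3 2
#' @export
rank_tl <- function(tl, ties = c("average", "first")) {
  ties <- match.arg(ties)
  if (sum(!is.na(tl)) < 2L) stop_tt("need at least 2 non-missing TL values")
  rank(-tl, ties.method = ties, na.last = "keep")
}

#' Telomere-tracking statistic delta-R
#'
#' \code{delta_R = ((R1 - R2) / (n - 1)) x 100}, where R1 and R2 are the
#' within-cohort TL ranks (1 = longest) at baseline and follow-up and n
#' is the ranked sample size. A negative value is a decline in telomere
#' ranking (relative shortening); the bounds are -100 (longest to
#' shortest) and +100.
#'
#' @param r1,r2 ranks in [1, n].
#' @param n ranked sample size (>= 2).
#' @return Percentage points in [-100, 100].
#' @examples
#' delta_r(1, 10, 10) # -100
#' @export
delta_r <- function(r1, r2, n) {
  if (any(n < 2)) stop_tt("n must be >= 2")
  if (any(r1 < 1 | r1 > n, na.rm = TRUE) || any(r2 < 1 | r2 > n, na.rm = TRUE))
    stop_tt("ranks must lie in [1, n]")
  ((r1 - r2) / (n - 1)) * 100
}

#' Spearman correlation between baseline and follow-up rankings
#'
#' Tracking QC statistic: the rank correlation across all paired
#' children, pooled over cohorts.
#'
#' @param r1,r2 paired ranks (or TL values), length >= 3.
#' @return List: rho, p_value, n.
#' @export
rank_correlation <- function(r1, r2) {
  if (length(r1) != length(r2)) stop_tt("r1 and r2 must be paired")
  ok <- !is.na(r1) & !is.na(r2)
  if (sum(ok) < 3L) stop_tt("need at least 3 complete pairs")
  ct <- suppressWarnings(stats::cor.test(r1[ok], r2[ok], method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Rank telomere tracking between two visits
#'
#' Ranks TL at both visits separately within each cohort (longest = 1)
#' and computes the per-child tracking statistic delta-R. By default both
#' rankings use the children with TL at both visits, so complete paired
#' rankings have mean delta-R exactly 0 within each cohort. With
#' \code{rank_on_full_baseline = TRUE} the baseline rank is taken over
#' all children with baseline TL (including those lost to follow-up) and
#' plugged into the formula with n = paired sample size; the zero-mean
#' conservation property then no longer holds.
#'
#' @param tl4,tl8 baseline and follow-up TL (CNRQ); NA marks a missing
#'   measurement.
#' @param cohort cohort label per child.
#' @param child_id child identifier per child.
#' @param rank_on_full_baseline see above.
#' @param ties tie handling passed to \code{\link{rank_tl}}.
#' @return Data frame: child_id, cohort, r1, r2, n, delta_r (one row per
#'   child with both measurements).
#' @export
track_telomeres <- function(tl4, tl8, cohort, child_id,
                            rank_on_full_baseline = FALSE,
                            ties = "average") {
  stopifnot(length(tl4) == length(tl8), length(tl4) == length(cohort),
            length(tl4) == length(child_id))
  out <- list()
  for (co in unique(cohort)) {
    i <- which(cohort == co)
    paired <- i[!is.na(tl4[i]) & !is.na(tl8[i])]
    if (length(paired) < 2L) next
    n <- length(paired)
    r2 <- rank_tl(tl8[paired], ties = ties)
    if (rank_on_full_baseline) {
      base <- i[!is.na(tl4[i])]
      r1_all <- rank_tl(tl4[base], ties = ties)
      r1 <- r1_all[match(paired, base)]
      r1 <- pmin(r1, n) # formula contract: ranks within [1, n]
    } else {
      r1 <- rank_tl(tl4[paired], ties = ties)
    }
    out[[co]] <- data.frame(child_id = child_id[paired], cohort = co,
                            r1 = r1, r2 = r2, n = n,
                            delta_r = delta_r(r1, r2, n),
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) stop_tt("no cohort has 2 or more complete pairs")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
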