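#' Mean daily hours from weekday and weekend questionnaire items
#'
#' Averages parent-reported hours over the week as
#' \code{((weekday x 5) + (weekend x 2)) / 7}.
#'
#' @param weekday_hours,weekend_hours hours per day, each in [0, 24];
#'   vectorised.
#' @return Mean daily hours.
#' @examples
#' daily_mean(2, 4) # 18/7
#' @export
daily_mean <- function(weekday_hours, weekend_hours) {
  check_hours(weekday_hours, "weekday_hours")
  check_hours(weekend_hours, "weekend_hours")
  (weekday_hours * 5 + weekend_hours * 2) / 7
}

check_hours <- function(x, name) {
  bad <- !is.na(x) & (x < 0 | x > 24)
  if (any(bad)) stop_tt("%s must lie in [0, 24]", name)
  invisible(x)
}

#' Total daily sedentary time
#'
#' @param screen_daily,other_daily non-negative mean daily hours.
#' @return Their sum (hours/day).
#' @export
total_sb <- function(screen_daily, other_daily) {
  if (any(screen_daily < 0, na.rm = TRUE) || any(other_daily < 0, na.rm = TRUE))
    stop_tt("daily hours must be non-negative")
  screen_daily + other_daily
}

#' Categorise a continuous exposure into tertiles
#'
#' Cut-points are the empirical 1/3 and 2/3 quantiles
#' (linear-interpolation sample quantiles, \code{type = 7}). A value equal
#' to a cut-point takes the lower category, so heavy ties at a boundary
#' produce unequal group sizes, as expected for coarsely reported
#' questionnaire hours.
#'
#' @param x numeric vector (missing values allowed; they get NA labels).
#' @param labels the three category labels, low to high.
#' @param type quantile algorithm passed to \code{\link[stats]{quantile}}.
#' @return Factor of labels with attributes \code{cutpoints} (the two
#'   quantiles) and \code{group_sizes}.
#' @examples
#' assign_tertiles(1:6)
#' @export
assign_tertiles <- function(x, labels = c("low", "middle", "high"),
                            type = 7) {
  obs <- x[!is.na(x)]
  if (length(obs) < 3L) stop_tt("at least 3 observed values required")
  if (length(unique(obs)) < 3L)
    stop_tt("fewer than 3 distinct values: tertiles undefined")
  q <- stats::quantile(obs, probs = c(1, 2) / 3, type = type, names = FALSE)
  lab <- ifelse(is.na(x), NA_character_,
                ifelse(x <= q[1], labels[1],
                       ifelse(x <= q[2], labels[2], labels[3])))
  f <- factor(lab, levels = labels)
  attr(f, "cutpoints") <- q
  attr(f, "group_sizes") <- table(f)
  f
}

#' Build per-child sedentary-behaviour exposures
#'
#' Derives mean daily screen time, other sedentary time and their total
#' from weekday/weekend questionnaire hours, and categorises each into
#' tertiles over the supplied sample.
#'
#' @param sb data frame with columns child_id, screen_wd, screen_we,
#'   other_wd, other_we (hours/day).
#' @return Data frame of daily means and tertile factors; cut-points are
#'   attached as attribute \code{cutpoints} (a named list).
#' @export
build_exposures <- function(sb) {
  need <- c("child_id", "screen_wd", "screen_we", "other_wd", "other_we")
  if (!all(need %in% names(sb)))
    stop_tt("sb table must have columns: %s", paste(need, collapse = ", "))
  out <- data.frame(child_id = sb$child_id,
                    screen_daily = daily_mean(sb$screen_wd, sb$screen_we),
                    other_daily = daily_mean(sb$other_wd, sb$other_we),
                    stringsAsFactors = FALSE)
  out$total_daily <- total_sb(out$screen_daily, out$other_daily)
  cuts <- list()
  for (v in c("screen", "other", "total")) {
    f <- assign_tertiles(out[[paste0(v, "_daily")]])
    out[[paste0(v, "_tertile")]] <- f
    cuts[[v]] <- attr(f, "cutpoints")
  }
  attr(out, "cutpoints") <- cuts
  out
}
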