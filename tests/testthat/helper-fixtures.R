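# Fixtures built in code: tiny plate tables with known chemistry.

# A noise-free single-run plate: n samples with given true T/S ratios,
# perfect doubling chemistry (E = 2 for both targets), triplicates.
make_single_plate <- function(ratios, input = rep(1, length(ratios)),
                              base_t = 20, base_s = 24, reps = 3) {
  n <- length(ratios)
  ids <- sprintf("S%02d", seq_len(n))
  rows <- list()
  for (tgt in c("T", "S")) {
    q <- if (tgt == "T") input * ratios else input
    base <- if (tgt == "T") base_t else base_s
    idx <- rep(seq_len(n), each = reps)
    rows[[tgt]] <- data.frame(
      sample_id = ids[idx], run_id = "r1", target = tgt,
      replicate = rep(seq_len(reps), n),
      cq = base - log2(q[idx]),
      well_class = "sample", dilution_factor = NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Brute-force 2^(-ddCq) oracle relative to the all-sample mean Cq,
# computed straight from replicate-mean Cq values.
oracle_ddcq <- function(plate) {
  agg <- aggregate(cq ~ sample_id + target, data = plate, FUN = mean)
  wide <- merge(agg[agg$target == "T", c("sample_id", "cq")],
                agg[agg$target == "S", c("sample_id", "cq")],
                by = "sample_id", suffixes = c("_t", "_s"))
  ddcq <- (wide$cq_t - mean(wide$cq_t)) - (wide$cq_s - mean(wide$cq_s))
  data.frame(sample_id = wide$sample_id, ts = 2^(-ddcq),
             stringsAsFactors = FALSE)
}

# noise-free dilution-series wells for one target
make_dilution <- function(E, steps = 2^(0:5), base = 20, target = "T") {
  data.frame(sample_id = "POOL", run_id = "r1", target = target,
             replicate = 1L, cq = base + log(steps) / log(E),
             well_class = "dilution", dilution_factor = steps,
             stringsAsFactors = FALSE)
}

# small default study configuration for fast end-to-end tests
small_config <- function(seed = 1, n = 60, ...) {
  sim_config(seed = seed, n_per_cohort = n, ...)
}

# analysis table straight from the truth table (no qPCR layer): fast
# input for association-module tests
make_truth_analysis <- function(sim) {
  d <- merge(sim$cohort, build_exposures(sim$sb)[, c("child_id",
                                                     "screen_daily",
                                                     "other_daily",
                                                     "total_daily")],
             by = "child_id")
  d <- merge(d, sim$truth[, c("child_id", "tl4_true", "tl8_true",
                              "followed")], by = "child_id")
  d$tl4 <- d$tl4_true
  d$tl8 <- ifelse(d$followed, d$tl8_true, NA_real_)
  trk <- track_telomeres(d$tl4, d$tl8, d$cohort, d$child_id)
  merge(d, trk[, c("child_id", "delta_r")], by = "child_id", all.x = TRUE)
}
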