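test_that("standard-curve efficiency matches closed forms", {
  # perfect doubling: slope -1/log10(2), efficiency 100%
  dil <- make_dilution(E = 2)
  eff <- estimate_efficiency(dil, target = "T")
  expect_equal(eff$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(eff$E, 2, tolerance = 1e-9)
  expect_equal(eff$efficiency_pct, 100, tolerance = 1e-6)
  expect_equal(eff$r_squared, 1, tolerance = 1e-9)

  # closed-form oracle: build a series with an exact slope of -3.10
  slope <- -3.10
  d2 <- data.frame(dilution_factor = 10^(0:4),
                   cq = 25 + slope * (-(0:4)), # cq = 25 + slope*log10(q)
                   target = "T")
  e2 <- estimate_efficiency(d2)
  expect_equal(e2$slope, slope, tolerance = 1e-9)
  expect_equal(e2$E, 10^(1 / 3.10), tolerance = 1e-9)
  expect_equal(e2$efficiency_pct, (10^(1 / 3.10) - 1) * 100,
               tolerance = 1e-6)
})

test_that("degenerate dilution series are refused", {
  one <- data.frame(dilution_factor = 1, cq = 20)
  expect_error(estimate_efficiency(one), "3 distinct")
  two <- data.frame(dilution_factor = c(1, 2, 1, 2), cq = c(20, 21, 20, 21))
  expect_error(estimate_efficiency(two), "3 distinct")
})

test_that("replicate aggregation is an arithmetic mean with QC flags", {
  expect_equal(aggregate_replicates(c(20, 20, 20))$mean_cq, 20)
  r <- aggregate_replicates(c(20.0, 20.2))
  expect_equal(r$mean_cq, 20.1)
  expect_false(r$flag_low_rep)
  expect_false(r$flag_spread)
  single <- aggregate_replicates(20.0)
  expect_equal(single$mean_cq, 20.0)
  expect_true(single$flag_low_rep)
  expect_true(aggregate_replicates(c(19.5, 20.2, 20.1))$flag_spread)
  expect_error(aggregate_replicates(numeric(0)), "no replicate")
})

test_that("delta-Cq relative quantities follow E^(ref - cq)", {
  expect_equal(compute_rq(20, 20, E = 2), 1)
  expect_equal(compute_rq(19, 20, E = 2), 2)
  expect_equal(compute_rq(20.5, 20, E = 2.07), 2.07^(-0.5))
  expect_error(compute_rq(20, 20, E = 1), "E must")
  expect_equal(compute_nrq(1, 1), 1)
  expect_equal(compute_nrq(2, 1), 2)
  expect_equal(compute_nrq(1.5, 0.5), 3)
  expect_error(compute_nrq(1, 0), "positive")
})

test_that("inter-run correction reproduces hand-computed geometric means", {
  # two runs where every IRC doubles on run 2: per-IRC geometric mean over
  # runs is v*sqrt(2), so CF1 = 1/sqrt(2), CF2 = sqrt(2), ratio 2
  v <- c(0.8, 1.1, 1.4)
  irc <- data.frame(sample_id = rep(c("I1", "I2", "I3"), 2),
                    run_id = rep(c("r1", "r2"), each = 3),
                    nrq = c(v, 2 * v))
  cf <- compute_inter_run_cf(irc)
  expect_equal(cf$cf[cf$run_id == "r1"], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(cf$cf[cf$run_id == "r2"], sqrt(2), tolerance = 1e-12)
  expect_equal(cf$cf[cf$run_id == "r2"] / cf$cf[cf$run_id == "r1"], 2,
               tolerance = 1e-12)
  # a sample's CNRQ is then invariant to which run measured it
  nrq_run1 <- 0.9
  nrq_run2 <- 2 * 0.9 # same sample, doubled like the IRCs on run 2
  expect_equal(nrq_run1 / cf$cf[cf$run_id == "r1"],
               nrq_run2 / cf$cf[cf$run_id == "r2"], tolerance = 1e-12)
})

test_that("geometric mean of correction factors is 1 for any input", {
  set.seed(17)
  for (rep in 1:10) {
    n_irc <- sample(2:8, 1)
    n_run <- sample(2:6, 1)
    irc <- expand.grid(sample_id = sprintf("I%d", seq_len(n_irc)),
                       run_id = sprintf("r%d", seq_len(n_run)))
    irc$nrq <- rlnorm(nrow(irc), 0, 0.5)
    cf <- compute_inter_run_cf(irc)
    expect_equal(exp(mean(log(cf$cf))), 1, tolerance = 1e-12)
  }
})

test_that("single-run input yields CF = 1, and incomplete IRCs are handled", {
  one <- data.frame(sample_id = c("I1", "I2"), run_id = "r1", nrq = c(1, 2))
  expect_equal(compute_inter_run_cf(one)$cf, 1)
  # an IRC missing from one run is flagged and excluded
  irc <- expand.grid(sample_id = sprintf("I%d", 1:3),
                     run_id = c("r1", "r2"))
  irc$nrq <- rlnorm(6)
  irc <- irc[!(irc$sample_id == "I3" & irc$run_id == "r2"), ]
  expect_warning(cf <- compute_inter_run_cf(irc), "excluded")
  expect_equal(attr(cf, "excluded_ircs"), "I3")
  # fewer than 2 complete IRCs across >= 2 runs is an error
  bad <- irc[!(irc$sample_id == "I2" & irc$run_id == "r2"), ]
  expect_error(suppressWarnings(compute_inter_run_cf(bad)), "fewer than 2")
})

test_that("ICC limits: perfect repeatability and no between-subject variance", {
  v <- rep(c(1, 2, 3, 4), each = 3)
  s <- rep(1:4, each = 3)
  r <- compute_icc(v, s)
  expect_equal(r$icc, 1, tolerance = 1e-12)
  expect_equal(r$p_value, 0)
  # equal subject means, noisy replicates: ICC <= 0, reported as computed
  v2 <- c(1, 3, 2, 2, 3, 1, 1, 2, 3)
  r2 <- compute_icc(v2, rep(1:3, each = 3))
  expect_true(r2$icc <= 0)
  expect_error(compute_icc(c(1, 2), c(1, 2)), "single measure")
})

test_that("ICC recovers the variance-components ratio", {
  # between-SD 1.0, within-SD 0.5 => ICC = 1/(1 + 0.25) = 0.8
  set.seed(8)
  n <- 500
  mu <- rnorm(n, 10, 1.0)
  v <- rep(mu, each = 3) + rnorm(3 * n, 0, 0.5)
  r <- compute_icc(v, rep(seq_len(n), each = 3), kind = "intra")
  expect_equal(r$icc, 0.8, tolerance = 0.03)
  expect_true(r$ci_low < r$icc && r$icc < r$ci_high)
  expect_lt(r$p_value, 1e-10)
})

test_that("ICC agrees with a variance-components oracle (lme4)", {
  skip_if_not_installed("lme4")
  set.seed(12)
  n <- 120
  mu <- rnorm(n, 0, 0.8)
  v <- rep(mu, each = 3) + rnorm(3 * n, 0, 0.6)
  s <- factor(rep(seq_len(n), each = 3))
  r <- compute_icc(v, s)
  fit <- lme4::lmer(v ~ 1 + (1 | s),
                    control = lme4::lmerControl(calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  icc_reml <- vc$vcov[1] / sum(vc$vcov)
  expect_equal(r$icc, icc_reml, tolerance = 0.02)
})

test_that("noise-free plates round-trip to true T/S up to one scale factor", {
  cfg <- small_config(seed = 3, n = 50, cq_noise_sd = 0, run_shift_sd = 0)
  sim <- simulate_study(cfg)
  for (co in c("cohort_A", "cohort_B")) {
    q <- quantify_cohort(sim$plates, cohort = co, age = 4)
    s <- q$quantities[q$quantities$well_class == "sample", ]
    truth <- sim$truth$tl4_true[match(s$sample_id, sim$truth$child_id)]
    ratio <- s$cnrq / truth
    expect_lt(max(ratio) / min(ratio) - 1, 1e-9)
  }
})

test_that("within-run Cq shifts leave that run's RQ unchanged", {
  cfg <- small_config(seed = 6, n = 45, cq_noise_sd = 0.05,
                      run_shift_sd = 0.3)
  sim <- simulate_study(cfg)
  p <- sim$plates[sim$plates$cohort == "cohort_A" & sim$plates$age == 4, ]
  run1 <- unique(p$run_id)[1]
  p2 <- p
  sel <- p2$run_id == run1 & p2$target == "T"
  p2$cq[sel] <- p2$cq[sel] + 2.5
  q1 <- quantify_cohort(p)
  q2 <- quantify_cohort(p2)
  m <- merge(q1$quantities, q2$quantities, by = c("sample_id", "run_id"))
  expect_equal(m$rq_T.x, m$rq_T.y, tolerance = 1e-12)
  expect_equal(m$cnrq.x, m$cnrq.y, tolerance = 1e-12)
})

test_that("cohorts processed jointly equal cohorts processed separately", {
  cfg <- small_config(seed = 9, n = 40)
  sim <- simulate_study(cfg)
  all_q <- quantify_all(sim$plates)
  for (co in cfg$cohorts) {
    solo <- quantify_cohort(sim$plates, cohort = co, age = 4)
    s_solo <- solo$quantities[solo$quantities$well_class == "sample", ]
    joint <- all_q$cnrq[all_q$cnrq$cohort == co & all_q$cnrq$age == 4, ]
    m <- merge(s_solo, joint, by = "sample_id")
    expect_equal(m$cnrq.x, m$cnrq.y, tolerance = 1e-12)
  }
})

test_that("a sample missing one target is flagged and excluded", {
  plate <- make_single_plate(ratios = c(1, 2, 0.5, 1.5))
  plate <- plate[!(plate$sample_id == "S02" & plate$target == "S"), ]
  expect_warning(q <- quantify_cohort(plate, efficiency = c(T = 2, S = 2)),
                 "missing a target")
  expect_false("S02" %in% q$quantities$sample_id)
  expect_true("S02" %in% q$excluded$sample_id)
})

test_that("quantification reports reliability ICCs in plausible ranges", {
  cfg <- small_config(seed = 10, n = 80)
  sim <- simulate_study(cfg)
  q <- quantify_cohort(sim$plates, cohort = "cohort_A", age = 4)
  for (k in c("intra_T", "intra_S", "intra_TS")) {
    expect_s3_class(q$icc[[k]], "tl_icc")
    expect_gt(q$icc[[k]]$icc, 0.7)
    expect_lte(q$icc[[k]]$icc, 1)
  }
  expect_gt(q$icc$inter_assay$icc, 0.5)
  expect_equal(q$efficiency$T$E, 2.07, tolerance = 0.05)
  expect_equal(q$efficiency$S$E, 2.0, tolerance = 0.05)
})
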