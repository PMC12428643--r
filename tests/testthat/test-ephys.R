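test_that("success calling applies the noise-threshold rule", {
  expect_true(call_success(20, noise_sd = 2, threshold_k = 3))
  expect_false(call_success(0, noise_sd = 2))
  expect_false(call_success(6, noise_sd = 2))  # exactly 3 * SD is a failure
  expect_equal(call_success(c(20, 0, 7, 5), 2), c(TRUE, FALSE, TRUE, FALSE))
  expect_error(call_success(10, noise_sd = 0), "> 0")
  expect_error(call_success(-1, noise_sd = 2), "positive")
})

test_that("per-trial calls match generator truth almost always", {
  acc <- vapply(1:100, function(s) {
    ss <- simulate_minimal_stim(ephys_sim_config(
      pr_basal = 0.5, pr_post = 0.5,
      potency_dist = function(n) rep(20, n), noise_sd = 2, seed = s))
    mean(call_success(ss$trials$peak_pA, 2, 3) == ss$trials$truth_success)
  }, numeric(1))
  expect_gt(mean(acc), 0.99)
})

test_that("efficacy, potency and Pr follow their definitions", {
  sp <- synaptic_params(c(10, 0, 10, 0), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(sp$efficacy_pA, 5)
  expect_equal(sp$potency_pA, 10)
  expect_equal(sp$Pr, 0.5)

  allfail <- synaptic_params(c(0, 0, 0), c(FALSE, FALSE, FALSE))
  expect_equal(allfail$efficacy_pA, 0)
  expect_equal(allfail$Pr, 0)
  expect_false(allfail$potency_defined)
  expect_true(is.na(allfail$potency_pA))

  expect_error(synaptic_params(numeric(0), logical(0)), "at least one")
})

test_that("with zero failure peaks, efficacy = Pr * potency exactly", {
  for (s in 1:20) {
    ss <- simulate_minimal_stim(ephys_sim_config(
      pr_basal = stats::runif(1, 0.2, 0.8), seed = s))
    tr <- ss$trials
    sp <- synaptic_params(ifelse(tr$truth_success, tr$peak_pA, 0),
                          tr$truth_success, failure_mode = "zero")
    if (sp$potency_defined) {
      expect_equal(sp$efficacy_pA, sp$Pr * sp$potency_pA)
    }
  }
})

test_that("Pr is recovered across release-probability regimes", {
  for (pr in c(0.2, 0.5, 0.8)) {
    est <- vapply(1:200, function(s) {
      ss <- simulate_minimal_stim(ephys_sim_config(
        pr_basal = pr, pr_post = pr,
        potency_dist = function(n) rep(20, n), noise_sd = 2,
        seed = 10000 * pr + s))
      tr <- ss$trials[ss$trials$phase == "basal", ]
      synaptic_params(tr$peak_pA, call_success(tr$peak_pA, 2, 3))$Pr
    }, numeric(1))
    se <- sqrt(pr * (1 - pr) / 150) / sqrt(200)
    expect_lt(abs(mean(est) - pr), 3 * se)
  }
})

test_that("stability QC applies the 20% rule with an inclusive boundary", {
  expect_true(stability_qc(list(Rs = rep(20, 10)))$stable)
  expect_false(stability_qc(list(Rs = c(20, 21, 25)))$stable)   # +25%
  expect_true(stability_qc(list(Rs = c(20, 22, 24)))$stable)    # exactly +20%
  expect_true(stability_qc(list(Vm = c(-70, -75, -80)))$stable) # |.| on negatives
  expect_warning(q <- stability_qc(list(bad = c(0, 1, 2), Rs = rep(10, 3))),
                 "skipped")
  expect_true(q$stable)
  expect_error(stability_qc(list(Rs = numeric(0))), "empty")
})

test_that("tightening the QC tolerance never rescues an unstable channel", {
  withr::with_seed(5, {
    for (i in 1:20) {
      s <- 20 * cumprod(c(1, 1 + stats::rnorm(30, 0, 0.05)))
      stable_at <- vapply(seq(0.5, 0.05, by = -0.05), function(tol)
        stability_qc(list(ch = s), tolerance = tol)$stable, logical(1))
      # once unstable at some tolerance, unstable at every tighter one
      expect_true(all(diff(as.integer(stable_at)) <= 0))
    }
  })
})

test_that("outcome classification handles identity, exclusion and windows", {
  ss <- simulate_minimal_stim(ephys_sim_config(seed = 31))
  tr <- ss$trials
  # copy the basal trials into the post window: differences are exactly 0
  post5 <- tr$t_s >= 300 & tr$t_s < 600
  tr$peak_pA[post5] <- tr$peak_pA[tr$t_s < 300]
  tr$truth_success[post5] <- tr$truth_success[tr$t_s < 300]
  oc <- classify_outcome(tr)
  expect_equal(oc$call, "unchanged")
  expect_equal(oc$p_value, 1)

  # unstable recordings are excluded with a reason
  bad_qc <- stability_qc(list(Rs = c(20, 26)))
  oc2 <- suppressMessages(classify_outcome(ss, qc = bad_qc))
  expect_equal(oc2$call, "excluded")
  expect_match(oc2$reason, "unstable")

  expect_error(classify_outcome(ss$trials[1:40, ]), "30 trials")
})

test_that("efficacy time course is anchored at 1 and uses half-open bins", {
  ss <- simulate_minimal_stim(ephys_sim_config(
    pr_basal = 1, pr_post = 1, potency_dist = function(n) rep(20, n),
    noise_sd = 0, seed = 3))
  tc <- efficacy_timecourse(ss)
  expect_true(all(abs(tc$efficacy_norm - 1) < 1e-12))
  expect_equal(nrow(tc), 15)

  # trial at exactly 60 s belongs to the second bin
  tr <- data.frame(trial_idx = 1:4, t_s = c(0, 59, 60, 100),
                   peak_pA = c(10, 10, 30, 30))
  tc2 <- efficacy_timecourse(tr, bin_s = 60, basal_window = c(0, 60))
  expect_equal(tc2$efficacy_pA[tc2$bin == 1], 10)
  expect_equal(tc2$efficacy_pA[tc2$bin == 2], 30)

  # a release-probability step shows up as post bins below 1
  ss3 <- simulate_minimal_stim(ephys_sim_config(pr_basal = 0.5,
                                                pr_post = 0.1, seed = 13))
  tc3 <- efficacy_timecourse(ss3, failure_mode = "zero")
  expect_true(all(tc3$efficacy_norm[tc3$bin > 5] < 1))

  expect_error(efficacy_timecourse(
    data.frame(trial_idx = 1:40, t_s = seq(0, 78, 2), peak_pA = 0)),
    "zero")
})

test_that("cohort proportions are exact fractions at two decimals", {
  cs <- cohort_summary(c(rep("potentiated", 7), rep("unchanged", 6)))
  expect_equal(cs$percent[cs$call == "potentiated"], 53.85)
  expect_equal(cs$percent[cs$call == "depressed"], 0)
  expect_equal(attr(cs, "n_total"), 13)
  expect_lt(abs(sum(cs$percent) - 100), 0.02)

  calls <- c(rep("depressed", 6), rep("unchanged", 7), "potentiated")
  expect_equal(cohort_summary(calls)$n,
               cohort_summary(sample(calls))$n)

  cs2 <- cohort_summary(c("potentiated", "excluded", "unchanged"))
  expect_equal(attr(cs2, "n_total"), 2)
  expect_equal(attr(cs2, "n_excluded"), 1)
  expect_error(cohort_summary(character(0)), "at least one")
  expect_error(cohort_summary("weird"), "unknown")
})
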