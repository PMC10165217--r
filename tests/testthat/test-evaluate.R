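# Evaluation harness: the convergence filter, metric summaries, the
# replication-size formula, and the case-study report.

test_that("convergence filter applies the estimability window", {
  mk <- function(b1, conv) list(coefficients = c(0, b1), converged = conv)
  expect_false(convergence_filter(mk(log(1000), TRUE)))
  expect_true(convergence_filter(mk(log(998), TRUE)))
  expect_true(convergence_filter(mk(0, TRUE)))
  expect_false(convergence_filter(mk(0, FALSE)))
  expect_false(convergence_filter(mk(log(0.0009), TRUE)))
  expect_false(convergence_filter(mk(NA_real_, TRUE)))
})

test_that("a separated replicate fails under ML but passes under Firth", {
  d <- data.frame(y = c(rep(1, 3), rep(1, 4), rep(0, 33)),
                  x = c(rep(1, 3), rep(0, 37)))
  ml <- sparselogit(y ~ x, d, method = "ML", ci = "none")
  fr <- sparselogit(y ~ x, d, method = "FIR", ci = "none")
  expect_false(convergence_filter(ml))
  expect_true(convergence_filter(fr))
})

test_that("summarize_metrics reproduces a hand computation", {
  # four fits, two passing the ML filter; truth OR = 1
  recs <- list(
    ML = data.frame(est = c(0.5, 9.9, -0.3, NA),
                    low = c(-0.1, 9, -1, NA), high = c(1.2, 11, 0.4, NA),
                    pass = c(TRUE, FALSE, TRUE, FALSE), skipped = FALSE),
    FIR = data.frame(est = c(0.4, 2.0, -0.2, 0.1),
                     low = c(-0.2, 1, -0.9, -0.5),
                     high = c(1.0, 3, 0.5, 0.7),
                     pass = c(TRUE, TRUE, TRUE, TRUE), skipped = FALSE))
  mt <- summarize_metrics(recs, true_or = 1)
  ml <- mt$metrics[mt$metrics$method == "ML", ]
  expect_equal(ml$n_effective, 2L)
  expect_equal(ml$average_or, exp(mean(c(0.5, -0.3))))
  expect_equal(ml$bias_log_or, mean(c(0.5, -0.3)))
  expect_equal(ml$coverage, 1)        # both intervals contain 0
  expect_equal(ml$convergence_rate, 0.5)
  fir <- mt$metrics[mt$metrics$method == "FIR", ]
  # restriction: averaged over exactly the ML-pass replicates
  expect_equal(fir$n_effective, 2L)
  expect_equal(fir$average_or, exp(mean(c(0.4, -0.2))))
  # all estimates equal to truth -> bias 0, average OR = true OR
  same <- list(ML = data.frame(est = rep(log(4), 3), low = 1, high = 2,
                               pass = TRUE, skipped = FALSE))
  m2 <- summarize_metrics(same, true_or = 4)
  expect_equal(m2$metrics$bias_log_or, 0)
  expect_equal(m2$metrics$average_or, 4)
})

test_that("open interval bounds count as covering on their side", {
  recs <- list(ML = data.frame(est = c(1, -1),
                               low = c(-Inf, -2), high = c(0.5, Inf),
                               pass = TRUE, skipped = FALSE))
  mt <- summarize_metrics(recs, true_or = 1)   # truth log OR = 0
  expect_equal(mt$metrics$coverage, 1)
})

test_that("required_replications implements its defining inequality", {
  # rho = 0.5 collapses to n = ceiling((z * sigma / log ratio)^2)
  z <- qnorm(0.975)
  for (s2 in c(0.5, 2.263)) {
    expect_equal(required_replications(s2, 0.5, 1.1),
                 ceiling((z * sqrt(s2) / log(1.1))^2))
  }
  # frozen oracle value: sigma^2 = 2.263 gives 957
  expect_equal(required_replications(2.263, 0.5, 1.1), 957)
  # the returned n satisfies the inequality, n - 1 does not
  n <- required_replications(1.7, 0.3, 1.2)
  hw <- function(r) z * sqrt(2 * (1 - 0.3) * 1.7 / r)
  expect_lte(hw(n), log(1.2))
  expect_gt(hw(n - 1), log(1.2))
  # doubling sigma^2 quadruples n (up to ceiling granularity)
  n1 <- required_replications(1, 0.5, 1.05)
  n2 <- required_replications(2, 0.5, 1.05)
  expect_equal(n2, ceiling(2 * (qnorm(0.975) / log(1.05))^2))
  expect_lt(abs(n2 - 2 * n1), 2)
  expect_error(required_replications(1, 0.5, 1), "ratio")
})

test_that("run_scenario produces a coherent metrics table on a tiny stream", {
  cfg <- scenario_config(2, n = 150, n_e = 15, pi_x1 = 0.2, or_x1 = 2,
                         seed = 3, n_reps = 30)
  mt <- run_scenario(cfg, methods = c("ML", "FIR", "F2"), conf_int = TRUE)
  tab <- mt$metrics
  expect_setequal(tab$method, c("ML", "FIR", "F2"))
  expect_true(all(tab$convergence_rate >= 0 & tab$convergence_rate <= 1))
  expect_true(all(tab$n_effective <= 30))
  expect_true(all(is.finite(tab$average_or)))
  # restriction: every method shares the ML replicate set
  expect_equal(length(unique(tab$n_effective)), 1L)
  expect_true(all(tab$coverage >= 0.5))   # nominal 95% intervals
})

test_that("case_study reports the reference unadjusted odds-ratio column for fast methods", {
  rep <- case_study(methods = c("ML", "FIR", "EX", "MDP", "F1", "F2"))
  hy <- rep[rep$table == "hydramnios", ]
  expect_equal(round(hy$or[hy$method == "ML"], 1), 20.6)
  expect_equal(round(hy$or[hy$method == "FIR"], 1), 28.4)
  expect_equal(round(hy$or[hy$method == "EX"], 1), 20.5)
  expect_equal(round(hy$or[hy$method == "F1"], 1), 11.2)
  expect_equal(round(hy$or[hy$method == "F2"], 1), 5.6)
  va <- rep[rep$table == "vascular", ]
  expect_equal(round(va$or[va$method == "ML"], 2), 7.83)
  expect_match(hy$formatted[hy$method == "ML"], "^21 \\(1.1-120\\)|^20.6")
})

test_that("fit writers serialize method, estimate and intervals", {
  ft <- sparselogit(outcome ~ vascular, vascular_2x2(), weights = n)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_fits(ft, csv, "csv")
  tab <- read.csv(csv)
  expect_equal(tab$method, rep("ML", 2))
  expect_equal(tab$or[2], 7.8333, tolerance = 1e-4)
  write_fits(ft, js, "json")
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed[[2]]$term, "vascular")
  unlink(c(csv, js))
})
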