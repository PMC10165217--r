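# Exact conditional inference: enumeration, conditional MLE, exact and
# mid-P intervals.

test_that("2x2 conditional counts match the hypergeometric closed form", {
  tb <- two_by_two(3, 5, 4, 10)
  xy <- tab_xyw(tb)
  d <- cond_dist(xy$X, xy$y, 2, xy$w)
  n1 <- 8; n0 <- 14; m <- 7
  sup <- max(0, m - n0):min(n1, m)
  expect_equal(d$support, sup)
  expect_equal(round(d$counts), choose(n1, sup) * choose(n0, m - sup))
  expect_equal(d$observed, 3)
  # probabilities at beta = 0 sum to 1
  expect_equal(sum(cd_probs(d, 0)), 1, tolerance = 1e-12)
})

test_that("DP counts equal exhaustive 2^n enumeration on multivariate data", {
  for (s in 1:4) {
    set.seed(300 + s)
    n <- 11
    X <- cbind(1, rbinom(n, 1, 0.4), sample(0:2, n, replace = TRUE))
    y <- rbinom(n, 1, 0.45)
    if (sum(y) %in% c(0, n)) y[1:2] <- c(0, 1)
    for (j in 2:3) {
      d <- cond_dist(X, y, j)
      bf <- brute_cond_dist(X, y, j)
      expect_equal(d$support, bf$support)
      expect_equal(round(d$counts), unname(bf$counts))
    }
  }
})

test_that("grouped weights are equivalent to expanded records", {
  tb <- two_by_two(2, 3, 5, 9)
  xy <- tab_xyw(tb)
  d1 <- cond_dist(xy$X, xy$y, 2, xy$w)
  Xe <- xy$X[rep(seq_along(xy$y), xy$w), ]
  ye <- rep(xy$y, xy$w)
  d2 <- cond_dist(Xe, ye, 2)
  expect_equal(d1$support, d2$support)
  expect_equal(d1$log_counts, d2$log_counts, tolerance = 1e-10)
})

test_that("conditional MLE solves the tilted-mean equation and matches a 1-D optimizer", {
  tb <- two_by_two(3, 6, 5, 12)
  xy <- tab_xyw(tb)
  d <- cond_dist(xy$X, xy$y, 2, xy$w)
  cm <- conditional_mle(d)
  expect_identical(cm$note, "")
  expect_equal(cd_mean(d, cm$estimate), d$observed, tolerance = 1e-6)
  # golden-section maximization of the conditional log-likelihood
  cll <- function(b) b * d$observed -
    log(sum(exp(d$log_counts + b * d$support - max(d$log_counts))))
  gold <- optimize(cll, c(-10, 10), maximum = TRUE)$maximum
  expect_equal(cm$estimate, gold, tolerance = 1e-4)
  # symmetric distribution with observed at its center -> estimate 0
  tbs <- two_by_two(3, 3, 3, 3)
  xys <- tab_xyw(tbs)
  ds <- cond_dist(xys$X, xys$y, 2, xys$w)
  expect_equal(conditional_mle(ds)$estimate, 0, tolerance = 1e-8)
})

test_that("median-unbiased fallback engages at the support boundary", {
  # all exposed are events: observed t at the support maximum
  X <- cbind(1, c(rep(1, 3), rep(0, 17)))
  y <- c(rep(1, 3), rep(1, 4), rep(0, 13))
  d <- cond_dist(X, y, 2)
  expect_equal(d$observed, max(d$support))
  cm <- conditional_mle(d)
  expect_match(cm$note, "median-unbiased")
  expect_true(is.finite(cm$estimate))
  expect_equal(cd_tail(d, cm$estimate, d$observed, "ge"), 0.5,
               tolerance = 1e-6)
  # exact interval has an open upper bound there
  ci <- exact_ci(d)
  expect_true(is.finite(ci[1]) && is.infinite(ci[2]))
})

test_that("exact and mid-P intervals satisfy their defining tail equations", {
  tb <- two_by_two(3, 5, 4, 12)
  xy <- tab_xyw(tb)
  d <- cond_dist(xy$X, xy$y, 2, xy$w)
  ci <- exact_ci(d, 0.95)
  expect_equal(cd_tail(d, ci[1], d$observed, "ge"), 0.025, tolerance = 1e-6)
  expect_equal(cd_tail(d, ci[2], d$observed, "le"), 0.025, tolerance = 1e-6)
  mp <- midp_ci(d, 0.95)
  expect_equal(cd_tail(d, mp[1], d$observed, "ge") -
                 cd_tail(d, mp[1], d$observed, "eq") / 2, 0.025,
               tolerance = 1e-6)
  expect_equal(cd_tail(d, mp[2], d$observed, "le") -
                 cd_tail(d, mp[2], d$observed, "eq") / 2, 0.025,
               tolerance = 1e-6)
  # mid-P interval strictly inside the exact interval
  expect_gt(mp[1], ci[1]); expect_lt(mp[2], ci[2])
})

test_that("tilted mean is strictly increasing in beta (log-concavity)", {
  tb <- two_by_two(2, 6, 5, 10)
  xy <- tab_xyw(tb)
  d <- cond_dist(xy$X, xy$y, 2, xy$w)
  grid <- seq(-4, 4, by = 0.25)
  means <- vapply(grid, function(b) cd_mean(d, b), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("hydramnios exact inference matches the reference values", {
  ex <- sparselogit(outcome ~ hydramnios, hydramnios_2x2(), weights = n,
                    method = "EX")
  md <- sparselogit(outcome ~ hydramnios, hydramnios_2x2(), weights = n,
                    method = "MDP")
  expect_equal(round(exp(coef(ex)[["hydramnios"]]), 1), 20.5)
  expect_equal(coef(md), coef(ex))  # same point estimate by construction
  expect_equal(round(unname(exp(ex$ci[2, ])), 1), c(0.4, 164.2))
  expect_equal(round(unname(exp(md$ci[2, ])), 1), c(0.9, 136.1))
  # conditional vs unconditional MLE: shrunk, within 10% on the log scale
  ml <- sparselogit(outcome ~ hydramnios, hydramnios_2x2(), weights = n,
                    ci = "none")
  expect_lte(abs(coef(ex)[2]), abs(coef(ml)[2]))
  expect_lt(abs(coef(ex)[2] - coef(ml)[2]) / abs(coef(ml)[2]), 0.1)
})

test_that("input contracts: integer covariates, state cap, intercept target", {
  X <- cbind(1, c(0.5, 1, 0, 1, 0, 1)); y <- c(1, 0, 1, 0, 0, 1)
  expect_error(cond_dist(X, y, 2), "integer")
  Xi <- cbind(1, rbinom(40, 1, 0.5))
  yi <- rbinom(40, 1, 0.5)
  expect_error(cond_dist(Xi, yi, 2, cap = 3), "cap")
  expect_error(cond_dist(Xi, yi, 1), "non-intercept")
})
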