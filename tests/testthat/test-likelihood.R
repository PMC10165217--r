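# Core likelihood machinery: values, derivatives, ML fitting, Wald
# intervals, and the weights contract.

test_that("log-likelihood matches closed forms and the naive oracle", {
  d <- rand_dataset(30, 2, seed = 101)
  # beta = 0 gives pi = 1/2 everywhere
  expect_equal(sl_loglik(d$X, d$y, c(0, 0, 0)), -30 * log(2))
  # arbitrary beta vs per-record loop
  for (s in 1:5) {
    set.seed(200 + s)
    b <- rnorm(3)
    expect_equal(sl_loglik(d$X, d$y, b), naive_loglik(d$X, d$y, b),
                 tolerance = 1e-12)
  }
  # weights contract: duplicated records equal doubled weights
  X2 <- rbind(d$X, d$X); y2 <- c(d$y, d$y)
  b <- c(0.3, -1, 0.5)
  expect_equal(sl_loglik(X2, y2, b),
               sl_loglik(d$X, d$y, b, w = rep(2, 30)), tolerance = 1e-12)
  expect_error(sl_loglik(d$X, d$y, c(0, 0)), "length")
})

test_that("score matches numerical gradient; information has closed form", {
  d <- rand_dataset(25, 2, seed = 77)
  set.seed(7)
  b <- rnorm(3, sd = 0.5)
  si <- sl_score_info(d$X, d$y, b)
  eps <- 1e-6
  num <- vapply(1:3, function(j) {
    e <- numeric(3); e[j] <- eps
    (sl_loglik(d$X, d$y, b + e) - sl_loglik(d$X, d$y, b - e)) / (2 * eps)
  }, numeric(1))
  expect_equal(unname(si$score), num, tolerance = 1e-5)
  expect_equal(si$info, t(si$info), tolerance = 1e-12)
  # intercept-only: I(beta) = n exp(beta) / (1 + exp(beta))^2
  n <- 40; Xi <- matrix(1, n, 1); yi <- rep(c(0, 1), 20)
  for (b0 in c(-1, 0, 0.7)) {
    Ii <- sl_score_info(Xi, yi, b0)$info[1, 1]
    expect_equal(Ii, n * exp(b0) / (1 + exp(b0))^2, tolerance = 1e-12)
  }
})

test_that("ML fit solves the score equation and reproduces 2x2 odds ratios", {
  # worked example: vascular disease table -> OR 7.83
  ft <- sparselogit(outcome ~ vascular, vascular_2x2(), weights = n)
  expect_true(ft$converged)
  expect_equal(round(exp(coef(ft)[["vascular"]]), 2), 7.83)
  # score vanishes at the optimum
  si <- sl_score_info(ft$X, ft$y, coef(ft), ft$w)
  expect_lt(max(abs(si$score)), 1e-6)
  # balanced table: OR exactly 1
  bal <- sparselogit(outcome ~ exposure, two_by_two(10, 10, 10, 10),
                     weights = n, ci = "none")
  expect_equal(exp(coef(bal)[["exposure"]]), 1, tolerance = 1e-10)
  # any all-positive 2x2: estimate equals the log cross-product ratio
  set.seed(5)
  for (s in 1:6) {
    cells <- rpois(4, 8) + 1
    tb <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    f <- sparselogit(outcome ~ exposure, tb, weights = n, ci = "none")
    expect_equal(coef(f)[["exposure"]],
                 log(cells[1] * cells[4] / (cells[2] * cells[3])),
                 tolerance = 1e-8)
  }
  # hydramnios table: OR 20.6 to 1 d.p.
  hy <- sparselogit(outcome ~ hydramnios, hydramnios_2x2(), weights = n,
                    ci = "none")
  expect_equal(round(exp(coef(hy)[["hydramnios"]]), 1), 20.6)
})

test_that("degenerate outcomes flag non-convergence, not an exception", {
  d <- data.frame(y = rep(1, 8), x = rbinom(8, 1, 0.5))
  ft <- sparselogit(y ~ x, d, ci = "none")
  expect_false(ft$converged)
  expect_match(ft$notes, "degenerate")
})

test_that("Wald intervals use the closed-form 2x2 variance and respect label symmetry", {
  tb <- vascular_2x2()
  ft <- sparselogit(outcome ~ vascular, tb, weights = n, ci = "wald")
  half <- (ft$ci[2, 2] - ft$ci[2, 1]) / 2
  expect_equal(half,
               qnorm(0.975) * sqrt(1 / 2 + 1 / 3 + 1 / 12 + 1 / 141),
               tolerance = 1e-7)
  # swapping event labels negates both endpoints
  tb2 <- tb; tb2$outcome <- 1 - tb2$outcome
  ft2 <- sparselogit(outcome ~ vascular, tb2, weights = n, ci = "wald")
  expect_equal(unname(ft2$ci[2, ]), unname(-rev(ft$ci[2, ])),
               tolerance = 1e-7)
})

test_that("fit accessors behave like a standard modelling object", {
  ft <- sparselogit(outcome ~ vascular, vascular_2x2(), weights = n)
  expect_s3_class(ft, "sparselogit")
  expect_named(coef(ft), c("(Intercept)", "vascular"))
  expect_equal(dim(vcov(ft)), c(2, 2))
  expect_equal(as.numeric(logLik(ft)), ft$loglik)
  p <- predict(ft, type = "response")
  expect_true(all(p > 0 & p < 1))
  r <- residuals(ft)
  expect_equal(length(r), 4)
  s <- summary(ft)
  expect_output(print(s), "vascular")
  sim <- simulate(ft, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(4, 2))
})
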