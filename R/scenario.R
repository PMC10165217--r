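# Synthetic sparse-data generator: six covariate scenarios of increasing
# complexity, a logistic outcome model with stated true odds ratios, and
# exact calibration of the intercept so the expected number of events hits
# a target.  Scenario 1 is a single rare exposure; scenarios 2-5 add
# independent or correlated binary covariates and a trinomial score;
# scenario 6 mimics the obstetric case study with eight covariates and a
# fixed coefficient vector.

#' Configure one cell of the simulation design
#'
#' @param scenario integer 1-6.
#' @param n total sample size.
#' @param n_e target expected number of events (scenarios 1-5; the
#'   intercept is calibrated so that \eqn{E[\pi_y] = n_e/n} exactly over
#'   the covariate distribution).  Ignored for scenario 6, whose intercept
#'   is fixed at -6.40.
#' @param pi_x1 exposure prevalence parameter (scenarios 1-5; in scenario
#'   3-5 the exposure prevalence depends on x2: Bern(((x2+1)/2) pi_x1)).
#' @param or_x1 true odds ratio for the exposure x1 (1, 4 or 16 in the
#'   study design; any positive value accepted).
#' @param or_other odds ratio shared by the remaining covariates in
#'   scenarios 2-5 (default 2).  Scenario 6 uses its fixed coefficients.
#' @param seed master seed; each replicate gets its own derived substream
#'   seed so any single replicate is reproducible in isolation.
#' @param n_reps number of replicate data sets (default 1000).
#' @return a list of class `"scenario_config"` including the full
#'   coefficient vector (`beta0`, `beta`).
#' @export
scenario_config <- function(scenario, n, n_e = NULL, pi_x1 = 0.05,
                            or_x1 = 1, or_other = 2, seed = 1,
                            n_reps = 1000) {
  if (!scenario %in% 1:6) stop("unknown scenario id", call. = FALSE)
  if (scenario != 6) {
    if (is.null(n_e)) stop("n_e is required for scenarios 1-5",
                           call. = FALSE)
    if (n_e <= 0 || n_e >= n)
      stop("n_e/n must lie in (0, 1)", call. = FALSE)
    if (pi_x1 <= 0 || pi_x1 >= 1)
      stop("pi_x1 must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(or_x1 > 0, or_other > 0, n_reps >= 1)
  cfg <- list(scenario = scenario, n = n, n_e = n_e, pi_x1 = pi_x1,
              or_x1 = or_x1, or_other = or_other, seed = as.integer(seed),
              n_reps = as.integer(n_reps))
  if (scenario == 6) {
    cfg$beta <- c(log(or_x1), 0.57, 0.96, 2.09, 1.24, 1.52, 0.99, -0.64)
    cfg$beta0 <- -6.40
  } else {
    k <- c(1, 2, 2, 4, 8)[scenario]
    cfg$beta <- c(log(or_x1), rep(log(or_other), k - 1))
    cfg$beta0 <- calibrate_intercept(cfg)
  }
  class(cfg) <- "scenario_config"
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(cfg$seed)
  cfg$rep_seeds <- sample.int(.Machine$integer.max - 1, cfg$n_reps)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Simulation scenario", x$scenario, ": n =", x$n,
      if (!is.null(x$n_e)) paste(", expected events =", x$n_e),
      ", true OR(x1) =", x$or_x1, "\n")
  cat("beta0 =", format(x$beta0, digits = 6),
      " beta =", paste(format(x$beta, digits = 4), collapse = " "), "\n")
  invisible(x)
}

# Exhaustive covariate support with probabilities, honoring the
# scenario-3 dependence of x1 on x2.  Returns list(X, prob); X has one
# column per covariate (no intercept), rows are the distinct value
# combinations.
scenario_support <- function(config) {
  s <- config$scenario
  pi1 <- config$pi_x1
  cross <- function(sup) {
    # sup: list of list(X = matrix over some columns, p = probs)
    X <- sup[[1]]$X; p <- sup[[1]]$p
    for (i in seq_along(sup)[-1]) {
      Xi <- sup[[i]]$X; pi <- sup[[i]]$p
      X <- cbind(X[rep(seq_len(nrow(X)), each = nrow(Xi)), , drop = FALSE],
                 Xi[rep(seq_len(nrow(Xi)), nrow(X)), , drop = FALSE])
      p <- rep(p, each = length(pi)) * rep(pi, length(p))
    }
    list(X = X, p = p)
  }
  bern <- function(pr) list(X = matrix(0:1, 2, 1), p = c(1 - pr, pr))
  multi <- function(pr) list(X = matrix(seq_along(pr) - 1, ncol = 1),
                             p = pr)
  pair13 <- function() {
    # joint (x1, x2): x2 ~ Bern(0.5), x1 | x2 ~ Bern(((x2+1)/2) pi1)
    X <- cbind(x1 = c(0, 1, 0, 1), x2 = c(0, 0, 1, 1))
    p1 <- c(pi1 / 2, pi1)
    p <- c(0.5 * (1 - p1[1]), 0.5 * p1[1], 0.5 * (1 - p1[2]), 0.5 * p1[2])
    list(X = X, p = p)
  }
  sup <- switch(s,
    `1` = cross(list(bern(pi1))),
    `2` = cross(list(bern(pi1), bern(0.5))),
    `3` = pair13(),
    `4` = cross(list(pair13(), bern(0.3), bern(0.1))),
    `5` = cross(list(pair13(), bern(0.3), bern(0.1), bern(0.5), bern(0.3),
                     bern(0.1), multi(c(0.8, 0.1, 0.1)))),
    `6` = cross(list(bern(0.0033), bern(0.1858), bern(0.0100),
                     bern(0.0157), bern(0.0391),
                     multi(c(0.8021, 0.1715, 0.0264)),
                     multi(c(0.9850, 0.0090, 0.0060)),
                     multi(c(0.8269, 0.0234, 0.0498, 0.0999)))))
  colnames(sup$X) <- paste0("x", seq_len(ncol(sup$X)))
  sup
}

#' Calibrate the intercept to a target event count
#'
#' Solves \eqn{E[\mathrm{expit}(\beta_0 + \beta^T x)] = n_e/n} for
#' \eqn{\beta_0}, with the expectation taken exactly over the finite
#' covariate support of the scenario (enumeration of all value
#' combinations with their probabilities, honoring the scenario-3
#' dependence between exposure and x2).
#'
#' @param config a [scenario_config()] (scenarios 1-5), or a bare list
#'   with fields `scenario`, `pi_x1`, `beta`, `n`, `n_e`.
#' @return the calibrated intercept.
#' @export
calibrate_intercept <- function(config) {
  if (config$scenario == 6)
    stop("scenario 6 uses the fixed intercept -6.40", call. = FALSE)
  target <- config$n_e / config$n
  if (target <= 0 || target >= 1)
    stop("n_e/n must lie in (0, 1)", call. = FALSE)
  sup <- scenario_support(config)
  eta <- drop(sup$X %*% config$beta)
  f <- function(b0) sum(sup$p * plogis(b0 + eta)) - target
  uniroot(f, lower = -60, upper = 60, tol = 1e-12)$root
}

#' Expected event probability under a configuration
#'
#' Exact-enumeration value of \eqn{E[\pi_y]}; equals `n_e/n` after
#' calibration for scenarios 1-5.
#'
#' @param config a [scenario_config()].
#' @export
expected_event_rate <- function(config) {
  sup <- scenario_support(config)
  sum(sup$p * plogis(config$beta0 + drop(sup$X %*% config$beta)))
}

#' Draw one covariate matrix for a scenario
#'
#' Samples `n` covariate rows from the scenario's distribution using the
#' current RNG state.  Multinomial covariates are coded as consecutive
#' integer scores starting at 0 and are meant to enter the model as
#' quantitative variables.
#'
#' @param config a [scenario_config()].
#' @param n number of rows (default `config$n`).
#' @return integer-valued matrix with columns `x1`, `x2`, ...
#' @export
draw_covariates <- function(config, n = config$n) {
  s <- config$scenario
  pi1 <- config$pi_x1
  rb <- function(p) rbinom(n, 1, p)
  rm_ <- function(p) sample.int(length(p), n, replace = TRUE,
                                prob = p) - 1L
  X <- switch(s,
    `1` = cbind(x1 = rb(pi1)),
    `2` = cbind(x1 = rb(pi1), x2 = rb(0.5)),
    `3` = { x2 <- rb(0.5); cbind(x1 = rbinom(n, 1, (x2 + 1) / 2 * pi1),
                                 x2 = x2) },
    `4` = { x2 <- rb(0.5)
            cbind(x1 = rbinom(n, 1, (x2 + 1) / 2 * pi1), x2 = x2,
                  x3 = rb(0.3), x4 = rb(0.1)) },
    `5` = { x2 <- rb(0.5)
            cbind(x1 = rbinom(n, 1, (x2 + 1) / 2 * pi1), x2 = x2,
                  x3 = rb(0.3), x4 = rb(0.1), x5 = rb(0.5), x6 = rb(0.3),
                  x7 = rb(0.1), x8 = rm_(c(0.8, 0.1, 0.1))) },
    `6` = cbind(x1 = rb(0.0033), x2 = rb(0.1858), x3 = rb(0.0100),
                x4 = rb(0.0157), x5 = rb(0.0391),
                x6 = rm_(c(0.8021, 0.1715, 0.0264)),
                x7 = rm_(c(0.9850, 0.0090, 0.0060)),
                x8 = rm_(c(0.8269, 0.0234, 0.0498, 0.0999))))
  X
}

#' Generate replicate data sets
#'
#' `replicate_dataset(config, i)` rebuilds replicate `i` in isolation from
#' its substream seed; `generate_replicates(config)` returns the list of
#' all replicates.  Outcomes are Bernoulli with
#' \eqn{\pi_y = \mathrm{expit}(\beta_0 + \beta^T x)}.  Degenerate
#' replicates (no events, constant covariate column) are generated and
#' passed through: handling them is the estimators' and the convergence
#' filter's job.
#'
#' @param config a [scenario_config()].
#' @param i replicate index in `1:n_reps`.
#' @param indices which replicates to generate (default all).
#' @return a data frame with column `y` then the covariates; attributes
#'   `replicate` and `events`.
#' @export
replicate_dataset <- function(config, i) {
  stopifnot(i >= 1, i <= config$n_reps)
  set.seed(config$rep_seeds[i])
  X <- draw_covariates(config)
  py <- plogis(config$beta0 + drop(X %*% config$beta))
  y <- rbinom(config$n, 1, py)
  out <- data.frame(y = y, X)
  attr(out, "replicate") <- i
  attr(out, "events") <- sum(y)
  out
}

#' @rdname replicate_dataset
#' @export
generate_replicates <- function(config, indices = seq_len(config$n_reps)) {
  lapply(indices, function(i) replicate_dataset(config, i))
}
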