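# Log F(m, m) prior data augmentation.  The prior log-density for a
# target coefficient is m*beta/2 - m*log(1 + exp(beta)) (up to a
# constant), which equals the likelihood contribution of one pseudo-trial
# of weight m on that coefficient's own column (intercept 0, all other
# covariates 0) with event fraction 1/2.  Fitting therefore reuses the
# plain Newton machinery on the augmented data; the penalty form is kept
# as an independent representation of the same objective.

#' Log-F penalty term
#'
#' The additive penalty \eqn{\sum_{j \in targets} [m\beta_j/2 -
#' m\log\{1+\exp(\beta_j)\}]} placed on the targeted (non-intercept)
#' coefficients; `m = 0` gives no penalty (plain maximum likelihood).
#'
#' @param beta coefficient vector, intercept first.
#' @param m prior degrees of freedom (nonnegative).
#' @param targets indices of penalized coefficients (default: all but the
#'   intercept).  The intercept (index 1) may never be targeted.
#' @export
logf_penalty <- function(beta, m, targets = seq_along(beta)[-1]) {
  stopifnot(m >= 0)
  if (length(targets) && any(targets == 1))
    stop("the intercept cannot carry a log-F prior", call. = FALSE)
  if (m == 0 || length(targets) == 0) return(0)
  b <- beta[targets]
  sum(m * b / 2 - m * log1pexp(b))
}

#' Log-F augmented objective (penalty form)
#'
#' \eqn{l(\beta)} plus [logf_penalty()]; identical (up to 1e-10) to the
#' plain log-likelihood of the pseudo-record-augmented data produced by
#' [logf_augment()].
#'
#' @inheritParams sl_loglik
#' @inheritParams logf_penalty
#' @export
logf_objective <- function(X, y, beta, m, w = rep(1, length(y)),
                           targets = seq_len(ncol(as.matrix(X)))[-1]) {
  sl_loglik(X, y, beta, w) + logf_penalty(beta, m, targets)
}

#' Pseudo-record augmentation for a log-F prior
#'
#' Appends, for each target coefficient, two pseudo-records of weight
#' `m/2` each (one event, one non-event) whose design row is 1 on the
#' target column and 0 everywhere else including the intercept, so the
#' plain likelihood of the augmented data equals [logf_objective()].
#'
#' @inheritParams logf_objective
#' @return list with augmented `X`, `y`, `w`.
#' @export
logf_augment <- function(X, y, w = rep(1, length(y)), m,
                         targets = seq_len(ncol(as.matrix(X)))[-1]) {
  X <- as.matrix(X)
  stopifnot(m >= 0)
  if (length(targets) && any(targets == 1))
    stop("the intercept cannot carry a log-F prior", call. = FALSE)
  if (m == 0 || length(targets) == 0) return(list(X = X, y = y, w = w))
  rows <- matrix(0, 2 * length(targets), ncol(X),
                 dimnames = list(NULL, colnames(X)))
  for (i in seq_along(targets)) {
    rows[2 * i - 1, targets[i]] <- 1
    rows[2 * i, targets[i]] <- 1
  }
  list(X = rbind(X, rows),
       y = c(y, rep(c(1, 0), length(targets))),
       w = c(w, rep(m / 2, 2 * length(targets))))
}

sl_fit_logf <- function(X, y, w, m, level, ci, control,
                        targets = seq_len(ncol(X))[-1], ci_parm = NULL) {
  aug <- logf_augment(X, y, w, m, targets)
  events <- sum(aug$w * aug$y)
  if (events <= 0 || events >= sum(aug$w))
    return(list(coefficients = rep(NA_real_, ncol(X)),
                ci = matrix(NA_real_, ncol(X), 2), converged = FALSE,
                n_iter = 0L, loglik = NA_real_,
                notes = "degenerate outcome (all events or all non-events)"))
  nt <- sl_newton(aug$X, aug$y, aug$w, "none", control = control)
  out <- sl_wrap_newton(aug$X, aug$y, aug$w, nt, level, ci, "none",
                        control, ci_parm)
  # loglik reported for the actual data; the augmented objective is kept
  out$loglik <- sl_loglik(X, y, nt$beta, w)
  out$m <- m
  out$targets <- targets
  out$augmented <- aug
  out
}

#' Prior interval implied by a log F(m, m) prior
#'
#' Equal-tailed prior interval for the odds ratio \eqn{e^\beta} when
#' \eqn{\beta} has the log F(m, m) distribution, i.e. \eqn{e^\beta \sim
#' F(m, m)}.  The interval is reciprocal-symmetric: lower = 1/upper.
#'
#' @param m prior degrees of freedom (> 0).
#' @param level interval probability (default 0.95).
#' @return numeric vector `c(low, high)` on the odds-ratio scale.
#' @examples
#' logf_prior_interval(2)   # about (1/39, 39)
#' @export
logf_prior_interval <- function(m, level = 0.95) {
  if (m <= 0) stop("prior interval undefined for m <= 0", call. = FALSE)
  a <- (1 - level) / 2
  c(qf(a, m, m), qf(1 - a, m, m))
}
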