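# Core likelihood machinery shared by every estimation method: weighted
# Bernoulli log-likelihood, score and expected (Fisher) information, a
# Newton--Raphson fitter with step-halving that optionally carries the
# Jeffreys penalty, and profile-likelihood interval inversion.

# Numerically stable log(1 + exp(eta)).
log1pexp <- function(eta) {
  pmax(eta, 0) + log1p(exp(-abs(eta)))
}

# Validate and pack the design; X must already contain the intercept
# column in position 1.
sl_check_data <- function(X, y, w) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != length(y))
    stop("outcome and covariates have different record counts", call. = FALSE)
  if (length(w) != length(y))
    stop("weights and outcome have different record counts", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y)) || any(!is.finite(w)))
    stop("non-finite entries in data", call. = FALSE)
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1", call. = FALSE)
  invisible(TRUE)
}

#' Weighted logistic log-likelihood
#'
#' Evaluates \eqn{\sum_i w_i [y_i \log \pi_i + (1-y_i)\log(1-\pi_i)]} with
#' \eqn{\pi_i = \mathrm{expit}(\beta^T x_i)}, computed on the linear
#' predictor scale so that no probability is ever formed as an exact 0 or 1.
#'
#' @param X design matrix whose first column is the intercept.
#' @param y 0/1 outcome vector.
#' @param beta coefficient vector, intercept first.
#' @param w nonnegative record weights (fractional weights allowed;
#'   defaults to 1).
#' @return the log-likelihood (a scalar).
#' @export
sl_loglik <- function(X, y, beta, w = rep(1, length(y))) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (ncol(X) != length(beta))
    stop("beta length does not match number of design columns", call. = FALSE)
  sl_check_data(X, y, w)
  eta <- drop(X %*% beta)
  sum(w * (y * eta - log1pexp(eta)))
}

#' Score vector and Fisher information
#'
#' @inheritParams sl_loglik
#' @return a list with `score` (\eqn{U = X^T W (y - \pi)} with prior
#'   weights) and `info` (\eqn{I(\beta) = X^T \mathrm{diag}(w\pi(1-\pi)) X}).
#' @export
sl_score_info <- function(X, y, beta, w = rep(1, length(y))) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (ncol(X) != length(beta))
    stop("beta length does not match number of design columns", call. = FALSE)
  sl_check_data(X, y, w)
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  v <- w * p * (1 - p)
  list(score = drop(crossprod(X, w * (y - p))),
       info  = crossprod(X, X * v),
       p = p, v = v)
}

# Penalized objective value. penalty: "none" or "jeffreys".
sl_objective <- function(X, y, w, beta, penalty) {
  ll <- sl_loglik(X, y, beta, w)
  if (penalty == "jeffreys") {
    si <- sl_score_info(X, y, beta, w)
    ld <- determinant(si$info, logarithm = TRUE)
    if (ld$sign <= 0) return(-Inf)
    ll <- ll + 0.5 * as.numeric(ld$modulus)
  }
  ll
}

# Gradient of the objective restricted to the free coordinates.  For the
# Jeffreys penalty the gradient uses the hat-diagonal form
#   U*_j = sum_i [w_i (y_i - pi_i) + h_i (1/2 - pi_i)] x_ij ,
# h_i = w_i pi_i (1-pi_i) x_i' I^{-1} x_i.
sl_gradient <- function(X, y, w, beta, penalty, free) {
  si <- sl_score_info(X, y, beta, w)
  if (penalty == "none") return(list(grad = si$score[free], si = si))
  Iinv <- tryCatch(chol2inv(chol(si$info)), error = function(e) NULL)
  if (is.null(Iinv)) return(list(grad = NULL, si = si))
  h <- si$v * rowSums((X %*% Iinv) * X)
  g <- drop(crossprod(X, w * (y - si$p) + h * (0.5 - si$p)))
  list(grad = g[free], si = si)
}

#' Optimizer settings for likelihood-based fits
#'
#' @param tol convergence tolerance on the score sup-norm (default 1e-8).
#' @param max_iter Newton iteration cap (default 50).
#' @param guard estimability guard on non-intercept coefficients: an
#'   estimate beyond `log(999)` means the odds ratio left the
#'   \[0.001, 999\] window and is noted on the fit.
#' @param max_half maximum step-halvings per Newton iteration.
#' @export
fit_control <- function(tol = 1e-8, max_iter = 50, guard = log(999),
                        max_half = 25) {
  stopifnot(tol > 0, max_iter >= 1, guard > 0)
  list(tol = tol, max_iter = max_iter, guard = guard, max_half = max_half)
}

# Newton--Raphson with step-halving on the (possibly penalized)
# log-likelihood.  `free` gives the indices actually updated; the others
# stay fixed at their value in `start` (used for profiling).  Returns
# beta, converged flag, iterations, objective, info at the optimum, and a
# diagnostic note.
sl_newton <- function(X, y, w, penalty = c("none", "jeffreys"),
                      start = NULL, free = NULL, control = fit_control()) {
  penalty <- match.arg(penalty)
  if (!is.matrix(X)) X <- as.matrix(X)
  k <- ncol(X)
  if (is.null(start)) start <- numeric(k)
  if (is.null(free)) free <- seq_len(k)
  beta <- start
  obj <- sl_objective(X, y, w, beta, penalty)
  if (!is.finite(obj)) { # e.g. singular information at the start
    beta[free] <- 0
    obj <- sl_objective(X, y, w, beta, penalty)
  }
  note <- ""
  converged <- FALSE
  iter <- 0L
  extra <- 0L
  plateau <- FALSE
  repeat {
    iter <- iter + 1L
    gr <- sl_gradient(X, y, w, beta, penalty, free)
    if (is.null(gr$grad)) { note <- "singular information"; break }
    if (max(abs(gr$grad)) < control$tol || extra > 3L) {
      converged <- TRUE; break
    }
    if (plateau) extra <- extra + 1L
    H <- gr$si$info[free, free, drop = FALSE]
    step <- tryCatch(solve(H, gr$grad), error = function(e) NULL)
    if (is.null(step)) { note <- "singular information"; break }
    # relative-gradient criterion g'H^{-1}g / (|l| + 1e-6) — declares
    # convergence on likelihood plateaus (e.g. quasi-separation in a
    # nuisance covariate); a few polishing steps follow so that on
    # regular data the score itself ends near machine precision
    if (penalty == "none" &&
        sum(gr$grad * step) < (abs(obj) + 1e-6) * control$tol)
      plateau <- TRUE
    ok <- FALSE
    slack <- max(1e-12, 1e-14 * abs(obj))  # float granularity of l(beta)
    for (half in 0:control$max_half) {
      cand <- beta
      cand[free] <- beta[free] + step / 2^half
      cand_obj <- sl_objective(X, y, w, cand, penalty)
      if (is.finite(cand_obj) && cand_obj > obj - slack) {
        beta <- cand; obj <- cand_obj; ok <- TRUE; break
      }
    }
    if (!ok) { note <- "step-halving failed to improve objective"; break }
    if (iter >= control$max_iter) { note <- "iteration limit reached"; break }
  }
  si <- sl_score_info(X, y, beta, w)
  if (!converged && penalty == "none" &&
      max(abs(beta[free])) > 10 && note == "iteration limit reached")
    note <- "separation (monotone likelihood)"
  list(beta = beta, converged = converged, n_iter = iter, objective = obj,
       info = si$info, note = note)
}

# Profile-likelihood interval for coefficient j by inverting the signed
# deviance 2*[obj(hat) - profile obj(b)] = qchisq(level, 1).  Works for
# the plain and the Jeffreys-penalized objective.  An endpoint that the
# profile deviance never reaches within `span` coefficient units is
# reported as -Inf / +Inf (open bound).
sl_profile_ci <- function(X, y, w, beta_hat, obj_hat, j,
                          level = 0.95, penalty = "none",
                          control = fit_control(), span = 80) {
  thresh <- qchisq(level, 1)
  k <- ncol(X)
  free <- setdiff(seq_len(k), j)
  prof <- function(b) {
    st <- beta_hat; st[j] <- b
    ft <- sl_newton(X, y, w, penalty, start = st, free = free,
                    control = control)
    ft$objective
  }
  dev <- function(b) 2 * (obj_hat - prof(b))
  Iinv <- tryCatch(chol2inv(chol(sl_score_info(X, y, beta_hat, w)$info)),
                   error = function(e) NULL)
  se <- if (!is.null(Iinv) && Iinv[j, j] > 0) sqrt(Iinv[j, j]) else 1
  one_side <- function(dir) {
    step <- max(se, 0.25)
    lo <- beta_hat[j]
    repeat {
      hi <- lo + dir * step
      d <- dev(hi)
      if (is.finite(d) && d >= thresh) {
        r <- uniroot(function(b) dev(b) - thresh,
                     lower = min(lo, hi), upper = max(lo, hi),
                     tol = 1e-6)
        return(r$root)
      }
      lo <- hi
      step <- step * 2
      if (abs(lo - beta_hat[j]) > span) return(dir * Inf)
    }
  }
  c(one_side(-1), one_side(1))
}
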