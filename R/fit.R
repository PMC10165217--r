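# User-facing model front-end and the "sparselogit" S3 class.

#' Fit a sparse-data logistic regression
#'
#' Fits the binary logistic model \eqn{\mathrm{logit}\,\pi_i = \beta^T x_i}
#' by one of eight estimation strategies chosen for their behaviour on
#' sparse data:
#'
#' \describe{
#'   \item{`"ML"`}{maximum likelihood (Newton--Raphson with step-halving),
#'     profile-likelihood intervals.}
#'   \item{`"FIR"`}{Firth's penalized likelihood
#'     \eqn{l^*(\beta) = l(\beta) + \frac12 \log|I(\beta)|}; finite
#'     estimates even under complete separation.}
#'   \item{`"EX"`, `"MDP"`}{exact conditional inference: for each
#'     non-intercept coefficient, the permutational distribution of its
#'     sufficient statistic given all others; conditional MLE (or
#'     median-unbiased estimate at the support boundary) with exact or
#'     mid-P tail-inverted intervals.  Point estimates are identical for
#'     the two labels.}
#'   \item{`"NP"`, `"HG"`}{posterior median and equal-tailed credible
#'     interval under independent N(0, `normal_variance`) priors, or under
#'     the hyper-g prior \eqn{\beta \sim N(0, g\Sigma)},
#'     \eqn{f(g) = \frac{a-2}{2}(1+g)^{-a/2}} (MCMC; see [mcmc_control()]
#'     and [prior_spec()]).}
#'   \item{`"F1"`, `"F2"`}{log F(1,1) / log F(2,2) prior data augmentation:
#'     the posterior mode on the pseudo-record-augmented data, with
#'     profile intervals of the augmented likelihood.  Arbitrary prior
#'     degrees of freedom via `m`.}
#' }
#'
#' The intercept is always the first coefficient.  Covariates are used as
#' given -- multi-level categorical variables are expected as integer
#' scores, not expanded into dummies.
#'
#' @param formula model formula, e.g. `outcome ~ x1 + x2`.
#' @param data data frame holding the variables.
#' @param weights optional nonnegative record weights (evaluated in
#'   `data`); fractional weights are allowed and used for grouped tables
#'   and pseudo-records.
#' @param method estimation method label (see Details).
#' @param m log-F prior degrees of freedom; overrides the value implied by
#'   `"F1"`/`"F2"`.
#' @param level interval level (default 0.95).
#' @param ci interval type for the likelihood-based methods: profile
#'   (default), Wald, or none.  Exact methods always use tail inversion,
#'   Bayesian methods always use posterior quantiles.
#' @param prior prior settings for `"NP"`/`"HG"`, see [prior_spec()].
#' @param mcmc chain settings for `"NP"`/`"HG"`, see [mcmc_control()].
#' @param control optimizer settings, see [fit_control()].
#' @return an object of class `"sparselogit"` with `coefficients`, `ci`,
#'   `converged`, `n_iter`, `loglik`, `notes`, and method-specific fields
#'   (`cond_dists` for exact methods, `posterior` for Bayesian methods).
#' @examples
#' fit <- sparselogit(outcome ~ vascular, vascular_2x2(), weights = n)
#' exp(coef(fit))["vascular"]   # odds ratio 7.83
#' @export
sparselogit <- function(formula, data, weights = NULL,
                        method = c("ML", "FIR", "EX", "MDP", "NP", "HG",
                                   "F1", "F2"),
                        m = NULL, level = 0.95,
                        ci = c("profile", "wald", "none"),
                        prior = NULL, mcmc = mcmc_control(),
                        control = fit_control()) {
  method <- match.arg(method)
  ci <- match.arg(ci)
  cl <- match.call()
  mf <- match.call(expand.dots = FALSE)
  keep <- match(c("formula", "data", "weights"), names(mf), 0L)
  mf <- mf[c(1L, keep)]
  mf$drop.unused.levels <- TRUE
  mf[[1L]] <- quote(stats::model.frame)
  mf <- eval(mf, parent.frame())
  mt <- attr(mf, "terms")
  y <- model.response(mf)
  X <- model.matrix(mt, mf)
  if (colnames(X)[1] != "(Intercept)")
    stop("the model must include an intercept", call. = FALSE)
  w <- model.weights(mf)
  if (is.null(w)) w <- rep(1, length(y))
  sl_check_data(X, y, w)
  if (ncol(X) > sum(w > 0))
    stop("more coefficients than records", call. = FALSE)

  fit <- sl_dispatch(method, X, y, w, level = level, ci = ci, m = m,
                     prior = prior, mcmc = mcmc, control = control)
  fit$method <- method
  fit$call <- cl
  fit$terms <- mt
  fit$level <- level
  fit$X <- X; fit$y <- y; fit$w <- w
  names(fit$coefficients) <- colnames(X)
  if (!is.null(fit$ci))
    dimnames(fit$ci) <- list(colnames(X), c("low", "high"))
  class(fit) <- "sparselogit"
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# matrix-level dispatcher shared by sparselogit() and the simulation
# harness.  `parm` restricts interval computation (and, for the exact
# methods, estimation) to the given coefficient indices; NULL = all.
sl_dispatch <- function(method, X, y, w, level = 0.95, ci = "profile",
                        m = NULL, prior = NULL, mcmc = mcmc_control(),
                        control = fit_control(), parm = NULL,
                        exact_cap = 5e7) {
  switch(method,
    ML  = sl_fit_ml(X, y, w, level, ci, control, parm),
    FIR = sl_fit_firth(X, y, w, level, ci, control, parm),
    F1  = sl_fit_logf(X, y, w, if (is.null(m)) 1 else m, level, ci,
                      control, ci_parm = parm),
    F2  = sl_fit_logf(X, y, w, if (is.null(m)) 2 else m, level, ci,
                      control, ci_parm = parm),
    EX  = sl_fit_exact(X, y, w, level, midp = FALSE, control, parm,
                       cap = exact_cap),
    MDP = sl_fit_exact(X, y, w, level, midp = TRUE, control, parm,
                       cap = exact_cap),
    NP  = sl_fit_bayes(X, y, w, level,
                       prior %||% prior_spec("normal"), mcmc),
    HG  = sl_fit_bayes(X, y, w, level,
                       prior %||% prior_spec("hyper_g"), mcmc),
    stop("unknown method ", method, call. = FALSE))
}

# --- ML --------------------------------------------------------------

sl_fit_ml <- function(X, y, w, level, ci, control, ci_parm = NULL) {
  k <- ncol(X)
  events <- sum(w * y)
  if (events <= 0 || events >= sum(w)) {
    return(list(coefficients = rep(NA_real_, k),
                ci = matrix(NA_real_, k, 2), converged = FALSE,
                n_iter = 0L, loglik = NA_real_,
                notes = "degenerate outcome (all events or all non-events)"))
  }
  nt <- sl_newton(X, y, w, "none", control = control)
  out <- sl_wrap_newton(X, y, w, nt, level, ci, "none", control, ci_parm)
  # estimability window: note any non-intercept estimate beyond the guard
  # (odds ratio outside [0.001, 999]); the convergence filter applied to
  # the coefficient of interest turns this into a failed attempt
  if (out$converged && k > 1) {
    oor <- which(abs(out$coefficients[-1]) > control$guard) + 1
    if (length(oor))
      out$notes <- paste0(out$notes, if (nzchar(out$notes)) "; ",
                          "out of range: ",
                          paste(colnames(X)[oor], collapse = ", "))
  }
  out
}

sl_wrap_newton <- function(X, y, w, nt, level, ci, penalty, control,
                           ci_parm = NULL) {
  k <- ncol(X)
  if (is.null(ci_parm)) ci_parm <- seq_len(k)
  cimat <- matrix(NA_real_, k, 2)
  if (nt$converged && ci != "none") {
    if (ci == "profile") {
      for (j in ci_parm)
        cimat[j, ] <- sl_profile_ci(X, y, w, nt$beta, nt$objective, j,
                                    level, penalty, control)
    } else {
      V <- tryCatch(chol2inv(chol(nt$info)), error = function(e) NULL)
      if (is.null(V)) {
        bad <- colnames(X)[which(diag(nt$info) == min(diag(nt$info)))[1]]
        stop("singular information (degenerate covariate: ", bad, ")",
             call. = FALSE)
      }
      z <- qnorm(1 - (1 - level) / 2)
      se <- sqrt(diag(V))
      cimat <- cbind(nt$beta - z * se, nt$beta + z * se)
    }
  }
  list(coefficients = nt$beta, ci = cimat, converged = nt$converged,
       n_iter = nt$n_iter,
       loglik = sl_loglik(X, y, nt$beta, w),
       objective = nt$objective, info = nt$info, notes = nt$note)
}

# --- S3 methods ------------------------------------------------------

#' @export
print.sparselogit <- function(x, digits = 3, ...) {
  cat("Sparse-data logistic regression (method: ", x$method, ")\n", sep = "")
  tab <- cbind(estimate = x$coefficients,
               OR = exp(x$coefficients),
               low = exp(x$ci[, 1]), high = exp(x$ci[, 2]))
  colnames(tab)[3:4] <- paste0(c("OR.low", "OR.high"))
  print(round(tab, digits))
  if (!x$converged) cat("Warning: fit did not converge (", x$notes, ")\n")
  invisible(x)
}

#' @export
summary.sparselogit <- function(object, ...) {
  out <- list(call = object$call, method = object$method,
              level = object$level,
              table = sl_result_frame(object),
              converged = object$converged, notes = object$notes,
              n_iter = object$n_iter, loglik = object$loglik,
              posterior = object$posterior)
  class(out) <- "summary.sparselogit"
  out
}

#' @export
print.summary.sparselogit <- function(x, digits = 3, ...) {
  cat("Call: "); print(x$call)
  cat("Method:", x$method, "  ",
      sprintf("%d%% intervals", round(100 * x$level)), "\n\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$loglik) && !is.na(x$loglik))
    cat("\nlog-likelihood:", format(x$loglik, digits = 6), "\n")
  if (!is.null(x$posterior))
    cat("posterior draws:", x$posterior$n_draws,
        " min ESS:", round(min(x$posterior$ess)), "\n")
  if (!x$converged) cat("fit did not converge (", x$notes, ")\n")
  invisible(x)
}

#' @export
coef.sparselogit <- function(object, ...) object$coefficients

#' @export
vcov.sparselogit <- function(object, ...) {
  if (is.null(object$info)) {
    if (!is.null(object$posterior)) return(object$posterior$vcov)
    stop("no covariance available for method ", object$method, call. = FALSE)
  }
  V <- chol2inv(chol(object$info))
  dimnames(V) <- list(names(object$coefficients), names(object$coefficients))
  V
}

#' @export
logLik.sparselogit <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- length(object$coefficients)
  class(val) <- "logLik"
  val
}

#' Intervals for a fitted sparselogit model
#'
#' For likelihood-based methods recomputes profile (default) or Wald
#' intervals at any level; for exact and Bayesian fits returns the stored
#' tail-inversion / posterior-quantile intervals (only at the fitted
#' level).
#'
#' @param object a [sparselogit()] fit.
#' @param parm coefficient names or indices (default: all).
#' @param level confidence/credible level.
#' @param type `"profile"` or `"wald"` where applicable.
#' @param ... unused.
#' @export
confint.sparselogit <- function(object, parm = NULL, level = 0.95,
                                type = c("profile", "wald"), ...) {
  type <- match.arg(type)
  k <- length(object$coefficients)
  idx <- seq_len(k)
  if (!is.null(parm))
    idx <- if (is.character(parm)) match(parm, names(object$coefficients))
           else parm
  if (object$method %in% c("EX", "MDP", "NP", "HG")) {
    if (level != object$level)
      stop("intervals for ", object$method,
           " fits are only stored at the fitted level", call. = FALSE)
    out <- object$ci[idx, , drop = FALSE]
    return(out)
  }
  if (!object$converged)
    stop("cannot compute intervals: fit did not converge", call. = FALSE)
  penalty <- if (object$method == "FIR") "jeffreys" else "none"
  dat <- sl_method_data(object)
  out <- matrix(NA_real_, length(idx), 2,
                dimnames = list(names(object$coefficients)[idx],
                                c("low", "high")))
  if (type == "wald") {
    V <- chol2inv(chol(object$info))
    z <- qnorm(1 - (1 - level) / 2)
    se <- sqrt(diag(V))[idx]
    out[, 1] <- object$coefficients[idx] - z * se
    out[, 2] <- object$coefficients[idx] + z * se
    return(out)
  }
  for (i in seq_along(idx))
    out[i, ] <- sl_profile_ci(dat$X, dat$y, dat$w, object$coefficients,
                              object$objective, idx[i], level, penalty)
  out
}

# data actually optimized over (log-F methods profile the augmented data)
sl_method_data <- function(object) {
  if (!is.null(object$augmented)) object$augmented
  else list(X = object$X, y = object$y, w = object$w)
}

#' @export
predict.sparselogit <- function(object, newdata = NULL,
                                type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (any(is.na(object$coefficients)))
    stop("method ", object$method,
         " does not estimate every coefficient; prediction unavailable",
         call. = FALSE)
  X <- if (is.null(newdata)) object$X
       else model.matrix(delete.response(object$terms), newdata)
  eta <- drop(X %*% object$coefficients)
  if (type == "link") eta else plogis(eta)
}

#' @export
residuals.sparselogit <- function(object,
                                  type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  p <- predict(object, type = "response")
  y <- object$y; w <- object$w
  if (type == "pearson") return((y - p) * sqrt(w) / sqrt(p * (1 - p)))
  d2 <- -2 * w * (y * log(p) + (1 - y) * log(1 - p))
  sign(y - p) * sqrt(pmax(d2, 0))
}

#' @export
simulate.sparselogit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, type = "response")
  if (any(object$w != round(object$w)))
    stop("simulate requires integer weights", call. = FALSE)
  out <- as.data.frame(replicate(nsim, rbinom(length(p), object$w, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.sparselogit <- function(x, ...) {
  cf <- x$coefficients
  keep <- !is.na(cf)
  or <- exp(cf[keep]); lo <- exp(x$ci[keep, 1]); hi <- exp(x$ci[keep, 2])
  idx <- seq_along(or)
  xlim <- range(c(or, lo[is.finite(lo)], hi[is.finite(hi)], 1))
  plot(or, idx, xlim = xlim, log = "x", yaxt = "n",
       xlab = "odds ratio (log scale)", ylab = "",
       main = paste("sparselogit:", x$method), pch = 19, ...)
  segments(pmax(lo, xlim[1] * 0.9), idx, pmin(hi, xlim[2] * 1.1), idx)
  axis(2, at = idx, labels = names(or), las = 1)
  abline(v = 1, lty = 2, col = "grey50")
  invisible(x)
}
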