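# Firth's bias-reduced logistic regression: maximizes the Jeffreys-prior
# penalized likelihood l*(beta) = l(beta) + 1/2 log|I(beta)|, whose
# modified score U*_j = U_j + sum_i h_i (1/2 - pi_i) x_ij removes the
# first-order bias of the ML estimator and keeps estimates finite under
# separation.  Intervals invert the penalized profile likelihood.

sl_fit_firth <- function(X, y, w, level, ci, control, ci_parm = NULL) {
  # structurally singular designs (e.g. duplicated constant column) have
  # no Jeffreys penalty anywhere: fail early with a clear message
  qrX <- qr(X * sqrt(pmax(w, 1e-12)))
  if (qrX$rank < ncol(X))
    stop("design is singular (column ",
         colnames(X)[qrX$pivot[qrX$rank + 1]],
         " is collinear); Firth penalty undefined", call. = FALSE)
  nt <- sl_newton(X, y, w, "jeffreys", control = control)
  out <- sl_wrap_newton(X, y, w, nt, level, ci, "jeffreys", control, ci_parm)
  out$objective_kind <- "penalized"
  out
}

#' Jeffreys-penalized log-likelihood
#'
#' Evaluates Firth's objective \eqn{l^*(\beta) = l(\beta) +
#' \frac12\log|I(\beta)|}.  Returns `-Inf` when the information matrix is
#' not positive definite at `beta`.
#'
#' @inheritParams sl_loglik
#' @export
sl_penalized_loglik <- function(X, y, beta, w = rep(1, length(y))) {
  sl_objective(as.matrix(X), y, w, beta, "jeffreys")
}
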