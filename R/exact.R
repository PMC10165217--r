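# Exact conditional logistic inference.  For a coefficient j the
# permutational distribution of its sufficient statistic T_j = sum y_i x_ij
# is enumerated conditional on the observed values of every other
# sufficient statistic (including the intercept's event total).  The
# enumeration is a forward dynamic program over groups of identical
# covariate rows: a group of size s contributing r events multiplies the
# count by choose(s, r), so counts are exact without touching the 2^n
# outcome vectors.  Counts are carried in log scale; for small problems
# they are exact integers after exponentiation.

logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Conditional distribution of a sufficient statistic
#'
#' Enumerates the support and (log) counts of \eqn{T_j = \sum_i y_i x_{ij}}
#' over all 0/1 outcome vectors consistent with the observed values of all
#' other sufficient statistics \eqn{T_J, J \ne j} (the intercept total
#' \eqn{\sum_i y_i} is always conditioned on).  Covariates must be
#' integer-valued and weights nonnegative integers (group sizes).
#'
#' @param X design matrix with intercept column first.
#' @param y 0/1 outcome vector.
#' @param j column index of the coefficient of interest (not the intercept).
#' @param w integer record weights (group sizes).
#' @param cap maximum number of dynamic-programming states before the
#'   enumeration refuses (default 5e7).
#' @return an object of class `"cond_dist"`: `support` (sorted integer
#'   values of \eqn{T_j}), `log_counts`, `counts`, `observed`
#'   \eqn{t_j}, and the conditioning values `t_other`.
#' @export
cond_dist <- function(X, y, j, w = rep(1, length(y)), cap = 5e7) {
  X <- as.matrix(X)
  sl_check_data(X, y, w)
  if (j < 1 || j > ncol(X)) stop("invalid coefficient index", call. = FALSE)
  if (j == 1) stop("conditional inference targets a non-intercept column",
                   call. = FALSE)
  if (any(X != round(X)))
    stop("exact conditional inference requires integer-valued covariates",
         call. = FALSE)
  if (any(w != round(w)))
    stop("exact conditional inference requires integer weights",
         call. = FALSE)
  keep <- w > 0
  X <- X[keep, , drop = FALSE]; y <- y[keep]; w <- w[keep]
  k <- ncol(X)
  t_all <- drop(crossprod(X, w * y))            # observed sufficient stats
  other <- setdiff(seq_len(k), j)

  # collapse identical covariate rows into groups
  key <- do.call(paste, c(asplit(X, 2), sep = ","))
  gidx <- match(key, unique(key))
  ng <- max(gidx)
  gx <- X[!duplicated(gidx), , drop = FALSE]
  gs <- as.vector(tapply(w, gidx, sum))[order(unique(gidx))]

  nonneg <- all(X >= 0)
  # suffix maxima of what the remaining groups can still add per statistic
  contrib <- gx * gs
  suffix <- apply(rbind(contrib, 0), 2, function(col)
    rev(cumsum(rev(col)))[-1])
  suffix <- matrix(suffix, nrow = ng)

  states <- matrix(0, 1, k)                     # partial statistic sums
  logc <- 0
  for (g in seq_len(ng)) {
    smax <- gs[g]
    nstate <- nrow(states)
    rmin <- rep(0, nstate); rmax <- rep(smax, nstate)
    if (nonneg) {
      # per-state feasible event range for this group, from the remaining
      # attainable contribution to each conditioning statistic
      for (cc in other) {
        xg <- gx[g, cc]
        if (xg > 0) {
          rmax <- pmin(rmax, floor((t_all[cc] - states[, cc]) / xg))
          rmin <- pmax(rmin,
                       ceiling((t_all[cc] - states[, cc] - suffix[g, cc]) /
                                 xg))
        }
      }
      keep <- rmin <= rmax
      states <- states[keep, , drop = FALSE]; logc <- logc[keep]
      rmin <- rmin[keep]; rmax <- rmax[keep]
      if (!nrow(states))
        stop("no outcome vector satisfies the conditioning constraints",
             call. = FALSE)
    }
    nper <- rmax - rmin + 1
    sidx <- rep(seq_len(nrow(states)), nper)
    r <- sequence(nper, from = rmin)
    ns <- states[sidx, , drop = FALSE] + outer(r, gx[g, ])
    nc <- logc[sidx] + lchoose(smax, r)
    skey <- do.call(paste, c(asplit(ns, 2), sep = ","))
    u <- !duplicated(skey)
    if (all(u)) {
      states <- ns
      logc <- nc
    } else {
      agg <- vapply(split(nc, skey), logsumexp, numeric(1))
      states <- ns[u, , drop = FALSE]
      logc <- unname(agg[match(skey[u], names(agg))])
    }
    if (nrow(states) > cap)
      stop("conditional state space exceeds the cap of ", cap,
           " states; use a smaller data set or raise `cap`", call. = FALSE)
  }
  ok <- rep(TRUE, nrow(states))
  for (cc in other) ok <- ok & states[, cc] == t_all[cc]
  states <- states[ok, , drop = FALSE]; logc <- logc[ok]
  if (!nrow(states))
    stop("no outcome vector satisfies the conditioning constraints",
         call. = FALSE)
  ord <- order(states[, j])
  support <- states[ord, j]
  log_counts <- logc[ord]
  structure(list(support = support, log_counts = log_counts,
                 counts = exp(log_counts), observed = unname(t_all[j]),
                 j = j, name = colnames(X)[j],
                 t_other = t_all[other]),
            class = "cond_dist")
}

#' @export
print.cond_dist <- function(x, ...) {
  cat("Conditional distribution of T[", x$name, "] given all other",
      "sufficient statistics\n")
  cat("support:", paste(x$support, collapse = " "), "\n")
  cat("observed:", x$observed, "\n")
  invisible(x)
}

# conditional log-likelihood, tilted probabilities and tail areas
cd_probs <- function(dist, beta) {
  lw <- dist$log_counts + beta * dist$support
  exp(lw - logsumexp(lw))
}

cd_mean <- function(dist, beta) sum(cd_probs(dist, beta) * dist$support)

cd_tail <- function(dist, beta, t, side = c("ge", "le", "eq")) {
  side <- match.arg(side)
  p <- cd_probs(dist, beta)
  idx <- switch(side, ge = dist$support >= t, le = dist$support <= t,
                eq = dist$support == t)
  sum(p[idx])
}

# find beta with f(beta) = target, f monotone; expands the bracket
# geometrically before uniroot.
cd_invert <- function(f, target, increasing = TRUE, tol = 1e-8) {
  g <- function(b) f(b) - target
  lo <- -1; hi <- 1
  for (i in 1:14) {
    if (g(lo) * g(hi) <= 0) break
    lo <- lo * 2; hi <- hi * 2
  }
  if (g(lo) * g(hi) > 0) return(NA_real_)
  uniroot(g, lower = lo, upper = hi, tol = tol)$root
}

#' Conditional maximum likelihood estimate
#'
#' Maximizes the conditional likelihood \eqn{\Pr(T_j = t_j \mid \beta_j)}
#' in the log odds ratio.  When the observed statistic sits at the edge of
#' its conditional support the CMLE is infinite and the median-unbiased
#' estimate (tail probability 1/2) is substituted, with a note.
#'
#' @param dist a [cond_dist()] object.
#' @return list with `estimate` and `note` (`""`, `"median-unbiased
#'   substituted"`, or `"inestimable"`).
#' @export
conditional_mle <- function(dist) {
  t <- dist$observed
  if (length(dist$support) == 1)
    return(list(estimate = NA_real_, note = "inestimable"))
  if (t == max(dist$support))
    return(list(estimate = cd_invert(function(b) cd_tail(dist, b, t, "ge"),
                                     0.5, increasing = TRUE),
                note = "median-unbiased substituted"))
  if (t == min(dist$support))
    return(list(estimate = cd_invert(function(b) cd_tail(dist, b, t, "le"),
                                     0.5, increasing = FALSE),
                note = "median-unbiased substituted"))
  list(estimate = cd_invert(function(b) cd_mean(dist, b), t), note = "")
}

#' Exact and mid-P conditional intervals
#'
#' `exact_ci` inverts the conditional tail probabilities:
#' \eqn{\Pr(T_j \ge t_j \mid \beta_-) = \alpha/2} for the lower bound and
#' \eqn{\Pr(T_j \le t_j \mid \beta_+) = \alpha/2} for the upper.
#' `midp_ci` gives the observed point mass half weight in each tail,
#' yielding a strictly narrower interval.  A bound is `-Inf`/`Inf` (open)
#' when the observed statistic sits at the corresponding support edge.
#'
#' @param dist a [cond_dist()] object.
#' @param level interval level (default 0.95).
#' @return `c(low, high)` on the log odds-ratio scale.
#' @export
exact_ci <- function(dist, level = 0.95) {
  a <- (1 - level) / 2
  t <- dist$observed
  lo <- if (t == min(dist$support)) -Inf else
    cd_invert(function(b) cd_tail(dist, b, t, "ge"), a)
  hi <- if (t == max(dist$support)) Inf else
    cd_invert(function(b) cd_tail(dist, b, t, "le"), a, increasing = FALSE)
  c(lo, hi)
}

#' @rdname exact_ci
#' @export
midp_ci <- function(dist, level = 0.95) {
  a <- (1 - level) / 2
  t <- dist$observed
  mid_ge <- function(b) cd_tail(dist, b, t, "ge") -
    cd_tail(dist, b, t, "eq") / 2
  mid_le <- function(b) cd_tail(dist, b, t, "le") -
    cd_tail(dist, b, t, "eq") / 2
  lo <- if (t == min(dist$support)) -Inf else cd_invert(mid_ge, a)
  hi <- if (t == max(dist$support)) Inf else
    cd_invert(mid_le, a, increasing = FALSE)
  c(lo, hi)
}

sl_fit_exact <- function(X, y, w, level, midp, control, parm = NULL,
                         cap = 5e7) {
  k <- ncol(X)
  if (is.null(parm)) parm <- seq_len(k)[-1]
  est <- rep(NA_real_, k)
  cimat <- matrix(NA_real_, k, 2)
  notes <- character(0)
  dists <- vector("list", k)
  for (j in parm) {
    d <- cond_dist(X, y, j, w, cap = cap)
    dists[[j]] <- d
    cm <- conditional_mle(d)
    est[j] <- cm$estimate
    if (nzchar(cm$note))
      notes <- c(notes, paste0(colnames(X)[j], ": ", cm$note))
    if (!identical(cm$note, "inestimable"))
      cimat[j, ] <- if (midp) midp_ci(d, level) else exact_ci(d, level)
  }
  list(coefficients = est, ci = cimat,
       converged = all(is.finite(est[parm])),
       n_iter = 0L, loglik = NA_real_,
       notes = paste(notes, collapse = "; "),
       cond_dists = dists)
}
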