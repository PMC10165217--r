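# Shared fixtures and independent oracles, built in code.

# random small binary data set with integer-coded covariates
rand_dataset <- function(n, k, seed, px = 0.4) {
  set.seed(seed)
  X <- cbind(1, matrix(rbinom(n * k, 1, px), n, k))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(k)))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * X[, 2]))
  list(X = X, y = y, w = rep(1, n))
}

# naive per-record log-likelihood (independent of the vectorized path)
naive_loglik <- function(X, y, beta, w = rep(1, length(y))) {
  total <- 0
  for (i in seq_along(y)) {
    p <- 1 / (1 + exp(-sum(X[i, ] * beta)))
    total <- total + w[i] * (y[i] * log(p) + (1 - y[i]) * log(1 - p))
  }
  total
}

# design matrix + outcome from a grouped two_by_two() frame
tab_xyw <- function(tab) {
  list(X = cbind(1, tab[[2]]), y = tab$outcome, w = tab$n)
}

# brute-force conditional distribution by looping over all 2^n outcome
# vectors (exhaustive oracle for the dynamic program)
brute_cond_dist <- function(X, y, j) {
  n <- length(y)
  other <- setdiff(seq_len(ncol(X)), j)
  t_obs <- drop(crossprod(X, y))
  counts <- new.env()
  for (code in 0:(2^n - 1)) {
    ys <- as.integer(intToBits(code)[1:n])
    ts <- drop(crossprod(X, ys))
    if (all(ts[other] == t_obs[other])) {
      key <- as.character(ts[j])
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  sup <- sort(as.numeric(ls(counts)))
  list(support = sup,
       counts = vapply(as.character(sup), function(k) counts[[k]],
                       numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
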