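# Metropolis-within-Gibbs sampler for the hierarchical regression
#
#   y_i ~ f(x_i' b_{u(i)}),   b_u ~ N(beta, diag(tau^2))
#
# with weakly informative priors on the standardized predictor scale:
# beta_j ~ N(0, prior_beta_sd^2); tau_j, sigma ~ half-normal(prior_sd_scale).
# Gaussian-family user coefficients are conjugate draws; logistic ones use
# an adaptive random-walk proposal tuned during warmup. Group means and
# scales are conjugate / log-scale MH. Small and dependency-free by design:
# intended for experiment-scale data, not the full review stream.

hier_mcmc <- function(y, Xs, cluster, family, n_chains = 2L, n_iter = 1500L,
                      n_warmup = 500L, prior_beta_sd = 10,
                      prior_sd_scale = 5, seed = 1L) {
  X <- cbind(1, Xs)
  p <- ncol(X)
  groups <- levels(cluster)
  U <- length(groups)
  rows <- split(seq_along(y), cluster)
  Xu <- lapply(rows, function(i) X[i, , drop = FALSE])
  yu <- lapply(rows, function(i) y[i])
  XtXu <- if (family == "gaussian") lapply(Xu, crossprod) else NULL
  Xtyu <- if (family == "gaussian") {
    purrr::map2(Xu, yu, function(Xi, yi) crossprod(Xi, yi))
  } else NULL

  # pooled starting values
  start <- if (family == "binomial") {
    ridge_logit(Xs, y, lambda = 1 / prior_beta_sd^2)$beta
  } else {
    coef(lm.fit(X, y))
  }
  start[!is.finite(start)] <- 0

  loglik_u <- function(Xi, yi, b) {
    eta <- drop(Xi %*% b)
    if (family == "binomial") {
      # log(1 + e^eta) computed overflow-safe
      sum(yi * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
    } else {
      stop("unused") # gaussian path is conjugate
    }
  }

  n_keep <- n_iter - n_warmup
  all_beta <- vector("list", n_chains)
  b_accum <- matrix(0, U, p)

  for (ch in seq_len(n_chains)) {
    set.seed(derive_seed(seed, 100L + ch))
    beta <- start + rnorm(p, 0, 0.05)
    tau <- rep(0.5, p)
    b <- matrix(rep(beta, each = U), U, p)
    sigma <- if (family == "gaussian") max(sd(y), 0.1) else NA_real_
    step <- rep(0.3, U)
    keep <- matrix(NA_real_, n_keep, p)

    for (it in seq_len(n_iter)) {
      Dinv <- 1 / tau^2
      if (family == "gaussian") {
        for (u in seq_len(U)) {
          P <- XtXu[[u]] / sigma^2 + diag(Dinv, p)
          m <- solve(P, Xtyu[[u]] / sigma^2 + Dinv * beta)
          L <- chol(P)
          b[u, ] <- drop(m + backsolve(L, rnorm(p)))
        }
      } else {
        for (u in seq_len(U)) {
          cur <- b[u, ]
          prop <- cur + rnorm(p, 0, step[u])
          la <- loglik_u(Xu[[u]], yu[[u]], prop) -
            loglik_u(Xu[[u]], yu[[u]], cur) -
            0.5 * sum(Dinv * ((prop - beta)^2 - (cur - beta)^2))
          acc <- is.finite(la) && log(runif(1)) < la
          if (acc) b[u, ] <- prop
          if (it <= n_warmup) {
            step[u] <- exp(log(step[u]) + (if (acc) 0.02 else -0.01))
          }
        }
      }

      # group-level means: conjugate normal
      prec <- U * Dinv + 1 / prior_beta_sd^2
      mean_b <- colSums(b) * Dinv / prec
      beta <- rnorm(p, mean_b, sqrt(1 / prec))

      # group-level scales: MH on log tau with half-normal prior
      for (j in seq_len(p)) {
        lt <- log(tau[j])
        lt_prop <- lt + rnorm(1, 0, 0.25)
        ssq <- sum((b[, j] - beta[j])^2)
        lpost <- function(l) {
          t2 <- exp(2 * l)
          -U * l - ssq / (2 * t2) - t2 / (2 * prior_sd_scale^2) + l
        }
        if (log(runif(1)) < lpost(lt_prop) - lpost(lt)) tau[j] <- exp(lt_prop)
      }

      if (family == "gaussian") {
        eta <- rowSums(X * b[as.integer(cluster), , drop = FALSE])
        ssr <- sum((y - eta)^2)
        ls <- log(sigma)
        ls_prop <- ls + rnorm(1, 0, 0.1)
        lpost_s <- function(l) {
          s2 <- exp(2 * l)
          -length(y) * l - ssr / (2 * s2) - s2 / (2 * prior_sd_scale^2) + l
        }
        if (log(runif(1)) < lpost_s(ls_prop) - lpost_s(ls)) sigma <- exp(ls_prop)
      }

      if (it > n_warmup) {
        keep[it - n_warmup, ] <- beta
        b_accum <- b_accum + b / (n_keep * n_chains)
      }
    }
    all_beta[[ch]] <- keep
  }

  draws <- do.call(rbind, all_beta)
  list(
    beta_draws = draws,
    rhat = vapply(seq_len(p), function(j) {
      split_rhat(lapply(all_beta, function(m) m[, j]))
    }, numeric(1)),
    ess = vapply(seq_len(p), function(j) ess_acf(draws[, j]), numeric(1)),
    b_means = b_accum,
    groups = groups
  )
}

# split-Rhat over chains halved into sub-chains
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[(n + 1):(2 * n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# crude effective sample size from the empirical autocorrelation
ess_acf <- function(x, max_lag = 100) {
  n <- length(x)
  if (var(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(max_lag, n - 1), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  k <- if (length(pos)) pos[1] - 1 else length(ac)
  denom <- 1 + 2 * sum(ac[seq_len(k)])
  min(n, n / max(denom, 1e-6))
}
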