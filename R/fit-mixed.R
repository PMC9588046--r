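#' Fit a mixed-effects regression with per-user random slopes
#'
#' The workhorse behind every analysis model. Predictors are given as
#' expression strings (e.g. `"mean_set"`, `"log(n_options)"`,
#' `"log1p(review_text_length)"`), evaluated in `data`, centered and scaled
#' internally for numerical conditioning, and back-transformed for
#' reporting, so coefficients are always on the original predictor scale.
#'
#' Three engines share one output schema:
#' \describe{
#'   \item{`"mixed"` (default)}{lme4 maximum likelihood (Laplace for
#'     logistic): every fixed effect is also a per-group random effect
#'     (uncorrelated slopes). Provides conditional per-user coefficients
#'     for [subject_effects()].}
#'   \item{`"fast"`}{pooled ML with cluster-robust (sandwich) standard
#'     errors over the grouping factor — the quick screening path; no
#'     per-user effects.}
#'   \item{`"mcmc"`}{a built-in Metropolis-within-Gibbs sampler for the
#'     hierarchical model with weakly informative priors — zero-mean
#'     normals with scale 10 on standardized predictors, half-normal
#'     scale-5 on random-effect and residual SDs — reporting posterior
#'     means, credible intervals, split-Rhat and effective sample sizes.}
#' }
#'
#' @param data A data frame of analysis rows.
#' @param response Response column name. Logistic fits need a logical or
#'   0/1 column.
#' @param terms Character vector of predictor expressions.
#' @param family `"gaussian"` or `"binomial"` (logit link).
#' @param group Grouping column for random effects (e.g. the user id), or
#'   `NULL` for a pooled fit (check-in and order streams carry no user
#'   identity).
#' @param method `"mixed"`, `"fast"`, or `"mcmc"`.
#' @param seed Seed for the MCMC engine.
#' @param mcmc_control List overriding sampler settings: `n_chains`,
#'   `n_iter`, `n_warmup`, `prior_beta_sd`, `prior_sd_scale`.
#' @return A `ctx_fit` object; see [tidy.ctx_fit()] and [glance.ctx_fit()].
#' @export
fit_mixed <- function(data, response, terms,
                      family = c("gaussian", "binomial"), group = NULL,
                      method = c("mixed", "fast", "mcmc"), seed = 1L,
                      mcmc_control = list()) {
  family <- match.arg(family)
  method <- match.arg(method)
  mf <- build_model_frame(data, response, terms, family, group)
  if (is.null(group) && method != "fast") {
    method <- "fast" # no grouping -> pooled fit is the model
  }
  fit <- switch(method,
    fast = fit_fast(mf, family),
    mixed = fit_lme4(mf, family),
    mcmc = fit_mcmc(mf, family, seed, mcmc_control)
  )
  fit$response <- response
  fit$terms <- terms
  fit$family <- family
  fit$group <- group
  fit$method <- method
  fit$n_obs <- length(mf$y)
  fit$n_groups <- if (is.null(mf$cluster)) NA_integer_ else nlevels(mf$cluster)
  class(fit) <- "ctx_fit"
  if (!isTRUE(fit$converged)) {
    rlang::warn("fit flagged as not (cleanly) converged; inspect glance().",
                class = "contextchoice_convergence_warning")
  }
  fit
}

# evaluate term expressions, validate, standardize
build_model_frame <- function(data, response, terms, family, group) {
  y <- data[[response]]
  if (is.null(y)) stopf("response column `%s` not found.", response)
  if (is.logical(y)) y <- as.numeric(y)
  if (family == "binomial" && !all(y %in% c(0, 1), na.rm = TRUE)) {
    stopf("logistic response must be logical or 0/1.")
  }
  if (nrow(data) == 0) stopf("no rows to fit.")
  Xraw <- vapply(terms, function(tm) {
    v <- suppressWarnings(
      eval(parse(text = tm)[[1]], envir = data, enclos = baseenv())
    )
    if (!is.numeric(v)) stopf("term `%s` is not numeric.", tm)
    if (any(!is.finite(v))) {
      stopf("term `%s` produced non-finite values (log of non-positive input?).", tm)
    }
    as.numeric(v)
  }, numeric(nrow(data)))
  Xraw <- matrix(Xraw, nrow = nrow(data),
                 dimnames = list(NULL, terms))
  ok <- complete.cases(Xraw) & !is.na(y)
  Xraw <- Xraw[ok, , drop = FALSE]
  y <- y[ok]
  if (length(y) == 0) stopf("no complete rows to fit.")
  if (stats::var(y) == 0) stopf("response has zero variance; nothing to fit.")
  ctr <- colMeans(Xraw)
  scl <- apply(Xraw, 2, stats::sd)
  if (any(scl == 0)) {
    stopf("zero-variance predictor(s): %s",
          paste(terms[scl == 0], collapse = ", "))
  }
  Xs <- sweep(sweep(Xraw, 2, ctr), 2, scl, "/")
  cluster <- NULL
  if (!is.null(group)) {
    g <- data[[group]]
    if (is.null(g)) stopf("grouping column `%s` not found.", group)
    cluster <- droplevels(factor(g[ok]))
  }
  list(y = y, Xs = Xs, center = ctr, scale = scl, cluster = cluster,
       n_dropped = sum(!ok))
}

# map standardized-scale coefficient vector/vcov to original predictor scale
unstandardize <- function(beta_std, V_std, center, scale) {
  p <- length(scale)
  A <- diag(c(1, 1 / scale))
  A[1, -1] <- -center / scale
  list(beta = drop(A %*% beta_std),
       V = if (is.null(V_std)) NULL else A %*% V_std %*% t(A))
}

summarise_wald <- function(beta, V, labels) {
  se <- sqrt(pmax(diag(V), 0))
  z <- beta / se
  tibble::tibble(
    term = labels,
    estimate = beta,
    std.error = se,
    conf.low = beta - qnorm(0.975) * se,
    conf.high = beta + qnorm(0.975) * se,
    p.value = 2 * pnorm(-abs(z))
  )
}

fit_fast <- function(mf, family) {
  df <- data.frame(y = mf$y, mf$Xs, check.names = FALSE)
  fam <- if (family == "binomial") binomial() else gaussian()
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = fam),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (sep_warn) {
    rlang::warn(paste0("possible separation in logistic fit; ",
                       "reporting a ridge-regularized estimate"),
                class = "contextchoice_separation_warning")
    fit <- ridge_logit(mf$Xs, mf$y, lambda = 1 / 100)
    beta_std <- fit$beta
    V_std <- fit$V
  } else {
    beta_std <- coef(fit)
    V_std <- vcov(fit)
  }
  if (!is.null(mf$cluster) && !sep_warn) {
    V_std <- cluster_robust_vcov(fit, mf$cluster)
  }
  un <- unstandardize(beta_std, V_std, mf$center, mf$scale)
  labels <- c("(Intercept)", colnames(mf$Xs))
  list(summary = summarise_wald(un$beta, un$V, labels),
       user_effects = NULL, converged = TRUE,
       engine = if (sep_warn) "ridge" else "glm")
}

# CR0-style sandwich with a G/(G-1) small-sample factor; canonical links only
cluster_robust_vcov <- function(fit, cluster) {
  X <- model.matrix(fit)
  res <- fit$y - fit$fitted.values
  U <- rowsum(X * res, cluster)
  B <- vcov(fit)
  info <- if (stats::family(fit)$family == "gaussian") {
    B / summary(fit)$dispersion
  } else {
    B
  }
  G <- nlevels(cluster)
  meat <- crossprod(U)
  info %*% meat %*% info * G / (G - 1)
}

# logistic IRLS with an L2 penalty matching a N(0, 1/(2*lambda)) prior scale;
# used as the separation fallback
ridge_logit <- function(Xs, y, lambda = 0.01, max_iter = 50) {
  X <- cbind(`(Intercept)` = 1, Xs)
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- numeric(p)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-8) break
  }
  list(beta = setNames(beta, colnames(X)), V = solve(H))
}

fit_lme4 <- function(mf, family) {
  df <- data.frame(y = mf$y, mf$Xs, check.names = FALSE)
  std_names <- paste0("x", seq_len(ncol(mf$Xs)))
  names(df) <- c("y", std_names)
  df$.grp <- mf$cluster
  rhs <- paste(std_names, collapse = " + ")
  form <- as.formula(sprintf("y ~ %s + (1 + %s || .grp)", rhs, rhs))
  conv_ok <- TRUE
  catch_conv <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("converge|singular", conditionMessage(w), ignore.case = TRUE)) {
        conv_ok <<- FALSE
        invokeRestart("muffleWarning")
      }
    }, message = function(m) {
      if (grepl("singular", conditionMessage(m), ignore.case = TRUE)) {
        invokeRestart("muffleMessage")
      }
    })
  }
  # nAGQ = 0 trades a little fixed-effect accuracy for large speedups and
  # robustness on big grouped tables; conditional modes are unaffected
  fit <- if (family == "binomial") {
    catch_conv(lme4::glmer(form, data = df, family = binomial(), nAGQ = 0,
                           control = lme4::glmerControl(calc.derivs = FALSE)))
  } else {
    catch_conv(lme4::lmer(form, data = df, REML = FALSE,
                          control = lme4::lmerControl(calc.derivs = FALSE)))
  }
  beta_std <- lme4::fixef(fit)
  V_std <- as.matrix(vcov(fit))
  un <- unstandardize(beta_std, V_std, mf$center, mf$scale)
  labels <- c("(Intercept)", colnames(mf$Xs))

  # conditional per-group coefficients, back-transformed per group
  co <- coef(fit)$.grp
  A <- diag(c(1, 1 / mf$scale))
  A[1, -1] <- -mf$center / mf$scale
  ue <- as.matrix(co) %*% t(A)
  colnames(ue) <- labels
  user_effects <- tibble::as_tibble(ue) |>
    dplyr::mutate(.group = rownames(co), .before = 1)

  list(summary = summarise_wald(un$beta, un$V, labels),
       user_effects = user_effects, converged = conv_ok, engine = "lme4")
}

fit_mcmc <- function(mf, family, seed, control) {
  ctl <- utils::modifyList(
    list(n_chains = 2L, n_iter = 1500L, n_warmup = 500L,
         prior_beta_sd = 10, prior_sd_scale = 5),
    control
  )
  res <- hier_mcmc(
    y = mf$y, Xs = mf$Xs, cluster = mf$cluster, family = family,
    n_chains = ctl$n_chains, n_iter = ctl$n_iter, n_warmup = ctl$n_warmup,
    prior_beta_sd = ctl$prior_beta_sd, prior_sd_scale = ctl$prior_sd_scale,
    seed = seed
  )
  labels <- c("(Intercept)", colnames(mf$Xs))
  # back-transform every draw so summaries are on the original scale
  A <- diag(c(1, 1 / mf$scale))
  A[1, -1] <- -mf$center / mf$scale
  draws <- res$beta_draws %*% t(A) # (draws x p)
  est <- colMeans(draws)
  ci <- apply(draws, 2, quantile, probs = c(0.025, 0.975))
  tail_p <- apply(draws, 2, function(d) {
    2 * min(mean(d > 0), mean(d < 0))
  })
  tail_p <- pmax(tail_p, 1 / nrow(draws)) # never exactly zero
  summary <- tibble::tibble(
    term = labels,
    estimate = est,
    std.error = apply(draws, 2, sd),
    conf.low = ci[1, ],
    conf.high = ci[2, ],
    p.value = tail_p,
    rhat = res$rhat,
    ess = res$ess
  )
  ue <- res$b_means %*% t(A)
  colnames(ue) <- labels
  user_effects <- tibble::as_tibble(ue) |>
    dplyr::mutate(.group = res$groups, .before = 1)
  list(summary = summary, user_effects = user_effects,
       converged = all(res$rhat < 1.05, na.rm = TRUE), engine = "mcmc")
}
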