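#' Headline analysis models
#'
#' Convenience wrappers around [fit_mixed()] with the regressor sets of the
#' main analyses. All count-like predictors are log-transformed and review
#' text length is `log(x + 1)`-transformed, mitigating skew.
#'
#' \describe{
#'   \item{`choice_context_model()`}{logistic fit of the ratings-maximizing
#'     choice indicator on the mean displayed rating of the choice set (the
#'     context effect), log set size, the top option's log review count and
#'     price, and the set rating variance; per-user random effects.}
#'   \item{`rating_deviation_model()`}{gaussian fit of the post-choice
#'     rating deviation on the chosen option's prior mean, log review text
#'     length, the chosen option's log review count and price, the set mean
#'     excluding the chosen option (the context effect), and log set size.}
#'   \item{`distractor_model()`}{logistic fit, on the top-two choice subset
#'     only, of choosing the top option on the distractor mean (sub-top-two
#'     mean rating) plus covariates; a direct IIA-violation probe.
#'     `include_gap12 = TRUE` adds the top-two rating gap as a robustness
#'     covariate.}
#'   \item{`expectation_model()`}{gaussian fit of 0-100 expected
#'     satisfaction on the highlighted option's rating, log review count
#'     and price, the set mean excluding the highlighted option, and log
#'     set size; per-participant random effects.}
#' }
#'
#' @param choice_table A [build_choice_table()] tibble (or the experiment
#'   analogue).
#' @param group Grouping column (default `"user_id"`); use `NULL` for
#'   pooled fits on streams without user identity (check-ins).
#' @param method,seed,mcmc_control Passed to [fit_mixed()].
#' @return A `ctx_fit`.
#' @export
choice_context_model <- function(choice_table, group = "user_id",
                                 method = "mixed", seed = 1L,
                                 mcmc_control = list()) {
  fit_mixed(
    choice_table, "is_target",
    c("mean_set", "log(n_options)", "log(n_reviews_top)", "price_top",
      "var_set"),
    family = "binomial", group = group, method = method, seed = seed,
    mcmc_control = mcmc_control
  )
}

#' @rdname choice_context_model
#' @export
rating_deviation_model <- function(choice_table, group = "user_id",
                                   method = "mixed", seed = 1L,
                                   mcmc_control = list()) {
  fit_mixed(
    choice_table, "rating_deviation",
    c("raw_prior_mean_chosen", "log1p(review_text_length)",
      "log(n_reviews_chosen)", "price_chosen", "mean_set_excl_chosen",
      "log(n_options)"),
    family = "gaussian", group = group, method = method, seed = seed,
    mcmc_control = mcmc_control
  )
}

#' @rdname choice_context_model
#' @param distractor_table A [build_distractor_table()] tibble.
#' @param include_gap12 Add the top-two gap as a covariate (robustness
#'   check).
#' @export
distractor_model <- function(distractor_table, group = "user_id",
                             method = "mixed", include_gap12 = FALSE,
                             seed = 1L, mcmc_control = list()) {
  terms <- c("distractor_mean", "log(n_options)", "log(n_reviews_top)",
             "price_top")
  if (include_gap12) terms <- c(terms, "gap12")
  fit_mixed(
    distractor_table, "chose_top", terms,
    family = "binomial", group = group, method = method, seed = seed,
    mcmc_control = mcmc_control
  )
}

#' @rdname choice_context_model
#' @param expectation_tbl An [expectation_table()] tibble.
#' @export
expectation_model <- function(expectation_tbl, group = "user_id",
                              method = "mixed", seed = 1L,
                              mcmc_control = list()) {
  fit_mixed(
    expectation_tbl, "response_satisfaction",
    c("r_highlighted", "log(n_reviews_highlighted)", "price_highlighted",
      "mean_set_excl_highlighted", "log(n_options)"),
    family = "gaussian", group = group, method = method, seed = seed,
    mcmc_control = mcmc_control
  )
}

#' Per-user conditional coefficients for one term
#'
#' Extracts each user's conditional coefficient (posterior/conditional mean
#' of the user-level effect, shrunk toward the fixed effect) for a named
#' term from a mixed or MCMC fit.
#'
#' @param fit A `ctx_fit` fitted with per-user random effects.
#' @param term Term label as reported by [tidy.ctx_fit()].
#' @return Tibble of `.group`, `effect`.
#' @export
subject_effects <- function(fit, term) {
  stopifnot(inherits(fit, "ctx_fit"))
  if (is.null(fit$user_effects)) {
    stopf("fit has no per-user effects (pooled/fast fit).")
  }
  if (!term %in% names(fit$user_effects)) {
    stopf("term `%s` not in fit (have: %s).", term,
          paste(setdiff(names(fit$user_effects), ".group"), collapse = ", "))
  }
  tibble::tibble(
    .group = fit$user_effects$.group,
    effect = fit$user_effects[[term]]
  )
}
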