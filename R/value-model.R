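#' Divisively normalized option value
#'
#' Computes the context-sensitive subjective value of a displayed rating,
#' `v_i = r_i / (sigma + omega * sum_j r_j)`, where the sum runs over every
#' option in the choice set (including option *i* itself). With `omega = 0`
#' the transform reduces to the context-independent `r_i / sigma`, so a
#' softmax over these values is an ordinary logit and satisfies independence
#' of irrelevant alternatives; any `omega > 0` scales values down as the
#' pooled context value grows, producing distractor effects.
#'
#' @param r Numeric vector of displayed ratings to evaluate (each must be a
#'   member of `set_ratings`).
#' @param set_ratings Numeric vector of all displayed ratings in the choice
#'   set (the context), including `r`.
#' @param sigma Semi-saturation constant, in stars; must be `> 0`.
#' @param omega Context weight, unitless, `>= 0`.
#' @return Numeric vector of normalized values, same length as `r`.
#' @examples
#' normalized_value(4, c(4, 4, 2), sigma = 1, omega = 1)  # 4/11
#' normalized_value(4, c(4, 4, 2), sigma = 1, omega = 0)  # 4
#' @export
normalized_value <- function(r, set_ratings, sigma, omega) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0) {
    stopf("`sigma` must be a single positive number (got %s).", format(sigma))
  }
  if (!is.numeric(omega) || length(omega) != 1 || !is.finite(omega) || omega < 0) {
    stopf("`omega` must be a single non-negative number.")
  }
  if (length(set_ratings) == 0) stopf("`set_ratings` must be non-empty.")
  r / (sigma + omega * sum(set_ratings))
}

#' Softmax choice probabilities
#'
#' Maps a vector of option values to choice probabilities
#' `p_i = exp(v_i / tau) / sum_j exp(v_j / tau)`, computed with
#' max-subtraction so extreme `v / tau` ratios do not overflow.
#'
#' @param values Numeric vector of finite option values.
#' @param tau Softmax temperature, `> 0`; small values approach argmax choice.
#' @return Numeric probability vector summing to 1.
#' @examples
#' choice_probabilities(c(1, 0), tau = 1)  # c(e, 1) / (1 + e)
#' @export
choice_probabilities <- function(values, tau) {
  if (length(values) == 0) stopf("`values` must be non-empty.")
  if (!all(is.finite(values))) stopf("`values` must all be finite.")
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0) {
    stopf("`tau` must be a single positive number.")
  }
  z <- values / tau
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Simulate a post-choice star rating from the prediction-error model
#'
#' The emitted rating is the experienced utility minus a contextually
#' computed expectation, re-expressed on the rating scale. Experienced
#' utility is `u ~ Normal(prior_mean_chosen, sigma_u^2)` (symmetric noise
#' around the option's running value); the expectation is
#' `E = prior_mean_chosen - kappa * (context_mean_excl_chosen - 3)`, with 3
#' the neutral midpoint of the 1-5 scale, so richer contexts lower the
#' expectation and inflate the emitted rating:
#' `rating = u - (E - prior_mean_chosen) = u + kappa * (context_mean - 3)`.
#' In discretized mode the rating is rounded half-away-from-zero to a whole
#' star and clamped to `[1, 5]`; in continuous mode it is returned as-is so
#' the closed-form deviation slope `kappa * (m - 3)` is exact.
#'
#' @param prior_mean_chosen Running mean rating of the chosen option at
#'   choice time, in `[1, 5]`.
#' @param context_mean_excl_chosen Mean displayed rating of the other options
#'   in the set, in `[1, 5]`.
#' @param config A [world_config()] (fields `kappa`, `sigma_u`, `discretize`).
#' @param n Number of independent draws.
#' @return Numeric vector of `n` ratings (whole stars if `config$discretize`).
#' @export
simulate_rating <- function(prior_mean_chosen, context_mean_excl_chosen,
                            config, n = 1) {
  stopifnot(length(prior_mean_chosen) == 1, length(context_mean_excl_chosen) == 1)
  if (prior_mean_chosen < 1 || prior_mean_chosen > 5 ||
      context_mean_excl_chosen < 1 || context_mean_excl_chosen > 5) {
    stopf("rating-model inputs must lie in [1, 5].")
  }
  u <- rnorm(n, mean = prior_mean_chosen, sd = config$sigma_u)
  rating <- u + config$kappa * (context_mean_excl_chosen - 3)
  if (isTRUE(config$discretize)) {
    rating <- clamp(round_half_away(rating), 1, 5)
  }
  rating
}
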