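#' Generate a synthetic review world
#'
#' Builds the full stated world from a [world_config()]: cities laid out on a
#' coarse grid, Gaussian neighborhood clusters inside each city, restaurants
#' scattered around cluster centers with a latent quality in `[1, 5]`, a
#' price level, and one or more category terms (the generator's true primary
#' term plus, sometimes, a second term so category inference has work to do),
#' a user population assigned to home cities, and a block of seed reviews per
#' restaurant so every option carries a displayable rating before the choice
#' stream begins. Seed reviews are whole-star draws centered on latent
#' quality, written by throwaway reviewer ids (few reviews each, so the
#' downstream >= 100-review user filter excludes them mechanically).
#'
#' Review text is a bag of category-term tokens whose frequencies favor the
#' true primary term at `salience:1`, plus neutral filler words — only term
#' counts are consumed downstream, so no natural language is attempted.
#'
#' @param config A [world_config()].
#' @param salience Ratio favoring the true primary term in synthetic review
#'   text (default 3).
#' @return A `ctx_world` list with tibbles `restaurants`, `users`, `reviews`
#'   (the seed reviews, time-ordered, unique timestamps), and the `config`.
#'   Deterministic given `config$seed`.
#' @export
generate_world <- function(config, salience = 3) {
  stopifnot(inherits(config, "world_config"))
  with_seed(derive_seed(config$seed, 1L), {
    cities <- sprintf("city_%02d", seq_len(config$n_cities))
    # city centers far apart so clusters never straddle cities
    city_lat <- 10 * seq_len(config$n_cities)
    city_lon <- 10 * seq_len(config$n_cities)

    n_clusters <- config$n_cities * config$clusters_per_city
    cl <- tibble::tibble(
      city = rep(cities, each = config$clusters_per_city),
      cluster = rep(seq_len(config$clusters_per_city), times = config$n_cities),
      center_lat = rep(city_lat, each = config$clusters_per_city) +
        rnorm(n_clusters, 0, config$cluster_center_spread),
      center_lon = rep(city_lon, each = config$clusters_per_city) +
        rnorm(n_clusters, 0, config$cluster_center_spread)
    )

    n_rest <- n_clusters * config$restaurants_per_cluster
    idx <- rep(seq_len(n_clusters), each = config$restaurants_per_cluster)
    primary <- sample(config$categories, n_rest, replace = TRUE)
    # ~40% of restaurants get one extra (non-primary) term, Yelp-style
    extra <- ifelse(
      runif(n_rest) < 0.4 & length(config$categories) > 1,
      vapply(primary, function(p) {
        sample(setdiff(config$categories, p), 1)
      }, character(1)),
      NA_character_
    )
    quality <- clamp(rnorm(n_rest, config$quality_mean, config$quality_sd), 1, 5)
    restaurants <- tibble::tibble(
      business_id = sprintf("b_%05d", seq_len(n_rest)),
      city = cl$city[idx],
      true_cluster = cl$cluster[idx],
      lat = cl$center_lat[idx] + rnorm(n_rest, 0, config$within_cluster_sd),
      lon = cl$center_lon[idx] + rnorm(n_rest, 0, config$within_cluster_sd),
      true_primary_term = primary,
      assigned_terms = purrr::map2(primary, extra, function(p, e) {
        if (is.na(e)) p else c(p, e)
      }),
      price = sample(1:4, n_rest, replace = TRUE, prob = config$price_probs),
      quality = quality
    )

    users <- tibble::tibble(
      user_id = sprintf("u_%05d", seq_len(config$n_users)),
      city = sample(cities, config$n_users, replace = TRUE)
    )

    reviews <- seed_reviews(restaurants, config, salience)

    structure(
      list(restaurants = restaurants, users = users, reviews = reviews,
           config = config),
      class = "ctx_world"
    )
  })
}

# whole-star seed reviews centered on latent quality; timestamps are a strict
# global sequence so prefix means are always well-defined. Counts are
# Poisson around the configured mean (popularity varies; identical counts
# would make review-count covariates degenerate in the static streams).
seed_reviews <- function(restaurants, config, salience) {
  k <- config$init_reviews_per_restaurant
  n_rest <- nrow(restaurants)
  counts <- pmax(1L, stats::rpois(n_rest, k))
  n <- sum(counts)
  b_idx <- sample(rep(seq_len(n_rest), times = counts))
  stars <- clamp(
    round_half_away(rnorm(n, restaurants$quality[b_idx], config$sigma_u)),
    1, 5
  )
  texts <- synth_review_text(
    restaurants$true_primary_term[b_idx],
    restaurants$assigned_terms[b_idx],
    salience
  )
  tibble::tibble(
    review_id = sprintf("seed_%07d", seq_len(n)),
    user_id = sprintf("seeder_%05d", ((seq_len(n) - 1L) %% (n_rest * 2L)) + 1L),
    business_id = restaurants$business_id[b_idx],
    timestamp = as.numeric(seq_len(n)),
    stars = stars,
    text = texts
  )
}

# bag-of-tokens review text; primary term appears salience times as often as
# each other assigned term
synth_review_text <- function(primary, assigned, salience) {
  filler <- c("great", "food", "service", "visit", "again")
  purrr::map2_chr(primary, assigned, function(p, terms) {
    toks <- c(rep(tolower(p), salience),
              tolower(setdiff(terms, p)),
              sample(filler, 3, replace = TRUE))
    paste(sample(toks), collapse = " ")
  })
}

#' @export
print.ctx_world <- function(x, ...) {
  cat("<ctx_world>\n")
  cat(sprintf("  %d restaurants, %d users, %d seed reviews\n",
              nrow(x$restaurants), nrow(x$users), nrow(x$reviews)))
  if (!is.null(x$choice_events)) {
    cat(sprintf("  %d choice events simulated\n", nrow(x$choice_events)))
  }
  invisible(x)
}
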