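#' Configuration of the synthetic review world
#'
#' Bundles every generative parameter of the synthetic world: geography
#' (Gaussian neighborhood clusters inside cities), the restaurant population,
#' the user population and event counts, and the behavioral mechanisms —
#' divisive-normalization choice (`sigma`, `omega`, `tau`) and the
#' prediction-error rating model (`kappa`, `sigma_u`). Defaults describe the
#' package's reference world: 200 users making 100 choices each (~20k
#' events), 60 neighborhoods of 12 restaurants drawn from 3 category terms
#' (enough distinct sets that binned statistics average over set
#' composition), latent quality centered on 3.7 stars (the platform-wide
#' average rating), and calibration values `sigma = 1`, `omega = 0.5`, `tau = 0.05`,
#' `kappa = 0.4`, `sigma_u = 0.7` chosen to qualitatively reproduce the
#' directions of real-world context effects, not fitted to any dataset.
#'
#' @param n_cities Number of cities.
#' @param clusters_per_city Spatial neighborhoods per city.
#' @param cluster_center_spread SD (decimal degrees) of cluster centers
#'   around the city center.
#' @param within_cluster_sd SD (decimal degrees) of restaurants around their
#'   cluster center.
#' @param categories Character vector of category terms (the umbrella term
#'   "Restaurants" is implicit and never used as a category).
#' @param restaurants_per_cluster Restaurants per neighborhood; each samples
#'   its primary category from `categories`.
#' @param n_users Number of reviewing users.
#' @param events_per_user Choice events (hence reviews) per user.
#' @param init_reviews_per_restaurant Seed reviews per restaurant before the
#'   choice stream starts, so every option has a displayable rating.
#' @param quality_mean,quality_sd Mean/SD (stars) of latent restaurant
#'   quality, truncated to `[1, 5]`.
#' @param price_probs Probabilities of price levels 1-4 (dollar signs);
#'   must sum to 1.
#' @param sigma Semi-saturation of divisive normalization (stars, `> 0`).
#' @param omega Context weight (unitless, `>= 0`); 0 disables context
#'   dependence in choice.
#' @param tau Softmax temperature (`> 0`).
#' @param kappa Expectation-context slope (stars per star, `>= 0` expected);
#'   0 disables context dependence in ratings.
#' @param sigma_u SD of experience noise around an option's running value.
#' @param discretize If `TRUE` (default) emitted ratings are whole stars
#'   clamped to `[1, 5]`; if `FALSE`, continuous unclamped ratings (useful
#'   for exact slope-recovery checks).
#' @param use_rounded_display If `TRUE` (default) the generator's choice
#'   mechanism sees half-star-rounded displayed means, as users do; if
#'   `FALSE`, exact running means.
#' @param seed Integer master seed; all generator randomness descends from it.
#' @return A `world_config` list, validated.
#' @export
world_config <- function(n_cities = 4,
                         clusters_per_city = 15,
                         cluster_center_spread = 0.15,
                         within_cluster_sd = 0.004,
                         categories = c("Pizza", "Chinese", "Mexican"),
                         restaurants_per_cluster = 12,
                         n_users = 200,
                         events_per_user = 100,
                         init_reviews_per_restaurant = 25,
                         quality_mean = 3.7,
                         quality_sd = 0.8,
                         price_probs = c(0.3, 0.4, 0.2, 0.1),
                         sigma = 1,
                         omega = 0.5,
                         tau = 0.05,
                         kappa = 0.4,
                         sigma_u = 0.7,
                         discretize = TRUE,
                         use_rounded_display = TRUE,
                         seed = 1L) {
  cfg <- list(
    n_cities = n_cities, clusters_per_city = clusters_per_city,
    cluster_center_spread = cluster_center_spread,
    within_cluster_sd = within_cluster_sd, categories = categories,
    restaurants_per_cluster = restaurants_per_cluster, n_users = n_users,
    events_per_user = events_per_user,
    init_reviews_per_restaurant = init_reviews_per_restaurant,
    quality_mean = quality_mean, quality_sd = quality_sd,
    price_probs = price_probs, sigma = sigma, omega = omega, tau = tau,
    kappa = kappa, sigma_u = sigma_u, discretize = isTRUE(discretize),
    use_rounded_display = isTRUE(use_rounded_display),
    seed = as.integer(seed)
  )
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

validate_world_config <- function(cfg) {
  counts <- c("n_cities", "clusters_per_city", "restaurants_per_cluster",
              "n_users", "events_per_user", "init_reviews_per_restaurant")
  for (f in counts) {
    if (!is_count(cfg[[f]])) {
      stopf("`%s` must be a positive integer (got %s).", f, format(cfg[[f]]),
            class = "contextchoice_config_error")
    }
  }
  if (abs(sum(cfg$price_probs) - 1) > 1e-12 || length(cfg$price_probs) != 4 ||
      any(cfg$price_probs < 0)) {
    stopf("`price_probs` must be 4 non-negative probabilities summing to 1.",
          class = "contextchoice_config_error")
  }
  if (cfg$sigma <= 0) stopf("`sigma` must be > 0.", class = "contextchoice_config_error")
  if (cfg$tau <= 0) stopf("`tau` must be > 0.", class = "contextchoice_config_error")
  if (cfg$omega < 0) stopf("`omega` must be >= 0.", class = "contextchoice_config_error")
  if (cfg$sigma_u < 0) stopf("`sigma_u` must be >= 0.", class = "contextchoice_config_error")
  if (length(cfg$categories) < 1) {
    stopf("`categories` must contain at least one term.",
          class = "contextchoice_config_error")
  }
  if ("Restaurants" %in% cfg$categories) {
    stopf("the umbrella term \"Restaurants\" may not be used as a category.",
          class = "contextchoice_config_error")
  }
  invisible(cfg)
}

#' @export
print.world_config <- function(x, ...) {
  cat("<world_config>\n")
  cat(sprintf("  geography: %d cities x %d clusters x %d restaurants; %d categories\n",
              x$n_cities, x$clusters_per_city, x$restaurants_per_cluster,
              length(x$categories)))
  cat(sprintf("  population: %d users x %d events; %d seed reviews/restaurant\n",
              x$n_users, x$events_per_user, x$init_reviews_per_restaurant))
  cat(sprintf("  mechanism: sigma=%g omega=%g tau=%g kappa=%g sigma_u=%g %s\n",
              x$sigma, x$omega, x$tau, x$kappa, x$sigma_u,
              if (x$discretize) "(whole-star)" else "(continuous)"))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
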