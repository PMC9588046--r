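test_that("generate_world produces the configured counts and is deterministic", {
  cfg <- world_config(n_cities = 1, clusters_per_city = 2,
                      restaurants_per_cluster = 4, categories = "Pizza",
                      n_users = 5, events_per_user = 3,
                      init_reviews_per_restaurant = 5, seed = 9)
  w <- generate_world(cfg)
  expect_equal(nrow(w$restaurants), 8)
  expect_true(all(purrr::map_lgl(w$restaurants$assigned_terms,
                                 ~ "Pizza" %in% .x)))
  expect_true(all(w$restaurants$price %in% 1:4))
  expect_true(all(w$restaurants$quality >= 1 & w$restaurants$quality <= 5))

  w2 <- generate_world(cfg)
  expect_identical(w, w2)

  expect_error(world_config(n_users = 0), class = "contextchoice_config_error")
  expect_error(world_config(price_probs = c(0.5, 0.5, 0, 0.1)),
               class = "contextchoice_config_error")
  expect_error(world_config(sigma = 0), class = "contextchoice_config_error")
})

test_that("seed-review means converge on latent quality at large counts", {
  # independent Monte-Carlo bound: simulate the same clamp-and-round noise
  # directly and measure the 95th percentile of |mean - q| at n = 400
  set.seed(1)
  qs <- seq(1.5, 4.8, length.out = 40)
  dev <- vapply(qs, function(q) {
    abs(mean(pmin(pmax(round(rnorm(400, q, 0.7)), 1), 5)) - q)
  }, numeric(1))
  # rounding bias plus sampling noise stays within 0.15 for interior qualities
  cfg <- world_config(n_cities = 1, clusters_per_city = 2,
                      restaurants_per_cluster = 10,
                      init_reviews_per_restaurant = 400,
                      n_users = 2, events_per_user = 2, seed = 4)
  w <- generate_world(cfg)
  means <- w$reviews |>
    dplyr::summarise(m = mean(stars), .by = "business_id")
  means$q <- w$restaurants$quality[match(means$business_id,
                                         w$restaurants$business_id)]
  frac_ok <- mean(abs(means$m - means$q) <= 0.15)
  expect_gte(frac_ok, 0.95)
})

test_that("normalized_value matches its closed form and monotonicity", {
  expect_equal(normalized_value(4, c(4, 4, 2), 1, 1), 4 / 11)
  expect_equal(normalized_value(4, c(4, 4, 2), 1, 0), 4)
  expect_error(normalized_value(4, c(4, 2), 0, 1))
  # strictly decreasing in any other member's rating when omega > 0
  others <- seq(1, 5, by = 0.5)
  vals <- vapply(others, function(o) normalized_value(4, c(4, o), 1, 0.5),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("choice_probabilities is a softmax with overflow safety", {
  expect_equal(choice_probabilities(c(2, 2, 2), 0.7), rep(1 / 3, 3))
  expect_equal(choice_probabilities(c(1, 0), 1),
               c(exp(1), 1) / (1 + exp(1)))
  p <- choice_probabilities(c(3, 2.9, 1), 0.001)
  expect_gt(p[1], 0.999)
  # huge magnitudes must not overflow
  expect_equal(sum(choice_probabilities(c(1e6, 0), 0.01)), 1)
  expect_error(choice_probabilities(numeric(0), 1))
  expect_error(choice_probabilities(c(1, Inf), 1))
})

test_that("simulate_rating follows the prediction-error closed form", {
  cfg0 <- world_config(kappa = 0, sigma_u = 0, discretize = FALSE)
  expect_equal(simulate_rating(3.5, 4.5, cfg0), 3.5)
  cfg1 <- world_config(kappa = 0.4, sigma_u = 0, discretize = FALSE)
  expect_equal(simulate_rating(3.5, 4.5, cfg1), 3.5 + 0.4 * 1.5)
  # Monte-Carlo: mean deviation within 3 SE of kappa * (m - 3)
  cfg2 <- world_config(kappa = 0.4, sigma_u = 0.5, discretize = FALSE, seed = 2)
  set.seed(7)
  r <- simulate_rating(3.2, 4, cfg2, n = 1e4)
  se <- 0.5 / sqrt(1e4)
  expect_lt(abs(mean(r - 3.2) - 0.4), 3 * se)
  expect_error(simulate_rating(0.5, 3, cfg2))
})

test_that("discretized ratings are whole stars in [1,5] and clamping only
           attenuates, never flips, the deviation slope", {
  cfg <- world_config(kappa = 0.4, sigma_u = 0.5, discretize = TRUE)
  set.seed(11)
  r <- simulate_rating(4.6, 4.5, cfg, n = 500)
  expect_true(all(r %in% 1:5))
  # grid of prior means incl. near-boundary: slope of E[dev] on context mean
  for (prior in c(1.3, 3, 4.7)) {
    devs <- vapply(c(2, 4.5), function(m) {
      mean(simulate_rating(prior, m, cfg, n = 4000)) - prior
    }, numeric(1))
    slope <- (devs[2] - devs[1]) / 2.5
    expect_gt(slope, 0)        # never flips sign
    expect_lt(slope, 0.4 + 0.05) # attenuates relative to kappa
  }
})

test_that("the choice stream is deterministic, skip-free by construction, and
           ratings-maximizing when context-free and sharp", {
  tw <- tiny_world()
  st2 <- simulate_choice_stream(tw$world)
  expect_identical(tw$stream$events, st2$events)
  expect_identical(tw$stream$reviews, st2$reviews)
  expect_equal(attr(tw$stream, "skipped"), 0L)
  expect_equal(nrow(tw$stream$events),
               tw$config$n_users * tw$config$events_per_user)
  # review timestamps unique per business across seed + stream
  expect_false(any(duplicated(
    tw$reviews_all[, c("business_id", "timestamp")]
  )))

  # omega = 0, tiny tau: nearly every choice is ratings-maximizing
  cfg0 <- tiny_config(seed = 5, omega = 0, tau = 0.01)
  st0 <- simulate_choice_stream(generate_world(cfg0), cfg0)
  expect_gt(mean(st0$events$is_target), 0.95)
})

test_that("divisive normalization lowers target rates in richer sets at
           matched top-two gaps (analytic choice probabilities)", {
  # enumerate p(target) directly: same 0.5-star gap, different set means
  p_target <- function(ratings) {
    v <- normalized_value(ratings, ratings, 1, 0.5)
    p <- choice_probabilities(v, 0.05)
    sum(p[ratings >= max(ratings) - 1e-12])
  }
  lean <- c(3.5, 3.0, 2.5)   # mean 3.0
  rich <- c(5.0, 4.5, 4.0)   # mean 4.5, same gap12
  expect_lt(p_target(rich), p_target(lean))
})

test_that("IIA holds exactly at omega 0 and breaks directionally at omega > 0", {
  top_ratio <- function(omega, distractor) {
    r <- c(4.5, 4.0, distractor)
    v <- normalized_value(r, r, 1, omega)
    p <- choice_probabilities(v, 0.05)
    p[1] / p[2]
  }
  grid <- seq(1, 3.5, by = 0.25)
  ratios0 <- vapply(grid, function(d) top_ratio(0, d), numeric(1))
  expect_lt((max(ratios0) - min(ratios0)) / mean(ratios0), 1e-12)
  # with omega > 0, p(top | top-two) strictly decreases in distractor value
  ratios1 <- vapply(grid, function(d) top_ratio(0.5, d), numeric(1))
  cond_top <- ratios1 / (1 + ratios1)
  expect_true(all(diff(cond_top) < 0))
})

test_that("check-in and order streams share the mechanism but drop the right
           identity fields", {
  tw <- tiny_world()
  ck <- simulate_checkins(tw$world, n_events = 400)
  expect_named(ck, c("business_id", "timestamp"))
  expect_true(all(ck$timestamp > max(tw$world$reviews$timestamp)))
  expect_true(all(ck$timestamp < min(tw$stream$reviews$timestamp)))
  ck2 <- simulate_checkins(tw$world, n_events = 400)
  expect_identical(ck, ck2)

  od <- simulate_orders(tw$world, n_events = 400)
  expect_true(all(c("user_id", "restaurant_id", "city", "cuisine", "stars",
                    "n_ratings", "price", "timestamp") %in% names(od)))
  expect_true(all(od$stars %in% seq(1, 5, by = 0.5)))
  # static ratings: every order of a restaurant shows the same stars
  per_rest <- od |>
    dplyr::summarise(k = dplyr::n_distinct(stars), .by = "restaurant_id")
  expect_true(all(per_rest$k == 1))
})

test_that("check-in target rate decreases across set-mean bins with omega > 0", {
  cfg <- world_config(seed = 21, n_users = 60, events_per_user = 100)
  w <- generate_world(cfg)
  ck <- simulate_checkins(w, n_events = 6000)
  # score check-ins against the generator's static post-seed display
  sets <- true_sets_long(w, min_members = 2L)
  st <- contextchoice:::post_seed_state(w)
  disp <- floor(2 * pmin(pmax(st$sums / pmax(st$cnt, 1), 1), 5) + 0.5) / 2
  names(disp) <- w$restaurants$business_id
  per_set <- sets |>
    dplyr::mutate(d = disp[business_id]) |>
    dplyr::summarise(mean_set = mean(d), max_d = max(d), .by = "set_id")
  scored <- ck |>
    dplyr::inner_join(sets, by = "business_id") |>
    dplyr::inner_join(per_set, by = "set_id") |>
    dplyr::mutate(is_target = disp[business_id] >= max_d - 1e-12,
                  bin = cut(mean_set, c(-Inf, 3.25, 3.75, Inf)))
  rates <- scored |>
    dplyr::summarise(r = mean(is_target), n = dplyr::n(), .by = "bin") |>
    dplyr::arrange(bin)
  expect_gt(dplyr::first(rates$r), dplyr::last(rates$r))
})

test_that("simulate_experiment partitions trials 135/135/5 with one response
           field each", {
  tw <- tiny_world()
  pool <- experiment_pool(tw$world)
  trials <- suppressWarnings(
    simulate_experiment(pool, 4, tw$config)
  )
  counts <- trials |>
    dplyr::count(participant_id, trial_type) |>
    tidyr::pivot_wider(names_from = trial_type, values_from = n)
  expect_true(all(counts$choice == 135))
  expect_true(all(counts$rating == 135))
  expect_true(all(counts$catch == 5))
  # exactly one response field per trial
  n_resp <- (!is.na(trials$response_choice)) +
    (!is.na(trials$response_satisfaction))
  expect_true(all(n_resp == 1))
  expect_true(all(is.na(trials$response_satisfaction) |
                    (trials$response_satisfaction >= 0 &
                       trials$response_satisfaction <= 100)))
  expect_warning(simulate_experiment(pool, 2, tw$config),
                 "re-used")
  expect_error(simulate_experiment(pool, 0, tw$config),
               class = "contextchoice_config_error")
})

test_that("lapse rate 0.5 drives expected catch accuracy to ~0.5 and the 60%
           rule flags those participants", {
  tw <- tiny_world()
  pool <- experiment_pool(tw$world)
  trials <- suppressWarnings(
    simulate_experiment(pool, 40, tw$config,
                        heterogeneity = list(lapse = 0.5))
  )
  catch <- catch_trial_exclusion(trials, pool)
  expect_lt(abs(mean(catch$accuracy) - 0.5), 0.12)
  expect_true(any(!catch$retained))
  expect_identical(catch$retained, catch$accuracy >= 0.6)

  trials0 <- suppressWarnings(
    simulate_experiment(pool, 10, tw$config,
                        heterogeneity = list(lapse = 0))
  )
  catch0 <- catch_trial_exclusion(trials0, pool)
  expect_true(all(catch0$retained))
})
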