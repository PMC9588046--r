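#' Simulate the review-based choice stream
#'
#' Runs the generative counterpart of the ratings-based choice analysis. At
#' each event a user is assigned a ground-truth (neighborhood, category)
#' choice set in their home city; every member's displayed rating at the
#' event timestamp is computed from the running review state (half-star
#' rounded by default, as users see it); the choice is drawn from
#' [choice_probabilities()] over [normalized_value()]s; and a post-choice
#' review is emitted from [simulate_rating()] and folded into the state, so
#' later choosers see it. The displayed state used for a choice never
#' includes the review that choice emits.
#'
#' Sets are sampled only among those with at least 2 members in the user's
#' city; a sampled set that still presents fewer than 2 rated options at
#' event time is skipped and tallied (`attr(, "skipped")`).
#'
#' @param world A `ctx_world` from [generate_world()].
#' @param config A [world_config()]; defaults to the world's own.
#' @return A list with `events` (one row per realized choice: ids, set,
#'   displayed context actually used, chosen option, target flag) and
#'   `reviews` (the emitted [ReviewEvent]-shaped tibble, timestamps strictly
#'   after all seed reviews). Deterministic given `config$seed`.
#' @export
simulate_choice_stream <- function(world, config = world$config) {
  stopifnot(inherits(world, "ctx_world"))
  sets <- build_true_sets(world, min_members = 2L)
  st <- post_seed_state(world)
  n_rest <- nrow(world$restaurants)

  user_city <- world$users$city
  city_sets <- split(seq_len(nrow(sets$index)), sets$index$city)
  bad <- setdiff(unique(user_city), names(city_sets))
  if (length(bad) > 0) {
    rlang::warn(sprintf("no eligible choice sets in: %s; those users emit no events",
                        paste(bad, collapse = ", ")))
  }

  with_seed(derive_seed(config$seed, 2L), {
    eligible_users <- which(user_city %in% names(city_sets))
    stream_users <- rep(eligible_users, each = config$events_per_user)
    stream_users <- sample(stream_users)
    n_ev <- length(stream_users)
    t0 <- if (nrow(world$reviews)) max(world$reviews$timestamp) else 0

    ev_user <- integer(n_ev); ev_set <- integer(n_ev)
    ev_chosen <- integer(n_ev); ev_n_opt <- integer(n_ev)
    ev_target <- logical(n_ev); ev_mean <- numeric(n_ev)
    ev_ctx_excl <- numeric(n_ev); ev_prior <- numeric(n_ev)
    ev_stars <- numeric(n_ev); ev_time <- numeric(n_ev)
    keep <- logical(n_ev)
    skipped <- 0L

    sums <- st$sums; cnt <- st$cnt
    members <- sets$members
    sigma <- config$sigma; omega <- config$omega; tau <- config$tau
    kappa <- config$kappa; sigma_u <- config$sigma_u
    rounded <- config$use_rounded_display

    for (i in seq_len(n_ev)) {
      u <- stream_users[i]
      s <- city_sets[[user_city[u]]]
      s <- if (length(s) == 1L) s else s[sample.int(length(s), 1L)]
      m <- members[[s]]
      m <- m[cnt[m] > 0L]
      if (length(m) < 2L) { skipped <- skipped + 1L; next }
      raw <- clamp(sums[m] / cnt[m], 1, 5)
      disp <- if (rounded) floor(2 * raw + 0.5) / 2 else raw
      v <- disp / (sigma + omega * sum(disp))
      z <- v / tau; z <- exp(z - max(z))
      j <- sample.int(length(m), 1L, prob = z)
      ctx_excl <- if (length(m) > 1L) mean(disp[-j]) else NA_real_
      prior <- raw[j]
      stars <- rnorm(1, prior, sigma_u) + kappa * (ctx_excl - 3)
      if (config$discretize) stars <- clamp(round_half_away(stars), 1, 5)
      b <- m[j]
      sums[b] <- sums[b] + stars
      cnt[b] <- cnt[b] + 1L
      keep[i] <- TRUE
      ev_user[i] <- u; ev_set[i] <- s; ev_chosen[i] <- b
      ev_n_opt[i] <- length(m); ev_target[i] <- disp[j] >= max(disp) - 1e-12
      ev_mean[i] <- mean(disp); ev_ctx_excl[i] <- ctx_excl
      ev_prior[i] <- prior; ev_stars[i] <- stars
      ev_time[i] <- t0 + i
    }

    ke <- which(keep)
    events <- tibble::tibble(
      event_id = sprintf("ev_%07d", seq_along(ke)),
      user_id = world$users$user_id[ev_user[ke]],
      set_id = sets$index$set_id[ev_set[ke]],
      timestamp = ev_time[ke],
      chosen_id = world$restaurants$business_id[ev_chosen[ke]],
      n_options = ev_n_opt[ke],
      is_target = ev_target[ke],
      mean_set = ev_mean[ke],
      context_mean_excl_chosen = ev_ctx_excl[ke],
      prior_mean_chosen = ev_prior[ke],
      stars = ev_stars[ke]
    )
    reviews <- tibble::tibble(
      review_id = sprintf("rv_%07d", seq_along(ke)),
      user_id = events$user_id,
      business_id = events$chosen_id,
      timestamp = events$timestamp,
      stars = events$stars,
      text = synth_review_text(
        world$restaurants$true_primary_term[ev_chosen[ke]],
        world$restaurants$assigned_terms[ev_chosen[ke]],
        salience = 3
      )
    )
    out <- list(events = events, reviews = reviews)
    attr(out, "skipped") <- skipped
    out
  })
}

#' Simulate check-in and order streams
#'
#' Both replication streams reuse the divisive-normalization choice
#' mechanism against the post-seed rating state, which stays static over the
#' stream (no reviews are emitted). Check-ins carry no user identity and are
#' timestamped strictly between the seed reviews and any later choice
#' stream, so recomputing displayed ratings at check-in time from the review
#' stream reproduces the state the generator used. Orders are keyed by
#' (city, cuisine) sets pooled across neighborhoods, with static per-
#' restaurant displayed ratings, review counts and prices, mirroring a
#' delivery-platform export.
#'
#' @param world A `ctx_world`.
#' @param config A [world_config()]; defaults to the world's own.
#' @param n_events Number of events to draw (default
#'   `n_users * events_per_user`).
#' @return `simulate_checkins()`: a tibble of `business_id`, `timestamp`.
#'   `simulate_orders()`: a tibble with columns `user_id`, `restaurant_id`,
#'   `city`, `cuisine`, `stars`, `n_ratings`, `price`, `timestamp`.
#' @export
simulate_checkins <- function(world, config = world$config, n_events = NULL) {
  n_events <- n_events %||% (config$n_users * config$events_per_user)
  sim_static_stream(world, config, n_events, by_cluster = TRUE,
                    seed_offset = 3L, with_user = FALSE)
}

#' @rdname simulate_checkins
#' @export
simulate_orders <- function(world, config = world$config, n_events = NULL) {
  n_events <- n_events %||% (config$n_users * config$events_per_user)
  sim_static_stream(world, config, n_events, by_cluster = FALSE,
                    seed_offset = 4L, with_user = TRUE)
}

sim_static_stream <- function(world, config, n_events, by_cluster,
                              seed_offset, with_user) {
  min_m <- if (by_cluster) 2L else 2L
  sets <- build_true_sets(world, min_members = min_m, by_cluster = by_cluster)
  st <- post_seed_state(world)
  raw <- clamp(st$sums / pmax(st$cnt, 1L), 1, 5)
  disp <- floor(2 * raw + 0.5) / 2
  t0 <- if (nrow(world$reviews)) max(world$reviews$timestamp) else 0

  with_seed(derive_seed(config$seed, seed_offset), {
    user_city <- world$users$city
    city_sets <- split(seq_len(nrow(sets$index)), sets$index$city)
    n_sets_all <- nrow(sets$index)
    chosen <- integer(n_events)
    set_of <- integer(n_events)
    user_of <- integer(n_events)
    for (i in seq_len(n_events)) {
      if (with_user) {
        u <- sample.int(nrow(world$users), 1L)
        s_pool <- city_sets[[user_city[u]]]
        if (is.null(s_pool)) next
        user_of[i] <- u
      } else {
        s_pool <- seq_len(n_sets_all)
      }
      s <- if (length(s_pool) == 1L) s_pool else s_pool[sample.int(length(s_pool), 1L)]
      m <- sets$members[[s]]
      m <- m[st$cnt[m] > 0L]
      if (length(m) < 2L) next
      v <- disp[m] / (config$sigma + config$omega * sum(disp[m]))
      z <- exp(v / config$tau - max(v / config$tau))
      chosen[i] <- m[sample.int(length(m), 1L, prob = z)]
      set_of[i] <- s
    }
    ok <- which(chosen > 0L)
    ts <- t0 + seq_along(ok) / (length(ok) + 1) # strictly pre-choice-stream
    if (with_user) {
      tibble::tibble(
        user_id = world$users$user_id[user_of[ok]],
        restaurant_id = world$restaurants$business_id[chosen[ok]],
        city = world$restaurants$city[chosen[ok]],
        cuisine = world$restaurants$true_primary_term[chosen[ok]],
        stars = disp[chosen[ok]],
        n_ratings = st$cnt[chosen[ok]],
        price = world$restaurants$price[chosen[ok]],
        timestamp = ts
      )
    } else {
      tibble::tibble(
        business_id = world$restaurants$business_id[chosen[ok]],
        timestamp = ts
      )
    }
  })
}

# ground-truth choice sets from generator labels; members as integer indices
build_true_sets <- function(world, min_members = 2L, by_cluster = TRUE) {
  r <- world$restaurants
  key <- if (by_cluster) {
    paste(r$city, r$true_cluster, r$true_primary_term, sep = "|")
  } else {
    paste(r$city, r$true_primary_term, sep = "|")
  }
  members <- split(seq_len(nrow(r)), key)
  members <- members[lengths(members) >= min_members]
  index <- tibble::tibble(
    set_id = names(members),
    city = r$city[vapply(members, `[`, integer(1), 1L)],
    n_members = lengths(members)
  )
  list(index = index, members = unname(members))
}

# running review sums/counts after the seed block only
post_seed_state <- function(world) {
  n_rest <- nrow(world$restaurants)
  sums <- numeric(n_rest); cnt <- integer(n_rest)
  if (nrow(world$reviews)) {
    idx <- match(world$reviews$business_id, world$restaurants$business_id)
    agg_n <- tabulate(idx, nbins = n_rest)
    agg_s <- vapply(split(world$reviews$stars, factor(idx, levels = seq_len(n_rest))),
                    sum, numeric(1))
    sums <- unname(agg_s); cnt <- agg_n
  }
  list(sums = sums, cnt = cnt)
}
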