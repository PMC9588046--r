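# Shared tiny-world fixtures, built in code at test time.

tiny_config <- function(seed = 42, ...) {
  world_config(
    n_cities = 1, clusters_per_city = 4, restaurants_per_cluster = 10,
    n_users = 25, events_per_user = 20, init_reviews_per_restaurant = 12,
    seed = seed, ...
  )
}

# a single cached small world + stream for read-mostly tests
tiny_world_cache <- new.env(parent = emptyenv())
tiny_world <- function() {
  if (is.null(tiny_world_cache$w)) {
    cfg <- tiny_config()
    w <- generate_world(cfg)
    st <- simulate_choice_stream(w)
    tiny_world_cache$w <- list(
      config = cfg, world = w, stream = st,
      reviews_all = rbind(w$reviews, st$reviews)
    )
  }
  tiny_world_cache$w
}

# long membership tibble for the generator's ground-truth sets
true_sets_long <- function(world, min_members = 1L) {
  ts <- contextchoice:::build_true_sets(world, min_members = min_members)
  purrr::imap_dfr(ts$members, function(m, i) {
    tibble::tibble(
      set_id = ts$index$set_id[i],
      city = world$restaurants$city[m][1],
      cluster = world$restaurants$true_cluster[m][1],
      category = world$restaurants$true_primary_term[m][1],
      business_id = world$restaurants$business_id[m]
    )
  })
}

# stream events annotated with the focal review id, ready for build_choice_table
stream_events <- function(tw) {
  ev <- tw$stream$events
  ev$event_id <- ev$event_id
  ev$review_id <- tw$stream$reviews$review_id[match(ev$timestamp,
                                                    tw$stream$reviews$timestamp)]
  ev
}
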