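#' Assemble (city, cluster, category) choice sets
#'
#' A choice set is all restaurants of one primary category inside one
#' spatial neighborhood. Noise-labeled restaurants (cluster 0) have no
#' neighborhood and belong to no set; every other business lands in exactly
#' one set, so sets partition the non-noise businesses.
#'
#' @param businesses Tibble with `business_id`, `city` (unique ids).
#' @param labeling Tibble with `business_id`, `cluster` (integer, 0 =
#'   noise), e.g. restaurant labels derived from [dbscan_cluster()].
#' @param assignments Tibble with `business_id`, `primary_term` from
#'   [infer_categories()]. Businesses absent here (no inferable category)
#'   are excluded.
#' @return Long tibble of set membership: `set_id`, `city`, `cluster`,
#'   `category`, `business_id` — one row per member.
#' @export
build_choice_sets <- function(businesses, labeling, assignments) {
  if (anyDuplicated(businesses$business_id)) {
    stopf("duplicate business ids in `businesses`.")
  }
  joined <- businesses |>
    dplyr::select("business_id", "city") |>
    dplyr::inner_join(labeling, by = "business_id") |>
    dplyr::inner_join(assignments, by = "business_id") |>
    dplyr::filter(.data$cluster != 0L)
  joined |>
    dplyr::transmute(
      set_id = paste(.data$city, .data$cluster, .data$primary_term, sep = "|"),
      city = .data$city,
      cluster = .data$cluster,
      category = .data$primary_term,
      business_id = .data$business_id
    ) |>
    dplyr::arrange(.data$set_id, .data$business_id)
}

#' Filter events to the analysis-eligible subset
#'
#' Applies the eligibility rules of the review-stream analysis: an event is
#' kept iff its user has at least `min_user_reviews` reviews in the whole
#' dataset, the event lies in the user's most-frequently-reviewed city, its
#' set has at least `min_set_size` rated members at event time, and those
#' members display at least `min_unique_ratings` distinct ratings. Order
#' events use only the `min_orders_set_size` rule; check-in events use only
#' the set-level rules (no user identity exists).
#'
#' Expects threshold inputs as columns (see below), so the function is a
#' pure, monotone thresholding step; [augment_events()] computes the
#' columns. Every exclusion is tallied by its first failing reason in
#' `attr(, "exclusions")`, and kept + excluded always equals the input
#' count.
#'
#' @param events Event tibble. For `source = "reviews"` it must carry
#'   `user_n_reviews`, `in_modal_city`, `n_options`, `n_unique_ratings`;
#'   for `"checkins"` the last two; for `"orders"` a `set_size` column.
#' @param min_set_size,min_unique_ratings,min_user_reviews,min_orders_set_size
#'   Eligibility thresholds (defaults 3, 3, 100, 5).
#' @param source One of `"reviews"`, `"checkins"`, `"orders"`.
#' @return The eligible rows, with `attr(, "exclusions")` a named integer
#'   vector of exclusion counts by reason.
#' @export
filter_events <- function(events, min_set_size = 3, min_unique_ratings = 3,
                          min_user_reviews = 100, min_orders_set_size = 5,
                          source = c("reviews", "checkins", "orders")) {
  source <- match.arg(source)
  n <- nrow(events)
  reason <- rep(NA_character_, n)
  mark <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  if (source == "orders") {
    mark(events$set_size < min_orders_set_size, "set_too_small")
  } else {
    if (source == "reviews") {
      mark(events$user_n_reviews < min_user_reviews, "user_too_few_reviews")
      mark(!events$in_modal_city, "outside_modal_city")
    }
    mark(events$n_options < min_set_size, "set_too_small")
    mark(events$n_unique_ratings < min_unique_ratings, "too_few_unique_ratings")
  }
  keep <- is.na(reason)
  out <- events[keep, , drop = FALSE]
  tally <- table(factor(reason[!keep]))
  attr(out, "exclusions") <- setNames(as.integer(tally), names(tally))
  attr(out, "n_input") <- n
  out
}

#' Attach eligibility columns to raw events
#'
#' Joins each event to its choice set and computes the quantities the
#' eligibility filter thresholds: the user's total review count and modal
#' (most-reviewed) city, and — from a strict leave-one-out snapshot at the
#' event timestamp — the number of rated options and of distinct displayed
#' ratings in the set.
#'
#' @param events Tibble with `event_id`, `user_id` (reviews), `business_id`
#'   or `chosen_id`, `timestamp`, and for review events the focal
#'   `review_id`.
#' @param sets Long membership tibble from [build_choice_sets()] (or
#'   ground-truth sets in the same shape).
#' @param state A [rating_state()].
#' @param reviews Full review tibble (used for user review counts / modal
#'   city); optional for check-ins.
#' @param source `"reviews"` or `"checkins"`.
#' @return `events` joined to `set_id` with added columns `n_options`,
#'   `n_unique_ratings`, and for reviews `user_n_reviews`, `in_modal_city`.
#'   Events whose business is in no set are dropped and tallied in
#'   `attr(, "no_set")`.
#' @export
augment_events <- function(events, sets, state, reviews = NULL,
                           source = c("reviews", "checkins")) {
  source <- match.arg(source)
  chosen_col <- if ("chosen_id" %in% names(events)) "chosen_id" else "business_id"
  ev <- events |>
    dplyr::inner_join(
      sets |> dplyr::select("business_id", "set_id", "city"),
      by = setNames("business_id", chosen_col)
    )
  n_no_set <- nrow(events) - nrow(ev)

  members <- sets |> dplyr::select("set_id", member_id = "business_id")
  long <- ev |>
    dplyr::select("event_id", "set_id", "timestamp",
                  dplyr::any_of("review_id")) |>
    dplyr::inner_join(members, by = "set_id", relationship = "many-to-many")
  q <- state_query(
    state, long$member_id, long$timestamp,
    if ("review_id" %in% names(long)) long$review_id else NULL
  )
  long$displayed <- ifelse(
    q$n_reviews > 0,
    floor(2 * clamp(q$raw_prior_mean, 1, 5) + 0.5) / 2,
    NA_real_
  )
  per_event <- long |>
    dplyr::summarise(
      n_options = sum(!is.na(.data$displayed)),
      n_unique_ratings = dplyr::n_distinct(.data$displayed[!is.na(.data$displayed)]),
      .by = "event_id"
    )
  ev <- ev |> dplyr::left_join(per_event, by = "event_id")

  if (source == "reviews") {
    if (is.null(reviews)) stopf("`reviews` required for review-based events.")
    ucount <- reviews |> dplyr::count(.data$user_id, name = "user_n_reviews")
    city_of <- sets |>
      dplyr::distinct(.data$business_id, .data$city) |>
      dplyr::rename(rev_city = "city")
    modal <- reviews |>
      dplyr::inner_join(city_of, by = "business_id") |>
      dplyr::count(.data$user_id, .data$rev_city) |>
      dplyr::slice_max(.data$n, n = 1, by = "user_id", with_ties = FALSE) |>
      dplyr::select("user_id", modal_city = "rev_city")
    ev <- ev |>
      dplyr::left_join(ucount, by = "user_id") |>
      dplyr::left_join(modal, by = "user_id") |>
      dplyr::mutate(
        user_n_reviews = dplyr::coalesce(.data$user_n_reviews, 0L),
        in_modal_city = !is.na(.data$modal_city) & .data$city == .data$modal_city
      )
  }
  attr(ev, "no_set") <- n_no_set
  ev
}
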