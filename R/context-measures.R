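#' Ratings-maximizing (target) choice indicator
#'
#' `TRUE` iff the chosen option's displayed rating equals the snapshot
#' maximum; ties count as target ("possibly non-unique" highest-rated).
#'
#' @param snap A [snapshot()] tibble.
#' @param chosen_id Business id of the chosen option; must be in `snap`.
#' @return Logical scalar.
#' @export
target_indicator <- function(snap, chosen_id) {
  i <- match(chosen_id, snap$business_id)
  if (is.na(i)) stopf("`chosen_id` is not in the snapshot.")
  snap$displayed_rating[i] >= max(snap$displayed_rating) - 1e-12
}

#' Context statistics of a snapshot
#'
#' Mean and population variance of the displayed ratings, the gap between
#' the highest and second-highest order statistics (tied maxima give gap
#' 0), and the distractor mean — the mean over all options below the top
#' two order statistics, which is undefined (`NA`) for fewer than 3
#' options. Tied values at the second-highest rating beyond the first two
#' instances count as distractors (order-statistic convention: exactly the
#' first two positions of the descending sort are the "top two").
#'
#' @param snap A [snapshot()] tibble with at least 2 options.
#' @return List with `mean_set`, `var_set`, `gap12`, `distractor_mean`.
#' @examples
#' s <- tibble::tibble(business_id = letters[1:4],
#'                     displayed_rating = c(4.5, 4.0, 3.0, 2.0))
#' set_statistics(s)  # mean 3.375, gap12 0.5, distractor_mean 2.5
#' @export
set_statistics <- function(snap) {
  x <- snap$displayed_rating
  if (length(x) < 2) stopf("need at least 2 options.")
  xs <- sort(x, decreasing = TRUE)
  list(
    mean_set = mean(x),
    var_set = mean((x - mean(x))^2),
    gap12 = xs[1] - xs[2],
    distractor_mean = if (length(x) >= 3) mean(xs[-(1:2)]) else NA_real_
  )
}

#' Post-choice rating deviation
#'
#' The user's star rating minus the chosen option's unrounded running mean
#' at choice time (signed; positive means the user rated above the
#' option's standing value). Records with no prior reviews have no defined
#' deviation and are excluded upstream.
#'
#' @param user_stars The user's given rating.
#' @param raw_prior_mean_chosen Unrounded prior mean of the chosen option.
#' @return `user_stars - raw_prior_mean_chosen`.
#' @export
rating_deviation <- function(user_stars, raw_prior_mean_chosen) {
  if (any(is.na(raw_prior_mean_chosen))) {
    stopf("prior mean undefined (no prior reviews).")
  }
  user_stars - raw_prior_mean_chosen
}

#' Build the per-decision analysis table
#'
#' Converts eligible events into one row per decision with every regressor
#' of the downstream models: target indicator, set statistics, top-option
#' and chosen-option covariates, the set mean excluding the chosen option,
#' and (for review-based events) the rating deviation. All snapshot
#' quantities are strict leave-one-out states at the event timestamp. When
#' the top displayed rating is tied, top-option covariates come from the
#' tied option with the smallest business id (deterministic).
#'
#' @param events Eligible event tibble (from [filter_events()]); must carry
#'   `event_id`, `set_id`, `timestamp`, the chosen `business_id`/
#'   `chosen_id`, and for reviews `review_id`, `user_id`, `stars`, `text`.
#' @param sets Long membership tibble.
#' @param state A [rating_state()].
#' @param businesses Business tibble with `business_id`, `price`.
#' @return A `ChoiceRecord` tibble, one row per event whose chosen option
#'   is rated in the snapshot (others tallied in
#'   `attr(, "chosen_unrated")`).
#' @export
build_choice_table <- function(events, sets, state, businesses) {
  chosen_col <- if ("chosen_id" %in% names(events)) "chosen_id" else "business_id"
  ev <- events
  ev$chosen <- ev[[chosen_col]]
  keep_cols <- intersect(
    c("event_id", "user_id", "set_id", "timestamp", "chosen", "review_id",
      "stars", "text"),
    names(ev)
  )
  ev <- ev[, keep_cols]

  members <- sets |> dplyr::select("set_id", member_id = "business_id")
  long <- ev |>
    dplyr::inner_join(members, by = "set_id", relationship = "many-to-many")
  q <- state_query(
    state, long$member_id, long$timestamp,
    if ("review_id" %in% names(long)) long$review_id else NULL
  )
  long$raw_mean <- clamp(q$raw_prior_mean, 1, 5)
  long$n_rev <- q$n_reviews
  long <- long[long$n_rev > 0L, ]
  long$displayed <- floor(2 * long$raw_mean + 0.5) / 2
  long$price <- businesses$price[match(long$member_id, businesses$business_id)]

  tab <- aggregate_choice_rows(long)

  out <- ev |>
    dplyr::inner_join(tab, by = "event_id") |>
    dplyr::rename(chosen_id = "chosen")
  n_unrated <- sum(is.na(out$chosen_row))
  out <- out[!is.na(out$chosen_row), ]
  out$chosen_row <- NULL
  if ("stars" %in% names(out)) {
    out$user_stars <- out$stars
    out$rating_deviation <- out$user_stars - out$raw_prior_mean_chosen
    out$stars <- NULL
  }
  if ("text" %in% names(out)) {
    out$review_text_length <- nchar(out$text)
    out$text <- NULL
  }
  attr(out, "chosen_unrated") <- n_unrated
  tibble::as_tibble(out)
}

# vectorized per-event aggregation over run boundaries of the sorted table;
# `long` needs columns event_id, member_id, displayed, raw_mean, n_rev,
# price, chosen
aggregate_choice_rows <- function(long) {
  long <- long |>
    dplyr::arrange(
      .data$event_id, dplyr::desc(.data$displayed), .data$member_id
    )
  nL <- nrow(long)
  starts <- which(!duplicated(long$event_id))
  ends <- c(starts[-1] - 1L, nL)
  nopt <- ends - starts + 1L
  cs <- cumsum(long$displayed)
  cs2 <- cumsum(long$displayed^2)
  sum_d <- cs[ends] - cs[starts] + long$displayed[starts]
  sum_d2 <- cs2[ends] - cs2[starts] + long$displayed[starts]^2
  mean_d <- sum_d / nopt
  top1 <- long$displayed[starts]
  top2 <- ifelse(nopt >= 2L, long$displayed[pmin(starts + 1L, nL)], NA_real_)

  hit <- which(long$member_id == long$chosen)
  ev_of_hit <- match(long$event_id[hit], long$event_id[starts])
  chosen_row <- rep(NA_integer_, length(starts))
  chosen_row[ev_of_hit] <- hit

  tab <- tibble::tibble(
    event_id = long$event_id[starts],
    n_options = nopt,
    mean_set = mean_d,
    var_set = pmax(sum_d2 / nopt - mean_d^2, 0),
    gap12 = top1 - top2,
    distractor_mean = ifelse(nopt >= 3L,
                             (sum_d - top1 - top2) / (nopt - 2L), NA_real_),
    price_top = long$price[starts],
    n_reviews_top = long$n_rev[starts],
    chosen_row = chosen_row
  )
  cr <- ifelse(is.na(tab$chosen_row), 1L, tab$chosen_row) # safe subscript
  tab$is_target <- !is.na(tab$chosen_row) &
    long$displayed[cr] >= top1 - 1e-12
  tab$in_top_two <- !is.na(tab$chosen_row) & (cr - starts + 1L) <= 2L
  tab$raw_prior_mean_chosen <- ifelse(is.na(tab$chosen_row), NA_real_,
                                      long$raw_mean[cr])
  tab$n_reviews_chosen <- ifelse(is.na(tab$chosen_row), NA_integer_,
                                 long$n_rev[cr])
  tab$price_chosen <- ifelse(is.na(tab$chosen_row), NA_real_,
                             long$price[cr])
  tab$mean_set_excl_chosen <- ifelse(
    is.na(tab$chosen_row) | nopt < 2L, NA_real_,
    (sum_d - long$displayed[cr]) / (nopt - 1L)
  )
  tab
}

#' Restrict to top-two choices for the distractor (IIA) analysis
#'
#' Keeps only decisions whose chosen option sat at one of the top two
#' positions of the descending displayed-rating sort, in sets of at least 3
#' options, and redefines the response as choosing the top option among the
#' top two (`chose_top`). Sets whose top two ratings are tied are dropped
#' (`attr(, "tied_top")`): with a tie the top-vs-second response is
#' undefined, and keeping such rows forces `chose_top = TRUE` by
#' construction, which biases the distractor coefficient. The retained
#' fraction among eligible untied sets — comparable to the real-world
#' 75%/72% retention — is reported in `attr(, "retained_frac")`.
#'
#' @param choice_table Output of [build_choice_table()].
#' @return The top-two subset with added `chose_top`.
#' @export
build_distractor_table <- function(choice_table) {
  pool <- choice_table |>
    dplyr::filter(.data$n_options >= 3)
  eligible <- pool |>
    dplyr::filter(.data$gap12 > 0)
  out <- eligible |>
    dplyr::filter(.data$in_top_two) |>
    dplyr::mutate(chose_top = .data$is_target)
  attr(out, "retained_frac") <-
    if (nrow(eligible)) nrow(out) / nrow(eligible) else NA_real_
  attr(out, "tied_top") <- nrow(pool) - nrow(eligible)
  out
}

#' Binned target-choice rates by set mean
#'
#' Tabular analogue of the headline context-effect figure: the proportion
#' of ratings-maximizing choices within bins of the mean displayed rating
#' of the choice set.
#'
#' @param choice_table Output of [build_choice_table()].
#' @param breaks Bin boundaries for `mean_set` (default the four bins
#'   `<=3`, `3-3.5`, `3.5-4`, `>4`).
#' @return Tibble of `bin`, `n`, `target_rate`.
#' @export
bin_target_rates <- function(choice_table,
                             breaks = c(-Inf, 3, 3.5, 4, Inf)) {
  choice_table |>
    dplyr::mutate(bin = cut(.data$mean_set, breaks = breaks)) |>
    dplyr::summarise(
      n = dplyr::n(),
      target_rate = mean(.data$is_target),
      .by = "bin"
    ) |>
    dplyr::arrange(.data$bin)
}
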