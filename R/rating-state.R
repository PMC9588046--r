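#' Round a star rating to the displayed half-star
#'
#' Displayed ratings are the running mean rounded to the nearest multiple of
#' 0.5, as review platforms present them. Exact midpoints (x ending in .25
#' or .75) round up; the function is idempotent on the half-star lattice.
#'
#' @param x Numeric vector in `[1, 5]`.
#' @return `x` rounded to `{1.0, 1.5, ..., 5.0}`.
#' @examples
#' round_half_star(c(3.24, 3.25, 3.26))  # 3.0 3.5 3.5
#' @export
round_half_star <- function(x) {
  if (any(!is.finite(x)) || any(x < 1 - 1e-9) || any(x > 5 + 1e-9)) {
    stopf("`x` must lie in [1, 5].")
  }
  floor(2 * x + 0.5) / 2
}

#' Leave-one-out prefix mean of a business's reviews
#'
#' Mean star rating and review count over reviews strictly before `t`,
#' excluding `exclude_review_id` even if it is stamped earlier than `t` —
#' the informational state a user plausibly saw when choosing, never
#' contaminated by the review under analysis.
#'
#' @param reviews Tibble of one business's reviews with columns `review_id`,
#'   `timestamp`, `stars`; timestamps must be strictly increasing.
#' @param t Query instant.
#' @param exclude_review_id Optional review id to leave out; must belong to
#'   `reviews`.
#' @return List with `raw_prior_mean` (`NA` when no prior reviews) and
#'   `n_reviews`.
#' @export
prefix_mean <- function(reviews, t, exclude_review_id = NULL) {
  if (is.unsorted(reviews$timestamp, strictly = TRUE)) {
    stopf("`reviews` must be strictly time-ordered.")
  }
  keep <- reviews$timestamp < t
  if (!is.null(exclude_review_id)) {
    hit <- reviews$review_id == exclude_review_id
    if (!any(hit)) stopf("`exclude_review_id` does not belong to this business.")
    keep <- keep & !hit
  }
  n <- sum(keep)
  list(raw_prior_mean = if (n > 0) mean(reviews$stars[keep]) else NA_real_,
       n_reviews = n)
}

#' Build an indexed, time-ordered review state
#'
#' Pre-sorts reviews per business (cumulative star sums over strictly
#' increasing timestamps) so displayed ratings at arbitrary instants can be
#' queried in logarithmic time. All prefix queries are strict
#' (`timestamp < t`) and leave-one-out.
#'
#' @param reviews Review tibble (`review_id`, `business_id`, `timestamp`,
#'   `stars`); timestamps must be unique within each business.
#' @return A `rating_state` object.
#' @export
rating_state <- function(reviews) {
  ord <- order(reviews$business_id, reviews$timestamp)
  r <- reviews[ord, c("review_id", "business_id", "timestamp", "stars")]
  grp <- split(seq_len(nrow(r)), r$business_id)
  idx <- purrr::map(grp, function(i) {
    ts <- r$timestamp[i]
    if (anyDuplicated(ts)) stopf("review timestamps must be unique per business.")
    list(times = ts, cum = cumsum(r$stars[i]), stars = r$stars[i],
         ids = r$review_id[i])
  })
  structure(list(index = idx, businesses = names(idx)), class = "rating_state")
}

# vectorized strict-prefix leave-one-out query; returns raw means and counts
state_query <- function(state, business_ids, times, exclude_ids = NULL) {
  n <- length(business_ids)
  raw <- rep(NA_real_, n)
  cnt <- integer(n)
  by_b <- split(seq_len(n), business_ids)
  for (b in names(by_b)) {
    qi <- by_b[[b]]
    ix <- state$index[[b]]
    if (is.null(ix)) next
    tq <- times[qi]
    k <- findInterval(tq, ix$times)
    # strictness: drop a review stamped exactly at t
    at_t <- k > 0 & ix$times[pmax(k, 1L)] == tq
    k <- k - as.integer(at_t)
    s <- ifelse(k > 0, ix$cum[pmax(k, 1L)], 0)
    if (!is.null(exclude_ids)) {
      ex <- match(exclude_ids[qi], ix$ids)
      drop <- !is.na(ex) & ex <= k
      s <- s - ifelse(drop, ix$stars[pmax(ex, 1L)], 0)
      k <- k - as.integer(drop)
    }
    raw[qi] <- ifelse(k > 0, s / pmax(k, 1L), NA_real_)
    cnt[qi] <- k
  }
  list(raw_prior_mean = raw, n_reviews = cnt)
}

#' Snapshot of a choice set's displayed options at an instant
#'
#' One [DisplayedOption] row per set member with at least one prior review:
#' unrounded running mean, half-star displayed rating, review count and
#' price, all computed strictly before `t` and excluding the focal review.
#' Members with no prior reviews are omitted (no displayable rating exists)
#' and tallied in `attr(, "omitted")`.
#'
#' @param state A [rating_state()].
#' @param member_ids Character vector of the set's business ids.
#' @param t Query instant.
#' @param exclude_review_id Optional focal review id to leave out.
#' @param prices Optional named numeric vector (by business id) of price
#'   levels to carry into the snapshot.
#' @return Tibble with `business_id`, `raw_prior_mean`, `displayed_rating`,
#'   `n_reviews`, `price`.
#' @export
snapshot <- function(state, member_ids, t, exclude_review_id = NULL,
                     prices = NULL) {
  if (length(member_ids) == 0) stopf("`member_ids` must be non-empty.")
  q <- state_query(state, member_ids, rep(t, length(member_ids)),
                   if (is.null(exclude_review_id)) NULL
                   else rep(exclude_review_id, length(member_ids)))
  keep <- q$n_reviews > 0
  out <- tibble::tibble(
    business_id = member_ids[keep],
    raw_prior_mean = q$raw_prior_mean[keep],
    displayed_rating = round_half_star(clamp(q$raw_prior_mean[keep], 1, 5)),
    n_reviews = q$n_reviews[keep],
    price = if (is.null(prices)) NA_real_ else unname(prices[member_ids[keep]])
  )
  attr(out, "omitted") <- sum(!keep)
  out
}
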