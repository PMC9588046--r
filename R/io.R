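# Readers/writers for the external formats: review-platform JSON Lines
# (business / review / check-in dialects), delivery-orders CSV, experiment
# trial and snapshot CSVs. Internal timestamps are minutes since
# 2012-01-01 UTC; they serialize as "YYYY-MM-DD HH:MM:SS.mmm" strings.

TIME_ORIGIN <- as.POSIXct("2012-01-01", tz = "UTC")

time_to_chr <- function(ts) {
  format(TIME_ORIGIN + ts * 60, "%Y-%m-%d %H:%M:%OS3", tz = "UTC")
}

chr_to_time <- function(s) {
  as.numeric(difftime(as.POSIXct(s, tz = "UTC",
                                 tryFormats = c("%Y-%m-%d %H:%M:%OS",
                                                "%Y-%m-%d %H:%M:%S",
                                                "%Y-%m-%d")),
                      TIME_ORIGIN, units = "mins"))
}

#' Read platform-dialect JSON Lines records
#'
#' Tolerant line-by-line parser for the three record kinds of the open
#' review-platform export: `business` (id, name, coordinates, comma-joined
#' category string, price attribute, city), `review` (ids, stars, date,
#' text), and `checkin` (business id plus a comma-joined timestamp list,
#' exploded into one event per timestamp). Malformed lines are skipped and
#' counted (`attr(, "malformed")`); more than 5% malformed lines is fatal.
#' Missing prices become `NA` and are counted in `attr(, "missing_price")`.
#' The umbrella category term "Restaurants" marks a business as a
#' restaurant (`is_restaurant`) and is dropped from `assigned_terms`.
#'
#' @param path File path.
#' @param record_kind `"business"`, `"review"`, or `"checkin"`.
#' @return A typed tibble; timestamps numeric (minutes since the epoch
#'   origin).
#' @export
read_yelp_jsonl <- function(path, record_kind = c("business", "review", "checkin")) {
  record_kind <- match.arg(record_kind)
  if (!file.exists(path)) stopf("cannot read `%s`.", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  bad <- 0L
  for (i in seq_along(lines)) {
    r <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(r) || !is.list(r)) bad <- bad + 1L else recs[[i]] <- r
  }
  if (length(lines) > 0 && bad / length(lines) > 0.05) {
    stopf("%d of %d lines malformed (> 5%%); first bad line: %s",
          bad, length(lines),
          substr(lines[which(vapply(recs, is.null, logical(1)))[1]], 1, 80))
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]

  out <- switch(record_kind,
    business = {
      missing_price <- 0L
      rows <- purrr::map(recs, function(r) {
        price <- suppressWarnings(as.integer(r$attributes$RestaurantsPriceRange2))
        if (length(price) != 1 || is.na(price)) {
          missing_price <<- missing_price + 1L
          price <- NA_integer_
        }
        terms <- strsplit(r$categories %||% "", ", ", fixed = TRUE)[[1]]
        tibble::tibble(
          business_id = r$business_id,
          name = r$name %||% r$business_id,
          lat = as.numeric(r$latitude),
          lon = as.numeric(r$longitude),
          city = r$city %||% NA_character_,
          is_restaurant = "Restaurants" %in% terms,
          assigned_terms = list(setdiff(terms, "Restaurants")),
          price = price
        )
      })
      res <- dplyr::bind_rows(rows)
      attr(res, "missing_price") <- missing_price
      res
    },
    review = {
      dplyr::bind_rows(purrr::map(recs, function(r) {
        tibble::tibble(
          review_id = r$review_id,
          user_id = r$user_id,
          business_id = r$business_id,
          timestamp = chr_to_time(r$date),
          stars = as.numeric(r$stars),
          text = r$text %||% ""
        )
      }))
    },
    checkin = {
      dplyr::bind_rows(purrr::map(recs, function(r) {
        ts <- strsplit(r$date %||% "", ", ", fixed = TRUE)[[1]]
        if (length(ts) == 0) return(NULL)
        tibble::tibble(business_id = r$business_id,
                       timestamp = chr_to_time(ts))
      }))
    }
  )
  attr(out, "malformed") <- bad
  out
}

#' Write platform-dialect JSON Lines
#'
#' Inverse of [read_yelp_jsonl()]: business records re-attach the umbrella
#' "Restaurants" term to the comma-joined category string; check-ins are
#' grouped into one line per business with a comma-joined timestamp list.
#'
#' @param businesses,reviews,checkins Tibbles in the package's internal
#'   shapes (see [generate_world()] and [simulate_checkins()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_yelp_businesses <- function(businesses, path) {
  lines <- purrr::pmap_chr(
    list(businesses$business_id,
         businesses[["name"]] %||% businesses$business_id,
         businesses$lat, businesses$lon, businesses$city,
         businesses$assigned_terms, businesses$price),
    function(id, nm, lat, lon, city, terms, price) {
      jsonlite::toJSON(list(
        business_id = id, name = nm, latitude = lat, longitude = lon,
        categories = paste(c("Restaurants", terms), collapse = ", "),
        attributes = list(RestaurantsPriceRange2 = as.character(price)),
        city = city
      ), auto_unbox = TRUE, digits = NA)
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yelp_businesses
#' @export
write_yelp_reviews <- function(reviews, path) {
  lines <- purrr::pmap_chr(
    list(reviews$review_id, reviews$user_id, reviews$business_id,
         reviews$stars, time_to_chr(reviews$timestamp), reviews$text),
    function(rid, uid, bid, stars, date, text) {
      jsonlite::toJSON(list(review_id = rid, user_id = uid,
                            business_id = bid, stars = stars, date = date,
                            text = text),
                       auto_unbox = TRUE, digits = NA)
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yelp_businesses
#' @export
write_yelp_checkins <- function(checkins, path) {
  grouped <- checkins |>
    dplyr::arrange(.data$business_id, .data$timestamp) |>
    dplyr::summarise(
      date = paste(time_to_chr(.data$timestamp), collapse = ", "),
      .by = "business_id"
    )
  lines <- purrr::map2_chr(grouped$business_id, grouped$date, function(b, d) {
    jsonlite::toJSON(list(business_id = b, date = d), auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(path)
}

ORDERS_HEADER <- c("user_id", "restaurant_id", "city", "cuisine", "stars",
                   "n_ratings", "price", "timestamp")

#' Read and write delivery-order CSVs
#'
#' Orders carry static displayed ratings (`stars`), review counts and
#' prices per restaurant — the two-month static treatment of the delivery
#' replication — and are keyed into (city, cuisine) choice sets. The header
#' must match exactly.
#'
#' @param path File path.
#' @param orders Order tibble from [simulate_orders()] (or same shape).
#' @return `read_orders_csv()`: an order tibble with numeric timestamps.
#' @export
read_orders_csv <- function(path) {
  if (!file.exists(path)) stopf("cannot read `%s`.", path)
  hdr <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  if (!identical(hdr, ORDERS_HEADER)) {
    stopf("order CSV header mismatch; expected: %s",
          paste(ORDERS_HEADER, collapse = ","))
  }
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    user_id = "c", restaurant_id = "c", city = "c",
                    cuisine = "c", stars = "d", n_ratings = "i",
                    price = "i", timestamp = "c"
                  )) |>
    dplyr::mutate(timestamp = chr_to_time(.data$timestamp))
}

#' @rdname read_orders_csv
#' @export
write_orders_csv <- function(orders, path) {
  orders |>
    dplyr::mutate(timestamp = time_to_chr(.data$timestamp)) |>
    readr::write_csv(path)
  invisible(path)
}

#' Read and write experiment trial and snapshot CSVs
#'
#' Trials serialize one row per trial (`participant_id`, `trial_id`,
#' `trial_type`, `snapshot_id`, `highlighted_id`, `response_choice`,
#' `response_satisfaction`); snapshots one row per displayed option.
#'
#' @param path File path.
#' @param trials,pool Tibbles from [simulate_experiment()] /
#'   [experiment_pool()].
#' @return The corresponding tibble.
#' @export
read_trials_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    participant_id = "c", trial_id = "i", trial_type = "c",
                    snapshot_id = "c", highlighted_id = "c",
                    response_choice = "c", response_satisfaction = "d"
                  ))
}

#' @rdname read_trials_csv
#' @export
write_trials_csv <- function(trials, path) {
  readr::write_csv(trials, path, na = "")
  invisible(path)
}

#' @rdname read_trials_csv
#' @export
read_snapshots_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    snapshot_id = "c", business_id = "c",
                    displayed_rating = "d", n_reviews = "i", price = "i"
                  ))
}

#' @rdname read_trials_csv
#' @export
write_snapshots_csv <- function(pool, path) {
  readr::write_csv(pool, path)
  invisible(path)
}
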