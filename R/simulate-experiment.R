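#' Build a snapshot pool for the laboratory-style experiment
#'
#' Extracts choice-set snapshots from a synthetic world's post-seed rating
#' state, keeping sets whose size lies in the experiment's range (3-7
#' options by default, matching the real stimuli).
#'
#' @param world A `ctx_world`.
#' @param min_size,max_size Allowed option counts.
#' @return Long tibble of snapshot options: `snapshot_id`, `business_id`,
#'   `displayed_rating`, `n_reviews`, `price`.
#' @export
experiment_pool <- function(world, min_size = 3, max_size = 7) {
  sets <- build_true_sets(world, min_members = min_size)
  st <- post_seed_state(world)
  raw <- clamp(st$sums / pmax(st$cnt, 1L), 1, 5)
  disp <- floor(2 * raw + 0.5) / 2
  purrr::imap(sets$members, function(m, i) {
    if (length(m) < min_size || length(m) > max_size) return(NULL)
    tibble::tibble(
      snapshot_id = sets$index$set_id[i],
      business_id = world$restaurants$business_id[m],
      displayed_rating = disp[m],
      n_reviews = st$cnt[m],
      price = world$restaurants$price[m]
    )
  }) |>
    dplyr::bind_rows()
}

#' Simulate a choice-and-rating laboratory experiment
#'
#' Each simulated participant completes 275 trials over snapshots drawn
#' from `pool`: 135 choice trials (answered through the divisive-
#' normalization choice model with a participant-specific context weight
#' `omega_p`), 135 rating trials (expected 0-100 satisfaction for one
#' highlighted option, `a + b * r_highlighted - c_p * mean(context) +
#' noise`, with the context-discounting slope `c_p` tied to the
#' participant's `kappa_p`), and 5 catch trials requiring the highest-rated
#' option, answered correctly except for a configurable lapse rate.
#' Participant-level `(omega_p, kappa_p)` pairs are drawn from a bivariate
#' normal with a configurable correlation — the generative hook for the
#' choice-rating concordance analysis.
#'
#' @param pool Snapshot pool from [experiment_pool()] (or the same shape).
#'   Fewer than 275 distinct snapshots is allowed; snapshots are then
#'   re-used with a warning.
#' @param n_participants Number of participants (`> 0`).
#' @param config A [world_config()] supplying `sigma`, `tau`, and the seed.
#' @param heterogeneity List of participant-level parameters:
#'   `omega_mean`, `omega_sd`, `kappa_mean`, `kappa_sd`, `correlation`,
#'   `lapse`, the lab choice temperature `tau_exp` (hypothetical grid
#'   choices are more rating-driven than real-world visits, so the default
#'   0.02 is sharper than the stream's `tau`), and the satisfaction model
#'   constants `a`, `b`, `c_scale` (`c_p = c_scale * kappa_p`), `noise_sd`.
#'   The `omega_p` population (mean 0.15, SD 0.10, truncated at 0) spans
#'   the weak-normalization branch where the regression-based choice
#'   context effect is a monotone readout of `omega_p` (see the methods
#'   vignette).
#' @param n_choice,n_rating,n_catch Trial counts per participant
#'   (defaults 135/135/5).
#' @return Trial tibble (`participant_id`, `trial_id`, `trial_type`,
#'   `snapshot_id`, `highlighted_id`, `response_choice`,
#'   `response_satisfaction`) with `attr(, "participants")` holding the
#'   true per-participant `(omega_p, kappa_p, c_p)`.
#' @export
simulate_experiment <- function(pool, n_participants, config,
                                heterogeneity = list(),
                                n_choice = 135, n_rating = 135, n_catch = 5) {
  if (!is_count(n_participants)) {
    stopf("`n_participants` must be a positive integer.",
          class = "contextchoice_config_error")
  }
  h <- utils::modifyList(
    list(omega_mean = 0.15, omega_sd = 0.10, kappa_mean = 0.4,
         kappa_sd = 0.15, correlation = 0.8, lapse = 0.05, tau_exp = 0.02,
         a = 20, b = 12, c_scale = 7.5, noise_sd = 8),
    heterogeneity
  )
  snap_ids <- unique(pool$snapshot_id)
  n_trials <- n_choice + n_rating + n_catch
  if (length(snap_ids) < n_trials) {
    rlang::warn(sprintf(
      "pool has %d snapshots for %d trials; snapshots will be re-used",
      length(snap_ids), n_trials
    ))
  }
  snaps <- split(pool, pool$snapshot_id)

  with_seed(derive_seed(config$seed, 5L), {
    z1 <- rnorm(n_participants)
    z2 <- rnorm(n_participants)
    rho <- h$correlation
    omega_p <- pmax(h$omega_mean + h$omega_sd * z1, 0)
    kappa_p <- h$kappa_mean + h$kappa_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    c_p <- h$c_scale * kappa_p
    participants <- tibble::tibble(
      participant_id = sprintf("p_%03d", seq_len(n_participants)),
      omega_p = omega_p, kappa_p = kappa_p, c_p = c_p
    )

    rows <- purrr::map(seq_len(n_participants), function(p) {
      ids <- if (length(snap_ids) >= n_trials) {
        sample(snap_ids, n_trials)
      } else {
        sample(rep(snap_ids, length.out = n_trials))
      }
      type <- sample(rep(c("choice", "rating", "catch"),
                         c(n_choice, n_rating, n_catch)))
      highlighted <- rep(NA_character_, n_trials)
      resp_choice <- rep(NA_character_, n_trials)
      resp_sat <- rep(NA_real_, n_trials)
      for (i in seq_len(n_trials)) {
        s <- snaps[[ids[i]]]
        r <- s$displayed_rating
        if (type[i] == "choice") {
          pr <- choice_probabilities(
            normalized_value(r, r, config$sigma, omega_p[p]), h$tau_exp
          )
          resp_choice[i] <- s$business_id[sample.int(length(r), 1, prob = pr)]
        } else if (type[i] == "rating") {
          j <- sample.int(length(r), 1)
          highlighted[i] <- s$business_id[j]
          sat <- h$a + h$b * r[j] - c_p[p] * mean(r[-j]) +
            rnorm(1, 0, h$noise_sd)
          resp_sat[i] <- clamp(sat, 0, 100)
        } else {
          best <- which(r >= max(r) - 1e-12)[1]
          pick <- if (runif(1) < h$lapse && length(r) > 1) {
            sample(setdiff(seq_along(r), best), 1)
          } else best
          resp_choice[i] <- s$business_id[pick]
        }
      }
      tibble::tibble(
        participant_id = participants$participant_id[p],
        trial_id = seq_len(n_trials),
        trial_type = type,
        snapshot_id = ids,
        highlighted_id = highlighted,
        response_choice = resp_choice,
        response_satisfaction = resp_sat
      )
    })
    trials <- dplyr::bind_rows(rows)
    attr(trials, "participants") <- participants
    trials
  })
}

#' Exclude participants by catch-trial accuracy
#'
#' A catch response is correct iff the chosen option's displayed rating
#' equals the snapshot maximum (ties count). Participants are retained iff
#' their catch accuracy is at least `threshold` (with 5 catch trials,
#' >= 3 of 5 correct at the default 60% rule).
#'
#' @param trials Trial tibble from [simulate_experiment()] (or same shape).
#' @param pool The snapshot pool the trials refer to.
#' @param threshold Minimum catch accuracy (default 0.6).
#' @return Tibble of `participant_id`, `n_catch`, `accuracy`, `retained`.
#' @export
catch_trial_exclusion <- function(trials, pool, threshold = 0.6) {
  catch <- trials |> dplyr::filter(.data$trial_type == "catch")
  all_p <- unique(trials$participant_id)
  missing <- setdiff(all_p, unique(catch$participant_id))
  if (length(missing) > 0) {
    stopf("participants without catch trials: %s",
          paste(missing, collapse = ", "))
  }
  maxes <- pool |>
    dplyr::summarise(max_rating = max(.data$displayed_rating),
                     .by = "snapshot_id")
  # a response that is not an option of its snapshot counts as incorrect
  catch |>
    dplyr::left_join(
      pool |> dplyr::select("snapshot_id", "business_id", "displayed_rating"),
      by = c("snapshot_id", response_choice = "business_id")
    ) |>
    dplyr::left_join(maxes, by = "snapshot_id") |>
    dplyr::mutate(correct = !is.na(.data$displayed_rating) &
                    .data$displayed_rating >= .data$max_rating - 1e-12) |>
    dplyr::summarise(
      n_catch = dplyr::n(),
      accuracy = mean(.data$correct),
      .by = "participant_id"
    ) |>
    dplyr::mutate(retained = .data$accuracy >= threshold)
}

#' Analysis tables for experiment trials
#'
#' `experiment_choice_table()` turns choice (or catch) trials into the same
#' per-decision row schema as [build_choice_table()], with the participant
#' as the grouping user. `expectation_table()` turns rating trials into
#' rows for the expected-satisfaction regression: the highlighted option's
#' rating, review count and price, the context mean excluding the
#' highlighted option, and the 0-100 response.
#'
#' @param trials Trial tibble.
#' @param pool Snapshot pool.
#' @return A tibble, one row per trial.
#' @export
experiment_choice_table <- function(trials, pool) {
  ch <- trials |> dplyr::filter(.data$trial_type == "choice")
  long <- ch |>
    dplyr::transmute(event_id = paste(.data$participant_id, .data$trial_id),
                     user_id = .data$participant_id,
                     snapshot_id = .data$snapshot_id,
                     chosen = .data$response_choice) |>
    dplyr::inner_join(pool, by = "snapshot_id",
                      relationship = "many-to-many") |>
    dplyr::mutate(member_id = .data$business_id,
                  displayed = .data$displayed_rating,
                  raw_mean = .data$displayed_rating,
                  n_rev = .data$n_reviews)
  tab <- aggregate_choice_rows(long)
  long |>
    dplyr::distinct(.data$event_id, .data$user_id, .data$snapshot_id,
                    .data$chosen) |>
    dplyr::inner_join(tab, by = "event_id") |>
    dplyr::filter(!is.na(.data$chosen_row)) |>
    dplyr::select(-"chosen_row") |>
    dplyr::rename(chosen_id = "chosen")
}

#' @rdname experiment_choice_table
#' @export
expectation_table <- function(trials, pool) {
  rt <- trials |> dplyr::filter(.data$trial_type == "rating")
  stats <- rt |>
    dplyr::transmute(event_id = paste(.data$participant_id, .data$trial_id),
                     user_id = .data$participant_id,
                     snapshot_id = .data$snapshot_id,
                     highlighted_id = .data$highlighted_id,
                     response_satisfaction = .data$response_satisfaction) |>
    dplyr::inner_join(pool, by = "snapshot_id",
                      relationship = "many-to-many")
  stats |>
    dplyr::summarise(
      user_id = .data$user_id[1],
      n_options = dplyr::n(),
      r_highlighted = .data$displayed_rating[.data$business_id ==
                                               .data$highlighted_id[1]][1],
      n_reviews_highlighted = .data$n_reviews[.data$business_id ==
                                                .data$highlighted_id[1]][1],
      price_highlighted = .data$price[.data$business_id ==
                                        .data$highlighted_id[1]][1],
      mean_set_excl_highlighted = mean(
        .data$displayed_rating[.data$business_id != .data$highlighted_id[1]]
      ),
      response_satisfaction = .data$response_satisfaction[1],
      .by = "event_id"
    )
}
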