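#' Run the full context-effect analysis pipeline
#'
#' Chains every stage end to end on a synthetic world: generation, review /
#' check-in / order / experiment stream simulation, category inference from
#' review text, per-city DBSCAN tuning and clustering of review
#' coordinates, choice-set assembly, eligibility filtering, per-decision
#' measure tables, the regression battery, and (for the experiment) the
#' catch-trial exclusion and choice-rating concordance. Every random draw
#' descends from `config$seed`; two runs with the same config are
#' identical.
#'
#' The review-stream regressions default to the fast pooled path with
#' cluster-robust errors (`method`); experiment fits always use the MCMC
#' engine because the concordance needs per-participant conditional effects
#' with non-degenerate spread.
#'
#' @param config A [world_config()].
#' @param sources Character subset of
#'   `c("reviews", "checkins", "orders", "experiment")`.
#' @param method Engine for the review-stream fits (`"fast"`, `"mixed"`,
#'   `"mcmc"`).
#' @param thresholds Named list overriding filter thresholds
#'   (`min_set_size`, `min_unique_ratings`, `min_user_reviews`,
#'   `min_orders_set_size`).
#' @param clustering Named list: either tuned (`k`, `quantile_p`,
#'   `target_min_pts_fraction`) or explicit overrides (`eps`, `min_pts`).
#' @param n_participants Experiment participants (default 100).
#' @param heterogeneity Passed to [simulate_experiment()].
#' @param use_true_sets Skip category inference + clustering and use the
#'   generator's ground-truth sets (for recovery tests).
#' @param out_dir Optional directory; tables (TSV), fits and the report
#'   (JSON) are written there.
#' @return A `ctx_report` list; see Details.
#' @export
run_pipeline <- function(config = world_config(),
                         sources = c("reviews", "checkins", "orders",
                                     "experiment"),
                         method = "fast",
                         thresholds = list(),
                         clustering = list(),
                         n_participants = 100,
                         heterogeneity = list(),
                         use_true_sets = FALSE,
                         out_dir = NULL) {
  if (length(sources) == 0) {
    stopf("at least one analysis source must be enabled.",
          class = "contextchoice_config_error")
  }
  sources <- match.arg(sources, several.ok = TRUE)
  th <- utils::modifyList(
    list(min_set_size = 3, min_unique_ratings = 3, min_user_reviews = 100,
         min_orders_set_size = 5),
    thresholds
  )
  cl <- utils::modifyList(
    list(k = 8, quantile_p = 0.5, target_min_pts_fraction = 0.01,
         eps = NULL, min_pts = NULL),
    clustering
  )

  world <- generate_world(config)
  stream <- simulate_choice_stream(world)
  reviews_all <- dplyr::bind_rows(world$reviews, stream$reviews)
  state <- rating_state(reviews_all)

  report <- list(config = config, seed = config$seed,
                 counts = list(), exclusions = list(), fits = list(),
                 clustering = NULL, binned = NULL, experiment = NULL)

  # --- choice sets: reconstructed from data, or ground truth ----------------
  if (use_true_sets) {
    ts <- build_true_sets(world, min_members = 1L)
    sets <- purrr::imap(ts$members, function(m, i) {
      tibble::tibble(set_id = ts$index$set_id[i],
                     city = world$restaurants$city[m][1],
                     cluster = world$restaurants$true_cluster[m][1],
                     category = world$restaurants$true_primary_term[m][1],
                     business_id = world$restaurants$business_id[m])
    }) |> dplyr::bind_rows()
  } else {
    assignments <- infer_categories(world$restaurants, reviews_all)
    rev_pts <- reviews_all |>
      dplyr::inner_join(
        world$restaurants |>
          dplyr::select("business_id", "city", "lat", "lon"),
        by = "business_id"
      )
    labelings <- list()
    cluster_log <- list()
    for (ct in unique(world$restaurants$city)) {
      rp <- rev_pts |> dplyr::filter(.data$city == ct)
      rc <- world$restaurants |> dplyr::filter(.data$city == ct)
      params <- if (!is.null(cl$eps) && !is.null(cl$min_pts)) {
        list(eps = cl$eps, min_pts = cl$min_pts)
      } else {
        tune_dbscan_params(rc[, c("lat", "lon")],
                           target_min_pts_fraction = cl$target_min_pts_fraction,
                           k = cl$k, quantile_p = cl$quantile_p,
                           n_points = nrow(rp))
      }
      lab <- dbscan_cluster(rp[, c("lat", "lon")], params$eps, params$min_pts)
      # restaurant label = label of its (identical) review points
      rest_lab <- lab[match(rc$business_id, rp$business_id)]
      rest_lab[is.na(rest_lab)] <- 0L
      labelings[[ct]] <- tibble::tibble(business_id = rc$business_id,
                                        cluster = rest_lab)
      occupied <- table(rest_lab[rest_lab > 0])
      cluster_log[[ct]] <- tibble::tibble(
        city = ct, eps = params$eps, min_pts = params$min_pts,
        n_clusters = length(occupied),
        mean_occupancy = if (length(occupied)) mean(occupied) else NA_real_,
        n_noise_restaurants = sum(rest_lab == 0)
      )
    }
    labeling <- dplyr::bind_rows(labelings)
    report$clustering <- dplyr::bind_rows(cluster_log)
    sets <- build_choice_sets(world$restaurants, labeling, assignments)
  }

  # --- review-based choices -------------------------------------------------
  if ("reviews" %in% sources) {
    events <- stream$reviews |>
      dplyr::mutate(event_id = .data$review_id)
    aug <- augment_events(events, sets, state, reviews = reviews_all,
                          source = "reviews")
    elig <- filter_events(aug, min_set_size = th$min_set_size,
                          min_unique_ratings = th$min_unique_ratings,
                          min_user_reviews = th$min_user_reviews,
                          source = "reviews")
    excl <- attr(elig, "exclusions")
    report$counts$reviews <- c(input = nrow(events),
                               no_set = attr(aug, "no_set"),
                               kept = nrow(elig), excluded = sum(excl))
    report$exclusions$reviews <- excl
    ct <- build_choice_table(elig, sets, state, world$restaurants)
    report$binned <- bin_target_rates(ct)
    report$fits$choice_context <- choice_context_model(ct, method = method,
                                                       seed = config$seed)
    dev_rows <- ct |> dplyr::filter(!is.na(.data$rating_deviation))
    report$fits$rating_deviation <- rating_deviation_model(
      dev_rows, method = method, seed = config$seed
    )
    dt <- build_distractor_table(ct)
    report$fits$distractor <- distractor_model(dt, method = method,
                                               seed = config$seed)
    report$distractor_retained_frac <- attr(dt, "retained_frac")
    report$choice_table <- ct
  }

  # --- check-ins (no user identity: pooled fits) ----------------------------
  if ("checkins" %in% sources) {
    checkins <- simulate_checkins(world)
    events <- checkins |>
      dplyr::mutate(event_id = sprintf("ck_%07d", dplyr::row_number()))
    aug <- augment_events(events, sets, state, source = "checkins")
    elig <- filter_events(aug, min_set_size = th$min_set_size,
                          min_unique_ratings = th$min_unique_ratings,
                          source = "checkins")
    excl <- attr(elig, "exclusions")
    report$counts$checkins <- c(input = nrow(events),
                                no_set = attr(aug, "no_set"),
                                kept = nrow(elig), excluded = sum(excl))
    report$exclusions$checkins <- excl
    ckt <- build_choice_table(elig, sets, state, world$restaurants)
    report$fits$checkin_context <- choice_context_model(
      ckt, group = NULL, method = "fast", seed = config$seed
    )
  }

  # --- orders (static ratings, (city, cuisine) sets) ------------------------
  if ("orders" %in% sources) {
    orders <- simulate_orders(world)
    ot <- build_order_table(orders)
    elig <- filter_events(ot, min_orders_set_size = th$min_orders_set_size,
                          source = "orders")
    excl <- attr(elig, "exclusions")
    report$counts$orders <- c(input = nrow(ot), kept = nrow(elig),
                              excluded = sum(excl))
    report$exclusions$orders <- excl
    report$fits$order_context <- choice_context_model(
      elig, group = NULL, method = "fast", seed = config$seed
    )
  }

  # --- laboratory-style experiment ------------------------------------------
  if ("experiment" %in% sources) {
    pool <- experiment_pool(world)
    trials <- suppressWarnings(
      simulate_experiment(pool, n_participants, config, heterogeneity)
    )
    catch <- catch_trial_exclusion(trials, pool)
    retained <- catch$participant_id[catch$retained]
    kept_trials <- trials |>
      dplyr::filter(.data$participant_id %in% retained)
    ect <- experiment_choice_table(kept_trials, pool)
    # MCMC engine: posterior conditional effects never collapse to zero
    # spread, which the concordance needs (and mirrors the original MCMC
    # mixed-effects analyses)
    fit_ch <- suppressWarnings(
      choice_context_model(ect, method = "mcmc", seed = config$seed)
    )
    et <- expectation_table(kept_trials, pool)
    fit_ex <- suppressWarnings(
      expectation_model(et, method = "mcmc", seed = config$seed)
    )
    conc <- concordance(
      subject_effects(fit_ch, "mean_set"),
      subject_effects(fit_ex, "mean_set_excl_highlighted"),
      seed = config$seed
    )
    report$counts$experiment <- c(
      input = nrow(trials),
      kept = nrow(kept_trials),
      excluded = nrow(trials) - nrow(kept_trials)
    )
    report$experiment <- list(catch = catch, concordance = conc)
    report$fits$experiment_choice <- fit_ch
    report$fits$experiment_expectation <- fit_ex
  }

  report$sign_battery <- sign_battery(report)
  class(report) <- "ctx_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# per-order decision rows from static displayed ratings
build_order_table <- function(orders) {
  rests <- orders |>
    dplyr::distinct(.data$city, .data$cuisine, .data$restaurant_id,
                    .data$stars, .data$n_ratings, .data$price)
  set_sizes <- rests |>
    dplyr::count(.data$city, .data$cuisine, name = "set_size")
  long <- orders |>
    dplyr::mutate(event_id = sprintf("or_%07d", dplyr::row_number()),
                  chosen = .data$restaurant_id) |>
    dplyr::select("event_id", "user_id", "city", "cuisine", "chosen") |>
    dplyr::inner_join(rests, by = c("city", "cuisine"),
                      relationship = "many-to-many") |>
    dplyr::mutate(member_id = .data$restaurant_id,
                  displayed = .data$stars, raw_mean = .data$stars,
                  n_rev = .data$n_ratings)
  tab <- aggregate_choice_rows(long)
  long |>
    dplyr::distinct(.data$event_id, .data$user_id, .data$city,
                    .data$cuisine, .data$chosen) |>
    dplyr::inner_join(tab, by = "event_id") |>
    dplyr::filter(!is.na(.data$chosen_row)) |>
    dplyr::select(-"chosen_row") |>
    dplyr::rename(chosen_id = "chosen") |>
    dplyr::left_join(set_sizes, by = c("city", "cuisine"))
}

# qualitative pattern of the five headline effects
sign_battery <- function(report) {
  grab <- function(fit, term) {
    if (is.null(fit)) return(NA_real_)
    s <- fit$summary
    s$estimate[match(term, s$term)]
  }
  rows <- tibble::tibble(
    effect = c("choice_context", "set_size", "distractor",
               "rating_deviation_context", "expectation_context",
               "concordance"),
    estimate = c(
      grab(report$fits$choice_context, "mean_set"),
      grab(report$fits$choice_context, "log(n_options)"),
      grab(report$fits$distractor, "distractor_mean"),
      grab(report$fits$rating_deviation, "mean_set_excl_chosen"),
      grab(report$fits$experiment_expectation, "mean_set_excl_highlighted"),
      if (is.null(report$experiment)) NA_real_ else
        report$experiment$concordance$slope
    ),
    expected_sign = c(-1, -1, -1, 1, -1, 1)
  )
  rows$sign_ok <- !is.na(rows$estimate) &
    sign(rows$estimate) == rows$expected_sign
  rows
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$choice_table)) {
    readr::write_tsv(report$choice_table,
                     file.path(out_dir, "choice_table.tsv"))
  }
  fits_json <- purrr::map(report$fits, function(f) {
    list(summary = f$summary, glance = glance(f))
  })
  jsonlite::write_json(
    list(
      seed = report$seed,
      counts = report$counts,
      exclusions = report$exclusions,
      clustering = report$clustering,
      binned_target_rates = report$binned,
      fits = fits_json,
      sign_battery = report$sign_battery
    ),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(out_dir)
}

#' @export
print.ctx_report <- function(x, ...) {
  cat("<ctx_report>\n")
  for (s in names(x$counts)) {
    cn <- x$counts[[s]]
    cat(sprintf("  %s: %d input, %d kept\n", s, cn[["input"]], cn[["kept"]]))
  }
  if (!is.null(x$sign_battery)) {
    cat("  sign battery:\n")
    sb <- x$sign_battery
    for (i in seq_len(nrow(sb))) {
      cat(sprintf("    %-26s %8s  [%s]\n", sb$effect[i],
                  ifelse(is.na(sb$estimate[i]), "n/a",
                         sprintf("%.4f", sb$estimate[i])),
                  ifelse(is.na(sb$estimate[i]), "-",
                         ifelse(isTRUE(sb$sign_ok[i]), "ok", "X"))))
    }
  }
  invisible(x)
}
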