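test_that("primary-category inference counts whole-word terms case-insensitively", {
  res <- infer_primary_category(
    c("Italian", "Pizza"),
    c("great pizza, will get pizza again", "best Pizza in town")
  )
  expect_equal(res$primary_term, "Pizza")
  expect_equal(res$term_counts, c(Italian = 0L, Pizza = 3L))

  res2 <- infer_primary_category(c("Bars", "Burgers"),
                                 c("bars and burgers", "burgers"))
  expect_equal(res2$term_counts, c(Bars = 1L, Burgers = 2L))
  expect_equal(res2$primary_term, "Burgers")

  # multi-word terms match as phrases, not word soup
  res3 <- infer_primary_category(
    c("Dim Sum", "Chinese"),
    c("amazing dim sum spot", "sum of all dim lights") # only one real phrase
  )
  expect_equal(unname(res3$term_counts["Dim Sum"]), 1L)

  # substring must not count: "Bar" inside "Barbecue"
  res4 <- infer_primary_category(c("Bar", "Barbecue"),
                                 c("best barbecue ever"))
  expect_equal(unname(res4$term_counts["Bar"]), 0L)
})

test_that("category inference edge cases: umbrella-only errors, empty text
           falls back with a warning, ties break by list position", {
  expect_error(infer_primary_category("Restaurants", "some text"),
               class = "contextchoice_no_category")
  expect_warning(
    res <- infer_primary_category(c("Thai"), character(0)),
    class = "contextchoice_category_fallback"
  )
  expect_equal(res$primary_term, "Thai")
  # tie at equal counts: earlier assigned term wins
  tie <- infer_primary_category(c("Sushi", "Ramen"), "sushi then ramen")
  expect_equal(tie$primary_term, "Sushi")
  tie2 <- infer_primary_category(c("Ramen", "Sushi"), "sushi then ramen")
  expect_equal(tie2$primary_term, "Ramen")
})

test_that("category inference recovers generator truth for salient text", {
  tw <- tiny_world()
  asg <- infer_categories(tw$world$restaurants, tw$reviews_all)
  truth <- tw$world$restaurants$true_primary_term[
    match(asg$business_id, tw$world$restaurants$business_id)
  ]
  expect_gte(mean(asg$primary_term == truth), 0.99)
})

test_that("dbscan matches hand-computable geometries", {
  # two tight triads far apart
  tri <- rbind(
    cbind(c(0, 0.05, 0.02), c(0, 0.02, 0.05)),
    cbind(c(1, 1.05, 1.02), c(1, 1.02, 1.05))
  )
  lab <- dbscan_cluster(tri, eps = 0.1, min_pts = 3)
  expect_equal(sort(unique(lab)), c(1L, 2L))
  expect_equal(as.integer(table(lab)), c(3L, 3L))
  expect_equal(lab[1:3], rep(lab[1], 3))

  # isolated point with min_pts 2 is noise
  lab2 <- dbscan_cluster(rbind(c(0, 0), c(5, 5), c(5.001, 5)), 0.1, 2)
  expect_equal(lab2[1], 0L)
  expect_equal(lab2[2], lab2[3])
  expect_gt(lab2[2], 0L)

  # n identical points, min_pts = n: one cluster
  same <- matrix(rep(c(2.5, 3.5), each = 7), ncol = 2)
  expect_equal(as.integer(dbscan_cluster(same, 1e-6, 7)), rep(1L, 7))

  expect_equal(length(dbscan_cluster(matrix(numeric(0), ncol = 2), 0.1, 3)), 0)
  expect_error(dbscan_cluster(tri, eps = 0, min_pts = 3))
})

test_that("dbscan equals the brute-force oracle on random instances", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(5:120, 1)
    # mixture of clumps and uniform scatter, with duplicated points
    k <- sample(1:4, 1)
    centers <- matrix(runif(2 * k, 0, 2), ncol = 2)
    pts <- centers[sample(k, n, replace = TRUE), , drop = FALSE] +
      matrix(rnorm(2 * n, 0, 0.08), ncol = 2)
    dup <- sample(n, size = floor(n / 4), replace = TRUE)
    pts <- rbind(pts, pts[dup, , drop = FALSE])
    eps <- runif(1, 0.03, 0.3)
    min_pts <- sample(2:6, 1)
    impl <- dbscan_cluster(pts, eps, min_pts)
    oracle <- dbscan_oracle(pts, eps, min_pts)
    expect_dbscan_equivalent(impl, oracle)
  }
})

test_that("parameter tuning follows the k-NN heuristic", {
  # uniform grid with spacing d: every 1-NN distance is d, so eps = d
  g <- expand.grid(x = seq(0, 0.9, by = 0.1), y = seq(0, 0.9, by = 0.1))
  tuned <- tune_dbscan_params(g, k = 1, target_min_pts_fraction = 0.01)
  expect_equal(tuned$eps, 0.1, tolerance = 1e-10)
  expect_equal(tuned$min_pts, 3L)  # max(3, round(0.01 * 100))

  tuned2 <- tune_dbscan_params(g, k = 1, target_min_pts_fraction = 0.2)
  expect_equal(tuned2$min_pts, 20L)

  # all-identical points: eps floor
  same <- matrix(rep(1, 20), ncol = 2)
  expect_equal(tune_dbscan_params(same, k = 2)$eps, 1e-6)
  expect_error(tune_dbscan_params(g[1:3, ], k = 4))
})

test_that("build_choice_sets partitions non-noise businesses by (cluster,
           category) with global uniqueness", {
  b <- tibble::tibble(business_id = sprintf("b%d", 1:6),
                      city = "cityA")
  lab <- tibble::tibble(business_id = b$business_id,
                        cluster = c(1L, 1L, 1L, 1L, 1L, 0L))
  asg <- tibble::tibble(business_id = b$business_id,
                        primary_term = c("Pizza", "Pizza", "Pizza",
                                         "Italian", "Italian", "Pizza"))
  sets <- build_choice_sets(b, lab, asg)
  expect_equal(dplyr::n_distinct(sets$set_id), 2)
  expect_equal(sort(as.integer(table(sets$set_id))), c(2L, 3L))
  expect_false("b6" %in% sets$business_id)          # noise excluded
  expect_false(any(duplicated(sets$business_id)))   # at most one set each
  # partition: members + noise = all businesses
  expect_setequal(c(sets$business_id, "b6"), b$business_id)

  expect_error(build_choice_sets(b[c(1, 1), ], lab, asg), "duplicate")
})

test_that("filter_events applies the eligibility thresholds and conserves
           counts", {
  ev <- tibble::tibble(
    event_id = sprintf("e%d", 1:6),
    user_n_reviews = c(100, 99, 150, 150, 150, 150),
    in_modal_city = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    n_options = c(3, 5, 5, 2, 4, 4),
    n_unique_ratings = c(3, 4, 4, 2, 1, 3)
  )
  kept <- filter_events(ev, source = "reviews")
  expect_equal(kept$event_id, c("e1", "e6"))
  excl <- attr(kept, "exclusions")
  expect_equal(sum(excl) + nrow(kept), nrow(ev))
  expect_equal(unname(excl["user_too_few_reviews"]), 1L)
  expect_equal(unname(excl["outside_modal_city"]), 1L)
  expect_equal(unname(excl["set_too_small"]), 1L)
  expect_equal(unname(excl["too_few_unique_ratings"]), 1L)

  # boundary semantics: >= 100 reviews kept, set of 2 dropped, 4 identical
  # displayed ratings dropped
  expect_true("e1" %in% kept$event_id)

  # orders: only the >= 5 members rule
  ov <- tibble::tibble(event_id = c("o1", "o2"), set_size = c(4, 5))
  kept_o <- filter_events(ov, source = "orders")
  expect_equal(kept_o$event_id, "o2")

  # check-ins: set rules only, no user columns needed
  cv <- tibble::tibble(event_id = c("c1", "c2"),
                       n_options = c(3, 3), n_unique_ratings = c(3, 2))
  expect_equal(filter_events(cv, source = "checkins")$event_id, "c1")
})

test_that("filter_events is monotone in its thresholds", {
  set.seed(3)
  ev <- tibble::tibble(
    event_id = sprintf("e%d", 1:300),
    user_n_reviews = sample(50:150, 300, TRUE),
    in_modal_city = sample(c(TRUE, FALSE), 300, TRUE, prob = c(0.8, 0.2)),
    n_options = sample(2:8, 300, TRUE),
    n_unique_ratings = sample(1:6, 300, TRUE)
  )
  base <- filter_events(ev, source = "reviews")
  for (relax in list(
    list(min_set_size = 2), list(min_unique_ratings = 2),
    list(min_user_reviews = 50)
  )) {
    args <- c(list(ev, source = "reviews"), relax)
    relaxed <- do.call(filter_events, args)
    expect_true(all(base$event_id %in% relaxed$event_id))
  }
})
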