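# simulate grouped data from the hierarchical model itself
sim_hier <- function(n_users, n_per, beta, re_sd, sigma = 1,
                     family = "gaussian", seed = 1) {
  set.seed(seed)
  u <- rep(seq_len(n_users), each = n_per)
  x <- rnorm(n_users * n_per)
  slope_u <- beta + rnorm(n_users, 0, re_sd)
  eta <- 0.3 + slope_u[u] * x
  y <- if (family == "gaussian") rnorm(length(eta), eta, sigma) else
    rbinom(length(eta), 1, plogis(eta))
  tibble::tibble(user_id = sprintf("u%03d", u), x = x, y = y)
}

test_that("fit_mixed recovers a known fixed effect with calibrated intervals", {
  hits <- 0L
  null_hits <- 0L
  for (r in 1:10) {
    d <- sim_hier(50, 40, beta = -0.5, re_sd = 0.3, seed = r)
    d$z <- rnorm(nrow(d)) # pure noise predictor
    fit <- fit_mixed(d, "y", c("x", "z"), family = "gaussian",
                     group = "user_id", method = "mixed")
    td <- tidy(fit)
    cx <- td[td$term == "x", ]
    cz <- td[td$term == "z", ]
    if (cx$conf.low <= -0.5 && cx$conf.high >= -0.5) hits <- hits + 1L
    if (cz$conf.low <= 0 && cz$conf.high >= 0) null_hits <- null_hits + 1L
  }
  expect_gte(hits, 8L)       # nominal 95% coverage, 10 replicates
  expect_gte(null_hits, 8L)
})

test_that("degenerate inputs fail loudly", {
  d <- sim_hier(10, 10, -0.5, 0.2)
  d$y <- 1
  expect_error(fit_mixed(d, "y", "x", group = "user_id"), "zero variance")
  d2 <- sim_hier(10, 10, -0.5, 0.2)
  d2$c1 <- 5
  expect_error(fit_mixed(d2, "y", c("x", "c1"), group = "user_id"),
               "zero-variance predictor")
  expect_error(fit_mixed(d2, "y", "log(x)", group = "user_id"),
               "non-finite")
  expect_error(fit_mixed(d2, "nope", "x"), "not found")
})

test_that("separation in a logistic fast fit warns and returns a regularized
           estimate", {
  d <- tibble::tibble(user_id = rep(c("a", "b"), each = 20),
                      x = c(rnorm(20, -2), rnorm(20, 2)))
  d$y <- as.integer(d$x > 0)
  expect_warning(
    fit <- fit_mixed(d, "y", "x", family = "binomial", group = "user_id",
                     method = "fast"),
    class = "contextchoice_separation_warning"
  )
  est <- tidy(fit)
  expect_true(all(is.finite(est$estimate)))
  expect_true(all(is.finite(est$std.error)))
})

test_that("subject effects shrink toward the fixed effect", {
  d <- sim_hier(40, 25, beta = 1, re_sd = 0.25, sigma = 1.5, seed = 5)
  fit <- fit_mixed(d, "y", "x", group = "user_id", method = "mixed")
  se <- subject_effects(fit, "x")
  expect_equal(nrow(se), 40)
  ml_var <- d |>
    dplyr::reframe(b = coef(lm(y ~ x))[["x"]], .by = "user_id")
  expect_lt(var(se$effect), var(ml_var$b))
  expect_error(subject_effects(fit, "w"), "not in fit")
  fitf <- fit_mixed(d, "y", "x", group = "user_id", method = "fast")
  expect_error(subject_effects(fitf, "x"), "no per-user effects")
})

test_that("fast, mixed and MCMC engines agree on well-conditioned fits", {
  d <- sim_hier(30, 30, beta = -0.6, re_sd = 0.2, seed = 11)
  est <- function(f) tidy(f)$estimate[tidy(f)$term == "x"]
  f_fast <- fit_mixed(d, "y", "x", group = "user_id", method = "fast")
  f_mix <- fit_mixed(d, "y", "x", group = "user_id", method = "mixed")
  f_mc <- suppressWarnings(
    fit_mixed(d, "y", "x", group = "user_id", method = "mcmc", seed = 2,
              mcmc_control = list(n_iter = 800, n_warmup = 300))
  )
  e <- c(est(f_fast), est(f_mix), est(f_mc))
  expect_true(all(sign(e) == -1))
  expect_lt(max(abs(e - e[1])) / abs(e[1]), 0.15)
  # binomial: sign agreement
  db <- sim_hier(30, 40, beta = -0.8, re_sd = 0.2, family = "binomial",
                 seed = 12)
  eb <- c(
    est(fit_mixed(db, "y", "x", family = "binomial", group = "user_id",
                  method = "fast")),
    est(fit_mixed(db, "y", "x", family = "binomial", group = "user_id",
                  method = "mixed")),
    est(suppressWarnings(
      fit_mixed(db, "y", "x", family = "binomial", group = "user_id",
                method = "mcmc", seed = 2,
                mcmc_control = list(n_iter = 800, n_warmup = 300))
    ))
  )
  expect_true(all(sign(eb) == -1))
})

test_that("the MCMC engine produces usable diagnostics and tail probabilities", {
  d <- sim_hier(25, 25, beta = 0.8, re_sd = 0.2, seed = 21)
  fit <- suppressWarnings(
    fit_mixed(d, "y", "x", group = "user_id", method = "mcmc", seed = 3)
  )
  td <- tidy(fit)
  expect_true(all(c("rhat", "ess") %in% names(td)))
  expect_true(all(td$rhat < 1.1, na.rm = TRUE))
  expect_true(all(td$p.value > 0 & td$p.value <= 1))
  # strong effect: small tail probability, CI excludes 0
  cx <- td[td$term == "x", ]
  expect_lt(cx$p.value, 0.05)
  expect_gt(cx$conf.low, 0)
})

test_that("log transforms are applied as specified (counts log, lengths
           log1p)", {
  set.seed(4)
  d <- tibble::tibble(
    user_id = rep(sprintf("u%d", 1:20), each = 15),
    n = sample(1:50, 300, TRUE),
    len = sample(0:100, 300, TRUE)
  )
  d$y <- 1 - 0.7 * log(d$n) + 0.3 * log1p(d$len) + rnorm(300, 0, 0.5)
  fit <- fit_mixed(d, "y", c("log(n)", "log1p(len)"), group = "user_id",
                   method = "fast")
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "log(n)"], -0.7, tolerance = 0.1)
  expect_equal(td$estimate[td$term == "log1p(len)"], 0.3, tolerance = 0.15)
})

test_that("concordance recovers a planted relation between subject effects", {
  set.seed(13)
  n <- 100
  ce <- rnorm(n, -0.5, 0.3)
  re <- -2 + 3 * ce + rnorm(n, 0, 0.5)   # true slope 3
  choice <- tibble::tibble(.group = sprintf("p%d", 1:n), effect = ce)
  rating <- tibble::tibble(.group = sprintf("p%d", 1:n), effect = re)
  conc <- concordance(choice, rating, n_boot = 500, seed = 1)
  expect_gt(conc$slope, 0)
  expect_lt(conc$p.value, 0.05)
  expect_equal(conc$slope, 3, tolerance = 0.25)
  # median split: strong (more negative) choice group has lower rating effects
  ms <- conc$median_split
  expect_lt(ms$mean_rating_effect[ms$group == "strong"],
            ms$mean_rating_effect[ms$group == "weak"])

  # independent effects: slope near zero, not significant
  re0 <- rnorm(n, -2, 1)
  conc0 <- concordance(choice,
                       tibble::tibble(.group = choice$.group, effect = re0),
                       n_boot = 500, seed = 1)
  expect_gt(conc0$p.value, 0.05)
})

test_that("the robust slope resists planted gross outliers where OLS does not", {
  set.seed(14)
  n <- 100
  ce <- rnorm(n, 0, 0.4)
  re <- 2 * ce + rnorm(n, 0, 0.3)
  clean <- contextchoice:::huber_slope(ce, re)$slope
  re_out <- re
  out_idx <- 1:10
  re_out[out_idx] <- re_out[out_idx] + 15   # 10% gross outliers
  robust <- contextchoice:::huber_slope(ce, re_out)$slope
  ols <- coef(lm(re_out ~ ce))[2]
  expect_lt(abs(robust - clean) / abs(clean), 0.2)
  expect_gt(abs(ols - clean) / abs(clean), 0.2)
})

test_that("catch-trial exclusion applies the 60% rule exactly", {
  pool <- tibble::tibble(
    snapshot_id = rep(c("s1", "s2"), each = 3),
    business_id = c("a", "b", "c", "d", "e", "f"),
    displayed_rating = c(5, 4, 3, 4.5, 4.5, 2),
    n_reviews = 10, price = 2
  )
  mk <- function(pid, answers) {
    tibble::tibble(
      participant_id = pid, trial_id = seq_along(answers),
      trial_type = "catch",
      snapshot_id = rep(c("s1", "s2"), length.out = length(answers)),
      highlighted_id = NA_character_,
      response_choice = answers, response_satisfaction = NA_real_
    )
  }
  # p1: 3/5 correct (a, d or e are correct answers); p2: 2/5 correct
  trials <- dplyr::bind_rows(
    mk("p1", c("a", "d", "a", "b", "f")),
    mk("p2", c("a", "e", "c", "b", "f"))
  )
  res <- catch_trial_exclusion(trials, pool)
  expect_true(res$retained[res$participant_id == "p1"])
  expect_false(res$retained[res$participant_id == "p2"])
  # tied maxima: either tied option counts as correct
  expect_equal(res$accuracy[res$participant_id == "p1"], 3 / 5)

  other <- tibble::tibble(participant_id = "p3", trial_id = 1L,
                          trial_type = "choice", snapshot_id = "s1",
                          highlighted_id = NA, response_choice = "a",
                          response_satisfaction = NA)
  expect_error(catch_trial_exclusion(dplyr::bind_rows(trials, other), pool),
               "without catch trials")
})
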