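#' Concordance between choice and rating context effects
#'
#' Relates each participant's context effect in choice (their conditional
#' coefficient for the set-mean term in the choice model) to their context
#' effect in expectation ratings. Reports (1) a median split of the choice
#' effects with per-group mean rating effects — participants with stronger
#' (more negative) choice context effects should show stronger rating
#' context effects — and (2) a Huber-loss IRLS robust regression of rating
#' effects on choice effects, with a case-resampling bootstrap p-value for
#' the slope.
#'
#' @param choice_effects Tibble from [subject_effects()] on the choice
#'   model (`.group`, `effect`).
#' @param rating_effects Tibble from [subject_effects()] on the
#'   expectation/rating model; matched by `.group`.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap.
#' @return A `ctx_concordance` list: `median_split` (tibble of group, n,
#'   mean rating effect), `slope`, `intercept`, `p.value`, `n`,
#'   `boot_slopes`.
#' @export
concordance <- function(choice_effects, rating_effects, n_boot = 1000,
                        seed = 1L) {
  d <- dplyr::inner_join(
    choice_effects |> dplyr::rename(choice_effect = "effect"),
    rating_effects |> dplyr::rename(rating_effect = "effect"),
    by = ".group"
  )
  if (nrow(d) < 4) stopf("need at least 4 matched participants.")

  med <- median(d$choice_effect)
  median_split <- d |>
    dplyr::mutate(
      group = ifelse(.data$choice_effect <= med, "strong", "weak")
    ) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_rating_effect = mean(.data$rating_effect),
      .by = "group"
    ) |>
    dplyr::arrange(.data$group)

  if (sd(d$choice_effect) == 0 || sd(d$rating_effect) == 0) {
    rlang::warn("degenerate subject effects (zero spread); concordance undefined")
    return(structure(
      list(median_split = median_split, slope = NA_real_,
           intercept = NA_real_, p.value = NA_real_, n = nrow(d),
           boot_slopes = numeric(0)),
      class = "ctx_concordance"
    ))
  }
  fit <- huber_slope(d$choice_effect, d$rating_effect)
  boot <- with_seed(derive_seed(seed, 7L), {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(d), replace = TRUE)
      tryCatch(
        huber_slope(d$choice_effect[idx], d$rating_effect[idx])$slope,
        error = function(e) NA_real_
      )
    }, numeric(1))
  })
  boot <- boot[is.finite(boot)]
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  p <- max(p, 1 / (length(boot) + 1))

  structure(
    list(median_split = median_split, slope = fit$slope,
         intercept = fit$intercept, p.value = p, n = nrow(d),
         boot_slopes = boot),
    class = "ctx_concordance"
  )
}

# Huber-loss M-estimate of a simple regression (IRLS via MASS::rlm)
huber_slope <- function(x, y) {
  if (sd(x) == 0) stopf("degenerate predictor in robust regression.")
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.huber, maxit = 100)
  co <- coef(fit)
  list(intercept = unname(co[1]), slope = unname(co[2]))
}

#' @export
print.ctx_concordance <- function(x, ...) {
  cat("<ctx_concordance>\n")
  cat(sprintf("  robust slope %.4f (bootstrap p = %.4g, n = %d)\n",
              x$slope, x$p.value, x$n))
  ms <- x$median_split
  for (i in seq_len(nrow(ms))) {
    cat(sprintf("  %s-context group: n = %d, mean rating effect %.4f\n",
                ms$group[i], ms$n[i], ms$mean_rating_effect[i]))
  }
  invisible(x)
}
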