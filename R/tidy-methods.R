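#' Tidy a fitted context-effect regression
#'
#' @param x A `ctx_fit`.
#' @param ... Unused.
#' @return One row per term: `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `p.value` (two-sided Wald p, or `2 * min` posterior tail
#'   probability for MCMC fits, where `rhat`/`ess` columns are added).
#' @exportS3Method generics::tidy
tidy.ctx_fit <- function(x, ...) {
  x$summary
}

#' One-row fit summary
#'
#' @param x A `ctx_fit`.
#' @param ... Unused.
#' @return Tibble with `method`, `engine`, `family`, `response`, `n_obs`,
#'   `n_groups`, `converged`.
#' @export
glance.ctx_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    engine = x$engine,
    family = x$family,
    response = x$response,
    n_obs = x$n_obs,
    n_groups = x$n_groups,
    converged = x$converged
  )
}

#' @export
print.ctx_fit <- function(x, ...) {
  cat(sprintf("<ctx_fit: %s %s of `%s` (%d obs%s)%s>\n",
              x$method, x$family, x$response, x$n_obs,
              if (is.na(x$n_groups)) "" else
                sprintf(", %d groups", x$n_groups),
              if (isTRUE(x$converged)) "" else " [not converged]"))
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}

#' Coefficient plot for a fitted model
#'
#' Forest-style plot of estimates and 95% intervals, intercept omitted.
#'
#' @param object A `ctx_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ctx_fit <- function(object, ...) {
  d <- object$summary |> dplyr::filter(.data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high)
    ) +
    ggplot2::labs(x = "estimate (95% interval)", y = NULL) +
    ggplot2::theme_minimal()
}
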