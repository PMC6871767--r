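# broom-style tidiers and ggplot2 autoplot methods

#' Tidy a relapse model
#'
#' Returns the model parameters as a long `term`/`estimate` tibble, with
#' units.
#'
#' @param x A [relapse_model()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `unit`.
#' @export
tidy.relapse_model <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("delta", "lambda", "alpha", "beta", "q", "nu", "M", "N",
             "t_resect"),
    estimate = c(p$delta, p$lambda, p$alpha, p$beta, p$q, p$nu, p$M,
                 if (is.null(p$N)) NA_real_ else p$N, x$growth$t_resect),
    unit = c("1/day", "1/day", "1/day", "1/day", "", "1/cell/day", "cells",
             "cells", "day")
  )
}

#' Summarize a relapse model at its resection time
#'
#' One-row overview: resection time and size, probabilities of seeded /
#' synchronous / occult-only metastases, cure probability, and the expected
#' relapse time after resection conditioned on occult disease (only
#' computed for a finite resection).
#'
#' @param x A [relapse_model()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.relapse_model <- function(x, ...) {
  Tr <- x$growth$t_resect
  finite <- is.finite(Tr)
  tibble::tibble(
    cancer_type = x$cancer_type,
    resection_days = Tr,
    resection_cells = if (finite) x$params$N %||% NA_real_ else NA_real_,
    p_seeded = if (finite) prob_seeded(x) else 1,
    p_synchronous = if (finite) prob_synchronous(x) else NA_real_,
    p_undetectable_only = if (finite) prob_undetectable_only(x) else NA_real_,
    cure_prob = if (finite) cure_probability(x) else 0,
    e_relapse_after_resection_days =
      if (finite) expected_relapse_after_resection(x) else NA_real_
  )
}

#' Tidy a simulation
#'
#' @param x A `relapse_sim` from [simulate_relapse()].
#' @param ... Unused.
#' @return The per-replicate tibble.
#' @export
tidy.relapse_sim <- function(x, ...) x$replicates

#' Summarize a simulation against the analytic distribution
#'
#' @param x A `relapse_sim` from [simulate_relapse()].
#' @param ... Unused.
#' @return One-row tibble: replicate count, relapse fraction, mean and
#'   median relapse day among relapsing replicates, analytic relapse mass,
#'   and the KS distance to the analytic CDF.
#' @export
glance.relapse_sim <- function(x, ...) {
  rd <- x$replicates$relapse_day
  Tr <- x$model$growth$t_resect
  tibble::tibble(
    n_reps = nrow(x$replicates),
    relapse_fraction = mean(!is.na(rd)),
    mean_relapse_day = mean(rd, na.rm = TRUE),
    median_relapse_day = stats::median(rd, na.rm = TRUE),
    analytic_relapse_mass =
      if (is.finite(Tr)) prob_seeded(x$model) else 1,
    ks_distance = sim_ks_distance(x)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a relapse model
#'
#' Relapse-time CDF and numerically differentiated density on a time grid
#' spanning the bulk of the distribution.
#'
#' @param object A [relapse_model()].
#' @param times Optional time grid (days).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.relapse_model <- function(object, times = NULL, ...) {
  if (is.null(times)) {
    mu <- mean_relapse_time(object)$mean_days
    sd <- pi / (sqrt(6) * object$params$delta)
    times <- seq(max(0, mu - 6 * sd), mu + 4 * sd, length.out = 400)
  }
  df <- tibble::tibble(
    time_years = days_to_years(times),
    cdf = relapse_cdf(object, times),
    density = numeric_density(function(t) relapse_cdf(object, t), times)
  )
  df <- tidyr::pivot_longer(df, c("cdf", "density"), names_to = "panel")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_years, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time since primary onset (years)", y = NULL,
                  title = "Relapse-time distribution")
}

#' Plot a simulation against the analytic CDF
#'
#' @param object A `relapse_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.relapse_sim <- function(object, ...) {
  rd <- sort(object$replicates$relapse_day[!is.na(object$replicates$relapse_day)])
  n <- nrow(object$replicates)
  df <- tibble::tibble(time_years = days_to_years(rd),
                       empirical = seq_along(rd) / n,
                       analytic = relapse_cdf(object$model, rd))
  df <- tidyr::pivot_longer(df, c("empirical", "analytic"),
                            names_to = "curve", values_to = "cdf")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_years, .data$cdf,
                                   linetype = .data$curve)) +
    ggplot2::geom_step(data = ~dplyr::filter(.x, .data$curve == "empirical")) +
    ggplot2::geom_line(data = ~dplyr::filter(.x, .data$curve == "analytic")) +
    ggplot2::labs(x = "relapse time (years)", y = "CDF",
                  title = "Simulated vs analytic relapse-time CDF")
}

#' Plot classification curves
#'
#' Probabilities of extant and synchronous metastases as functions of the
#' resection time, with the occult-only band between them.
#'
#' @param model A [relapse_model()].
#' @param threshold Optional high-risk threshold drawn as a reference line.
#' @param ... Passed to [classification_curves()].
#' @return A ggplot object.
#' @export
plot_classification_curves <- function(model, threshold = 0.85, ...) {
  df <- classification_curves(model, ...)
  long <- tidyr::pivot_longer(df, c("p_seeded", "p_synchronous"),
                              names_to = "curve", values_to = "prob")
  ggplot2::ggplot(long, ggplot2::aes(days_to_years(.data$time_days),
                                     .data$prob, linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, colour = "grey60") +
    ggplot2::labs(x = "resection time (years)", y = "probability",
                  title = "Extant vs synchronous metastases at resection")
}
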