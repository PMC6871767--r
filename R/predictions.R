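# -------------------------------------------------------------------------
# Headline clinical outputs: threshold resection sizes, high-risk windows,
# prediction tables, cure-probability inverses and surgery-delay grids.
# All root-finding is bracketed bisection/Brent (uniroot) on monotone
# functions; the P(U_T) maximum is located from a coarse log-size grid
# before local refinement, since the bump occupies a small part of the
# admissible resection-time axis.
# -------------------------------------------------------------------------

# bracket helper: times at which the (unresected) primary spans a size range
.time_grid_for_sizes <- function(growth, from = 1e2, to = 1e13, n = 300) {
  to <- min(to, if (is.finite(growth$K)) growth$K * 0.999999 else Inf)
  sizes <- 10^seq(log10(from), log10(to), length.out = n)
  g_open <- growth
  g_open$t_resect <- Inf
  resection_time_for_size(g_open, sizes)
}

#' Resection size at a given synchronous-metastasis probability
#'
#' Solves \eqn{P(S_T \ge 1) = 1 - e^{-b_T} = p} for the resection time `T`
#' by monotone root-finding, and reports the corresponding primary size
#' \eqn{n(T)} and diameter.
#'
#' @inheritParams prob_synchronous
#' @param p Target probability (vector allowed), strictly inside (0, 1).
#' @return Tibble with columns `probability`, `time_days`, `cells`,
#'   `diameter_cm`.
#' @export
#' @examples
#' threshold_resection_size(relapse_model("colorectal"), c(0.01, 0.99))
threshold_resection_size <- function(model, p) {
  stopifnot(inherits(model, "relapse_model"), all(p > 0), all(p < 1))
  g_open <- model$growth
  g_open$t_resect <- Inf
  grid <- .time_grid_for_sizes(model$growth, 1, 1e15, n = 2)
  f <- function(Tr, target) {
    expected_detectable(model, Tr, t_resect = Tr) + log1p(-target)
  }
  res <- purrr::map_dfr(p, function(pp) {
    if (f(grid[2], pp) < 0)
      stop("probability ", pp, " is not attainable within the size bracket",
           call. = FALSE)
    Tr <- uniroot(f, interval = grid, target = pp, tol = 1e-8)$root
    tibble::tibble(probability = pp, time_days = Tr,
                   cells = tumor_size(g_open, Tr))
  })
  dplyr::mutate(res, diameter_cm = diameter_from_size(.data$cells))
}

#' Resection time for a target cure probability
#'
#' Inverts \eqn{P(K_T = 0) = e^{-a_T} = p} for the latest resection time
#' still achieving cure probability `p`.
#'
#' @inheritParams prob_synchronous
#' @param p Target cure probability (vector allowed), in (0, 1].
#' @return Tibble with `cure_prob`, `time_days`, `time_years`, `cells`,
#'   `diameter_cm`.
#' @export
#' @examples
#' resection_time_for_cure_prob(relapse_model("colorectal"),
#'                              c(0.75, 0.6, 0.45, 0.3, 0.15, 0.001))
resection_time_for_cure_prob <- function(model, p) {
  stopifnot(inherits(model, "relapse_model"), all(p > 0), all(p <= 1))
  p_ <- model$params
  g_open <- model$growth
  g_open$t_resect <- Inf
  target_mass <- -log(p) / (p_$nu * (1 - p_$q))  # tumor_mass(T) = this
  Tr <- if (model$growth$kind == "exponential") {
    r <- .g_rate(g_open)
    log1p(r * target_mass) / r
  } else {
    vapply(target_mass, function(m) {
      if (m == 0) return(0)
      uniroot(function(t) tumor_mass(g_open, t) - m,
              interval = c(0, .time_grid_for_sizes(g_open, to = 1e15, n = 2)[2]),
              tol = 1e-10)$root
    }, numeric(1))
  }
  tibble::tibble(cure_prob = p, time_days = Tr,
                 time_years = days_to_years(Tr),
                 cells = tumor_size(g_open, Tr),
                 diameter_cm = diameter_from_size(tumor_size(g_open, Tr)))
}

#' High-risk resection window
#'
#' The interval of resection times over which the probability of
#' established but all-undetectable metastases exceeds `threshold`
#' (default 85%): \eqn{\{T : P(U_T) > 0.85\}}. \eqn{P(U_T)} is unimodal in
#' `T` for realistic parameters; its peak is located on a coarse grid and
#' refined, then the two crossings are found by bracketed root-finding. If
#' the threshold is never attained an empty window (zero width, `NA`
#' endpoints) is returned rather than an error.
#'
#' @inheritParams prob_synchronous
#' @param threshold Probability threshold defining the window.
#' @return One-row tibble: `t_lo`, `t_hi` (days), `width_days`,
#'   `width_years`, `size_lo`, `size_hi` (cells), `peak_time`, `peak_prob`.
#' @export
#' @examples
#' high_risk_window(relapse_model("breast"))
high_risk_window <- function(model, threshold = 0.85) {
  stopifnot(inherits(model, "relapse_model"),
            threshold > 0, threshold < 1)
  PU <- function(Tr) prob_undetectable_only(model, t_resect = Tr)
  grid <- .time_grid_for_sizes(model$growth)
  vals <- vapply(grid, PU, numeric(1))
  k <- which.max(vals)
  lo_idx <- max(k - 1, 1)
  hi_idx <- min(k + 1, length(grid))
  opt <- optimize(function(Tr) -PU(Tr), interval = grid[c(lo_idx, hi_idx)],
                  tol = 1e-7)
  peak_t <- opt$minimum
  peak_p <- -opt$objective
  if (peak_p <= threshold) {
    return(tibble::tibble(t_lo = NA_real_, t_hi = NA_real_, width_days = 0,
                          width_years = 0, size_lo = NA_real_,
                          size_hi = NA_real_, peak_time = peak_t,
                          peak_prob = peak_p))
  }
  g_open <- model$growth
  g_open$t_resect <- Inf
  t_lo <- uniroot(function(Tr) PU(Tr) - threshold,
                  interval = c(grid[1], peak_t), tol = 1e-8)$root
  t_hi <- uniroot(function(Tr) PU(Tr) - threshold,
                  interval = c(peak_t, grid[length(grid)]), tol = 1e-8)$root
  tibble::tibble(t_lo = t_lo, t_hi = t_hi, width_days = t_hi - t_lo,
                 width_years = days_to_years(t_hi - t_lo),
                 size_lo = tumor_size(g_open, t_lo),
                 size_hi = tumor_size(g_open, t_hi),
                 peak_time = peak_t, peak_prob = peak_p)
}

#' Fraction of resections falling in the high-risk window
#'
#' Combines the normal resection-diameter model of
#' [diameter_distribution()] with [high_risk_window()]: the probability that
#' a resection diameter drawn from the clinical distribution corresponds to
#' a resection time inside the high-risk window. Since diameter and
#' resection time are monotonically linked, this is the normal mass between
#' the window's two boundary diameters.
#'
#' @inheritParams prob_synchronous
#' @param data One row of clinical inputs (columns `d_lo`, `d_hi`), e.g. a
#'   row of [clinical_inputs()].
#' @param threshold Probability threshold defining the window.
#' @return The probability (scalar).
#' @export
#' @examples
#' inp <- dplyr::filter(clinical_inputs(), cancer_type == "prostate")
#' high_risk_fraction(relapse_model("prostate"), inp)
high_risk_fraction <- function(model, data, threshold = 0.85) {
  stopifnot(nrow(data) == 1)
  dd <- diameter_distribution(data)
  win <- high_risk_window(model, threshold)
  if (win$width_days == 0) return(0)
  pnorm(diameter_from_size(win$size_hi), dd$d_mean, dd$d_sd) -
    pnorm(diameter_from_size(win$size_lo), dd$d_mean, dd$d_sd)
}

#' Classification curves over resection times
#'
#' Evaluates, on a grid of resection times, the probabilities of extant
#' metastases \eqn{P(K_T \ge 1)}, synchronous metastases
#' \eqn{P(S_T \ge 1)}, occult-only disease \eqn{P(U_T)} and cure
#' \eqn{P(K_T = 0)} — the curves from which the high-risk window is read
#' off.
#'
#' @inheritParams prob_synchronous
#' @param times Resection times (days); default a log-size grid from 100 to
#'   10^13 cells.
#' @return Tibble with columns `time_days`, `cells`, `p_seeded`,
#'   `p_synchronous`, `p_undetectable_only`, `cure_prob`.
#' @export
classification_curves <- function(model, times = NULL) {
  stopifnot(inherits(model, "relapse_model"))
  if (is.null(times)) times <- .time_grid_for_sizes(model$growth, n = 200)
  g_open <- model$growth
  g_open$t_resect <- Inf
  ps <- vapply(times, function(Tr) prob_seeded(model, Tr), numeric(1))
  py <- vapply(times, function(Tr) prob_synchronous(model, Tr), numeric(1))
  tibble::tibble(time_days = times, cells = tumor_size(g_open, times),
                 p_seeded = ps, p_synchronous = py,
                 p_undetectable_only = ps - py, cure_prob = 1 - ps)
}

#' Five-cancer prediction table
#'
#' Builds the headline prediction table across cancer types: probability of
#' synchronous metastases and expected relapse time after resection
#' conditioned on occult disease, both at the estimated resection size,
#' together with seeding/occult probabilities, the high-risk window width
#' and the fraction of resections falling in it.
#'
#' @param data Clinical input rows, default [clinical_inputs()].
#' @param dissemination_size Primary size (cells) at expected first seeding
#'   passed to the estimation chain.
#' @param threshold High-risk window threshold.
#' @return Tibble, one row per cancer type, with columns `cancer_type`,
#'   `resection_years`, `p_synchronous_pct`, `e_relapse_days`,
#'   `p_seeded_pct`, `p_undetectable_pct`, `window_years`,
#'   `high_risk_fraction_pct`, `lambda_over_delta`.
#' @export
#' @examples
#' \donttest{prediction_table()}
prediction_table <- function(data = clinical_inputs(),
                             dissemination_size = 1e8, threshold = 0.85) {
  purrr::map_dfr(seq_len(nrow(data)), function(i) {
    row <- data[i, ]
    model <- relapse_model(estimate_parameters(
      row, dissemination_size = dissemination_size))
    win <- high_risk_window(model, threshold)
    frac <- if (all(c("d_lo", "d_hi") %in% names(row)))
      high_risk_fraction(model, row, threshold) else NA_real_
    tibble::tibble(
      cancer_type = row$cancer_type,
      resection_years = days_to_years(model$growth$t_resect),
      p_synchronous_pct = 100 * prob_synchronous(model),
      e_relapse_days = expected_relapse_after_resection(model),
      p_seeded_pct = 100 * prob_seeded(model),
      p_undetectable_pct = 100 * prob_undetectable_only(model),
      window_years = win$width_years,
      high_risk_fraction_pct = 100 * frac,
      lambda_over_delta = model$params$lambda / model$params$delta
    )
  })
}

#' Surgery-delay risk grid
#'
#' Evaluates [surgery_delay_risk()] over a grid of planned resection sizes
#' and delays, the decrease in cure probability attributable to postponing
#' surgery.
#'
#' @inheritParams prob_synchronous
#' @param sizes Planned resection sizes in cells.
#' @param delays Surgery delays in days.
#' @return Tibble in long format: `cells`, `time_days`, `delay_days`,
#'   `risk`.
#' @export
#' @examples
#' delay_grid(relapse_model("colorectal"),
#'            sizes = 10^seq(7, 10, 0.5), delays = c(30, 60, 90))
delay_grid <- function(model, sizes = 10^seq(6, 11, length.out = 60),
                       delays = seq(0, 90, by = 15)) {
  stopifnot(inherits(model, "relapse_model"), all(sizes >= 1),
            all(delays >= 0))
  g_open <- model$growth
  g_open$t_resect <- Inf
  times <- resection_time_for_size(g_open, sizes)
  out <- tidyr::expand_grid(
    tibble::tibble(cells = sizes, time_days = times),
    delay_days = delays
  )
  dplyr::mutate(out, risk = surgery_delay_risk(model, .data$time_days,
                                               .data$delay_days))
}
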