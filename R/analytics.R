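# -------------------------------------------------------------------------
# Seeding intensities a_t, b_t, c_t and the relapse-time distributions.
#
# a_t = nu (1-q) \int_0^{min(t,T)} n(s) ds   expected surviving metastases
# b_t = nu (1-q) \int_0^{min(t,T)} n(s) G(t-s) ds   expected detectable-by-t
# G(t) = exp(-(1-q) M e^{-lambda t})   asymptotic hitting-time CDF (Gumbel-max)
#
# For exponential primary growth b_t has a closed form in terms of lower
# incomplete gamma functions, obtained by the substitution
# x = (1-q) M e^{-lambda (t-s)}:
#   b_t = nu (1-q) e^{dt} [ g(d/l, x1) - g(d/l, x0) ] / ( l ((1-q)M)^{d/l} )
# with x0 = (1-q) M e^{-lambda t}, x1 = (1-q) M e^{-lambda (t - min(t,T))}.
# The difference is evaluated in log space, switching to upper-tail
# differences when both arguments are large, since the naive lower-gamma
# difference cancels catastrophically for small t.
# -------------------------------------------------------------------------

.resolve_T <- function(model, t_resect) {
  if (is.null(t_resect)) model$growth$t_resect else t_resect
}

#' Expected metastasis counts
#'
#' `expected_seeded()` returns \eqn{a_t}, the expected number of surviving
#' metastases initiated by time `t`; `expected_detectable()` returns
#' \eqn{b_t}, the expected number that have also reached the detectable size
#' `M` by `t`; `expected_occult()` returns \eqn{c_t = a_t - b_t}, those
#' seeded but still below `M`. All respect the growth model's resection
#' cut-off (seeding stops at resection; growth of existing metastases does
#' not).
#'
#' @param model A [relapse_model()].
#' @param t Times in days (vector).
#' @param t_resect Optional resection-time override in days (default: the
#'   growth model's own cut-off).
#' @return Numeric vector of expected counts.
#' @export
#' @examples
#' m <- relapse_model("colorectal")
#' expected_seeded(m, c(1000, 4000, 6000))
expected_seeded <- function(model, t, t_resect = NULL) {
  stopifnot(inherits(model, "relapse_model"))
  p <- model$params
  p$nu * (1 - p$q) * tumor_mass(model$growth, t,
                                t_resect = .resolve_T(model, t_resect))
}

#' @rdname expected_seeded
#' @export
expected_detectable <- function(model, t, t_resect = NULL) {
  stopifnot(inherits(model, "relapse_model"), is.numeric(t))
  if (any(t < 0)) stop("times must be non-negative", call. = FALSE)
  Tr <- .resolve_T(model, t_resect)
  if (model$growth$kind == "exponential") {
    .b_exponential(model$params, model$growth, t, Tr)
  } else {
    .b_quadrature(model$params, model$growth, t, Tr, model$quadrature_tol)
  }
}

#' @rdname expected_seeded
#' @export
expected_occult <- function(model, t, t_resect = NULL) {
  expected_seeded(model, t, t_resect) - expected_detectable(model, t, t_resect)
}

.b_exponential <- function(p, growth, t, Tr) {
  d <- growth$gamma * growth$delta
  a <- d / p$lambda
  qM <- (1 - p$q) * p$M
  u <- pmin(t, Tr)
  x1 <- qM * exp(-p$lambda * (t - u))
  x0 <- qM * exp(-p$lambda * t)
  logpre <- d * t - log(p$lambda) - a * log(qM) + lgamma(a)
  out <- numeric(length(t))
  lower <- pgamma(x0, a) < 0.5
  if (any(lower)) {
    lp1 <- pgamma(x1[lower], a, log.p = TRUE)
    lp0 <- pgamma(x0[lower], a, log.p = TRUE)
    out[lower] <- exp(logpre[lower] + lp1 + log1p(-exp(lp0 - lp1)))
  }
  if (any(!lower)) {
    lq0 <- pgamma(x0[!lower], a, lower.tail = FALSE, log.p = TRUE)
    lq1 <- pgamma(x1[!lower], a, lower.tail = FALSE, log.p = TRUE)
    out[!lower] <- exp(logpre[!lower] + lq0 + log1p(-exp(lq1 - lq0)))
  }
  out[t == 0] <- 0
  p$nu * (1 - p$q) * out
}

.b_quadrature <- function(p, growth, t, Tr, tol) {
  G <- function(s) exp(-(1 - p$q) * p$M * exp(-p$lambda * s))
  # evaluate n(s) ignoring the cut-off; the cut-off is the upper limit
  g_open <- growth
  g_open$t_resect <- Inf
  vapply(t, function(tt) {
    upper <- min(tt, Tr)
    if (upper <= 0) return(0)
    val <- tryCatch(
      integrate(function(s) tumor_size(g_open, s) * G(tt - s),
                0, upper, rel.tol = tol, subdivisions = 400L)$value,
      error = function(e) stop("quadrature for b_t failed at t = ", tt,
                               ": ", conditionMessage(e), call. = FALSE))
    p$nu * (1 - p$q) * val
  }, numeric(1))
}

#' Hitting-time distribution of a single surviving metastasis
#'
#' Asymptotic (large `M`) CDF of the time \eqn{\Theta} for a surviving
#' birth-death clone started from one cell to reach `M` cells:
#' \eqn{G(t) = \exp(-(1-q) M e^{-\lambda t})}, a Gumbel (max) law with
#' location \eqn{\log(M(1-q))/\lambda} and scale \eqn{1/\lambda}, hence mean
#' \eqn{(\log(M(1-q)) + \gamma_E)/\lambda} and variance
#' \eqn{\pi^2/(6\lambda^2)}.
#'
#' @param params A [model_params()] object (or [relapse_model()], whose
#'   parameters are used).
#' @param t Times in days (any real; the support extends below 0).
#' @return CDF values.
#' @export
hitting_time_cdf <- function(params, t) {
  p <- if (inherits(params, "relapse_model")) params$params else params
  exp(-(1 - p$q) * p$M * exp(-p$lambda * t))
}

#' Relapse-time distribution
#'
#' CDF of the relapse time \eqn{\tau}, the first time any metastasis reaches
#' the detectable size: \eqn{P(\tau \le t) = 1 - e^{-b_t}}. With a finite
#' resection time the distribution is defective: its total mass is
#' \eqn{1 - e^{-a_T}} and the remaining mass \eqn{e^{-a_T}} is the cure
#' probability (no surviving metastasis ever seeded).
#'
#' @inheritParams expected_seeded
#' @return CDF values in `[0, 1]`.
#' @export
#' @examples
#' m <- relapse_model("colorectal", resect = FALSE)
#' relapse_cdf(m, c(3000, 5000, 7000))
relapse_cdf <- function(model, t, t_resect = NULL) {
  -expm1(-expected_detectable(model, t, t_resect))
}

#' Scaled relapse-time distribution
#'
#' CDF of the scaled relapse time \eqn{\bar\tau}, the large-`M` limit of
#' \eqn{\tau - \log(M)/\lambda}. For exponential growth this has the closed
#' form
#' \deqn{P(\bar\tau \le t) = 1 - \exp\left(-\nu (1-q)^{1-\delta/\lambda}
#'   e^{\delta t} \Gamma(\delta/\lambda, (1-q)e^{-\lambda t}) / \lambda\right)}
#' with \eqn{\Gamma(a, x)} the upper incomplete gamma function (for
#' \eqn{\lambda = \delta} it reduces via \eqn{\Gamma(1,x) = e^{-x}}).
#' For other growth kinds the defining integral is evaluated by adaptive
#' quadrature.
#'
#' @inheritParams expected_seeded
#' @param t Scaled times in days (any real).
#' @return CDF values.
#' @export
scaled_relapse_cdf <- function(model, t) {
  stopifnot(inherits(model, "relapse_model"))
  p <- model$params
  g <- model$growth
  if (g$kind == "exponential") {
    d <- g$gamma * g$delta
    a <- d / p$lambda
    if (a <= 0) stop("delta / lambda must be positive", call. = FALSE)
    x <- (1 - p$q) * exp(-p$lambda * t)
    # upper incomplete gamma in log space
    lgam_up <- pgamma(x, a, lower.tail = FALSE, log.p = TRUE) + lgamma(a)
    -expm1(-exp(log(p$nu) + (1 - a) * log(1 - p$q) + d * t - log(p$lambda) +
                  lgam_up))
  } else {
    g_open <- g
    g_open$t_resect <- Inf
    vapply(t, function(tt) {
      val <- integrate(function(s) tumor_size(g_open, pmax(tt - s, 0)) *
                         exp(-(1 - p$q) * exp(-p$lambda * s)),
                       -Inf, tt, rel.tol = model$quadrature_tol,
                       subdivisions = 800L)$value
      -expm1(-p$nu * (1 - p$q) * val)
    }, numeric(1))
  }
}

#' Small-initiation-rate Gumbel limit of the scaled relapse time
#'
#' As \eqn{\nu \to 0} (exponential growth), the scaled relapse time
#' \eqn{\bar\tau} converges to a Gumbel distribution for the minimum with
#' location \eqn{-\log[\nu (1-q)^{1-\delta/\lambda}
#' \Gamma(\delta/\lambda)/\lambda] / \delta} and (negative) scale
#' \eqn{-1/\delta}; its CDF is \eqn{1 - \exp(-e^{-(x-a)/b})}, its mean
#' \eqn{a + b\gamma_E} and its variance \eqn{\pi^2 b^2 / 6}.
#'
#' @inheritParams hitting_time_cdf
#' @return A one-row tibble with columns `location` and `scale` (days).
#' @export
small_nu_gumbel <- function(params) {
  p <- if (inherits(params, "relapse_model")) params$params else params
  stopifnot(p$nu > 0, p$delta > 0, p$lambda > 0)
  a <- p$delta / p$lambda
  loc <- -(log(p$nu) + (1 - a) * log(1 - p$q) + lgamma(a) - log(p$lambda)) /
    p$delta
  tibble::tibble(location = loc, scale = -1 / p$delta)
}

# Gumbel CDF shared by both orientations: scale > 0 is the max-type,
# scale < 0 the min-type.
.pgumbel <- function(x, location, scale) {
  z <- exp(-(x - location) / scale)
  if (scale > 0) exp(-z) else -expm1(-z)
}

.rgumbel <- function(n, location, scale) {
  location - scale * log(-log(runif(n)))
}

#' Mean relapse time (small-initiation, large-M expansion)
#'
#' \deqn{E[\tau] \approx \log(M)/\lambda + \log(\delta/\nu)/\delta + C,
#'   \quad C = -\left(\log[\delta (1-q)^{1-\delta/\lambda}
#'   \Gamma(\delta/\lambda)/\lambda] + \gamma_E\right)/\delta.}
#'
#' @inheritParams hitting_time_cdf
#' @return One-row tibble: `mean_days`, the constant `C_days`, and the two
#'   leading terms `logM_term` and `lognu_term` (days).
#' @export
#' @examples
#' mean_relapse_time(relapse_model("colorectal"))
mean_relapse_time <- function(params) {
  p <- if (inherits(params, "relapse_model")) params$params else params
  a <- p$delta / p$lambda
  C <- -(log(p$delta / p$lambda) + (1 - a) * log(1 - p$q) + lgamma(a) +
           .gamma_e) / p$delta
  t1 <- log(p$M) / p$lambda
  t2 <- log(p$delta / p$nu) / p$delta
  tibble::tibble(mean_days = t1 + t2 + C, C_days = C,
                 logM_term = t1, lognu_term = t2)
}

#' Mean time to detectability of the first-established metastasis
#'
#' Decomposes \eqn{E[\tau_1] = E[\sigma_1] + E[\Theta_1]}: the expected
#' first surviving seeding time plus the expected hitting time to `M`. It
#' shares the leading \eqn{\log M} and \eqn{\log \nu} terms with
#' [mean_relapse_time()] but has a different constant
#' \eqn{\tilde C = C_1 - C_2}, with
#' \eqn{C_1 = -(\log(1-q) + \gamma_E)/\delta} and
#' \eqn{C_2 = -(\log(1-q) + \gamma_E)/\lambda}. Because later metastases can
#' outrun the first one, \eqn{E[\tau_1] \ge E[\tau]}.
#'
#' @inheritParams hitting_time_cdf
#' @return One-row tibble: `mean_days`, `Ctilde_days`, `mean_seeding_days`
#'   (\eqn{E[\sigma_1]}) and `mean_hitting_days` (\eqn{E[\Theta]}).
#' @export
mean_first_detection <- function(params) {
  p <- if (inherits(params, "relapse_model")) params$params else params
  C1 <- -(log(1 - p$q) + .gamma_e) / p$delta
  C2 <- -(log(1 - p$q) + .gamma_e) / p$lambda
  e_sigma <- log(p$delta / p$nu) / p$delta + C1
  e_theta <- (log(p$M * (1 - p$q)) + .gamma_e) / p$lambda
  tibble::tibble(mean_days = e_sigma + e_theta, Ctilde_days = C1 - C2,
                 mean_seeding_days = e_sigma, mean_hitting_days = e_theta)
}

#' Relapse-time distribution conditioned on metastases at resection
#'
#' CDF of \eqn{\tau} given that at least one surviving metastasis was seeded
#' before the resection at `T`:
#' \eqn{P(\tau \le t \mid K_T \ge 1) = (1 - e^{-b_t}) / (1 - e^{-a_T})},
#' a proper distribution. As `T -> 0` it converges to the single-clone
#' hitting-time law [hitting_time_cdf()]; as `T -> Inf` it converges to the
#' unconditional [relapse_cdf()].
#'
#' @inheritParams expected_seeded
#' @return CDF values.
#' @export
conditional_relapse_cdf <- function(model, t, t_resect = NULL) {
  Tr <- .resolve_T(model, t_resect)
  aT <- expected_seeded(model, Tr, t_resect = Tr)
  if (aT <= 0)
    stop("conditioning on a null event: no seeding possible by resection",
         call. = FALSE)
  relapse_cdf(model, t, t_resect = Tr) / -expm1(-aT)
}

#' Probability of synchronous metastases
#'
#' \eqn{P(S_T \ge 1) = 1 - e^{-b_T}}: the probability that some metastasis
#' is already detectable at the resection time `T` (equivalently, that
#' relapse has occurred by `T`).
#'
#' @inheritParams expected_seeded
#' @param t_resect Resection time in days; defaults to the model's cut-off.
#' @return Probability.
#' @export
#' @examples
#' prob_synchronous(relapse_model("lung"))
prob_synchronous <- function(model, t_resect = NULL) {
  Tr <- .resolve_T(model, t_resect)
  -expm1(-expected_detectable(model, Tr, t_resect = Tr))
}

#' @rdname prob_synchronous
#' @description `prob_seeded()` is \eqn{P(K_T \ge 1) = 1 - e^{-a_T}}, the
#'   probability that any surviving metastasis exists at resection, and
#'   `cure_probability()` its complement \eqn{e^{-a_T}}.
#' @export
prob_seeded <- function(model, t_resect = NULL) {
  Tr <- .resolve_T(model, t_resect)
  -expm1(-expected_seeded(model, Tr, t_resect = Tr))
}

#' @rdname prob_synchronous
#' @export
cure_probability <- function(model, t_resect = NULL) {
  1 - prob_seeded(model, t_resect)
}

#' Probability of established but all-undetectable metastases
#'
#' The high-risk event \eqn{U_T = \{K_T \ge 1, S_T = 0\}}: metastases exist
#' at resection but none is detectable. By independence of the synchronous
#' and metachronous processes,
#' \eqn{P(U_T) = e^{-b_T} - e^{-a_T} = P(K_T \ge 1) - P(S_T \ge 1)}.
#' `prob_metachronous()` gives \eqn{P(M_T \ge 1) = 1 - e^{-c_T}}, which by
#' the same independence equals \eqn{P(K_T \ge 1 \mid S_T = 0)}.
#'
#' @inheritParams prob_synchronous
#' @return Probability.
#' @export
#' @examples
#' prob_undetectable_only(relapse_model("headneck"))
prob_undetectable_only <- function(model, t_resect = NULL) {
  Tr <- .resolve_T(model, t_resect)
  exp(-expected_detectable(model, Tr, t_resect = Tr)) -
    exp(-expected_seeded(model, Tr, t_resect = Tr))
}

#' @rdname prob_undetectable_only
#' @export
prob_metachronous <- function(model, t_resect = NULL) {
  Tr <- .resolve_T(model, t_resect)
  -expm1(-expected_occult(model, Tr, t_resect = Tr))
}

#' Relapse after resection, conditioned on occult metastases
#'
#' CDF (for `t >= T`) of the relapse time given the high-risk event
#' \eqn{U_T} (metastases established, none detectable at resection):
#' \deqn{P(\tau \le t \mid U_T) =
#'   (e^{-b_T} - e^{-b_t}) / (e^{-b_T} - e^{-a_T}).}
#' `expected_relapse_after_resection()` integrates the corresponding
#' survival function over `[T, Inf)` to give \eqn{E[\tau - T \mid U_T]} in
#' days; the improper integral is truncated where the conditional survival
#' drops below `tail_tol` and evaluated by adaptive quadrature.
#'
#' @inheritParams prob_synchronous
#' @param t Times in days, all at least the resection time.
#' @return CDF values / expected days from resection to relapse.
#' @export
#' @examples
#' expected_relapse_after_resection(relapse_model("colorectal"))
relapse_after_resection_cdf <- function(model, t, t_resect = NULL) {
  Tr <- .resolve_T(model, t_resect)
  stopifnot(is.finite(Tr))
  if (any(t < Tr)) stop("t must not precede the resection time", call. = FALSE)
  ebT <- exp(-expected_detectable(model, Tr, t_resect = Tr))
  eaT <- exp(-expected_seeded(model, Tr, t_resect = Tr))
  if (ebT - eaT <= 0)
    stop("P(U_T) is zero: conditioning impossible", call. = FALSE)
  (ebT - exp(-expected_detectable(model, t, t_resect = Tr))) / (ebT - eaT)
}

#' @rdname relapse_after_resection_cdf
#' @param tail_tol Survival mass below which the improper integral is
#'   truncated.
#' @export
expected_relapse_after_resection <- function(model, t_resect = NULL,
                                             tail_tol = 1e-12) {
  Tr <- .resolve_T(model, t_resect)
  stopifnot(is.finite(Tr))
  ebT <- exp(-expected_detectable(model, Tr, t_resect = Tr))
  eaT <- exp(-expected_seeded(model, Tr, t_resect = Tr))
  if (ebT - eaT <= 0)
    stop("P(U_T) is zero: conditioning impossible", call. = FALSE)
  surv <- function(t) {
    (exp(-expected_detectable(model, t, t_resect = Tr)) - eaT) / (ebT - eaT)
  }
  # exponential tail: expand upper limit until the survival is negligible
  upper <- Tr + 10 / model$params$lambda
  while (surv(upper) > tail_tol) upper <- upper + 10 / model$params$lambda
  integrate(surv, Tr, upper, rel.tol = 1e-9, subdivisions = 400L)$value
}

#' Disease-free distribution after resection
#'
#' CDF (for `t >= T`) of the relapse time conditioned on no synchronous
#' metastases at resection:
#' \eqn{P(\tau \le t \mid S_T = 0) = 1 - e^{-(b_t - b_T)}}. The distribution
#' is defective, plateauing at \eqn{1 - e^{-c_T} = P(M_T \ge 1)}; the
#' conditional cure probability is \eqn{e^{-c_T}}.
#'
#' @inheritParams relapse_after_resection_cdf
#' @return CDF values.
#' @export
disease_free_cdf <- function(model, t, t_resect = NULL) {
  Tr <- .resolve_T(model, t_resect)
  stopifnot(is.finite(Tr))
  if (any(t < Tr)) stop("t must not precede the resection time", call. = FALSE)
  bT <- expected_detectable(model, Tr, t_resect = Tr)
  -expm1(-(expected_detectable(model, t, t_resect = Tr) - bT))
}

#' Risk of first seeding during a surgery delay
#'
#' Probability that the first surviving metastasis is initiated in the
#' window `(T, T + dT)` — i.e. that a delay of `dT` days turns a cured
#' patient into a relapsing one:
#' \eqn{P(K_{T+\Delta T} \ge 1, K_T = 0) = e^{-a_T} - e^{-a_{T+\Delta T}}},
#' the decrease in cure probability caused by the delay.
#'
#' @inheritParams prob_synchronous
#' @param t_resect Planned resection time, days.
#' @param delay Surgery delay(s), days.
#' @return Probability (vectorized over `delay` and `t_resect`).
#' @export
#' @examples
#' m <- relapse_model("colorectal")
#' surgery_delay_risk(m, t_resect = resection_time_for_size(m$growth, 2e8),
#'                    delay = 60)
surgery_delay_risk <- function(model, t_resect = NULL, delay) {
  Tr <- .resolve_T(model, t_resect)
  stopifnot(all(delay >= 0), all(Tr >= 0))
  exp(-expected_seeded(model, Tr, t_resect = Inf)) -
    exp(-expected_seeded(model, Tr + delay, t_resect = Inf))
}

#' Logistic-vs-exponential regime indicator
#'
#' The dimensionless quantity \eqn{\nu (1-q) K / \delta}. When it is much
#' larger than 1, the metastases that drive relapse are seeded during the
#' early (exponential-like) phase of a logistic primary, and logistic and
#' exponential growth give indistinguishable relapse-time distributions;
#' values near or below 1 signal a genuine difference between the two
#' growth laws.
#'
#' @inheritParams hitting_time_cdf
#' @param K Carrying capacity in cells.
#' @return The indicator value (vectorized over `K`).
#' @export
#' @examples
#' logistic_regime_indicator(relapse_model("colorectal"), K = 1e12)
logistic_regime_indicator <- function(params, K) {
  p <- if (inherits(params, "relapse_model")) params$params else params
  stopifnot(all(K > 0))
  p$nu * (1 - p$q) * K / p$delta
}

#' Numerical density of a relapse-model CDF
#'
#' Central-difference derivative of one of the model CDF functions; the
#' model defines its densities only as derivatives of the corresponding
#' CDFs.
#'
#' @param cdf_fun A function of a time vector returning CDF values.
#' @param t Times at which to evaluate the density.
#' @param step Relative step for the central difference (multiplied by the
#'   scale `1/lambda` is the caller's concern; here an absolute step of
#'   `step * max(abs(t), 1)` per point is used).
#' @return Numeric vector of density values.
#' @export
numeric_density <- function(cdf_fun, t, step = 1e-3) {
  h <- step * pmax(abs(t), 1)
  (cdf_fun(t + h) - cdf_fun(t - h)) / (2 * h)
}
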