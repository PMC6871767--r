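#' Deterministic primary-tumor growth laws
#'
#' Constructs a primary-tumor growth model: a deterministic cell-count
#' function \eqn{n(t)} starting from a single cell, \eqn{n(0) = 1}, with an
#' optional resection cut-off after which \eqn{n(t) \equiv 0}.
#'
#' Two growth kinds are supported:
#' \describe{
#'   \item{exponential}{\eqn{n(t) = e^{\gamma\delta t}}. The exponent
#'     \eqn{\gamma \le 1} models scenarios where only a fraction of the
#'     primary (e.g. its surface, \eqn{\gamma = 2/3}) can seed metastases;
#'     it simply rescales the net growth rate.}
#'   \item{logistic}{\eqn{n(t) = K e^{\delta t} / (K + e^{\delta t} - 1)},
#'     bounded by the carrying capacity \eqn{K}.}
#' }
#'
#' @param kind `"exponential"` or `"logistic"`.
#' @param delta Primary net growth rate, per day. Must be positive.
#' @param K Carrying capacity in cells (logistic only). Must exceed 1.
#' @param gamma Dimensionless seeding-fraction exponent (exponential only);
#'   default 1.
#' @param t_resect Resection time in days; `Inf` (default) means the primary
#'   is never removed.
#' @return An object of class `growth_model`.
#' @seealso [tumor_size()], [tumor_mass()], [resection_time_for_size()],
#'   [set_resection()]
#' @export
#' @examples
#' g <- growth_model("exponential", delta = log(2) / 175)
#' tumor_size(g, c(0, 1000, 5000))
growth_model <- function(kind = c("exponential", "logistic"), delta,
                         K = NULL, gamma = 1, t_resect = Inf) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(delta), length(delta) == 1, delta > 0,
            is.numeric(gamma), length(gamma) == 1, gamma > 0,
            is.numeric(t_resect), length(t_resect) == 1, t_resect > 0)
  if (kind == "logistic") {
    if (is.null(K) || !is.numeric(K) || length(K) != 1 || K <= 1)
      stop("logistic growth requires a carrying capacity K > 1", call. = FALSE)
    if (gamma != 1)
      stop("the seeding-fraction exponent gamma is defined for exponential growth only",
           call. = FALSE)
  } else {
    K <- Inf
  }
  structure(
    list(kind = kind, delta = delta, K = K, gamma = gamma,
         t_resect = t_resect),
    class = "growth_model"
  )
}

#' @export
print.growth_model <- function(x, ...) {
  cat("<growth_model> ", x$kind, "\n", sep = "")
  cat("  delta: ", signif(x$delta, 4), " /day",
      if (x$kind == "exponential" && x$gamma != 1)
        paste0("  (gamma = ", x$gamma, ")"), "\n", sep = "")
  if (is.finite(x$K)) cat("  K:     ", format(x$K), " cells\n", sep = "")
  cat("  resection: ",
      if (is.finite(x$t_resect)) paste0("day ", signif(x$t_resect, 6)) else "none",
      "\n", sep = "")
  invisible(x)
}

# effective exponential rate (gamma folded in)
.g_rate <- function(g) g$gamma * g$delta

#' Evaluate a growth model
#'
#' Returns the primary cell count \eqn{n(t)}, identically 0 for
#' `t >= t_resect`.
#'
#' @param growth A [growth_model()].
#' @param t Numeric vector of times in days, all non-negative.
#' @return Numeric vector of cell counts.
#' @export
tumor_size <- function(growth, t) {
  stopifnot(inherits(growth, "growth_model"), is.numeric(t))
  if (any(t < 0)) stop("times must be non-negative", call. = FALSE)
  n <- if (growth$kind == "exponential") {
    exp(.g_rate(growth) * t)
  } else {
    # K e^{dt} / (K + e^{dt} - 1), written to avoid overflow of e^{dt}
    growth$K / ((growth$K - 1) * exp(-growth$delta * t) + 1)
  }
  n[t >= growth$t_resect] <- 0
  n
}

#' Cumulative tumor mass
#'
#' The integral \eqn{\int_0^{\min(t, T)} n(s)\,ds} (cell-days), the quantity
#' that drives the expected number of seeded metastases. Closed forms are
#' used for both growth kinds.
#'
#' @inheritParams tumor_size
#' @param t_resect Optional resection-time override (days); defaults to the
#'   model's own cut-off.
#' @return Numeric vector of cell-day masses.
#' @export
tumor_mass <- function(growth, t, t_resect = growth$t_resect) {
  stopifnot(inherits(growth, "growth_model"), is.numeric(t))
  if (any(t < 0)) stop("times must be non-negative", call. = FALSE)
  u <- pmin(t, t_resect)
  if (growth$kind == "exponential") {
    r <- .g_rate(growth)
    expm1(r * u) / r
  } else {
    # antiderivative of K e^{ds}/(K - 1 + e^{ds}) is (K/d) log((K-1+e^{dt})/K),
    # computed as log1p(expm1(dt)/K) to stay accurate when e^{dt} << K
    K <- growth$K; d <- growth$delta
    x <- d * u
    lr <- ifelse(x < 700, log1p(expm1(x) / K),
                 x - log(K) + log1p((K - 1) * exp(-x)))
    K / d * lr
  }
}

#' Resection time reaching a given size
#'
#' Inverts \eqn{n(T) = N} for the time at which the primary reaches `N`
#' cells. Closed-form for both growth kinds.
#'
#' @inheritParams tumor_size
#' @param N Target size in cells; at least 1, and below `K` for logistic
#'   growth.
#' @return Time in days.
#' @export
#' @examples
#' g <- growth_model("exponential", delta = log(2) / 84)
#' resection_time_for_size(g, 1.15e10) / 365   # years
resection_time_for_size <- function(growth, N) {
  stopifnot(inherits(growth, "growth_model"), is.numeric(N), all(N >= 1))
  if (growth$kind == "exponential") {
    log(N) / .g_rate(growth)
  } else {
    if (any(N >= growth$K))
      stop("target size is not reachable: N >= carrying capacity K",
           call. = FALSE)
    log(N * (growth$K - 1) / (growth$K - N)) / growth$delta
  }
}

#' Apply a resection cut-off
#'
#' Returns the growth model truncated at a resection time (or, equivalently,
#' at the time the primary reaches a given size). Applying a later cut-off to
#' an already-resected model has no effect, so cut-offs are idempotent.
#'
#' @inheritParams tumor_size
#' @param time Resection time in days.
#' @param size Alternative to `time`: resect when the primary reaches this
#'   many cells.
#' @return A [growth_model()] with the cut-off applied.
#' @export
set_resection <- function(growth, time = NULL, size = NULL) {
  stopifnot(inherits(growth, "growth_model"))
  if (is.null(time) == is.null(size))
    stop("supply exactly one of `time` or `size`", call. = FALSE)
  if (!is.null(size)) time <- resection_time_for_size(growth, size)
  growth$t_resect <- min(growth$t_resect, time)
  growth
}
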