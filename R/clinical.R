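#' Bundled clinical inputs for five cancer types
#'
#' Literature-derived clinical quantities for breast, colorectal, head and
#' neck (`headneck`), lung and prostate cancer: primary and metastatic
#' volume doubling times `DT_pt` and `DT_m` (days), potential doubling time
#' `T_pot` (days, the mean cell-division interval in the absence of death),
#' the typical primary diameter at resection `d_pt` (cm) and its typical
#' range (`d_lo`, `d_hi`).
#'
#' @return A tibble with one row per cancer type.
#' @seealso [estimate_parameters()]
#' @export
#' @examples
#' clinical_inputs()
clinical_inputs <- function() {
  path <- system.file("extdata", "clinical_inputs.csv",
                      package = "metarelapse", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Growth and death rates from doubling times
#'
#' Converts doubling times to the model's rates: primary net growth rate
#' \eqn{\delta = \log 2 / DT_{pt}}, metastatic net growth rate
#' \eqn{\lambda = \log 2 / DT_m}, metastatic birth rate
#' \eqn{\alpha = 1 / T_{pot}}, death rate \eqn{\beta = \alpha - \lambda}
#' and extinction probability \eqn{q = \beta / \alpha = 1 - \lambda/\alpha}.
#'
#' @param data A data frame with columns `DT_pt`, `DT_m`, `T_pot` (days),
#'   e.g. [clinical_inputs()].
#' @return The input tibble with columns `delta`, `lambda`, `alpha`, `beta`
#'   and `q` appended (rates in 1/day).
#' @export
#' @examples
#' rates_from_doubling_times(clinical_inputs())
rates_from_doubling_times <- function(data) {
  stopifnot(all(c("DT_pt", "DT_m", "T_pot") %in% names(data)))
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    delta  = log(2) / .data$DT_pt,
    lambda = log(2) / .data$DT_m,
    alpha  = 1 / .data$T_pot,
    beta   = .data$alpha - .data$lambda,
    q      = 1 - .data$lambda / .data$alpha
  )
  if (any(out$delta <= 0 | out$lambda <= 0))
    stop("doubling times must be positive", call. = FALSE)
  if (any(out$q < 0))
    stop("metastases would be subcritical: T_pot must not exceed DT_m / log 2",
         call. = FALSE)
  out
}

#' Convert tumor diameter to cell count and back
#'
#' Assumes spherical lesions at `cells_per_cm3` cells per cm^3 (default
#' 10^9), so a diameter `d` cm corresponds to \eqn{\pi d^3 / 6 \times 10^9}
#' cells. The default detection limit of 0.2 cm gives the minimal detectable
#' size \eqn{M \approx 4.19 \times 10^6} cells.
#'
#' @param d Diameter(s) in cm.
#' @param cells_per_cm3 Packing density, cells per cm^3.
#' @return Cell count(s).
#' @export
#' @examples
#' size_from_diameter(0.2)
#' diameter_from_size(4.77e10)
size_from_diameter <- function(d, cells_per_cm3 = 1e9) {
  stopifnot(all(d > 0))
  pi / 6 * d^3 * cells_per_cm3
}

#' @rdname size_from_diameter
#' @param n Cell count(s).
#' @export
diameter_from_size <- function(n, cells_per_cm3 = 1e9) {
  stopifnot(all(n > 0))
  (6 * n / (pi * cells_per_cm3))^(1 / 3)
}

#' Metastasis initiation rate from the early-dissemination assumption
#'
#' The per-cell initiation rate \eqn{\nu} is calibrated so that the primary
#' size at the expected first seeding time equals `dissemination_size`
#' (default 10^8 cells, about 0.58 cm): since
#' \eqn{E[\sigma_1] = (\log(\delta / \nu(1-q)) - \gamma_E)/\delta}, setting
#' \eqn{e^{\delta E[\sigma_1]}} to the dissemination size and solving for
#' \eqn{\nu} gives
#' \eqn{\nu = \delta e^{-\gamma_E} e^{-\delta E[\sigma_1]} / (1 - q)}.
#'
#' @param delta Primary net growth rate, 1/day.
#' @param q Metastasis extinction probability.
#' @param dissemination_size Primary size (cells) at the expected first
#'   surviving seeding event.
#' @return Initiation rate in metastases per primary cell per day.
#' @export
#' @examples
#' nu_from_dissemination(log(2) / 175, 1 - (log(2) / 105) * 4)
nu_from_dissemination <- function(delta, q, dissemination_size = 1e8) {
  stopifnot(all(dissemination_size > 1), all(delta > 0), all(q >= 0 & q < 1))
  delta * exp(-.gamma_e) / (1 - q) / dissemination_size
}

#' Normal model of the resection-diameter distribution
#'
#' Fits a normal distribution to the typical range of primary diameters at
#' resection: the mean is the midpoint of (`d_lo`, `d_hi`) and the standard
#' deviation is chosen so that the range covers 95% of the mass,
#' `sd = (d_hi - d_lo) / (2 * qnorm(0.975))`.
#'
#' @param data Data frame with columns `d_lo` and `d_hi` (cm).
#' @return Input tibble with columns `d_mean` and `d_sd` (cm) appended.
#' @export
#' @examples
#' diameter_distribution(clinical_inputs())
diameter_distribution <- function(data) {
  stopifnot(all(c("d_lo", "d_hi") %in% names(data)))
  if (any(data$d_hi <= data$d_lo))
    stop("degenerate diameter range: d_hi must exceed d_lo", call. = FALSE)
  dplyr::mutate(
    tibble::as_tibble(data),
    d_mean = (.data$d_lo + .data$d_hi) / 2,
    d_sd   = (.data$d_hi - .data$d_lo) / (2 * qnorm(0.975))
  )
}

#' Derive model parameters from clinical inputs
#'
#' Runs the full estimation chain on a table of clinical inputs: rates from
#' doubling times, resection size `N` from the primary diameter, minimal
#' detectable size `M` from the detection-limit diameter, and the initiation
#' rate `nu` from the early-dissemination assumption. All values are kept at
#' full double precision; rounding is left to presentation.
#'
#' @param data Data frame like [clinical_inputs()] (columns `cancer_type`,
#'   `DT_pt`, `DT_m`, `T_pot`, `d_pt`, and optionally `d_lo`, `d_hi`).
#' @param d_detect Minimal detectable lesion diameter, cm.
#' @param dissemination_size Primary size (cells) at expected first seeding;
#'   see [nu_from_dissemination()].
#' @return A tibble with one row per input row and columns `delta`, `lambda`,
#'   `alpha`, `beta`, `q`, `nu`, `N`, `M` (rates 1/day, sizes in cells).
#' @export
#' @examples
#' estimate_parameters(clinical_inputs())
estimate_parameters <- function(data, d_detect = 0.2,
                                dissemination_size = 1e8) {
  stopifnot("d_pt" %in% names(data))
  out <- rates_from_doubling_times(data)
  dplyr::mutate(
    out,
    nu = nu_from_dissemination(.data$delta, .data$q, dissemination_size),
    N  = size_from_diameter(.data$d_pt),
    M  = size_from_diameter(d_detect)
  )
}

#' Model parameter set
#'
#' Bundles the parameters of the relapse model: primary net growth rate
#' `delta`, metastatic net growth rate `lambda = alpha - beta > 0`,
#' extinction probability `q = beta / alpha`, initiation rate `nu`, minimal
#' detectable size `M` and primary size at resection `N`. Either
#' (`lambda`, `q`) or (`alpha`, `beta`) may be given; the other pair is
#' derived.
#'
#' @param delta Primary net growth rate, 1/day.
#' @param lambda Metastatic net growth rate, 1/day.
#' @param q Extinction probability in `[0, 1)`.
#' @param alpha,beta Metastatic birth and death rates, 1/day.
#' @param nu Initiation rate per primary cell per day.
#' @param M Minimal detectable size, cells.
#' @param N Primary size at resection, cells.
#' @return An object of class `model_params`.
#' @export
#' @examples
#' model_params(delta = log(2) / 175, lambda = log(2) / 105,
#'              alpha = 0.25, nu = 8.42e-10, N = 4.77e10)
model_params <- function(delta, lambda = NULL, q = NULL, alpha = NULL,
                         beta = NULL, nu, M = size_from_diameter(0.2),
                         N = NULL) {
  if (is.null(lambda) && !is.null(alpha) && !is.null(beta)) lambda <- alpha - beta
  if (is.null(q)) {
    if (is.null(alpha)) stop("supply q, or alpha (and beta or lambda)", call. = FALSE)
    if (is.null(beta)) beta <- alpha - lambda
    q <- beta / alpha
  }
  if (is.null(alpha) && !is.null(lambda)) {
    # alpha only needed when q is derived or for simulation; recover if possible
    alpha <- lambda / (1 - q)
  }
  if (is.null(beta)) beta <- alpha - lambda
  stopifnot(delta > 0, lambda > 0, nu > 0, M > 1, q >= 0, q < 1)
  if (abs(beta / alpha - q) > 1e-12)
    stop("inconsistent rates: q must equal beta / alpha", call. = FALSE)
  if (!is.null(N)) stopifnot(N >= 1)
  structure(
    list(delta = delta, lambda = lambda, alpha = alpha, beta = beta,
         q = q, nu = nu, M = M, N = N),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  delta  %.4g /day    lambda %.4g /day\n", x$delta, x$lambda))
  cat(sprintf("  alpha  %.4g /day    beta   %.4g /day    q %.4f\n",
              x$alpha, x$beta, x$q))
  cat(sprintf("  nu     %.3e /cell/day\n", x$nu))
  cat(sprintf("  M      %.3e cells", x$M))
  if (!is.null(x$N)) cat(sprintf("    N %.3e cells", x$N))
  cat("\n")
  invisible(x)
}

#' Relapse model: parameters plus primary growth law
#'
#' The central object of the package: binds a [model_params()] set to a
#' primary [growth_model()] and exposes every distribution of the relapse
#' model through the `*_cdf`, `prob_*` and prediction functions.
#'
#' `x` may be a cancer-type name from [clinical_inputs()] (the growth model
#' then defaults to exponential growth resected at the estimated size `N`),
#' a one-row data frame as produced by [estimate_parameters()], or a
#' [model_params()] object.
#'
#' @param x Cancer-type name, one-row parameter data frame, or
#'   [model_params()].
#' @param growth Optional [growth_model()]; defaults to exponential growth
#'   with the parameter set's `delta`, resected at size `N` (no resection if
#'   `N` is absent).
#' @param resect Logical; when `x` names a cancer type or carries `N`,
#'   should the default growth be resected at `N`? Default `TRUE`.
#' @param quadrature_tol Relative tolerance for adaptive quadrature used
#'   with non-exponential growth.
#' @param ... Passed to [estimate_parameters()] when `x` is a cancer name
#'   (e.g. `dissemination_size`).
#' @return An object of class `relapse_model`.
#' @export
#' @examples
#' m <- relapse_model("colorectal")
#' prob_synchronous(m)
relapse_model <- function(x, growth = NULL, resect = TRUE,
                          quadrature_tol = 1e-9, ...) {
  params <- x
  if (is.character(x)) {
    stopifnot(length(x) == 1)
    inp <- clinical_inputs()
    row <- inp[inp$cancer_type == x, ]
    if (nrow(row) != 1)
      stop("unknown cancer type '", x, "'; see clinical_inputs()", call. = FALSE)
    params <- estimate_parameters(row, ...)
  }
  if (is.data.frame(params)) {
    stopifnot(nrow(params) == 1)
    params <- model_params(
      delta = params$delta, lambda = params$lambda,
      alpha = if ("alpha" %in% names(params)) params$alpha else NULL,
      q = params$q, nu = params$nu, M = params$M,
      N = if ("N" %in% names(params)) params$N else NULL
    )
  }
  stopifnot(inherits(params, "model_params"))
  if (is.null(growth)) {
    growth <- growth_model("exponential", delta = params$delta)
    if (resect && !is.null(params$N))
      growth <- set_resection(growth, size = params$N)
  }
  stopifnot(inherits(growth, "growth_model"))
  structure(
    list(params = params, growth = growth, quadrature_tol = quadrature_tol,
         cancer_type = if (is.character(x)) x else NA_character_),
    class = "relapse_model"
  )
}

#' @export
print.relapse_model <- function(x, ...) {
  cat("<relapse_model>",
      if (!is.na(x$cancer_type)) paste0(" [", x$cancer_type, "]"), "\n", sep = "")
  print(x$params)
  print(x$growth)
  invisible(x)
}
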