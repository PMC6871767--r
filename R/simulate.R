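# -------------------------------------------------------------------------
# Stochastic simulation of the full model: non-homogeneous Poisson seeding
# from the (deterministic or stochastic) primary, exact Gillespie birth-
# death dynamics per metastasis, and first-passage detection at M.
# The simulator is the package's Monte-Carlo oracle for the analytic
# distributions. All randomness flows through R's global RNG, so a single
# set.seed() (or the `seed` argument) makes runs reproducible.
# -------------------------------------------------------------------------

#' Exact birth-death first-passage simulation
#'
#' Gillespie realizations of a linear birth-death process (per-cell birth
#' rate `alpha`, death rate `beta`) from `z0` cells until extinction or
#' first passage at `target` cells. Inter-event times are exponential with
#' rate \eqn{i(\alpha+\beta)} at size `i`, and each event is a birth with
#' probability \eqn{\alpha/(\alpha+\beta)}.
#'
#' @param n Number of independent realizations.
#' @param alpha,beta Birth and death rates, 1/day; `alpha > beta >= 0`.
#' @param target First-passage level, cells.
#' @param z0 Initial size, cells.
#' @return Tibble with columns `fate` (`"extinct"` or `"detected"`) and
#'   `time` (days to absorption or first passage).
#' @export
#' @examples
#' set.seed(1)
#' simulate_birth_death(5, alpha = 0.25, beta = 0.2434, target = 100)
simulate_birth_death <- function(n, alpha, beta, target, z0 = 1) {
  stopifnot(alpha > beta, beta >= 0, target >= 1)
  res <- bd_first_passage_cpp(as.integer(n), alpha, beta, target, z0)
  tibble::tibble(
    fate = ifelse(res[, 1] == 1, "detected", "extinct"),
    time = res[, 2]
  )
}

#' Sample first-passage times to the detectable size
#'
#' Draws hitting times to `target` cells for metastases started from one
#' cell. In `"exact"` mode the full Gillespie path is simulated to
#' `target`; in `"hybrid"` mode (default) the path is simulated exactly
#' only up to `switch_size` cells, after which growth is continued
#' deterministically as \eqn{T_{target} = T_m + \log(target/m)/\lambda},
#' justified by the almost-sure convergence \eqn{e^{-\lambda t} Z_t \to W}.
#' With `conditioned = TRUE` the survival-conditioned process is simulated
#' directly via its Doob h-transform (\eqn{h(i) = 1 - q^i}), which
#' reproduces the conditional first-passage law exactly, with no rejection.
#'
#' @param n Number of draws.
#' @param params A [model_params()] (or [relapse_model()]).
#' @param target Detection level in cells; defaults to the parameter set's
#'   `M`.
#' @param mode `"hybrid"` or `"exact"`.
#' @param switch_size Gillespie/deterministic switch level for hybrid mode.
#' @param conditioned Condition on survival? If `FALSE`, extinct clones are
#'   returned with `fate = "extinct"`.
#' @return Tibble with columns `fate` and `time`; with
#'   `conditioned = TRUE` all fates are `"detected"`.
#' @export
sample_hitting_times <- function(n, params, target = NULL,
                                 mode = c("hybrid", "exact"),
                                 switch_size = 1000, conditioned = TRUE) {
  p <- if (inherits(params, "relapse_model")) params$params else params
  mode <- match.arg(mode)
  if (is.null(target)) target <- p$M
  m <- if (mode == "exact") target else min(switch_size, target)
  tail_shift <- log(target / m) / p$lambda
  if (n == 0)
    return(tibble::tibble(fate = character(), time = numeric()))
  if (!conditioned) {
    res <- bd_first_passage_cpp(as.integer(n), p$alpha, p$beta, m, 1)
    return(tibble::tibble(
      fate = ifelse(res[, 1] == 1, "detected", "extinct"),
      time = ifelse(res[, 1] == 1, res[, 2] + tail_shift, res[, 2])
    ))
  }
  res <- bd_first_passage_cpp(as.integer(n), p$alpha, p$beta, m, 1,
                              q_cond = p$q)
  tibble::tibble(fate = "detected", time = res[, 2] + tail_shift)
}

# inverse of the cumulative seeding intensity for exponential growth:
# Lambda(t) = rate * (e^{rt}-1)/r  =>  t = log1p(r y / rate) / r
.seed_times_interval <- function(model, rate_per_cell, from, to) {
  g <- model$growth
  g$t_resect <- Inf
  to <- min(to, model$growth$t_resect)
  if (to <= from) return(numeric(0))
  if (g$kind == "exponential") {
    r <- .g_rate(g)
    Lambda <- function(t) rate_per_cell * expm1(r * t) / r
    n_ev <- rpois(1, Lambda(to) - Lambda(from))
    if (n_ev == 0) return(numeric(0))
    y <- Lambda(from) + runif(n_ev) * (Lambda(to) - Lambda(from))
    sort(log1p(r * y / rate_per_cell) / r)
  } else {
    # thinning against the exponential envelope e^{delta t} >= n_logistic(t)
    env <- growth_model("exponential", delta = g$delta)
    env_model <- model
    env_model$growth <- env
    cand <- .seed_times_interval(env_model, rate_per_cell, from, to)
    if (length(cand) == 0) return(numeric(0))
    keep <- runif(length(cand)) <
      tumor_size(g, cand) / exp(g$delta * cand)
    cand[keep]
  }
}

#' Sample metastasis seeding times
#'
#' Event times of the non-homogeneous Poisson seeding process on
#' `[0, min(horizon, T))`. In `"surviving"` mode (the default) only the
#' metastases destined to survive are generated, at rate
#' \eqn{\nu(1-q)n(t)}; in `"all_clones"` mode every initiation event is
#' generated at rate \eqn{\nu n(t)} and each clone's survival is left to
#' its own birth-death dynamics. Sampling is by inversion of the cumulative
#' intensity for exponential growth and by thinning against an exponential
#' envelope for logistic growth.
#'
#' @inheritParams expected_seeded
#' @param horizon Upper end of the sampling window, days.
#' @param mode `"surviving"` or `"all_clones"`.
#' @return Sorted numeric vector of seeding times (days).
#' @export
#' @examples
#' m <- relapse_model("colorectal")
#' set.seed(7)
#' sample_seeding_times(m, horizon = 6000)
sample_seeding_times <- function(model, horizon,
                                 mode = c("surviving", "all_clones")) {
  stopifnot(inherits(model, "relapse_model"), horizon >= 0)
  mode <- match.arg(mode)
  p <- model$params
  rate <- if (mode == "surviving") p$nu * (1 - p$q) else p$nu
  if (rate == 0) return(numeric(0))
  .seed_times_interval(model, rate, 0, horizon)
}

# deterministic-primary replicate: returns list(sigma, theta, fate, tau)
.replicate_deterministic <- function(model, detect_model, seeding, hitting,
                                     switch_size) {
  p <- detect_model$params
  Tr <- model$growth$t_resect
  rate <- if (seeding == "surviving") p$nu * (1 - p$q) else p$nu
  g <- model$growth
  g$t_resect <- Inf
  r <- .g_rate(g)
  Linv <- function(y) {
    if (g$kind == "exponential") log1p(r * y / rate) / r
    else uniroot(function(t) rate * tumor_mass(g, t) - y,
                 c(0, 1e7), tol = 1e-8)$root
  }
  Lam <- function(t) rate * tumor_mass(g, t)
  sigma <- numeric(0); theta <- numeric(0); fate <- character(0)
  tau_best <- Inf
  h_prev <- 0
  h <- min(Tr, Linv(3))
  for (iter in 1:200) {
    s_new <- .seed_times_interval(model, rate, h_prev, h)
    if (length(s_new) > 0) {
      ht <- sample_hitting_times(length(s_new), p, target = p$M,
                                 mode = hitting, switch_size = switch_size,
                                 conditioned = (seeding == "surviving"))
      sigma <- c(sigma, s_new)
      theta <- c(theta, ht$time)
      fate <- c(fate, ht$fate)
      det <- ht$fate == "detected"
      if (any(det))
        tau_best <- min(tau_best, s_new[det] + ht$time[det])
    }
    if (h >= Tr) break
    if (is.finite(tau_best)) {
      if (h >= tau_best) break
      h_prev <- h
      h <- min(Tr, tau_best)
    } else {
      h_prev <- h
      h <- min(Tr, Linv(Lam(h) + 3))
    }
  }
  list(sigma = sigma, theta = theta, fate = fate,
       tau = if (is.finite(tau_best)) tau_best else NA_real_)
}

# stochastic-primary replicate: primary itself is a Yule process with
# per-cell rate delta; seeding is Poisson at rate nu(1-q) Z_t along the
# realized path (piecewise constant between jumps). The path is grown in
# stages of ~3 expected seeding events each (E[seeds] over a size increment
# dz is rate * dz / delta) and stops once no later seed can beat the
# current relapse candidate. Because the deterministic law n(t) = e^{dt}
# fixes the time origin through the asymptotic trajectory, the realized
# path Z_t ~ W e^{dt} is re-origined by log(W)/delta (W estimated from the
# end of the path, where Z_t e^{-dt} has converged); resection is triggered
# by the primary reaching size n(T), the observable clinical event.
.replicate_stochastic <- function(model, detect_model, seeding, hitting,
                                  switch_size) {
  p <- detect_model$params
  Tr <- model$growth$t_resect
  delta <- .g_rate(model$growth)
  N_res <- if (is.finite(Tr)) exp(delta * Tr) else Inf
  rate <- if (seeding == "surviving") p$nu * (1 - p$q) else p$nu
  dz_stage <- ceiling(3 * delta / rate)
  sigma <- numeric(0); theta <- numeric(0); fate <- character(0)
  tau_best <- Inf      # unshifted clock; the shift is common to all seeds
  t_cur <- 0; z_cur <- 1; jumps_used <- 0
  repeat {
    dz <- max(dz_stage, z_cur)
    if (is.finite(N_res)) dz <- min(dz, max(1, ceiling(N_res) - z_cur))
    jumps_used <- jumps_used + dz
    if (jumps_used > 2e7)
      stop("stochastic primary too large to simulate per-division at this ",
           "initiation rate; use primary = \"deterministic\"", call. = FALSE)
    jump_t <- t_cur + cumsum(rexp(dz, delta * (z_cur:(z_cur + dz - 1))))
    edges <- c(t_cur, pmin(jump_t, tau_best))
    widths <- diff(edges)
    live <- widths > 0
    if (any(live)) {
      sz <- (z_cur:(z_cur + dz - 1))[live]
      wd <- widths[live]
      counts <- rpois(length(wd), rate * sz * wd)
      idx <- rep.int(which(live), counts)
      s_new <- sort(edges[idx] + runif(length(idx)) * widths[idx])
      if (length(s_new) > 0) {
        ht <- sample_hitting_times(length(s_new), p, target = p$M,
                                   mode = hitting,
                                   switch_size = switch_size,
                                   conditioned = (seeding == "surviving"))
        sigma <- c(sigma, s_new)
        theta <- c(theta, ht$time)
        fate <- c(fate, ht$fate)
        det <- ht$fate == "detected"
        if (any(det))
          tau_best <- min(tau_best, s_new[det] + ht$time[det])
      }
    }
    t_cur <- jump_t[dz]
    z_cur <- z_cur + dz
    if (z_cur >= N_res || t_cur >= tau_best) break
  }
  # pin W = lim Z_t e^{-dt}: extend the path seed-free until Z is large
  # enough that the estimate has ~1% relative error
  while (z_cur < 1e4 && z_cur < N_res) {
    dz <- min(1e4, ceiling(N_res)) - z_cur
    t_cur <- t_cur + sum(rexp(dz, delta * (z_cur:(z_cur + dz - 1))))
    z_cur <- z_cur + dz
  }
  shift <- log(z_cur) / delta - t_cur
  list(sigma = sigma + shift, theta = theta, fate = fate,
       tau = if (is.finite(tau_best)) tau_best + shift else NA_real_)
}

#' Simulate the relapse model
#'
#' Monte-Carlo realization of the full model: metastases are seeded from
#' the growing primary, each evolves as a birth-death process, and the
#' relapse time of a replicate is the earliest time any of its metastases
#' reaches the detection level. Replicates in which no metastasis is ever
#' detected (possible after resection) have `relapse_day = NA` — these are
#' the cure events of the defective relapse distribution.
#'
#' @inheritParams prob_synchronous
#' @param n_reps Number of replicates.
#' @param detect_size Detection level in cells; defaults to the model's
#'   `M`. Smaller values make exact simulation affordable.
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @param primary `"deterministic"` (the growth-law primary) or
#'   `"stochastic"` (the primary itself a pure-birth branching process with
#'   net rate `delta`).
#' @param hitting `"hybrid"` or `"exact"` first-passage sampling; see
#'   [sample_hitting_times()].
#' @param seeding `"surviving"` (thinned process, every clone conditioned
#'   to survive) or `"all_clones"` (all initiations, unconditioned clones).
#'   Both modes target the same relapse distribution.
#' @param switch_size Hybrid switch level in cells.
#' @param keep_details Keep per-metastasis records (seeding time, growth
#'   time, fate) as a list-column?
#' @return An object of class `relapse_sim`: a list with `replicates` (a
#'   tibble with `replicate`, `n_seeded`, `n_detected`, `relapse_day`),
#'   the effective `model`, and the simulation `config`.
#' @export
#' @examples
#' m <- relapse_model("colorectal", resect = FALSE)
#' sim <- simulate_relapse(m, n_reps = 50, detect_size = 100, seed = 1)
#' glance(sim)
simulate_relapse <- function(model, n_reps, detect_size = NULL, seed = NULL,
                             primary = c("deterministic", "stochastic"),
                             hitting = c("hybrid", "exact"),
                             seeding = c("surviving", "all_clones"),
                             switch_size = 1000, keep_details = FALSE) {
  stopifnot(inherits(model, "relapse_model"), n_reps >= 1)
  primary <- match.arg(primary)
  hitting <- match.arg(hitting)
  seeding <- match.arg(seeding)
  if (!is.null(seed)) set.seed(seed)
  detect_model <- model
  if (!is.null(detect_size)) detect_model$params$M <- detect_size
  rep_fun <- if (primary == "deterministic") .replicate_deterministic
             else .replicate_stochastic
  runs <- purrr::map(seq_len(n_reps), function(i) {
    rep_fun(model, detect_model, seeding, hitting, switch_size)
  })
  replicates <- tibble::tibble(
    replicate = seq_len(n_reps),
    n_seeded = vapply(runs, function(r) length(r$sigma), integer(1)),
    n_detected = vapply(runs, function(r) sum(r$fate == "detected"),
                        integer(1)),
    relapse_day = vapply(runs, function(r) r$tau, numeric(1))
  )
  if (keep_details) {
    replicates$details <- purrr::map(runs, function(r) {
      tibble::tibble(sigma = r$sigma, theta = r$theta, fate = r$fate)
    })
  }
  structure(
    list(replicates = replicates, model = detect_model,
         config = list(n_reps = n_reps, detect_size = detect_model$params$M,
                       seed = seed, primary = primary, hitting = hitting,
                       seeding = seeding, switch_size = switch_size)),
    class = "relapse_sim"
  )
}

#' @export
print.relapse_sim <- function(x, ...) {
  cat("<relapse_sim> ", x$config$n_reps, " replicates (",
      x$config$primary, " primary, ", x$config$seeding, " seeding, ",
      x$config$hitting, " hitting)\n", sep = "")
  cat("  detection level:", format(x$config$detect_size), "cells\n")
  cat("  relapse fraction:",
      signif(mean(!is.na(x$replicates$relapse_day)), 4), "\n")
  invisible(x)
}

#' Kolmogorov-Smirnov distance between a simulation and the analytic CDF
#'
#' Sup-norm distance between the empirical relapse-time CDF of a
#' [simulate_relapse()] run (cure replicates counting as mass at infinity)
#' and the analytic [relapse_cdf()] of the same model.
#'
#' @param sim A `relapse_sim` object.
#' @return The KS distance (scalar).
#' @export
sim_ks_distance <- function(sim) {
  stopifnot(inherits(sim, "relapse_sim"))
  x <- sort(sim$replicates$relapse_day[!is.na(sim$replicates$relapse_day)])
  n <- nrow(sim$replicates)
  if (length(x) == 0) return(abs(0))
  Fth <- relapse_cdf(sim$model, x)
  i <- seq_along(x)
  max(abs(Fth - i / n), abs(Fth - (i - 1) / n))
}
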