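test_that("expected seeded counts vanish at zero and saturate after resection", {
  m <- cancer_model("colorectal")
  expect_equal(expected_seeded(m, 0), 0)
  expect_equal(expected_detectable(m, 0), 0)
  Tr <- m$growth$t_resect
  expect_equal(expected_seeded(m, 3 * Tr), expected_seeded(m, Tr))
  # seeding is near certain well before typical colorectal resection sizes
  expect_gt(prob_seeded(m), 0.999)
})

test_that("the hitting-time law is Gumbel-max with the stated mean", {
  m <- cancer_model("colorectal")
  p <- m$params
  mean_theta <- (log(p$M * (1 - p$q)) + 0.57721566) / p$lambda
  expect_equal(mean_first_detection(m)$mean_hitting_days, mean_theta,
               tolerance = 1e-8)
  expect_equal(mean_theta / 365, 5.06, tolerance = 5e-3)  # about five years
  # numerical mean of the CDF agrees with the closed-form moment identity
  t <- seq(0, 8000, by = 1)
  num_mean <- sum(1 - hitting_time_cdf(p, t))  # survival-function sum
  expect_equal(num_mean, mean_theta, tolerance = 1e-3)
  expect_equal(hitting_time_cdf(p, 1e6), 1)
})

test_that("closed-form b_t agrees with quadrature across random parameter sets", {
  for (p in random_params(20, seed = 2203)) {
    m <- relapse_model(p, resect = FALSE)
    t <- relapse_time_grid(p, n = 4)
    t <- t[t > 0]
    expect_equal(expected_detectable(m, t), b_quad_oracle(p, t),
                 tolerance = 1e-7)
    # and with a resection cutting the seeding integral short
    Tr <- t[1] * 0.8
    expect_equal(expected_detectable(m, t, t_resect = Tr),
                 b_quad_oracle(p, t, t_resect = Tr), tolerance = 1e-7)
  }
})

test_that("b_t stays within [0, a_t] and all CDFs are monotone in [0,1]", {
  for (p in random_params(10, seed = 331)) {
    m <- relapse_model(p, resect = FALSE)
    t <- seq(0, 1.3 * mean_relapse_time(p)$mean_days, length.out = 80)
    a <- expected_seeded(m, t)
    b <- expected_detectable(m, t)
    expect_true(all(b >= 0 & b <= a + 1e-12))
    cdf <- relapse_cdf(m, t)
    expect_true(all(cdf >= 0 & cdf <= 1))
    expect_true(all(diff(cdf) >= -1e-12))
  }
})

test_that("the unresected relapse density integrates to one", {
  m <- cancer_model("colorectal", resect = FALSE)
  mu <- mean_relapse_time(m)$mean_days
  sd <- pi / (sqrt(6) * m$params$delta)
  t <- seq(max(0, mu - 8 * sd), mu + 6 * sd, length.out = 3000)
  dens <- numeric_density(function(x) relapse_cdf(m, x), t)
  mass <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(t))
  expect_equal(mass, 1, tolerance = 1e-3)
  expect_true(all(dens >= -1e-12))
})

test_that("the scaled distribution is the large-M limit of the relapse CDF", {
  m <- cancer_model("colorectal", resect = FALSE)
  p <- m$params
  t <- seq(-1500, 6000, length.out = 200)
  shifted <- relapse_cdf(m, pmax(t + log(p$M) / p$lambda, 0))
  expect_lt(max(abs(shifted - scaled_relapse_cdf(m, t))), 1e-3)
})

test_that("equal primary and metastatic rates reduce to the printed simplification", {
  p <- model_params(delta = 0.006, lambda = 0.006, q = 0.9, nu = 1e-9,
                    alpha = 0.06, M = 4.19e6)
  m <- relapse_model(p, resect = FALSE)
  t <- seq(-1000, 3000, length.out = 40)
  # Gamma(1, x) = exp(-x): the scaled CDF collapses to an elementary form
  direct <- -expm1(-p$nu / p$lambda *
                     exp(-(1 - p$q) * exp(-p$lambda * t) + p$lambda * t))
  expect_equal(scaled_relapse_cdf(m, t), direct, tolerance = 1e-12)
})

test_that("general scaled CDF via quadrature equals the incomplete-gamma form", {
  # evaluate the defining integral with a quadrature-only code path by
  # treating the exponential as a logistic with an astronomically large K
  p <- cancer_params("colorectal")
  me <- relapse_model(p, resect = FALSE)
  ml <- relapse_model(p, growth = growth_model("logistic", delta = p$delta,
                                               K = 1e18))
  t <- seq(-1200, 2500, length.out = 25)
  expect_equal(scaled_relapse_cdf(ml, t), scaled_relapse_cdf(me, t),
               tolerance = 1e-7)
})

test_that("the small-nu Gumbel limit brackets and approaches the exact law", {
  p <- cancer_params("colorectal")
  p$nu <- 1e-10
  m <- relapse_model(p, resect = FALSE)
  gum <- small_nu_gumbel(m)
  t <- seq(gum$location - 5 / p$delta, gum$location + 3 / p$delta,
           length.out = 300)
  exact <- scaled_relapse_cdf(m, t)
  limit <- metarelapse:::.pgumbel(t, gum$location, gum$scale)
  expect_lt(max(abs(exact - limit)), 1e-3)

  # the survival-ratio bound: 1 <= S_limit / S_exact <= exp(nu (1-q)/delta)
  p2 <- cancer_params("colorectal")   # realistic nu, looser bound
  m2 <- relapse_model(p2, resect = FALSE)
  gum2 <- small_nu_gumbel(m2)
  t2 <- seq(gum2$location - 4 / p2$delta, gum2$location + 2 / p2$delta,
            length.out = 120)
  ratio <- (1 - scaled_relapse_cdf(m2, t2)) /
    (1 - metarelapse:::.pgumbel(t2, gum2$location, gum2$scale))
  expect_true(all(ratio >= 1 - 1e-10))
  expect_true(all(ratio <= exp(p2$nu * (1 - p2$q) / p2$delta) + 1e-10))
})

test_that("a tenfold initiation rate shifts the Gumbel location by log(10)/delta", {
  p <- cancer_params("breast")
  p10 <- p
  p10$nu <- 10 * p$nu
  shift <- small_nu_gumbel(relapse_model(p))$location -
    small_nu_gumbel(relapse_model(p10))$location
  expect_equal(shift, log(10) / p$delta, tolerance = 1e-12)
  # variance of the limit law is pi^2 / (6 delta^2), independent of nu
  expect_equal(small_nu_gumbel(relapse_model(p))$scale^2 * pi^2 / 6,
               pi^2 / (6 * p$delta^2), tolerance = 1e-12)
})

test_that("mean relapse expansion: constants, log-M linearity, first-seed ordering", {
  m <- cancer_model("colorectal")
  expect_equal(mean_relapse_time(m)$C_days, 250, tolerance = 0.02)
  expect_equal(mean_first_detection(m)$Ctilde_days, 309, tolerance = 0.02)

  pe <- m$params
  pe$M <- exp(1) * m$params$M
  expect_equal(mean_relapse_time(pe)$mean_days -
                 mean_relapse_time(m)$mean_days, 1 / m$params$lambda,
               tolerance = 1e-10)

  # the first-established metastasis is never expected to relapse first
  for (p in random_params(30, seed = 88)) {
    expect_gte(mean_first_detection(p)$mean_days,
               mean_relapse_time(p)$mean_days - 1e-9)
  }
  # lambda = delta makes the two constants coincide
  peq <- model_params(delta = 0.005, lambda = 0.005, q = 0.9, alpha = 0.05,
                      nu = 1e-9)
  expect_equal(mean_first_detection(peq)$Ctilde_days, 0, tolerance = 1e-12)
})

test_that("conditioning on seeding interpolates between hitting and relapse laws", {
  m <- cancer_model("colorectal", resect = FALSE)
  p <- m$params
  mu <- mean_relapse_time(p)$mean_days
  t <- seq(0, mu + 3000, length.out = 250)

  # late resection: conditional law converges to the unconditional one
  late <- conditional_relapse_cdf(m, t, t_resect = years_to_days(50))
  expect_lt(max(abs(late - relapse_cdf(m, t))), 1e-6)

  # immediate resection: the relapse time is a single clone's hitting time
  early <- conditional_relapse_cdf(m, t, t_resect = 1e-3)
  expect_lt(max(abs(early - hitting_time_cdf(p, t))), 1e-3)

  # at t = T the value is P(S_T >= 1) / P(K_T >= 1) by substitution
  Tr <- resection_time_for_size(m$growth, 4.77e10)
  expect_equal(conditional_relapse_cdf(m, Tr, t_resect = Tr),
               prob_synchronous(m, Tr) / prob_seeded(m, Tr),
               tolerance = 1e-12)
})

test_that("the conditional density flips from right- to left-skewed with resection time", {
  m <- cancer_model("colorectal", resect = FALSE)
  skew <- function(Tr) {
    cdf <- function(t) conditional_relapse_cdf(m, t, t_resect = Tr)
    t <- seq(1, mean_relapse_time(m)$mean_days + 9000, length.out = 5000)
    f <- numeric_density(cdf, t)
    w <- f / sum(f)
    mu <- sum(w * t)
    sum(w * (t - mu)^3)
  }
  expect_gt(skew(1e-3), 0)      # early resection: Gumbel-max tail
  expect_lt(skew(6208), 0)      # late resection: Gumbel-min tail
})

test_that("classification probabilities at resection match their definitions", {
  m <- cancer_model("lung")
  expect_equal(100 * prob_synchronous(m), 33.96, tolerance = 2e-3)
  expect_equal(prob_undetectable_only(m),
               prob_seeded(m) - prob_synchronous(m), tolerance = 1e-12)
  # independence splitting: P(M_T >= 1) = 1 - e^{-c_T}
  Tr <- m$growth$t_resect
  expect_equal(prob_metachronous(m),
               -expm1(-(expected_seeded(m, Tr) - expected_detectable(m, Tr))),
               tolerance = 1e-12)
  expect_equal(prob_synchronous(m, t_resect = 1e-6), 0, tolerance = 1e-12)
})

test_that("the disease-free distribution plateaus at the metachronous probability", {
  m <- cancer_model("colorectal")
  Tr <- m$growth$t_resect
  expect_equal(disease_free_cdf(m, Tr), 0)
  plateau <- disease_free_cdf(m, Tr + 40 / m$params$lambda)
  expect_equal(plateau, prob_metachronous(m), tolerance = 1e-9)
  expect_error(disease_free_cdf(m, Tr - 1), "precede")
})

test_that("surgery delay risk is zero at no delay and increases with the delay", {
  m <- cancer_model("colorectal")
  Tr <- resection_time_for_size(m$growth, 2e8)
  expect_equal(surgery_delay_risk(m, Tr, 0), 0)
  risks <- surgery_delay_risk(m, Tr, seq(0, 120, by = 10))
  expect_true(all(diff(risks) > 0))
})

test_that("the logistic regime indicator separates the two growth behaviours", {
  m <- cancer_model("colorectal")
  ind <- logistic_regime_indicator(m, K = 1e12)
  expect_equal(ind, 5.6e3, tolerance = 0.01)
  p_small <- m$params
  p_small$nu <- 1e-14
  expect_lt(logistic_regime_indicator(p_small, K = 1e12), 1)
  expect_equal(logistic_regime_indicator(m, K = 2e12), 2 * ind)
})

test_that("Gumbel moment identities hold for sampled draws", {
  withr::with_seed(99, {
    loc <- 1850; scale <- 151  # hitting-time-like values
    x <- metarelapse:::.rgumbel(1e6, loc, scale)
    expect_equal(mean(x), loc + scale * 0.5772157, tolerance = 1e-3)
    expect_equal(var(x), pi^2 * scale^2 / 6, tolerance = 5e-3)
    # min-type: negative scale flips the skew but keeps the identities
    y <- metarelapse:::.rgumbel(1e6, loc, -scale)
    expect_equal(mean(y), loc - scale * 0.5772157, tolerance = 1e-3)
    expect_equal(var(y), pi^2 * scale^2 / 6, tolerance = 5e-3)
  })
})
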