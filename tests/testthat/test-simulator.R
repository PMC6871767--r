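test_that("seeding is reproducible, empty at nu = 0, and Poisson with mean a_t", {
  m <- cancer_model("colorectal", resect = FALSE)
  set.seed(42)
  s1 <- sample_seeding_times(m, horizon = 6000)
  set.seed(42)
  s2 <- sample_seeding_times(m, horizon = 6000)
  expect_identical(s1, s2)
  expect_true(all(diff(s1) >= 0))

  m0 <- m
  m0$params$nu <- 0
  expect_identical(sample_seeding_times(m0, horizon = 6000), numeric(0))

  # mean count over many replicates matches a_t within 3 standard errors
  withr::with_seed(7, {
    counts <- replicate(4000, length(sample_seeding_times(m, horizon = 6000)))
  })
  a6000 <- expected_seeded(m, 6000)
  se <- sqrt(a6000 / 4000)
  expect_lt(abs(mean(counts) - a6000), 3 * se)
  # resection stops seeding
  mres <- cancer_model("colorectal")
  withr::with_seed(8, {
    smax <- max(sample_seeding_times(mres, horizon = 1e5))
  })
  expect_lte(smax, mres$growth$t_resect)
})

test_that("first seeding times follow the reverse Gumbel law at small nu", {
  p <- cancer_params("colorectal")
  p$nu <- 1e-10
  m <- relapse_model(p, resect = FALSE)
  # horizon with ~6 expected seeds; the truncation mass e^-6 is far below
  # the KS resolution at this replicate count
  withr::with_seed(11, {
    firsts <- replicate(2000, {
      s <- sample_seeding_times(m, horizon = 5800)
      while (length(s) == 0) s <- sample_seeding_times(m, horizon = 5800)
      s[1]
    })
  })
  # sigma_1 ~ Gumbel-min with location log(delta/(nu(1-q)))/delta, scale -1/delta
  loc <- log(p$delta / (p$nu * (1 - p$q))) / p$delta
  ks <- stats::ks.test(firsts, function(x)
    metarelapse:::.pgumbel(x, loc, -1 / p$delta))
  expect_gt(ks$p.value, 0.01)
})

test_that("birth-death extinction frequency and pure-birth splitting time", {
  withr::with_seed(21, {
    bd <- simulate_birth_death(30000, alpha = 0.25, beta = 0.2434,
                               target = 500)
    q <- 0.2434 / 0.25
    se <- sqrt(q * (1 - q) / 30000)
    expect_lt(abs(mean(bd$fate == "extinct") - q), 3 * se)

    # beta = 0, target 2: the first split is exponential with rate alpha
    pb <- simulate_birth_death(20000, alpha = 0.5, beta = 0, target = 2)
    expect_true(all(pb$fate == "detected"))
    expect_lt(abs(mean(pb$time) - 2), 3 * 2 / sqrt(20000))
  })
})

test_that("conditioned hitting times follow the Gumbel-max law", {
  p <- model_params(delta = 0.004, alpha = 0.25, beta = 0.2434, nu = 1e-9,
                    M = 1e4)
  withr::with_seed(31, {
    ht <- sample_hitting_times(2000, p, mode = "hybrid", switch_size = 2000)
  })
  lam <- 0.25 - 0.2434
  loc <- log(1e4 * (1 - 0.9736)) / lam
  ks <- max(abs(
    metarelapse:::.pgumbel(sort(ht$time), loc, 1 / lam) -
      seq_len(2000) / 2000))
  # 0.036 is the 1% Monte-Carlo band at this n; the rest allows for the
  # finite-M error of the asymptotic law
  expect_lt(ks, 0.045)
})

test_that("hybrid hitting sampling agrees with full Gillespie", {
  p <- model_params(delta = 0.004, alpha = 0.25, beta = 0.2434, nu = 1e-9,
                    M = 2000)
  withr::with_seed(41, {
    exact <- sample_hitting_times(2000, p, mode = "exact")
    hybrid <- sample_hitting_times(2000, p, mode = "hybrid",
                                   switch_size = 500)
  })
  ks <- suppressWarnings(stats::ks.test(exact$time, hybrid$time))
  expect_gt(ks$p.value, 0.005)

  # unconditioned fates are unaffected by hybridization
  withr::with_seed(43, {
    f_ex <- sample_hitting_times(6000, p, mode = "exact",
                                 conditioned = FALSE)
    f_hy <- sample_hitting_times(6000, p, mode = "hybrid",
                                 switch_size = 500, conditioned = FALSE)
  })
  pe <- mean(f_ex$fate == "extinct")
  ph <- mean(f_hy$fate == "extinct")
  expect_lt(abs(pe - ph), 3 * sqrt(2 * 0.9736 * 0.0264 / 6000))

  # switch at the target reduces hybrid to the exact sampler
  set.seed(45); a <- sample_hitting_times(50, p, mode = "hybrid",
                                          switch_size = 2000)
  set.seed(45); b <- sample_hitting_times(50, p, mode = "exact")
  expect_equal(a, b)
})

test_that("full runs are seed-deterministic and internally consistent", {
  m <- cancer_model("colorectal", resect = FALSE)
  s1 <- simulate_relapse(m, n_reps = 30, detect_size = 100, seed = 5,
                         keep_details = TRUE)
  s2 <- simulate_relapse(m, n_reps = 30, detect_size = 100, seed = 5,
                         keep_details = TRUE)
  expect_equal(s1$replicates, s2$replicates)

  for (i in seq_len(30)) {
    det <- s1$replicates$details[[i]]
    expect_true(all(diff(det$sigma) >= 0))
    expect_true(all(det$fate %in% c("extinct", "detected")))
    tau_i <- det$sigma + det$theta
    expect_equal(s1$replicates$relapse_day[i],
                 min(tau_i[det$fate == "detected"]))
  }
})

test_that("simulated relapse times match the analytic distribution", {
  m <- cancer_model("colorectal", resect = FALSE)
  sim <- simulate_relapse(m, n_reps = 2000, detect_size = 100, seed = 61,
                          hitting = "exact")
  expect_lt(sim_ks_distance(sim), 0.04)
})

test_that("surviving-thinned and all-clones seeding give the same relapse law", {
  # detection at 500 cells: q^M is then negligible, so the per-clone
  # detection probability matches the 1-q thinning both modes assume
  m <- cancer_model("colorectal", resect = FALSE)
  s_cond <- simulate_relapse(m, n_reps = 1200, detect_size = 500, seed = 71,
                             hitting = "exact")
  s_all <- simulate_relapse(m, n_reps = 1200, detect_size = 500, seed = 72,
                            hitting = "exact", seeding = "all_clones")
  ks <- suppressWarnings(stats::ks.test(s_cond$replicates$relapse_day,
                                        s_all$replicates$relapse_day))
  expect_gt(ks$p.value, 0.001)
  expect_lt(sim_ks_distance(s_all), 0.05)
})

test_that("resection produces cure events with the analytic cure mass", {
  m <- cancer_model("colorectal")
  # resect where the cure probability is appreciable
  m$growth <- set_resection(growth_model("exponential",
                                         delta = m$params$delta),
                            size = 2e8)
  sim <- simulate_relapse(m, n_reps = 1200, detect_size = 1000, seed = 81)
  cure_hat <- mean(is.na(sim$replicates$relapse_day))
  cure_th <- cure_probability(m)
  se <- sqrt(cure_th * (1 - cure_th) / 1200)
  expect_lt(abs(cure_hat - cure_th), 3.5 * se)
})

test_that("doubling the detection size shifts the mean by log(2)/lambda", {
  m <- cancer_model("colorectal", resect = FALSE)
  s1 <- simulate_relapse(m, n_reps = 1500, detect_size = 200, seed = 91)
  s2 <- simulate_relapse(m, n_reps = 1500, detect_size = 400, seed = 92)
  shift <- mean(s2$replicates$relapse_day) - mean(s1$replicates$relapse_day)
  mc_se <- pi / (sqrt(6) * m$params$delta) * sqrt(2 / 1500)
  expect_lt(abs(shift - log(2) / m$params$lambda), 3 * mc_se)
})
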