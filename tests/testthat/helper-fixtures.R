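# Shared fixtures: unrounded parameter chains for the bundled cancer types
# and random parameter draws for property-style tests.

cancer_params <- function(type, dissemination_size = 1e8) {
  inp <- clinical_inputs()
  estimate_parameters(inp[inp$cancer_type == type, ],
                      dissemination_size = dissemination_size)
}

cancer_model <- function(type, resect = TRUE, ...) {
  relapse_model(cancer_params(type, ...), resect = resect)
}

# random supercritical parameter sets covering the clinically relevant
# ranges (delta/lambda in (0.2, 1], q in (0.5, 0.99), nu tiny, M large)
random_params <- function(n, seed = 1405) {
  withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      lambda <- log(2) / runif(1, 40, 200)
      delta <- lambda * runif(1, 0.2, 1)
      q <- runif(1, 0.5, 0.99)
      alpha <- lambda / (1 - q)
      model_params(delta = delta, lambda = lambda, alpha = alpha,
                   nu = 10^runif(1, -12, -8), M = 10^runif(1, 4, 7))
    })
  })
}

# quadrature oracle for b_t, independent of the closed form under test
b_quad_oracle <- function(params, t, t_resect = Inf, rel.tol = 1e-11) {
  p <- params
  G <- function(s) exp(-(1 - p$q) * p$M * exp(-p$lambda * s))
  vapply(t, function(tt) {
    p$nu * (1 - p$q) *
      stats::integrate(function(s) exp(p$delta * s) * G(tt - s),
                       0, min(tt, t_resect), rel.tol = rel.tol,
                       subdivisions = 600L)$value
  }, numeric(1))
}

# times where the relapse distribution has appreciable mass
relapse_time_grid <- function(params, n = 7) {
  mu <- mean_relapse_time(params)$mean_days
  sd <- pi / (sqrt(6) * params$delta)
  seq(mu - 3 * sd, mu + 3 * sd, length.out = n)
}
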