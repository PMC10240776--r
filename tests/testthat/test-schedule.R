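sch <- noise_schedule()

test_that("gamma is linear, strictly increasing, with the configured endpoints", {
  expect_equal(schedule_gamma(sch, 0), sch$gamma_min)
  expect_equal(schedule_gamma(sch, 1), sch$gamma_max)
  expect_gt(schedule_gamma(sch, 0.7), schedule_gamma(sch, 0.3))
  tt <- seq(0, 1, length.out = 101)
  expect_true(all(diff(schedule_gamma(sch, tt)) > 0))
  expect_error(schedule_gamma(sch, -0.1), "0, 1")
  expect_error(schedule_gamma(sch, 1.1), "0, 1")
  expect_error(noise_schedule(gamma_min = -3), "endpoint contract")
  expect_error(noise_schedule(gamma_max = 2), "endpoint contract")
})

test_that("the process is variance preserving and SNR = exp(-gamma)", {
  tt <- c(0, 0.25, 0.5, 0.75, 1)
  as_ <- schedule_alpha_sigma(sch, tt)
  expect_equal(as_$alpha^2 + as_$sigma^2, rep(1, 5), tolerance = 1e-14)
  grid <- seq(0, 1, length.out = 100)
  ag <- schedule_alpha_sigma(sch, grid)
  expect_equal(ag$alpha_sq / ag$sigma_sq, exp(-schedule_gamma(sch, grid)),
               tolerance = 1e-12)
  expect_true(all(diff(schedule_snr(sch, grid)) < 0))
  # gamma(t) = 0 would give alpha = sigma = sqrt(0.5)
  t0 <- -sch$gamma_min / (sch$gamma_max - sch$gamma_min)
  a0 <- schedule_alpha_sigma(sch, t0)
  expect_equal(a0$alpha, sqrt(0.5), tolerance = 1e-12)
  expect_equal(a0$sigma, sqrt(0.5), tolerance = 1e-12)
})

test_that("transition parameters: identity, composition, non-negative variance", {
  tr <- schedule_transition(sch, 0.4, 0.4)
  expect_equal(tr$alpha_ts, 1)
  expect_equal(tr$sigma2_ts, 0)
  expect_error(schedule_transition(sch, 0.6, 0.4), "s <= t")
  set.seed(1)
  for (k in 1:5) {
    rst <- sort(runif(3))
    a_rs <- schedule_transition(sch, rst[1], rst[2])$alpha_ts
    a_st <- schedule_transition(sch, rst[2], rst[3])$alpha_ts
    a_rt <- schedule_transition(sch, rst[1], rst[3])$alpha_ts
    expect_equal(a_rs * a_st, a_rt, tolerance = 1e-12)
    expect_gte(schedule_transition(sch, rst[1], rst[3])$sigma2_ts, 0)
  }
})

test_that("two-step sampling through z_s matches the direct marginal q(z_t|x)", {
  # Monte Carlo marginalization check of the transition decomposition
  set.seed(42)
  n <- 1e5
  for (pair in list(c(0.3, 0.7), c(0.5, 0.9), c(0.1, 0.4))) {
    s <- pair[1]; t <- pair[2]
    x <- 1.7  # scalar coordinate
    as_ <- schedule_alpha_sigma(sch, s)
    at_ <- schedule_alpha_sigma(sch, t)
    tr <- schedule_transition(sch, s, t)
    z_s <- as_$alpha * x + as_$sigma * rnorm(n)
    z_t <- tr$alpha_ts * z_s + sqrt(tr$sigma2_ts) * rnorm(n)
    # q(z_t | x) has mean alpha_t x and variance sigma_t^2
    se_mean <- at_$sigma / sqrt(n)
    expect_lt(abs(mean(z_t) - at_$alpha * x), 3 * se_mean)
    se_var <- at_$sigma_sq * sqrt(2 / (n - 1))
    expect_lt(abs(var(z_t) - at_$sigma_sq), 3 * se_var)
  }
})

test_that("posterior parameters match the Gaussian-conjugacy closed form", {
  # Independent oracle: precision-weighted combination of q(z_s | x) and the
  # likelihood q(z_t | z_s) in one dimension.
  s <- 0.35; t <- 0.8
  as_ <- schedule_alpha_sigma(sch, s)
  at_ <- schedule_alpha_sigma(sch, t)
  tr <- schedule_transition(sch, s, t)
  x1 <- 0.9; z1 <- -0.4
  prec <- 1 / as_$sigma_sq + tr$alpha_ts^2 / tr$sigma2_ts
  mu_oracle <- (as_$alpha * x1 / as_$sigma_sq +
                  tr$alpha_ts * z1 / tr$sigma2_ts) / prec
  sd_oracle <- sqrt(1 / prec)
  post <- schedule_posterior(sch, matrix(z1, 1, 3), matrix(x1, 1, 3), s, t)
  expect_equal(post$mu[1, 1], mu_oracle, tolerance = 1e-10)
  expect_equal(post$sigma_post, sd_oracle, tolerance = 1e-10)
})

test_that("posterior degenerates to z_t as s -> t and keeps the centroid at zero", {
  x <- project_zero_centroid(matrix(rnorm(15), 5, 3))
  z <- project_zero_centroid(matrix(rnorm(15), 5, 3))
  post <- schedule_posterior(sch, z, x, 0.69999, 0.7)
  expect_equal(post$mu, z, tolerance = 1e-3)
  expect_lt(post$sigma_post, 0.01)
  post2 <- schedule_posterior(sch, z, x, 0.2, 0.9)
  expect_centered(post2$mu)
  expect_error(schedule_posterior(sch, z, x[1:4, ], 0.2, 0.9), "shape")
})

test_that("the terminal marginal is indistinguishable from the subspace prior", {
  set.seed(7)
  n_draw <- 1e4
  x <- project_zero_centroid(matrix(rnorm(30, sd = 0.5), 10, 3))
  a1 <- schedule_alpha_sigma(sch, 1)
  # marginal per-coordinate draws of q(z_1 | x) vs the prior, as two samples
  z1 <- replicate(n_draw / 100, a1$alpha * x + a1$sigma *
                    project_zero_centroid(matrix(rnorm(30), 10, 3)))
  prior <- replicate(n_draw / 100,
                     project_zero_centroid(matrix(rnorm(30), 10, 3)))
  ks <- suppressWarnings(ks.test(as.numeric(z1), as.numeric(prior)))
  expect_gt(ks$p.value, 0.01)
})
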