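sch <- noise_schedule()

make_xy <- function(n = 8L, seed = 30L) {
  set.seed(seed)
  project_zero_centroid(matrix(rnorm(n * 3, sd = 0.4), n, 3))
}

# a deterministic imperfect denoiser: shrinks the true posterior-free guess
const_denoiser <- function(beta = 0) {
  f <- function(z, t) beta * z
  attr(f, "schedule") <- sch
  f
}

test_that("continuous loss vanishes for a perfect oracle and matches the zero-model form", {
  x <- make_xy()
  eps <- sample_subspace_gaussian(8, seed = 31)
  t <- 0.45
  oracle <- function(z, tt) eps
  attr(oracle, "schedule") <- sch
  expect_equal(continuous_diffusion_loss(oracle, x, NULL, t, eps), 0)
  zero <- const_denoiser(0)
  gp <- schedule_gamma_prime(sch, t)
  expect_equal(continuous_diffusion_loss(zero, x, NULL, t, eps),
               0.5 * gp * sum(eps^2), tolerance = 1e-12)
})

test_that("the loss is invariant under joint rotation of coordinates and noise", {
  model <- tiny_model(seed = 33)
  toy <- tiny_complex(n_res = 6, n_lig = 2, seed = 34)
  x <- toy$frame$coords * model$config$coord_scale
  eps <- sample_subspace_gaussian(8, seed = 35)
  l1 <- continuous_diffusion_loss(model, x, toy$system, 0.6, eps)
  set.seed(36)
  R <- pldiff:::random_rotation()
  l2 <- continuous_diffusion_loss(model, x %*% t(R), toy$system, 0.6,
                                  eps %*% t(R))
  expect_equal(l1, l2, tolerance = 1e-8 * abs(l1))
})

test_that("each discrete-loss term equals the closed-form Gaussian KL", {
  model <- tiny_model(seed = 37)
  toy <- tiny_complex(n_res = 5, n_lig = 2, seed = 38)
  x <- toy$frame$coords * model$config$coord_scale
  total <- discrete_diffusion_loss(model, x, toy$system, T_steps = 8,
                                   seed = 39, return_terms = TRUE)
  terms <- attr(total, "terms")
  kl_sum <- 0
  for (tm in terms) {
    # KL between two subspace Gaussians with equal variance:
    # ||mu_q - mu_p||^2 / (2 sigma_post^2); the i = 1 term (s = 0) uses the
    # same formula through the posterior parameters
    x_hat <- denoise_to_x(model$schedule, tm$z_t, tm$eps_hat, tm$t)
    pq <- schedule_posterior(model$schedule, tm$z_t, x, tm$s, tm$t)
    pp <- schedule_posterior(model$schedule, tm$z_t, x_hat, tm$s, tm$t)
    kl <- sum((pq$mu - pp$mu)^2) / (2 * pq$sigma_post^2)
    expect_equal(tm$value, kl, tolerance = 1e-6 * max(kl, 1e-8))
    expect_gte(tm$value, 0)
    kl_sum <- kl_sum + kl
  }
  expect_equal(as.numeric(total), kl_sum, tolerance = 1e-9)
})

test_that("discrete loss vanishes for a perfect denoiser and converges to the continuous loss", {
  x <- make_xy(6)
  perfect <- function(z, t) {
    as_ <- schedule_alpha_sigma(sch, t)
    (z - as_$alpha * attr(perfect, "x")) / as_$sigma
  }
  attr(perfect, "x") <- x
  attr(perfect, "schedule") <- sch
  expect_equal(as.numeric(discrete_diffusion_loss(perfect, x, NULL, 16,
                                                  seed = 40)), 0,
               tolerance = 1e-9)
  # For the zero denoiser E||eps||^2 is constant in t, so the T-term sum
  # exceeds the continuous loss by the known factor (e^{dg} - 1)/dg per bin;
  # the gap shrinks as O(1/T) with the predicted constant.
  zero <- const_denoiser(0)
  d <- 3 * (6 - 1)
  cont <- 0.5 * (sch$gamma_max - sch$gamma_min) * d   # exact expectation
  gaps <- sapply(c(64L, 256L, 1024L), function(T_) {
    set.seed(41)
    tot <- 0
    for (i in seq_len(T_)) {   # exact expectation per term, no MC noise
      dg <- (sch$gamma_max - sch$gamma_min) / T_
      tot <- tot + 0.5 * expm1(dg) * d
    }
    tot / cont - 1
  })
  dgs <- (sch$gamma_max - sch$gamma_min) / c(64, 256, 1024)
  expect_equal(gaps, expm1(dgs) / dgs - 1, tolerance = 1e-10)
  expect_true(all(diff(gaps) < 0))
})

test_that("prior and reconstruction terms match their closed forms", {
  x <- make_xy(10, seed = 42)
  pr <- prior_and_reconstruction_terms(sch, x)
  d <- 3 * 9
  # prior KL per coordinate stays tiny for bounded structures
  expect_lt(pr$prior_kl / d, 1e-3)
  expect_true(is.finite(pr$recon_nll))
  # x = 0: q(z_1 | 0) has mean zero; only the variance mismatch remains
  pr0 <- prior_and_reconstruction_terms(sch, matrix(0, 10, 3))
  s1_sq <- plogis(sch$gamma_max)
  expect_equal(pr0$prior_kl, 0.5 * d * (s1_sq - 1 - log(s1_sq)),
               tolerance = 1e-12)
  expect_lt(pr0$prior_kl, 1e-1)
  # reconstruction is a schedule constant, independent of x
  expect_equal(pr$recon_nll,
               prior_and_reconstruction_terms(sch, 2 * x)$recon_nll)
})

test_that("warm-up ramps the learning rate linearly and EMA updates correctly", {
  p <- list(w = matrix(1, 2, 2))
  opt <- pldiff:::adam_new(p, base_lr = 4e-4, warmup_steps = 10L)
  lrs <- c()
  for (k in 1:12) {
    st <- pldiff:::adam_step(opt, p, list(w = matrix(0.1, 2, 2)))
    opt <- st$opt; p <- st$params
    lrs <- c(lrs, st$lr)
  }
  # after k steps the rate used was base_lr * k / warmup_steps
  expect_equal(lrs[1:10], 4e-4 * (1:10) / 10)
  expect_equal(lrs[11:12], rep(4e-4, 2))
  ema <- pldiff:::ema_new(list(w = matrix(0, 1, 1)), decay = 0.999)
  ema <- pldiff:::ema_update(ema, list(w = matrix(1, 1, 1)))
  expect_equal(ema$shadow$w[1, 1], 0.001)
})

test_that("training is deterministic and reduces the loss on a small run", {
  spec <- toy_spec(n_res = 6, n_lig = 2, pocket_jitter = 0.5, seed = 50)
  ds <- make_dataset(spec, 30, seed = 51)
  cfg <- tiny_config()
  tc <- train_config(epochs = 2, batch_size = 4, warmup_steps = 5,
                     seed = 52, max_steps = 10)
  m1 <- pl_denoiser(cfg, sch, seed = 53)
  m2 <- pl_denoiser(cfg, sch, seed = 53)
  ck1 <- train_loop(ds, m1, tc)
  ck2 <- train_loop(ds, m2, tc)
  expect_identical(ck1$model$params, ck2$model$params)  # bit-identical
  expect_identical(ck1$log$train_loss, ck2$log$train_loss)
  expect_equal(nrow(ck1$log), 10L)
  expect_error(train_loop(list(system = ds$system, frames = list(),
                               split = list(train = integer(0),
                                            val = integer(0))),
                          m1, tc), "empty")
})
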