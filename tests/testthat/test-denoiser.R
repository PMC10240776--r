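test_that("residual blocks are the identity at initialization", {
  model <- pl_denoiser(tiny_config(), noise_schedule(), seed = 2)  # zero-init outputs
  toy <- tiny_complex()
  set.seed(6)
  reps <- list(single = matrix(rnorm(11 * 16), 11, 16),
               pair = matrix(rnorm(121 * 8), 121, 8))
  out <- trunk_update(model, reps)
  expect_equal(out$single, reps$single, tolerance = 1e-12)
  expect_equal(out$pair, reps$pair, tolerance = 1e-12)
})

test_that("trunk output shapes match input shapes and activations stay finite", {
  model <- tiny_model()
  for (n in c(4L, 9L)) {
    set.seed(n)
    reps <- list(single = matrix(rnorm(n * 16), n, 16),
                 pair = matrix(rnorm(n * n * 8), n * n, 8))
    out <- trunk_update(model, reps)
    expect_identical(dim(out$single), dim(reps$single))
    expect_identical(dim(out$pair), dim(reps$pair))
    expect_true(all(is.finite(out$single)))
    expect_true(all(is.finite(out$pair)))
  }
})

test_that("trunk is equivariant under token permutation", {
  model <- tiny_model(seed = 4)
  n <- 6L
  set.seed(8)
  reps <- list(single = matrix(rnorm(n * 16), n, 16),
               pair = matrix(rnorm(n * n * 8), n * n, 8))
  perm <- c(1L, 2L, 4L, 3L, 6L, 5L)   # swap two pairs of tokens
  pair_rows <- function(p) as.vector(outer(p, p, function(i, j) (j - 1L) * n + i))
  reps_p <- list(single = reps$single[perm, ],
                 pair = reps$pair[pair_rows(perm), ])
  out <- trunk_update(model, reps)
  out_p <- trunk_update(model, reps_p)
  expect_equal(out_p$single, out$single[perm, ], tolerance = 1e-10)
  expect_equal(out_p$pair, out$pair[pair_rows(perm), ], tolerance = 1e-10)
})

test_that("the head computes the weighted relative-difference sum exactly", {
  # force a constant weight matrix: zero hidden layer, bias w on the output
  w <- 0.7
  model <- tiny_model(seed = 5)
  model$params[["head.W1"]][] <- 0
  model$params[["head.b1"]][] <- 0
  model$params[["head.W2"]][] <- 0
  model$params[["head.b2"]][] <- w
  lig <- ligand_graph(data.frame(atomic_number = 6))
  sys <- build_system("M", lig)   # 2 tokens
  z <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  out <- predict_noise(model, z, sys, 0.5)
  expect_equal(out$W, matrix(c(0, w, w, 0), 2, 2))
  expect_equal(out$eps_hat,
               matrix(c(-w, 0, 0, w, 0, 0), 2, 3, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("coincident atoms never divide by zero", {
  model <- tiny_model(seed = 6)
  lig <- ligand_graph(data.frame(atomic_number = c(6, 6)))
  sys <- build_system("MA", lig)
  z <- matrix(0, 4, 3)  # all atoms coincident
  out <- predict_noise(model, z, sys, 0.9)
  expect_true(all(is.finite(out$eps_hat)))
})

test_that("predict_noise is SE(3)-equivariant and centroid-free", {
  model <- tiny_model(seed = 7)
  set.seed(17)
  for (k in 1:5) {
    toy <- tiny_complex(n_res = 5 + k, n_lig = 2 + (k %% 3), seed = 40 + k)
    z <- toy$frame$coords * model$config$coord_scale
    out <- predict_noise(model, z, toy$system, runif(1))
    expect_centered(out$eps_hat, tol = 1e-10)
    R <- pldiff:::random_rotation(); tau <- rnorm(3)
    z2 <- sweep(z %*% t(R), 2, tau, "+")
    out2 <- predict_noise(model, z2, toy$system, 0.5)
    out1 <- predict_noise(model, z, toy$system, 0.5)
    rel <- norm(out2$eps_hat - out1$eps_hat %*% t(R), "F") /
      norm(out1$eps_hat, "F")
    expect_lt(rel, 1e-8)
  }
})

test_that("translating the latent leaves the prediction unchanged", {
  model <- tiny_model(seed = 8)
  toy <- tiny_complex()
  z <- toy$frame$coords * model$config$coord_scale
  out1 <- predict_noise(model, z, toy$system, 0.3)
  out2 <- predict_noise(model, sweep(z, 2, c(5, -3, 1), "+"), toy$system, 0.3)
  expect_equal(out1$eps_hat, out2$eps_hat, tolerance = 1e-9)
})

test_that("denoise_to_x inverts the forward map and is affine", {
  sch <- noise_schedule()
  set.seed(9)
  x <- project_zero_centroid(matrix(rnorm(18), 6, 3))
  eps <- sample_subspace_gaussian(6, seed = 10)
  t <- 0.55
  as_ <- schedule_alpha_sigma(sch, t)
  z <- as_$alpha * x + as_$sigma * eps
  expect_equal(denoise_to_x(sch, z, eps, t), x, tolerance = 1e-10)
  expect_equal(denoise_to_x(sch, z, 0 * eps, t), z / as_$alpha,
               tolerance = 1e-12)
  # affine superposition in (z, eps)
  z2 <- project_zero_centroid(matrix(rnorm(18), 6, 3))
  e2 <- sample_subspace_gaussian(6, seed = 11)
  lhs <- denoise_to_x(sch, 0.3 * z + 0.7 * z2, 0.3 * eps + 0.7 * e2, t)
  rhs <- 0.3 * denoise_to_x(sch, z, eps, t) + 0.7 * denoise_to_x(sch, z2, e2, t)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("analytic parameter gradients match finite differences", {
  model <- tiny_model(seed = 12)
  toy <- tiny_complex(n_res = 5, n_lig = 2, seed = 14)
  feat <- pldiff:::sys_features(toy$system)
  z <- toy$frame$coords * model$config$coord_scale
  eps <- sample_subspace_gaussian(7, seed = 15)
  set.seed(16)
  h <- 1e-5
  for (nat in c(FALSE, TRUE)) {   # R reference path and compiled path
    lg <- pldiff:::loss_and_grad(model, feat, z, 0.4, eps, native = nat)
    for (nm in sample(names(model$params), 8)) {
      i <- sample(length(model$params[[nm]]), 1)
      mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + h
      mm <- model; mm$params[[nm]][i] <- mm$params[[nm]][i] - h
      num <- (pldiff:::loss_and_grad(mp, feat, z, 0.4, eps,
                                     native = nat)$loss -
                pldiff:::loss_and_grad(mm, feat, z, 0.4, eps,
                                       native = nat)$loss) / (2 * h)
      ana <- lg$grads[[nm]][i]
      expect_equal(ana, num, tolerance = 1e-4,
                   label = sprintf("grad of %s[%d] (native=%s)", nm, i, nat))
    }
  }
})

test_that("template conditioning is off by default, distance-only when on", {
  toy <- tiny_complex(n_res = 6, n_lig = 2, seed = 18)
  n <- toy$system$n_tokens
  set.seed(19)
  reps <- list(single = matrix(rnorm(n * 16), n, 16),
               pair = matrix(rnorm(n * n * 8), n * n, 8))
  m_off <- tiny_model(seed = 20)
  expect_identical(apply_template(m_off, reps, matrix(0, 6, 3), 6), reps)
  m_on <- tiny_model(seed = 20,
                     cfg = tiny_config(template_conditioning = "backbone"))
  tmpl <- toy$frame$coords[toy$frame$roles == "protein", ]
  r1 <- apply_template(m_on, reps, tmpl, 6)
  expect_false(identical(r1$pair, reps$pair))
  # rigidly moving the template changes nothing (distances only)
  r2 <- apply_template(m_on, reps, rigid_move(tmpl, 3), 6)
  expect_equal(r1$pair, r2$pair, tolerance = 1e-9)
  # ligand blocks untouched
  ii <- rep(seq_len(n), times = n); jj <- rep(seq_len(n), each = n)
  lig_rows <- which(ii > 6 | jj > 6)
  expect_equal(r1$pair[lig_rows, ], reps$pair[lig_rows, ])
  expect_error(apply_template(m_on, reps, tmpl[1:3, ], 6), "one coordinate row")
})
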