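sch <- noise_schedule()

test_that("the two algebraic forms of the ancestral mean agree to machine precision", {
  model <- tiny_model(seed = 60)
  toy <- tiny_complex(n_res = 6, n_lig = 2, seed = 61)
  feat <- pldiff:::sys_features(toy$system)
  z <- sample_subspace_gaussian(8, seed = 62)
  for (st in list(c(0.2, 0.4), c(0.5, 0.52), c(0.9, 1.0))) {
    s <- st[1]; t <- st[2]
    eh <- predict_noise(model, z, feat, t)$eps_hat
    x_hat <- denoise_to_x(model$schedule, z, eh, t)
    mu_posterior <- schedule_posterior(model$schedule, z, x_hat, s, t)$mu
    z_s <- ancestral_step(model, z, feat, s, t, matrix(0, 8, 3))
    expect_equal(z_s, mu_posterior, tolerance = 1e-12)
  }
})

test_that("ancestral step reduces to pure rescaling for a zero denoiser", {
  zero <- function(z, t) 0 * z
  attr(zero, "schedule") <- sch
  z <- sample_subspace_gaussian(5, seed = 63)
  tr <- schedule_transition(sch, 0.3, 0.6)
  z_s <- ancestral_step(zero, z, NULL, 0.3, 0.6, matrix(0, 5, 3))
  expect_equal(z_s, z / tr$alpha_ts, tolerance = 1e-12)
  expect_centered(ancestral_step(zero, z, NULL, 0.3, 0.6,
                                 sample_subspace_gaussian(5, seed = 64)))
  expect_error(ancestral_step(zero, z, NULL, 0.6, 0.3, 0 * z), "s < t")
})

test_that("sampling a 1-token system returns the origin", {
  lig <- ligand_graph(data.frame(atomic_number = 6))
  sys <- structure(list(sequence = "", residue_index = integer(0),
                        ligand = lig, n_res = 0L, n_lig = 1L, n_tokens = 1L,
                        roles = "ligand"), class = "molecular_system")
  zero <- function(z, t) 0 * z
  attr(zero, "schedule") <- sch
  attr(zero, "coord_scale") <- 1
  fr <- sample_structure(zero, sys, sampler_config(n_steps = 5, seed = 1))
  expect_equal(fr$coords, matrix(0, 1, 3))
})

test_that("sampling is deterministic in (seed, sample_index) and varies across indices", {
  model <- tiny_model(seed = 65)
  toy <- tiny_complex(n_res = 5, n_lig = 2, seed = 66)
  cfg <- sampler_config(n_steps = 8, n_samples = 2, seed = 7)
  f1 <- sample_structure(model, toy$system, cfg, sample_index = 1)
  f1b <- sample_structure(model, toy$system, cfg, sample_index = 1)
  f2 <- sample_structure(model, toy$system, cfg, sample_index = 2)
  expect_identical(f1$coords, f1b$coords)
  expect_false(identical(f1$coords, f2$coords))
})

test_that("the sampler recovers a point-mass target with the oracle denoiser", {
  toy <- tiny_complex(n_res = 8, n_lig = 3, seed = 67)
  x_star <- toy$frame$coords * 0.1
  oracle <- oracle_denoiser(x_star, sch)
  fr <- sample_structure(oracle, toy$system, sampler_config(n_steps = 250,
                                                            seed = 11))
  fit <- kabsch_superpose(fr$coords, x_star)
  # 0.1 A in angstroms = 0.01 in the scaled units the oracle works in
  expect_lt(fit$rmsd, 0.01)
})

test_that("ensembles carry the requested number of centered frames and seeds", {
  model <- tiny_model(seed = 68)
  toy <- tiny_complex(n_res = 5, n_lig = 2, seed = 69)
  ens <- generate_ensemble(model, toy$system,
                           sampler_config(n_steps = 4, n_samples = 6, seed = 3))
  expect_length(ens$frames, 6L)
  expect_length(unique(ens$seeds), 6L)
  for (fr in ens$frames) expect_centered(fr$coords, tol = 1e-6)
})

test_that("the sampled distribution is rotationally symmetric on average", {
  # no structural input in sequence-only mode: the second-moment tensor of
  # generated coordinates must be isotropic up to Monte Carlo error
  toy <- tiny_complex(n_res = 6, n_lig = 2, seed = 70)
  x_star <- toy$frame$coords * 0.1
  oracle <- oracle_denoiser(x_star, sch)
  ens <- generate_ensemble(oracle, toy$system,
                           sampler_config(n_steps = 20, n_samples = 200,
                                          seed = 5))
  M <- matrix(0, 3, 3)
  for (fr in ens$frames) M <- M + crossprod(fr$coords) / length(ens$frames)
  evs <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  expect_lt((max(evs) - min(evs)) / mean(evs), 0.35)
})
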