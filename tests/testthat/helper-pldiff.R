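# Shared fixtures: a tiny model configuration and toy systems, built in code.

tiny_config <- function(...) {
  denoiser_config(n_blocks = 1L, c_s = 16L, c_p = 8L, n_heads = 2L,
                  c_outer = 4L, c_tri = 4L, c_head = 8L, n_rbf = 8L,
                  d_time = 8L, ...)
}

# A model whose residual output projections are randomized (they are
# zero-initialized, which would make many properties hold trivially).
tiny_model <- function(seed = 1L, cfg = tiny_config(), sd = 0.1) {
  model <- pl_denoiser(cfg, noise_schedule(), seed = seed)
  set.seed(seed + 1000L)
  for (nm in names(model$params))
    if (grepl("(Wo|W2|Wzo)$", nm))
      model$params[[nm]][] <- rnorm(length(model$params[[nm]]), sd = sd)
  model
}

tiny_complex <- function(n_res = 8L, n_lig = 3L, seed = 3L, jitter = 0.5) {
  make_toy_complex(toy_spec(n_res = n_res, n_lig = n_lig,
                            pocket_jitter = jitter, seed = seed))
}

expect_centered <- function(coords, tol = 1e-8) {
  expect_lt(max(abs(colMeans(coords))), tol)
}

rigid_move <- function(coords, seed = 1L) {
  set.seed(seed)
  R <- pldiff:::random_rotation()
  tau <- rnorm(3, sd = 5)
  sweep(coords %*% t(R), 2L, tau, "+")
}
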