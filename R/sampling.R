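# Ancestral sampling of complex structures from the trained denoiser.
#
# Time is discretized uniformly into T steps; the latent is initialized from
# the standard subspace Gaussian at t = 1 and walked backward with the
# learned reverse transitions. The final output is the mean of p(x | z_0)
# (z_0 / alpha_0): sigma_0 is negligible by the endpoint contract, and
# returning the mean makes sampling deterministic given the seeds.

#' Sampler configuration
#'
#' @param n_steps Number of ancestral steps `T` (uniform time grid).
#' @param n_samples Ensemble size (64 structures per complex in the benchmark
#'   protocol).
#' @param seed Base seed; each frame uses a seed derived from
#'   `(seed, sample_index)`.
#' @param use_ema Sample with the EMA shadow parameters when available.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_steps = 250L, n_samples = 64L, seed = 1L,
                           use_ema = TRUE) {
  stopifnot(n_steps >= 1L, n_samples >= 1L)
  structure(list(n_steps = as.integer(n_steps),
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 use_ema = isTRUE(use_ema)),
            class = "sampler_config")
}

frame_seed <- function(seed, sample_index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(sample_index) * 16807) %%
               2147483647)
}

#' One ancestral denoising step
#'
#' Draws `z_s ~ p(z_s | z_t)`:
#' `z_s = z_t / alpha_{t|s} - (sigma_{t|s}^2 / (alpha_{t|s} sigma_t)) *
#' eps_hat + sigma_{t->s} * noise`. Algebraically identical to the forward
#' posterior mean with the clean coordinates replaced by the denoised
#' estimate.
#'
#' @param model A [pl_denoiser()] or a function `(z, t) -> eps_hat` carrying
#'   a `schedule` attribute.
#' @param z_t Current latent (`N x 3`, zero centroid, diffusion units).
#' @param system System or feature cache.
#' @param s,t Times with `s < t`.
#' @param noise `N x 3` subspace Gaussian draw (zero matrix for the
#'   noise-free mean step).
#' @param use_ema Use EMA parameters if present.
#' @return `z_s` (`N x 3`).
#' @export
ancestral_step <- function(model, z_t, system, s, t, noise, use_ema = FALSE) {
  sch <- if (is.function(model)) attr(model, "schedule") else model$schedule
  if (s >= t) stop("ancestral step requires s < t")
  eps_hat <- eval_denoiser(model, z_t, system, t, use_ema = use_ema)
  tr <- schedule_transition(sch, s, t)
  at_ <- schedule_alpha_sigma(sch, t)
  as_ <- schedule_alpha_sigma(sch, s)
  sigma_ts <- sqrt(tr$sigma2_ts) * as_$sigma / at_$sigma
  z_s <- z_t / tr$alpha_ts -
    (tr$sigma2_ts / (tr$alpha_ts * at_$sigma)) * eps_hat +
    sigma_ts * noise
  if (!all(is.finite(z_s)))
    stop(sprintf("non-finite latent in ancestral step at t = %.4f", t))
  z_s
}

#' Sample one complex structure
#'
#' Initializes `z_1` from the subspace prior and runs `n_steps` ancestral
#' steps down the uniform grid `t = i/T`, returning `x = z_0 / alpha_0` (the
#' mean of the reconstruction distribution; no final noise injection).
#' Deterministic given `(config$seed, sample_index)`.
#'
#' @param model A [pl_denoiser()] or denoiser function with a `schedule`
#'   attribute.
#' @param system A [build_system()] result.
#' @param config A [sampler_config()].
#' @param sample_index Index of the frame within the ensemble.
#' @param plm,template Optional conditioning inputs (see [predict_noise()]).
#' @return A centered [coordinate_frame()] in angstroms.
#' @export
sample_structure <- function(model, system, config = sampler_config(),
                             sample_index = 1L, plm = NULL, template = NULL) {
  sch <- if (is.function(model)) attr(model, "schedule") else model$schedule
  coord_scale <- if (is.function(model)) attr(model, "coord_scale") %||% 1
                 else model$config$coord_scale
  feat <- sys_features(system)
  n <- feat$n
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(frame_seed(config$seed, sample_index))
  z <- sample_subspace_gaussian(n)
  T_ <- config$n_steps
  use_ema <- config$use_ema
  m <- model
  if (!is.function(model) && use_ema && !is.null(model$best_ema))
    m$params <- model$best_ema
  fn <- if (is.function(m)) m else {
    f <- function(z, t)
      predict_noise(m, z, feat, t, plm = plm, template = template)$eps_hat
    attr(f, "schedule") <- sch
    f
  }
  for (i in rev(seq_len(T_))) {
    s <- (i - 1) / T_; t <- i / T_
    noise <- sample_subspace_gaussian(n)
    z <- ancestral_step(fn, z, feat, s, t, noise)
  }
  a0 <- schedule_alpha_sigma(sch, 0)$alpha
  x <- z / a0 / coord_scale
  coordinate_frame(x, feat$roles, center = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a structure ensemble
#'
#' `n_samples` statistically independent frames for one system, with the
#' per-frame seeds recorded.
#'
#' @inheritParams sample_structure
#' @return A `structure_ensemble`: list with `system`, `frames`, `seeds`,
#'   `config`.
#' @export
generate_ensemble <- function(model, system, config = sampler_config(),
                              plm = NULL, template = NULL) {
  frames <- vector("list", config$n_samples)
  seeds <- integer(config$n_samples)
  for (k in seq_len(config$n_samples)) {
    frames[[k]] <- sample_structure(model, system, config, k,
                                    plm = plm, template = template)
    seeds[k] <- frame_seed(config$seed, k)
  }
  structure(list(system = system, frames = frames, seeds = seeds,
                 config = config),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble %d frames of %d atoms>\n",
              length(x$frames), x$system$n_tokens))
  invisible(x)
}

#' Closed-form oracle denoiser for a point-mass data distribution
#'
#' For data concentrated on a single centered configuration `x_star`, the
#' posterior-optimal noise prediction (up to the global rotation left
#' unresolved by an equivariant model) is
#' `eps = (z_t - alpha_t R_hat x_star) / sigma_t`, where `R_hat` superposes
#' `x_star` onto `z_t / alpha_t`. Used to validate the sampler independently
#' of any trained network.
#'
#' @param x_star Target configuration (`N x 3`, zero centroid, diffusion
#'   units).
#' @param schedule A [noise_schedule()].
#' @return A function `(z, t) -> eps_hat` carrying the schedule as an
#'   attribute (directly usable by [sample_structure()]).
#' @export
oracle_denoiser <- function(x_star, schedule) {
  x_star <- project_zero_centroid(as.matrix(x_star))
  f <- function(z, t) {
    as_ <- schedule_alpha_sigma(schedule, t)
    fit <- kabsch_superpose(x_star, z / as_$alpha)
    x_aligned <- fit$transform(x_star)
    (z - as_$alpha * x_aligned) / as_$sigma
  }
  attr(f, "schedule") <- schedule
  attr(f, "coord_scale") <- 1
  f
}
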