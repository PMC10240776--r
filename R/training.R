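# Training: the variational diffusion objective and the optimization loop.
#
# The model is trained on the continuous-time diffusion loss
#   L = 1/2 * gamma'(t) * || eps - eps_hat(z_t; t) ||^2,
# with t ~ Uniform(0,1) and z_t = alpha_t x + sigma_t eps, estimated by Monte
# Carlo. The discrete T-term sum is provided as a cross-check: each term is a
# closed-form Gaussian KL between the forward posterior and the model's
# reverse transition, with weight SNR(s)/SNR(t) - 1 = exp(gamma(t)-gamma(s)) - 1.
# Prior and reconstruction terms contain no learnable parameters and are
# reported as diagnostics only.

#' Training configuration
#'
#' Defaults follow the protocol standard for this model family (Adam with base learning rate
#' 4e-4, beta1 0.9, beta2 0.999, eps 1e-8, linear warm-up over the first 1000
#' steps, EMA decay 0.999); the batch size defaults to the desk-scale 4
#' rather than the corpus-scale 24.
#'
#' @param base_lr Base learning rate after warm-up.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decays and epsilon.
#' @param warmup_steps Linear warm-up length in optimizer steps (`>= 1`).
#' @param batch_size Frames per optimization step.
#' @param epochs Passes over the training frames.
#' @param max_steps Optional hard cap on optimizer steps.
#' @param ema_decay Decay of the parameter exponential moving average.
#' @param seed RNG seed for batching, time and noise draws.
#' @param val_seed Base seed of the fixed validation noise (one derived seed
#'   per validation frame, so model selection is not dominated by estimator
#'   variance).
#' @return A `train_config` list.
#' @export
train_config <- function(base_lr = 4e-4, adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8, warmup_steps = 1000L,
                         batch_size = 4L, epochs = 10L, max_steps = NULL,
                         ema_decay = 0.999, seed = 1L, val_seed = 777L) {
  stopifnot(warmup_steps >= 1L, ema_decay > 0, ema_decay < 1, batch_size >= 1L)
  structure(list(base_lr = base_lr, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, adam_eps = adam_eps,
                 warmup_steps = as.integer(warmup_steps),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps),
                 ema_decay = ema_decay, seed = as.integer(seed),
                 val_seed = as.integer(val_seed)),
            class = "train_config")
}

# Loss and parameter gradients for one (frame, t, eps) draw.
# x, eps in diffusion units; loss averaged over atoms. The compiled core is
# the default; the R reference path remains for cross-checks.
loss_and_grad <- function(model, feat, x, t, eps, average_atoms = TRUE,
                          native = TRUE) {
  sch <- model$schedule
  as_ <- schedule_alpha_sigma(sch, t)
  gp <- schedule_gamma_prime(sch, t)
  if (native) {
    out <- .cpp_loss_grad(model$params, unclass(model$config), feat$single,
                          feat$pair, x, eps, as_$alpha, as_$sigma, gp,
                          time_embedding(t, model$config$d_time),
                          average_atoms)
    return(list(loss = out$loss, grads = out$grads))
  }
  z <- as_$alpha * x + as_$sigma * eps
  fw <- model_forward(model, feat, z, t, want_cache = TRUE)
  r <- fw$eps_hat - eps
  scale <- if (average_atoms) 1 / nrow(x) else 1
  loss <- 0.5 * gp * sum(r^2) * scale
  if (!is.finite(loss)) stop("non-finite diffusion loss (model output diverged)")
  grads <- model_backward(model, fw$cache, (gp * scale) * r)
  list(loss = loss, grads = grads)
}

#' Continuous-time diffusion loss (Monte Carlo estimator)
#'
#' `1/2 * gamma'(t) * ||eps - eps_hat(z_t; t)||^2` with
#' `z_t = alpha_t x + sigma_t eps`. The caller supplies `t` (drawn uniform on
#' (0,1) during training) and the subspace noise draw.
#'
#' @param model A [pl_denoiser()] (or a function `(z, t) -> eps_hat` for
#'   oracle checks).
#' @param x Clean coordinates (`N x 3`, zero centroid, diffusion units).
#' @param system A [build_system()] result or feature cache.
#' @param t Scalar time in `[0, 1]`.
#' @param noise `N x 3` subspace Gaussian draw.
#' @param average_atoms Divide by the atom count (the per-system weighting
#'   used for training); `FALSE` gives the plain squared norm form.
#' @return Scalar loss.
#' @export
continuous_diffusion_loss <- function(model, x, system, t, noise,
                                      average_atoms = FALSE) {
  sch <- if (is.function(model)) attr(model, "schedule") else model$schedule
  if (is.null(sch)) stop("denoiser carries no schedule")
  as_ <- schedule_alpha_sigma(sch, t)
  gp <- schedule_gamma_prime(sch, t)
  z <- as_$alpha * x + as_$sigma * noise
  eps_hat <- eval_denoiser(model, z, system, t)
  scale <- if (average_atoms) 1 / nrow(x) else 1
  0.5 * gp * sum((noise - eps_hat)^2) * scale
}

# Evaluate either a pl_denoiser or a plain function denoiser.
eval_denoiser <- function(model, z, system, t, use_ema = FALSE) {
  if (is.function(model)) return(model(z, t))
  feat <- if (inherits(system, "molecular_system")) sys_features(system)
          else system
  predict_noise(model, z, feat, t, use_ema = use_ema)$eps_hat
}

#' Discrete T-term diffusion loss
#'
#' The sum over `i = 1..T` of
#' `1/2 * (SNR(s) / SNR(t) - 1) * ||eps - eps_hat(z_t; t)||^2` with
#' `s = (i-1)/T`, `t = i/T` and one fresh subspace noise draw per term. Each
#' term equals the Gaussian KL divergence between the forward posterior
#' `q(z_s | z_t, x)` and the model reverse transition on the zero-centroid
#' subspace; its expectation converges to the continuous-time loss as `T`
#' grows.
#'
#' @param model A [pl_denoiser()] or denoiser function.
#' @param x Clean coordinates (`N x 3`, zero centroid, diffusion units).
#' @param system System or feature cache.
#' @param T_steps Number of time bins (`>= 1`).
#' @param seed Seed for the per-term noise draws.
#' @param return_terms If `TRUE`, attach a per-term data list (times, noise,
#'   latents, predictions) for term-by-term cross-checks.
#' @return Scalar loss (with attribute `terms` when requested).
#' @export
discrete_diffusion_loss <- function(model, x, system, T_steps, seed = 1L,
                                    return_terms = FALSE) {
  stopifnot(T_steps >= 1L)
  sch <- if (is.function(model)) attr(model, "schedule") else model$schedule
  if (is.null(sch)) stop("denoiser carries no schedule")
  feat <- if (inherits(system, "molecular_system")) sys_features(system)
          else system
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  total <- 0
  terms <- if (return_terms) vector("list", T_steps) else NULL
  for (i in seq_len(T_steps)) {
    s <- (i - 1) / T_steps; t <- i / T_steps
    gs <- schedule_gamma(sch, s); gt <- schedule_gamma(sch, t)
    w <- expm1(gt - gs)                      # SNR(s)/SNR(t) - 1
    eps <- sample_subspace_gaussian(nrow(x))
    as_ <- schedule_alpha_sigma(sch, t)
    z <- as_$alpha * x + as_$sigma * eps
    eps_hat <- eval_denoiser(model, z, feat, t)
    term <- 0.5 * w * sum((eps - eps_hat)^2)
    total <- total + term
    if (return_terms)
      terms[[i]] <- list(i = i, s = s, t = t, eps = eps, z_t = z,
                         eps_hat = eps_hat, value = term)
  }
  if (return_terms) attr(total, "terms") <- terms
  total
}

#' Prior and reconstruction terms of the variational bound
#'
#' Closed forms on the zero-centroid subspace (dimension `3(N-1)`); both are
#' free of learnable parameters and reported as diagnostics only, never
#' backpropagated. The prior term is
#' `KL[q(z_1|x) || N_x(0, I)] = 1/2 (alpha_1^2 ||x||^2 + d (sigma_1^2 - 1 -
#' log sigma_1^2))`; the reconstruction term is
#' `E[-log p(x | z_0)] = d/2 (log(2 pi sigma_0^2 / alpha_0^2) + 1)`.
#'
#' @param schedule A [noise_schedule()].
#' @param x Clean coordinates (`N x 3`, zero centroid, diffusion units).
#' @return A list with `prior_kl` and `recon_nll` (nats).
#' @export
prior_and_reconstruction_terms <- function(schedule, x) {
  x <- as.matrix(x)
  d <- 3 * (nrow(x) - 1L)
  g0 <- schedule_gamma(schedule, 0); g1 <- schedule_gamma(schedule, 1)
  s1_sq <- stats::plogis(g1); a1_sq <- stats::plogis(-g1)
  s0_sq <- stats::plogis(g0); a0_sq <- stats::plogis(-g0)
  prior_kl <- 0.5 * (a1_sq * sum(x^2) + d * (s1_sq - 1 - log(s1_sq)))
  recon_nll <- 0.5 * d * (log(2 * pi * s0_sq / a0_sq) + 1)
  list(prior_kl = prior_kl, recon_nll = recon_nll)
}

#' Train the denoiser
#'
#' Adam with linear learning-rate warm-up; an EMA shadow of the parameters is
#' updated after every step, and the shadow snapshot at the best validation
#' loss is retained for inference. Validation uses fixed per-frame noise and
#' time draws. Coordinates are scaled by `config$coord_scale` of the model
#' before diffusion. Fully deterministic given the seeds.
#'
#' @param dataset A [make_dataset()] result (fields `system`, `frames`,
#'   `split`), or a list of `list(system, frame)` entries with an 80/20
#'   index split applied.
#' @param model A [pl_denoiser()].
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return A `pl_checkpoint`: the trained model (with `ema` and `best_ema`
#'   attached), the configs, and a training log data.frame with columns
#'   `step`, `lr`, `train_loss`, `val_loss`.
#' @export
train_loop <- function(dataset, model, config = train_config(),
                       verbose = FALSE) {
  entries <- normalize_dataset(dataset)
  if (length(entries$train) == 0L) stop("empty training dataset")
  cfg <- model$config
  feats <- lapply(entries$systems, sys_features)
  for (f in feats)
    if (f$n > cfg$max_tokens)
      stop("training system exceeds max_tokens")
  xs <- lapply(seq_along(entries$frames), function(k)
    entries$frames[[k]]$coords * cfg$coord_scale)
  sys_of <- entries$sys_of
  sch <- model$schedule
  ucfg <- unclass(cfg)
  proto <- model$params
  # optimizer and EMA state kept as flat vectors, updated in place by the
  # compiled core; snapshots are deep-copied before any in-place update
  pflat <- as.numeric(unlist(model$params, use.names = FALSE))
  opt <- list(m = 0 * pflat, v = 0 * pflat, step = 0L)
  ema_flat <- pflat + 0
  # fixed per-frame validation draws (times, noise)
  val_draws <- lapply(entries$val, function(k) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    set.seed(config$val_seed + k)
    t <- stats::runif(1)
    eps <- sample_subspace_gaussian(nrow(xs[[k]]))
    restore_rng(old)
    list(k = k, t = t, eps = eps)
  })
  val_loss_fn <- function(pf) {
    if (length(val_draws) == 0L) return(NA_real_)
    # single-system datasets evaluate in one compiled call
    ks <- vapply(val_draws, `[[`, 1L, "k")
    if (length(unique(sys_of[ks])) == 1L) {
      f <- feats[[sys_of[ks[1L]]]]
      ts <- vapply(val_draws, `[[`, 1.0, "t")
      as_ <- schedule_alpha_sigma(sch, ts)
      tembs <- t(vapply(ts, time_embedding, numeric(cfg$d_time),
                        dim = cfg$d_time))
      return(.cpp_loss_batch_flat(pf, proto, ucfg, f$single, f$pair,
                                  xs[ks], lapply(val_draws, `[[`, "eps"),
                                  as_$alpha, as_$sigma,
                                  schedule_gamma_prime(sch, ts), tembs,
                                  TRUE))
    }
    m <- model; m$params <- unflatten_params(pf, proto)
    tot <- 0
    for (d in val_draws)
      tot <- tot + continuous_diffusion_loss(m, xs[[d$k]],
                                             feats[[sys_of[d$k]]], d$t,
                                             d$eps, average_atoms = TRUE)
    tot / length(val_draws)
  }
  init_val <- val_loss_fn(pflat)
  best_val <- init_val
  best_ema <- ema_flat + 0
  n_cap <- if (is.null(config$max_steps)) {
    config$epochs * ceiling(length(entries$train) / config$batch_size)
  } else config$max_steps
  log_step <- integer(n_cap); log_lr <- numeric(n_cap)
  log_train <- numeric(n_cap); log_val <- rep(NA_real_, n_cap)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(config$seed)
  step <- 0L
  done <- FALSE
  b1 <- config$adam_beta1; b2 <- config$adam_beta2
  for (ep in seq_len(config$epochs)) {
    order_idx <- sample(entries$train)
    batches <- split(order_idx, ceiling(seq_along(order_idx) / config$batch_size))
    ep_losses <- numeric(0)
    for (bt in batches) {
      # stratified diffusion times across the batch: one uniform offset,
      # equally spaced bins (lower-variance unbiased estimator of the
      # uniform-time expectation)
      u <- stats::runif(1)
      tb <- pmin(pmax((seq_along(bt) - u) / length(bt), 1e-6), 1)
      epss <- lapply(bt, function(k) sample_subspace_gaussian(nrow(xs[[k]])))
      as_ <- schedule_alpha_sigma(sch, tb)
      tembs <- t(vapply(tb, time_embedding, numeric(cfg$d_time),
                        dim = cfg$d_time))
      if (length(unique(sys_of[bt])) == 1L) {
        f <- feats[[sys_of[bt[1L]]]]
        out <- .cpp_loss_grad_batch_flat(pflat, proto, ucfg, f$single,
                                         f$pair, xs[bt], epss, as_$alpha,
                                         as_$sigma,
                                         schedule_gamma_prime(sch, tb),
                                         tembs, TRUE)
        bl <- out$loss
        gflat <- out$gflat
      } else {
        model$params <- unflatten_params(pflat, proto)
        grads <- NULL; bl <- 0
        for (bi in seq_along(bt)) {
          k <- bt[bi]
          lg <- loss_and_grad(model, feats[[sys_of[k]]], xs[[k]], tb[bi],
                              epss[[bi]])
          bl <- bl + lg$loss / length(bt)
          grads <- if (is.null(grads)) lg$grads else Map(`+`, grads, lg$grads)
        }
        gflat <- unlist(grads, use.names = FALSE) / length(bt)
      }
      # Adam with linear warm-up plus EMA, updating the flat state in place
      opt$step <- opt$step + 1L
      lr <- .cpp_adam_ema_step(pflat, opt$m, opt$v, ema_flat, gflat,
                               opt$step, config$base_lr,
                               config$warmup_steps, b1, b2,
                               config$adam_eps, config$ema_decay)
      step <- step + 1L
      ep_losses <- c(ep_losses, bl)
      log_step[step] <- step; log_lr[step] <- lr; log_train[step] <- bl
      if (!is.null(config$max_steps) && step >= config$max_steps) {
        done <- TRUE; break
      }
    }
    vl <- val_loss_fn(pflat)
    log_val[step] <- vl
    if (verbose)
      message(sprintf("epoch %d  step %d  train %.4f  val %.4f",
                      ep, step, mean(ep_losses), vl))
    if (!is.na(vl) && (is.na(best_val) || vl < best_val)) {
      best_val <- vl
      best_ema <- ema_flat + 0   # deep copy: ema_flat mutates in place
    }
    if (done) break
  }
  model$params <- unflatten_params(pflat, proto)
  model$ema <- list(shadow = unflatten_params(ema_flat, proto),
                    decay = config$ema_decay)
  model$best_ema <- unflatten_params(best_ema, proto)
  structure(list(model = model, train_config = config,
                 log = data.frame(step = log_step[seq_len(step)],
                                  lr = log_lr[seq_len(step)],
                                  train_loss = log_train[seq_len(step)],
                                  val_loss = log_val[seq_len(step)]),
                 init_val_loss = init_val, best_val_loss = best_val),
            class = "pl_checkpoint")
}

# Rebuild the named parameter list (matrices and bare vectors) from a flat
# vector, using an existing parameter list as the layout prototype.
unflatten_params <- function(v, proto) {
  out <- proto
  pos <- 0L
  for (nm in names(proto)) {
    len <- length(proto[[nm]])
    chunk <- v[(pos + 1L):(pos + len)]
    d <- dim(proto[[nm]])
    out[[nm]] <- if (is.null(d)) chunk else matrix(chunk, d[1L], d[2L])
    pos <- pos + len
  }
  out
}

#' @export
print.pl_checkpoint <- function(x, ...) {
  cat(sprintf("<pl_checkpoint %d steps, init val %.4f -> best val %.4f>\n",
              nrow(x$log), x$init_val_loss, x$best_val_loss))
  invisible(x)
}

# Accepts a make_dataset() result or a list of list(system, frame) entries;
# returns systems (unique), frames, sys_of (frame -> system index), and
# train/val index vectors.
normalize_dataset <- function(dataset) {
  if (!is.null(dataset$frames) && !is.null(dataset$system)) {
    n <- length(dataset$frames)
    split <- dataset$split
    if (is.null(split)) {
      n_train <- as.integer(ceiling(0.8 * n))
      split <- list(train = seq_len(n_train),
                    val = if (n_train < n) (n_train + 1L):n else integer(0))
    }
    return(list(systems = list(dataset$system), frames = dataset$frames,
                sys_of = rep(1L, n), train = split$train, val = split$val))
  }
  n <- length(dataset)
  systems <- lapply(dataset, `[[`, "system")
  frames <- lapply(dataset, `[[`, "frame")
  n_train <- as.integer(ceiling(0.8 * n))
  list(systems = systems, frames = frames, sys_of = seq_len(n),
       train = seq_len(n_train),
       val = if (n_train < n) (n_train + 1L):n else integer(0))
}
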