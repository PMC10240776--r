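# Minimal neural-network layer library: forward passes returning caches and
# hand-derived analytic backward passes over base-R matrix operations.
# Analytic gradients are verified against finite differences in the test
# suite. Parameters live in a flat named list; gradients are accumulated in an
# environment keyed by parameter name.

nn_zeros <- function(nr, nc) matrix(0, nr, nc)

nn_init_linear <- function(nr, nc, zero = FALSE) {
  if (zero) nn_zeros(nr, nc)
  else matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
}

grad_acc_new <- function() new.env(parent = emptyenv())

grad_add <- function(acc, name, g) {
  cur <- get0(name, envir = acc, inherits = FALSE)
  assign(name, if (is.null(cur)) g else cur + g, envir = acc)
  invisible(NULL)
}

grad_collect <- function(acc, params) {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) {
    g <- get0(nm, envir = acc, inherits = FALSE)
    out[[nm]] <- if (is.null(g)) params[[nm]] * 0 else g
  }
  out
}

## ---- linear ----

linear_fwd <- function(x, W, b = NULL) {
  out <- x %*% W
  if (!is.null(b)) out <- sweep(out, 2L, b, "+")
  list(out = out, x = x, W = W, has_b = !is.null(b))
}

linear_bwd <- function(cache, dout, acc, wname, bname = NULL) {
  grad_add(acc, wname, crossprod(cache$x, dout))
  if (cache$has_b && !is.null(bname)) grad_add(acc, bname, colSums(dout))
  dout %*% t(cache$W)
}

## ---- layer norm (over columns, per row) ----

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+")
  list(out = out, xhat = xhat, inv = inv, g = g)
}

layernorm_bwd <- function(cache, dout, acc, gname, bname) {
  grad_add(acc, gname, colSums(dout * cache$xhat))
  grad_add(acc, bname, colSums(dout))
  dxhat <- sweep(dout, 2L, cache$g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  (dxhat - m1 - cache$xhat * m2) * cache$inv
}

## ---- activations ----

relu_fwd <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_bwd <- function(cache, dout) dout * cache$mask

sigmoid_fwd <- function(x) {
  s <- stats::plogis(x)
  list(out = s, s = s)
}
sigmoid_bwd <- function(cache, dout) dout * cache$s * (1 - cache$s)

## ---- row-wise softmax ----

softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

softmax_rows_bwd <- function(p, dp) {
  p * (dp - rowSums(dp * p))
}

## ---- Adam optimizer with linear warm-up ----

adam_new <- function(params, base_lr = 4e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, warmup_steps = 1000L) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       step = 0L, base_lr = base_lr, beta1 = beta1, beta2 = beta2,
       eps = eps, warmup_steps = as.integer(warmup_steps))
}

adam_lr <- function(opt) {
  k <- opt$step
  if (k < opt$warmup_steps) opt$base_lr * k / opt$warmup_steps else opt$base_lr
}

adam_step <- function(opt, params, grads) {
  opt$step <- opt$step + 1L
  lr <- adam_lr(opt)
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$step; bc2 <- 1 - b2^opt$step
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, params = params, lr = lr)
}

## ---- exponential moving average of parameters ----

ema_new <- function(params, decay = 0.999) list(shadow = params, decay = decay)

ema_update <- function(ema, params) {
  d <- ema$decay
  for (nm in names(params))
    ema$shadow[[nm]] <- d * ema$shadow[[nm]] + (1 - d) * params[[nm]]
  ema
}
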