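# The noise-prediction network.
#
# Three stages, mirroring the architecture the model family uses:
#   (1) input embedding: learned linear maps of the fixed token features, plus
#       radial-basis embeddings of current atom distances and a sinusoidal
#       diffusion-time embedding, giving the single (N x c_s) and pair
#       (N^2 x c_p, flattened column-major) representations;
#   (2) residual feature update: n_blocks folding-style blocks (pair-biased
#       self-attention over tokens, transitions, outer-product update of the
#       pair, optional triangular multiplicative update);
#   (3) equivariant denoising head: the symmetrized pair representation is
#       mapped by an MLP to a weight matrix W, and the predicted noise is the
#       W-weighted sum of unit relative-position vectors, centroid-removed.
# The head output depends on coordinates only through distances, so the whole
# model is SE(3)-equivariant by construction.
#
# The model operates in scaled coordinate units (angstroms times
# `coord_scale`), the units in which diffusion runs; distance-derived features
# convert back to angstroms internally so config lengths are in angstroms.

#' Denoiser configuration
#'
#' Desk-scale defaults: a 2-block trunk with small channel widths, trainable
#' in minutes on one CPU while keeping the full architectural contract. The
#' full-scale setting (12 blocks, wider channels) is a configuration
#' choice, not a separate code path.
#'
#' @param n_blocks Number of folding blocks (`>= 1`).
#' @param c_s,c_p Single and pair channel widths.
#' @param n_heads Attention heads (`c_s` must be divisible by `n_heads`).
#' @param c_outer Hidden width of the outer-product pair update.
#' @param c_tri Hidden width of the triangular multiplicative update.
#' @param transition_factor Expansion factor of the transition MLPs.
#' @param c_head Hidden width of the weight-matrix MLP.
#' @param n_rbf,d_max Radial-basis count and span (angstroms) for distance
#'   embeddings. The span must cover the distances seen at high noise (the
#'   unit-variance prior spreads scaled coordinates well beyond the data's
#'   extent), not only the folded-structure scale.
#' @param d_time Width of the sinusoidal time embedding.
#' @param use_triangular_update Enable the triangular multiplicative pair
#'   update.
#' @param epsilon_dist Floor (angstroms) on the denominator of the weighted
#'   relative-difference sum; keeps coincident atoms (which occur at high
#'   noise) finite.
#' @param template_conditioning `"off"` for the sequence-only model or
#'   `"backbone"` to accept a protein C-alpha template whose distances
#'   condition the protein-protein pair block (the template variant).
#' @param plm_dim Column count of an optional per-residue protein language
#'   model embedding supplied at run time (0 disables the input).
#' @param coord_scale Multiplier taking angstroms to diffusion units (default
#'   1/10, so typical inter-atom distances are order one under the
#'   unit-variance prior).
#' @param max_tokens Size cutoff on residues + ligand heavy atoms.
#' @return A `denoiser_config` list.
#' @export
denoiser_config <- function(n_blocks = 2L, c_s = 64L, c_p = 32L, n_heads = 4L,
                            c_outer = 8L, c_tri = 16L, transition_factor = 2L,
                            c_head = 32L, n_rbf = 64L, d_max = 60,
                            d_time = 32L, use_triangular_update = TRUE,
                            epsilon_dist = 1e-2,
                            template_conditioning = c("off", "backbone"),
                            plm_dim = 0L, coord_scale = 0.1,
                            max_tokens = 384L) {
  template_conditioning <- match.arg(template_conditioning)
  stopifnot(n_blocks >= 1L, c_s %% n_heads == 0L, epsilon_dist > 0,
            coord_scale > 0)
  structure(list(n_blocks = as.integer(n_blocks), c_s = as.integer(c_s),
                 c_p = as.integer(c_p), n_heads = as.integer(n_heads),
                 c_outer = as.integer(c_outer), c_tri = as.integer(c_tri),
                 transition_factor = as.integer(transition_factor),
                 c_head = as.integer(c_head), n_rbf = as.integer(n_rbf),
                 d_max = d_max, d_time = as.integer(d_time),
                 use_triangular_update = isTRUE(use_triangular_update),
                 epsilon_dist = epsilon_dist,
                 template_conditioning = template_conditioning,
                 plm_dim = as.integer(plm_dim), coord_scale = coord_scale,
                 max_tokens = as.integer(max_tokens)),
            class = "denoiser_config")
}

denoiser_init_params <- function(cfg) {
  p <- list()
  d_s0 <- n_single_feat(); d_p0 <- n_pair_feat()
  p[["emb.Ws"]] <- nn_init_linear(d_s0, cfg$c_s)
  p[["emb.bs"]] <- numeric(cfg$c_s)
  p[["emb.Wp"]] <- nn_init_linear(d_p0, cfg$c_p)
  p[["emb.bp"]] <- numeric(cfg$c_p)
  p[["emb.Wrbf"]] <- nn_init_linear(cfg$n_rbf, cfg$c_p)
  p[["emb.Wts"]] <- nn_init_linear(cfg$d_time, cfg$c_s)
  p[["emb.Wtp"]] <- nn_init_linear(cfg$d_time, cfg$c_p)
  if (cfg$plm_dim > 0L) {
    p[["emb.plm_g"]] <- rep(1, cfg$plm_dim)
    p[["emb.plm_b"]] <- numeric(cfg$plm_dim)
    p[["emb.Wplm"]] <- nn_init_linear(cfg$plm_dim, cfg$c_s)
  }
  if (cfg$template_conditioning == "backbone")
    p[["emb.Wtmpl"]] <- nn_init_linear(cfg$n_rbf, cfg$c_p)
  for (k in seq_len(cfg$n_blocks)) {
    pre <- sprintf("blk%d.", k)
    add <- function(nm, val) p[[paste0(pre, nm)]] <<- val
    add("attn.ln_s.g", rep(1, cfg$c_s)); add("attn.ln_s.b", numeric(cfg$c_s))
    add("attn.ln_p.g", rep(1, cfg$c_p)); add("attn.ln_p.b", numeric(cfg$c_p))
    add("attn.Wq", nn_init_linear(cfg$c_s, cfg$c_s))
    add("attn.Wk", nn_init_linear(cfg$c_s, cfg$c_s))
    add("attn.Wv", nn_init_linear(cfg$c_s, cfg$c_s))
    add("attn.Wb", nn_init_linear(cfg$c_p, cfg$n_heads))
    add("attn.Wo", nn_init_linear(cfg$c_s, cfg$c_s, zero = TRUE))
    f <- cfg$transition_factor
    add("strans.ln.g", rep(1, cfg$c_s)); add("strans.ln.b", numeric(cfg$c_s))
    add("strans.W1", nn_init_linear(cfg$c_s, f * cfg$c_s))
    add("strans.b1", numeric(f * cfg$c_s))
    add("strans.W2", nn_init_linear(f * cfg$c_s, cfg$c_s, zero = TRUE))
    add("strans.b2", numeric(cfg$c_s))
    add("outer.ln.g", rep(1, cfg$c_s)); add("outer.ln.b", numeric(cfg$c_s))
    add("outer.Wa", nn_init_linear(cfg$c_s, cfg$c_outer))
    add("outer.Wb", nn_init_linear(cfg$c_s, cfg$c_outer))
    add("outer.Wo", nn_init_linear(cfg$c_outer^2, cfg$c_p, zero = TRUE))
    add("outer.bo", numeric(cfg$c_p))
    if (cfg$use_triangular_update) {
      add("tri.ln.g", rep(1, cfg$c_p)); add("tri.ln.b", numeric(cfg$c_p))
      add("tri.Wpa", nn_init_linear(cfg$c_p, cfg$c_tri))
      add("tri.Wga", nn_init_linear(cfg$c_p, cfg$c_tri))
      add("tri.bga", numeric(cfg$c_tri))
      add("tri.Wpb", nn_init_linear(cfg$c_p, cfg$c_tri))
      add("tri.Wgb", nn_init_linear(cfg$c_p, cfg$c_tri))
      add("tri.bgb", numeric(cfg$c_tri))
      add("tri.ln2.g", rep(1, cfg$c_tri)); add("tri.ln2.b", numeric(cfg$c_tri))
      add("tri.Wgo", nn_init_linear(cfg$c_p, cfg$c_tri))
      add("tri.bgo", numeric(cfg$c_tri))
      add("tri.Wzo", nn_init_linear(cfg$c_tri, cfg$c_p, zero = TRUE))
      add("tri.bzo", numeric(cfg$c_p))
    }
    add("ptrans.ln.g", rep(1, cfg$c_p)); add("ptrans.ln.b", numeric(cfg$c_p))
    add("ptrans.W1", nn_init_linear(cfg$c_p, f * cfg$c_p))
    add("ptrans.b1", numeric(f * cfg$c_p))
    add("ptrans.W2", nn_init_linear(f * cfg$c_p, cfg$c_p, zero = TRUE))
    add("ptrans.b2", numeric(cfg$c_p))
  }
  p[["head.ln.g"]] <- rep(1, cfg$c_p); p[["head.ln.b"]] <- numeric(cfg$c_p)
  p[["head.W1"]] <- nn_init_linear(cfg$c_p, cfg$c_head)
  p[["head.b1"]] <- numeric(cfg$c_head)
  p[["head.W2"]] <- nn_init_linear(cfg$c_head, 1L, zero = TRUE)
  p[["head.b2"]] <- numeric(1L)
  p
}

#' Construct a denoiser model
#'
#' @param config A [denoiser_config()].
#' @param schedule A [noise_schedule()].
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `pl_denoiser` with fields `config`, `schedule`,
#'   `params` (flat named list of weight matrices).
#' @export
pl_denoiser <- function(config = denoiser_config(),
                        schedule = noise_schedule(), seed = 0L) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  structure(list(config = config, schedule = schedule,
                 params = denoiser_init_params(config)),
            class = "pl_denoiser")
}

#' @export
print.pl_denoiser <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<pl_denoiser %d blocks, c_s=%d, c_p=%d, %d parameters%s>\n",
              x$config$n_blocks, x$config$c_s, x$config$c_p, n_par,
              if (x$config$template_conditioning == "backbone")
                ", template-conditioned" else ""))
  invisible(x)
}

## ---- input embedding ----

embed_fwd <- function(params, cfg, feat, z, t, plm = NULL, template_rbf = NULL,
                      pp_rows = NULL) {
  n <- feat$n
  rbf <- distance_embedding(z / cfg$coord_scale, cfg$n_rbf, cfg$d_max)
  temb <- time_embedding(t, cfg$d_time)
  ln_s <- linear_fwd(feat$single, params[["emb.Ws"]], params[["emb.bs"]])
  single <- ln_s$out +
    matrix(temb %*% params[["emb.Wts"]], n, cfg$c_s, byrow = TRUE)
  plm_cache <- NULL
  if (!is.null(plm)) {
    if (cfg$plm_dim == 0L)
      stop("model was built without a PLM input (plm_dim = 0)")
    if (ncol(plm) != cfg$plm_dim)
      stop("PLM embedding width does not match config plm_dim")
    n_res <- sum(feat$roles == "protein")
    if (nrow(plm) != n_res)
      stop("PLM embedding must have one row per residue")
    pl_ln <- layernorm_fwd(plm, params[["emb.plm_g"]], params[["emb.plm_b"]])
    pl_lin <- linear_fwd(pl_ln$out, params[["emb.Wplm"]])
    single[seq_len(n_res), ] <- single[seq_len(n_res), ] + pl_lin$out
    plm_cache <- list(ln = pl_ln, lin = pl_lin, n_res = n_res)
  }
  lp <- linear_fwd(feat$pair, params[["emb.Wp"]], params[["emb.bp"]])
  lrbf <- linear_fwd(rbf, params[["emb.Wrbf"]])
  pair <- lp$out + lrbf$out +
    matrix(temb %*% params[["emb.Wtp"]], n * n, cfg$c_p, byrow = TRUE)
  tmpl_cache <- NULL
  if (!is.null(template_rbf)) {
    lt <- linear_fwd(template_rbf, params[["emb.Wtmpl"]])
    pair[pp_rows, ] <- pair[pp_rows, ] + lt$out
    tmpl_cache <- list(lin = lt, rows = pp_rows)
  }
  list(single = single, pair = pair,
       cache = list(ls = ln_s, lp = lp, lrbf = lrbf, temb = temb, n = n,
                    plm = plm_cache, tmpl = tmpl_cache))
}

embed_bwd <- function(params, cfg, cache, dsingle, dpair, acc) {
  if (!is.null(cache$tmpl)) {
    dt_rows <- dpair[cache$tmpl$rows, , drop = FALSE]
    linear_bwd(cache$tmpl$lin, dt_rows, acc, "emb.Wtmpl")
  }
  grad_add(acc, "emb.Wtp", cache$temb %o% colSums(dpair))
  linear_bwd(cache$lrbf, dpair, acc, "emb.Wrbf")
  linear_bwd(cache$lp, dpair, acc, "emb.Wp", "emb.bp")
  if (!is.null(cache$plm)) {
    dplm_rows <- dsingle[seq_len(cache$plm$n_res), , drop = FALSE]
    dln <- linear_bwd(cache$plm$lin, dplm_rows, acc, "emb.Wplm")
    layernorm_bwd(cache$plm$ln, dln, acc, "emb.plm_g", "emb.plm_b")
  }
  grad_add(acc, "emb.Wts", cache$temb %o% colSums(dsingle))
  linear_bwd(cache$ls, dsingle, acc, "emb.Ws", "emb.bs")
  invisible(NULL)
}

## ---- folding block ----

attn_fwd <- function(params, pre, cfg, single, pair, n) {
  h <- cfg$n_heads; dh <- cfg$c_s %/% h
  ln_s <- layernorm_fwd(single, params[[paste0(pre, "attn.ln_s.g")]],
                        params[[paste0(pre, "attn.ln_s.b")]])
  ln_p <- layernorm_fwd(pair, params[[paste0(pre, "attn.ln_p.g")]],
                        params[[paste0(pre, "attn.ln_p.b")]])
  q <- ln_s$out %*% params[[paste0(pre, "attn.Wq")]]
  k <- ln_s$out %*% params[[paste0(pre, "attn.Wk")]]
  v <- ln_s$out %*% params[[paste0(pre, "attn.Wv")]]
  bias <- ln_p$out %*% params[[paste0(pre, "attn.Wb")]]   # N^2 x h
  o <- matrix(0, n, cfg$c_s)
  Ps <- vector("list", h)
  for (m in seq_len(h)) {
    cols <- ((m - 1L) * dh + 1L):(m * dh)
    logits <- tcrossprod(q[, cols, drop = FALSE], k[, cols, drop = FALSE]) /
      sqrt(dh) + matrix(bias[, m], n, n)
    P <- softmax_rows(logits)
    Ps[[m]] <- P
    o[, cols] <- P %*% v[, cols, drop = FALSE]
  }
  lo <- linear_fwd(o, params[[paste0(pre, "attn.Wo")]])
  list(out = single + lo$out,
       cache = list(ln_s = ln_s, ln_p = ln_p, q = q, k = k, v = v,
                    Ps = Ps, lo = lo, n = n))
}

attn_bwd <- function(params, pre, cfg, cache, dout, acc) {
  h <- cfg$n_heads; dh <- cfg$c_s %/% h; n <- cache$n
  do_ <- linear_bwd(cache$lo, dout, acc, paste0(pre, "attn.Wo"))
  dq <- matrix(0, n, cfg$c_s); dk <- dq; dv <- dq
  dbias <- matrix(0, n * n, h)
  for (m in seq_len(h)) {
    cols <- ((m - 1L) * dh + 1L):(m * dh)
    P <- cache$Ps[[m]]
    dP <- tcrossprod(do_[, cols, drop = FALSE], cache$v[, cols, drop = FALSE])
    dv[, cols] <- crossprod(P, do_[, cols, drop = FALSE])
    dlog <- softmax_rows_bwd(P, dP)
    dq[, cols] <- dlog %*% cache$k[, cols, drop = FALSE] / sqrt(dh)
    dk[, cols] <- crossprod(dlog, cache$q[, cols, drop = FALSE]) / sqrt(dh)
    dbias[, m] <- as.vector(dlog)
  }
  grad_add(acc, paste0(pre, "attn.Wq"), crossprod(cache$ln_s$out, dq))
  grad_add(acc, paste0(pre, "attn.Wk"), crossprod(cache$ln_s$out, dk))
  grad_add(acc, paste0(pre, "attn.Wv"), crossprod(cache$ln_s$out, dv))
  grad_add(acc, paste0(pre, "attn.Wb"), crossprod(cache$ln_p$out, dbias))
  dln_s <- dq %*% t(params[[paste0(pre, "attn.Wq")]]) +
    dk %*% t(params[[paste0(pre, "attn.Wk")]]) +
    dv %*% t(params[[paste0(pre, "attn.Wv")]])
  dln_p <- dbias %*% t(params[[paste0(pre, "attn.Wb")]])
  dsingle <- dout +
    layernorm_bwd(cache$ln_s, dln_s, acc,
                  paste0(pre, "attn.ln_s.g"), paste0(pre, "attn.ln_s.b"))
  dpair <- layernorm_bwd(cache$ln_p, dln_p, acc,
                         paste0(pre, "attn.ln_p.g"), paste0(pre, "attn.ln_p.b"))
  list(dsingle = dsingle, dpair = dpair)
}

transition_fwd <- function(params, pre, x) {
  ln <- layernorm_fwd(x, params[[paste0(pre, "ln.g")]],
                      params[[paste0(pre, "ln.b")]])
  l1 <- linear_fwd(ln$out, params[[paste0(pre, "W1")]],
                   params[[paste0(pre, "b1")]])
  r <- relu_fwd(l1$out)
  l2 <- linear_fwd(r$out, params[[paste0(pre, "W2")]],
                   params[[paste0(pre, "b2")]])
  list(out = x + l2$out, cache = list(ln = ln, l1 = l1, r = r, l2 = l2))
}

transition_bwd <- function(params, pre, cache, dout, acc) {
  d2 <- linear_bwd(cache$l2, dout, acc, paste0(pre, "W2"), paste0(pre, "b2"))
  dr <- relu_bwd(cache$r, d2)
  d1 <- linear_bwd(cache$l1, dr, acc, paste0(pre, "W1"), paste0(pre, "b1"))
  dout + layernorm_bwd(cache$ln, d1, acc, paste0(pre, "ln.g"),
                       paste0(pre, "ln.b"))
}

outer_fwd <- function(params, pre, cfg, single, pair, n) {
  co <- cfg$c_outer
  ln <- layernorm_fwd(single, params[[paste0(pre, "outer.ln.g")]],
                      params[[paste0(pre, "outer.ln.b")]])
  a <- ln$out %*% params[[paste0(pre, "outer.Wa")]]
  b <- ln$out %*% params[[paste0(pre, "outer.Wb")]]
  ii <- rep(seq_len(n), times = n); jj <- rep(seq_len(n), each = n)
  # O[(i,j), (u,v)] = a[i,u] * b[j,v], column index m = (v-1)*co + u
  O <- a[ii, rep(seq_len(co), times = co), drop = FALSE] *
    b[jj, rep(seq_len(co), each = co), drop = FALSE]
  lo <- linear_fwd(O, params[[paste0(pre, "outer.Wo")]],
                   params[[paste0(pre, "outer.bo")]])
  list(out = pair + lo$out,
       cache = list(ln = ln, a = a, b = b, O = O, lo = lo, ii = ii, jj = jj,
                    n = n))
}

outer_bwd <- function(params, pre, cfg, cache, dout, acc) {
  co <- cfg$c_outer; n <- cache$n
  dO <- linear_bwd(cache$lo, dout, acc, paste0(pre, "outer.Wo"),
                   paste0(pre, "outer.bo"))
  da <- matrix(0, n, co); db <- matrix(0, n, co)
  for (u in seq_len(co)) {
    cols <- (seq_len(co) - 1L) * co + u       # all v for this u
    tmp <- dO[, cols, drop = FALSE] * cache$b[cache$jj, , drop = FALSE]
    da[, u] <- rowsum(rowSums(tmp), cache$ii)[, 1L]
  }
  for (v in seq_len(co)) {
    cols <- (v - 1L) * co + seq_len(co)       # all u for this v
    tmp <- dO[, cols, drop = FALSE] * cache$a[cache$ii, , drop = FALSE]
    db[, v] <- rowsum(rowSums(tmp), cache$jj)[, 1L]
  }
  dln <- da %*% t(params[[paste0(pre, "outer.Wa")]]) +
    db %*% t(params[[paste0(pre, "outer.Wb")]])
  grad_add(acc, paste0(pre, "outer.Wa"), crossprod(cache$ln$out, da))
  grad_add(acc, paste0(pre, "outer.Wb"), crossprod(cache$ln$out, db))
  layernorm_bwd(cache$ln, dln, acc, paste0(pre, "outer.ln.g"),
                paste0(pre, "outer.ln.b"))
}

tri_fwd <- function(params, pre, cfg, pair, n) {
  ct <- cfg$c_tri
  ln <- layernorm_fwd(pair, params[[paste0(pre, "tri.ln.g")]],
                      params[[paste0(pre, "tri.ln.b")]])
  ga <- sigmoid_fwd(sweep(ln$out %*% params[[paste0(pre, "tri.Wga")]], 2L,
                          params[[paste0(pre, "tri.bga")]], "+"))
  pa <- ln$out %*% params[[paste0(pre, "tri.Wpa")]]
  a <- ga$out * pa
  gb <- sigmoid_fwd(sweep(ln$out %*% params[[paste0(pre, "tri.Wgb")]], 2L,
                          params[[paste0(pre, "tri.bgb")]], "+"))
  pb <- ln$out %*% params[[paste0(pre, "tri.Wpb")]]
  b <- gb$out * pb
  # outgoing-edge contraction: z[(i,j), c] = sum_k a[(i,k), c] * b[(j,k), c]
  z <- matrix(0, n * n, ct)
  for (cc in seq_len(ct)) {
    A <- matrix(a[, cc], n, n); B <- matrix(b[, cc], n, n)
    z[, cc] <- as.vector(tcrossprod(A, B))
  }
  ln2 <- layernorm_fwd(z, params[[paste0(pre, "tri.ln2.g")]],
                       params[[paste0(pre, "tri.ln2.b")]])
  # output gate acts on the hidden channels, before the zero-init projection
  go <- sigmoid_fwd(sweep(ln$out %*% params[[paste0(pre, "tri.Wgo")]], 2L,
                          params[[paste0(pre, "tri.bgo")]], "+"))
  gated <- go$out * ln2$out
  zo <- linear_fwd(gated, params[[paste0(pre, "tri.Wzo")]],
                   params[[paste0(pre, "tri.bzo")]])
  list(out = pair + zo$out,
       cache = list(ln = ln, ga = ga, pa = pa, a = a, gb = gb, pb = pb, b = b,
                    ln2 = ln2, go = go, zo = zo, n = n))
}

tri_bwd <- function(params, pre, cfg, cache, dout, acc) {
  ct <- cfg$c_tri; n <- cache$n
  dgated <- linear_bwd(cache$zo, dout, acc, paste0(pre, "tri.Wzo"),
                       paste0(pre, "tri.bzo"))
  dgo <- sigmoid_bwd(cache$go, dgated * cache$ln2$out)
  grad_add(acc, paste0(pre, "tri.Wgo"), crossprod(cache$ln$out, dgo))
  grad_add(acc, paste0(pre, "tri.bgo"), colSums(dgo))
  dln <- dgo %*% t(params[[paste0(pre, "tri.Wgo")]])
  dz <- layernorm_bwd(cache$ln2, dgated * cache$go$out, acc,
                      paste0(pre, "tri.ln2.g"), paste0(pre, "tri.ln2.b"))
  da <- matrix(0, n * n, ct); db <- matrix(0, n * n, ct)
  for (cc in seq_len(ct)) {
    A <- matrix(cache$a[, cc], n, n); B <- matrix(cache$b[, cc], n, n)
    dZ <- matrix(dz[, cc], n, n)
    da[, cc] <- as.vector(dZ %*% B)
    db[, cc] <- as.vector(crossprod(dZ, A))
  }
  dga <- sigmoid_bwd(cache$ga, da * cache$pa)
  dpa <- da * cache$ga$out
  dgb <- sigmoid_bwd(cache$gb, db * cache$pb)
  dpb <- db * cache$gb$out
  grad_add(acc, paste0(pre, "tri.Wga"), crossprod(cache$ln$out, dga))
  grad_add(acc, paste0(pre, "tri.bga"), colSums(dga))
  grad_add(acc, paste0(pre, "tri.Wpa"), crossprod(cache$ln$out, dpa))
  grad_add(acc, paste0(pre, "tri.Wgb"), crossprod(cache$ln$out, dgb))
  grad_add(acc, paste0(pre, "tri.bgb"), colSums(dgb))
  grad_add(acc, paste0(pre, "tri.Wpb"), crossprod(cache$ln$out, dpb))
  dln <- dln + dga %*% t(params[[paste0(pre, "tri.Wga")]]) +
    dpa %*% t(params[[paste0(pre, "tri.Wpa")]]) +
    dgb %*% t(params[[paste0(pre, "tri.Wgb")]]) +
    dpb %*% t(params[[paste0(pre, "tri.Wpb")]])
  dout + layernorm_bwd(cache$ln, dln, acc, paste0(pre, "tri.ln.g"),
                       paste0(pre, "tri.ln.b"))
}

block_fwd <- function(params, cfg, k, single, pair, n) {
  pre <- sprintf("blk%d.", k)
  at <- attn_fwd(params, pre, cfg, single, pair, n)
  st <- transition_fwd(params, paste0(pre, "strans."), at$out)
  ou <- outer_fwd(params, pre, cfg, st$out, pair, n)
  tr <- if (cfg$use_triangular_update) tri_fwd(params, pre, cfg, ou$out, n)
        else list(out = ou$out, cache = NULL)
  pt <- transition_fwd(params, paste0(pre, "ptrans."), tr$out)
  check_finite_block(pt$out, st$out, k)
  list(single = st$out, pair = pt$out,
       cache = list(at = at$cache, st = st$cache, ou = ou$cache,
                    tr = tr$cache, pt = pt$cache))
}

check_finite_block <- function(pair, single, k) {
  if (!all(is.finite(pair)) || !all(is.finite(single)))
    stop(sprintf("non-finite activations in folding block %d", k))
}

block_bwd <- function(params, cfg, k, cache, dsingle, dpair, acc) {
  pre <- sprintf("blk%d.", k)
  dpair <- transition_bwd(params, paste0(pre, "ptrans."), cache$pt, dpair, acc)
  if (cfg$use_triangular_update)
    dpair <- tri_bwd(params, pre, cfg, cache$tr, dpair, acc)
  dsingle2 <- outer_bwd(params, pre, cfg, cache$ou, dpair, acc)
  dsingle <- dsingle + dsingle2
  dsingle <- transition_bwd(params, paste0(pre, "strans."), cache$st,
                            dsingle, acc)
  ab <- attn_bwd(params, pre, cfg, cache$at, dsingle, acc)
  list(dsingle = ab$dsingle, dpair = dpair + ab$dpair)
}

## ---- equivariant denoising head ----

head_fwd <- function(params, cfg, pair, z, n) {
  tr_idx <- as.vector(t(matrix(seq_len(n * n), n, n)))  # (i,j) -> (j,i)
  psym <- (pair + pair[tr_idx, , drop = FALSE]) / 2
  ln <- layernorm_fwd(psym, params[["head.ln.g"]], params[["head.ln.b"]])
  l1 <- linear_fwd(ln$out, params[["head.W1"]], params[["head.b1"]])
  r <- relu_fwd(l1$out)
  l2 <- linear_fwd(r$out, params[["head.W2"]], params[["head.b2"]])
  W <- matrix(l2$out, n, n)
  diag(W) <- 0
  dz <- as.matrix(stats::dist(z))
  dimnames(dz) <- NULL
  dclamp <- pmax(dz, cfg$epsilon_dist * cfg$coord_scale)
  C <- W / dclamp
  eps_raw <- rowSums(C) * z - C %*% z
  eps_hat <- project_zero_centroid(eps_raw)
  list(eps_hat = eps_hat, W = W,
       cache = list(tr_idx = tr_idx, ln = ln, l1 = l1, r = r, l2 = l2,
                    dclamp = dclamp, z = z, n = n))
}

head_bwd <- function(params, cfg, cache, d_eps, acc) {
  n <- cache$n; z <- cache$z
  dpre <- project_zero_centroid(d_eps)   # projection is symmetric idempotent
  # dC[i, j] = sum_x dpre[i, x] * (z[i, x] - z[j, x])
  dC <- rowSums(dpre * z) - dpre %*% t(z)
  dW <- dC / cache$dclamp
  diag(dW) <- 0
  d2 <- linear_bwd(cache$l2, matrix(as.vector(dW), ncol = 1L), acc,
                   "head.W2", "head.b2")
  dr <- relu_bwd(cache$r, d2)
  d1 <- linear_bwd(cache$l1, dr, acc, "head.W1", "head.b1")
  dpsym <- layernorm_bwd(cache$ln, d1, acc, "head.ln.g", "head.ln.b")
  (dpsym + dpsym[cache$tr_idx, , drop = FALSE]) / 2
}

## ---- full model forward / backward ----

model_forward <- function(model, feat, z, t, plm = NULL, template_rbf = NULL,
                          pp_rows = NULL, want_cache = FALSE) {
  cfg <- model$config; params <- model$params
  n <- feat$n
  em <- embed_fwd(params, cfg, feat, z, t, plm, template_rbf, pp_rows)
  single <- em$single; pair <- em$pair
  blocks <- vector("list", cfg$n_blocks)
  for (k in seq_len(cfg$n_blocks)) {
    bl <- block_fwd(params, cfg, k, single, pair, n)
    single <- bl$single; pair <- bl$pair
    if (want_cache) blocks[[k]] <- bl$cache
  }
  hd <- head_fwd(params, cfg, pair, z, n)
  out <- list(eps_hat = hd$eps_hat, W = hd$W)
  if (want_cache)
    out$cache <- list(em = em$cache, blocks = blocks, hd = hd$cache)
  out
}

model_backward <- function(model, cache, d_eps) {
  cfg <- model$config; params <- model$params
  acc <- grad_acc_new()
  dpair <- head_bwd(params, cfg, cache$hd, d_eps, acc)
  dsingle <- matrix(0, nrow(cache$hd$z), cfg$c_s)
  for (k in rev(seq_len(cfg$n_blocks))) {
    bl <- block_bwd(params, cfg, k, cache$blocks[[k]], dsingle, dpair, acc)
    dsingle <- bl$dsingle; dpair <- bl$dpair
  }
  embed_bwd(params, cfg, cache$em, dsingle, dpair, acc)
  grad_collect(acc, params)
}

## ---- public operations ----

sys_features <- function(system) {
  f <- featurize_tokens(system)
  f$roles <- system$roles
  f
}

#' Build the initial single representation
#'
#' Protein rows are the learned amino-acid embedding, optionally plus a
#' normalized, linearly mapped protein-language-model embedding; ligand rows
#' are the learned embedding of the atom feature tuple. Time and distance
#' features are injected separately at each denoising call.
#'
#' @param model A [pl_denoiser()].
#' @param system A [build_system()] result.
#' @param plm Optional `n_res x plm_dim` embedding matrix.
#' @return `N x c_s` matrix.
#' @export
build_single_repr <- function(model, system, plm = NULL) {
  feat <- sys_features(system)
  cfg <- model$config; params <- model$params
  single <- linear_fwd(feat$single, params[["emb.Ws"]], params[["emb.bs"]])$out
  if (!is.null(plm)) {
    if (cfg$plm_dim == 0L)
      stop("model was built without a PLM input (plm_dim = 0)")
    if (nrow(plm) != system$n_res)
      stop("PLM embedding must have one row per residue")
    ln <- layernorm_fwd(plm, params[["emb.plm_g"]], params[["emb.plm_b"]])
    single[seq_len(system$n_res), ] <- single[seq_len(system$n_res), ] +
      linear_fwd(ln$out, params[["emb.Wplm"]])$out
  }
  single
}

#' Build the initial pair representation
#'
#' Protein-protein entries embed the clipped relative-position one-hot;
#' bonded ligand-ligand entries embed the bond features; the remaining blocks
#' carry learned relation-type embeddings distinguishing protein-ligand from
#' unbonded ligand-ligand pairs.
#'
#' @inheritParams build_single_repr
#' @return `N^2 x c_p` matrix (rows in column-major (i, j) order), with
#'   attribute `n_tokens`.
#' @export
build_pair_repr <- function(model, system) {
  feat <- sys_features(system)
  pair <- linear_fwd(feat$pair, model$params[["emb.Wp"]],
                     model$params[["emb.bp"]])$out
  attr(pair, "n_tokens") <- system$n_tokens
  pair
}

#' Run the residual trunk over representations
#'
#' Applies the configured number of folding blocks: pair-biased self-attention
#' updating the single representation, a transition MLP on the single, an
#' outer-product update of the pair from the single, the optional triangular
#' multiplicative update, and a transition on the pair -- all residual, so
#' zero-initialized output projections leave the input unchanged at
#' initialization.
#'
#' @param model A [pl_denoiser()].
#' @param reps A list with `single` (`N x c_s`) and `pair` (`N^2 x c_p`).
#' @return A list with updated `single` and `pair`.
#' @export
trunk_update <- function(model, reps) {
  cfg <- model$config
  n <- nrow(reps$single)
  stopifnot(nrow(reps$pair) == n * n)
  single <- reps$single; pair <- reps$pair
  for (k in seq_len(cfg$n_blocks)) {
    bl <- block_fwd(model$params, cfg, k, single, pair, n)
    single <- bl$single; pair <- bl$pair
  }
  list(single = single, pair = pair)
}

#' Condition the pair representation on a backbone template
#'
#' Adds radial-basis embeddings of the template C-alpha distances to the
#' protein-protein pair block (the template-conditioned model variant). Only
#' distances enter, so the conditioning is invariant to rigid motion of the
#' template; ligand blocks are untouched. With conditioning `"off"` the
#' representations are returned unchanged.
#'
#' @param model A [pl_denoiser()].
#' @param reps A list with `single` and `pair` for a system with `n_res`
#'   protein tokens.
#' @param backbone_coords `n_res x 3` template C-alpha coordinates
#'   (angstroms).
#' @param n_res Number of protein tokens in the system.
#' @return `reps` with the conditioned pair representation.
#' @export
apply_template <- function(model, reps, backbone_coords, n_res) {
  cfg <- model$config
  if (cfg$template_conditioning == "off") return(reps)
  backbone_coords <- as.matrix(backbone_coords)
  if (nrow(backbone_coords) != n_res)
    stop("template must have one coordinate row per residue")
  n <- nrow(reps$single)
  rbf <- distance_embedding(backbone_coords, cfg$n_rbf, cfg$d_max)
  add <- linear_fwd(rbf, model$params[["emb.Wtmpl"]])$out
  rows <- pp_row_index(n, n_res)
  reps$pair[rows, ] <- reps$pair[rows, ] + add
  reps
}

pp_row_index <- function(n, n_res) {
  ii <- rep(seq_len(n), times = n); jj <- rep(seq_len(n), each = n)
  which(ii <= n_res & jj <= n_res)
}

template_rbf_for <- function(cfg, backbone_coords)
  distance_embedding(as.matrix(backbone_coords), cfg$n_rbf, cfg$d_max)

#' Predict the diffusion noise for a latent configuration
#'
#' Runs input embedding (with distance and time features recomputed from the
#' current latent), the residual trunk, and the equivariant head: the final
#' pair representation is symmetrized and mapped by an MLP to a weight matrix
#' `W`, and the prediction for atom i is
#' `sum_{j != i} W_ij / max(||z_i - z_j||, eps) * (z_i - z_j)`,
#' centroid-removed. `W` depends on the coordinates only through distances,
#' so the output rotates with the input and ignores translations.
#'
#' @param model A [pl_denoiser()].
#' @param z_t `N x 3` latent coordinates in diffusion units (angstroms times
#'   `coord_scale`), zero centroid.
#' @param system A [build_system()] result (or a precomputed feature cache).
#' @param t Scalar diffusion time in `[0, 1]`.
#' @param plm Optional PLM embedding matrix.
#' @param template Optional `n_res x 3` backbone template (angstroms), used
#'   when the model was built with `template_conditioning = "backbone"`.
#' @param use_ema Use the EMA shadow parameters if the model carries them.
#' @param native Use the compiled (RcppArmadillo) forward pass where
#'   applicable; the R reference path is used for PLM- or
#'   template-conditioned calls and when `FALSE`.
#' @return A list with `eps_hat` (`N x 3`, zero centroid) and `W` (`N x N`).
#' @export
predict_noise <- function(model, z_t, system, t, plm = NULL, template = NULL,
                          use_ema = FALSE, native = TRUE) {
  feat <- if (inherits(system, "molecular_system")) sys_features(system)
          else system
  if (use_ema && !is.null(model$ema)) model$params <- model$ema$shadow
  z_t <- as.matrix(z_t)
  stopifnot(nrow(z_t) == feat$n)
  if (native && is.null(plm) && is.null(template)) {
    out <- .cpp_predict(model$params, unclass(model$config), feat$single,
                        feat$pair, z_t,
                        time_embedding(t, model$config$d_time))
    return(list(eps_hat = out$eps_hat, W = out$W))
  }
  tmpl_rbf <- NULL; rows <- NULL
  if (!is.null(template)) {
    if (model$config$template_conditioning != "backbone")
      stop("model was not built with template conditioning")
    n_res <- sum(feat$roles == "protein")
    if (nrow(as.matrix(template)) != n_res)
      stop("template must have one coordinate row per residue")
    tmpl_rbf <- template_rbf_for(model$config, template)
    rows <- pp_row_index(feat$n, n_res)
  }
  out <- model_forward(model, feat, z_t, t, plm, tmpl_rbf, rows)
  list(eps_hat = out$eps_hat, W = out$W)
}

#' Recover clean coordinates from a latent and a noise prediction
#'
#' The noise-prediction parameterization of the denoiser:
#' `x_hat = (z_t - sigma_t * eps_hat) / alpha_t`. Affine in both arguments;
#' preserves the zero centroid.
#'
#' @param schedule A [noise_schedule()].
#' @param z_t `N x 3` latent coordinates.
#' @param eps_hat `N x 3` predicted noise.
#' @param t Scalar time in `(0, 1]`.
#' @return `N x 3` denoised coordinate estimate.
#' @export
denoise_to_x <- function(schedule, z_t, eps_hat, t) {
  as_ <- schedule_alpha_sigma(schedule, t)
  (z_t - as_$sigma * eps_hat) / as_$alpha
}

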