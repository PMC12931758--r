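# Contract-level neural components: sequence/pair embedder, the RNA
# transformer block (pair-biased attention, outer-product mean, triangle
# multiplications, optional triangle attention), renormalized attention
# dropout, and the denoising structure module with distogram and pair-error
# heads. Forward passes run on the autodiff tape; inference discards it.

#' Configuration for the composite language model
#'
#' Desk-scale defaults (2 blocks, 32/16 dims); the full-scale settings are
#' expressible but not defaults.
#'
#' @param n_blocks transformer block count.
#' @param d_s,d_z sequence / pair representation widths.
#' @param n_heads sequence-attention heads (must divide `d_s`).
#' @param d_opm outer-product-mean bottleneck width.
#' @param relpos_clip relative-position clip (offsets beyond share one bin).
#' @param mask_fraction masking rate for training batches.
#' @param steps,batch_size,lr optimizer settings.
#' @param crop training sequences longer than this are cropped to a random
#'   contiguous window.
#' @param checkpoint_interval steps between checkpoints (`Inf` disables).
#' @param triangle_attention include triangle-attention sub-modules (the
#'   language model omits them; the folding stack keeps them).
#' @param attn_dropout attention dropout rate used in training mode.
#' @param d_tri triangle-attention width.
#' @return Named list of settings, class `clm_config`.
#' @export
clm_config <- function(n_blocks = 2L, d_s = 32L, d_z = 16L, n_heads = 2L,
                       d_opm = 8L, relpos_clip = 64L, mask_fraction = 0.15,
                       steps = 2000L, batch_size = 4L, lr = 1e-3,
                       crop = 256L, checkpoint_interval = Inf,
                       triangle_attention = FALSE, attn_dropout = 0,
                       d_tri = 8L, pair_weight = NULL) {
  stopifnot(d_s %% n_heads == 0L)
  structure(list(n_blocks = as.integer(n_blocks), d_s = as.integer(d_s),
                 d_z = as.integer(d_z), n_heads = as.integer(n_heads),
                 d_opm = as.integer(d_opm), relpos_clip = as.integer(relpos_clip),
                 mask_fraction = mask_fraction, steps = as.integer(steps),
                 batch_size = as.integer(batch_size), lr = lr,
                 crop = as.integer(crop),
                 checkpoint_interval = checkpoint_interval,
                 triangle_attention = triangle_attention,
                 attn_dropout = attn_dropout, d_tri = as.integer(d_tri),
                 pair_weight = pair_weight),
            class = "clm_config")
}

#' Configuration for the folding stack
#'
#' Full transformer blocks (with triangle attention) plus the denoising
#' structure module.
#'
#' @inheritParams clm_config
#' @param n_iter structure-module iterations.
#' @param d_ipa width of the structure-module attention.
#' @param noise_w,noise_sigma training-time initialization perturbation
#'   (slerp weight and translation scale).
#' @return Named list of settings, class `fold_config`.
#' @export
fold_config <- function(n_blocks = 2L, d_s = 32L, d_z = 16L, n_heads = 2L,
                        d_opm = 4L, relpos_clip = 64L, steps = 600L,
                        lr = 2e-3, attn_dropout = 0.25, d_tri = 8L,
                        n_iter = 2L, d_ipa = 16L,
                        noise_w = 0.1, noise_sigma = 0.1) {
  cfg <- clm_config(n_blocks = n_blocks, d_s = d_s, d_z = d_z,
                    n_heads = n_heads, d_opm = d_opm,
                    relpos_clip = relpos_clip, steps = steps, lr = lr,
                    triangle_attention = TRUE, attn_dropout = attn_dropout,
                    d_tri = d_tri)
  cfg$n_iter <- as.integer(n_iter)
  cfg$d_ipa <- as.integer(d_ipa)
  cfg$noise_w <- noise_w
  cfg$noise_sigma <- noise_sigma
  class(cfg) <- c("fold_config", "clm_config")
  cfg
}

rmat <- function(nr, nc, sd = 0.05) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
zmat <- function(nr, nc) matrix(0, nr, nc)

ln_pair <- function(p, nm, d) {
  p[[paste0(nm, "_g")]] <- matrix(1, 1, d)
  p[[paste0(nm, "_b")]] <- matrix(0, 1, d)
  p
}

init_block_params <- function(config, prefix = "blk1_") {
  d_s <- config$d_s; d_z <- config$d_z; H <- config$n_heads
  dh <- d_s %/% H; dt <- config$d_tri; dc <- config$d_opm
  p <- list()
  p <- ln_pair(p, paste0(prefix, "ln_att"), d_s)
  p <- ln_pair(p, paste0(prefix, "ln_bias"), d_z)
  for (h in seq_len(H)) {
    p[[paste0(prefix, "att_q", h)]] <- rmat(d_s, dh)
    p[[paste0(prefix, "att_k", h)]] <- rmat(d_s, dh)
    p[[paste0(prefix, "att_v", h)]] <- rmat(d_s, dh)
  }
  p[[paste0(prefix, "att_bw")]] <- rmat(d_z, H)
  p[[paste0(prefix, "att_o")]] <- rmat(d_s, d_s, 0.02)
  p <- ln_pair(p, paste0(prefix, "ln_tr"), d_s)
  p[[paste0(prefix, "tr_w1")]] <- rmat(d_s, 2L * d_s)
  p[[paste0(prefix, "tr_b1")]] <- zmat(1, 2L * d_s)
  p[[paste0(prefix, "tr_w2")]] <- rmat(2L * d_s, d_s, 0.02)
  p[[paste0(prefix, "tr_b2")]] <- zmat(1, d_s)
  p <- ln_pair(p, paste0(prefix, "ln_opm"), d_s)
  p[[paste0(prefix, "opm_a")]] <- rmat(d_s, dc)
  p[[paste0(prefix, "opm_b")]] <- rmat(d_s, dc)
  p[[paste0(prefix, "opm_o")]] <- rmat(dc * dc, d_z, 0.02)
  p[[paste0(prefix, "opm_ob")]] <- zmat(1, d_z)
  p <- ln_pair(p, paste0(prefix, "ln_pair"), d_z)
  for (nm in c("tmo", "tmi")) {
    p[[paste0(prefix, nm, "_a")]] <- rmat(d_z, d_z)
    p[[paste0(prefix, nm, "_b")]] <- rmat(d_z, d_z)
    p[[paste0(prefix, nm, "_go")]] <- rmat(d_z, d_z)
    p[[paste0(prefix, nm, "_o")]] <- rmat(d_z, d_z, 0.02)
  }
  if (isTRUE(config$triangle_attention)) {
    for (nm in c("tas", "tae")) {
      p[[paste0(prefix, nm, "_q")]] <- rmat(d_z, dt)
      p[[paste0(prefix, nm, "_k")]] <- rmat(d_z, dt)
      p[[paste0(prefix, nm, "_v")]] <- rmat(d_z, dt)
      p[[paste0(prefix, nm, "_bw")]] <- rmat(d_z, 1)
      p[[paste0(prefix, nm, "_g")]] <- rmat(d_z, d_z)
      p[[paste0(prefix, nm, "_o")]] <- rmat(dt, d_z, 0.02)
    }
  }
  p[[paste0(prefix, "pt_w1")]] <- rmat(d_z, 2L * d_z)
  p[[paste0(prefix, "pt_b1")]] <- zmat(1, 2L * d_z)
  p[[paste0(prefix, "pt_w2")]] <- rmat(2L * d_z, d_z, 0.02)
  p[[paste0(prefix, "pt_b2")]] <- zmat(1, d_z)
  p
}

init_clm_params <- function(config, seed = 1L) {
  with_seed(seed, {
    d_s <- config$d_s; d_z <- config$d_z
    p <- list(
      embed_w = rmat(5, d_s, 0.2),
      row_w = rmat(d_s, d_z),
      col_w = rmat(d_s, d_z),
      relpos_e = rmat(2L * config$relpos_clip + 2L, d_z, 0.1),
      pos_e = rmat(config$crop, d_s, 0.1)
    )
    for (b in seq_len(config$n_blocks)) {
      p <- c(p, init_block_params(config, paste0("blk", b, "_")))
    }
    p <- ln_pair(p, "ln_shead", d_s)
    p <- ln_pair(p, "ln_phead", d_z)
    p$seq_head_w <- rmat(d_s, 4)
    p$seq_head_b <- zmat(1, 4)
    p$pair_head_w <- rmat(d_z, 16)
    p$pair_head_b <- zmat(1, 16)
    p
  })
}

init_fold_params <- function(config, seed = 1L) {
  p <- init_clm_params(config, seed)
  with_seed(seed + 101L, {
    d_s <- config$d_s; d_z <- config$d_z; di <- config$d_ipa
    p <- ln_pair(p, "drsm_ln_s", d_s)
    p <- ln_pair(p, "drsm_ln_z", d_z)
    p$drsm_q <- rmat(d_s, di)
    p$drsm_k <- rmat(d_s, di)
    p$drsm_v <- rmat(d_s, di)
    p$drsm_bw <- rmat(d_z, 1)
    p$drsm_o <- rmat(di, d_s, 0.02)
    p <- ln_pair(p, "drsm_ln_u", d_s)
    p$drsm_quat_w <- zmat(d_s, 3)
    p$drsm_trans_w <- zmat(d_s, 3)
    p$dist_w <- rmat(d_z, 120, 0.02)
    p$dist_b <- zmat(1, 120)
    p$err_w <- rmat(d_z, 1, 0.02)
    p$err_b <- zmat(1, 1)
    p
  })
}

## ---- attention dropout (public numeric op) ----

# sample a keep mask with the all-zero-row fallback; rows with no survivor
# fall back to keeping the full row
dropout_mask <- function(nr, nc, rate) {
  keep <- matrix(stats::runif(nr * nc) >= rate, nr, nc)
  dead <- rowSums(keep) == 0L
  keep[dead, ] <- TRUE
  keep * 1
}

#' Renormalized attention dropout
#'
#' In training mode, independently zeroes each attention weight with
#' probability `rate` and rescales every surviving row to sum to one (rows
#' losing all mass fall back to the unmasked row). In inference mode the map
#' is returned unchanged. Deterministic given `seed`.
#'
#' @param weights attention map whose rows sum to 1.
#' @param rate dropout rate in `[0, 1)`.
#' @param seed integer seed.
#' @param training logical flag.
#' @return Attention map of the same shape with rows summing to 1.
#' @export
attention_dropout <- function(weights, rate = 0.25, seed = 1L,
                              training = TRUE) {
  if (!(rate >= 0 && rate < 1)) stop("dropout rate must be in [0, 1)")
  if (!training || rate == 0) return(weights)
  keep <- with_seed(seed, dropout_mask(nrow(weights), ncol(weights), rate))
  w <- weights * keep
  w / rowSums(w)
}

## ---- tape-level building blocks ----

tape_layernorm <- function(x, leaves, nm) {
  tp_layernorm_rows(x, leaves[[paste0(nm, "_g")]], leaves[[paste0(nm, "_b")]])
}

tape_transition <- function(x, leaves, ln, w1, b1, w2, b2) {
  tape_transition2(tape_layernorm(x, leaves, ln), leaves, w1, b1, w2, b2)
}

tape_transition2 <- function(h, leaves, w1, b1, w2, b2) {
  h <- tp_add_rowvec(tp_mm(h, leaves[[w1]]), leaves[[b1]])
  h <- tp_relu(h)
  tp_add_rowvec(tp_mm(h, leaves[[w2]]), leaves[[b2]])
}

# pair-biased multi-head attention over the sequence representation
tape_seq_attention <- function(s, z, leaves, prefix, L, B, config, training) {
  H <- config$n_heads
  dh <- config$d_s %/% H
  s_ln <- tape_layernorm(s, leaves, paste0(prefix, "ln_att"))
  z_ln <- tape_layernorm(z, leaves, paste0(prefix, "ln_bias"))
  bias_all <- tp_mm(z_ln, leaves[[paste0(prefix, "att_bw")]])
  outs <- vector("list", H)
  for (h in seq_len(H)) {
    q <- tp_mm(s_ln, leaves[[paste0(prefix, "att_q", h)]])
    k <- tp_mm(s_ln, leaves[[paste0(prefix, "att_k", h)]])
    v <- tp_mm(s_ln, leaves[[paste0(prefix, "att_v", h)]])
    logits <- tp_scale(tp_bmm(q, k, L, B, transpose_b = TRUE), 1 / sqrt(dh))
    logits <- tp_add(logits, tp_paircol_as_rows(bias_all, h, L, B))
    a <- tp_softmax_rows(logits)
    if (training && config$attn_dropout > 0) {
      keep <- dropout_mask(B * L, L, config$attn_dropout)
      a <- tp_rownorm1(tp_emul(a, tp_leaf_const(a$tape, keep)))
    }
    outs[[h]] <- tp_bmm(a, v, L, B, transpose_b = FALSE)
  }
  o <- if (H == 1L) outs[[1L]] else tp_cbind(outs)
  tp_mm(o, leaves[[paste0(prefix, "att_o")]])
}

# constant leaf (no gradient tracking needed, but must live on the tape)
tp_leaf_const <- function(tape, value) tp_leaf(tape, value)

tape_tri_mul <- function(z_ln, leaves, prefix, nm, L, B, incoming) {
  a <- tp_mm(z_ln, leaves[[paste0(prefix, nm, "_a")]])
  b <- tp_mm(z_ln, leaves[[paste0(prefix, nm, "_b")]])
  t <- tp_tri_mul(a, b, L, B, incoming = incoming)
  tp_emul(tp_sigmoid(tp_mm(z_ln, leaves[[paste0(prefix, nm, "_go")]])),
          tp_mm(t, leaves[[paste0(prefix, nm, "_o")]]))
}

# triangle attention around the starting node (ending node = transposed)
tape_tri_attention <- function(z_ln, leaves, prefix, nm, L, B, config) {
  dt <- config$d_tri
  q_all <- tp_mm(z_ln, leaves[[paste0(prefix, nm, "_q")]])
  k_all <- tp_mm(z_ln, leaves[[paste0(prefix, nm, "_k")]])
  v_all <- tp_mm(z_ln, leaves[[paste0(prefix, nm, "_v")]])
  bias_col <- tp_mm(z_ln, leaves[[paste0(prefix, nm, "_bw")]])
  att <- tp_tri_attn(q_all, k_all, v_all, bias_col, L, B, dt)
  tp_emul(tp_sigmoid(tp_mm(z_ln, leaves[[paste0(prefix, nm, "_g")]])),
          tp_mm(att, leaves[[paste0(prefix, nm, "_o")]]))
}

# one transformer block; reduced blocks omit the triangle attentions
tape_block <- function(s, z, leaves, prefix, L, B, config, training) {
  s <- tp_add(s, tape_seq_attention(s, z, leaves, prefix, L, B, config, training))
  s <- tp_add(s, tape_transition(s, leaves, paste0(prefix, "ln_tr"),
                                 paste0(prefix, "tr_w1"), paste0(prefix, "tr_b1"),
                                 paste0(prefix, "tr_w2"), paste0(prefix, "tr_b2")))
  s_ln <- tape_layernorm(s, leaves, paste0(prefix, "ln_opm"))
  a <- tp_mm(s_ln, leaves[[paste0(prefix, "opm_a")]])
  b <- tp_mm(s_ln, leaves[[paste0(prefix, "opm_b")]])
  zup <- tp_add_rowvec(tp_mm(tp_opm(a, b, L, B), leaves[[paste0(prefix, "opm_o")]]),
                       leaves[[paste0(prefix, "opm_ob")]])
  z <- tp_add(z, zup)
  # pair sub-modules read one shared normalized view and update in parallel
  z_ln <- tape_layernorm(z, leaves, paste0(prefix, "ln_pair"))
  z <- tp_add(z, tape_tri_mul(z_ln, leaves, prefix, "tmo", L, B, incoming = FALSE))
  z <- tp_add(z, tape_tri_mul(z_ln, leaves, prefix, "tmi", L, B, incoming = TRUE))
  if (isTRUE(config$triangle_attention)) {
    z <- tp_add(z, tape_tri_attention(z_ln, leaves, prefix, "tas", L, B, config))
    zt <- tp_pair_transpose(z_ln, L, B)
    upd <- tape_tri_attention(zt, leaves, prefix, "tae", L, B, config)
    z <- tp_add(z, tp_pair_transpose(upd, L, B))
  }
  z <- tp_add(z, tape_transition2(z_ln, leaves,
                                  paste0(prefix, "pt_w1"), paste0(prefix, "pt_b1"),
                                  paste0(prefix, "pt_w2"), paste0(prefix, "pt_b2")))
  list(s = s, z = z)
}

# full network trunk: one-hot batch (B*L x 5) -> (s, z) nodes. The embedding
# itself is position-free; learned absolute and relative position features
# are added here, at the entry of the block stack.
tape_trunk <- function(X, leaves, L, B, config, training) {
  s <- tp_mm(X, leaves$embed_w)
  s <- tp_add(s, tp_rows(leaves$pos_e, rep(seq_len(L), B)))
  z <- tp_pair_broadcast(tp_mm(s, leaves$row_w), tp_mm(s, leaves$col_w), L, B)
  z <- tp_add(z, tp_relpos(leaves$relpos_e, L, B, config$relpos_clip))
  for (b in seq_len(config$n_blocks)) {
    sz <- tape_block(s, z, leaves, paste0("blk", b, "_"), L, B, config, training)
    s <- sz$s
    z <- sz$z
  }
  list(s = s, z = z)
}

tape_seq_head <- function(s, leaves) {
  tp_add_rowvec(tp_mm(tape_layernorm(s, leaves, "ln_shead"),
                      leaves$seq_head_w), leaves$seq_head_b)
}

tape_pair_head <- function(z, leaves) {
  tp_add_rowvec(tp_mm(tape_layernorm(z, leaves, "ln_phead"),
                      leaves$pair_head_w), leaves$pair_head_b)
}

softmax_rows_num <- function(x) {
  x <- x - rowmax(x)
  e <- exp(x)
  e / rowSums(e)
}

## ---- public contract-level interfaces ----

#' Embed a sequence into initial sequence and pair representations
#'
#' The sequence representation is a learned linear map of the one-hot input;
#' the pair representation broadcasts two independent projections of it along
#' rows and columns and sums them (entry (i, j) = rowproj(i) + colproj(j)).
#' Learned relative-position features are added later, at the entry of the
#' block stack, so the embedding itself is position-free.
#'
#' @param model a `clm_model` (or a bare list with `params`).
#' @param seq RNA sequence (may contain the mask symbol `N`).
#' @return List with `s` (`L x d_s`) and `z` (`L x L x d_z`).
#' @export
embed_sequence <- function(model, seq) {
  if (nchar(seq) < 1L) stop("empty sequence")
  p <- model$params
  X <- one_hot(seq)
  L <- nrow(X)
  s <- X %*% p$embed_w
  zr <- s %*% p$row_w
  zc <- s %*% p$col_w
  d_z <- ncol(zr)
  z <- matrix(0, L * L, d_z)
  ii <- rep(seq_len(L), times = L)
  jj <- rep(seq_len(L), each = L)
  z <- zr[ii, , drop = FALSE] + zc[jj, , drop = FALSE]
  list(s = s, z = array(z, c(L, L, d_z)))
}

#' Apply one transformer block
#'
#' Shape-preserving update of the sequence and pair representations:
#' pair-biased multi-head attention plus transition on the sequence side;
#' outer-product mean, gated triangle multiplications (outgoing/incoming),
#' optional triangle attention around starting and ending nodes, and a pair
#' transition on the pair side. The `triangle_attention` flag in `config`
#' switches between the full and the reduced (language-model) block.
#'
#' @param s `L x d_s` sequence representation.
#' @param z `L x L x d_z` pair representation.
#' @param config a `clm_config`.
#' @param params block parameters (default: freshly initialized from `seed`).
#' @param seed seed for parameter initialization and dropout.
#' @param training training mode (enables attention dropout).
#' @return List with updated `s` and `z` of identical shapes.
#' @export
transformer_block <- function(s, z, config = clm_config(), params = NULL,
                              seed = 1L, training = FALSE) {
  L <- nrow(s)
  d_z <- dim(z)[3]
  stopifnot(dim(z)[1] == L, dim(z)[2] == L,
            ncol(s) == config$d_s, d_z == config$d_z)
  if (is.null(params)) {
    params <- with_seed(seed, init_block_params(config, prefix = "blk1_"))
  }
  run <- function() {
    tape <- tp_tape()
    leaves <- tp_params(tape, params)
    sn <- tp_leaf(tape, s)
    zn <- tp_leaf(tape, matrix(z, L * L, d_z))
    out <- tape_block(sn, zn, leaves, "blk1_", L, 1L, config, training)
    list(s = out$s$value, z = array(out$z$value, c(L, L, d_z)))
  }
  if (training) with_seed(seed, run()) else run()
}

## ---- denoising structure module ----

tape_drsm <- function(s, z, leaves, L, config, init_q, init_t, training) {
  s_ln <- tape_layernorm(s, leaves, "drsm_ln_s")
  z_ln <- tape_layernorm(z, leaves, "drsm_ln_z")
  bias_col <- tp_mm(z_ln, leaves$drsm_bw)
  bias <- tp_paircol_as_rows(bias_col, 1L, L, 1L)
  q_cur <- init_q
  t_cur <- init_t
  s_work <- s_ln
  for (it in seq_len(config$n_iter)) {
    q <- tp_mm(s_work, leaves$drsm_q)
    k <- tp_mm(s_work, leaves$drsm_k)
    v <- tp_mm(s_work, leaves$drsm_v)
    logits <- tp_add(tp_scale(tp_mm(q, tp_t(k)), 1 / sqrt(config$d_ipa)), bias)
    a <- tp_softmax_rows(logits)
    if (training && config$attn_dropout > 0) {
      keep <- dropout_mask(L, L, config$attn_dropout)
      a <- tp_rownorm1(tp_emul(a, tp_leaf_const(a$tape, keep)))
    }
    s_work <- tp_add(s_work, tp_mm(tp_mm(a, v), leaves$drsm_o))
    u <- tape_layernorm(s_work, leaves, "drsm_ln_u")
    qv <- tp_mm(u, leaves$drsm_quat_w)
    ones <- tp_leaf_const(qv$tape, matrix(1, L, 1))
    q_upd <- tp_quat_normalize(tp_cbind(list(ones, qv)))
    t_upd <- tp_mm(u, leaves$drsm_trans_w)
    r_upd <- tp_quat_to_R9(q_upd)
    # left-compose the predicted update: T <- T_upd o T
    q_cur <- tp_quat_normalize(tp_quat_mul(q_upd, q_cur))
    t_cur <- tp_add(tp_rotate_rows(r_upd, t_cur), t_upd)
  }
  dist_logits <- tp_add_rowvec(tp_mm(z_ln, leaves$dist_w), leaves$dist_b)
  err <- tp_softplus(tp_add_rowvec(tp_mm(z_ln, leaves$err_w), leaves$err_b))
  list(q = q_cur, t = t_cur, dist_logits = dist_logits, err = err)
}

#' Denoising structure module forward pass
#'
#' Iteratively refines per-nucleotide rigid frames from the sequence and pair
#' representations, starting from `init` (black-hole initialization by
#' default). In training mode the initial frames are first perturbed with
#' [perturb_frames()] (`noise_w`, `noise_sigma` from the config). Rotations
#' are re-orthogonalized on output. Also emits the distogram head (40 bins
#' over three atom-pair channels) and the non-negative pair-error map.
#'
#' @param s `L x d_s` sequence representation.
#' @param z `L x L x d_z` pair representation.
#' @param init a `frame_set` (default black-hole).
#' @param config a `fold_config`.
#' @param params folding parameters (default: initialized from `seed`).
#' @param training training mode (adds initialization noise and dropout).
#' @param seed seed for noise.
#' @return List with `frames` (a `frame_set`), `distogram` and `pair_error`
#'   (`L x L` matrix).
#' @export
drsm_forward <- function(s, z, init = NULL, config = fold_config(),
                         params = NULL, training = FALSE, seed = 1L) {
  L <- nrow(s)
  d_z <- dim(z)[3]
  if (is.null(init)) init <- black_hole_frames(L)
  stopifnot(length(init) == L)
  if (is.null(params)) params <- init_fold_params(config, seed)
  if (training) {
    init <- perturb_frames(init, config$noise_w, config$noise_sigma, seed)
  }
  q0 <- t(apply(fs_R9(init), 1L, function(r) {
    rot_to_quat(matrix(r, 3, 3, byrow = TRUE))
  }))
  run <- function() {
    tape <- tp_tape()
    leaves <- tp_params(tape, params)
    sn <- tp_leaf(tape, s)
    zn <- tp_leaf(tape, matrix(z, L * L, d_z))
    init_q <- tp_leaf(tape, q0)
    init_t <- tp_leaf(tape, init$translations)
    out <- tape_drsm(sn, zn, leaves, L, config, init_q, init_t, training)
    out
  }
  out <- if (training) with_seed(seed + 7L, run()) else run()
  R9 <- quat_to_R9(out$q$value)
  rot <- array(0, c(3, 3, L))
  for (l in seq_len(L)) {
    rot[, , l] <- symmetric_orthogonalize(matrix(R9[l, ], 3, 3, byrow = TRUE))
  }
  frames <- frame_set(rot, out$t$value)
  dg <- distogram_from_logits(out$dist_logits$value, L)
  err <- matrix(out$err$value, L, L)
  list(frames = frames, distogram = dg, pair_error = err)
}

distogram_from_logits <- function(logits, L) {
  distogram(list(PP = softmax_rows_num(logits[, 1:40, drop = FALSE]),
                 CC = softmax_rows_num(logits[, 41:80, drop = FALSE]),
                 NN = softmax_rows_num(logits[, 81:120, drop = FALSE])), L)
}
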