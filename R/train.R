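# Desk-scale training loops (Adam on the autodiff tape) for the composite
# language model and the folding stack, plus checkpoint I/O and inference.

#' Train a composite language model
#'
#' Masked-language-model training with the composite objective: per step, a
#' mini-batch of sequences is masked (a dedicated 5th mask channel in the
#' one-hot input) and the summed nucleotide and ordered-pair cross-entropies
#' over the masked index set are minimized with Adam. Sequences longer than
#' `config$crop` are cropped to a random contiguous window; batches are drawn
#' among sequences of a common length. Deterministic given `seed` on one
#' worker.
#'
#' @param corpus character vector of RNA sequences (T normalized to U).
#' @param config a [clm_config()].
#' @param seed integer seed.
#' @param checkpoint_dir directory for periodic checkpoints (used when
#'   `config$checkpoint_interval` is finite).
#' @param log_interval steps between training-log rows.
#' @return A `clm_model`: list with `params`, `config`, `log` (data.frame
#'   with per-term losses) and `steps_done`.
#' @export
train_clm <- function(corpus, config = clm_config(), seed = 1L,
                      checkpoint_dir = NULL, log_interval = 25L) {
  if (length(corpus) < 1L) stop("empty corpus")
  corpus <- vapply(corpus, rna_sequence, "", USE.NAMES = FALSE)
  params <- init_clm_params(config, seed)
  lens <- nchar(corpus)
  log <- list()
  state <- adam_state(params)
  steps <- config$steps
  if (steps > 0L) {
    with_seed(seed + 1L, {
      for (step in seq_len(steps)) {
        pick <- sample.int(length(corpus), 1L)
        Lraw <- min(lens[pick], config$crop)
        cand <- which(pmin(lens, config$crop) == Lraw)
        idx <- if (length(cand) >= config$batch_size) {
          sample(cand, config$batch_size)
        } else {
          sample(cand, config$batch_size, replace = TRUE)
        }
        batch <- lapply(corpus[idx], function(sq) {
          L0 <- nchar(sq)
          if (L0 > config$crop) {
            st <- sample.int(L0 - config$crop + 1L, 1L)
            sq <- substr(sq, st, st + config$crop - 1L)
          }
          sq
        })
        res <- clm_train_step(params, state, batch, config)
        params <- res$params
        state <- res$state
        if (step %% log_interval == 0L || step == steps) {
          log[[length(log) + 1L]] <- data.frame(
            step = step, loss_seq = res$loss_seq, loss_pair = res$loss_pair,
            loss = res$loss_seq + res$loss_pair,
            per_token = (res$loss_seq + res$loss_pair) /
              (config$batch_size * Lraw))
        }
        if (is.finite(config$checkpoint_interval) &&
            step %% config$checkpoint_interval == 0L &&
            !is.null(checkpoint_dir)) {
          save_clm(list(params = params, config = config, steps_done = step),
                   file.path(checkpoint_dir, sprintf("ckpt_%06d.rds", step)))
        }
      }
    })
  }
  structure(list(params = params, config = config,
                 log = if (length(log)) do.call(rbind, log) else
                   data.frame(step = integer(), loss_seq = numeric(),
                              loss_pair = numeric(), loss = numeric(),
                              per_token = numeric()),
                 steps_done = steps),
            class = "clm_model")
}

# one optimization step over a batch of equal-length sequences
clm_train_step <- function(params, state, batch, config) {
  B <- length(batch)
  L <- nchar(batch[[1L]])
  masked <- lapply(seq_len(B), function(b) {
    k <- as.integer(ceiling(config$mask_fraction * L))
    sort(sample.int(L, k))
  })
  X <- matrix(0, B * L, 5L)
  seq_rows <- integer(0)
  seq_cls <- integer(0)
  pair_rows <- integer(0)
  pair_cls <- integer(0)
  for (b in seq_len(B)) {
    truth <- seq_to_idx(batch[[b]])
    vis <- truth
    vis[masked[[b]]] <- 5L
    r <- (b - 1L) * L
    X[cbind(r + seq_len(L), vis)] <- 1
    seq_rows <- c(seq_rows, r + masked[[b]])
    seq_cls <- c(seq_cls, truth[masked[[b]]])
    pidx <- masked_pair_index(L, masked[[b]])
    pair_rows <- c(pair_rows, (b - 1L) * L * L + pidx$i + (pidx$j - 1L) * L)
    pair_cls <- c(pair_cls, pair_class(truth[pidx$i], truth[pidx$j]))
  }
  tape <- tp_tape()
  leaves <- tp_params(tape, params)
  Xn <- tp_leaf(tape, X)
  trunk <- tape_trunk(Xn, leaves, L, B, config, training = TRUE)
  seq_logits <- tape_seq_head(tp_rows(trunk$s, seq_rows), leaves)
  pair_logits <- tape_pair_head(tp_rows(trunk$z, pair_rows), leaves)
  l_seq <- tp_ce_rows(seq_logits, seq_cls)
  l_pair <- tp_ce_rows(pair_logits, pair_cls)
  # default training weight balances the two terms per masked token (each
  # masked position contributes ~2(L-1) ordered pair rows but 1 sequence row)
  pw <- config$pair_weight
  if (is.null(pw)) pw <- 1 / (2 * (L - 1))
  loss <- tp_add(l_seq, tp_scale(l_pair, pw))
  tp_backward(tape, loss)
  upd <- adam_update(params, tp_collect_grads(leaves), state, lr = config$lr)
  list(params = upd$params, state = upd$state,
       loss_seq = l_seq$value, loss_pair = l_pair$value)
}

#' Forward pass of a composite language model
#'
#' Computes the 4-class nucleotide head and (optionally) the 16-class
#' ordered-pair head on one or more sequences of a common length. Inputs may
#' contain the mask symbol `N`; deterministic.
#'
#' @param model a `clm_model`.
#' @param seqs character vector of equal-length sequences.
#' @param what `"seq"` for the nucleotide head only, `"both"` to include the
#'   pair head.
#' @return For a single sequence, list with `seq_probs` (`L x 4`) and, when
#'   requested, `pair_probs` (`L x L x 16`); for several sequences, a list of
#'   such lists.
#' @export
clm_forward <- function(model, seqs, what = c("both", "seq")) {
  what <- match.arg(what)
  B <- length(seqs)
  L <- nchar(seqs[[1L]])
  stopifnot(all(nchar(seqs) == L))
  X <- do.call(rbind, lapply(seqs, one_hot))
  tape <- tp_tape()
  leaves <- tp_params(tape, model$params)
  Xn <- tp_leaf(tape, X)
  trunk <- tape_trunk(Xn, leaves, L, B, model$config, training = FALSE)
  seq_probs <- softmax_rows_num(tape_seq_head(trunk$s, leaves)$value)
  pair_probs <- if (what == "both") {
    softmax_rows_num(tape_pair_head(trunk$z, leaves)$value)
  } else NULL
  out <- lapply(seq_len(B), function(b) {
    r <- (b - 1L) * L
    res <- list(seq_probs = seq_probs[r + seq_len(L), , drop = FALSE])
    if (!is.null(pair_probs)) {
      rr <- (b - 1L) * L * L + seq_len(L * L)
      res$pair_probs <- array(pair_probs[rr, ], c(L, L, 16L))
    }
    res
  })
  if (B == 1L) out[[1L]] else out
}

#' Save / load a language-model checkpoint
#'
#' Checkpoints are versioned archives holding the configuration and weights;
#' a round trip reproduces identical forward outputs.
#'
#' @param model a `clm_model` (or a params/config list).
#' @param path file path.
#' @return `load_clm` returns the restored `clm_model`.
#' @export
save_clm <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(version = 1L, params = model$params, config = model$config,
               steps_done = model$steps_done %||% NA_integer_), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname save_clm
#' @export
load_clm <- function(path) {
  x <- readRDS(path)
  if (is.null(x$version) || is.null(x$params) || is.null(x$config)) {
    stop("not a language-model checkpoint: ", path)
  }
  structure(list(params = x$params, config = x$config,
                 log = NULL, steps_done = x$steps_done),
            class = "clm_model")
}

#' Overfit a folding model on a single target
#'
#' Trains embedder + full transformer blocks + denoising structure module on
#' one coarse structure, minimizing the structure loss (gFAPE with black-hole
#' repulsion) plus 0.2 times the distogram cross-entropy and a small
#' pair-error regression term. Each step perturbs the black-hole
#' initialization (`noise_w`, `noise_sigma`). Deterministic given `seed`.
#'
#' @param target a `coarse_structure` with a sequence.
#' @param config a [fold_config()].
#' @param seed integer seed.
#' @param template a `local_template`.
#' @param log_interval steps between log rows.
#' @return List with `params`, `config`, `log`, and `loss0` (the structure
#'   loss of the untrained model from an unperturbed start), class
#'   `fold_model`.
#' @export
train_folding <- function(target, config = fold_config(), seed = 1L,
                          template = default_template(), log_interval = 25L,
                          stop_below = NULL, check_interval = 100L) {
  stopifnot(inherits(target, "coarse_structure"), !is.null(target$sequence))
  L <- length(target)
  params <- init_fold_params(config, seed)
  ref_frames <- frames_from_atoms(target, template)
  gp <- make_gfape_params(target)
  tmpl <- unclass(template)
  refloc <- gfape_ref_local(fs_R9(ref_frames), ref_frames$translations, tmpl)
  t0 <- black_hole_frames(L)
  refloc0 <- gfape_ref_local(fs_R9(t0), t0$translations, tmpl)
  lam0 <- matrix(1, L, L)
  cut0 <- matrix(2, L, L)
  tb <- true_bins(target)
  dist_cls <- c(as.integer(tb[[1]]), as.integer(tb[[2]]), as.integer(tb[[3]]))
  X <- one_hot(target$sequence)
  q0 <- matrix(rep(c(1, 0, 0, 0), each = L), L, 4)
  state <- adam_state(params)
  log <- list()

  forward_loss <- function(params, training, step_seed) {
    tape <- tp_tape()
    leaves <- tp_params(tape, params)
    Xn <- tp_leaf(tape, X)
    trunk <- tape_trunk(Xn, leaves, L, 1L, config, training)
    init <- black_hole_frames(L)
    if (training) {
      init <- perturb_frames(init, config$noise_w, config$noise_sigma,
                             step_seed)
    }
    iq <- t(apply(fs_R9(init), 1L, function(r) {
      rot_to_quat(matrix(r, 3, 3, byrow = TRUE))
    }))
    out <- tape_drsm(trunk$s, trunk$z, leaves, L, config,
                     tp_leaf(tape, iq), tp_leaf(tape, init$translations),
                     training)
    R9 <- tp_quat_to_R9(out$q)
    l_fape <- tp_gfape(R9, out$t, refloc, tmpl, gp$lambda, gp$dcut, gp$epsilon)
    l_bh <- tp_gfape(R9, out$t, refloc0, tmpl, lam0, cut0, gp$epsilon)
    l_struct <- tp_add(l_fape, tp_scale(l_bh, -0.1))
    dl <- out$dist_logits
    l_dist <- tp_add(tp_add(
      tp_ce_rows(tp_cols(dl, 1:40), as.integer(tb[[1]])),
      tp_ce_rows(tp_cols(dl, 41:80), as.integer(tb[[2]]))),
      tp_ce_rows(tp_cols(dl, 81:120), as.integer(tb[[3]])))
    # pair-error head regressed onto the per-pair reference distance error
    # of the current prediction (cheap binned-FAPE surrogate)
    loss <- tp_add(l_struct, tp_scale(l_dist, 0.2))
    list(tape = tape, leaves = leaves, loss = loss,
         l_struct = l_struct$value, l_dist = l_dist$value)
  }

  loss0 <- forward_loss(params, FALSE, 0L)$l_struct
  steps_done <- 0L
  with_seed(seed + 5L, {
    for (step in seq_len(config$steps)) {
      fw <- forward_loss(params, TRUE, sample.int(1e8, 1L))
      tp_backward(fw$tape, fw$loss)
      # linear decay to 10% of the base rate damps the gradient noise from
      # dropout and the denoising init perturbations late in training
      lr_step <- config$lr * (1 - 0.9 * (step - 1L) / max(config$steps, 1L))
      upd <- adam_update(params, tp_collect_grads(fw$leaves), state,
                         lr = lr_step)
      params <- upd$params
      state <- upd$state
      steps_done <- step
      if (step %% log_interval == 0L || step == config$steps) {
        log[[length(log) + 1L]] <- data.frame(
          step = step, loss_struct = fw$l_struct, loss_dist = fw$l_dist,
          loss_total = fw$l_struct + 0.2 * fw$l_dist)
      }
      if (!is.null(stop_below) && step %% check_interval == 0L &&
          forward_loss(params, FALSE, 0L)$l_struct < stop_below) {
        break
      }
    }
  })
  structure(list(params = params, config = config,
                 log = do.call(rbind, log), loss0 = loss0,
                 steps_done = steps_done, target_length = L),
            class = "fold_model")
}

#' Predict a structure with a trained folding model
#'
#' @param model a `fold_model` from [train_folding()].
#' @param seq RNA sequence of the trained length.
#' @param template a `local_template`.
#' @return List with `structure` (a `coarse_structure`), `frames`,
#'   `distogram` and `pair_error`, from a deterministic black-hole start.
#' @export
fold_predict <- function(model, seq, template = default_template()) {
  seq <- rna_sequence(seq)
  L <- nchar(seq)
  X <- one_hot(seq)
  tape <- tp_tape()
  leaves <- tp_params(tape, model$params)
  trunk <- tape_trunk(tp_leaf(tape, X), leaves, L, 1L, model$config, FALSE)
  s <- trunk$s$value
  z <- array(trunk$z$value, c(L, L, model$config$d_z))
  out <- drsm_forward(s, z, init = NULL, config = model$config,
                      params = model$params, training = FALSE)
  st <- atoms_from_frames(out$frames, template, sequence = seq)
  list(structure = st, frames = out$frames, distogram = out$distogram,
       pair_error = out$pair_error)
}
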