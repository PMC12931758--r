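# Consensus post-processing over a decoy pool: composite deep-learning
# energies (frame-consensus gFAPE + distogram agreement), base-pair-count
# filtering, top-k selection, L-BFGS conformation optimization, greedy
# RMSD clustering and final model ranking.

#' Decoy pool
#'
#' A collection of candidate conformations with their predicted distance
#' probability maps and per-pair error weights.
#'
#' @param decoys list of decoys; each is a list with `structure` (a
#'   `coarse_structure`), `distogram` (a [distogram()], may be `NULL`) and
#'   `weights` (`L x L` non-negative matrix, may be `NULL` for uniform).
#' @return Object of class `decoy_pool`.
#' @export
decoy_pool <- function(decoys) {
  stopifnot(length(decoys) >= 1L)
  L <- length(decoys[[1L]]$structure)
  for (d in decoys) {
    stopifnot(inherits(d$structure, "coarse_structure"),
              length(d$structure) == L)
    if (!is.null(d$distogram)) stopifnot(d$distogram$L == L)
    if (!is.null(d$weights)) {
      stopifnot(nrow(d$weights) == L, ncol(d$weights) == L,
                all(is.finite(d$weights)), all(d$weights >= 0))
    }
  }
  structure(list(decoys = decoys, L = L), class = "decoy_pool")
}

#' @export
length.decoy_pool <- function(x) length(x$decoys)

#' @export
print.decoy_pool <- function(x, ...) {
  cat("<decoy_pool>", length(x), "decoys of length", x$L, "\n")
  invisible(x)
}

pool_weights <- function(pool, n) {
  w <- pool$decoys[[n]]$weights
  if (is.null(w)) matrix(1, pool$L, pool$L) else w
}

# cached per-decoy frame sets and gFAPE reference locals
pool_frame_cache <- function(pool, template) {
  lapply(pool$decoys, function(d) {
    fs <- frames_from_atoms(d$structure, template)
    list(frames = fs,
         refloc = gfape_ref_local(fs_R9(fs), fs$translations,
                                  unclass(template)))
  })
}

#' Consensus end-to-end (frame) energy
#'
#' Sum over the pool of gFAPE deviations between the scored conformation and
#' each decoy's frames, weighted per pair by the decoy's error map (uniform
#' weights when absent) with no deviation clamp. Invariant to global rigid
#' motion of the scored conformation.
#'
#' @param conf a `frame_set` (or `coarse_structure`) to score.
#' @param pool a `decoy_pool`.
#' @param template a `local_template`.
#' @param epsilon gFAPE smoothing constant.
#' @return Scalar energy.
#' @export
e2e_energy <- function(conf, pool, template = default_template(),
                       epsilon = 1e-3) {
  if (length(pool) < 1L) stop("empty decoy pool")
  if (inherits(conf, "coarse_structure")) {
    conf <- frames_from_atoms(conf, template)
  }
  stopifnot(length(conf) == pool$L)
  cache <- pool_frame_cache(pool, template)
  R9 <- fs_R9(conf)
  tr <- conf$translations
  tot <- 0
  dct <- matrix(Inf, pool$L, pool$L)
  for (n in seq_along(cache)) {
    tot <- tot + gfape_core(R9, tr, cache[[n]]$refloc, unclass(template),
                            pool_weights(pool, n), dct, epsilon)$value
  }
  tot
}

# per-pool score tables for the distogram energy: for each channel, an
# (L^2 x 40) matrix of log((P + c) / (P_gM + c)) summed over decoys
dist_score_tables <- function(pool, c0 = 0.001) {
  gM <- last_closed_bin()
  chans <- c("PP", "CC", "NN")
  out <- lapply(chans, function(ch) {
    acc <- NULL
    for (d in pool$decoys) {
      if (is.null(d$distogram)) {
        stop("decoy without distogram cannot enter the distance energy")
      }
      p <- d$distogram$channels[[ch]]
      s <- -log((p + c0) / (p[, gM] + c0))
      acc <- if (is.null(acc)) s else acc + s
    }
    acc
  })
  names(out) <- chans
  out
}

#' Consensus distance (distogram) energy
#'
#' For every decoy, channel (P-P, C4'-C4', N-N) and nucleotide pair, the
#' negative log ratio of the predicted probability at the conformation's
#' binned distance to the probability of the last closed bin below 40
#' Angstrom (both offset by 0.001); the reference-state form makes low
#' energy correspond to agreement with the predicted maps. Uniform
#' distogram slices give exactly zero. Ordered pairs (i != j) are summed.
#'
#' @param conf a `coarse_structure`.
#' @param pool a `decoy_pool` whose decoys carry distograms.
#' @param binning a [distance_binning()].
#' @return Scalar energy.
#' @export
dist_energy <- function(conf, pool, binning = distance_binning()) {
  stopifnot(inherits(conf, "coarse_structure"), length(conf) == pool$L)
  dist_energy_tables(conf, dist_score_tables(pool), pool$L, binning)
}

# cache-aware internals shared by scoring and selection
e2e_energy_cached <- function(conf, pool, cache, template, epsilon = 1e-3) {
  R9 <- fs_R9(conf)
  tr <- conf$translations
  dct <- matrix(Inf, pool$L, pool$L)
  tot <- 0
  for (n in seq_along(cache)) {
    tot <- tot + gfape_core(R9, tr, cache[[n]]$refloc, unclass(template),
                            pool_weights(pool, n), dct, epsilon)$value
  }
  tot
}

dist_energy_tables <- function(conf, tables, L, binning = distance_binning()) {
  atoms <- c("P", "C4'", "N")
  off_diag <- rep(seq_len(L), times = L) != rep(seq_len(L), each = L)
  tot <- 0
  for (k in 1:3) {
    d <- as.matrix(stats::dist(atom_coords(conf, atoms[k])))
    b <- bin_distance(as.numeric(d), binning)
    sc <- tables[[k]][cbind(seq_len(L * L), b)]
    tot <- tot + sum(sc[off_diag])
  }
  tot
}

#' Global consensus energy
#'
#' @param conf a `coarse_structure` (frames are fitted for the end-to-end
#'   term).
#' @param pool a `decoy_pool`.
#' @param template a `local_template`.
#' @return List with `e2e`, `dist` and `total` (their sum), class
#'   `energy_breakdown`.
#' @export
global_energy <- function(conf, pool, template = default_template()) {
  e <- e2e_energy(conf, pool, template)
  d <- dist_energy(conf, pool)
  structure(list(e2e = e, dist = d, total = e + d),
            class = "energy_breakdown")
}

#' Base-pair-count filter for large targets
#'
#' For targets longer than 150 nucleotides, removes decoys whose detected
#' base-pair count falls below 90 percent of the pool maximum; shorter
#' targets pass through unchanged. The maximal-count decoy always survives.
#'
#' @param pool a `decoy_pool`.
#' @param length_threshold length above which the filter applies.
#' @param fraction count threshold as a fraction of the maximum.
#' @return The filtered `decoy_pool`.
#' @export
bp_count_filter <- function(pool, length_threshold = 150L, fraction = 0.9) {
  if (pool$L <= length_threshold) return(pool)
  counts <- vapply(pool$decoys, function(d) {
    length(detect_base_pairs(d$structure))
  }, 1L)
  keep <- counts >= fraction * max(counts)
  decoy_pool(pool$decoys[keep])
}

#' Select the lowest-energy decoys
#'
#' Scores every decoy against the whole pool with the global consensus
#' energy and returns the `k` lowest, ties broken by pool index. If `k`
#' exceeds the pool size, all decoys are returned with a warning.
#'
#' @param pool a `decoy_pool`.
#' @param k number of decoys to select.
#' @param template a `local_template`.
#' @return List with `pool` (the selected `decoy_pool`), `order` (original
#'   indices) and `energies` (data.frame of per-decoy breakdowns).
#' @export
select_models <- function(pool, k = 5L, template = default_template()) {
  N <- length(pool)
  if (k > N) {
    warning("k exceeds the pool size; returning all decoys")
    k <- N
  }
  cache <- pool_frame_cache(pool, template)
  tables <- dist_score_tables(pool)
  eb <- lapply(seq_len(N), function(n) {
    e <- e2e_energy_cached(cache[[n]]$frames, pool, cache, template)
    d <- dist_energy_tables(pool$decoys[[n]]$structure, tables, pool$L)
    structure(list(e2e = e, dist = d, total = e + d),
              class = "energy_breakdown")
  })
  tot <- vapply(eb, `[[`, 1, "total")
  o <- order(tot, seq_len(N))[seq_len(k)]
  list(pool = decoy_pool(pool$decoys[o]), order = o,
       energies = data.frame(index = seq_len(N),
                             e2e = vapply(eb, `[[`, 1, "e2e"),
                             dist = vapply(eb, `[[`, 1, "dist"),
                             total = tot))
}

# smooth (piecewise-linear in distance) optimization objective on the tape;
# returns a closure value/gradient over the 7L frame parameter vector
make_opt_objective <- function(selected, template, epsilon = 1e-3,
                               local_atoms = NULL) {
  L <- selected$L
  cache <- pool_frame_cache(selected, template)
  tables <- dist_score_tables(selected)
  centers <- c(1.5, seq(2.5, 39.5, by = 1), 40.5)
  # zero out the diagonal rows so they contribute no score or gradient
  diag_rows <- which(rep(seq_len(L), times = L) == rep(seq_len(L), each = L))
  for (k in 1:3) tables[[k]][diag_rows, ] <- 0
  tmpl <- unclass(template)
  if (is.null(local_atoms)) {
    local_atoms <- lapply(1:3, function(k) {
      matrix(tmpl[k, ], L, 3, byrow = TRUE)
    })
  }
  dct <- matrix(Inf, L, L)
  eval_fn <- function(par, want_grad = TRUE) {
    q <- matrix(par[seq_len(4L * L)], L, 4)
    tr <- matrix(par[4L * L + seq_len(3L * L)], L, 3)
    tape <- tp_tape()
    qn <- tp_leaf(tape, q)
    tn <- tp_leaf(tape, tr)
    qu <- tp_quat_normalize(qn)
    R9 <- tp_quat_to_R9(qu)
    terms <- vector("list", 0L)
    for (n in seq_along(cache)) {
      terms[[length(terms) + 1L]] <-
        tp_gfape(R9, tn, cache[[n]]$refloc, tmpl,
                 pool_weights(selected, n), dct, epsilon)
    }
    # atom coordinates for the smooth distance term (per-nucleotide local
    # coordinates of the starting structure, so a zero update reproduces
    # its actual distances)
    for (k in 1:3) {
      ak <- tp_add(tp_rotate_rows(R9, tp_leaf_const(tape, local_atoms[[k]])),
                   tn)
      terms[[length(terms) + 1L]] <-
        tp_dist_score(tp_pairdist(ak), tables[[k]], centers)
    }
    loss <- terms[[1L]]
    for (t in terms[-1L]) loss <- tp_add(loss, t)
    if (!want_grad) return(list(value = loss$value))
    tp_backward(tape, loss)
    list(value = loss$value,
         grad = c(as.numeric(qn$grad), as.numeric(tn$grad)))
  }
  eval_fn
}

frames_to_par <- function(fs) {
  L <- length(fs)
  q <- t(apply(fs_R9(fs), 1L, function(r) {
    rot_to_quat(matrix(r, 3, 3, byrow = TRUE))
  }))
  c(as.numeric(q), as.numeric(fs$translations))
}

par_to_frames <- function(par, L) {
  q <- matrix(par[seq_len(4L * L)], L, 4)
  q <- q / sqrt(rowSums(q^2))
  tr <- matrix(par[4L * L + seq_len(3L * L)], L, 3)
  rot <- array(0, c(3, 3, L))
  R9 <- quat_to_R9(q)
  for (l in seq_len(L)) {
    rot[, , l] <- symmetric_orthogonalize(matrix(R9[l, ], 3, 3, byrow = TRUE))
  }
  frame_set(rot, tr)
}

#' L-BFGS optimization of a conformation against selected decoys
#'
#' Frames are parameterized as per-nucleotide quaternions plus translations
#' and optimized with L-BFGS-B on the consensus energy (frame term plus a
#' piecewise-linear interpolation of the distogram term, which makes the
#' objective differentiable in the coordinates). The optimizer runs in
#' restarted chunks; the best value seen is always kept, so the returned
#' energy never exceeds the starting energy. Deterministic.
#'
#' @param start a `frame_set` (or `coarse_structure`).
#' @param selected a `decoy_pool` of at most a handful of decoys.
#' @param template a `local_template`.
#' @param maxit total L-BFGS iterations (split into chunks).
#' @param chunk iterations per restart chunk.
#' @return List with `frames` (optimized `frame_set`), `energy` (final
#'   smooth objective), `start_energy` and `history` (objective after each
#'   chunk; non-increasing).
#' @export
optimize_conformation <- function(start, selected,
                                  template = default_template(),
                                  maxit = 60L, chunk = 20L) {
  local_atoms <- NULL
  if (inherits(start, "coarse_structure")) {
    st <- start
    start <- frames_from_atoms(st, template)
    L <- length(start)
    local_atoms <- lapply(1:3, function(k) {
      out <- matrix(0, L, 3)
      for (l in seq_len(L)) {
        out[l, ] <- as.numeric(t(start$rotations[, , l]) %*%
                                 (st$coords[l, k, ] - start$translations[l, ]))
      }
      out
    })
  }
  stopifnot(length(start) == selected$L)
  obj0 <- make_opt_objective(selected, template, local_atoms = local_atoms)
  memo <- new.env(parent = emptyenv())
  obj <- function(par, want_grad = TRUE) {
    key <- paste(format(par[c(1L, length(par) %/% 2L, length(par))],
                        digits = 17), collapse = ",")
    hit <- memo$res
    if (!is.null(hit) && identical(memo$key, key) &&
        (!want_grad || !is.null(hit$grad))) {
      return(hit)
    }
    res <- obj0(par, want_grad = TRUE)
    memo$key <- key
    memo$res <- res
    res
  }
  par <- frames_to_par(start)
  f0 <- obj(par, want_grad = FALSE)$value
  if (!is.finite(f0)) stop("non-finite energy at the starting conformation")
  best_par <- par
  best_val <- f0
  history <- f0
  done <- 0L
  while (done < maxit) {
    it <- min(chunk, maxit - done)
    res <- tryCatch(
      stats::optim(best_par,
                   fn = function(p) obj(p, want_grad = FALSE)$value,
                   gr = function(p) obj(p)$grad,
                   method = "L-BFGS-B", control = list(maxit = it)),
      error = function(e) NULL)
    done <- done + it
    if (!is.null(res) && is.finite(res$value) && res$value < best_val) {
      best_val <- res$value
      best_par <- res$par
    }
    history <- c(history, best_val)
  }
  list(frames = par_to_frames(best_par, selected$L), energy = best_val,
       start_energy = f0, history = history)
}

#' Greedy RMSD clustering of a decoy pool
#'
#' Iteratively picks the decoy with the most neighbors within `cutoff`
#' P-atom RMSD as a cluster center, removes its cluster and repeats. With
#' `cutoff = NULL` an adaptive cutoff is used: the smallest of 2, 4, 6, 8
#' Angstrom that places at least 30 percent of the decoys in the top
#' cluster (8 otherwise). Deterministic; centers are pool members.
#'
#' @param pool a `decoy_pool`.
#' @param cutoff RMSD cutoff in Angstrom, or `NULL` for adaptive.
#' @param max_clusters maximum number of clusters returned.
#' @return List with `centers` (pool indices), `members` (list of index
#'   vectors) and `cutoff`.
#' @export
cluster_decoys <- function(pool, cutoff = NULL, max_clusters = 5L) {
  N <- length(pool)
  P <- lapply(pool$decoys, function(d) atom_coords(d$structure, "P"))
  rms <- matrix(0, N, N)
  if (N > 1L) {
    for (i in 1:(N - 1L)) for (j in (i + 1L):N) {
      rms[i, j] <- rms[j, i] <- kabsch_rmsd(P[[i]], P[[j]])
    }
  }
  pick_cutoff <- function() {
    for (ct in c(2, 4, 6, 8)) {
      if (max(rowSums(rms <= ct)) >= 0.3 * N) return(ct)
    }
    8
  }
  if (is.null(cutoff)) cutoff <- pick_cutoff()
  alive <- rep(TRUE, N)
  centers <- integer(0)
  members <- list()
  while (any(alive) && length(centers) < max_clusters) {
    nb <- vapply(seq_len(N), function(i) {
      if (!alive[i]) -1L else sum(rms[i, alive] <= cutoff)
    }, 1L)
    c0 <- which.max(nb)
    cl <- which(alive & rms[c0, ] <= cutoff)
    centers <- c(centers, c0)
    members[[length(members) + 1L]] <- cl
    alive[cl] <- FALSE
  }
  list(centers = centers, members = members, cutoff = cutoff)
}

#' Full consensus selection/optimization pipeline
#'
#' Applies the base-pair-count filter, scores the pool and optimizes the
#' best-scoring decoy, then clusters the filtered pool and scores/optimizes
#' each cluster center; the optimized conformations are ranked by their
#' final consensus energy, so model 1 has the lowest energy. At most
#' `max_models` models are returned. An optional full-atom refinement hook
#' is invoked on each final structure (identity by default).
#'
#' @param pool a `decoy_pool`.
#' @param max_models maximum number of emitted models (up to 5).
#' @param k decoys entering the optimization consensus.
#' @param template a `local_template`.
#' @param maxit L-BFGS iterations per optimization.
#' @param refine_hook function applied to each final `coarse_structure`.
#' @return List of models, each with `structure`, `frames`, `energy`
#'   (`energy_breakdown` against the filtered pool), `opt_energy` and
#'   `source` (pool index of the starting decoy).
#' @export
csor_pipeline <- function(pool, max_models = 5L, k = 5L,
                          template = default_template(), maxit = 60L,
                          refine_hook = identity) {
  pool <- bp_count_filter(pool)
  sel <- select_models(pool, k = min(k, length(pool)), template = template)
  starts <- sel$order[1L]
  cl <- cluster_decoys(pool)
  starts <- unique(c(starts, cl$centers))
  models <- lapply(starts, function(idx) {
    start_st <- pool$decoys[[idx]]$structure
    start_fr <- frames_from_atoms(start_st, template)
    opt <- optimize_conformation(start_st, sel$pool,
                                 template = template, maxit = maxit)
    # move the decoy's own atoms by the per-nucleotide frame updates rather
    # than rebuilding from the template (which would add projection error)
    st <- apply_frame_delta(start_st, start_fr, opt$frames)
    st <- refine_hook(st)
    list(structure = st, frames = opt$frames,
         energy = global_energy(st, pool, template),
         opt_energy = opt$energy, source = idx)
  })
  o <- order(vapply(models, `[[`, 1, "opt_energy"))
  models[o[seq_len(min(max_models, length(models)))]]
}
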