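# Unsupervised contact extraction from any sequence->distribution model:
# categorical Jacobian, squared-norm collapse, average product correction,
# and top-N precision evaluation.

#' Categorical Jacobian of a sequence model
#'
#' Finite-difference sensitivity of the model's nucleotide-wise output
#' distribution to single-position mutations:
#' `J[i, a, j, b] = f(X with xi -> a)[j, b] - f(X)[j, b]`, computed from
#' exactly `4L + 1` forward passes on complete (mask-free) sequences.
#'
#' @param model_fn function mapping a character sequence to an `L x 4`
#'   row-stochastic matrix. It may accept a character vector and return a
#'   list of such matrices (batched evaluation is used when available).
#' @param seq RNA sequence.
#' @param batch_size how many mutants to evaluate per call when `model_fn`
#'   supports batching.
#' @return `L x 4 x L x 4` array, class `coupling_tensor`.
#' @export
categorical_jacobian <- function(model_fn, seq, batch_size = 32L) {
  seq <- rna_sequence(seq)
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  muts <- character(4L * L)
  for (i in seq_len(L)) {
    for (a in 1:4) {
      m <- chars
      m[i] <- RNA_ALPHABET[a]
      muts[(i - 1L) * 4L + a] <- paste(m, collapse = "")
    }
  }
  eval_batch <- function(seqs) {
    out <- tryCatch(model_fn(seqs), error = function(e) NULL)
    if (is.list(out) && !is.matrix(out) && length(out) == length(seqs)) {
      return(out)
    }
    lapply(seqs, model_fn)
  }
  check_dist <- function(p) {
    if (!is.matrix(p) || nrow(p) != L || ncol(p) != 4L ||
        any(p < -1e-9) || max(abs(rowSums(p) - 1)) > 1e-4) {
      stop("model_fn must return L x 4 row-stochastic matrices")
    }
    p
  }
  base <- check_dist(if (is.list(fb <- eval_batch(seq))) fb[[1L]] else fb)
  J <- array(0, c(L, 4L, L, 4L))
  # the identity mutation (a = xi) reproduces the input, so its forward pass
  # is served from the base evaluation and the slice is exactly zero
  xi <- match(chars, RNA_ALPHABET)
  todo <- which(rep(1:4, L) != rep(xi, each = 4L))
  done <- 0L
  while (done < length(todo)) {
    take <- todo[seq(done + 1L, min(done + batch_size, length(todo)))]
    res <- eval_batch(muts[take])
    for (t in seq_along(take)) {
      k <- take[t] - 1L
      i <- k %/% 4L + 1L
      a <- k %% 4L + 1L
      J[i, a, , ] <- check_dist(res[[t]]) - base
    }
    done <- done + length(take)
  }
  structure(J, class = "coupling_tensor")
}

#' Collapse a coupling tensor to a contact map
#'
#' `M[i, j] = sqrt(sum_ab J[i, a, j, b]^2)` (Frobenius norm of each 4x4
#' coupling block).
#'
#' @param j a `coupling_tensor`.
#' @return A `contact_map` (uncorrected, unsymmetrized).
#' @export
collapse_coupling <- function(j) {
  stopifnot(inherits(j, "coupling_tensor"))
  L <- dim(j)[1]
  m <- sqrt(apply(unclass(j)^2, c(1, 3), sum))
  contact_map(m, corrected = FALSE, symmetrized = FALSE)
}

#' Contact score map
#'
#' @param values `L x L` numeric matrix of contact scores.
#' @param corrected has the average product correction been applied?
#' @param symmetrized is the matrix symmetric?
#' @param min_separation minimum `|i - j|` used when ranking.
#' @return Object of class `contact_map`.
#' @export
contact_map <- function(values, corrected = FALSE, symmetrized = FALSE,
                        min_separation = 4L) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), all(is.finite(values)))
  if (symmetrized && max(abs(values - t(values))) > 1e-8) {
    stop("symmetrized flag set but matrix is not symmetric")
  }
  structure(list(values = values,
                 meta = list(corrected = corrected, symmetrized = symmetrized,
                             min_separation = as.integer(min_separation))),
            class = "contact_map")
}

#' Average product correction
#'
#' `C[i, j] = M[i, j] - rowsum_i * colsum_j / total`, removing the background
#' coupling signal; annihilates constant and rank-1 outer-product maps. A map
#' with zero total is returned unchanged with a warning.
#'
#' @param m an uncorrected `contact_map`.
#' @return The corrected `contact_map`.
#' @export
apc <- function(m) {
  stopifnot(inherits(m, "contact_map"))
  if (isTRUE(m$meta$corrected)) stop("map is already corrected")
  v <- m$values
  tot <- sum(v)
  if (tot == 0) {
    warning("zero total score: average product correction skipped")
    return(m)
  }
  corr <- v - outer(rowSums(v), colSums(v)) / tot
  contact_map(corr, corrected = TRUE, symmetrized = m$meta$symmetrized,
              min_separation = m$meta$min_separation)
}

#' Rank eligible contacts of a map
#'
#' Symmetrizes the scores as `(C + C') / 2`, restricts to pairs `i < j` with
#' `j - i >= min_separation` and orders them by decreasing score, ties broken
#' by ascending (i, j).
#'
#' @param c a `contact_map`.
#' @param min_separation override of the map's minimum separation.
#' @return data.frame with columns `i`, `j`, `score` (1-based indices).
#' @export
rank_contacts <- function(c, min_separation = NULL) {
  stopifnot(inherits(c, "contact_map"))
  sep <- min_separation %||% c$meta$min_separation
  v <- (c$values + t(c$values)) / 2
  L <- nrow(v)
  el <- which(upper.tri(v), arr.ind = TRUE)
  el <- el[el[, 2] - el[, 1] >= sep, , drop = FALSE]
  sc <- v[el]
  o <- order(-sc, el[, 1], el[, 2])
  data.frame(i = el[o, 1], j = el[o, 2], score = sc[o])
}

#' Top-N contact precision
#'
#' Fraction of the `n` top-ranked eligible pairs that are true contacts,
#' where truth is either an explicit pair set or a structure with contacts
#' defined by an N-N distance below `contact_threshold`. With fewer than `n`
#' eligible pairs, all are evaluated (with a warning).
#'
#' @param c a `contact_map`.
#' @param truth a `coarse_structure` or a `base_pair_set` / two-column matrix
#'   of true pairs.
#' @param n number of top pairs (e.g. `L` for top-L).
#' @param contact_threshold N-N contact distance in Angstrom.
#' @param min_separation minimum sequence separation.
#' @return Precision in [0, 1].
#' @export
top_n_precision <- function(c, truth, n, contact_threshold = 12,
                            min_separation = NULL) {
  stopifnot(n >= 1)
  ranked <- rank_contacts(c, min_separation)
  if (nrow(ranked) < n) {
    warning("fewer than n eligible pairs; evaluating over all of them")
    n <- nrow(ranked)
  }
  top <- ranked[seq_len(n), , drop = FALSE]
  if (inherits(truth, "coarse_structure")) {
    nd <- as.matrix(stats::dist(atom_coords(truth, "N")))
    hits <- nd[cbind(top$i, top$j)] < contact_threshold
  } else {
    pairs <- if (inherits(truth, "base_pair_set")) truth$pairs else as.matrix(truth)
    keys <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    hits <- paste(top$i, top$j) %in% keys
  }
  mean(hits)
}

#' Contact map from a language model
#'
#' Runs the full unsupervised pipeline: categorical Jacobian of the 4-class
#' head (or of the marginalized pair head), squared-norm collapse, and
#' average product correction.
#'
#' @param model a `clm_model`.
#' @param seq RNA sequence.
#' @param marginalized use the marginalized pair-head path instead of the
#'   sequence head.
#' @return A corrected `contact_map`.
#' @export
clm_contact_map <- function(model, seq, marginalized = FALSE) {
  model_fn <- if (marginalized) {
    function(s) {
      out <- clm_forward(model, s, what = "both")
      if (length(s) == 1L) marginalize_pair(out$pair_probs)
      else lapply(out, function(o) marginalize_pair(o$pair_probs))
    }
  } else {
    function(s) {
      out <- clm_forward(model, s, what = "seq")
      if (length(s) == 1L) out$seq_probs else lapply(out, `[[`, "seq_probs")
    }
  }
  apc(collapse_coupling(categorical_jacobian(model_fn, seq)))
}
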