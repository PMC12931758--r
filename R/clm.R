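# Composite-likelihood masked RNA language modeling: masking, the
# nucleotide-wise (4-class) and ordered-pair (16-class) objective, marginal
# pair predictions and recovery metrics.

RNA_ALPHABET <- c("A", "C", "G", "U")
MASK_CHAR <- "N"

#' Normalize and validate an RNA sequence
#'
#' Uppercases, converts T to U (DNA-style input) and checks the alphabet.
#'
#' @param x character scalar.
#' @return Normalized character scalar over A/C/G/U.
#' @export
rna_sequence <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  if (nchar(x) < 1L) stop("empty sequence")
  if (grepl(paste0("[^", paste(RNA_ALPHABET, collapse = ""), "]"), x)) {
    stop("sequence contains symbols outside A/C/G/U/T")
  }
  x
}

seq_to_idx <- function(x) {
  match(strsplit(x, "")[[1]], c(RNA_ALPHABET, MASK_CHAR))
}

idx_to_seq <- function(idx) {
  paste(c(RNA_ALPHABET, MASK_CHAR)[idx], collapse = "")
}

# one-hot over A, C, G, U, mask
one_hot <- function(x) {
  idx <- seq_to_idx(x)
  m <- matrix(0, length(idx), 5L)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Mask a fraction of sequence positions
#'
#' Selects `ceiling(fraction * L)` distinct positions uniformly without
#' replacement and replaces them with the mask symbol. Deterministic given
#' `seed`.
#'
#' @param seq RNA sequence (character scalar; T is normalized to U).
#' @param fraction fraction of positions to mask, in (0, 1].
#' @param seed integer seed.
#' @return Object of class `masked_batch` with fields `original`,
#'   `masked_positions` and `visible`.
#' @export
mask_sequence <- function(seq, fraction = 0.15, seed = 1L) {
  seq <- rna_sequence(seq)
  L <- nchar(seq)
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  k <- as.integer(ceiling(fraction * L))
  pos <- with_seed(seed, sort(sample.int(L, k)))
  chars <- strsplit(seq, "")[[1]]
  chars[pos] <- MASK_CHAR
  structure(list(original = seq, masked_positions = pos,
                 visible = paste(chars, collapse = "")),
            class = "masked_batch")
}

# ordered supervised pair rows for a masked batch: (i, j), i != j, with
# i or j masked; returned as two integer vectors
masked_pair_index <- function(L, masked) {
  inm <- seq_len(L) %in% masked
  ii <- rep(seq_len(L), times = L)
  jj <- rep(seq_len(L), each = L)
  keep <- (ii != jj) & (inm[ii] | inm[jj])
  list(i = ii[keep], j = jj[keep])
}

pair_class <- function(a, b) 4L * (a - 1L) + b

#' Negative log-composite-likelihood of a masked batch
#'
#' Sums the nucleotide-wise term over masked positions and the ordered-pair
#' term over all pairs (i, j), i != j, with i or j masked:
#' `-sum log P(Xi = xi) - sum log P(Xi = xi, Xj = xj)`. Probabilities are
#' floored at 1e-9 before the logarithm, so the value is always finite.
#'
#' @param seq_pred `L x 4` row-stochastic matrix of nucleotide probabilities.
#' @param pair_pred `L x L x 16` array of ordered-pair joint probabilities
#'   (class `4*(a-1)+b` for states `Xi = a`, `Xj = b`).
#' @param batch a `masked_batch`.
#' @return Scalar loss (a sum, not a mean).
#' @export
composite_loss <- function(seq_pred, pair_pred, batch) {
  stopifnot(inherits(batch, "masked_batch"))
  L <- nchar(batch$original)
  if (nrow(seq_pred) != L || ncol(seq_pred) != 4L) {
    stop("seq_pred shape does not match the sequence length")
  }
  if (!all(dim(pair_pred) == c(L, L, 16L))) {
    stop("pair_pred shape does not match the sequence length")
  }
  truth <- seq_to_idx(batch$original)
  m <- batch$masked_positions
  loss <- -sum(log(pmax(seq_pred[cbind(m, truth[m])], 1e-9)))
  pidx <- masked_pair_index(L, m)
  cls <- pair_class(truth[pidx$i], truth[pidx$j])
  loss - sum(log(pmax(pair_pred[cbind(pidx$i, pidx$j, cls)], 1e-9)))
}

#' Marginalize an ordered-pair joint distribution to nucleotide-wise
#'
#' For each position i, the 16-class slices (i, j) are summed over the
#' partner state and averaged over all j != i, then renormalized. This is the
#' marginal-pair prediction path used to evaluate the pair head as a
#' sequence-recovery model.
#'
#' @param pair_pred `L x L x 16` array of ordered-pair joint probabilities.
#' @return `L x 4` row-stochastic matrix.
#' @export
marginalize_pair <- function(pair_pred) {
  d <- dim(pair_pred)
  stopifnot(length(d) == 3L, d[3] == 16L, d[1] == d[2])
  L <- d[1]
  if (L < 2L) stop("marginalization needs at least 2 positions (no partners)")
  out <- matrix(0, L, 4L)
  for (a in 1:4) {
    cls <- pair_class(a, 1:4)
    # sum over partner state b for every (i, j)
    sl <- pair_pred[, , cls[1]] + pair_pred[, , cls[2]] +
      pair_pred[, , cls[3]] + pair_pred[, , cls[4]]
    diag(sl) <- 0
    out[, a] <- rowSums(sl) / (L - 1)
  }
  out / rowSums(out)
}

#' Masked-position recovery rate
#'
#' Fraction of masked positions where the argmax of the model's 4-class
#' nucleotide head (computed on the masked input) equals the true nucleotide.
#' Ties break toward the lowest class index.
#'
#' @param model a trained `clm_model`, or a function mapping a (masked)
#'   sequence to an `L x 4` probability matrix.
#' @param batch a `masked_batch`.
#' @param marginalized use the marginalized pair head instead of the
#'   sequence head (ignored for function models).
#' @return Recovery rate in [0, 1].
#' @export
sequence_recovery <- function(model, batch, marginalized = FALSE) {
  stopifnot(inherits(batch, "masked_batch"))
  probs <- if (is.function(model)) {
    model(batch$visible)
  } else {
    fw <- clm_forward(model, batch$visible)
    if (marginalized) marginalize_pair(fw$pair_probs) else fw$seq_probs
  }
  truth <- seq_to_idx(batch$original)
  m <- batch$masked_positions
  pred <- apply(probs[m, , drop = FALSE], 1L, which.max)
  mean(pred == truth[m])
}
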