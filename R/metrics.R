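# Structure assessment: optimal-superposition RMSD, TM-score on P atoms,
# geometric base-pair detection, interaction network fidelity (INF) and the
# deformation index (DI).

# Kabsch fit: rotation/translation mapping a onto b (minimizing ||R a + t - b||)
kabsch_fit <- function(a, b) {
  ca <- colMeans(a)
  cb <- colMeans(b)
  h <- t(sweep(a, 2L, ca)) %*% sweep(b, 2L, cb)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = r, translation = cb - as.numeric(r %*% ca))
}

#' RMSD after optimal rigid superposition
#'
#' Superposes `a` onto `b` with the optimal proper rotation (no reflection)
#' and translation, then returns the root-mean-square deviation.
#'
#' @param a,b `n x 3` coordinate matrices with equal `n >= 1`.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (nrow(a) != nrow(b) || nrow(a) < 1L) stop("point sets must match in size")
  if (nrow(a) == 1L) return(0)
  fit <- kabsch_fit(a, b)
  moved <- sweep(a %*% t(fit$rotation), 2L, fit$translation, "+")
  sqrt(mean(rowSums((moved - b)^2)))
}

#' Length-dependent TM-score distance scale for RNA
#'
#' `d0 = 0.6 * sqrt(L - 0.5) - 2.5`, clamped below at `floor`.
#'
#' @param L reference length.
#' @param floor lower clamp in Angstrom.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(L, floor = 0.5) {
  max(0.6 * sqrt(L - 0.5) - 2.5, floor)
}

#' Reference TM-score thresholds
#'
#' Conventional interpretation levels: scores above `fold` indicate a shared
#' global fold; `random` is the expected score between unrelated structures.
#' Used for labeling only.
#'
#' @return Named numeric vector with elements `fold` and `random`.
#' @export
tm_thresholds <- function() c(fold = 0.45, random = 0.21)

tm_from_superposition <- function(pm, rm, d0) {
  d <- sqrt(rowSums((pm - rm)^2))
  mean(1 / (1 + (d / d0)^2))
}

#' Template modeling score on P atoms
#'
#' Length-normalized structure similarity in (0, 1]. The superposition search
#' seeds from contiguous fragments of lengths L, L/2 and L/4 (minimum 4),
#' each followed by iterative distance-threshold refinement; the best score
#' over all searched superpositions is returned, normalized by the reference
#' length.
#'
#' @param model,ref `coarse_structure` objects of equal length (>= 3).
#' @param d0 optional distance scale override.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, ref, d0 = NULL) {
  L <- length(ref)
  if (length(model) != L) stop("model and reference lengths differ")
  if (L < 3L) stop("TM-score needs at least 3 nucleotides")
  p <- atom_coords(model, "P")
  r <- atom_coords(ref, "P")
  if (is.null(d0)) d0 <- tm_d0(L)
  best <- 0
  frag_lens <- unique(pmax(4L, c(L, L %/% 2L, L %/% 4L)))
  frag_lens <- frag_lens[frag_lens <= L]
  for (fl in frag_lens) {
    starts <- unique(round(seq(1L, L - fl + 1L, length.out = min(8L, L - fl + 1L))))
    for (st in starts) {
      idx <- st:(st + fl - 1L)
      fit <- kabsch_fit(p[idx, , drop = FALSE], r[idx, , drop = FALSE])
      sel <- idx
      for (iter in 1:20) {
        moved <- sweep(p %*% t(fit$rotation), 2L, fit$translation, "+")
        best <- max(best, tm_from_superposition(moved, r, d0))
        d <- sqrt(rowSums((moved - r)^2))
        cut <- max(d0 + 1, 4.5)
        new_sel <- which(d < cut)
        while (length(new_sel) < 3L) {
          cut <- cut + 1
          new_sel <- which(d < cut)
        }
        if (length(new_sel) == length(sel) && all(new_sel == sel)) break
        sel <- new_sel
        fit <- kabsch_fit(p[sel, , drop = FALSE], r[sel, , drop = FALSE])
      }
    }
  }
  best
}

#' Base-pair set
#'
#' @param pairs two-column integer matrix of base-paired positions (unordered
#'   pairs, stored with i < j), or `NULL` for an empty set.
#' @param category interaction category: Watson-Crick (`wc`), non-canonical
#'   (`nwc`), stacking (`stack`) or uncategorized (`any`).
#' @param L optional sequence length for index validation.
#' @return Object of class `base_pair_set`.
#' @export
base_pair_set <- function(pairs = NULL, category = c("any", "wc", "nwc", "stack"),
                          L = NULL) {
  category <- match.arg(category)
  if (is.null(pairs) || nrow(as.matrix(pairs)) == 0L) {
    pairs <- matrix(integer(0), 0L, 2L)
  } else {
    pairs <- as.matrix(pairs)
    stopifnot(ncol(pairs) == 2L)
    if (any(pairs[, 1] == pairs[, 2])) stop("a base cannot pair with itself")
    pairs <- t(apply(pairs, 1L, sort))
    pairs <- unique(pairs)
    if (!is.null(L) && any(pairs < 1L | pairs > L)) {
      stop("pair indices outside 1..L")
    }
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  structure(list(pairs = pairs, category = category), class = "base_pair_set")
}

#' @export
length.base_pair_set <- function(x) nrow(x$pairs)

pair_keys <- function(bp) {
  if (nrow(bp$pairs) == 0L) character(0)
  else paste(bp$pairs[, 1], bp$pairs[, 2], sep = "-")
}

#' Geometric base-pair detection on coarse structures
#'
#' Greedy one-partner-per-nucleotide matching: candidate pairs must be at
#' least `min_sep` apart in sequence and have both their N-N and C4'-C4'
#' distances inside calibrated windows (defaults match the ideal A-form
#' geometry used by the toy-structure builder). Candidates are accepted in
#' order of increasing deviation from the ideal pair geometry (summed |N-N -
#' ideal| + |C4'-C4' - ideal| over the window midpoints), ties by (i, j); a
#' nucleotide joins at most one pair. Deterministic.
#'
#' @param s a `coarse_structure`.
#' @param nn_window,cc_window numeric length-2 distance windows (Angstrom).
#' @param min_sep minimum sequence separation `|i - j|`.
#' @return A `base_pair_set` with category `"any"`.
#' @export
detect_base_pairs <- function(s, nn_window = c(9.0, 9.9),
                              cc_window = c(9.9, 10.9), min_sep = 3L) {
  L <- length(s)
  nd <- as.matrix(stats::dist(atom_coords(s, "N")))
  cd <- as.matrix(stats::dist(atom_coords(s, "C4'")))
  cand <- which(upper.tri(nd), arr.ind = TRUE)
  cand <- cand[abs(cand[, 1] - cand[, 2]) >= min_sep, , drop = FALSE]
  nn <- nd[cand]
  cc <- cd[cand]
  ok <- nn >= nn_window[1] & nn <= nn_window[2] &
    cc >= cc_window[1] & cc <= cc_window[2]
  cand <- cand[ok, , drop = FALSE]
  dev <- abs(nn[ok] - mean(nn_window)) + abs(cc[ok] - mean(cc_window))
  o <- order(dev, cand[, 1], cand[, 2])
  cand <- cand[o, , drop = FALSE]
  used <- rep(FALSE, L)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]
    j <- cand[r, 2]
    if (!used[i] && !used[j]) {
      keep[r] <- TRUE
      used[i] <- TRUE
      used[j] <- TRUE
    }
  }
  base_pair_set(cand[keep, , drop = FALSE], "any", L = L)
}

#' Interaction network fidelity
#'
#' Geometric mean of base-pair precision and recall:
#' `sqrt(precision * recall)`. Returns 0 when the prediction shares no pair
#' with the reference (or predicts none); errors on an empty reference.
#'
#' @param pred,ref `base_pair_set` objects of the same category.
#' @return INF in [0, 1].
#' @export
inf_score <- function(pred, ref) {
  if (pred$category != ref$category) stop("category mismatch between pair sets")
  if (length(ref) == 0L) stop("INF undefined for an empty reference pair set")
  if (length(pred) == 0L) return(0)
  inter <- length(intersect(pair_keys(pred), pair_keys(ref)))
  if (inter == 0L) return(0)
  sqrt((inter / length(pred)) * (inter / length(ref)))
}

#' Deformation index
#'
#' `DI = RMSD / INF_all`; since INF is at most 1, DI is bounded below by the
#' RMSD. Undefined (error) when `inf_all` is zero.
#'
#' @param rmsd RMSD in Angstrom.
#' @param inf_all overall interaction network fidelity in (0, 1].
#' @return DI value.
#' @export
deformation_index <- function(rmsd, inf_all) {
  if (!is.finite(inf_all) || inf_all <= 0) {
    stop("deformation index undefined: INF_all must be positive")
  }
  rmsd / inf_all
}

#' Full metric report for a model against a reference
#'
#' @param model,ref `coarse_structure` objects of equal length.
#' @param annotations optional data.frame (i, j, category) of reference base
#'   pairs with categories in wc/nwc/stack; when absent, the geometric
#'   detector supplies an uncategorized reference pair set.
#' @return One-row data.frame with tm_score, rmsd, inf columns and di.
#' @export
evaluate_structure <- function(model, ref, annotations = NULL) {
  tm <- tm_score(model, ref)
  rmsd <- kabsch_rmsd(atom_coords(model, "P"), atom_coords(ref, "P"))
  pred_bp <- detect_base_pairs(model)
  out <- data.frame(tm_score = tm, rmsd = rmsd,
                    inf_wc = NA_real_, inf_nwc = NA_real_,
                    inf_stack = NA_real_, inf_all = NA_real_, di = NA_real_)
  if (is.null(annotations)) {
    ref_bp <- detect_base_pairs(ref)
    if (length(ref_bp) > 0L) out$inf_all <- inf_score(pred_bp, ref_bp)
  } else {
    stopifnot(all(c("i", "j", "category") %in% names(annotations)))
    all_ref <- base_pair_set(as.matrix(annotations[, c("i", "j")]), "any",
                             L = length(ref))
    if (length(all_ref) > 0L) out$inf_all <- inf_score(pred_bp, all_ref)
    for (cat in c("wc", "nwc", "stack")) {
      sub <- annotations[annotations$category == cat, , drop = FALSE]
      if (nrow(sub) > 0L) {
        rbp <- base_pair_set(as.matrix(sub[, c("i", "j")]), cat, L = length(ref))
        pbp <- base_pair_set(pred_bp$pairs, cat, L = length(model))
        out[[paste0("inf_", cat)]] <- inf_score(pbp, rbp)
      }
    }
  }
  if (!is.na(out$inf_all) && out$inf_all > 0) {
    out$di <- deformation_index(rmsd, out$inf_all)
  }
  out
}
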