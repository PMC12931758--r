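# Training losses for end-to-end structure learning: generalized FAPE with
# distance-dependent reweighting, black-hole repulsion, and the binned
# distance (distogram) cross-entropy.

#' Per-pair gFAPE parameters from a reference structure
#'
#' Pairs closer than `cutoff` (default 20 Angstrom, C4'-C4' distance) in the
#' reference get weight `lambda = 3` and no deviation clamp; all other pairs
#' get `lambda = 1` and a 30 Angstrom clamp. Distances exactly at the cutoff
#' fall in the far branch.
#'
#' @param ref a `coarse_structure` (the experimental reference).
#' @param cutoff inter-nucleotide distance cutoff in Angstrom.
#' @param atom atom used for the inter-nucleotide distance rule.
#' @param epsilon smoothing constant added under the square root.
#' @return List with `lambda`, `dcut` (L x L matrices) and `epsilon`,
#'   class `gfape_params`.
#' @export
make_gfape_params <- function(ref, cutoff = 20, atom = "C4'", epsilon = 1e-3) {
  x <- atom_coords(ref, atom)
  if (any(!is.finite(x))) stop("reference has missing atoms")
  d <- as.matrix(stats::dist(x))
  near <- d < cutoff
  lambda <- ifelse(near, 3, 1)
  dcut <- ifelse(near, Inf, 30)
  structure(list(lambda = lambda, dcut = dcut, epsilon = epsilon),
            class = "gfape_params")
}

#' Uniform gFAPE parameters
#'
#' @param L number of nucleotides.
#' @param lambda scalar weight applied to every pair.
#' @param dcut scalar clamp (Angstrom, may be `Inf`).
#' @param epsilon smoothing constant.
#' @return A `gfape_params` object.
#' @export
uniform_gfape_params <- function(L, lambda = 1, dcut = Inf, epsilon = 1e-3) {
  structure(list(lambda = matrix(lambda, L, L), dcut = matrix(dcut, L, L),
                 epsilon = epsilon),
            class = "gfape_params")
}

#' Generalized frame-aligned point error
#'
#' Sums, over all ordered nucleotide pairs (i, j) including i = j and the
#' three template atoms, the clamped deviation
#' `lambda_ij * min(dcut_ij, sqrt(||T_i^-1 T_j(r) - T_i^ref-1 T_j^ref(r)||^2 +
#' epsilon))`. The floor attained when the two frame sets agree is
#' `sum(lambda) * 3 * sqrt(epsilon)`. Invariant to a common global rigid
#' motion of either frame set.
#'
#' @param frames,ref_frames `frame_set` objects of equal length.
#' @param params a `gfape_params`.
#' @param template a `local_template`.
#' @return Scalar loss value.
#' @export
gfape <- function(frames, ref_frames, params, template = default_template()) {
  L <- length(frames)
  if (length(ref_frames) != L) stop("frame sets differ in length")
  stopifnot(inherits(params, "gfape_params"), params$epsilon > 0)
  refloc <- gfape_ref_local(fs_R9(ref_frames), ref_frames$translations,
                            unclass(template))
  gfape_core(fs_R9(frames), frames$translations, refloc, unclass(template),
             params$lambda, params$dcut, params$epsilon)$value
}

# gFAPE value + gradient wrt (R9, translations); internal (optimizer, tests)
gfape_with_grad <- function(R9, tr, refloc, template, lambda, dcut, eps) {
  gfape_core(R9, tr, refloc, template, lambda, dcut, eps, want_grad = TRUE)
}

#' Structure loss with black-hole repulsion
#'
#' `gfape(frames, exp_frames, params) - 0.1 * gfape(frames, T0, lambda = 1,
#' dcut = 2)`, where `T0` is the black-hole frame set (identity rotations,
#' zero translations). The subtracted term pushes predictions away from the
#' degenerate all-at-origin initialization; its clamp bounds it by
#' `0.1 * 3 * L^2 * 2`.
#'
#' @inheritParams gfape
#' @param exp_frames reference (experimental) `frame_set`.
#' @return Scalar loss value.
#' @export
structure_loss <- function(frames, exp_frames, params,
                           template = default_template()) {
  L <- length(frames)
  t0 <- black_hole_frames(L)
  p0 <- uniform_gfape_params(L, lambda = 1, dcut = 2, epsilon = params$epsilon)
  gfape(frames, exp_frames, params, template) -
    0.1 * gfape(frames, t0, p0, template)
}

#' Distance binning scheme
#'
#' 38 one-Angstrom bins spanning 2-40 Angstrom plus two open bins for
#' distances below 2 and at or above 40, i.e. 40 bins in total.
#'
#' @return List with `edges` (39 ascending interior edges) and `n_bins`.
#' @export
distance_binning <- function() {
  list(edges = seq(2, 40, by = 1), n_bins = 40L)
}

#' Assign a distance to its bin
#'
#' Bins are 1-based: bin 1 is `d < 2`, bins 2..39 cover 2-40 Angstrom in
#' 1-Angstrom steps, bin 40 is `d >= 40`.
#'
#' @param d non-negative distance(s) in Angstrom.
#' @param binning a binning scheme from [distance_binning()].
#' @return Integer bin indices in 1..40.
#' @export
bin_distance <- function(d, binning = distance_binning()) {
  if (any(d < 0)) stop("distances must be non-negative")
  b <- findInterval(d, binning$edges) + 1L
  pmin(b, binning$n_bins)
}

# index of the last closed bin below the 40 A threshold (consensus scoring)
last_closed_bin <- function(binning = distance_binning()) binning$n_bins - 1L

#' Binned distance distribution (distogram)
#'
#' Per-pair categorical distributions over binned distances for the three
#' atom-pair channels P-P, C4'-C4' and N-N.
#'
#' @param channels named list of three `L^2 x 40` row-stochastic matrices
#'   (`PP`, `CC`, `NN`), pair index column-major in (i, j).
#' @param L sequence length.
#' @return Object of class `distogram`.
#' @export
distogram <- function(channels, L) {
  stopifnot(is.list(channels), all(c("PP", "CC", "NN") %in% names(channels)))
  for (nm in c("PP", "CC", "NN")) {
    m <- channels[[nm]]
    stopifnot(nrow(m) == L * L, ncol(m) == distance_binning()$n_bins)
    if (any(m < 0) || max(abs(rowSums(m) - 1)) > 1e-6) {
      stop("distogram slices must be non-negative and sum to 1")
    }
  }
  structure(list(channels = channels[c("PP", "CC", "NN")], L = L),
            class = "distogram")
}

# true bin index matrix per channel for a structure
true_bins <- function(truth, binning = distance_binning()) {
  lapply(c(P = "P", `C4'` = "C4'", N = "N"), function(a) {
    d <- as.matrix(stats::dist(atom_coords(truth, a)))
    matrix(bin_distance(as.numeric(d), binning), nrow(d), ncol(d))
  })
}

#' Distogram cross-entropy loss
#'
#' Negative log-likelihood of the observed distance bin, summed over the
#' three atom-pair channels and all ordered nucleotide pairs (including the
#' diagonal, whose zero distance falls in the first bin). Probabilities are
#' floored at 1e-9; uniform predictions give `3 * L^2 * log(40)`.
#'
#' @param pred a `distogram`.
#' @param truth a `coarse_structure` of matching length.
#' @return Scalar loss value.
#' @export
distogram_loss <- function(pred, truth) {
  L <- pred$L
  if (length(truth) != L) stop("distogram and structure lengths differ")
  tb <- true_bins(truth)
  chans <- list(pred$channels$PP, pred$channels$CC, pred$channels$NN)
  loss <- 0
  for (k in 1:3) {
    idx <- as.integer(tb[[k]])
    p <- chans[[k]][cbind(seq_len(L * L), idx)]
    loss <- loss - sum(log(pmax(p, 1e-9)))
  }
  loss
}

#' Total structure-prediction loss
#'
#' @param structure structure-loss value.
#' @param dist distogram-loss value.
#' @return `structure + 0.2 * dist`.
#' @export
total_loss <- function(structure, dist) {
  stopifnot(is.finite(structure), is.finite(dist))
  structure + 0.2 * dist
}
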