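# Rigid-frame algebra for three-atom (P, C4', N) nucleotide models.
# Frames act on column vectors; coordinates are right-handed and in Angstrom.

#' Run code with a temporary RNG seed
#'
#' Restores the caller's RNG state on exit so that seeded toolkit calls do not
#' disturb the session stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Validate a 3x3 rotation matrix
#'
#' @param m numeric 3x3 matrix.
#' @param tol tolerance on orthogonality and determinant.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_rotation <- function(m, tol = 1e-6) {
  stopifnot(is.matrix(m), all(dim(m) == c(3L, 3L)))
  if (max(abs(t(m) %*% m - diag(3))) > tol) {
    stop("matrix is not orthogonal within tolerance")
  }
  if (abs(det(m) - 1) > tol) stop("matrix is not a proper rotation (det != 1)")
  invisible(TRUE)
}

#' Rigid frame: rotation plus translation
#'
#' A nucleotide-local coordinate frame. The rotation maps local coordinates to
#' global ones; the translation is the frame origin in Angstrom.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @return An object of class `rigid_frame`.
#' @export
rigid_frame <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  check_rotation(rotation)
  stopifnot(length(translation) == 3L, all(is.finite(translation)))
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_frame")
}

#' Ordered set of rigid frames
#'
#' @param rotations 3x3xL array of rotation matrices.
#' @param translations L x 3 matrix of frame origins (Angstrom).
#' @return An object of class `frame_set`.
#' @export
frame_set <- function(rotations, translations) {
  if (is.matrix(rotations)) rotations <- array(rotations, c(3, 3, 1))
  stopifnot(length(dim(rotations)) == 3L, dim(rotations)[1] == 3L,
            dim(rotations)[2] == 3L)
  translations <- matrix(translations, ncol = 3L)
  L <- dim(rotations)[3]
  stopifnot(nrow(translations) == L)
  for (l in seq_len(L)) check_rotation(rotations[, , l])
  structure(list(rotations = rotations, translations = translations),
            class = "frame_set")
}

#' @export
length.frame_set <- function(x) dim(x$rotations)[3]

#' @export
print.frame_set <- function(x, ...) {
  cat("<frame_set> of", length(x), "rigid frames\n")
  invisible(x)
}

#' Black-hole initialization: identity rotations, zero translations
#'
#' @param L number of nucleotides.
#' @return A `frame_set` with all frames at the identity.
#' @export
black_hole_frames <- function(L) {
  frame_set(array(diag(3), c(3, 3, L)), matrix(0, L, 3))
}

# frame_set <-> L x 9 row-major rotation storage (tape interop)
fs_R9 <- function(fs) {
  L <- length(fs)
  out <- matrix(0, L, 9)
  for (l in seq_len(L)) out[l, ] <- as.numeric(t(fs$rotations[, , l]))
  out
}

fs_from_R9 <- function(R9, tr) {
  L <- nrow(R9)
  rot <- array(0, c(3, 3, L))
  for (l in seq_len(L)) rot[, , l] <- matrix(R9[l, ], 3, 3, byrow = TRUE)
  frame_set(rot, tr)
}

#' Symmetric (Loewdin) orthogonalization
#'
#' Projects a full-rank 3x3 matrix with positive determinant onto the nearest
#' rotation in Frobenius norm, computed as `m (m'm)^(-1/2)` through an
#' eigendecomposition of `m'm`.
#'
#' @param m numeric 3x3 matrix, full rank, `det(m) > 0`.
#' @return The nearest 3x3 rotation matrix.
#' @export
symmetric_orthogonalize <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(3L, 3L)), all(is.finite(m)))
  d <- det(m)
  if (!is.finite(d) || d <= .Machine$double.eps^0.75) {
    stop("degenerate input: matrix must be full rank with positive determinant")
  }
  e <- eigen(crossprod(m), symmetric = TRUE)
  if (min(e$values) <= 1e-12) {
    stop("degenerate input: matrix is (numerically) singular")
  }
  inv_sqrt <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  r <- m %*% inv_sqrt
  # polish once against accumulated roundoff
  s <- svd(r)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) stop("degenerate input: reflection-dominant matrix")
  r
}

#' Coarse-grained RNA structure
#'
#' L nucleotides, each represented by its P, C4' and glycosidic N atom.
#'
#' @param coords numeric array `L x 3 x 3` (nucleotide x atom x xyz, Angstrom);
#'   atom order is P, C4', N.
#' @param sequence optional character scalar over A/C/G/U of length L.
#' @return An object of class `coarse_structure`.
#' @export
coarse_structure <- function(coords, sequence = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L,
            dim(coords)[2] == 3L, dim(coords)[3] == 3L)
  if (any(!is.finite(coords))) stop("coordinates contain NaN/Inf")
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != dim(coords)[1]) {
      stop("sequence length does not match coordinate count")
    }
    if (grepl("[^ACGU]", sequence)) stop("sequence must be over A/C/G/U")
  }
  structure(list(coords = coords, sequence = sequence),
            class = "coarse_structure")
}

#' @export
length.coarse_structure <- function(x) dim(x$coords)[1]

#' @export
print.coarse_structure <- function(x, ...) {
  cat("<coarse_structure>", length(x), "nucleotides (P, C4', N)\n")
  invisible(x)
}

#' Extract one atom type as an L x 3 coordinate matrix
#'
#' @param s a `coarse_structure`.
#' @param atom one of "P", "C4'", "N".
#' @return L x 3 matrix.
#' @export
atom_coords <- function(s, atom = c("P", "C4'", "N")) {
  atom <- match.arg(atom)
  k <- match(atom, c("P", "C4'", "N"))
  s$coords[, k, , drop = TRUE]
}

#' Local three-atom template
#'
#' Idealized coordinates of P, C4' and glycosidic N in the nucleotide-local
#' frame. One template is shared across the four nucleotide types.
#'
#' @param coords 3x3 numeric matrix, rows P, C4', N (Angstrom).
#' @return Object of class `local_template`.
#' @export
local_template <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(all(dim(coords) == c(3L, 3L)), all(is.finite(coords)))
  d <- as.numeric(stats::dist(coords))
  if (any(d <= 0) || any(d >= 10)) {
    stop("template atom pairwise distances must be in (0, 10) Angstrom")
  }
  rownames(coords) <- c("P", "C4'", "N")
  structure(coords, class = c("local_template", "matrix"))
}

#' Packaged default nucleotide template
#'
#' Loads the idealized A-form-like three-atom template shipped with the
#' package (see `inst/extdata/template_aform_synthetic.tsv` for provenance).
#'
#' @return A `local_template`.
#' @export
default_template <- function() {
  path <- system.file("extdata", "template_aform_synthetic.tsv",
                      package = "ribofold")
  m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1L,
                                   sep = "\t", quote = ""))
  local_template(m)
}

#' Fit per-nucleotide frames to observed atoms
#'
#' For every nucleotide, finds the rigid frame that maps the local template
#' onto the three observed atoms with least squared error (Kabsch fit through
#' the same symmetric orthogonalization used throughout the toolkit).
#'
#' @param s a `coarse_structure`.
#' @param template a `local_template` (default: packaged template).
#' @return A `frame_set` of the same length as `s`.
#' @export
frames_from_atoms <- function(s, template = default_template()) {
  L <- length(s)
  a <- unclass(template)
  ca <- colMeans(a)
  ac <- sweep(a, 2L, ca)
  rot <- array(0, c(3, 3, L))
  tr <- matrix(0, L, 3)
  for (l in seq_len(L)) {
    b <- s$coords[l, , ]
    cb <- colMeans(b)
    bc <- sweep(b, 2L, cb)
    h <- t(ac) %*% bc
    sv <- svd(h)
    if (sv$d[2] < 1e-8) {
      stop("degenerate atom triple (collinear) at nucleotide ", l)
    }
    d <- sign(det(sv$v %*% t(sv$u)))
    r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    rot[, , l] <- r
    tr[l, ] <- cb - as.numeric(r %*% ca)
  }
  frame_set(rot, tr)
}

#' Reconstruct atoms from frames and a template
#'
#' `coords[l, k, ] = R_l template[k, ] + t_l`.
#'
#' @param frames a `frame_set`.
#' @param template a `local_template`.
#' @param sequence optional sequence string attached to the output.
#' @return A `coarse_structure`.
#' @export
atoms_from_frames <- function(frames, template = default_template(),
                              sequence = NULL) {
  L <- length(frames)
  a <- unclass(template)
  coords <- array(0, c(L, 3, 3))
  for (l in seq_len(L)) {
    r <- frames$rotations[, , l]
    coords[l, , ] <- t(r %*% t(a) + frames$translations[l, ])
  }
  coarse_structure(coords, sequence)
}

## ---- quaternion helpers (scalar-first) ----

rot_to_quat <- function(r) {
  tr <- r[1, 1] + r[2, 2] + r[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (r[3, 2] - r[2, 3]) / s, (r[1, 3] - r[3, 1]) / s,
           (r[2, 1] - r[1, 2]) / s)
  } else if (r[1, 1] > r[2, 2] && r[1, 1] > r[3, 3]) {
    s <- sqrt(1 + r[1, 1] - r[2, 2] - r[3, 3]) * 2
    q <- c((r[3, 2] - r[2, 3]) / s, 0.25 * s, (r[1, 2] + r[2, 1]) / s,
           (r[1, 3] + r[3, 1]) / s)
  } else if (r[2, 2] > r[3, 3]) {
    s <- sqrt(1 + r[2, 2] - r[1, 1] - r[3, 3]) * 2
    q <- c((r[1, 3] - r[3, 1]) / s, (r[1, 2] + r[2, 1]) / s, 0.25 * s,
           (r[2, 3] + r[3, 2]) / s)
  } else {
    s <- sqrt(1 + r[3, 3] - r[1, 1] - r[2, 2]) * 2
    q <- c((r[2, 1] - r[1, 2]) / s, (r[1, 3] + r[3, 1]) / s,
           (r[2, 3] + r[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

quat_to_rot <- function(q) {
  matrix(quat_to_R9(matrix(q, 1L)), 3, 3, byrow = TRUE)
}

# one uniform random rotation from the current RNG stream
draw_random_rotation <- function() {
  q <- stats::rnorm(4)
  quat_to_rot(q / sqrt(sum(q^2)))
}

rotation_angle <- function(r) {
  acos(pmin(pmax((sum(diag(r)) - 1) / 2, -1), 1))
}

#' Geodesic rotation interpolation (slerp)
#'
#' Spherical-linear interpolation between two rotations along the geodesic of
#' the rotation group; `w = 0` returns `a`, `w = 1` returns `b`.
#'
#' @param a,b 3x3 rotation matrices.
#' @param w interpolation weight in `[0, 1]`.
#' @return A 3x3 rotation matrix.
#' @export
slerp_rotation <- function(a, b, w) {
  check_rotation(a)
  check_rotation(b)
  if (!is.numeric(w) || length(w) != 1L || w < 0 || w > 1) {
    stop("interpolation weight w must be a scalar in [0, 1]")
  }
  if (w == 0) return(a)
  if (w == 1) return(b)
  qa <- rot_to_quat(a)
  qb <- rot_to_quat(b)
  d <- sum(qa * qb)
  if (d < 0) {
    qb <- -qb
    d <- -d
  }
  d <- min(d, 1)
  th <- acos(d)
  q <- if (th < 1e-8) {
    (1 - w) * qa + w * qb
  } else {
    (sin((1 - w) * th) * qa + sin(w * th) * qb) / sin(th)
  }
  quat_to_rot(q / sqrt(sum(q^2)))
}

#' Denoising perturbation of a frame set
#'
#' Each rotation is interpolated toward an independently sampled uniform
#' random rotation with weight `w`; each translation receives isotropic
#' Gaussian noise of scale `sigma`. Deterministic given `seed`.
#'
#' @param frames a `frame_set`.
#' @param w slerp weight in `[0, 1]` (training default 0.1).
#' @param sigma translation noise scale in Angstrom (training default 0.1).
#' @param seed integer seed.
#' @return A perturbed `frame_set`.
#' @export
perturb_frames <- function(frames, w = 0.1, sigma = 0.1, seed = 1L) {
  stopifnot(w >= 0, w <= 1, sigma >= 0)
  L <- length(frames)
  with_seed(seed, {
    rot <- array(0, c(3, 3, L))
    tr <- frames$translations
    for (l in seq_len(L)) {
      rr <- draw_random_rotation()
      rot[, , l] <- if (w == 0) frames$rotations[, , l]
      else slerp_rotation(frames$rotations[, , l], rr, w)
      tr[l, ] <- tr[l, ] + stats::rnorm(3, 0, sigma)
    }
    frame_set(rot, tr)
  })
}

#' Transport a structure's atoms between two frame sets
#'
#' Applies, per nucleotide, the rigid delta `T_new o T_old^-1` to the
#' observed atoms: `x' = R_new R_old' (x - t_old) + t_new`. With
#' `new = old` the structure is returned unchanged, so frame-level
#' refinement moves the original atoms rather than template
#' reconstructions.
#'
#' @param s a `coarse_structure`.
#' @param old,new `frame_set`s of the same length as `s`.
#' @return The transported `coarse_structure`.
#' @export
apply_frame_delta <- function(s, old, new) {
  L <- length(s)
  stopifnot(length(old) == L, length(new) == L)
  coords <- s$coords
  for (l in seq_len(L)) {
    rd <- new$rotations[, , l] %*% t(old$rotations[, , l])
    coords[l, , ] <- t(rd %*% (t(s$coords[l, , ]) - old$translations[l, ]) +
                         new$translations[l, ])
  }
  coarse_structure(coords, s$sequence)
}

#' Apply one global rigid motion to a structure or frame set
#'
#' @param x a `coarse_structure` or `frame_set`.
#' @param rotation 3x3 rotation.
#' @param translation length-3 vector.
#' @return The transformed object (same class).
#' @export
transform_rigid <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  check_rotation(rotation)
  if (inherits(x, "coarse_structure")) {
    L <- length(x)
    coords <- x$coords
    for (l in seq_len(L)) {
      coords[l, , ] <- t(rotation %*% t(x$coords[l, , ]) + translation)
    }
    return(coarse_structure(coords, x$sequence))
  }
  if (inherits(x, "frame_set")) {
    L <- length(x)
    rot <- x$rotations
    tr <- x$translations
    for (l in seq_len(L)) {
      rot[, , l] <- rotation %*% x$rotations[, , l]
      tr[l, ] <- as.numeric(rotation %*% x$translations[l, ]) + translation
    }
    return(frame_set(rot, tr))
  }
  stop("x must be a coarse_structure or frame_set")
}
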