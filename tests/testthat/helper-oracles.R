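# Shared fixtures and independent oracles used across the suite.

rot_z <- function(a) {
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

rot_x <- function(a) {
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}

random_rotation_oracle <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)), 3, 3,
    byrow = TRUE)
}

# random frame_set fixture
random_frames <- function(L, scale = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rot <- array(0, c(3, 3, L))
  for (l in seq_len(L)) rot[, , l] <- random_rotation_oracle()
  frame_set(rot, matrix(stats::rnorm(L * 3, 0, scale), L, 3))
}

# brute-force nearest-rotation oracle via SVD (the construction the
# implementation is checked against; the implementation itself uses the
# Loewdin eigendecomposition route)
svd_rotation_oracle <- function(m) {
  s <- svd(m)
  s$u %*% diag(c(1, 1, det(s$u %*% t(s$v)))) %*% t(s$v)
}

# rigid-superposition RMSD by quaternion sampling + Nelder-Mead polish
grid_rmsd_oracle <- function(a, b, n_grid = 4000) {
  best <- Inf
  score <- function(r) {
    moved <- a %*% t(r)
    moved <- sweep(moved, 2L, colMeans(moved))
    bc <- sweep(b, 2L, colMeans(b))
    sqrt(mean(rowSums((moved - bc)^2)))
  }
  best_q <- c(1, 0, 0, 0)
  for (i in seq_len(n_grid)) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    r <- quat_mat_oracle(q)
    v <- score(r)
    if (v < best) {
      best <- v
      best_q <- q
    }
  }
  polish <- stats::optim(best_q, function(q) {
    score(quat_mat_oracle(q / sqrt(sum(q^2))))
  }, method = "Nelder-Mead", control = list(maxit = 500, reltol = 1e-12))
  min(best, polish$value)
}

quat_mat_oracle <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)), 3, 3,
    byrow = TRUE)
}

# plug-in mutual information of two discrete columns
mi_oracle <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab)
  pb <- colSums(tab)
  s <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  }
  s
}

# tiny language model trained for a handful of steps (shared across tests)
tiny_clm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- family_spec(14, cbind(c(1, 2), c(14, 13)))
      fam <- sample_family(sp, 60, seed = 5)
      cache <<- train_clm(fam, clm_config(steps = 10L, batch_size = 2L),
                          seed = 3)
    }
    cache
  }
})
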