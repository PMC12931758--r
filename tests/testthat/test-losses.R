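# Folding losses: gFAPE parameter rules, floors, invariances and gradients;
# distance binning and the distogram cross-entropy.

# a compact structure whose C4'-C4' distances we control exactly
two_nt_structure <- function(c4_gap) {
  coords <- array(0, c(2, 3, 3))
  coords[1, , ] <- rbind(c(-2, 0, 1), c(0, 0, 0), c(1, 2, 0))
  coords[2, , ] <- rbind(c(-2, 0, 1), c(0, 0, 0), c(1, 2, 0))
  coords[2, , 1] <- coords[2, , 1] + c4_gap
  coords[2, 1, ] <- coords[2, 1, ] + c(0, 0.5, 0)  # break exact overlap
  coarse_structure(coords)
}

test_that("gFAPE parameters follow the 20-Angstrom rule with the far boundary", {
  near <- two_nt_structure(10)
  p <- make_gfape_params(near)
  expect_true(all(p$lambda == 3))
  expect_true(all(is.infinite(p$dcut)))

  far <- two_nt_structure(50)
  pf <- make_gfape_params(far)
  expect_equal(pf$lambda[1, 2], 1)
  expect_equal(pf$dcut[1, 2], 30)
  expect_equal(pf$lambda[1, 1], 3)  # the diagonal is always near

  exact <- two_nt_structure(20)
  pe <- make_gfape_params(exact)
  expect_equal(pe$lambda[1, 2], 1)  # d == 20 falls in the far branch
  expect_equal(pe$epsilon, 1e-3)
})

test_that("gFAPE attains its analytic floor and is rigid-motion invariant", {
  L <- 5L
  fs <- random_frames(L, seed = 21)
  p <- uniform_gfape_params(L, lambda = 3)
  floor_val <- 3 * L^2 * 3 * sqrt(1e-3)
  expect_equal(gfape(fs, fs, p), floor_val, tolerance = 1e-9)

  set.seed(22)
  g <- random_rotation_oracle()
  fs2 <- random_frames(L, seed = 23)
  v <- gfape(fs, fs2, p)
  expect_gt(v, floor_val)
  v_moved <- gfape(transform_rigid(fs, g, c(3, -8, 2)),
                   transform_rigid(fs2, g, c(3, -8, 2)), p)
  expect_equal(v, v_moved, tolerance = 1e-6)
  # moving only one side changes nothing either (per-side invariance)
  expect_equal(v, gfape(transform_rigid(fs, g, c(1, 2, 3)), fs2, p),
               tolerance = 1e-6)
  expect_error(gfape(fs, random_frames(3), p), "length")
})

test_that("gFAPE matches a term-by-term hand computation on a 2-nucleotide toy", {
  tmpl <- unclass(default_template())
  fs_a <- frame_set(array(c(diag(3), rot_z(0.4)), c(3, 3, 2)),
                    rbind(c(0, 0, 0), c(5, 1, 0)))
  fs_b <- frame_set(array(c(rot_x(0.2), diag(3)), c(3, 3, 2)),
                    rbind(c(0, 1, 0), c(5, 0, 0)))
  p <- uniform_gfape_params(2L, lambda = 2, dcut = 3)
  # independent direct enumeration
  hand <- 0
  for (i in 1:2) for (j in 1:2) for (k in 1:3) {
    Ti <- list(fs_a$rotations[, , i], fs_a$translations[i, ])
    Tj <- list(fs_a$rotations[, , j], fs_a$translations[j, ])
    Si <- list(fs_b$rotations[, , i], fs_b$translations[i, ])
    Sj <- list(fs_b$rotations[, , j], fs_b$translations[j, ])
    xa <- t(Ti[[1]]) %*% (Tj[[1]] %*% tmpl[k, ] + Tj[[2]] - Ti[[2]])
    xb <- t(Si[[1]]) %*% (Sj[[1]] %*% tmpl[k, ] + Sj[[2]] - Si[[2]])
    hand <- hand + 2 * min(3, sqrt(sum((xa - xb)^2) + 1e-3))
  }
  expect_equal(gfape(fs_a, fs_b, p), hand, tolerance = 1e-9)
})

test_that("gFAPE is non-decreasing in each clamp entry", {
  L <- 4L
  fs <- random_frames(L, seed = 24)
  fs2 <- random_frames(L, seed = 25)
  vals <- vapply(c(0.5, 1, 2, 5, 20, Inf), function(cut) {
    gfape(fs, fs2, uniform_gfape_params(L, lambda = 1, dcut = cut))
  }, 1)
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("structure loss is bounded, signed and has a correct gradient", {
  L <- 4L
  tmpl <- default_template()
  fs_ref <- random_frames(L, seed = 26, scale = 30)
  p <- make_gfape_params(atoms_from_frames(fs_ref, tmpl))
  # black-hole term bounded by its clamp
  bh <- gfape(fs_ref, black_hole_frames(L),
              uniform_gfape_params(L, lambda = 1, dcut = 2))
  expect_lte(0.1 * bh, 0.1 * 3 * L^2 * 2)
  # at the reference (far from the origin) the loss sits below the floor
  floor_val <- sum(p$lambda) * 3 * sqrt(p$epsilon)
  expect_lt(structure_loss(fs_ref, fs_ref, p, tmpl), floor_val)

  # finite-difference gradient of gFAPE wrt translations
  fs_t <- random_frames(L, seed = 27, scale = 10)
  refloc <- ribofold:::gfape_ref_local(ribofold:::fs_R9(fs_ref),
                                       fs_ref$translations, unclass(tmpl))
  gr <- ribofold:::gfape_with_grad(ribofold:::fs_R9(fs_t), fs_t$translations,
                                   refloc, unclass(tmpl), p$lambda, p$dcut,
                                   p$epsilon)
  eps <- 1e-6
  for (probe in list(c(1, 1), c(2, 3), c(4, 2))) {
    tr_up <- fs_t$translations
    tr_up[probe[1], probe[2]] <- tr_up[probe[1], probe[2]] + eps
    up <- ribofold:::gfape_core(ribofold:::fs_R9(fs_t), tr_up, refloc,
                                unclass(tmpl), p$lambda, p$dcut, p$epsilon)$value
    tr_dn <- fs_t$translations
    tr_dn[probe[1], probe[2]] <- tr_dn[probe[1], probe[2]] - eps
    dn <- ribofold:::gfape_core(ribofold:::fs_R9(fs_t), tr_dn, refloc,
                                unclass(tmpl), p$lambda, p$dcut, p$epsilon)$value
    fd <- (up - dn) / (2 * eps)
    expect_lt(abs(fd - gr$dtr[probe[1], probe[2]]) / max(1, abs(fd)), 1e-4)
  }
})

test_that("distance binning follows the 38 + 2 scheme", {
  expect_identical(bin_distance(1.5), 1L)
  expect_identical(bin_distance(2.5), 2L)
  expect_identical(bin_distance(45), 40L)
  expect_identical(bin_distance(2), 2L)     # left-closed interior bins
  expect_identical(bin_distance(40), 40L)   # >= 40 is the open top bin
  expect_identical(bin_distance(39.99), 39L)
  expect_identical(bin_distance(0), 1L)
  expect_error(bin_distance(-1), "non-negative")
  b <- distance_binning()
  expect_length(b$edges, 39L)
  expect_identical(b$n_bins, 40L)
})

test_that("distogram loss is zero for one-hot truth and analytic for uniform", {
  sp <- family_spec(8, cbind(1, 8))
  st <- build_toy_structure(sp)
  L <- 8L
  tb <- ribofold:::true_bins(st)
  onehot <- lapply(tb, function(bins) {
    m <- matrix(0, L * L, 40)
    m[cbind(seq_len(L * L), as.integer(bins))] <- 1
    m
  })
  dg1 <- distogram(list(PP = onehot[[1]], CC = onehot[[2]], NN = onehot[[3]]), L)
  expect_equal(distogram_loss(dg1, st), 0)

  u <- matrix(1 / 40, L * L, 40)
  dgu <- distogram(list(PP = u, CC = u, NN = u), L)
  expect_equal(distogram_loss(dgu, st), 3 * L^2 * log(40), tolerance = 1e-9)

  # hand-built 2-nucleotide case
  st2 <- two_nt_structure(10)
  tb2 <- ribofold:::true_bins(st2)
  ch <- lapply(tb2, function(bins) {
    m <- matrix((1 - 0.6) / 39, 4, 40)
    m[cbind(1:4, as.integer(bins))] <- 0.6
    m / rowSums(m)
  })
  dg2 <- distogram(list(PP = ch[[1]], CC = ch[[2]], NN = ch[[3]]), 2L)
  hand <- -3 * 4 * log(0.6)
  expect_equal(distogram_loss(dg2, st2), hand, tolerance = 1e-9)

  expect_error(distogram_loss(dg2, st), "lengths")
})

test_that("distogram loss decreases as mass moves onto the true bin", {
  st <- two_nt_structure(10)
  L <- 2L
  tb <- ribofold:::true_bins(st)
  losses <- vapply(seq(0.05, 0.9, length.out = 8), function(w) {
    ch <- lapply(tb, function(bins) {
      wrong <- ifelse(as.integer(bins) == 5L, 6L, 5L)
      m <- matrix(1e-12, L * L, 40)
      m[cbind(seq_len(L * L), as.integer(bins))] <- w
      m[cbind(seq_len(L * L), wrong)] <- 1 - w
      m / rowSums(m)
    })
    distogram_loss(distogram(list(PP = ch[[1]], CC = ch[[2]], NN = ch[[3]]), L),
                   st)
  }, 1)
  expect_true(all(diff(losses) < 0))
})

test_that("the total loss combines its terms with the 0.2 weight", {
  expect_equal(total_loss(0, 0), 0)
  expect_equal(total_loss(1, 5), 2)
  expect_equal(total_loss(2, 0) + total_loss(0, 3), total_loss(2, 3))
  expect_error(total_loss(Inf, 1), "finite")
})
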