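# Consensus selection/optimization: energies, filtering, L-BFGS refinement
# and greedy clustering.

make_uniform_pool <- function(ref, n = 1) {
  L <- length(ref)
  u <- matrix(1 / 40, L * L, 40)
  dg <- distogram(list(PP = u, CC = u, NN = u), L)
  decoy_pool(lapply(seq_len(n), function(i) {
    list(structure = ref, distogram = dg, weights = NULL)
  }))
}

test_that("the end-to-end energy has the identity floor and rigid invariance", {
  sp <- family_spec(12, cbind(c(1, 2), c(12, 11)))
  ref <- build_toy_structure(sp)
  L <- length(ref)
  fr <- frames_from_atoms(ref)
  pool <- make_uniform_pool(ref)
  floor_val <- L^2 * 3 * sqrt(1e-3)
  expect_equal(e2e_energy(fr, pool), floor_val, tolerance = 1e-9)

  set.seed(31)
  g <- random_rotation_oracle()
  moved <- transform_rigid(fr, g, c(10, -4, 2))
  expect_equal(e2e_energy(moved, pool), floor_val, tolerance = 1e-6)

  # conf equal to one of two decoys scores lower than one equal to neither
  other <- make_decoy_pool(ref, 1, noise_scales = 3, sharpness = 1,
                           seed = 9)$decoys[[1]]$structure
  third <- make_decoy_pool(ref, 2, noise_scales = 3, sharpness = 1,
                           seed = 10)$decoys[[2]]$structure
  p2 <- decoy_pool(list(list(structure = ref, distogram = NULL, weights = NULL),
                        list(structure = other, distogram = NULL, weights = NULL)))
  expect_lt(e2e_energy(frames_from_atoms(ref), p2),
            e2e_energy(frames_from_atoms(third), p2))
})

test_that("the distance energy is zero for uniform maps and matches a hand case", {
  sp <- family_spec(10, cbind(1, 10))
  ref <- build_toy_structure(sp)
  pool <- make_uniform_pool(ref)
  expect_equal(dist_energy(ref, pool), 0, tolerance = 1e-12)

  # single pair, single decoy, P(true bin) = 0.5, P(gM) = 0.001
  st <- coarse_structure(array(c(0, 10, 0, 10, 1, 11,
                                 0, 0, 0, 0, 2, 2,
                                 0, 0, 0, 0, 0, 0), c(2, 3, 3)))
  L <- 2L
  tb <- ribofold:::true_bins(st)
  gM <- ribofold:::last_closed_bin()
  ch <- lapply(tb, function(bins) {
    m <- matrix(0, 4, 40)
    m[cbind(1:4, as.integer(bins))] <- 0.5
    m[, gM] <- m[, gM] + 0.001
    # spread the remainder over a far bin to normalize
    m[, 20] <- m[, 20] + 1 - rowSums(m)
    m
  })
  dg <- distogram(list(PP = ch[[1]], CC = ch[[2]], NN = ch[[3]]), L)
  p1 <- decoy_pool(list(list(structure = st, distogram = dg, weights = NULL)))
  # ordered pairs (1,2) and (2,1), three channels, reference-state log ratio
  expected <- -2 * 3 * log((0.5 + 0.001) / (0.001 + 0.001))
  expect_equal(dist_energy(st, p1), expected, tolerance = 1e-9)
})

test_that("the global energy is the sum of its parts", {
  sp <- family_spec(10, cbind(1, 10))
  ref <- build_toy_structure(sp)
  pool <- make_decoy_pool(ref, 4, noise_scales = 1, sharpness = 0.8, seed = 3)
  eb <- global_energy(ref, pool)
  expect_equal(eb$total, eb$e2e + eb$dist, tolerance = 1e-9)
  expect_equal(eb$e2e, e2e_energy(ref, pool), tolerance = 1e-9)
  expect_equal(eb$dist, dist_energy(ref, pool), tolerance = 1e-9)
})

test_that("the base-pair filter obeys the 90 percent / 150-nucleotide rules", {
  short_pool <- make_decoy_pool(build_toy_structure(family_spec(20, cbind(1:2, 20:19))),
                                3, noise_scales = 1, seed = 4)
  expect_identical(length(bp_count_filter(short_pool)), 3L)

  # L = 200 decoys with graded detected-pair counts
  mk <- function(k) build_toy_structure(sample_structure_spec(200, k, seed = 60))
  pool200 <- decoy_pool(lapply(c(10, 9, 8), function(k) {
    list(structure = mk(k), distogram = NULL, weights = NULL)
  }))
  counts <- vapply(pool200$decoys, function(d) length(detect_base_pairs(d$structure)), 1L)
  kept <- bp_count_filter(pool200)
  expect_identical(length(kept), sum(counts >= 0.9 * max(counts)))
  expect_lt(length(kept), 3L)  # the low-count decoy is removed
  expect_true(which.max(counts) <= length(kept))  # max-count decoy survives

  # all counts equal: unchanged
  pool_eq <- decoy_pool(lapply(1:3, function(i) {
    list(structure = mk(9), distogram = NULL, weights = NULL)
  }))
  expect_identical(length(bp_count_filter(pool_eq)), 3L)
})

test_that("selection ranks a consensus cluster above an outlier", {
  sp <- family_spec(16, cbind(1:4, 16:13))
  ref <- build_toy_structure(sp)
  pool <- make_decoy_pool(ref, 6, noise_scales = 0.5, sharpness = 0.9, seed = 5)
  # replace the last decoy by a heavily perturbed outlier
  outlier <- make_decoy_pool(ref, 1, noise_scales = 12, sharpness = 0.9,
                             seed = 6)$decoys[[1]]
  decoys <- pool$decoys
  decoys[[6]] <- outlier
  pool <- decoy_pool(decoys)
  sel <- select_models(pool, 5)
  expect_identical(nrow(sel$energies), 6L)
  expect_identical(which.max(sel$energies$total), 6L)  # outlier scores worst
  expect_false(6L %in% sel$order)
  expect_identical(sel$order, select_models(pool, 5)$order)  # deterministic

  p1 <- decoy_pool(pool$decoys[1])
  expect_warning(s1 <- select_models(p1, 5), "pool size")
  expect_identical(s1$order, 1L)
})

test_that("L-BFGS optimization is near-stationary at a consensus and improves a perturbed start", {
  sp <- family_spec(14, cbind(1:3, 14:12))
  ref <- build_toy_structure(sp)
  refP <- atom_coords(ref, "P")
  pool <- make_decoy_pool(ref, 5, noise_scales = 1, sharpness = 0.9, seed = 7)
  sel <- select_models(pool, 5)

  # start at a pool member: energy never increases
  opt0 <- optimize_conformation(pool$decoys[[sel$order[1]]]$structure,
                                sel$pool, maxit = 20)
  expect_lte(opt0$energy, opt0$start_energy + 1e-6)
  expect_true(all(diff(opt0$history) <= 1e-9))

  # perturbed start converges back toward the consensus
  start <- perturb_frames(frames_from_atoms(ref), 0.05, 1.0, seed = 9)
  start_rmsd <- kabsch_rmsd(atom_coords(atoms_from_frames(start), "P"), refP)
  opt <- optimize_conformation(start, sel$pool, maxit = 60)
  final_rmsd <- kabsch_rmsd(atom_coords(atoms_from_frames(opt$frames), "P"),
                            refP)
  expect_lt(final_rmsd, start_rmsd)

  # objective gradient matches finite differences at the start point
  obj <- ribofold:::make_opt_objective(sel$pool, default_template())
  par <- ribofold:::frames_to_par(start)
  g <- obj(par)$grad
  set.seed(10)
  for (k in sample(length(par), 5)) {
    eps <- 1e-5
    pp <- par
    pp[k] <- pp[k] + eps
    up <- obj(pp, want_grad = FALSE)$value
    pp[k] <- pp[k] - 2 * eps
    dn <- obj(pp, want_grad = FALSE)$value
    fd <- (up - dn) / (2 * eps)
    expect_lt(abs(g[k] - fd) / max(1, abs(fd)), 1e-4)
  }
})

test_that("greedy clustering separates constructed groups deterministically", {
  sp <- family_spec(12, cbind(c(1, 2), c(12, 11)))
  ref <- build_toy_structure(sp)
  # all identical: one cluster centered on the first decoy
  same <- make_uniform_pool(ref, 4)
  cl_same <- cluster_decoys(same)
  expect_identical(cl_same$centers, 1L)
  expect_identical(sort(cl_same$members[[1]]), 1:4)

  # two tight groups around genuinely different conformations (a rigidly
  # moved copy would superpose back onto the first group)
  ref2 <- build_toy_structure(family_spec(12, cbind(c(1, 7), c(6, 12))))
  near_pool <- make_decoy_pool(ref, 3, noise_scales = 0.3, sharpness = 1, seed = 8)
  far_pool <- make_decoy_pool(ref2, 3, noise_scales = 0.3, sharpness = 1, seed = 9)
  pool2 <- decoy_pool(c(near_pool$decoys, far_pool$decoys))
  cl2 <- cluster_decoys(pool2, cutoff = 2)
  expect_identical(length(cl2$centers), 2L)
  grp <- vapply(cl2$members, function(m) all(m <= 3) || all(m >= 4), TRUE)
  expect_true(all(grp))

  p1 <- decoy_pool(near_pool$decoys[1])
  expect_identical(cluster_decoys(p1)$centers, 1L)
})

test_that("the pipeline emits at most five models ranked by optimization energy", {
  sp <- family_spec(14, cbind(1:3, 14:12))
  ref <- build_toy_structure(sp)
  pool <- make_decoy_pool(ref, 8, noise_scales = c(0.5, 1), sharpness = 0.9,
                          seed = 11)
  models <- csor_pipeline(pool, maxit = 30)
  expect_lte(length(models), 5L)
  eopt <- vapply(models, `[[`, 1, "opt_energy")
  expect_equal(eopt[1], min(eopt))
  expect_true(all(diff(eopt) >= 0))

  # identical decoys collapse to a single model close to the decoy
  same <- make_uniform_pool(ref, 4)
  ms <- csor_pipeline(same, maxit = 10)
  expect_identical(length(ms), 1L)
  expect_lt(kabsch_rmsd(atom_coords(ms[[1]]$structure, "P"),
                        atom_coords(ref, "P")), 0.5)
})
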