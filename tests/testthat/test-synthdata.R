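# Synthetic study material: structure sampling, covariation-bearing
# families, deterministic toy folds and decoy pools.

test_that("structure sampling respects its constraints and determinism", {
  expect_identical(nrow(sample_structure_spec(20, 0, seed = 1)$pairs), 0L)
  sp <- sample_structure_spec(10, 3, seed = 2)
  expect_identical(nrow(sp$pairs), 3L)
  expect_true(all(sp$pairs[, 2] - sp$pairs[, 1] >= 4))

  for (seed in 1:8) {
    s <- sample_structure_spec(30, 9, seed = seed)
    expect_identical(nrow(s$pairs), 9L)
    expect_true(all(s$pairs[, 2] - s$pairs[, 1] >= 4))
    expect_false(anyDuplicated(as.integer(s$pairs)) > 0)
    # nestedness: no crossing pairs
    for (r in seq_len(nrow(s$pairs))) for (q in seq_len(nrow(s$pairs))) {
      if (r == q) next
      i <- s$pairs[r, 1]; j <- s$pairs[r, 2]
      k <- s$pairs[q, 1]; l <- s$pairs[q, 2]
      expect_false(i < k && k < j && j < l)
    }
  }
  expect_identical(sample_structure_spec(30, 9, seed = 5)$pairs,
                   sample_structure_spec(30, 9, seed = 5)$pairs)
  expect_error(sample_structure_spec(10, 4, seed = 1), "infeasible")
})

test_that("family sampling plants complementarity at the specified rate", {
  comp_set <- c("AU", "UA", "GC", "CG", "GU", "UG")
  sp1 <- family_spec(20, cbind(c(1, 2, 3), c(20, 19, 18)),
                     complement_prob = 1, mutation_rate = 0)
  fam1 <- sample_family(sp1, 300, seed = 3)
  for (s in fam1) {
    x <- strsplit(s, "")[[1]]
    expect_true(all(paste0(x[1:3], x[20:18]) %in% comp_set))
  }

  # complement_prob = 0.9: empirical complementarity = 0.9 + 0.1 * chance
  sp2 <- family_spec(20, cbind(c(1, 4), c(20, 15)), complement_prob = 0.9,
                     mutation_rate = 0)
  n <- 5000L
  fam2 <- sample_family(sp2, n, seed = 4)
  bg <- sp2$background
  chance <- sum(bg["A"] * bg["U"], bg["U"] * bg["A"], bg["G"] * bg["C"],
                bg["C"] * bg["G"], bg["G"] * bg["U"], bg["U"] * bg["G"])
  expected <- 0.9 + 0.1 * chance
  chars <- do.call(rbind, strsplit(fam2, ""))
  freq <- mean(paste0(chars[, 1], chars[, 20]) %in% comp_set)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(freq - expected), 3 * se)
})

test_that("mutual information concentrates on planted pairs", {
  sp <- sample_structure_spec(24, 6, seed = 11, complement_prob = 0.85)
  n <- 3000L
  fam <- matrix(unlist(strsplit(sample_family(sp, n, seed = 12), "")),
                n, sp$L, byrow = TRUE)
  planted_mi <- vapply(seq_len(nrow(sp$pairs)), function(r) {
    mi_oracle(fam[, sp$pairs[r, 1]], fam[, sp$pairs[r, 2]])
  }, 1)
  unpaired <- setdiff(seq_len(sp$L), as.integer(sp$pairs))
  set.seed(13)
  null_pairs <- t(replicate(20, sample(unpaired, 2)))
  null_mi <- vapply(seq_len(nrow(null_pairs)), function(r) {
    mi_oracle(fam[, null_pairs[r, 1]], fam[, null_pairs[r, 2]])
  }, 1)
  # planted columns carry signal far above background, with a 3-sigma margin
  expect_gt(min(planted_mi),
            mean(null_mi) + 3 * stats::sd(null_mi))

  # without complementarity the planted columns look like background
  sp0 <- family_spec(sp$L, sp$pairs, complement_prob = 0)
  fam0 <- matrix(unlist(strsplit(sample_family(sp0, n, seed = 14), "")),
                 n, sp$L, byrow = TRUE)
  mi0 <- vapply(seq_len(nrow(sp$pairs)), function(r) {
    mi_oracle(fam0[, sp$pairs[r, 1]], fam0[, sp$pairs[r, 2]])
  }, 1)
  null0 <- vapply(seq_len(nrow(null_pairs)), function(r) {
    mi_oracle(fam0[, null_pairs[r, 1]], fam0[, null_pairs[r, 2]])
  }, 1)
  expect_lt(abs(mean(mi0) - mean(null0)),
            3 * stats::sd(null0) / sqrt(length(null0)) +
              3 * stats::sd(mi0) / sqrt(length(mi0)))
})

test_that("toy structures are deterministic with calibrated geometry", {
  sp <- family_spec(16, cbind(1:6, 16:11))
  st <- build_toy_structure(sp)
  expect_true(all(is.finite(st$coords)))
  expect_identical(st$coords, build_toy_structure(sp)$coords)

  # designed stem pairs recovered exactly (round trip with the detector)
  bp <- detect_base_pairs(st)
  expect_identical(unname(bp$pairs), unname(cbind(1:6, 16:11)))

  # empty pair list: extended curve without detected pairs
  st0 <- build_toy_structure(family_spec(12))
  expect_identical(length(detect_base_pairs(st0)), 0L)

  # backbone adjacency and pair-window contracts, over several shapes
  for (s in list(c(16, 6, 1), c(30, 8, 3), c(40, 18, 7), c(52, 22, 5))) {
    spk <- sample_structure_spec(s[1], s[2], seed = s[3])
    stk <- build_toy_structure(spk)
    pp <- atom_coords(stk, "P")
    adj <- sqrt(rowSums((pp[-1, , drop = FALSE] -
                           pp[-nrow(pp), , drop = FALSE])^2))
    expect_true(all(adj >= 4 & adj <= 8))
    nn <- as.matrix(stats::dist(atom_coords(stk, "N")))
    expect_true(all(abs(nn[spk$pairs] - 9.42) < 0.5))
  }
})

test_that("decoy pools degrade gracefully with the noise scale", {
  sp <- family_spec(14, cbind(1:3, 14:12))
  ref <- build_toy_structure(sp)
  p0 <- make_decoy_pool(ref, 2, noise_scales = 0, sharpness = 1, seed = 5)
  expect_equal(p0$decoys[[1]]$structure$coords, ref$coords, tolerance = 1e-12)
  for (ch in p0$decoys[[1]]$distogram$channels) {
    expect_true(all(ch %in% c(0, 1)))
    expect_equal(rowSums(ch), rep(1, length(ref)^2))
  }

  refP <- atom_coords(ref, "P")
  mean_rmsd <- function(pool) {
    mean(vapply(pool$decoys, function(d) {
      kabsch_rmsd(atom_coords(d$structure, "P"), refP)
    }, 1))
  }
  r_small <- mean_rmsd(make_decoy_pool(ref, 20, noise_scales = 0.5,
                                       sharpness = 0.9, seed = 6))
  r_big <- mean_rmsd(make_decoy_pool(ref, 20, noise_scales = 2,
                                     sharpness = 0.9, seed = 6))
  expect_lt(r_small, r_big)

  # pool invariants across configurations
  for (sharp in c(0, 0.5, 1)) {
    pool <- make_decoy_pool(ref, 3, noise_scales = c(0.5, 2), sharpness = sharp,
                            seed = 7)
    expect_identical(length(pool), 3L)
    for (d in pool$decoys) {
      expect_true(all(is.finite(d$structure$coords)))
      for (ch in d$distogram$channels) {
        expect_equal(rowSums(ch), rep(1, length(ref)^2), tolerance = 1e-9)
      }
      expect_true(all(d$weights == 1))
    }
  }
})
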