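# Composite-likelihood objective: masking, the two-term loss, pair
# marginalization, recovery, and the desk-scale training loop.

test_that("mask_sequence masks ceiling(fraction*L) positions deterministically", {
  sq <- strrep("ACGU", 5)  # L = 20
  b <- mask_sequence(sq, 0.15, seed = 1)
  expect_length(b$masked_positions, 3L)
  expect_identical(nchar(b$visible), 20L)
  out <- strsplit(b$visible, "")[[1]]
  expect_true(all(out[b$masked_positions] == "N"))
  expect_identical(out[-b$masked_positions],
                   strsplit(sq, "")[[1]][-b$masked_positions])
  expect_length(mask_sequence(sq, 1, seed = 2)$masked_positions, 20L)
  expect_identical(mask_sequence(sq, 0.3, seed = 9),
                   mask_sequence(sq, 0.3, seed = 9))
  expect_error(mask_sequence(sq, 0), "fraction")
  expect_error(mask_sequence("", 0.5), "empty")
})

test_that("composite loss matches hand enumeration and degenerates correctly", {
  # perfect one-hot predictions give zero loss
  sq <- "ACGU"
  b <- mask_sequence(sq, 0.5, seed = 1)
  truth <- ribofold:::seq_to_idx(sq)
  sp <- matrix(0, 4, 4)
  sp[cbind(1:4, truth)] <- 1
  pp <- array(0, c(4, 4, 16))
  for (i in 1:4) for (j in 1:4) {
    pp[i, j, ribofold:::pair_class(truth[i], truth[j])] <- 1
  }
  expect_equal(composite_loss(sp, pp, b), 0)

  # L = 3, M = {2}, uniform predictions: pairs (2,1),(2,3),(1,2),(3,2)
  b3 <- structure(list(original = "ACG", masked_positions = 2L,
                       visible = "ANG"), class = "masked_batch")
  u_s <- matrix(1 / 4, 3, 4)
  u_p <- array(1 / 16, c(3, 3, 16))
  expect_equal(composite_loss(u_s, u_p, b3), log(4) + 4 * log(16))

  # doubling the masked set can only increase the loss under uniform preds
  b3b <- structure(list(original = "ACG", masked_positions = c(1L, 2L),
                        visible = "NNG"), class = "masked_batch")
  expect_gt(composite_loss(u_s, u_p, b3b), composite_loss(u_s, u_p, b3))

  expect_error(composite_loss(matrix(1 / 4, 2, 4), u_p, b3), "shape")
})

test_that("the first loss term equals an independent pseudo-likelihood implementation", {
  set.seed(21)
  L <- 8L
  sq <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
  b <- mask_sequence(sq, 0.4, seed = 2)
  sp <- matrix(runif(L * 4), L, 4)
  sp <- sp / rowSums(sp)
  pp <- array(runif(L * L * 16), c(L, L, 16))
  for (i in 1:L) for (j in 1:L) pp[i, j, ] <- pp[i, j, ] / sum(pp[i, j, ])

  # independent pseudo-likelihood masked-LM loss (first sum only)
  truth <- match(strsplit(sq, "")[[1]], c("A", "C", "G", "U"))
  pll <- -sum(log(sp[cbind(b$masked_positions, truth[b$masked_positions])]))
  # independent enumeration of the ordered pair term
  pair_term <- 0
  for (i in 1:L) for (j in 1:L) {
    if (i != j && (i %in% b$masked_positions || j %in% b$masked_positions)) {
      pair_term <- pair_term -
        log(pp[i, j, 4 * (truth[i] - 1) + truth[j]])
    }
  }
  expect_equal(composite_loss(sp, pp, b) - pair_term, pll, tolerance = 1e-9)
})

test_that("composite loss is covariant under consistent relabeling of positions", {
  set.seed(33)
  L <- 7L
  sq <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
  b <- mask_sequence(sq, 0.3, seed = 3)
  sp <- matrix(runif(L * 4), L, 4)
  sp <- sp / rowSums(sp)
  pp <- array(runif(L * L * 16), c(L, L, 16))
  for (i in 1:L) for (j in 1:L) pp[i, j, ] <- pp[i, j, ] / sum(pp[i, j, ])
  perm <- sample(L)
  sq_p <- paste(strsplit(sq, "")[[1]][perm], collapse = "")
  b_p <- structure(list(original = sq_p,
                        masked_positions = sort(match(b$masked_positions, perm)),
                        visible = NA), class = "masked_batch")
  expect_equal(composite_loss(sp, pp, b),
               composite_loss(sp[perm, ], pp[perm, perm, ], b_p),
               tolerance = 1e-12)
})

test_that("marginalize_pair recovers factors and hand-computed sums", {
  # outer-product joint: marginal at i equals its own factor
  L <- 5L
  set.seed(12)
  pfac <- matrix(runif(L * 4), L, 4)
  pfac <- pfac / rowSums(pfac)
  pp <- array(0, c(L, L, 16))
  for (i in 1:L) for (j in 1:L) for (a in 1:4) for (bb in 1:4) {
    pp[i, j, 4 * (a - 1) + bb] <- pfac[i, a] * pfac[j, bb]
  }
  expect_equal(marginalize_pair(pp), pfac, tolerance = 1e-9)

  expect_equal(marginalize_pair(array(1 / 16, c(4, 4, 16))),
               matrix(1 / 4, 4, 4), tolerance = 1e-12)

  # L = 2 with one hand-written 16-vector
  v <- (1:16) / sum(1:16)
  pp2 <- array(0, c(2, 2, 16))
  pp2[1, 2, ] <- v
  pp2[2, 1, ] <- v
  pp2[1, 1, ] <- 1 / 16
  pp2[2, 2, ] <- 1 / 16
  hand <- vapply(1:4, function(a) sum(v[4 * (a - 1) + 1:4]), 1)
  m <- marginalize_pair(pp2)
  expect_equal(m[1, ], hand / sum(hand), tolerance = 1e-9)

  expect_error(marginalize_pair(array(1, c(1, 1, 16))), "partners")
})

test_that("sequence recovery handles forced, wrong and uniform models", {
  sq <- strrep("ACGU", 3)
  b <- mask_sequence(sq, 0.5, seed = 4)
  truth <- ribofold:::seq_to_idx(sq)
  L <- nchar(sq)
  onehot_model <- function(visible) {
    m <- matrix(0, L, 4)
    m[cbind(seq_len(L), truth)] <- 1
    m
  }
  wrong_model <- function(visible) {
    m <- matrix(0, L, 4)
    m[, (truth[1] %% 4) + 1] <- 1
    m[cbind(seq_len(L), truth)] <- 0
    m <- m + 1e-6
    m / rowSums(m)
  }
  expect_equal(sequence_recovery(onehot_model, b), 1)
  # constant wrong class everywhere it matters
  const_wrong <- function(visible) {
    m <- matrix(1e-9, L, 4)
    wrong <- ifelse(truth == 1L, 2L, 1L)
    m[cbind(seq_len(L), wrong)] <- 1
    m / rowSums(m)
  }
  expect_equal(sequence_recovery(const_wrong, b), 0)

  # uniform model: binomial around 1/4 over many masked sites
  set.seed(6)
  hits <- 0L
  n_sites <- 0L
  uniform_model <- function(visible) {
    matrix(runif(nchar(visible) * 4), ncol = 4) -> m
    m / rowSums(m)
  }
  for (k in 1:250) {
    sqk <- paste(sample(c("A", "C", "G", "U"), 40, TRUE), collapse = "")
    bk <- mask_sequence(sqk, 1, seed = 600 + k)
    hits <- hits + sequence_recovery(uniform_model, bk) * 40
    n_sites <- n_sites + 40L
  }
  p_hat <- hits / n_sites
  expect_lt(abs(p_hat - 0.25), 3 * sqrt(0.25 * 0.75 / n_sites))
})

test_that("training reduces the loss and checkpoints round-trip", {
  sp <- family_spec(14, cbind(c(1, 2, 3), c(14, 13, 12)))
  fam <- sample_family(sp, 150, seed = 2)
  cfg <- clm_config(steps = 60L, batch_size = 3L, lr = 2e-3)
  m <- train_clm(fam, cfg, seed = 11, log_interval = 10L)
  lg <- m$log
  first <- mean(head(lg$loss, 2))
  last <- mean(tail(lg$loss, 2))
  expect_lt(last, first)

  # zero steps leaves the initialization untouched
  cfg0 <- clm_config(steps = 0L)
  m0 <- train_clm(fam, cfg0, seed = 11)
  expect_identical(m0$params, ribofold:::init_clm_params(cfg0, 11))

  # save/load reproduces forward outputs exactly
  path <- file.path(tempdir(), "ck.rds")
  save_clm(m, path)
  m2 <- load_clm(path)
  fw1 <- clm_forward(m, fam[1])
  fw2 <- clm_forward(m2, fam[1])
  expect_identical(fw1, fw2)

  expect_error(train_clm(c("ACGX"), cfg), "symbols")
  expect_error(train_clm(character(0), cfg), "empty")
})
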