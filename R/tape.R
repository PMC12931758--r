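# Reverse-mode autodiff tape used by the trainable components (composite
# language model, folding stack, conformation optimizer).  Nodes hold plain
# numeric matrices; ops are coarse-grained (attention-sized) so that the R
# overhead per training step stays small.  Batches are stacked along rows and
# block-aware ops take the block length L explicitly.

tp_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

tp_push <- function(tape, value, parents, backward) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$grad <- NULL
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

tp_leaf <- function(tape, value) {
  node <- tp_push(tape, value, list(), NULL)
  node$tape <- tape
  node
}

tp_value <- function(node) node$value

#' @noRd
tp_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  for (k in seq(tape$n, 1L)) {
    node <- tape$nodes[[k]]
    if (is.null(node$grad) || is.null(node$backward)) next
    pg <- node$backward(node$grad, node)
    for (i in seq_along(node$parents)) {
      p <- node$parents[[i]]
      g <- pg[[i]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

tp_mm <- function(a, b) {
  tp_push_ab(a, b, a$value %*% b$value, function(g, node) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

# helper: binary op; the tape ref travels on each node
tp_push_ab <- function(a, b, value, backward) {
  node <- tp_push(a$tape, value, list(a, b), backward)
  node$tape <- a$tape
  node
}

tp_add <- function(a, b) {
  tp_push_ab(a, b, a$value + b$value, function(g, node) list(g, g))
}

tp_sub <- function(a, b) {
  tp_push_ab(a, b, a$value - b$value, function(g, node) list(g, -g))
}

tp_emul <- function(a, b) {
  tp_push_ab(a, b, a$value * b$value, function(g, node) {
    list(g * b$value, g * a$value)
  })
}

tp_push1 <- function(a, value, backward) {
  node <- tp_push(a$tape, value, list(a), backward)
  node$tape <- a$tape
  node
}

tp_scale <- function(a, s) {
  tp_push1(a, a$value * s, function(g, node) list(g * s))
}

tp_shift <- function(a, s) {
  tp_push1(a, a$value + s, function(g, node) list(g))
}

bcast_rows <- function(v, n, k) matrix(v, n, k, byrow = TRUE)

# add a constant matrix (same shape, or broadcast row vector)
tp_addc <- function(a, C) {
  v <- if (is.matrix(C) && nrow(C) == 1L && nrow(a$value) > 1L) {
    a$value + bcast_rows(as.numeric(C), nrow(a$value), ncol(a$value))
  } else a$value + C
  tp_push1(a, v, function(g, node) list(g))
}

# broadcast-add a 1 x k parameter row to all rows
tp_add_rowvec <- function(a, v) {
  val <- a$value + bcast_rows(as.numeric(v$value), nrow(a$value), ncol(a$value))
  tp_push_ab(a, v, val, function(g, node) {
    list(g, matrix(colSums(g), 1L))
  })
}

tp_t <- function(a) {
  tp_push1(a, t(a$value), function(g, node) list(t(g)))
}

tp_rows <- function(a, idx) {
  tp_push1(a, a$value[idx, , drop = FALSE], function(g, node) {
    out <- matrix(0, nrow(a$value), ncol(a$value))
    acc <- rowsum(g, idx)
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

tp_cols <- function(a, idx) {
  tp_push1(a, a$value[, idx, drop = FALSE], function(g, node) {
    out <- matrix(0, nrow(a$value), ncol(a$value))
    out[, idx] <- g
    list(out)
  })
}

tp_cbind <- function(args) {
  vals <- lapply(args, tp_value)
  ks <- vapply(vals, ncol, 1L)
  node <- tp_push(args[[1L]]$tape, do.call(cbind, vals), args, function(g, node) {
    out <- vector("list", length(args))
    at <- 0L
    for (i in seq_along(args)) {
      out[[i]] <- g[, at + seq_len(ks[i]), drop = FALSE]
      at <- at + ks[i]
    }
    out
  })
  node$tape <- args[[1L]]$tape
  node
}

tp_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  tp_push1(a, s, function(g, node) list(g * s * (1 - s)))
}

tp_softplus <- function(a) {
  x <- a$value
  v <- ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  tp_push1(a, v, function(g, node) list(g / (1 + exp(-x))))
}

tp_relu <- function(a) {
  keep <- a$value > 0
  tp_push1(a, a$value * keep, function(g, node) list(g * keep))
}

tp_gelu <- function(a) {
  x <- a$value
  ph <- stats::pnorm(x)
  tp_push1(a, x * ph, function(g, node) {
    list(g * (ph + x * stats::dnorm(x)))
  })
}

tp_log <- function(a) {
  tp_push1(a, log(a$value), function(g, node) list(g / a$value))
}

tp_sqrt <- function(a) {
  s <- sqrt(a$value)
  tp_push1(a, s, function(g, node) list(g * 0.5 / s))
}

tp_square <- function(a) {
  tp_push1(a, a$value^2, function(g, node) list(2 * g * a$value))
}

tp_clamp_max <- function(a, cut) {
  keep <- a$value < cut
  tp_push1(a, pmin(a$value, cut), function(g, node) list(g * keep))
}

tp_sum <- function(a) {
  tp_push1(a, sum(a$value), function(g, node) {
    list(array(as.numeric(g), dim = dim(a$value)))
  })
}

rowmax <- function(x) x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]

tp_softmax_rows <- function(a) {
  x <- a$value
  x <- x - rowmax(x)
  e <- exp(x)
  s <- e / rowSums(e)
  tp_push1(a, s, function(g, node) {
    list(s * (g - rowSums(g * s)))
  })
}

# rows divided by their sums (used by renormalized attention dropout)
tp_rownorm1 <- function(a) {
  rs <- rowSums(a$value)
  out <- a$value / rs
  tp_push1(a, out, function(g, node) {
    list(g / rs - out * (rowSums(g * out) / rs))
  })
}

tp_layernorm_rows <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$value
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sd
  n <- nrow(x); k <- ncol(x)
  gam <- as.numeric(gamma$value)
  gb <- bcast_rows(gam, n, k)
  val <- xhat * gb + bcast_rows(as.numeric(beta$value), n, k)
  node <- tp_push(a$tape, val, list(a, gamma, beta), function(g, node) {
    dgamma <- matrix(colSums(g * xhat), 1L)
    dbeta <- matrix(colSums(g), 1L)
    dxhat <- g * gb
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd
    list(dx, dgamma, dbeta)
  })
  node$tape <- a$tape
  node
}

# cross-entropy over selected rows: -sum(w * log softmax(logits)[i, cls[i]])
tp_ce_rows <- function(logits, cls, w = NULL) {
  x <- logits$value
  x <- x - rowmax(x)
  e <- exp(x)
  p <- e / rowSums(e)
  n <- nrow(p)
  if (is.null(w)) w <- rep(1, n)
  picked <- p[cbind(seq_len(n), cls)]
  val <- -sum(w * log(pmax(picked, 1e-12)))
  tp_push1(logits, val, function(g, node) {
    y <- p
    y[cbind(seq_len(n), cls)] <- y[cbind(seq_len(n), cls)] - 1
    list(as.numeric(g) * (w * y))
  })
}

# per-block matmul: a is (B*L) x p, blocks of L rows.
#  transpose_b = TRUE : out block = A_b %*% t(B_b)   (B_b is (L x p))
#  transpose_b = FALSE: out block = A_b %*% B_b      (B_b is (L x q), stacked)
tp_bmm <- function(a, b, L, B, transpose_b = TRUE) {
  fwd <- function(av, bv) {
    blocks <- vector("list", B)
    for (k in seq_len(B)) {
      r <- (k - 1L) * L + seq_len(L)
      blocks[[k]] <- if (transpose_b) tcrossprod(av[r, , drop = FALSE], bv[r, , drop = FALSE])
      else av[r, , drop = FALSE] %*% bv[r, , drop = FALSE]
    }
    do.call(rbind, blocks)
  }
  val <- fwd(a$value, b$value)
  tp_push_ab(a, b, val, function(g, node) {
    da <- matrix(0, nrow(a$value), ncol(a$value))
    db <- matrix(0, nrow(b$value), ncol(b$value))
    for (k in seq_len(B)) {
      r <- (k - 1L) * L + seq_len(L)
      gk <- g[r, , drop = FALSE]
      ak <- a$value[r, , drop = FALSE]
      bk <- b$value[r, , drop = FALSE]
      if (transpose_b) {
        da[r, ] <- gk %*% bk
        db[r, ] <- t(gk) %*% ak
      } else {
        da[r, ] <- gk %*% t(bk)
        db[r, ] <- t(ak) %*% gk
      }
    }
    list(da, db)
  })
}

# take column j of a (B*L^2) x k pair tensor and lay each batch's L^2 slice
# out as an L x L block => (B*L) x L (bias matrices for attention)
tp_paircol_as_rows <- function(a, j, L, B) {
  col <- a$value[, j]
  val <- matrix(0, B * L, L)
  for (k in seq_len(B)) {
    val[(k - 1L) * L + seq_len(L), ] <- matrix(col[(k - 1L) * L * L + seq_len(L * L)], L, L)
  }
  tp_push1(a, val, function(g, node) {
    out <- matrix(0, nrow(a$value), ncol(a$value))
    for (k in seq_len(B)) {
      out[(k - 1L) * L * L + seq_len(L * L), j] <-
        as.numeric(g[(k - 1L) * L + seq_len(L), , drop = FALSE])
    }
    list(out)
  })
}

# broadcast sequence features into the pair tensor: out[(b, i + (j-1)L), ] =
# a[(b,i), ] + bb[(b,j), ]   (the "vertical + horizontal" pair embedding)
tp_pair_broadcast <- function(a, bb, L, B) {
  ii <- rep(seq_len(L), times = L)
  jj <- rep(seq_len(L), each = L)
  val <- matrix(0, B * L * L, ncol(a$value))
  for (k in seq_len(B)) {
    r <- (k - 1L) * L
    rr <- (k - 1L) * L * L + seq_len(L * L)
    val[rr, ] <- a$value[r + ii, , drop = FALSE] + bb$value[r + jj, , drop = FALSE]
  }
  tp_push_ab(a, bb, val, function(g, node) {
    da <- matrix(0, nrow(a$value), ncol(a$value))
    db <- matrix(0, nrow(bb$value), ncol(bb$value))
    for (k in seq_len(B)) {
      r <- (k - 1L) * L
      rr <- (k - 1L) * L * L + seq_len(L * L)
      gk <- g[rr, , drop = FALSE]
      da[r + seq_len(L), ] <- rowsum(gk, ii)
      db[r + seq_len(L), ] <- rowsum(gk, jj)
    }
    list(da, db)
  })
}

# learned relative-position features added to the pair tensor: embedding
# table E ((2*clip+2) x d) indexed by clipped j - i (last row = |off| > clip)
tp_relpos <- function(E, L, B, clip) {
  off <- rep(seq_len(L), each = L) - rep(seq_len(L), times = L)  # j - i
  idx <- ifelse(abs(off) > clip, 2L * clip + 2L, off + clip + 1L)
  idx <- rep(idx, times = B)
  tp_push1(E, E$value[idx, , drop = FALSE], function(g, node) {
    out <- matrix(0, nrow(E$value), ncol(E$value))
    acc <- rowsum(g, idx)
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

tp_rowbind <- function(args) {
  vals <- lapply(args, tp_value)
  ns <- vapply(vals, nrow, 1L)
  node <- tp_push(args[[1L]]$tape, do.call(rbind, vals), args, function(g, node) {
    out <- vector("list", length(args))
    at <- 0L
    for (i in seq_along(args)) {
      out[[i]] <- g[at + seq_len(ns[i]), , drop = FALSE]
      at <- at + ns[i]
    }
    out
  })
  node$tape <- args[[1L]]$tape
  node
}

# scatter rows of a into an n-row matrix at positions idx (idx a partition:
# every target row receives exactly one source row)
tp_scatter_rows <- function(a, idx, n) {
  val <- matrix(0, n, ncol(a$value))
  val[idx, ] <- a$value
  tp_push1(a, val, function(g, node) {
    list(g[idx, , drop = FALSE])
  })
}

# fused triangle attention around the starting node: for each batch block
# and anchor row i, out[i, j] = sum_k softmax_k(q[i,j].k[i,k]/sqrt(dt) +
# bias[j, k]) v[i, k]. q, k, v: (B*L^2) x dt; bias_col: (B*L^2) x 1.
tp_tri_attn <- function(q, k, v, bias_col, L, B, dt) {
  sc <- 1 / sqrt(dt)
  qa <- q$value; ka <- k$value; va <- v$value; bc <- bias_col$value
  val <- matrix(0, B * L * L, dt)
  amats <- vector("list", B * L)
  for (bb in seq_len(B)) {
    off <- (bb - 1L) * L * L
    Bmat <- matrix(bc[off + seq_len(L * L)], L, L)
    for (i in seq_len(L)) {
      idx <- off + i + (seq_len(L) - 1L) * L
      Qi <- qa[idx, , drop = FALSE]
      Ki <- ka[idx, , drop = FALSE]
      logits <- tcrossprod(Qi, Ki) * sc + Bmat
      logits <- logits - rowmax(logits)
      e <- exp(logits)
      A <- e / rowSums(e)
      amats[[(bb - 1L) * L + i]] <- A
      val[idx, ] <- A %*% va[idx, , drop = FALSE]
    }
  }
  node <- tp_push(q$tape, val, list(q, k, v, bias_col), function(g, node) {
    dq <- matrix(0, nrow(qa), dt)
    dk <- matrix(0, nrow(ka), dt)
    dv <- matrix(0, nrow(va), dt)
    db <- matrix(0, nrow(bc), 1L)
    for (bb in seq_len(B)) {
      off <- (bb - 1L) * L * L
      dB <- matrix(0, L, L)
      for (i in seq_len(L)) {
        idx <- off + i + (seq_len(L) - 1L) * L
        A <- amats[[(bb - 1L) * L + i]]
        gi <- g[idx, , drop = FALSE]
        Vi <- va[idx, , drop = FALSE]
        dv[idx, ] <- dv[idx, ] + crossprod(A, gi)
        dA <- tcrossprod(gi, Vi)
        dlog <- A * (dA - rowSums(dA * A))
        dq[idx, ] <- dq[idx, ] + dlog %*% ka[idx, , drop = FALSE] * sc
        dk[idx, ] <- dk[idx, ] + crossprod(dlog, qa[idx, , drop = FALSE]) * sc
        dB <- dB + dlog
      }
      db[off + seq_len(L * L)] <- as.numeric(dB)
    }
    list(dq, dk, dv, db)
  })
  node$tape <- q$tape
  node
}

# transpose each batch block of a pair tensor: (i, j) -> (j, i)
tp_pair_transpose <- function(a, L, B) {
  perm0 <- as.integer(t(matrix(seq_len(L * L), L, L)))
  perm <- unlist(lapply(seq_len(B), function(k) (k - 1L) * L * L + perm0))
  tp_push1(a, a$value[perm, , drop = FALSE], function(g, node) {
    out <- matrix(0, nrow(a$value), ncol(a$value))
    out[perm, ] <- g
    list(out)
  })
}

# outer-product pair update: a, b are (B*L) x c ->
# out[(batch, i + (j-1)L), (p-1)*c + q] = a[batch,i,p] * b[batch,j,q]
tp_opm <- function(a, b, L, B) {
  c1 <- ncol(a$value)
  c2 <- ncol(b$value)
  val <- matrix(0, B * L * L, c1 * c2)
  for (k in seq_len(B)) {
    r <- (k - 1L) * L + seq_len(L)
    rr <- (k - 1L) * L * L + seq_len(L * L)
    for (p in seq_len(c1)) for (q in seq_len(c2)) {
      val[rr, (p - 1L) * c2 + q] <- as.numeric(outer(a$value[r, p], b$value[r, q]))
    }
  }
  tp_push_ab(a, b, val, function(g, node) {
    da <- matrix(0, nrow(a$value), c1)
    db <- matrix(0, nrow(b$value), c2)
    for (k in seq_len(B)) {
      r <- (k - 1L) * L + seq_len(L)
      rr <- (k - 1L) * L * L + seq_len(L * L)
      for (p in seq_len(c1)) for (q in seq_len(c2)) {
        Gm <- matrix(g[rr, (p - 1L) * c2 + q], L, L)
        da[r, p] <- da[r, p] + Gm %*% b$value[r, q]
        db[r, q] <- db[r, q] + t(Gm) %*% a$value[r, p]
      }
    }
    list(da, db)
  })
}

# triangle multiplication on pair tensors (B*L^2) x c.
#  outgoing: out[i,j,ch] = sum_k a[i,k,ch] * b[j,k,ch]
#  incoming: out[i,j,ch] = sum_k a[k,i,ch] * b[k,j,ch]
tp_tri_mul <- function(a, b, L, B, incoming = FALSE) {
  nc <- ncol(a$value)
  val <- matrix(0, B * L * L, nc)
  for (k in seq_len(B)) {
    rr <- (k - 1L) * L * L + seq_len(L * L)
    for (ch in seq_len(nc)) {
      A <- matrix(a$value[rr, ch], L, L)
      Bm <- matrix(b$value[rr, ch], L, L)
      val[rr, ch] <- if (incoming) as.numeric(crossprod(A, Bm)) else as.numeric(tcrossprod(A, Bm))
    }
  }
  tp_push_ab(a, b, val, function(g, node) {
    da <- matrix(0, nrow(a$value), nc)
    db <- matrix(0, nrow(b$value), nc)
    for (k in seq_len(B)) {
      rr <- (k - 1L) * L * L + seq_len(L * L)
      for (ch in seq_len(nc)) {
        A <- matrix(a$value[rr, ch], L, L)
        Bm <- matrix(b$value[rr, ch], L, L)
        Gm <- matrix(g[rr, ch], L, L)
        if (incoming) {
          da[rr, ch] <- as.numeric(tcrossprod(Bm, Gm))
          db[rr, ch] <- as.numeric(A %*% Gm)
        } else {
          da[rr, ch] <- as.numeric(Gm %*% Bm)
          db[rr, ch] <- as.numeric(crossprod(Gm, A))
        }
      }
    }
    list(da, db)
  })
}

## ---- quaternion / frame ops (L x 4 rows, scalar-first convention) ----

tp_quat_normalize <- function(q) {
  x <- q$value
  nrm <- sqrt(rowSums(x^2))
  out <- x / nrm
  tp_push1(q, out, function(g, node) {
    list((g - out * rowSums(g * out)) / nrm)
  })
}

quat_rows_mul <- function(p, q) {
  cbind(
    p[, 1] * q[, 1] - p[, 2] * q[, 2] - p[, 3] * q[, 3] - p[, 4] * q[, 4],
    p[, 1] * q[, 2] + p[, 2] * q[, 1] + p[, 3] * q[, 4] - p[, 4] * q[, 3],
    p[, 1] * q[, 3] - p[, 2] * q[, 4] + p[, 3] * q[, 1] + p[, 4] * q[, 2],
    p[, 1] * q[, 4] + p[, 2] * q[, 3] - p[, 3] * q[, 2] + p[, 4] * q[, 1]
  )
}

quat_rows_conj <- function(p) cbind(p[, 1], -p[, 2], -p[, 3], -p[, 4])

# rowwise Hamilton product a (x) b; grads via dL/da = G (x) conj(b),
# dL/db = conj(a) (x) G
tp_quat_mul <- function(a, b) {
  tp_push_ab(a, b, quat_rows_mul(a$value, b$value), function(g, node) {
    list(quat_rows_mul(g, quat_rows_conj(b$value)),
         quat_rows_mul(quat_rows_conj(a$value), g))
  })
}

# unit quaternion rows -> rotation matrices as L x 9 rows
# (row-major: R11 R12 R13 R21 ... R33)
quat_to_R9 <- function(q) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  )
}

tp_quat_to_R9 <- function(qn) {
  q <- qn$value
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  tp_push1(qn, quat_to_R9(q), function(g, node) {
    dw <- -2 * z * g[, 2] + 2 * y * g[, 3] + 2 * z * g[, 4] - 2 * x * g[, 6] +
      -2 * y * g[, 7] + 2 * x * g[, 8]
    dx <- 2 * y * g[, 2] + 2 * z * g[, 3] + 2 * y * g[, 4] - 4 * x * g[, 5] +
      -2 * w * g[, 6] + 2 * z * g[, 7] + 2 * w * g[, 8] - 4 * x * g[, 9]
    dy <- -4 * y * g[, 1] + 2 * x * g[, 2] + 2 * w * g[, 3] + 2 * x * g[, 4] +
      2 * z * g[, 6] - 2 * w * g[, 7] + 2 * z * g[, 8] - 4 * y * g[, 9]
    dz <- -4 * z * g[, 1] - 2 * w * g[, 2] + 2 * x * g[, 3] + 2 * w * g[, 4] +
      -4 * z * g[, 5] + 2 * y * g[, 6] + 2 * x * g[, 7] + 2 * y * g[, 8]
    list(cbind(dw, dx, dy, dz))
  })
}

rot_apply_rows <- function(r, x, tr) {
  if (!tr) {
    cbind(
      r[, 1] * x[, 1] + r[, 2] * x[, 2] + r[, 3] * x[, 3],
      r[, 4] * x[, 1] + r[, 5] * x[, 2] + r[, 6] * x[, 3],
      r[, 7] * x[, 1] + r[, 8] * x[, 2] + r[, 9] * x[, 3]
    )
  } else {
    cbind(
      r[, 1] * x[, 1] + r[, 4] * x[, 2] + r[, 7] * x[, 3],
      r[, 2] * x[, 1] + r[, 5] * x[, 2] + r[, 8] * x[, 3],
      r[, 3] * x[, 1] + r[, 6] * x[, 2] + r[, 9] * x[, 3]
    )
  }
}

# out[l,] = R_l %*% v[l,]   (or R_l^T %*% v[l,] when transpose = TRUE)
tp_rotate_rows <- function(R9, v, transpose = FALSE) {
  val <- rot_apply_rows(R9$value, v$value, transpose)
  tp_push_ab(R9, v, val, function(g, node) {
    r <- R9$value
    x <- v$value
    dv <- rot_apply_rows(r, g, !transpose)
    if (!transpose) {
      dr <- cbind(
        g[, 1] * x[, 1], g[, 1] * x[, 2], g[, 1] * x[, 3],
        g[, 2] * x[, 1], g[, 2] * x[, 2], g[, 2] * x[, 3],
        g[, 3] * x[, 1], g[, 3] * x[, 2], g[, 3] * x[, 3]
      )
    } else {
      # out_i = sum_j R[j,i] v_j  => dR[j,i] = g_i v_j ; dR9 col (j-1)*3+i
      dr <- cbind(
        g[, 1] * x[, 1], g[, 2] * x[, 1], g[, 3] * x[, 1],
        g[, 1] * x[, 2], g[, 2] * x[, 2], g[, 3] * x[, 2],
        g[, 1] * x[, 3], g[, 2] * x[, 3], g[, 3] * x[, 3]
      )
    }
    list(dr, dv)
  })
}

# pairwise distances of rows of x (L x 3) -> (L^2) x 1, column-major (i,j)
tp_pairdist <- function(x, eps = 1e-12) {
  L <- nrow(x$value)
  xm <- x$value
  d1 <- outer(xm[, 1], xm[, 1], "-")
  d2 <- outer(xm[, 2], xm[, 2], "-")
  d3 <- outer(xm[, 3], xm[, 3], "-")
  Dm <- sqrt(d1^2 + d2^2 + d3^2 + eps)
  tp_push1(x, matrix(as.numeric(Dm), ncol = 1L), function(g, node) {
    Gm <- matrix(g, L, L)
    W <- Gm / Dm
    dx <- cbind(
      rowSums(W * d1) - colSums(W * d1),
      rowSums(W * d2) - colSums(W * d2),
      rowSums(W * d3) - colSums(W * d3)
    )
    list(dx)
  })
}

# piecewise-linear interpolation of per-pair score tables over distance.
# D: (L^2) x 1 node; S: const (L^2) x nbin score matrix; centers: knots.
tp_dist_score <- function(D, S, centers) {
  d <- as.numeric(D$value)
  nb <- length(centers)
  lo <- findInterval(d, centers)
  lo <- pmin(pmax(lo, 1L), nb - 1L)
  hi <- lo + 1L
  w <- (d - centers[lo]) / (centers[hi] - centers[lo])
  w <- pmin(pmax(w, 0), 1)
  n <- length(d)
  slo <- S[cbind(seq_len(n), lo)]
  shi <- S[cbind(seq_len(n), hi)]
  val <- sum((1 - w) * slo + w * shi)
  slope <- (shi - slo) / (centers[hi] - centers[lo])
  slope[w <= 0 | w >= 1] <- 0
  tp_push1(D, val, function(g, node) {
    list(matrix(as.numeric(g) * slope, ncol = 1L))
  })
}

## ---- generalized FAPE as a single fused node ----

# forward/backward share this helper; template: 3 x 3 (rows = atoms, local Å)
# refloc: precomputed list over i of (3L x 3) reference local coordinates
gfape_core <- function(R9, tr, refloc, template, lambda, dcut, eps,
                       want_grad = FALSE) {
  L <- nrow(R9)
  natom <- nrow(template)
  # global atom coordinates X: (natom*L) x 3, atom-major blocks
  X <- matrix(0, natom * L, 3)
  for (k in seq_len(natom)) {
    a <- template[k, ]
    X[(k - 1L) * L + seq_len(L), ] <- cbind(
      R9[, 1] * a[1] + R9[, 2] * a[2] + R9[, 3] * a[3] + tr[, 1],
      R9[, 4] * a[1] + R9[, 5] * a[2] + R9[, 6] * a[3] + tr[, 2],
      R9[, 7] * a[1] + R9[, 8] * a[2] + R9[, 9] * a[3] + tr[, 3]
    )
  }
  total <- 0
  dR9 <- if (want_grad) matrix(0, L, 9) else NULL
  dtr <- if (want_grad) matrix(0, L, 3) else NULL
  dX <- if (want_grad) matrix(0, natom * L, 3) else NULL
  lam3 <- do.call(cbind, rep(list(lambda), natom))  # L x (natom*L), row i
  cut3 <- do.call(cbind, rep(list(dcut), natom))
  nX <- natom * L
  for (i in seq_len(L)) {
    Ri <- matrix(R9[i, ], 3, 3, byrow = TRUE)
    Dm <- X - matrix(tr[i, ], nX, 3, byrow = TRUE)
    U <- Dm %*% Ri                       # rows are R_i^T (x - t_i)
    diff <- U - refloc[[i]]
    s <- rowSums(diff^2)
    val <- sqrt(s + eps)
    lam_i <- lam3[i, ]
    cut_i <- cut3[i, ]
    m <- pmin(val, cut_i)
    total <- total + sum(lam_i * m)
    if (want_grad) {
      wts <- lam_i * (val < cut_i) / val
      V <- diff * wts
      dR9[i, ] <- dR9[i, ] + as.numeric(t(t(Dm) %*% V))
      dD <- V %*% t(Ri)
      dX <- dX + dD
      dtr[i, ] <- dtr[i, ] - colSums(dD)
    }
  }
  if (want_grad) {
    for (k in seq_len(natom)) {
      a <- template[k, ]
      gk <- dX[(k - 1L) * L + seq_len(L), , drop = FALSE]
      dR9 <- dR9 + cbind(
        gk[, 1] * a[1], gk[, 1] * a[2], gk[, 1] * a[3],
        gk[, 2] * a[1], gk[, 2] * a[2], gk[, 2] * a[3],
        gk[, 3] * a[1], gk[, 3] * a[2], gk[, 3] * a[3]
      )
      dtr <- dtr + gk
    }
  }
  list(value = total, dR9 = dR9, dtr = dtr)
}

# precompute reference local coordinates for gfape_core
gfape_ref_local <- function(refR9, reftr, template) {
  L <- nrow(refR9)
  natom <- nrow(template)
  X <- matrix(0, natom * L, 3)
  for (k in seq_len(natom)) {
    a <- template[k, ]
    X[(k - 1L) * L + seq_len(L), ] <- cbind(
      refR9[, 1] * a[1] + refR9[, 2] * a[2] + refR9[, 3] * a[3] + reftr[, 1],
      refR9[, 4] * a[1] + refR9[, 5] * a[2] + refR9[, 6] * a[3] + reftr[, 2],
      refR9[, 7] * a[1] + refR9[, 8] * a[2] + refR9[, 9] * a[3] + reftr[, 3]
    )
  }
  lapply(seq_len(L), function(i) {
    Ri <- matrix(refR9[i, ], 3, 3, byrow = TRUE)
    sweep(X, 2L, reftr[i, ], "-") %*% Ri
  })
}

tp_gfape <- function(R9, tr, refloc, template, lambda, dcut, eps) {
  fwd <- gfape_core(R9$value, tr$value, refloc, template, lambda, dcut, eps,
                    want_grad = FALSE)
  tp_push_ab(R9, tr, fwd$value, function(g, node) {
    bk <- gfape_core(R9$value, tr$value, refloc, template, lambda, dcut, eps,
                     want_grad = TRUE)
    list(as.numeric(g) * bk$dR9, as.numeric(g) * bk$dtr)
  })
}

## ---- parameter helpers (Adam) ----

adam_state <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = dim(p))),
    v = lapply(params, function(p) array(0, dim = dim(p))),
    t = 0L
  )
}

adam_update <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# wrap a named parameter list as tape leaves; collect gradients by name
tp_params <- function(tape, params) {
  leaves <- lapply(params, function(p) {
    n <- tp_leaf(tape, p)
    n$tape <- tape
    n
  })
  leaves
}

tp_collect_grads <- function(leaves) {
  lapply(leaves, function(n) {
    if (is.null(n$grad)) NULL else n$grad
  })
}
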