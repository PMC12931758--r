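# Synthetic study material: covariation-bearing RNA sequence families with
# planted base pairs, deterministic toy 3D folds built from idealized A-form
# helices, and noisy decoy pools with matched synthetic distograms.

#' Default nucleotide background composition
#'
#' Mildly G-rich composition typical of structured non-coding RNA; used for
#' unpaired family columns.
#'
#' @return Named numeric 4-vector over A, C, G, U summing to 1.
#' @export
default_background <- function() {
  c(A = 0.26, C = 0.21, G = 0.31, U = 0.22)
}

#' Specification of a synthetic RNA family
#'
#' @param L sequence length.
#' @param pairs two-column matrix of planted (paired) column indices; must be
#'   disjoint, non-crossing (nested) and separated by at least `min_sep`.
#' @param complement_prob probability that a planted pair is drawn jointly as
#'   one of the six complementary combinations (AU/UA/GC/CG/GU/UG).
#' @param mutation_rate per-symbol probability of replacement by a uniform
#'   random nucleotide, applied after column sampling.
#' @param background nucleotide composition for independent draws.
#' @param min_sep minimum `|i - j|` for planted pairs.
#' @return Object of class `family_spec`.
#' @export
family_spec <- function(L, pairs = NULL, complement_prob = 0.9,
                        mutation_rate = 0, background = default_background(),
                        min_sep = 4L) {
  stopifnot(L >= 1, complement_prob >= 0, complement_prob <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            length(background) == 4L, abs(sum(background) - 1) < 1e-8)
  if (is.null(pairs) || nrow(as.matrix(pairs)) == 0L) {
    pairs <- matrix(integer(0), 0L, 2L)
  } else {
    pairs <- as.matrix(pairs)
    pairs <- t(apply(pairs, 1L, sort))
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    if (any(pairs < 1L | pairs > L)) stop("pair indices outside 1..L")
    if (anyDuplicated(as.integer(pairs))) stop("pair columns must be disjoint")
    if (any(pairs[, 2] - pairs[, 1] < min_sep)) {
      stop("pairs closer than the minimum separation")
    }
    if (nrow(pairs) > 1L) {
      for (r in 2:nrow(pairs)) {
        for (q in 1:(r - 1L)) {
          i <- pairs[q, 1]; j <- pairs[q, 2]
          k <- pairs[r, 1]; l <- pairs[r, 2]
          if (k < j && j < l && i < k) stop("pair list must be non-crossing")
        }
      }
    }
  }
  structure(list(L = as.integer(L), pairs = pairs,
                 complement_prob = complement_prob,
                 mutation_rate = mutation_rate,
                 background = background, min_sep = as.integer(min_sep)),
            class = "family_spec")
}

# DP table: f[n+1, k+1] = number of nested k-pair structures on n positions
# with pair span >= min_sep (i.e. j - i >= min_sep)
count_nested_table <- function(L, K, min_sep = 4L) {
  f <- matrix(0, L + 1L, K + 1L)
  f[, 1L] <- 1
  if (K == 0L) return(f)
  for (n in seq_len(L)) {
    if (n < min_sep + 1L) next
    kmax <- min(K, n %/% 2L)
    for (k in seq_len(kmax)) {
      tot <- f[n, k + 1L]  # first position unpaired
      # first position paired with position m (span m-1 >= min_sep)
      for (m in seq(min_sep + 1L, n)) {
        inner <- m - 2L
        outer <- n - m
        for (a in 0:(k - 1L)) {
          tot <- tot + f[inner + 1L, a + 1L] * f[outer + 1L, k - a]
        }
      }
      f[n + 1L, k + 1L] <- tot
    }
  }
  f
}

#' Sample a uniform nested pair structure
#'
#' Draws uniformly among all nested sets of exactly `n_pairs` disjoint column
#' pairs on `1..L` with separation at least `min_sep`, via dynamic-programming
#' counts. Deterministic given `seed`.
#'
#' @param L sequence length.
#' @param n_pairs number of planted pairs; must satisfy
#'   `n_pairs <= floor((L - min_sep + 1) / 2)`.
#' @param seed integer seed.
#' @param ... further arguments passed to [family_spec()] (complement_prob,
#'   mutation_rate, background).
#' @param min_sep minimum pair separation.
#' @return A `family_spec`.
#' @export
sample_structure_spec <- function(L, n_pairs, seed, ..., min_sep = 4L) {
  f <- count_nested_table(L, n_pairs, min_sep)
  if (f[L + 1L, n_pairs + 1L] <= 0) {
    stop("infeasible: no nested structure with ", n_pairs, " pairs at L = ", L)
  }
  with_seed(seed, {
    pairs <- matrix(integer(0), 0L, 2L)
    sample_segment <- function(lo, n, k) {
      while (n > 0L && k > 0L) {
        total <- f[n + 1L, k + 1L]
        u <- stats::runif(1) * total
        acc <- f[n, k + 1L]
        if (u < acc) {  # lo unpaired
          lo <- lo + 1L
          n <- n - 1L
          next
        }
        if (n < min_sep + 1L) stop("internal sampling inconsistency")
        done <- FALSE
        for (m in seq(min_sep + 1L, n)) {
          inner <- m - 2L
          outer <- n - m
          for (a in 0:(k - 1L)) {
            wt <- f[inner + 1L, a + 1L] * f[outer + 1L, k - a]
            if (wt <= 0) next
            acc <- acc + wt
            if (u < acc) {
              pairs <<- rbind(pairs, c(lo, lo + m - 1L))
              sample_segment(lo + 1L, inner, a)
              lo <- lo + m
              n <- outer
              k <- k - a - 1L
              done <- TRUE
              break
            }
          }
          if (done) break
        }
        if (!done) stop("internal sampling inconsistency")
      }
    }
    sample_segment(1L, L, n_pairs)
    family_spec(L, pairs, ..., min_sep = min_sep)
  })
}

complement_pairs_table <- function() {
  matrix(c("A", "U",  "U", "A",  "G", "C",  "C", "G",  "G", "U",  "U", "G"),
         ncol = 2L, byrow = TRUE)
}

#' Sample sequences from a family specification
#'
#' Unpaired columns are drawn independently from the background composition;
#' planted pair columns are drawn jointly complementary (uniform over the six
#' AU/UA/GC/CG/GU/UG combinations) with probability `complement_prob` and
#' independently from the background otherwise. Per-symbol mutation noise is
#' applied last. Deterministic given `seed`.
#'
#' @param spec a `family_spec`.
#' @param n number of sequences.
#' @param seed integer seed.
#' @return Character vector of `n` sequences over A/C/G/U.
#' @export
sample_family <- function(spec, n, seed) {
  stopifnot(inherits(spec, "family_spec"), n >= 1)
  nts <- c("A", "C", "G", "U")
  comp <- complement_pairs_table()
  with_seed(seed, {
    m <- matrix("", n, spec$L)
    paired_cols <- as.integer(spec$pairs)
    unpaired <- setdiff(seq_len(spec$L), paired_cols)
    for (col in unpaired) {
      m[, col] <- sample(nts, n, replace = TRUE, prob = spec$background)
    }
    if (nrow(spec$pairs) > 0L) {
      for (r in seq_len(nrow(spec$pairs))) {
        i <- spec$pairs[r, 1]
        j <- spec$pairs[r, 2]
        is_comp <- stats::runif(n) < spec$complement_prob
        type <- sample.int(6L, n, replace = TRUE)
        m[, i] <- ifelse(is_comp, comp[type, 1],
                         sample(nts, n, replace = TRUE, prob = spec$background))
        m[, j] <- ifelse(is_comp, comp[type, 2],
                         sample(nts, n, replace = TRUE, prob = spec$background))
      }
    }
    if (spec$mutation_rate > 0) {
      hit <- matrix(stats::runif(n * spec$L) < spec$mutation_rate, n, spec$L)
      m[hit] <- sample(nts, sum(hit), replace = TRUE)
    }
    apply(m, 1L, paste0, collapse = "")
  })
}

## ---- deterministic toy 3D structures ----

# idealized helix parameters shared by the builder and the base-pair detector
# (paired C4'-C4' comes out at 10.40 A, paired N-N at 9.42 A, adjacent
# same-strand C4'-C4' near 5.9 A)
helix_params <- function() {
  list(
    twist = 32.7 * pi / 180, rise = 2.81,
    r_c4 = 9.2, r_n = 6.3,
    pair_sep_c4 = 68.8 * pi / 180,   # angular separation of paired C4' atoms
    n_offset = 14 * pi / 180,        # N angular offset (toward the partner)
    bridge_off = 1.2,                # P offset off the backbone midpoint
    nt_width = 6.0, nt_pad = 0.5, helix_pad = 1.0
  )
}

# parse a nested pair list into a tree of loops and maximal helices
ss_tree <- function(L, pairs) {
  partner <- integer(L)
  if (nrow(pairs) > 0L) {
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
  }
  parse_loop <- function(lo, hi) {
    items <- list()
    i <- lo
    while (i <= hi) {
      j <- partner[i]
      if (j == 0L || j < i) {
        items[[length(items) + 1L]] <- list(kind = "nt", idx = i)
        i <- i + 1L
      } else {
        # maximal stacked run starting at (i, j)
        m <- 1L
        while (i + m <= j - m && partner[i + m] == j - m) m <- m + 1L
        items[[length(items) + 1L]] <-
          list(kind = "helix", i = i, j = j, m = m,
               inner = parse_loop(i + m, j - m))
        i <- j + 1L
      }
    }
    items
  }
  parse_loop(1L, L)
}

# solve loop radius so that chord spans close the circle
loop_radius <- function(widths) {
  lo <- max(widths) / 2 + 1e-6
  hi <- max(sum(widths), lo * 2) + 10
  fn <- function(R) sum(2 * asin(pmin(widths / (2 * R), 1))) - 2 * pi
  if (fn(lo) < 0) return(lo)
  stats::uniroot(fn, c(lo, hi), tol = 1e-10)$root
}

#' Deterministic toy 3D structure from a family specification
#'
#' Embeds the nested secondary structure in 3D: maximal helices are rendered
#' as idealized A-form segments (twist 32.7 degrees, rise 2.81 Angstrom),
#' bulges and small internal loops continue coaxially, and larger loops are
#' laid out as circles sized to their content with helices extending
#' radially. P atoms bridge consecutive C4\' atoms as real phosphates do.
#' Planted pairs land inside the geometric base-pair detector\'s distance
#' windows; adjacent backbone atoms stay a few Angstrom apart. No randomness.
#'
#' @param spec a `family_spec`.
#' @return A `coarse_structure` with a deterministic consistent sequence
#'   (G-C at planted pairs, A elsewhere).
#' @export
build_toy_structure <- function(spec) {
  hp <- helix_params()
  L <- spec$L
  c4 <- matrix(NA_real_, L, 3)
  nat <- matrix(NA_real_, L, 3)
  chord_w <- 2 * hp$r_c4 * sin(hp$pair_sep_c4 / 2)   # paired C4'-C4' distance
  z_off <- hp$r_c4 * cos(hp$pair_sep_c4 / 2)         # common transverse offset

  cross3 <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }

  # render a helix whose entry C4' atoms sit at a_pos (5' strand, nt i) and
  # b_pos (3' strand, nt j), extending along unit axis `axis`; returns the
  # exit chord and a cylinder-point closure for coaxial continuation
  render_helix <- function(item, a_pos, b_pos, axis) {
    uh <- (b_pos - a_pos)
    uh <- uh / sqrt(sum(uh^2))
    vh <- axis - sum(axis * uh) * uh
    vh <- vh / sqrt(sum(vh^2))
    wh <- cross3(uh, vh)
    mid <- (a_pos + b_pos) / 2
    center <- mid - z_off * wh
    base1 <- pi / 2 + hp$pair_sep_c4 / 2   # 5' strand C4' at entry
    base2 <- pi / 2 - hp$pair_sep_c4 / 2   # 3' strand C4' at entry
    pt <- function(r, ang, ax) {
      center + ax * vh + r * cos(ang) * uh + r * sin(ang) * wh
    }
    for (k in seq_len(item$m)) {
      tw <- (k - 1L) * hp$twist
      ax <- (k - 1L) * hp$rise
      i <- item$i + k - 1L
      j <- item$j - k + 1L
      c4[i, ] <<- pt(hp$r_c4, base1 + tw, ax)
      nat[i, ] <<- pt(hp$r_n, base1 + tw + hp$n_offset, ax)
      c4[j, ] <<- pt(hp$r_c4, base2 + tw, ax)
      nat[j, ] <<- pt(hp$r_n, base2 + tw - hp$n_offset, ax)
    }
    list(pt = pt, base1 = base1, base2 = base2, m = item$m, axis = vh,
         a = pt(hp$r_c4, base1 + (item$m - 1L) * hp$twist, (item$m - 1L) * hp$rise),
         b = pt(hp$r_c4, base2 + (item$m - 1L) * hp$twist, (item$m - 1L) * hp$rise))
  }

  # coaxial continuation: one child helix plus up to two bulged nucleotides.
  # The child keeps the parent axis with a single-rung twist; the axial gap
  # stretches with the bulge size and bulged nts ride an outward arc.
  place_coaxial <- function(items, ex) {
    hel <- items[[which(vapply(items, function(it) it$kind == "helix", TRUE))]]
    pre <- Filter(function(it) it$kind == "nt" && it$idx < hel$i, items)
    post <- Filter(function(it) it$kind == "nt" && it$idx > hel$j, items)
    tw0 <- (ex$m - 1L) * hp$twist
    ax0 <- (ex$m - 1L) * hp$rise
    u_max <- max(length(pre), length(post))
    axial <- hp$rise * (1 + 0.7 * u_max)
    a_new <- ex$pt(hp$r_c4, ex$base1 + tw0 + hp$twist, ax0 + axial)
    b_new <- ex$pt(hp$r_c4, ex$base2 + tw0 + hp$twist, ax0 + axial)
    # bulged nts interpolate between their flanking backbone positions,
    # bumped outward radially (and fanned out angularly when two deep)
    bulge_arc <- function(idxs, base, sgn) {
      u <- length(idxs)
      if (u == 0L) return(invisible(NULL))
      extra <- (u - 1) * 60 * pi / 180
      for (t in seq_len(u)) {
        fr <- t / (u + 1)
        ang <- base + tw0 + fr * hp$twist + (fr - 0.5) * extra
        c4[idxs[t], ] <<- ex$pt(hp$r_c4 + 4, ang, ax0 + fr * axial)
        nat[idxs[t], ] <<- ex$pt(hp$r_n + 4, ang + sgn * hp$n_offset,
                                 ax0 + fr * axial)
      }
    }
    # chain order: pre runs parent->child on the 5' strand, post runs
    # child->parent on the 3' strand (so its flank fractions reverse)
    bulge_arc(vapply(pre, function(it) it$idx, 1L), ex$base1, 1)
    bulge_arc(rev(vapply(post, function(it) it$idx, 1L)), ex$base2, -1)
    ex2 <- render_helix(hel, a_new, b_new, ex$axis)
    descend(hel$inner, ex2)
  }

  descend <- function(items, ex) {
    if (length(items) == 0L) return(invisible(NULL))
    n_hel <- sum(vapply(items, function(it) it$kind == "helix", TRUE))
    n_nt <- length(items) - n_hel
    if (!is.null(ex) && n_hel == 1L && n_nt <= 2L) {
      place_coaxial(items, ex)
    } else {
      place_loop(items, if (is.null(ex)) NULL else ex$a,
                 if (is.null(ex)) NULL else ex$b,
                 if (is.null(ex)) NULL else ex$axis)
    }
    invisible(NULL)
  }

  # junction clearance between consecutive loop elements: helix chord ends
  # are atoms, so helices need extra room on each side
  side_pad <- function(kind) if (kind == "nt") 0 else 3
  # lay out a loop circle given entry chord endpoints (or NULL for exterior)
  place_loop <- function(items, entry_a, entry_b, outward) {
    kinds <- vapply(items, function(it) it$kind, "")
    widths <- ifelse(kinds == "nt", hp$nt_width, chord_w)
    if (!is.null(entry_a)) {
      w0c <- sqrt(sum((entry_b - entry_a)^2))
      all_k <- c("helix", kinds)
      all_w <- c(w0c, widths)
      ne <- length(all_w)
      # gap between element ii and ii+1 (cyclic): sum of their side pads,
      # with a minimum backbone step of nt_width between atom centers
      gaps <- vapply(seq_len(ne), function(ii) {
        jj <- if (ii == ne) 1L else ii + 1L
        max(side_pad(all_k[ii]) + side_pad(all_k[jj]), 0) +
          if (all_k[ii] == "nt" && all_k[jj] == "nt") 0 else 0
      }, 1)
      total_angle <- function(R) {
        sum(2 * asin(pmin(all_w / (2 * R), 1))) +
          sum(2 * asin(pmin(gaps / (2 * R), 1)))
      }
      lo <- max(c(all_w, gaps)) / 2 + 1e-6
      R <- if (total_angle(lo) < 2 * pi) lo else {
        stats::uniroot(function(R) total_angle(R) - 2 * pi,
                       c(lo, sum(all_w) + sum(gaps) + 10), tol = 1e-10)$root
      }
      u <- (entry_b - entry_a) / w0c
      v <- outward - sum(outward * u) * u
      v <- v / sqrt(sum(v^2))
      mid <- (entry_a + entry_b) / 2
      center <- mid + sqrt(max(R^2 - (w0c / 2)^2, 0)) * v
      nrm <- cross3(u, v)
      # circle parametrized by phi with phi = 0 at the entry-chord center
      # (-v from the loop center); entry_a sits at negative phi; the chain
      # traverses the major arc in the -phi direction toward entry_b
      circle_pt <- function(phi) center + R * (sin(phi) * u - cos(phi) * v)
      spans <- 2 * asin(pmin(all_w / (2 * R), 1))
      gap_sp <- 2 * asin(pmin(gaps / (2 * R), 1))
      # distribute any residual slack evenly across the junction gaps
      resid <- 2 * pi - sum(spans) - sum(gap_sp)
      gap_sp <- gap_sp + resid / ne
      cur <- -spans[1] / 2 - gap_sp[1]
      for (ii in seq_along(items)) {
        it <- items[[ii]]
        cur <- cur - spans[ii + 1L] / 2
        pos <- circle_pt(cur)
        radial <- (pos - center) / R
        if (it$kind == "nt") {
          c4[it$idx, ] <<- pos
          nat[it$idx, ] <<- pos - 2.0 * radial
        } else {
          half_c <- asin(min(chord_w / (2 * R), 1))
          a_end <- circle_pt(cur + half_c)
          b_end <- circle_pt(cur - half_c)
          ex <- render_helix(it, a_end, b_end, radial)
          descend(it$inner, ex)
        }
        cur <- cur - spans[ii + 1L] / 2 - gap_sp[ii + 1L]
      }
    } else {
      # exterior: straight line along +x; xpos tracks the last placed
      # backbone atom, and consecutive atoms step by one backbone spacing
      xpos <- 0
      first <- TRUE
      for (ii in seq_along(items)) {
        it <- items[[ii]]
        if (!first) xpos <- xpos + hp$nt_width
        if (it$kind == "nt") {
          c4[it$idx, ] <<- c(xpos, 0, 0)
          nat[it$idx, ] <<- c(xpos, -2, 0)
        } else {
          a_end <- c(xpos, 0, 0)
          b_end <- c(xpos + chord_w, 0, 0)
          ex <- render_helix(it, a_end, b_end, c(0, 1, 0))
          descend(it$inner, ex)
          xpos <- xpos + chord_w
        }
        first <- FALSE
      }
    }
    invisible(NULL)
  }

  descend(ss_tree(L, spec$pairs), NULL)

  # P atoms bridge consecutive C4' atoms, offset away from the flanking bases
  pcoord <- matrix(NA_real_, L, 3)
  off_dir <- function(mid, idxs) {
    d <- c(0, 0, 0)
    for (i in idxs) {
      w <- nat[i, ] - mid
      nw <- sqrt(sum(w^2))
      if (nw > 1e-6) d <- d + w / nw
    }
    nd <- sqrt(sum(d^2))
    if (nd < 1e-6) return(c(0, 0, 1))
    -d / nd
  }
  if (L == 1L) {
    pcoord[1, ] <- c4[1, ] + c(-2, 0, 1.5)
  } else {
    for (i in 2:L) {
      mid <- (c4[i - 1L, ] + c4[i, ]) / 2
      pcoord[i, ] <- mid + hp$bridge_off * off_dir(mid, c(i - 1L, i))
    }
    mid1 <- c4[1, ] - (c4[2, ] - c4[1, ]) / 2
    pcoord[1, ] <- mid1 + hp$bridge_off * off_dir(mid1, 1L)
  }

  # relaxation pass: nudge bridged P atoms apart where sharp backbone turns
  # compress consecutive P-P spacing below the backbone window
  if (L > 1L) {
    for (pass in 1:25) {
      moved <- FALSE
      for (i in 1:(L - 1L)) {
        d <- pcoord[i + 1L, ] - pcoord[i, ]
        nd <- sqrt(sum(d^2))
        if (nd < 4.2) {
          dir <- if (nd > 1e-6) d / nd else c(0, 0, 1)
          push <- (4.2 - nd) / 2
          pcoord[i, ] <- pcoord[i, ] - push * dir
          pcoord[i + 1L, ] <- pcoord[i + 1L, ] + push * dir
          moved <- TRUE
        }
      }
      if (!moved) break
    }
  }

  coords <- array(0, c(L, 3, 3))
  coords[, 1, ] <- pcoord
  coords[, 2, ] <- c4
  coords[, 3, ] <- nat
  seq_chars <- rep("A", L)
  if (nrow(spec$pairs) > 0L) {
    seq_chars[spec$pairs[, 1]] <- "G"
    seq_chars[spec$pairs[, 2]] <- "C"
  }
  coarse_structure(coords, paste0(seq_chars, collapse = ""))
}

#' Synthetic decoy pool around a reference structure
#'
#' Each decoy applies an independent per-nucleotide rigid perturbation to the
#' reference atoms: a rotation interpolated toward a uniform random rotation
#' (slerp weight `0.05 * sigma`, capped at 0.5) about the nucleotide centroid
#' plus isotropic Gaussian translation noise of scale `sigma`, with `sigma`
#' cycling round-robin through `noise_scales`. Each decoy carries a synthetic
#' distogram concentrating `sharpness` of its mass on the reference's true
#' distance bin (remainder uniform) and a uniform pair-error weight map.
#'
#' @param ref reference `coarse_structure`.
#' @param n number of decoys.
#' @param noise_scales translation noise scales in Angstrom (recycled).
#' @param sharpness fraction of distogram mass on the true bin, in [0, 1].
#' @param seed integer seed.
#' @return A `decoy_pool`.
#' @export
make_decoy_pool <- function(ref, n, noise_scales = c(0.5, 1, 2),
                            sharpness = 0.9, seed = 1L) {
  stopifnot(n >= 1, sharpness >= 0, sharpness <= 1)
  L <- length(ref)
  nb <- distance_binning()$n_bins
  tb <- true_bins(ref)
  mk_channel <- function(bins) {
    m <- matrix((1 - sharpness) / nb, L * L, nb)
    m[cbind(seq_len(L * L), as.integer(bins))] <-
      m[cbind(seq_len(L * L), as.integer(bins))] + sharpness
    m
  }
  dg <- distogram(list(PP = mk_channel(tb[[1]]), CC = mk_channel(tb[[2]]),
                       NN = mk_channel(tb[[3]])), L)
  centers <- t(apply(ref$coords, 1L, colMeans))
  decoys <- with_seed(seed, {
    lapply(seq_len(n), function(d) {
      sigma <- noise_scales[(d - 1L) %% length(noise_scales) + 1L]
      w <- min(0.5, 0.05 * sigma)
      coords <- ref$coords
      for (l in seq_len(L)) {
        rp <- if (w == 0) diag(3) else slerp_rotation(diag(3), draw_random_rotation(), w)
        shift <- stats::rnorm(3, 0, sigma)
        coords[l, , ] <- t(rp %*% (t(ref$coords[l, , ]) - centers[l, ]) +
                             centers[l, ] + shift)
      }
      list(structure = coarse_structure(coords, ref$sequence),
           distogram = dg,
           weights = matrix(1, L, L))
    })
  })
  decoy_pool(decoys)
}
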