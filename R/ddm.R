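# Double description method over exact rationals.
#
# Extreme rays of a pointed cone {Gy = 0, Hy >= 0} are built incrementally:
# start from a basis of ker(G) (held as free "lines"), consume lines by
# pivoting them onto constraints, then enforce the remaining halfspaces one
# at a time, combining adjacent positive/negative ray pairs and pruning
# candidates whose zero-set is a subset of another ray's (the combinatorial
# superset test of the binary null-space variant). Zero-sets are tracked as
# logical bitsets per processed constraint; ray values stay fully rational
# so the output is numeric modes, not just binary patterns.

# 15-bit popcount lookup table (built at load time)
.pc15 <- local({
  pc <- integer(32768)
  for (i in 1:32767) pc[i + 1L] <- pc[bitwShiftR(i, 1L) + 1L] + bitwAnd(i, 1L)
  pc
})

# constraint values of all rays: H'_h . r for each ray row of (Rn, Rd)
.dd_convals <- function(hn, hd, Rn, Rd) {
  k <- nrow(Rn)
  vn <- numeric(k); vd <- rep(1, k)
  for (j in seq_along(hn)) {
    if (hn[j] == 0) next
    p <- .rq_mul0(Rn[, j], Rd[, j], hn[j], hd[j])
    v <- .rq_add0(vn, vd, p$n, p$d)
    vn <- v$n; vd <- v$d
  }
  list(n = vn, d = vd)
}

# integer normalization that also reports the scale factor applied
# (normalized = raw * fn/fd), so cached linear functionals of a ray can be
# rescaled without recomputation
.rq_int_norm2 <- function(n, d) {
  nz <- which(n != 0)
  if (!length(nz)) return(list(n = n, d = rep(1, length(n)), fn = 1, fd = 1))
  l <- 1
  for (dd in unique(d[nz])) {
    g <- .rq_gcd0(l, dd)
    l <- l * (dd / g)
    .rq_guard(l)
  }
  v <- n * (l / d)
  .rq_guard(v)
  g <- 0
  for (vv in v[nz]) g <- .rq_gcd0(g, abs(vv))
  if (g > 1) v <- v / g else g <- 1
  list(n = v, d = rep(1, length(v)), fn = l, fd = g)
}

# Core: extreme rays of {Gy=0, Hy>=0}; returns rq matrix (rays x nv).
.dd_rays <- function(G, H, row_order = NULL, max_rays = 200000L,
                     progress = FALSE) {
  nv <- if (nrow(G$n)) ncol(G$n) else ncol(H$n)
  nh <- nrow(H$n)
  K <- rq_kernel(G)
  q <- ncol(K$n)
  if (q == 0L) return(rq_zeros(0, nv))
  if (nh == 0L) stop("cone is not pointed (no inequality constraints)", call. = FALSE)
  Hp <- rq_matmul(H, K)   # nh x q reduced constraint rows

  pref <- if (is.null(row_order)) seq_len(nh) else as.integer(row_order)
  if (!setequal(pref, seq_len(nh))) stop("row_order must permute constraint rows")

  # lines: q x q identity in reduced coords; rays: none yet
  Ln <- diag(q); Ld <- matrix(1, q, q)
  Rn <- matrix(0, 0, q); Rd <- matrix(1, 0, q)
  Z <- matrix(FALSE, 0, nh)
  processed <- logical(nh)

  # --- line-consumption stage ---------------------------------------------
  while (nrow(Ln) > 0) {
    pivot_h <- 0L; lv <- NULL
    for (h in pref[!processed[pref]]) {
      lv_h <- .dd_convals(Hp$n[h, ], Hp$d[h, ], Ln, Ld)
      if (any(lv_h$n != 0)) { pivot_h <- h; lv <- lv_h; break }
    }
    if (pivot_h == 0L) {
      stop("cone is not pointed; lineality direction: (",
           paste(rq_format(rq_matvec(K, .mkrq(Ln[1, ], Ld[1, ]))), collapse = ", "),
           ")", call. = FALSE)
    }
    h <- pivot_h
    li <- which(lv$n != 0)[1]
    star_n <- Ln[li, ]; star_d <- Ld[li, ]
    w_n <- lv$n[li]; w_d <- lv$d[li]
    if (w_n < 0) { star_n <- -star_n; w_n <- -w_n }
    # remaining lines: l' = l - (v_l / w) * star
    keep <- setdiff(seq_len(nrow(Ln)), li)
    newLn <- matrix(0, 0, q); newLd <- matrix(1, 0, q)
    for (i in keep) {
      if (lv$n[i] == 0) {
        newLn <- rbind(newLn, Ln[i, ]); newLd <- rbind(newLd, Ld[i, ])
      } else {
        f <- .rq_mul0(-lv$n[i], lv$d[i], w_d, w_n)     # -(v_l/w)
        p <- .rq_mul0(star_n, star_d, f$n, f$d)
        v <- .rq_add0(Ln[i, ], Ld[i, ], p$n, p$d)
        nl <- rq_int_normalize(.mkrq(v$n, v$d), sign_first = TRUE)
        newLn <- rbind(newLn, nl$n); newLd <- rbind(newLd, nl$d)
      }
    }
    # adjust rays onto the hyperplane, then add star as a ray
    if (nrow(Rn) > 0) {
      rv <- .dd_convals(Hp$n[h, ], Hp$d[h, ], Rn, Rd)
      for (i in which(rv$n != 0)) {
        f <- .rq_mul0(-rv$n[i], rv$d[i], w_d, w_n)
        p <- .rq_mul0(star_n, star_d, f$n, f$d)
        v <- .rq_add0(Rn[i, ], Rd[i, ], p$n, p$d)
        nr <- rq_int_normalize(.mkrq(v$n, v$d))
        Rn[i, ] <- nr$n; Rd[i, ] <- nr$d
      }
      Z[, h] <- TRUE
    }
    ns <- rq_int_normalize(.mkrq(star_n, star_d))
    Rn <- rbind(Rn, ns$n); Rd <- rbind(Rd, ns$d)
    zrow <- processed
    Z <- rbind(Z, zrow)          # star: zero on all processed, positive at h
    Ln <- newLn; Ld <- newLd
    processed[h] <- TRUE
    if (progress) message(sprintf("line pivot on row %d: %d rays, %d lines",
                                  h, nrow(Rn), nrow(Ln)))
  }

  # --- ray stage -----------------------------------------------------------
  # zero-sets packed into 30-bit integer words; constraint values of every
  # ray cached and updated incrementally (a candidate's value row follows
  # from its parents' cached rows by the same linear combination)
  W <- max(1L, as.integer(ceiling(nh / 30)))
  bit_word <- ((seq_len(nh) - 1L) %/% 30L) + 1L
  bit_mask <- bitwShiftL(1L, (seq_len(nh) - 1L) %% 30L)
  Zb <- matrix(0L, nrow(Z), W)
  for (hh in which(processed)) {
    set <- which(Z[, hh])
    if (length(set)) Zb[set, bit_word[hh]] <- bitwOr(Zb[set, bit_word[hh]],
                                                     bit_mask[hh])
  }
  todo0 <- pref[!processed[pref]]
  nr0 <- nrow(Rn)
  Vn <- matrix(0, nr0, nh); Vd <- matrix(1, nr0, nh)
  for (h in todo0) {
    cv <- .dd_convals(Hp$n[h, ], Hp$d[h, ], Rn, Rd)
    Vn[, h] <- cv$n; Vd[, h] <- cv$d
  }

  repeat {
    todo <- pref[!processed[pref]]
    if (!length(todo)) break
    npos <- colSums(Vn[, todo, drop = FALSE] > 0)
    nneg <- colSums(Vn[, todo, drop = FALSE] < 0)
    h <- todo[which.min(npos * nneg)]
    vn <- Vn[, h]; vd <- Vd[, h]
    pos <- which(vn > 0); neg <- which(vn < 0); zer <- which(vn == 0)

    cand_n <- list(); cand_d <- list(); cand_zb <- list()
    cand_vn <- list(); cand_vd <- list()
    seen <- new.env(hash = TRUE, parent = emptyenv())
    if (length(pos) && length(neg)) {
      for (qi in neg) {
        Zq <- Zb[qi, ]
        # necessary condition for adjacency: the common zero-set must have
        # rank q-2, hence at least q-2 members (vectorized popcount filter)
        cnt <- integer(length(pos))
        for (w in seq_len(W)) {
          cw <- bitwAnd(Zb[pos, w], Zq[w])
          cnt <- cnt + .pc15[bitwAnd(cw, 32767L) + 1L] +
            .pc15[bitwShiftR(cw, 15L) + 1L]
        }
        elig <- pos[cnt >= q - 2L]
        for (pi in elig) {
          Cw <- bitwAnd(Zb[pi, ], Zq)   # common zero-set (packed)
          # adjacency: no third surviving ray's zero-set is a superset
          hits <- TRUE
          for (w in seq_len(W)) {
            hits <- hits & (bitwAnd(Zb[, w], Cw[w]) == Cw[w])
          }
          if (sum(hits) > 2L) next
          key <- paste(Cw, collapse = "_")
          if (!is.null(seen[[key]])) next
          seen[[key]] <- TRUE
          # r' = v_p * q - v_q * p  (conic: v_q < 0)
          a <- .rq_mul0(Rn[qi, ], Rd[qi, ], vn[pi], vd[pi])
          b <- .rq_mul0(Rn[pi, ], Rd[pi, ], -vn[qi], vd[qi])
          s <- .rq_add0(a$n, a$d, b$n, b$d)
          nr <- .rq_int_norm2(s$n, s$d)
          cand_n[[length(cand_n) + 1L]] <- nr$n
          cand_d[[length(cand_d) + 1L]] <- nr$d
          zz <- Cw; w <- bit_word[h]
          zz[w] <- bitwOr(zz[w], bit_mask[h])
          cand_zb[[length(cand_zb) + 1L]] <- zz
          # cached values: val' = (v_p * val_q - v_q * val_p) * fn/fd
          a2 <- .rq_mul0(Vn[qi, ], Vd[qi, ], vn[pi], vd[pi])
          b2 <- .rq_mul0(Vn[pi, ], Vd[pi, ], -vn[qi], vd[qi])
          s2 <- .rq_add0(a2$n, a2$d, b2$n, b2$d)
          s2 <- .rq_mul0(s2$n, s2$d, nr$fn, nr$fd)
          cand_vn[[length(cand_vn) + 1L]] <- s2$n
          cand_vd[[length(cand_vd) + 1L]] <- s2$d
        }
      }
    }
    keep <- c(pos, zer)
    Rn <- rbind(Rn[keep, , drop = FALSE], do.call(rbind, cand_n))
    Rd <- rbind(Rd[keep, , drop = FALSE], do.call(rbind, cand_d))
    Vn <- rbind(Vn[keep, , drop = FALSE], do.call(rbind, cand_vn))
    Vd <- rbind(Vd[keep, , drop = FALSE], do.call(rbind, cand_vd))
    Zbn <- Zb[keep, , drop = FALSE]
    if (length(zer)) {
      at <- match(zer, keep); w <- bit_word[h]
      Zbn[at, w] <- bitwOr(Zbn[at, w], bit_mask[h])
    }
    Zb <- rbind(Zbn, do.call(rbind, cand_zb))
    processed[h] <- TRUE
    if (nrow(Rn) > max_rays) {
      stop("ray-count memory guard exceeded (", nrow(Rn), " > ", max_rays,
           ") at constraint row ", h,
           "; re-run with a larger max_rays", call. = FALSE)
    }
    if (progress) message(sprintf("processed row %d: %d rays", h, nrow(Rn)))
  }

  if (nrow(Rn) == 0L) return(rq_zeros(0, nv))
  out <- rq_matmul(.mkrq(Rn, Rd), rq_t(K))    # back to original coordinates
  for (i in seq_len(nrow(out$n))) {
    v <- rq_int_normalize(rq_row(out, i))
    out$n[i, ] <- v$n; out$d[i, ] <- v$d
  }
  out
}

#' Enumerate extreme rays of a cone by double description
#'
#' Runs the binary null-space double description method on a pointed cone
#' given as `"ConeH"` (`Gy = 0, Hy >= 0`) or `"FluxCone"` (`Nr = 0, r >= 0`).
#' Output rays are gcd-normalized integer vectors in a canonical order, so
#' the result is independent of the constraint processing order.
#'
#' @param x `"ConeH"` or `"FluxCone"`.
#' @param row_order optional permutation of the inequality rows overriding
#'   the default `|Pos|*|Neg|`-minimizing heuristic (used to check
#'   order-independence).
#' @param max_rays guard on the intermediate ray count; exceeding it raises
#'   an error naming the constraint row reached.
#' @param progress emit a message per processed constraint row.
#' @return `"ModeSet"` of rays (kind `"efm"`) over the cone's variables.
#' @export
enumerate_rays_ddm <- function(x, row_order = NULL, max_rays = 200000L,
                               progress = FALSE) {
  if (inherits(x, "FluxCone")) {
    G <- x$N; H <- rq_eye(ncol(x$N$n)); ids <- x$reaction_ids
  } else if (inherits(x, "ConeH")) {
    assert_pointed(x)
    G <- x$G; H <- x$H; ids <- x$var_ids
  } else stop("enumerate_rays_ddm expects ConeH or FluxCone")
  rays <- .dd_rays(G, H, row_order = row_order, max_rays = max_rays,
                   progress = progress)
  mode_set(rays, ids, kind = "efm")
}

#' Enumerate EFMs of a flux cone by double description
#'
#' Convenience wrapper of [enumerate_rays_ddm()] for flux cones: the
#' extreme rays of `{r : N r = 0, r >= 0}` are the network's EFMs (up to
#' two-cycle modes when the cone came from reversible splitting, which
#' [filter_two_cycles()] removes).
#'
#' @inheritParams enumerate_rays_ddm
#' @param cone `"FluxCone"`.
#' @return `"ModeSet"` of EFMs.
#' @export
enumerate_efms_ddm <- function(cone, row_order = NULL, max_rays = 200000L,
                               progress = FALSE) {
  stopifnot(inherits(cone, "FluxCone"))
  enumerate_rays_ddm(cone, row_order = row_order, max_rays = max_rays,
                     progress = progress)
}

# ---- support-test oracle ---------------------------------------------------

# exact rank of an integer matrix by fraction-free (Bareiss) elimination
.bareiss_rank <- function(M) {
  M <- as.matrix(M)
  nr <- nrow(M); nc <- ncol(M)
  if (nr == 0 || nc == 0) return(0L)
  prev <- 1; r <- 0L
  for (j in seq_len(nc)) {
    if (r == nr) break
    sub <- which(M[(r + 1):nr, j] != 0)
    if (!length(sub)) next
    p <- r + sub[1]
    if (p != r + 1L) { tmp <- M[r + 1L, ]; M[r + 1L, ] <- M[p, ]; M[p, ] <- tmp }
    piv <- M[r + 1L, j]
    if (r + 2L <= nr) {
      rows <- (r + 2L):nr
      M[rows, ] <- (M[rows, , drop = FALSE] * piv -
                      outer(M[rows, j], M[r + 1L, ])) / prev
      .rq_guard(M[rows, , drop = FALSE])
    }
    prev <- piv
    r <- r + 1L
  }
  r
}

#' Test whether a reaction set is an EFM support
#'
#' The defining property of an elementary flux mode: the kernel of `N`
#' restricted to the support columns is one-dimensional, and its generator
#' is nonzero on the whole support with a uniform sign (so it can be
#' oriented nonnegatively). This is an independent oracle — it never calls
#' the double description or reverse search code paths.
#'
#' @param N `"FluxCone"`, or `"rq"`/integer stoichiometric matrix.
#' @param support integer column indices (or reaction ids for a
#'   `"FluxCone"`).
#' @return `TRUE`/`FALSE`.
#' @export
efm_support_test <- function(N, support) {
  if (inherits(N, "FluxCone")) {
    if (is.character(support)) support <- match(support, N$reaction_ids)
    N <- N$N
  }
  N <- rq(N)
  support <- as.integer(support)
  if (length(support) == 0 || anyNA(support)) return(FALSE)
  sub <- rq_index(N, seq_len(nrow(N$n)), support)
  K <- rq_kernel(sub)
  if (ncol(K$n) != 1L) return(FALSE)
  g <- rq_col(K, 1)
  s <- rq_sign(g)
  all(s != 0) && (all(s > 0) || all(s < 0))
}

#' Brute-force EFM enumeration by minimal-support search
#'
#' Enumerates candidate supports in increasing size (capped at
#' `rank(N) + 1`, the largest possible EFM support), prunes proper supersets
#' of already-found EFM supports, and keeps those passing
#' [efm_support_test()], returning the gcd-normalized generator of each.
#' Exponential, intended as the independent test oracle for small cones.
#'
#' @param cone `"FluxCone"` with at most 14 reactions.
#' @return `"ModeSet"` of EFMs.
#' @export
brute_force_efms <- function(cone) {
  stopifnot(inherits(cone, "FluxCone"))
  N <- cone$N
  n <- ncol(N$n)
  if (n > 14) stop("brute-force oracle limited to 14 reactions")
  integerized <- all(N$d == 1)
  Nint <- if (integerized) N$n else NULL
  rk <- if (integerized) .bareiss_rank(Nint) else rq_rank(N)
  maxsz <- min(n, rk + 1L)
  found_masks <- list()
  vals <- list()
  for (sz in seq_len(maxsz)) {
    combs <- utils::combn(n, sz)
    for (ci in seq_len(ncol(combs))) {
      supp <- combs[, ci]
      mask <- logical(n); mask[supp] <- TRUE
      is_super <- any(vapply(found_masks, function(fm) all(mask[fm]), logical(1)))
      if (is_super) next
      # fast exact pre-check on integer data: kernel dim must be 1
      if (integerized) {
        if (sz - .bareiss_rank(Nint[, supp, drop = FALSE]) != 1L) next
      }
      if (!efm_support_test(N, supp)) next
      sub <- rq_index(N, seq_len(nrow(N$n)), supp)
      g <- rq_col(rq_kernel(sub), 1)
      if (any(rq_sign(g) < 0)) g <- rq_neg(g)
      full <- rq_zeros(n)
      full <- rq_set(full, supp, NULL, g)
      vals[[length(vals) + 1L]] <- rq_int_normalize(full)
      found_masks[[length(found_masks) + 1L]] <- supp
    }
  }
  mode_set(vals, cone$reaction_ids, kind = "efm")
}
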