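# Lexicographic reverse search vertex/ray enumeration.
#
# The engine works on the reduced system {t : A t >= b} (linearities are
# eliminated by exact substitution first). The right-hand side is perturbed
# symbolically, b_i -> b_i - eta_i with eta = Lambda (eps^1, ..., eps^k)',
# where the perturbation matrix Lambda is aligned with the initial basis
# B0: basic rows get unit vectors, nonbasic rows get their expansion over
# the basis plus a fresh higher-order epsilon. This choice makes B0
# lexicographically feasible by construction and the perturbed polyhedron
# provably simple, so every basis is a distinct perturbed vertex and the
# simplex path is unique. The objective is the negated sum of the initial
# basis rows (so B0 is the unique optimum) with a symbolic delta
# perturbation breaking dual ties. Reverse search then walks the simplex
# tree depth-first: children of a basis B are the adjacent bases C = B -
# e + j* along objective-decreasing edges whose deterministic improving
# pivot leads back to B; unbounded decreasing edges emit extreme rays.
#
# Degenerate vertices of the original polyhedron appear as clusters of
# bases; the engine reports the cluster size per vertex (the emission
# multiplicity) and returns each distinct vertex/ray once.

# sign of lex vector [a0, col1, col2, ...] given generator functions
.rs_lexsign <- function(n0, d0, coln, cold) {
  if (n0 != 0) return(sign(n0))
  for (ii in seq_along(coln)) if (coln[ii] != 0) return(sign(coln[ii]))
  0L
}

# scalar rational compare: a/b vs c/d (b, d > 0)
.rs_qcmp <- function(an, ad, bn, bd) {
  l <- an * bd; r <- bn * ad
  .rq_guard(l, r)
  sign(l - r)
}

# node data at a basis: T = inverse of A[B, ], x = T b_B, slacks, reduced
# costs, and the lex sign of each basis row's (delta-perturbed) cost
.rs_node <- function(B, Tm, Ared, bred, cobj) {
  d <- length(B)
  x <- rq_matvec(Tm, rq_index(bred, B))
  slack <- rq_sub(rq_matvec(Ared, x), bred)
  lam <- rq_matvec(rq_t(Tm), cobj)
  lsign <- integer(d)
  for (r in seq_len(d)) {
    lsign[r] <- .rs_lexsign(lam$n[r], lam$d[r], Tm$n[, r], Tm$d[, r])
  }
  list(B = B, T = Tm, x = x, slack = slack, lam = lam, lsign = lsign)
}

# lexicographic minimum-ratio row along direction u from basis B.
# cands: global row indices with a_i u < 0. Returns single row index.
.rs_min_ratio <- function(cands, vvals, node, Ared, Lam, kall) {
  B <- node$B
  slack <- node$slack
  Tm <- node$T
  d <- length(B)
  aiT <- list()   # cached a_i T per candidate
  get_aiT <- function(i) {
    key <- as.character(i)
    if (is.null(aiT[[key]])) {
      aiT[[key]] <<- rq_matvec(rq_t(Tm), rq_row(Ared, i))
    }
    aiT[[key]]
  }
  # component c of the lex ratio of row i (c = 0 is the numeric part):
  # base_c / (-v_i), base_0 = slack_i, base_c = Lam[i,c] - (a_i T) . Lam[B,c]
  comp <- function(i, ci, vi_n, vi_d) {
    if (ci == 0L) {
      bn <- slack$n[i]; bd <- slack$d[i]
    } else {
      at <- get_aiT(i)
      dotv <- .rq_qdot(at$n, at$d, Lam$n[B, ci], Lam$d[B, ci])
      s <- .rq_add0(Lam$n[i, ci], Lam$d[i, ci], -dotv[1], dotv[2])
      bn <- s$n; bd <- s$d
    }
    r <- .rq_mul0(bn, bd, vi_d, -vi_n)   # divide by (-v_i) > 0
    c(r$n, r$d)
  }
  active <- cands
  ci <- 0L
  while (length(active) > 1L && ci <= kall) {
    vals <- lapply(active, function(i) {
      j <- match(i, cands)
      comp(i, ci, vvals$n[j], vvals$d[j])
    })
    best <- 1L
    for (t in seq_along(vals)[-1]) {
      if (.rs_qcmp(vals[[t]][1], vals[[t]][2],
                   vals[[best]][1], vals[[best]][2]) < 0) best <- t
    }
    keep <- vapply(seq_along(vals), function(t) {
      .rs_qcmp(vals[[t]][1], vals[[t]][2],
               vals[[best]][1], vals[[best]][2]) == 0
    }, logical(1))
    active <- active[keep]
    ci <- ci + 1L
  }
  active[1]
}

# exact rational dot product on raw vectors
.rq_qdot <- function(an, ad, bn, bd) {
  sn <- 0; sd <- 1
  for (ii in seq_along(an)) {
    if (an[ii] == 0 || bn[ii] == 0) next
    p <- .rq_mul0(an[ii], ad[ii], bn[ii], bd[ii])
    s <- .rq_add0(sn, sd, p$n, p$d)
    sn <- s$n; sd <- s$d
  }
  c(sn, sd)
}

# reverse search over the reduced full-rank system A t >= b
.rs_core <- function(Ared, bred, max_nodes = 1e6L, progress = FALSE) {
  k <- nrow(Ared$n); d <- ncol(Ared$n)

  # ---- initial feasible point --------------------------------------------
  lp <- rq_lp(rq_zeros(d), A_ge = Ared, b_ge = bred, nonneg = FALSE)
  if (lp$status == "infeasible") return(list(status = "infeasible"))
  x <- lp$x

  # ---- crawl to a vertex --------------------------------------------------
  repeat {
    slack <- rq_sub(rq_matvec(Ared, x), bred)
    tight <- which(slack$n == 0)
    At <- rq_index(Ared, tight, seq_len(d))
    r <- if (length(tight)) rq_rank(At) else 0L
    if (r == d) break
    K <- if (length(tight)) rq_kernel(At) else rq_eye(d)
    u <- rq_col(K, 1)
    v <- rq_matvec(Ared, u)
    if (all(v$n == 0)) stop("system is not pointed", call. = FALSE)
    if (!any(v$n < 0)) { u <- rq_neg(u); v <- rq_neg(v) }
    # largest step keeping feasibility: min over v_i < 0 of slack_i / (-v_i)
    block <- which(v$n < 0)
    bn <- NULL
    for (i in block) {
      ratio <- .rq_mul0(slack$n[i], slack$d[i], v$d[i], -v$n[i])
      if (is.null(bn) || .rs_qcmp(ratio$n, ratio$d, bn[1], bn[2]) < 0) {
        bn <- c(ratio$n, ratio$d)
      }
    }
    x <- rq_add(x, rq_mul(u, .mkrq(bn[1], bn[2])))
  }

  slack <- rq_sub(rq_matvec(Ared, x), bred)
  tight <- which(slack$n == 0)
  # greedy lexicographically-minimal independent subset of the tight rows
  B0 <- integer(0)
  for (i in tight) {
    cand <- c(B0, i)
    if (rq_rank(rq_index(Ared, cand, seq_len(d))) == length(cand)) B0 <- cand
    if (length(B0) == d) break
  }
  if (length(B0) < d) stop("failed to assemble a full basis at the initial vertex")
  T0 <- rq_inv_mat(rq_index(Ared, B0, seq_len(d)))

  # ---- perturbation matrix Lambda (k x k) --------------------------------
  Ln <- matrix(0, k, k); Ld <- matrix(1, k, k)
  for (r in seq_along(B0)) Ln[B0[r], r] <- 1
  nonb <- setdiff(seq_len(k), B0)
  for (t in seq_along(nonb)) {
    i <- nonb[t]
    at <- rq_matvec(rq_t(T0), rq_row(Ared, i))   # expansion of a_i over basis
    Ln[i, seq_len(d)] <- at$n; Ld[i, seq_len(d)] <- at$d
    Ln[i, d + t] <- 1
  }
  Lam <- .mkrq(Ln, Ld)

  # objective: negated sum of initial basis rows -> B0 is the unique root
  cobj <- rq_neg(rq_matvec(rq_t(rq_index(Ared, B0, seq_len(d))),
                           rq(rep(1, d))))

  # ---- emissions ----------------------------------------------------------
  vkeys <- character(0); vcount <- integer(0); vvecs <- list()
  rkeys <- character(0); rcount <- integer(0); rvecs <- list()
  nodes <- 0L

  emit_vertex <- function(xv) {
    key <- paste(rq_format(xv), collapse = ",")
    j <- match(key, vkeys)
    if (is.na(j)) {
      vkeys[[length(vkeys) + 1L]] <<- key
      vcount[[length(vcount) + 1L]] <<- 1L
      vvecs[[length(vvecs) + 1L]] <<- xv
    } else vcount[[j]] <<- vcount[[j]] + 1L
  }
  emit_ray <- function(u) {
    u <- rq_int_normalize(u)
    key <- paste(rq_format(u), collapse = ",")
    j <- match(key, rkeys)
    if (is.na(j)) {
      rkeys[[length(rkeys) + 1L]] <<- key
      rcount[[length(rcount) + 1L]] <<- 1L
      rvecs[[length(rvecs) + 1L]] <<- u
    } else rcount[[j]] <<- rcount[[j]] + 1L
  }

  # ---- depth-first reverse traversal -------------------------------------
  root <- .rs_node(B0, T0, Ared, bred, cobj)
  emit_vertex(root$x)
  nodes <- 1L
  stack <- list(list(node = root, edges = root$B[root$lsign < 0], ei = 1L))

  while (length(stack)) {
    fr <- stack[[length(stack)]]
    if (fr$ei > length(fr$edges)) { stack[[length(stack)]] <- NULL; next }
    e <- fr$edges[fr$ei]
    stack[[length(stack)]]$ei <- fr$ei + 1L
    node <- fr$node
    B <- node$B
    pe <- match(e, B)
    u <- rq_col(node$T, pe)
    notB <- setdiff(seq_len(k), B)
    v_all <- rq_matvec(rq_index(Ared, notB, seq_len(ncol(Ared$n))), u)
    block <- notB[v_all$n < 0]
    if (!length(block)) {
      emit_ray(u)   # unbounded objective-decreasing edge: extreme ray
      next
    }
    vv <- rq_index(v_all, match(block, notB))
    jstar <- .rs_min_ratio(block, vv, node, Ared, Lam, k)
    C <- sort(c(setdiff(B, e), jstar))
    TC <- rq_inv_mat(rq_index(Ared, C, seq_len(d)))
    if (is.null(TC)) next
    child <- .rs_node(C, TC, Ared, bred, cobj)
    # parent test: the first positive-cost basis row at C must be jstar
    first_pos <- 0L
    for (r in seq_len(d)) {
      if (child$lsign[r] > 0) { first_pos <- C[r]; break }
    }
    if (first_pos != jstar) next
    nodes <- nodes + 1L
    if (nodes > max_nodes) {
      stop("reverse search node guard exceeded (", max_nodes, " bases)",
           call. = FALSE)
    }
    emit_vertex(child$x)
    if (progress && nodes %% 500L == 0L) {
      message(sprintf("reverse search: %d bases, %d vertices, %d rays",
                      nodes, length(vkeys), length(rkeys)))
    }
    stack[[length(stack) + 1L]] <-
      list(node = child, edges = child$B[child$lsign < 0], ei = 1L)
  }

  list(status = "ok",
       vertices = vvecs, vertex_mult = vcount,
       rays = rvecs, ray_mult = rcount,
       bases_visited = nodes)
}

#' Enumerate vertices and extreme rays by lexicographic reverse search
#'
#' Eliminates linearity rows by exact substitution, checks pointedness
#' (rejecting non-pointed input with a lineality witness), finds an initial
#' vertex (exact phase-1 LP plus a crawl to a basic solution), and walks
#' the reverse-search tree of the symbolically perturbed system. Under
#' degeneracy a vertex corresponds to several bases; the engine visits all
#' of them (the emission multiplicity, reported per vertex) and returns
#' each distinct vertex and ray once.
#'
#' @param rep `"GeneralHRep"`, `"ConeH"`, `"PolyhedronH"` or `"FluxCone"`.
#' @param max_nodes guard on the number of visited bases.
#' @param progress emit progress messages.
#' @return list with `status` (`"ok"`/`"infeasible"`), `vertices` (ModeSet,
#'   kind `"efv"`), `rays` (ModeSet, kind `"efm"`), and `emissions` (per
#'   vertex/ray multiplicities plus `bases_visited` and
#'   `mean_vertex_multiplicity`).
#' @export
enumerate_vertices_rs <- function(rep, max_nodes = 1e6L, progress = FALSE) {
  h <- .as_hview(rep)
  A <- h$A; b <- h$b; lin <- h$linearity
  l <- ncol(A$n)
  ids <- h$ids

  # ---- eliminate linearities ---------------------------------------------
  if (length(lin)) {
    AL <- rq_index(A, lin, seq_len(l)); bL <- rq_index(b, lin)
    aug <- rq_cbind(AL, rq_as_matrix(bL, nrow(AL$n), 1))
    rr <- rq_rref(aug)
    if (any(rr$pivots > l)) {
      return(list(status = "infeasible", vertices = mode_set(list(), ids, "efv"),
                  rays = mode_set(list(), ids, "efm"), emissions = NULL))
    }
    x0 <- rq_zeros(l)
    for (r in seq_along(rr$pivots)) {
      x0 <- rq_set(x0, rr$pivots[r], NULL, rq_elt(rr$R, r, l + 1L))
    }
    K <- rq_kernel(AL)
  } else {
    x0 <- rq_zeros(l)
    K <- rq_eye(l)
  }
  d <- ncol(K$n)
  ineq <- setdiff(seq_len(nrow(A$n)), lin)
  AI <- rq_index(A, ineq, seq_len(l)); bI <- rq_index(b, ineq)
  Ared <- rq_matmul(AI, K)
  bred <- rq_sub(bI, rq_matvec(AI, x0))

  # drop rows reduced to 0 >= b'
  zero_rows <- which(rowSums(Ared$n != 0) == 0)
  if (length(zero_rows)) {
    if (any(bred$n[zero_rows] > 0)) {
      return(list(status = "infeasible", vertices = mode_set(list(), ids, "efv"),
                  rays = mode_set(list(), ids, "efm"), emissions = NULL))
    }
    keep <- setdiff(seq_len(nrow(Ared$n)), zero_rows)
    Ared <- rq_index(Ared, keep, seq_len(d)); bred <- rq_index(bred, keep)
  }

  if (d == 0L) {
    # linearities pin a single point
    return(list(status = "ok",
                vertices = mode_set(list(x0), ids, "efv"),
                rays = mode_set(list(), ids, "efm"),
                emissions = list(vertex_multiplicity = 1L,
                                 ray_multiplicity = integer(0),
                                 bases_visited = 1L,
                                 mean_vertex_multiplicity = 1)))
  }

  if (rq_rank(Ared) < d) {
    w <- rq_col(rq_kernel(Ared), 1)
    stop("input is not pointed; lineality direction: (",
         paste(rq_format(rq_int_normalize(rq_matvec(K, w))), collapse = ", "),
         ")", call. = FALSE)
  }

  res <- .rs_core(Ared, bred, max_nodes = max_nodes, progress = progress)
  if (res$status == "infeasible") {
    return(list(status = "infeasible", vertices = mode_set(list(), ids, "efv"),
                rays = mode_set(list(), ids, "efm"), emissions = NULL))
  }

  verts <- lapply(res$vertices, function(t) rq_add(x0, rq_matvec(K, t)))
  rays <- lapply(res$rays, function(u) rq_int_normalize(rq_matvec(K, u)))
  vm <- res$vertex_mult
  list(status = "ok",
       vertices = mode_set(verts, ids, "efv"),
       rays = mode_set(rays, ids, "efm"),
       emissions = list(vertex_multiplicity = vm,
                        ray_multiplicity = res$ray_mult,
                        bases_visited = res$bases_visited,
                        mean_vertex_multiplicity =
                          if (length(vm)) mean(vm) else NA_real_))
}

# ---- brute-force oracle ----------------------------------------------------

#' Brute-force vertex/ray enumeration (test oracle)
#'
#' Enumerates vertices as feasible basic solutions over all row subsets of
#' size `d` and extreme rays as feasible one-dimensional null directions of
#' rank-`d-1` subsets, after the same exact linearity elimination the
#' reverse-search engine uses. Exponential; guarded to small instances.
#' Fully independent of the reverse-search traversal.
#'
#' @param rep a representation accepted by [enumerate_vertices_rs()].
#' @param max_subsets guard on `choose(rows, d)`.
#' @return list with `vertices` and `rays` ModeSets.
#' @export
brute_force_enumerate <- function(rep, max_subsets = 200000) {
  h <- .as_hview(rep)
  A <- h$A; b <- h$b; lin <- h$linearity; l <- ncol(A$n); ids <- h$ids
  if (length(lin)) {
    AL <- rq_index(A, lin, seq_len(l)); bL <- rq_index(b, lin)
    aug <- rq_cbind(AL, rq_as_matrix(bL, nrow(AL$n), 1))
    rr <- rq_rref(aug)
    if (any(rr$pivots > l)) {
      return(list(vertices = mode_set(list(), ids, "efv"),
                  rays = mode_set(list(), ids, "efm")))
    }
    x0 <- rq_zeros(l)
    for (r in seq_along(rr$pivots)) {
      x0 <- rq_set(x0, rr$pivots[r], NULL, rq_elt(rr$R, r, l + 1L))
    }
    K <- rq_kernel(AL)
  } else { x0 <- rq_zeros(l); K <- rq_eye(l) }
  d <- ncol(K$n)
  ineq <- setdiff(seq_len(nrow(A$n)), lin)
  Ared <- rq_matmul(rq_index(A, ineq, seq_len(l)), K)
  bred <- rq_sub(rq_index(b, ineq), rq_matvec(rq_index(A, ineq, seq_len(l)), x0))
  k <- nrow(Ared$n)
  if (d > 0 && choose(k, d) > max_subsets) {
    stop("instance above brute-force size guard")
  }
  feas <- function(t) {
    s <- rq_sub(rq_matvec(Ared, t), bred)
    all(s$n >= 0)
  }
  verts <- list(); seen <- character(0)
  if (d == 0L) {
    return(list(vertices = mode_set(list(x0), ids, "efv"),
                rays = mode_set(list(), ids, "efm")))
  }
  for (S in utils::combn(k, d, simplify = FALSE)) {
    As <- rq_index(Ared, S, seq_len(d))
    t <- rq_solve(As, rq_index(bred, S))
    if (is.null(t)) next
    if (!feas(t)) next
    xv <- rq_add(x0, rq_matvec(K, t))
    key <- paste(rq_format(xv), collapse = ",")
    if (!(key %in% seen)) { seen <- c(seen, key); verts[[length(verts) + 1L]] <- xv }
  }
  rays <- list(); rseen <- character(0)
  feasible_any <- length(verts) > 0 || {
    lp <- rq_lp(rq_zeros(d), A_ge = Ared, b_ge = bred, nonneg = FALSE)
    lp$status == "optimal"
  }
  if (feasible_any && d >= 1) {
    subs <- if (d == 1L) list(integer(0)) else utils::combn(k, d - 1L, simplify = FALSE)
    for (S in subs) {
      As <- if (length(S)) rq_index(Ared, S, seq_len(d)) else rq_zeros(0, d)
      Kd <- rq_kernel(As)
      if (ncol(Kd$n) != 1L) next
      u <- rq_col(Kd, 1)
      vu <- rq_matvec(Ared, u)
      dir <- if (all(vu$n >= 0)) u else if (all(vu$n <= 0)) rq_neg(u) else NULL
      if (is.null(dir)) next
      ru <- rq_int_normalize(rq_matvec(K, dir))
      if (all(ru$n == 0)) next
      key <- paste(rq_format(ru), collapse = ",")
      if (!(key %in% rseen)) { rseen <- c(rseen, key); rays[[length(rays) + 1L]] <- ru }
    }
  }
  list(vertices = mode_set(verts, ids, "efv"),
       rays = mode_set(rays, ids, "efm"))
}
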