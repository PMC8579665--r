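# Exact rational linear programming.
#
# A dense tableau simplex with Bland's anti-cycling rule, run entirely in
# exact rational arithmetic, so feasibility / boundedness / optimality
# decisions carry no floating-point tolerance at all. Problem sizes in this
# package (consistency checks, redundancy tests, reverse-search phase 1) are
# tens of rows, where the dense exact tableau is entirely adequate.

.spx_pivot <- function(Tn, Td, r, j) {
  piv_n <- Tn[r, j]; piv_d <- Td[r, j]
  v <- .rq_mul0(Tn[r, ], Td[r, ], sign(piv_n) * piv_d, abs(piv_n))
  Tn[r, ] <- v$n; Td[r, ] <- v$d
  rows <- which(Tn[, j] != 0)
  rows <- rows[rows != r]
  for (i in rows) {
    f_n <- Tn[i, j]; f_d <- Td[i, j]
    p <- .rq_mul0(Tn[r, ], Td[r, ], -f_n, f_d)
    v2 <- .rq_add0(Tn[i, ], Td[i, ], p$n, p$d)
    Tn[i, ] <- v2$n; Td[i, ] <- v2$d
  }
  list(Tn = Tn, Td = Td)
}

# eliminate basic columns from an objective row
.spx_reduce_obj <- function(zn, zd, Tn, Td, basis) {
  for (i in seq_along(basis)) {
    b <- basis[i]
    if (zn[b] != 0) {
      p <- .rq_mul0(Tn[i, ], Td[i, ], -zn[b], zd[b])
      v <- .rq_add0(zn, zd, p$n, p$d)
      zn <- v$n; zd <- v$d
    }
  }
  list(n = zn, d = zd)
}

# Bland simplex loop (maximize). state: Tn, Td, basis, zn, zd.
# cols: candidate entering columns; rhs: rhs column index.
.spx_run <- function(Tn, Td, basis, zn, zd, cols, rhs) {
  repeat {
    enter <- 0L
    for (j in cols) if (zn[j] > 0 && !(j %in% basis)) { enter <- j; break }
    if (enter == 0L) {
      return(list(status = "optimal", Tn = Tn, Td = Td, basis = basis,
                  zn = zn, zd = zd))
    }
    cand <- which(Tn[, enter] > 0)
    if (!length(cand)) {
      return(list(status = "unbounded", Tn = Tn, Td = Td, basis = basis,
                  zn = zn, zd = zd, enter = enter))
    }
    best <- 0L; bn <- 0; bd <- 1
    for (i in cand) {
      rn <- Tn[i, rhs] * Td[i, enter]
      rd <- Td[i, rhs] * Tn[i, enter]
      .rq_guard(rn, rd)
      if (best == 0L) { best <- i; bn <- rn; bd <- rd; next }
      l <- rn * bd; r <- bn * rd
      .rq_guard(l, r)
      cmpv <- sign(l - r)
      if (cmpv < 0 || (cmpv == 0 && basis[i] < basis[best])) {
        best <- i; bn <- rn; bd <- rd
      }
    }
    pv <- .spx_pivot(Tn, Td, best, enter)
    Tn <- pv$Tn; Td <- pv$Td
    if (zn[enter] != 0) {
      p <- .rq_mul0(Tn[best, ], Td[best, ], -zn[enter], zd[enter])
      v <- .rq_add0(zn, zd, p$n, p$d)
      zn <- v$n; zd <- v$d
    }
    basis[best] <- enter
  }
}

# Core solver: max c'x  s.t.  M x <= d, x >= 0.
# Returns list(status = "optimal"|"unbounded"|"infeasible", value, x).
.simplex_std <- function(cvec, M, d) {
  cvec <- rq(cvec); M <- rq(M); d <- rq(d)
  m <- nrow(M$n); n <- ncol(M$n)
  stopifnot(length(d$n) == m, length(cvec$n) == n)

  if (m == 0L) {
    if (any(cvec$n > 0)) return(list(status = "unbounded"))
    return(list(status = "optimal", value = rq(0), x = rq_zeros(n)))
  }

  Tn <- cbind(M$n, diag(m), as.vector(d$n))
  Td <- cbind(M$d, matrix(1, m, m), as.vector(d$d))
  basis <- n + seq_len(m)
  rhs <- n + m + 1L

  if (any(Tn[, rhs] < 0)) {
    # phase 1: artificial variable x0 with column -1, maximize -x0
    x0 <- n + m + 1L
    Tn1 <- cbind(Tn[, seq_len(n + m), drop = FALSE], -1, Tn[, rhs])
    Td1 <- cbind(Td[, seq_len(n + m), drop = FALSE], 1, Td[, rhs])
    rhs1 <- n + m + 2L
    zn <- numeric(rhs1); zd <- rep(1, rhs1); zn[x0] <- -1
    # enter x0 at the most negative rhs row
    neg <- which(Tn1[, rhs1] < 0)
    worst <- neg[1]
    for (i in neg[-1]) {
      l <- Tn1[i, rhs1] * Td1[worst, rhs1]; r <- Tn1[worst, rhs1] * Td1[i, rhs1]
      .rq_guard(l, r)
      if (l < r) worst <- i
    }
    z <- .spx_reduce_obj(zn, zd, Tn1, Td1, basis)  # no-op (slack basis)
    pv <- .spx_pivot(Tn1, Td1, worst, x0)
    Tn1 <- pv$Tn; Td1 <- pv$Td
    p <- .rq_mul0(Tn1[worst, ], Td1[worst, ], -z$n[x0], z$d[x0])
    v <- .rq_add0(z$n, z$d, p$n, p$d)
    zn <- v$n; zd <- v$d
    basis[worst] <- x0
    res <- .spx_run(Tn1, Td1, basis, zn, zd, seq_len(n + m + 1L), rhs1)
    # optimal value of phase 1 = -zn[rhs]/zd[rhs]; feasible iff it is 0
    if (res$zn[rhs1] != 0) return(list(status = "infeasible"))
    Tn1 <- res$Tn; Td1 <- res$Td; basis <- res$basis
    ir <- which(basis == x0)
    if (length(ir)) {
      # x0 basic at level 0: pivot it out on any nonzero non-artificial column
      j <- which(Tn1[ir, seq_len(n + m)] != 0)[1]
      if (is.na(j)) {
        # row is entirely zero: drop it
        keep <- setdiff(seq_len(nrow(Tn1)), ir)
        Tn1 <- Tn1[keep, , drop = FALSE]; Td1 <- Td1[keep, , drop = FALSE]
        basis <- basis[keep]
      } else {
        pv <- .spx_pivot(Tn1, Td1, ir, j)
        Tn1 <- pv$Tn; Td1 <- pv$Td
        basis[ir] <- j
      }
    }
    keep_cols <- c(seq_len(n + m), rhs1)
    Tn <- Tn1[, keep_cols, drop = FALSE]
    Td <- Td1[, keep_cols, drop = FALSE]
    rhs <- n + m + 1L
  }

  width <- ncol(Tn)
  zn <- c(as.vector(cvec$n), numeric(width - n - 1L), 0)
  zd <- c(as.vector(cvec$d), rep(1, width - n - 1L), 1)
  z <- .spx_reduce_obj(zn, zd, Tn, Td, basis)
  res <- .spx_run(Tn, Td, basis, z$n, z$d, seq_len(width - 1L), width)
  if (res$status == "unbounded") return(list(status = "unbounded"))
  x_n <- numeric(n); x_d <- rep(1, n)
  for (i in seq_along(res$basis)) {
    b <- res$basis[i]
    if (b <= n) { x_n[b] <- res$Tn[i, width]; x_d[b] <- res$Td[i, width] }
  }
  list(status = "optimal",
       value = .mkrq(-res$zn[width], res$zd[width]),
       x = rq(x_n, x_d))
}

#' Solve a small linear program in exact rational arithmetic
#'
#' General-form wrapper around the package's exact Bland-rule simplex:
#' optimize `obj' x` subject to `A_ge x >= b_ge`, `A_eq x = b_eq`, with
#' per-variable nonnegativity flags (free variables are split internally).
#' All data and results are exact rationals; there is no tolerance.
#'
#' @param obj objective coefficient vector (`"rq"` or integer-valued).
#' @param A_ge,b_ge inequality block (may be `NULL`).
#' @param A_eq,b_eq equality block (may be `NULL`).
#' @param nonneg logical per variable (default all `TRUE`).
#' @param maximize direction; `FALSE` minimizes.
#' @return list with `status` (`"optimal"`, `"unbounded"`, `"infeasible"`),
#'   and for optima `value` and `x` (both `"rq"`).
#' @export
rq_lp <- function(obj, A_ge = NULL, b_ge = NULL, A_eq = NULL, b_eq = NULL,
                  nonneg = TRUE, maximize = TRUE) {
  obj <- rq(obj)
  nv <- length(obj$n)
  if (length(nonneg) == 1L) nonneg <- rep(nonneg, nv)
  stopifnot(length(nonneg) == nv)

  rows_n <- NULL; rows_d <- NULL; rhs_n <- numeric(0); rhs_d <- numeric(0)
  add_le <- function(an, ad, bn, bd) {
    rows_n <<- rbind(rows_n, an); rows_d <<- rbind(rows_d, ad)
    rhs_n <<- c(rhs_n, bn); rhs_d <<- c(rhs_d, bd)
  }
  if (!is.null(A_ge)) {
    A_ge <- rq(A_ge); b_ge <- rq(b_ge)
    for (i in seq_len(nrow(A_ge$n))) {
      add_le(-A_ge$n[i, ], A_ge$d[i, ], -as.vector(b_ge$n)[i], as.vector(b_ge$d)[i])
    }
  }
  if (!is.null(A_eq)) {
    A_eq <- rq(A_eq); b_eq <- rq(b_eq)
    for (i in seq_len(nrow(A_eq$n))) {
      add_le(A_eq$n[i, ], A_eq$d[i, ], as.vector(b_eq$n)[i], as.vector(b_eq$d)[i])
      add_le(-A_eq$n[i, ], A_eq$d[i, ], -as.vector(b_eq$n)[i], as.vector(b_eq$d)[i])
    }
  }
  if (is.null(rows_n)) { rows_n <- matrix(0, 0, nv); rows_d <- matrix(1, 0, nv) }

  # split free variables: x_j = u_j - v_j
  free <- which(!nonneg)
  if (length(free)) {
    rows_n <- cbind(rows_n, -rows_n[, free, drop = FALSE])
    rows_d <- cbind(rows_d, rows_d[, free, drop = FALSE])
    cn <- c(obj$n, -obj$n[free]); cd <- c(obj$d, obj$d[free])
  } else {
    cn <- as.vector(obj$n); cd <- as.vector(obj$d)
  }
  if (!maximize) cn <- -cn

  res <- .simplex_std(rq(cn, cd), .mkrq(rows_n, rows_d), .mkrq(rhs_n, rhs_d))
  if (res$status != "optimal") return(res)
  x <- res$x
  xn <- as.vector(x$n)[seq_len(nv)]; xd <- as.vector(x$d)[seq_len(nv)]
  if (length(free)) {
    extra_n <- as.vector(x$n)[nv + seq_along(free)]
    extra_d <- as.vector(x$d)[nv + seq_along(free)]
    v <- .rq_add0(xn[free], xd[free], -extra_n, extra_d)
    xn[free] <- v$n; xd[free] <- v$d
  }
  val <- res$value
  if (!maximize) val <- rq_neg(val)
  list(status = "optimal", value = val, x = rq(xn, xd))
}
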