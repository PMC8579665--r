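# Exact rational linear algebra (dense, Gauss-Jordan based).
# Pivot choice is deterministic: first nonzero entry in scan order, so all
# derived objects (rref, kernel bases) are reproducible bit-for-bit.

#' Exact rational matrix product
#' @param A,B `"rq"` matrices with conformable dimensions.
#' @return `"rq"` matrix `A %*% B`.
#' @export
rq_matmul <- function(A, B) {
  A <- rq(A); B <- rq(B)
  nr <- nrow(A$n); nc <- ncol(B$n); k <- ncol(A$n)
  if (k != nrow(B$n)) stop("non-conformable rational matrices")
  outn <- matrix(0, nr, nc); outd <- matrix(1, nr, nc)
  for (j in seq_len(k)) {
    # out <- out + A[, j] outer B[j, ]
    a <- rq_col(A, j)
    if (all(a$n == 0)) next
    b <- rq_row(B, j)
    pn <- outer(a$n, b$n); pd <- outer(a$d, b$d)
    p <- .rq_canon(pn, pd)
    v <- .rq_add0(outn, outd, p$n, p$d)
    outn <- matrix(v$n, nr, nc); outd <- matrix(v$d, nr, nc)
  }
  .mkrq(outn, outd)
}

#' Exact matrix-vector product
#' @param A `"rq"` matrix; `x` `"rq"` vector.
#' @param x vector operand.
#' @return `"rq"` vector `A x`.
#' @export
rq_matvec <- function(A, x) {
  A <- rq(A); x <- rq(x)
  nr <- nrow(A$n)
  outn <- numeric(nr); outd <- rep(1, nr)
  xn <- as.vector(x$n); xd <- as.vector(x$d)
  for (j in seq_along(xn)) {
    if (xn[j] == 0) next
    p <- .rq_mul0(A$n[, j], A$d[, j], xn[j], xd[j])
    v <- .rq_add0(outn, outd, p$n, p$d)
    outn <- v$n; outd <- v$d
  }
  .mkrq(outn, outd)
}

#' Reduced row echelon form over the rationals
#'
#' Gauss-Jordan elimination with exact arithmetic; pivots are the first
#' nonzero entries in column order.
#'
#' @param A `"rq"` matrix.
#' @return list with `R` (the rref, `"rq"`), `pivots` (pivot column indices),
#'   and `rank`.
#' @export
rq_rref <- function(A) {
  A <- rq(A)
  N <- A$n; D <- A$d
  nr <- nrow(N); nc <- ncol(N)
  pivots <- integer(0)
  r <- 1L
  for (j in seq_len(nc)) {
    if (r > nr) break
    hit <- which(N[r:nr, j] != 0)
    if (length(hit) == 0) next
    p <- r + hit[1] - 1L
    if (p != r) {
      tmp <- N[r, ]; N[r, ] <- N[p, ]; N[p, ] <- tmp
      tmp <- D[r, ]; D[r, ] <- D[p, ]; D[p, ] <- tmp
    }
    # normalize pivot row
    pivn <- N[r, j]; pivd <- D[r, j]
    v <- .rq_mul0(N[r, ], D[r, ], sign(pivn) * pivd, abs(pivn))
    N[r, ] <- v$n; D[r, ] <- v$d
    # eliminate other rows
    rows <- which(N[, j] != 0)
    rows <- rows[rows != r]
    for (i in rows) {
      f_n <- N[i, j]; f_d <- D[i, j]
      p2 <- .rq_mul0(N[r, ], D[r, ], -f_n, f_d)
      v2 <- .rq_add0(N[i, ], D[i, ], p2$n, p2$d)
      N[i, ] <- v2$n; D[i, ] <- v2$d
    }
    pivots <- c(pivots, j)
    r <- r + 1L
  }
  list(R = .mkrq(N, D), pivots = pivots, rank = length(pivots))
}

#' Exact rank of a rational matrix
#' @param A `"rq"` matrix.
#' @return integer rank.
#' @export
rq_rank <- function(A) rq_rref(A)$rank

#' Exact rational kernel (null-space basis)
#'
#' Columns of the result form an exact basis of `{v : A v = 0}`; each basis
#' vector is scaled to coprime integers with its first nonzero entry
#' positive, so the basis is canonical for a given pivot structure.
#'
#' @param A `"rq"` matrix (m x n).
#' @return `"rq"` matrix (n x q), q = n - rank(A); 0 columns if trivial.
#' @export
rq_kernel <- function(A) {
  A <- rq(A)
  nc <- ncol(A$n)
  rr <- rq_rref(A)
  piv <- rr$pivots
  free <- setdiff(seq_len(nc), piv)
  q <- length(free)
  Kn <- matrix(0, nc, q); Kd <- matrix(1, nc, q)
  R <- rr$R
  for (k in seq_along(free)) {
    j <- free[k]
    Kn[j, k] <- 1
    if (length(piv)) {
      # pivot variable i (row r of rref) gets -R[r, j]
      Kn[piv, k] <- -R$n[seq_along(piv), j]
      Kd[piv, k] <- R$d[seq_along(piv), j]
    }
    col <- rq_int_normalize(.mkrq(Kn[, k], Kd[, k]), sign_first = TRUE)
    Kn[, k] <- col$n; Kd[, k] <- col$d
  }
  .mkrq(Kn, Kd)
}

#' Solve a square rational system exactly
#' @param A `"rq"` square matrix; `b` `"rq"` vector.
#' @param b right-hand side.
#' @return `"rq"` solution vector, or `NULL` if `A` is singular.
#' @export
rq_solve <- function(A, b) {
  A <- rq(A); b <- rq(b)
  n <- nrow(A$n)
  aug <- rq_cbind(A, rq_as_matrix(b, n, 1))
  rr <- rq_rref(aug)
  if (length(rr$pivots) != n || any(rr$pivots > n)) return(NULL)
  rq_col(rr$R, n + 1L)
}

#' Exact inverse of a rational matrix
#' @param A `"rq"` square nonsingular matrix.
#' @return `"rq"` inverse, or `NULL` if singular.
#' @export
rq_inv_mat <- function(A) {
  A <- rq(A)
  n <- nrow(A$n)
  aug <- rq_cbind(A, rq_eye(n))
  rr <- rq_rref(aug)
  if (length(rr$pivots) < n || any(rr$pivots[seq_len(n)] != seq_len(n))) return(NULL)
  rq_index(rr$R, seq_len(n), n + seq_len(n))
}
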