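# Exact rational arithmetic on IEEE doubles.
#
# A rational value is stored as a pair of numeric arrays (n, d) holding exact
# integers with d >= 1 and gcd(|n|, d) = 1 elementwise.  Doubles represent
# integers exactly up to 2^53; every operation that could push an intermediate
# product past 2^52 raises an error instead of silently rounding, so results
# are either exact or absent.

.RQ_LIMIT <- 2^52

.rq_guard <- function(...) {
  for (x in list(...)) {
    if (length(x) && max(abs(x), 0) >= .RQ_LIMIT) {
      stop("exact rational arithmetic overflow (intermediate value >= 2^52); ",
           "input coefficients are too large for the double-backed exact kernel",
           call. = FALSE)
    }
  }
  invisible(NULL)
}

# vectorized Euclid on nonnegative integers
.rq_gcd0 <- function(a, b) {
  if (length(a) != length(b)) {
    ln <- max(length(a), length(b))
    a <- rep_len(a, ln); b <- rep_len(b, ln)
  }
  a <- abs(a); b <- abs(b)
  repeat {
    act <- which(b != 0)
    if (!length(act)) break
    r <- a[act] %% b[act]
    a[act] <- b[act]
    b[act] <- r
  }
  a
}

# canonicalize raw numerator/denominator pairs
.rq_canon <- function(n, d) {
  if (any(d == 0)) stop("rational with zero denominator", call. = FALSE)
  .rq_guard(n, d)
  neg <- d < 0
  if (any(neg)) {
    n[neg] <- -n[neg]
    d[neg] <- -d[neg]
  }
  z <- n == 0
  if (any(z)) d[z] <- 1
  g <- .rq_gcd0(n, d)
  g[g == 0] <- 1
  list(n = n / g, d = d / g)
}

.rq_add0 <- function(n1, d1, n2, d2) {
  g <- .rq_gcd0(d1, d2)
  da <- d1 / g
  db <- d2 / g
  num <- n1 * db + n2 * da
  den <- d1 * db
  .rq_guard(n1 * db, n2 * da, num, den)
  .rq_canon(num, den)
}

.rq_mul0 <- function(n1, d1, n2, d2) {
  g1 <- .rq_gcd0(n1, d2); g1[g1 == 0] <- 1
  g2 <- .rq_gcd0(n2, d1); g2[g2 == 0] <- 1
  num <- (n1 / g1) * (n2 / g2)
  den <- (d1 / g2) * (d2 / g1)
  .rq_guard(num, den)
  .rq_canon(num, den)
}

.rq_shape <- function(a, b) {
  # result dim: prefer the non-scalar operand's dim
  if (!is.null(dim(a))) dim(a) else dim(b)
}

#' Construct an exact rational array
#'
#' Builds a rational vector or matrix from integer-valued numerators and
#' denominators. Values are canonicalized (positive denominator, fully
#' reduced). All package arithmetic on these objects is exact; operations
#' whose intermediates would exceed the exactly-representable integer range
#' of doubles fail loudly rather than round.
#'
#' @param n numerator(s); integer-valued numeric vector or matrix.
#' @param d denominator(s); integer-valued, recycled against `n`.
#' @return An object of class `"rq"`.
#' @examples
#' rq(c(2, 3), 4)        # 1/2, 3/4
#' rq(matrix(1:4, 2))    # 2x2 rational matrix
#' @export
rq <- function(n, d = 1) {
  if (inherits(n, "rq")) return(n)
  if (!is.numeric(n) || !is.numeric(d)) stop("rq() needs numeric input")
  if (any(n != round(n)) || any(d != round(d))) {
    stop("rq() numerators/denominators must be integer-valued; ",
         "use rq_parse() for decimal strings")
  }
  dm <- dim(n)
  if (length(d) != length(n)) d <- rep_len(d, length(n))
  v <- .rq_canon(as.numeric(n), as.numeric(d))
  if (!is.null(dm)) { dim(v$n) <- dm; dim(v$d) <- dm }
  structure(list(n = v$n, d = v$d), class = "rq")
}

.mkrq <- function(n, d) structure(list(n = n, d = d), class = "rq")

#' @export
print.rq <- function(x, ...) {
  s <- rq_format(x)
  if (!is.null(dim(x$n))) {
    m <- matrix(s, nrow(x$n), ncol(x$n))
    print(m, quote = FALSE)
  } else {
    print(s, quote = FALSE)
  }
  invisible(x)
}

#' @export
length.rq <- function(x) length(x$n)

#' @export
dim.rq <- function(x) dim(x$n)

#' Parse exact rationals from strings
#'
#' Accepts integers (`"-3"`), fractions (`"5/3"`), and decimal or scientific
#' notation (`"1.25"`, `"2e3"`, `"1.5e-2"`). Decimal strings are converted
#' digit-exactly (no float intermediate): `"0.1"` becomes 1/10.
#'
#' @param s character vector.
#' @return An `"rq"` vector of the same length.
#' @export
rq_parse <- function(s) {
  s <- trimws(as.character(s))
  n <- numeric(length(s)); d <- numeric(length(s))
  for (i in seq_along(s)) {
    t <- s[i]
    if (!nzchar(t)) stop("empty rational literal")
    if (grepl("/", t, fixed = TRUE)) {
      parts <- strsplit(t, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("malformed fraction: ", t)
      num <- suppressWarnings(as.numeric(parts[1]))
      den <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(num) || is.na(den) || num != round(num) || den != round(den)) {
        stop("malformed fraction: ", t)
      }
      n[i] <- num; d[i] <- den
    } else {
      m <- regmatches(t, regexec("^([+-]?)([0-9]*)(?:\\.([0-9]*))?(?:[eE]([+-]?[0-9]+))?$", t))[[1]]
      if (length(m) == 0 || (m[3] == "" && m[4] == "")) {
        stop("not a numeric literal: '", t, "'")
      }
      sgn <- if (m[2] == "-") -1 else 1
      ipart <- if (nzchar(m[3])) m[3] else "0"
      fpart <- m[4]
      expo <- if (nzchar(m[5])) as.numeric(m[5]) else 0
      digits <- paste0(ipart, fpart)
      if (nchar(gsub("0", "", digits)) == 0) { n[i] <- 0; d[i] <- 1; next }
      num <- as.numeric(digits)
      if (num >= .RQ_LIMIT) stop("literal too large for exact parsing: ", t)
      e <- expo - nchar(fpart)
      if (e >= 0) {
        num <- num * 10^e
        if (num >= .RQ_LIMIT) stop("literal too large for exact parsing: ", t)
        n[i] <- sgn * num; d[i] <- 1
      } else {
        den <- 10^(-e)
        if (den >= .RQ_LIMIT) stop("literal too precise for exact parsing: ", t)
        n[i] <- sgn * num; d[i] <- den
      }
    }
  }
  rq(n, d)
}

#' Format exact rationals as strings
#'
#' Integers print without a denominator; other values as `"p/q"`.
#'
#' @param x an `"rq"` object.
#' @return character vector (dim dropped).
#' @export
rq_format <- function(x) {
  n <- as.vector(x$n); d <- as.vector(x$d)
  ifelse(d == 1,
         format(n, scientific = FALSE, trim = TRUE),
         paste0(format(n, scientific = FALSE, trim = TRUE), "/",
                format(d, scientific = FALSE, trim = TRUE)))
}

#' Convert exact rationals to doubles
#' @param x an `"rq"` object.
#' @return numeric vector/matrix (inexact in general).
#' @export
rq_to_double <- function(x) {
  out <- x$n / x$d
  dim(out) <- dim(x$n)
  out
}

# ---- arithmetic ------------------------------------------------------------

#' Elementwise rational arithmetic
#'
#' `rq_add`, `rq_sub`, `rq_mul`, `rq_div` combine two rational arrays
#' elementwise with scalar broadcasting; `rq_neg`, `rq_abs`, `rq_inv` are
#' unary. All results are exact and canonical.
#'
#' @param x,y `"rq"` objects (or objects accepted by [rq()]).
#' @return An `"rq"` object.
#' @name rq-arith
NULL

#' @rdname rq-arith
#' @export
rq_add <- function(x, y) {
  x <- rq(x); y <- rq(y)
  v <- .rq_add0(x$n, x$d, y$n, y$d)
  dm <- .rq_shape(x$n, y$n)
  if (!is.null(dm)) { dim(v$n) <- dm; dim(v$d) <- dm }
  .mkrq(v$n, v$d)
}

#' @rdname rq-arith
#' @export
rq_sub <- function(x, y) rq_add(x, rq_neg(y))

#' @rdname rq-arith
#' @export
rq_mul <- function(x, y) {
  x <- rq(x); y <- rq(y)
  v <- .rq_mul0(x$n, x$d, y$n, y$d)
  dm <- .rq_shape(x$n, y$n)
  if (!is.null(dm)) { dim(v$n) <- dm; dim(v$d) <- dm }
  .mkrq(v$n, v$d)
}

#' @rdname rq-arith
#' @export
rq_div <- function(x, y) rq_mul(x, rq_inv(y))

#' @rdname rq-arith
#' @export
rq_neg <- function(x) { x <- rq(x); .mkrq(-x$n, x$d) }

#' @rdname rq-arith
#' @export
rq_abs <- function(x) { x <- rq(x); .mkrq(abs(x$n), x$d) }

#' @rdname rq-arith
#' @export
rq_inv <- function(x) {
  x <- rq(x)
  if (any(x$n == 0)) stop("division by exact zero")
  sgn <- sign(x$n)
  .mkrq(sgn * x$d, abs(x$n))
}

#' Rational comparison and predicates
#'
#' `rq_cmp` returns the elementwise sign of `x - y` (-1, 0, 1); `rq_eq`
#' tests exact equality; `rq_sign` the sign of `x`; `rq_is_zero` zero-ness.
#'
#' @param x,y `"rq"` objects.
#' @return integer/logical vector.
#' @name rq-compare
NULL

#' @rdname rq-compare
#' @export
rq_cmp <- function(x, y) {
  d <- rq_sub(x, y)
  as.integer(sign(d$n))
}

#' @rdname rq-compare
#' @export
rq_eq <- function(x, y) {
  x <- rq(x); y <- rq(y)
  ln <- max(length(x$n), length(y$n))
  n1 <- rep_len(as.vector(x$n), ln); d1 <- rep_len(as.vector(x$d), ln)
  n2 <- rep_len(as.vector(y$n), ln); d2 <- rep_len(as.vector(y$d), ln)
  n1 == n2 & d1 == d2
}

#' @rdname rq-compare
#' @export
rq_sign <- function(x) as.integer(sign(rq(x)$n))

#' @rdname rq-compare
#' @export
rq_is_zero <- function(x) rq(x)$n == 0

#' Identical rational arrays (same shape, same exact values)
#' @param x,y `"rq"` objects.
#' @return single logical.
#' @export
rq_identical <- function(x, y) {
  x <- rq(x); y <- rq(y)
  length(x$n) == length(y$n) &&
    identical(dim(x$n), dim(y$n)) &&
    all(x$n == y$n) && all(x$d == y$d)
}

# ---- structure -------------------------------------------------------------

#' Indexing and assembly of rational arrays
#'
#' Thin structural helpers: `rq_index` subsets like `[`, `rq_elt` extracts a
#' scalar from a matrix, `rq_row`/`rq_col` extract matrix slices as vectors,
#' `rq_rbind`/`rq_cbind` stack, `rq_t` transposes, `rq_c` concatenates,
#' `rq_zeros`/`rq_eye` build constants, `rq_set` writes a sub-array.
#'
#' @param x,... `"rq"` objects (for `rq_c`: any number of them).
#' @param i,j index vectors.
#' @param nr,nc,n dimensions.
#' @param value replacement `"rq"` array.
#' @name rq-structure
NULL

#' @rdname rq-structure
#' @export
rq_index <- function(x, i, j = NULL) {
  x <- rq(x)
  if (is.null(j) && is.null(dim(x$n))) {
    .mkrq(x$n[i], x$d[i])
  } else if (is.null(j)) {
    .mkrq(x$n[i, , drop = FALSE], x$d[i, , drop = FALSE])
  } else {
    .mkrq(x$n[i, j, drop = FALSE], x$d[i, j, drop = FALSE])
  }
}

#' @rdname rq-structure
#' @export
rq_elt <- function(x, i, j) .mkrq(x$n[i, j], x$d[i, j])

#' @rdname rq-structure
#' @export
rq_row <- function(x, i) .mkrq(as.vector(x$n[i, ]), as.vector(x$d[i, ]))

#' @rdname rq-structure
#' @export
rq_col <- function(x, j) .mkrq(as.vector(x$n[, j]), as.vector(x$d[, j]))

#' @rdname rq-structure
#' @export
rq_set <- function(x, i, j, value) {
  value <- rq(value)
  if (is.null(j)) {
    x$n[i] <- value$n; x$d[i] <- value$d
  } else {
    x$n[i, j] <- value$n; x$d[i, j] <- value$d
  }
  x
}

#' @rdname rq-structure
#' @export
rq_set_row <- function(x, i, value) {
  value <- rq(value)
  x$n[i, ] <- as.vector(value$n); x$d[i, ] <- as.vector(value$d)
  x
}

#' @rdname rq-structure
#' @export
rq_rbind <- function(...) {
  xs <- lapply(list(...), rq)
  .mkrq(do.call(rbind, lapply(xs, function(z) z$n)),
        do.call(rbind, lapply(xs, function(z) z$d)))
}

#' @rdname rq-structure
#' @export
rq_cbind <- function(...) {
  xs <- lapply(list(...), rq)
  .mkrq(do.call(cbind, lapply(xs, function(z) z$n)),
        do.call(cbind, lapply(xs, function(z) z$d)))
}

#' @rdname rq-structure
#' @export
rq_c <- function(...) {
  xs <- lapply(list(...), rq)
  .mkrq(unlist(lapply(xs, function(z) as.vector(z$n)), use.names = FALSE),
        unlist(lapply(xs, function(z) as.vector(z$d)), use.names = FALSE))
}

#' @rdname rq-structure
#' @export
rq_t <- function(x) { x <- rq(x); .mkrq(t(x$n), t(x$d)) }

#' @rdname rq-structure
#' @export
rq_zeros <- function(nr, nc = NULL) {
  if (is.null(nc)) .mkrq(numeric(nr), rep(1, nr))
  else .mkrq(matrix(0, nr, nc), matrix(1, nr, nc))
}

#' @rdname rq-structure
#' @export
rq_eye <- function(n) .mkrq(diag(n), matrix(1, n, n))

#' @rdname rq-structure
#' @export
rq_as_matrix <- function(x, nr, nc) {
  x <- rq(x)
  .mkrq(matrix(x$n, nr, nc), matrix(x$d, nr, nc))
}

# ---- reductions ------------------------------------------------------------

#' Rational reductions
#'
#' `rq_sum` totals a rational array; `rq_dot` is the exact inner product.
#'
#' @param x,y `"rq"` vectors.
#' @return scalar `"rq"`.
#' @name rq-reduce
NULL

#' @rdname rq-reduce
#' @export
rq_sum <- function(x) {
  x <- rq(x)
  n <- as.vector(x$n); d <- as.vector(x$d)
  accn <- 0; accd <- 1
  for (i in seq_along(n)) {
    v <- .rq_add0(accn, accd, n[i], d[i])
    accn <- v$n; accd <- v$d
  }
  .mkrq(accn, accd)
}

#' @rdname rq-reduce
#' @export
rq_dot <- function(x, y) rq_sum(rq_mul(x, y))

#' Scale a rational vector to coprime integers
#'
#' Multiplies by the least common multiple of the denominators and divides by
#' the gcd of the numerators, yielding an integer vector with no common
#' factor. `sign_first` flips the sign so the first nonzero entry is positive
#' (a canonical orientation for kernel basis vectors and rays).
#'
#' @param x `"rq"` vector.
#' @param sign_first make first nonzero entry positive.
#' @return `"rq"` vector of coprime integers (zero vector stays zero).
#' @export
rq_int_normalize <- function(x, sign_first = FALSE) {
  x <- rq(x)
  n <- as.vector(x$n); d <- as.vector(x$d)
  nz <- which(n != 0)
  if (length(nz) == 0) return(.mkrq(n, rep(1, length(n))))
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
  if (g > 1) v <- v / g
  if (sign_first && v[nz[1]] < 0) v <- -v
  .mkrq(v, rep(1, length(v)))
}
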