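# lrs file dialects: H-representation (.ine) writer/reader and
# V-representation (.ext) reader/writer.
#
# lrs encodes a constraint a x >= b as the row (-b | a); "linearity c i1
# ... ic" marks 1-based rows as equalities. Rows are written as integers
# after clearing denominators per row (gcd-reduced), which lrs accepts and
# keeps files diff-stable.

# any supported object -> (A, b, linearity) view over named variables
.as_hview <- function(obj) {
  if (inherits(obj, "GeneralHRep")) {
    list(A = obj$A, b = obj$b, linearity = obj$linearity,
         ids = paste0("x", seq_len(ncol(obj$A$n))))
  } else if (inherits(obj, "ConeH")) {
    ng <- nrow(obj$G$n)
    A <- if (ng) rq_rbind(obj$G, obj$H) else obj$H
    list(A = A, b = rq_zeros(nrow(A$n)), linearity = seq_len(ng),
         ids = obj$var_ids)
  } else if (inherits(obj, "FluxCone")) {
    m <- nrow(obj$N$n); n <- ncol(obj$N$n)
    list(A = rq_rbind(obj$N, rq_eye(n)), b = rq_zeros(m + n),
         linearity = seq_len(m), ids = obj$reaction_ids)
  } else if (inherits(obj, "PolyhedronH")) {
    l <- length(obj$nonneg); k1 <- nrow(obj$C$n); k2 <- nrow(obj$E$n)
    A <- if (k2) rq_rbind(obj$C, obj$E, rq_eye(l))
         else rq_rbind(obj$C, rq_eye(l))
    b <- if (k2) rq_c(obj$d, obj$f, rq_zeros(l)) else rq_c(obj$d, rq_zeros(l))
    list(A = A, b = b, linearity = seq_len(k1), ids = obj$var_ids)
  } else stop("cannot convert object to an H-representation view")
}

#' Write an H-representation in lrs .ine format
#'
#' Emits, in order: a name line, `H-representation`, an optional
#' `linearity` line (1-based row indices), `begin`, the `m n+1 rational`
#' size line, one row per constraint encoded as `(-b | a)` for `a x >= b`
#' (integer-scaled per row), and `end`.
#'
#' @param obj `"GeneralHRep"`, `"ConeH"`, `"PolyhedronH"` or `"FluxCone"`.
#' @param path output file path.
#' @param name name written on the first line.
#' @return `path`, invisibly.
#' @export
write_lrs_ine <- function(obj, path, name = "fluxmodes") {
  h <- .as_hview(obj)
  k <- nrow(h$A$n); l <- ncol(h$A$n)
  lines <- c(name, "H-representation")
  if (length(h$linearity)) {
    lines <- c(lines, paste("linearity", length(h$linearity),
                            paste(h$linearity, collapse = " ")))
  }
  lines <- c(lines, "begin", paste(k, l + 1L, "rational"))
  for (i in seq_len(k)) {
    row <- rq_c(rq_neg(rq_index(h$b, i)), rq_row(h$A, i))
    row <- rq_int_normalize(row)
    # preserve orientation: int-normalize never flips here (no sign_first),
    # so the constraint is unchanged up to positive scaling
    lines <- c(lines, paste(rq_format(row), collapse = " "))
  }
  lines <- c(lines, "end")
  writeLines(lines, path)
  invisible(path)
}

#' Parse an lrs .ine H-representation
#'
#' Inverse of [write_lrs_ine()]: returns a `"GeneralHRep"` with `A x >= b`
#' semantics and the linearity rows flagged.
#'
#' @param path .ine file path.
#' @return `"GeneralHRep"`.
#' @export
parse_lrs_ine <- function(path) {
  lines <- trimws(readLines(path))
  hr <- which(lines == "H-representation")
  if (!length(hr)) stop("not an lrs H-representation: ", path)
  lin <- integer(0)
  for (ln in lines[seq_len(hr[1] - 1 + 2)]) {
    if (startsWith(ln, "linearity")) {
      f <- strsplit(ln, "\\s+")[[1]]
      lin <- as.integer(f[-(1:2)])
    }
  }
  # also allow linearity between H-representation and begin
  bg <- which(lines == "begin")
  if (!length(bg)) stop("missing 'begin' in ", path)
  for (ln in lines[seq_len(bg[1])]) {
    if (startsWith(ln, "linearity")) {
      f <- strsplit(ln, "\\s+")[[1]]
      lin <- as.integer(f[-(1:2)])
    }
  }
  size <- strsplit(lines[bg[1] + 1L], "\\s+")[[1]]
  k <- as.integer(size[1]); l1 <- as.integer(size[2])
  if (is.na(k) || is.na(l1)) stop("malformed size line at line ", bg[1] + 1L)
  rows_n <- matrix(0, k, l1); rows_d <- matrix(1, k, l1)
  for (i in seq_len(k)) {
    ln <- lines[bg[1] + 1L + i]
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) != l1) {
      stop("malformed .ine row at line ", bg[1] + 1L + i,
           ": expected ", l1, " fields, got ", length(f))
    }
    v <- rq_parse(f)
    rows_n[i, ] <- v$n; rows_d[i, ] <- v$d
  }
  if (lines[bg[1] + 2L + k] != "end") {
    stop("missing 'end' after rows at line ", bg[1] + 2L + k)
  }
  M <- .mkrq(rows_n, rows_d)
  A <- rq_index(M, seq_len(k), 2:l1)
  b <- rq_neg(rq_col(M, 1))
  general_hrep(A, b, linearity = lin)
}

#' Parse an lrs .ext V-representation
#'
#' Reads a `V-representation` block: each row's leading field is `1` for a
#' vertex and `0` for a ray; coordinates are exact rationals.
#'
#' @param path .ext file path.
#' @return list with `vertices` and `rays` (`"rq"` matrices, possibly
#'   0-row) and `nvars`.
#' @export
parse_lrs_ext <- function(path) {
  lines <- trimws(readLines(path))
  vr <- which(lines == "V-representation")
  if (!length(vr)) stop("not an lrs V-representation: ", path)
  bg <- which(lines == "begin")
  bg <- bg[bg > vr[1]][1]
  if (is.na(bg)) stop("missing 'begin' in ", path)
  size <- strsplit(lines[bg + 1L], "\\s+")[[1]]
  l1 <- as.integer(size[2])
  vert_n <- NULL; vert_d <- NULL; ray_n <- NULL; ray_d <- NULL
  i <- bg + 2L
  nrow_seen <- 0L
  while (i <= length(lines) && lines[i] != "end") {
    if (nzchar(lines[i])) {
      f <- strsplit(lines[i], "\\s+")[[1]]
      if (length(f) != l1) {
        stop("malformed .ext row at line ", i, ": expected ", l1,
             " fields, got ", length(f))
      }
      v <- rq_parse(f)
      lead <- rq_index(v, 1)
      coords <- rq_index(v, 2:l1)
      if (lead$n == 1 && lead$d == 1) {
        vert_n <- rbind(vert_n, coords$n); vert_d <- rbind(vert_d, coords$d)
      } else if (lead$n == 0) {
        ray_n <- rbind(ray_n, coords$n); ray_d <- rbind(ray_d, coords$d)
      } else {
        stop("malformed .ext leading field at line ", i, ": ", f[1])
      }
      nrow_seen <- nrow_seen + 1L
    }
    i <- i + 1L
  }
  if (i > length(lines)) stop("missing 'end' in ", path)
  nv <- l1 - 1L
  list(vertices = if (is.null(vert_n)) rq_zeros(0, nv) else .mkrq(vert_n, vert_d),
       rays = if (is.null(ray_n)) rq_zeros(0, nv) else .mkrq(ray_n, ray_d),
       nvars = nv)
}

#' Write vertices and rays in lrs .ext format
#'
#' @param vertices,rays `"ModeSet"`s (either may be empty) over a common
#'   namespace.
#' @param path output file path.
#' @param name name line.
#' @return `path`, invisibly.
#' @export
write_lrs_ext <- function(vertices, rays, path, name = "fluxmodes") {
  nv <- length(vertices$reaction_ids)
  k <- mode_count(vertices) + mode_count(rays)
  lines <- c(name, "V-representation", "begin",
             paste(k, nv + 1L, "rational"))
  for (i in seq_len(mode_count(vertices))) {
    lines <- c(lines, paste(c("1", rq_format(rq_row(vertices$values, i))),
                            collapse = " "))
  }
  for (i in seq_len(mode_count(rays))) {
    lines <- c(lines, paste(c("0", rq_format(rq_row(rays$values, i))),
                            collapse = " "))
  }
  lines <- c(lines, "end")
  writeLines(lines, path)
  invisible(path)
}
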