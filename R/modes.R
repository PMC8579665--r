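# Flux modes and mode sets: exact rational vectors over a named reaction
# index, with a canonical order (support bitset, then lexicographic value
# order) so enumeration output is deterministic and diffable.

#' Construct a mode set
#'
#' A collection of flux modes over a common reaction namespace. Each mode
#' is an exact rational vector with a kind: `"efm"` (ray; gcd-normalized
#' integers) or `"efv"` (vertex; zeta scaled to 1 before projection).
#'
#' @param values list of `"rq"` vectors, or an `"rq"` matrix (rows = modes).
#' @param reaction_ids variable namespace.
#' @param kind character vector (`"efm"`/`"efv"`), recycled.
#' @param canonicalize sort modes canonically (default `TRUE`).
#' @return object of class `"ModeSet"`.
#' @export
mode_set <- function(values, reaction_ids, kind = "efm", canonicalize = TRUE) {
  n <- length(reaction_ids)
  if (inherits(values, "rq")) {
    stopifnot(is.matrix(values$n), ncol(values$n) == n)
    M <- values
  } else {
    stopifnot(is.list(values))
    if (length(values)) {
      lens <- vapply(values, function(v) length(rq(v)$n), integer(1))
      if (any(lens != n)) stop("mode length does not match reaction namespace")
      M <- .mkrq(do.call(rbind, lapply(values, function(v) as.vector(rq(v)$n))),
                 do.call(rbind, lapply(values, function(v) as.vector(rq(v)$d))))
    } else {
      M <- rq_zeros(0, n)
    }
  }
  k <- nrow(M$n)
  kind <- rep_len(as.character(kind), k)
  if (k && !all(kind %in% c("efm", "efv"))) stop("kind must be 'efm' or 'efv'")
  ms <- structure(list(values = M, reaction_ids = as.character(reaction_ids),
                       kind = kind),
                  class = "ModeSet")
  if (canonicalize && k > 1) ms <- .mode_sort(ms)
  ms
}

#' @export
print.ModeSet <- function(x, ...) {
  cat(sprintf("ModeSet: %d modes (%d efm, %d efv) over %d reactions\n",
              nrow(x$values$n), sum(x$kind == "efm"), sum(x$kind == "efv"),
              length(x$reaction_ids)))
  invisible(x)
}

#' Number of modes in a set
#' @param modes `"ModeSet"`.
#' @return integer count.
#' @export
mode_count <- function(modes) nrow(modes$values$n)

#' Support of each mode
#' @param modes `"ModeSet"`.
#' @return list of integer index vectors (nonzero positions).
#' @export
mode_supports <- function(modes) {
  lapply(seq_len(mode_count(modes)), function(i) which(modes$values$n[i, ] != 0))
}

# canonical key: support bitmask string, then exact value string
.mode_keys <- function(ms) {
  k <- mode_count(ms)
  if (k == 0) return(character(0))
  supp <- vapply(seq_len(k), function(i) {
    paste(ifelse(ms$values$n[i, ] != 0, "1", "0"), collapse = "")
  }, character(1))
  vals <- vapply(seq_len(k), function(i) {
    paste(rq_format(rq_index(ms$values, i)), collapse = ",")
  }, character(1))
  paste(supp, vals, sep = "|")
}

.mode_sort <- function(ms) {
  keys <- .mode_keys(ms)
  ord <- order(keys, method = "radix")
  ms$values <- rq_index(ms$values, ord)
  ms$kind <- ms$kind[ord]
  ms
}

#' Exact string key per mode (canonical identity)
#'
#' The key combines the support pattern and the exact rational values, so
#' two modes have equal keys iff they are identical vectors. Useful for
#' set comparisons across engines and formulations.
#'
#' @param modes `"ModeSet"`.
#' @return character vector.
#' @export
mode_keys <- function(modes) .mode_keys(modes)

#' Compare two mode sets as sets
#' @param a,b `"ModeSet"` over the same namespace.
#' @return TRUE iff they contain exactly the same modes.
#' @export
mode_sets_equal <- function(a, b) {
  identical(a$reaction_ids, b$reaction_ids) &&
    identical(sort(.mode_keys(a)), sort(.mode_keys(b)))
}

#' Write a mode set as TSV
#'
#' One mode per row; columns: `mode`, `kind`, then one column per reaction.
#' Values serialize as exact `p/q` strings (`rational = TRUE`) or decimals
#' with 10 significant digits.
#'
#' @param modes `"ModeSet"`.
#' @param path file path.
#' @param rational write exact `p/q` strings (default) or decimals.
#' @return `path`, invisibly.
#' @export
write_modes_tsv <- function(modes, path, rational = TRUE) {
  k <- mode_count(modes)
  header <- paste(c("mode", "kind", modes$reaction_ids), collapse = "\t")
  lines <- character(k)
  for (i in seq_len(k)) {
    v <- rq_index(modes$values, i)
    cell <- if (rational) rq_format(v) else
      formatC(rq_to_double(v), digits = 10, format = "g")
    lines[i] <- paste(c(i, modes$kind[i], cell), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a mode set from TSV
#' @param path file written by [write_modes_tsv()] with `rational = TRUE`.
#' @return `"ModeSet"`.
#' @export
read_modes_tsv <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3 || header[1] != "mode" || header[2] != "kind") {
    stop("not a mode TSV: ", path)
  }
  ids <- header[-(1:2)]
  body <- lines[-1]
  vals <- list(); kind <- character(0)
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != length(ids) + 2) stop("malformed mode TSV row: ", ln)
    kind <- c(kind, f[2])
    vals[[length(vals) + 1L]] <- rq_parse(f[-(1:2)])
  }
  mode_set(vals, ids, kind)
}
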