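# efmtool-style input quadruple: stoichiometric matrix, reversibility
# vector, reaction names, metabolite names — four plain-text files.

#' Write efmtool-style input files
#'
#' Emits the four text files the efmtool file interface expects:
#' * `model.sfile` — stoichiometric matrix, one whitespace-separated row per
#'   metabolite (entries as integers or `p/q` rationals);
#' * `model.rvfile` — reversibility vector, `0`/`1` space-separated, one line;
#' * `model.rfile` — double-quoted reaction names, one line;
#' * `model.mfile` — double-quoted metabolite names, one line.
#' Column order equals the model's reaction order.
#'
#' @param model `"MetabolicModel"`.
#' @param directory output directory (created if absent).
#' @return character vector of the four paths (sfile, rvfile, rfile, mfile).
#' @export
write_efmtool_inputs <- function(model, directory) {
  stopifnot(inherits(model, "MetabolicModel"))
  if (any(!nzchar(model$reaction_ids)) || any(!nzchar(model$metabolite_ids))) {
    stop("empty reaction or metabolite name")
  }
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory '", directory, "'")
  }
  paths <- file.path(directory, c("model.sfile", "model.rvfile",
                                  "model.rfile", "model.mfile"))
  m <- length(model$metabolite_ids)
  rows <- vapply(seq_len(m), function(i) {
    paste(rq_format(rq_row(model$S, i)), collapse = " ")
  }, character(1))
  writeLines(rows, paths[1])
  writeLines(paste(as.integer(model$rev), collapse = " "), paths[2])
  writeLines(paste(sprintf('"%s"', model$reaction_ids), collapse = " "), paths[3])
  writeLines(paste(sprintf('"%s"', model$metabolite_ids), collapse = " "), paths[4])
  invisible(paths)
}

#' Read efmtool-style input files back into a model
#'
#' Inverse of [write_efmtool_inputs()] for the package's own dialect.
#'
#' @param directory directory containing the four files.
#' @return `"MetabolicModel"`.
#' @export
read_efmtool_inputs <- function(directory) {
  paths <- file.path(directory, c("model.sfile", "model.rvfile",
                                  "model.rfile", "model.mfile"))
  if (!all(file.exists(paths))) stop("missing efmtool input file(s) in ", directory)
  rows <- readLines(paths[1])
  rv <- as.integer(strsplit(trimws(readLines(paths[2])[1]), "\\s+")[[1]])
  unquote <- function(line) {
    m <- regmatches(line, gregexpr('"[^"]*"', line))[[1]]
    gsub('^"|"$', "", m)
  }
  rids <- unquote(readLines(paths[3])[1])
  mids <- unquote(readLines(paths[4])[1])
  cells <- lapply(rows, function(r) rq_parse(strsplit(trimws(r), "\\s+")[[1]]))
  Sn <- do.call(rbind, lapply(cells, function(x) x$n))
  Sd <- do.call(rbind, lapply(cells, function(x) x$d))
  metabolic_model(.mkrq(Sn, Sd), mids, rids, rev = rv == 1L)
}
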