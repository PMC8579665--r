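# Metabolic model container: named stoichiometric system with reversibility
# flags and optional flux bounds, all stoichiometry held as exact rationals.

#' Construct a metabolic model
#'
#' A named stoichiometric system: exact rational matrix `S` (metabolites x
#' reactions), reversibility flags, and optional finite flux bounds
#' (conventionally mmol/gDW/h; units are not enforced). Irreversible
#' reactions must have a nonnegative lower bound.
#'
#' @param S stoichiometric matrix, `"rq"` or integer-valued numeric.
#' @param metabolite_ids,reaction_ids unique id vectors matching `S` dims.
#' @param rev logical vector, one flag per reaction.
#' @param lb,ub optional `"rq"` bound vectors; `NA` numerators are not
#'   allowed — use `-Inf`/`Inf` encoded via `lb = NULL` defaults. Defaults:
#'   `0` (irreversible) or `-Inf` (reversible) to `Inf`, where infinite
#'   bounds are stored as `NULL` entries in `bounded` masks.
#' @param objective_id optional reaction id.
#' @return object of class `"MetabolicModel"`.
#' @export
metabolic_model <- function(S, metabolite_ids, reaction_ids, rev,
                            lb = NULL, ub = NULL, objective_id = NULL) {
  S <- rq(S)
  m <- nrow(S$n); n <- ncol(S$n)
  stopifnot(length(metabolite_ids) == m, length(reaction_ids) == n,
            length(rev) == n, is.logical(rev))
  if (anyDuplicated(metabolite_ids)) stop("duplicate metabolite ids")
  if (anyDuplicated(reaction_ids)) stop("duplicate reaction ids")
  if (any(!nzchar(metabolite_ids)) || any(!nzchar(reaction_ids))) {
    stop("empty id string in model")
  }
  # bounds: rq vectors plus finite-ness masks
  if (is.null(lb)) {
    lb <- rq_zeros(n)
    lb_finite <- !rev           # reversible: -Inf; irreversible: 0
  } else {
    lb_finite <- attr(lb, "finite")
    lb <- rq(lb)
    if (is.null(lb_finite)) lb_finite <- rep(TRUE, n)
  }
  if (is.null(ub)) {
    ub <- rq_zeros(n)
    ub_finite <- rep(FALSE, n)
  } else {
    ub_finite <- attr(ub, "finite")
    ub <- rq(ub)
    if (is.null(ub_finite)) ub_finite <- rep(TRUE, n)
  }
  both <- lb_finite & ub_finite
  if (any(both)) {
    cmpv <- rq_cmp(rq_index(lb, which(both)), rq_index(ub, which(both)))
    if (any(cmpv > 0)) stop("model has lb > ub for reaction(s): ",
                            paste(reaction_ids[which(both)[cmpv > 0]], collapse = ", "))
  }
  bad <- !rev & lb_finite & (rq_sign(lb) < 0)
  if (any(bad)) stop("irreversible reaction with negative lower bound: ",
                     paste(reaction_ids[bad], collapse = ", "))
  if (!is.null(objective_id) && !(objective_id %in% reaction_ids)) {
    stop("objective_id not a reaction id: ", objective_id)
  }
  structure(list(S = S,
                 metabolite_ids = as.character(metabolite_ids),
                 reaction_ids = as.character(reaction_ids),
                 rev = rev,
                 lb = lb, ub = ub,
                 lb_finite = lb_finite, ub_finite = ub_finite,
                 objective_id = objective_id),
            class = "MetabolicModel")
}

#' @export
print.MetabolicModel <- function(x, ...) {
  cat(sprintf("MetabolicModel: %d metabolites x %d reactions (%d reversible)\n",
              length(x$metabolite_ids), length(x$reaction_ids), sum(x$rev)))
  invisible(x)
}

#' @export
dim.MetabolicModel <- function(x) c(length(x$metabolite_ids), length(x$reaction_ids))

# exact structural equality of two models
model_identical <- function(a, b) {
  identical(a$metabolite_ids, b$metabolite_ids) &&
    identical(a$reaction_ids, b$reaction_ids) &&
    identical(a$rev, b$rev) &&
    rq_identical(a$S, b$S) &&
    identical(a$lb_finite, b$lb_finite) &&
    identical(a$ub_finite, b$ub_finite) &&
    all(!a$lb_finite | rq_eq(a$lb, b$lb)) &&
    all(!a$ub_finite | rq_eq(a$ub, b$ub))
}

#' Build a bounds table
#'
#' A list of `(reaction_id, relation, value)` constraints, where relation is
#' `">="` or `"<="` and values are exact rationals. These are the
#' user-supplied inequality constraints that turn a flux cone into a flux
#' polyhedron (e.g. a substrate-uptake cap or a maintenance-ATP demand).
#'
#' @param reaction_id character vector.
#' @param relation character vector of `">="`/`"<="`.
#' @param value `"rq"` vector or character parsed by [rq_parse()].
#' @return object of class `"BoundsTable"`.
#' @export
bounds_table <- function(reaction_id, relation, value) {
  relation <- as.character(relation)
  if (!all(relation %in% c(">=", "<="))) stop("relation must be '>=' or '<='")
  value <- if (is.character(value)) rq_parse(value) else rq(value)
  stopifnot(length(reaction_id) == length(relation),
            length(relation) == length(value$n))
  structure(list(reaction_id = as.character(reaction_id),
                 relation = relation, value = value),
            class = "BoundsTable")
}

#' Read a bounds table from TSV
#'
#' Expected columns (no header): `reaction_id <TAB> relation <TAB> value`,
#' relation one of `>=`, `<=`; values parsed exactly (decimals allowed).
#'
#' @param path file path.
#' @return `"BoundsTable"`.
#' @export
read_bounds_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("reaction_id", "relation", "value"),
                          colClasses = "character")
  bounds_table(df$reaction_id, df$relation, df$value)
}

#' Write a bounds table as TSV
#' @param bounds `"BoundsTable"`.
#' @param path file path.
#' @export
write_bounds_tsv <- function(bounds, path) {
  stopifnot(inherits(bounds, "BoundsTable"))
  lines <- paste(bounds$reaction_id, bounds$relation, rq_format(bounds$value),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Apply reaction bounds to a model
#'
#' Tightens the model's `lb`/`ub` with the table's constraints; a `">="` row
#' raises `lb`, a `"<="` row lowers `ub`, and a bound looser than the
#' current one is a no-op (bounds never loosen). The input model is not
#' modified.
#'
#' @param model `"MetabolicModel"`.
#' @param bounds `"BoundsTable"`.
#' @return a new `"MetabolicModel"`.
#' @export
apply_bounds <- function(model, bounds) {
  stopifnot(inherits(model, "MetabolicModel"), inherits(bounds, "BoundsTable"))
  unknown <- setdiff(bounds$reaction_id, model$reaction_ids)
  if (length(unknown)) stop("bounds reference unknown reaction id(s): ",
                            paste(unknown, collapse = ", "))
  lb <- model$lb; ub <- model$ub
  lb_f <- model$lb_finite; ub_f <- model$ub_finite
  for (k in seq_along(bounds$reaction_id)) {
    i <- match(bounds$reaction_id[k], model$reaction_ids)
    v <- rq_index(bounds$value, k)
    if (bounds$relation[k] == ">=") {
      if (!lb_f[i] || rq_cmp(v, rq_index(lb, i)) > 0) {
        lb <- rq_set(lb, i, NULL, v); lb_f[i] <- TRUE
      }
    } else {
      if (!ub_f[i] || rq_cmp(v, rq_index(ub, i)) < 0) {
        ub <- rq_set(ub, i, NULL, v); ub_f[i] <- TRUE
      }
    }
    if (lb_f[i] && ub_f[i] &&
        rq_cmp(rq_index(lb, i), rq_index(ub, i)) > 0) {
      stop("bound makes lb > ub for reaction ", model$reaction_ids[i])
    }
  }
  out <- model
  out$lb <- lb; out$ub <- ub; out$lb_finite <- lb_f; out$ub_finite <- ub_f
  out
}
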