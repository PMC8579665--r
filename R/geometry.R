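# Geometric H-representations and the transformations among them:
# general polyhedron {Ax >= b}, flux polyhedron {Cx = d, Ex >= f, x >= 0},
# homogenized polyhedral cone {Gy = 0, Hy >= 0}, and flux cone
# {Nr = 0, r >= 0}, with the bookkeeping (TransformRecord) needed to map
# enumerated modes back to the original reaction space.

#' General H-representation
#'
#' The solution set of `A x >= b`, with a subset of rows flagged as
#' equalities ("linearity" rows, in lrs terminology).
#'
#' @param A `"rq"` matrix (k x l).
#' @param b `"rq"` vector of length k.
#' @param linearity integer indices of rows read as equalities.
#' @return object of class `"GeneralHRep"`.
#' @export
general_hrep <- function(A, b, linearity = integer(0)) {
  A <- rq(A); b <- rq(b)
  stopifnot(nrow(A$n) == length(b$n))
  linearity <- sort(unique(as.integer(linearity)))
  if (length(linearity) && (min(linearity) < 1 || max(linearity) > nrow(A$n))) {
    stop("linearity index out of range")
  }
  structure(list(A = A, b = b, linearity = linearity), class = "GeneralHRep")
}

#' @export
print.GeneralHRep <- function(x, ...) {
  cat(sprintf("GeneralHRep: %d rows x %d variables (%d linearities)\n",
              nrow(x$A$n), ncol(x$A$n), length(x$linearity)))
  invisible(x)
}

#' Flux polyhedron H-representation
#'
#' `{x : C x = d, E x >= f, x >= 0}` — equalities (typically the split
#' stoichiometric steady-state block), inequalities (capacity/allocation
#' bounds), and all-variable nonnegativity. By library convention all
#' variables are nonnegative: reversible reactions are split before this
#' object is built.
#'
#' @param C,d equality block.
#' @param E,f inequality block (may have zero rows).
#' @param var_ids variable (reaction/column) names.
#' @return object of class `"PolyhedronH"`.
#' @export
polyhedron_hrep <- function(C, d, E = NULL, f = NULL, var_ids = NULL) {
  C <- rq(C); d <- rq(d)
  l <- ncol(C$n)
  if (is.null(E)) { E <- rq_zeros(0, l); f <- rq_zeros(0) }
  E <- rq(E); f <- rq(f)
  stopifnot(nrow(C$n) == length(d$n), nrow(E$n) == length(f$n),
            ncol(E$n) == l || nrow(E$n) == 0)
  if (nrow(E$n) == 0 && ncol(E$n) != l) E <- rq_zeros(0, l)
  if (is.null(var_ids)) var_ids <- paste0("x", seq_len(l))
  structure(list(C = C, d = d, E = E, f = f,
                 nonneg = rep(TRUE, l), var_ids = as.character(var_ids)),
            class = "PolyhedronH")
}

#' @export
print.PolyhedronH <- function(x, ...) {
  cat(sprintf("PolyhedronH: %d equalities, %d inequalities, %d nonnegative variables\n",
              nrow(x$C$n), nrow(x$E$n), length(x$nonneg)))
  invisible(x)
}

#' Polyhedral cone H-representation
#'
#' `{y : G y = 0, H y >= 0}` over `l + 1` variables, the last one being the
#' homogenizing coordinate zeta; setting `zeta = 1` recovers the polyhedron
#' the cone was built from.
#'
#' @param G equality matrix.
#' @param H inequality matrix.
#' @param var_ids variable names (length `l + 1`).
#' @param zeta_index column of the homogenizing variable (always the last).
#' @return object of class `"ConeH"`.
#' @export
cone_hrep <- function(G, H, var_ids = NULL, zeta_index = NULL) {
  G <- rq(G); H <- rq(H)
  l1 <- if (nrow(G$n)) ncol(G$n) else ncol(H$n)
  stopifnot(nrow(H$n) == 0 || ncol(H$n) == l1)
  if (is.null(zeta_index)) zeta_index <- l1
  if (is.null(var_ids)) var_ids <- c(paste0("x", seq_len(l1 - 1)), "zeta")
  structure(list(G = G, H = H, var_ids = as.character(var_ids),
                 zeta_index = as.integer(zeta_index)),
            class = "ConeH")
}

#' @export
print.ConeH <- function(x, ...) {
  cat(sprintf("ConeH: %d equalities, %d inequalities, %d variables (zeta at %d)\n",
              nrow(x$G$n), nrow(x$H$n), length(x$var_ids), x$zeta_index))
  invisible(x)
}

#' Flux cone
#'
#' `{r : N r = 0, r >= 0}` — the steady-state flux cone of an
#' irreversible-reaction network; its extreme rays are the EFMs (after
#' two-cycle removal when the network was reversible-split).
#'
#' @param N `"rq"` stoichiometric matrix (m x n).
#' @param reaction_ids column names.
#' @return object of class `"FluxCone"`.
#' @export
flux_cone <- function(N, reaction_ids = NULL) {
  N <- rq(N)
  if (is.null(reaction_ids)) reaction_ids <- paste0("R", seq_len(ncol(N$n)))
  stopifnot(length(reaction_ids) == ncol(N$n))
  structure(list(N = N, reaction_ids = as.character(reaction_ids)),
            class = "FluxCone")
}

#' @export
print.FluxCone <- function(x, ...) {
  cat(sprintf("FluxCone: %d metabolites x %d reactions\n",
              nrow(x$N$n), ncol(x$N$n)))
  invisible(x)
}

# ---- transform record ------------------------------------------------------

#' Transformation record
#'
#' Bookkeeping that lets enumerated modes be mapped back to the original
#' reaction space: which original reaction maps to which forward/reverse
#' column pair after reversible splitting, where inequality slack columns
#' live, and where the homogenizing zeta column is.
#'
#' @param split_pairs named list: original id -> c(fwd = col, rev = col or NA).
#' @param slack_columns integer indices of slack (xi) variables.
#' @param zeta_column index of zeta or `NA`.
#' @param original_ids ordered original reaction ids.
#' @param split_ids column ids of the split space.
#' @return object of class `"TransformRecord"`.
#' @export
transform_record <- function(split_pairs, slack_columns = integer(0),
                             zeta_column = NA_integer_, original_ids,
                             split_ids = NULL) {
  idx <- c(unlist(lapply(split_pairs, function(p) p[!is.na(p)])),
           slack_columns, if (!is.na(zeta_column)) zeta_column)
  if (anyDuplicated(idx)) stop("transform record column indices overlap")
  if (!all(names(split_pairs) %in% original_ids) ||
      !all(original_ids %in% names(split_pairs))) {
    stop("split_pairs must map every original reaction id")
  }
  structure(list(split_pairs = split_pairs,
                 slack_columns = as.integer(slack_columns),
                 zeta_column = as.integer(zeta_column),
                 original_ids = as.character(original_ids),
                 split_ids = split_ids),
            class = "TransformRecord")
}

# ---- operations ------------------------------------------------------------

#' Split reversible reactions
#'
#' Replaces every reversible column `S_i` by the pair `S_i`, `-S_i`
#' (forward then reverse, the reverse inserted immediately after its
#' forward and suffixed `"_rev"`). Irreversible columns pass through. The
#' returned record maps each original reaction to its column(s).
#'
#' @param model `"MetabolicModel"`.
#' @return list with `model` (column-split, all-irreversible
#'   `"MetabolicModel"`) and `record` (`"TransformRecord"`).
#' @export
split_reversible <- function(model) {
  stopifnot(inherits(model, "MetabolicModel"))
  m <- length(model$metabolite_ids); n <- length(model$reaction_ids)
  cols_n <- list(); cols_d <- list(); ids <- character(0); pairs <- list()
  lbn <- numeric(0); lbd <- numeric(0); lbf <- logical(0)
  ubn <- numeric(0); ubd <- numeric(0); ubf <- logical(0)
  for (j in seq_len(n)) {
    id <- model$reaction_ids[j]
    k <- length(ids) + 1L
    cols_n[[k]] <- model$S$n[, j]; cols_d[[k]] <- model$S$d[, j]
    ids <- c(ids, id)
    if (model$rev[j]) {
      pairs[[id]] <- c(fwd = k, rev = k + 1L)
      cols_n[[k + 1L]] <- -model$S$n[, j]; cols_d[[k + 1L]] <- model$S$d[, j]
      ids <- c(ids, paste0(id, "_rev"))
      # forward keeps [0, ub]; reverse gets [0, -lb]
      lbn <- c(lbn, 0, 0); lbd <- c(lbd, 1, 1); lbf <- c(lbf, TRUE, TRUE)
      ubn <- c(ubn, model$ub$n[j], -model$lb$n[j])
      ubd <- c(ubd, model$ub$d[j], model$lb$d[j])
      ubf <- c(ubf, model$ub_finite[j], model$lb_finite[j])
    } else {
      pairs[[id]] <- c(fwd = k, rev = NA_integer_)
      lbn <- c(lbn, model$lb$n[j]); lbd <- c(lbd, model$lb$d[j]); lbf <- c(lbf, model$lb_finite[j])
      ubn <- c(ubn, model$ub$n[j]); ubd <- c(ubd, model$ub$d[j]); ubf <- c(ubf, model$ub_finite[j])
    }
  }
  Sn <- do.call(cbind, cols_n); Sd <- do.call(cbind, cols_d)
  lb <- .mkrq(lbn, lbd); attr(lb, "finite") <- lbf
  ub <- .mkrq(ubn, ubd); attr(ub, "finite") <- ubf
  split <- metabolic_model(.mkrq(Sn, Sd), model$metabolite_ids, ids,
                           rev = rep(FALSE, length(ids)), lb = lb, ub = ub)
  record <- transform_record(pairs, original_ids = model$reaction_ids,
                             split_ids = ids)
  list(model = split, record = record)
}

#' Build the flux polyhedron of a split model plus bounds
#'
#' Assembles `{v : S v = 0, E v >= f, v >= 0}` over the split (all
#' irreversible) reaction space: `C` is the split stoichiometric matrix with
#' `d = 0`, and each bounds-table row becomes one inequality row. A bound
#' on an originally reversible reaction constrains the *net* flux
#' `forward - reverse` via a two-entry row.
#'
#' @param split `"MetabolicModel"` after [split_reversible()] (or the list
#'   that function returns).
#' @param bounds `"BoundsTable"` over original reaction ids, or `NULL`.
#' @param record `"TransformRecord"` (needed when `bounds` touch split
#'   reactions; taken from `split` if a list is passed).
#' @return `"PolyhedronH"`.
#' @export
build_polyhedron <- function(split, bounds = NULL, record = NULL) {
  if (is.list(split) && !inherits(split, "MetabolicModel") &&
      all(c("model", "record") %in% names(split))) {
    record <- split$record
    split <- split$model
  }
  stopifnot(inherits(split, "MetabolicModel"))
  if (any(split$rev)) stop("model must be reversible-split first")
  n <- length(split$reaction_ids)
  En <- NULL; Ed <- NULL; fn <- numeric(0); fd <- numeric(0)
  if (!is.null(bounds) && length(bounds$reaction_id)) {
    for (k in seq_along(bounds$reaction_id)) {
      id <- bounds$reaction_id[k]
      row_n <- numeric(n); row_d <- rep(1, n)
      if (!is.null(record) && id %in% names(record$split_pairs)) {
        p <- record$split_pairs[[id]]
        row_n[p["fwd"]] <- 1
        if (!is.na(p["rev"])) row_n[p["rev"]] <- -1
      } else if (id %in% split$reaction_ids) {
        row_n[match(id, split$reaction_ids)] <- 1
      } else {
        stop("bound references unknown reaction id: ", id)
      }
      v <- rq_index(bounds$value, k)
      if (bounds$relation[k] == "<=") {
        row_n <- -row_n
        v <- rq_neg(v)
      }
      En <- rbind(En, unname(row_n), deparse.level = 0)
      Ed <- rbind(Ed, unname(row_d), deparse.level = 0)
      fn <- c(fn, v$n); fd <- c(fd, v$d)
    }
  }
  E <- if (is.null(En)) NULL else .mkrq(En, Ed)
  f <- if (is.null(En)) NULL else .mkrq(fn, fd)
  polyhedron_hrep(split$S, rq_zeros(nrow(split$S$n)), E, f,
                  var_ids = split$reaction_ids)
}

#' Homogenize a polyhedron into a polyhedral cone
#'
#' Embeds `{Cx = d, Ex >= f, x >= 0}` into one higher dimension with the
#' slack coordinate zeta: `G = (C | -d)`; `H` stacks `(E | -f)`, the
#' nonnegativity rows on the original variables, and the row `zeta >= 0`.
#' Any cone point with `zeta = 1` satisfies the original polyhedron exactly.
#'
#' @param P `"PolyhedronH"` or `"GeneralHRep"`.
#' @return `"ConeH"`.
#' @export
homogenize <- function(P) UseMethod("homogenize")

#' @export
homogenize.GeneralHRep <- function(P) {
  k <- nrow(P$A$n); l <- ncol(P$A$n)
  lin <- P$linearity
  ineq <- setdiff(seq_len(k), lin)
  G <- if (length(lin)) {
    rq_cbind(rq_index(P$A, lin, seq_len(l)),
             rq_as_matrix(rq_neg(rq_index(P$b, lin)), length(lin), 1))
  } else rq_zeros(0, l + 1)
  zeta_row <- rq(matrix(c(numeric(l), 1), 1, l + 1))
  H <- if (length(ineq)) {
    rq_rbind(rq_cbind(rq_index(P$A, ineq, seq_len(l)),
                      rq_as_matrix(rq_neg(rq_index(P$b, ineq)), length(ineq), 1)),
             zeta_row)
  } else zeta_row
  cone_hrep(G, H, var_ids = c(paste0("x", seq_len(l)), "zeta"),
            zeta_index = l + 1L)
}

#' @export
homogenize.PolyhedronH <- function(P) {
  l <- length(P$nonneg)
  G <- rq_cbind(P$C, rq_as_matrix(rq_neg(P$d), nrow(P$C$n), 1))
  H_top <- if (nrow(P$E$n)) {
    rq_cbind(P$E, rq_as_matrix(rq_neg(P$f), nrow(P$E$n), 1))
  } else NULL
  nonneg_rows <- rq_cbind(rq_eye(l), rq_zeros(l, 1))
  zeta_row <- rq(matrix(c(numeric(l), 1), 1, l + 1))
  H <- if (is.null(H_top)) rq_rbind(nonneg_rows, zeta_row) else
    rq_rbind(H_top, nonneg_rows, zeta_row)
  cone_hrep(G, H, var_ids = c(P$var_ids, "zeta"), zeta_index = l + 1L)
}

#' Embed a polyhedron as a flux cone via slack variables
#'
#' Builds `N = [[C, 0, -d], [E, -I, -f]]` over the variable order
#' `(x ..., xi ..., zeta)`: one nonnegative slack `xi` per inequality row
#' turns `E x >= f zeta` into an equality, and `zeta` homogenizes. The
#' record stores the slack and zeta columns for later projection.
#'
#' @param P `"PolyhedronH"`.
#' @return list with `cone` (`"FluxCone"`) and `record`
#'   (`"TransformRecord"` holding slack/zeta columns over polyhedron
#'   variables).
#' @export
to_flux_cone <- function(P) {
  stopifnot(inherits(P, "PolyhedronH"))
  l <- length(P$nonneg); k1 <- nrow(P$C$n); k2 <- nrow(P$E$n)
  top <- rq_cbind(P$C, rq_zeros(k1, k2),
                  rq_as_matrix(rq_neg(P$d), k1, 1))
  if (k2 > 0) {
    bot <- rq_cbind(P$E, rq_neg(rq_eye(k2)),
                    rq_as_matrix(rq_neg(P$f), k2, 1))
    N <- rq_rbind(top, bot)
  } else {
    N <- top
  }
  ids <- c(P$var_ids, if (k2) paste0("xi", seq_len(k2)), "zeta")
  pairs <- stats::setNames(
    lapply(seq_len(l), function(j) c(fwd = j, rev = NA_integer_)),
    P$var_ids)
  rec <- transform_record(pairs,
                          slack_columns = if (k2) l + seq_len(k2) else integer(0),
                          zeta_column = l + k2 + 1L,
                          original_ids = P$var_ids, split_ids = ids)
  list(cone = flux_cone(N, ids), record = rec)
}

#' Project homogenized modes back to the polyhedron
#'
#' Drops slack (`xi`) and `zeta` coordinates and classifies each mode:
#' `zeta > 0` rays are rescaled to `zeta = 1` and become vertices/EFVs;
#' `zeta = 0` rays are recession directions (EFMs), gcd-normalized.
#'
#' @param modes `"ModeSet"` over the cone variables (x..., [xi...,] zeta).
#' @param record `"TransformRecord"` carrying the zeta (and slack) columns,
#'   or `NULL` when the mode namespace itself ends in `"zeta"`.
#' @return `"ModeSet"` over the original x variables with kinds
#'   `"efv"`/`"efm"`.
#' @export
dehomogenize <- function(modes, record = NULL) {
  stopifnot(inherits(modes, "ModeSet"))
  ids <- modes$reaction_ids
  if (!is.null(record)) {
    zcol <- record$zeta_column
    drop <- c(record$slack_columns, zcol)
    keep <- setdiff(seq_along(ids), drop)
  } else {
    zcol <- length(ids)
    if (ids[zcol] != "zeta") stop("cannot locate zeta column")
    keep <- seq_len(zcol - 1L)
  }
  out_vals <- list(); kinds <- character(0)
  for (i in seq_len(mode_count(modes))) {
    v <- rq_row(modes$values, i)
    z <- rq_index(v, zcol)
    s <- rq_sign(z)
    if (s < 0) stop("mode with zeta < 0 violates the cone constraints")
    w <- rq_index(v, keep)
    if (s > 0) {
      w <- rq_div(w, z)
      kinds <- c(kinds, "efv")
    } else {
      w <- rq_int_normalize(w, sign_first = TRUE)
      kinds <- c(kinds, "efm")
    }
    out_vals[[length(out_vals) + 1L]] <- w
  }
  mode_set(out_vals, ids[keep], kinds)
}

# ---- pointedness -----------------------------------------------------------

# lineality space of {Gy=0, Hy>=0} is ker([G; H]); returns NULL if pointed,
# else one lineality vector
.lineality_witness <- function(G, H) {
  stacked <- if (nrow(G$n) && nrow(H$n)) rq_rbind(G, H)
             else if (nrow(G$n)) G else H
  K <- rq_kernel(stacked)
  if (ncol(K$n) == 0) return(NULL)
  rq_col(K, 1)
}

#' Check that a cone is pointed
#'
#' A cone `{Gy = 0, Hy >= 0}` is pointed iff its lineality space
#' `{y : Gy = 0, Hy = 0}` is trivial, i.e. `rank([G; H])` equals the
#' variable count. Enumeration engines require pointedness; a non-pointed
#' input is rejected with a lineality direction as witness.
#'
#' @param x `"ConeH"` or `"FluxCone"`.
#' @return `TRUE`, invisibly, or an error naming a lineality vector.
#' @export
assert_pointed <- function(x) {
  if (inherits(x, "FluxCone")) {
    G <- x$N; H <- rq_eye(ncol(x$N$n))
  } else if (inherits(x, "ConeH")) {
    G <- x$G; H <- x$H
  } else stop("assert_pointed expects ConeH or FluxCone")
  w <- .lineality_witness(G, H)
  if (!is.null(w)) {
    stop("cone is not pointed; lineality direction: (",
         paste(rq_format(w), collapse = ", "), ")", call. = FALSE)
  }
  invisible(TRUE)
}
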