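# Loss-free stoichiometric compression and exact decompression of modes.
#
# Four step kinds, applied to the signed (unsplit) model so the
# enzyme-subset sign logic can use direction information:
#   deadend_removal        - metabolites without producer or consumer force
#                            their incident reactions to zero (fixpoint);
#   kernel_blocked_removal - reactions with an all-zero kernel row are zero
#                            in every steady state;
#   enzyme_subset_merge    - reactions with pairwise proportional kernel
#                            rows carry proportional flux in every steady
#                            state and merge into one representative column;
#   dependent_row_removal  - metabolite rows linearly dependent on earlier
#                            rows are redundant conservation relations.
# Every step is recorded so modes of the compressed model decompress
# exactly onto the original reaction space.

#' Exact kernel of a stoichiometric matrix
#'
#' Columns form an exact rational basis of `{v : S v = 0}` (see
#' [rq_kernel()]); exposed under its domain name because the null space is
#' the shared primitive of the compression steps and the double
#' description start.
#'
#' @param S `"rq"` (or integer) matrix.
#' @return `"rq"` matrix of basis columns.
#' @export
rational_kernel <- function(S) rq_kernel(rq(S))

# internal: rebuild a model from parts
.mk_model <- function(S, mids, rids, rev, lb = NULL, ub = NULL) {
  metabolic_model(S, mids, rids, rev, lb = lb, ub = ub)
}

.subset_bounds <- function(model, keep) {
  lb <- rq_index(model$lb, keep); attr(lb, "finite") <- model$lb_finite[keep]
  ub <- rq_index(model$ub, keep); attr(ub, "finite") <- model$ub_finite[keep]
  list(lb = lb, ub = ub)
}

#' Remove dead-end metabolites
#'
#' Iterates to a fixpoint: a metabolite with no producer or no consumer
#' (reversible reactions count as both) forces all its incident reactions
#' to zero flux; those reactions and the metabolite are removed. Removing
#' reactions can orphan further metabolites, hence the fixpoint loop.
#'
#' @param model `"MetabolicModel"`.
#' @return list with `model` and `step` (a `deadend_removal` record, or
#'   `NULL` if nothing was removed).
#' @export
remove_deadend_metabolites <- function(model) {
  removed_mets <- character(0); removed_rxns <- character(0)
  repeat {
    Sn <- model$S$n
    m <- nrow(Sn); n <- ncol(Sn)
    if (m == 0 || n == 0) break
    has_prod <- logical(m); has_cons <- logical(m)
    for (i in seq_len(m)) {
      nz <- which(Sn[i, ] != 0)
      has_prod[i] <- any(Sn[i, nz] > 0 | model$rev[nz])
      has_cons[i] <- any(Sn[i, nz] < 0 | model$rev[nz])
    }
    dead <- which(!(has_prod & has_cons))
    if (!length(dead)) break
    kill_rxn <- which(colSums(abs(Sn[dead, , drop = FALSE])) > 0)
    removed_mets <- c(removed_mets, model$metabolite_ids[dead])
    removed_rxns <- c(removed_rxns, model$reaction_ids[kill_rxn])
    keep_m <- setdiff(seq_len(m), dead); keep_r <- setdiff(seq_len(n), kill_rxn)
    bnd <- .subset_bounds(model, keep_r)
    model <- .mk_model(rq_index(model$S, keep_m, keep_r),
                       model$metabolite_ids[keep_m], model$reaction_ids[keep_r],
                       model$rev[keep_r], bnd$lb, bnd$ub)
  }
  step <- if (length(removed_mets) || length(removed_rxns)) {
    list(kind = "deadend_removal",
         removed_metabolites = removed_mets, removed_reactions = removed_rxns)
  } else NULL
  list(model = model, step = step)
}

#' Remove reactions blocked in the kernel
#'
#' A reaction whose row in the kernel of `S` is identically zero has zero
#' flux in every steady state and is removed.
#'
#' @param model `"MetabolicModel"`.
#' @return list with `model` and `step` (`kernel_blocked_removal` or `NULL`).
#' @export
remove_blocked_by_kernel <- function(model) {
  n <- length(model$reaction_ids)
  K <- rq_kernel(model$S)
  blocked <- if (ncol(K$n) == 0) seq_len(n) else which(rowSums(K$n != 0) == 0)
  if (!length(blocked)) return(list(model = model, step = NULL))
  if (length(blocked) == n) {
    warning("all reactions blocked; model compresses to emptiness")
  }
  keep <- setdiff(seq_len(n), blocked)
  bnd <- .subset_bounds(model, keep)
  out <- .mk_model(rq_index(model$S, seq_along(model$metabolite_ids), keep),
                   model$metabolite_ids, model$reaction_ids[keep],
                   model$rev[keep], bnd$lb, bnd$ub)
  list(model = out,
       step = list(kind = "kernel_blocked_removal",
                   removed_reactions = model$reaction_ids[blocked]))
}

#' Merge enzyme subsets
#'
#' Reactions whose kernel rows are pairwise proportional carry fluxes in a
#' fixed ratio `c_j` in every steady state (an enzyme subset). Each subset
#' is replaced by one representative column `sum_j c_j S_j`. A negative
#' ratio between two irreversible members forces both fluxes to zero and
#' removes the whole subset. The merged reaction is reversible only if
#' every member is; the `c_j` are stored for decompression
#' (`v_j = c_j * v_merged`).
#'
#' @param model `"MetabolicModel"`.
#' @return list with `model` and `step` (`enzyme_subset_merge` carrying the
#'   merge table, or `NULL`).
#' @export
merge_enzyme_subsets <- function(model) {
  n <- length(model$reaction_ids); m <- length(model$metabolite_ids)
  if (n == 0) return(list(model = model, step = NULL))
  K <- rq_kernel(model$S)
  if (ncol(K$n) == 0) return(list(model = model, step = NULL))
  # group reactions by normalized kernel row (first nonzero scaled to 1)
  keys <- character(n); firstsign <- integer(n)
  for (j in seq_len(n)) {
    row <- rq_row(K, j)
    nz <- which(row$n != 0)
    if (!length(nz)) { keys[j] <- NA_character_; next }   # blocked; other step
    norm <- rq_div(row, rq_index(row, nz[1]))
    keys[j] <- paste(rq_format(norm), collapse = ",")
    firstsign[j] <- sign(row$n[nz[1]])
  }
  groups <- split(seq_len(n), keys)
  groups <- groups[vapply(groups, length, integer(1)) > 1]
  if (!length(groups)) return(list(model = model, step = NULL))

  merges <- list(); drop <- integer(0); blocked_sets <- list()
  newcols_n <- list(); newcols_d <- list(); newrev <- logical(0); newid <- character(0)
  for (g in groups) {
    g <- sort(g)
    rep_j <- g[1]
    # flux ratio of member j to representative: rows proportional, so the
    # ratio of any shared nonzero kernel coordinate gives c_j
    Krep <- rq_row(K, rep_j)
    nz <- which(Krep$n != 0)[1]
    cvals <- lapply(g, function(j) rq_div(rq_elt(K, j, nz), rq_elt(K, rep_j, nz)))
    irr <- !model$rev[g]
    sgn <- vapply(cvals, function(cv) rq_sign(cv), integer(1))
    if (any(irr & sgn > 0) && any(irr & sgn < 0)) {
      # irreversible members with opposite orientation: subset blocked
      blocked_sets[[length(blocked_sets) + 1L]] <- model$reaction_ids[g]
      drop <- c(drop, g)
      next
    }
    flip <- any(irr) && all(sgn[irr] < 0)
    if (flip) cvals <- lapply(cvals, rq_neg)
    # merged column = sum_j c_j S_j
    coln <- numeric(m); cold <- rep(1, m)
    for (t in seq_along(g)) {
      p <- .rq_mul0(model$S$n[, g[t]], model$S$d[, g[t]],
                    cvals[[t]]$n, cvals[[t]]$d)
      v <- .rq_add0(coln, cold, p$n, p$d)
      coln <- v$n; cold <- v$d
    }
    merges[[length(merges) + 1L]] <- list(
      representative = model$reaction_ids[rep_j],
      members = model$reaction_ids[g],
      coefficients = vapply(cvals, rq_format, character(1)))
    drop <- c(drop, g)
    newcols_n[[length(newcols_n) + 1L]] <- coln
    newcols_d[[length(newcols_d) + 1L]] <- cold
    newrev <- c(newrev, all(model$rev[g]))
    newid <- c(newid, model$reaction_ids[rep_j])
  }
  if (!length(drop)) return(list(model = model, step = NULL))

  keep <- setdiff(seq_len(n), drop)
  # merged columns are placed at the representative's position in order
  ord_ids <- model$reaction_ids
  all_n <- cbind(model$S$n[, keep, drop = FALSE], do.call(cbind, newcols_n))
  all_d <- cbind(model$S$d[, keep, drop = FALSE], do.call(cbind, newcols_d))
  all_ids <- c(model$reaction_ids[keep], newid)
  all_rev <- c(model$rev[keep], newrev)
  ord <- order(match(all_ids, ord_ids))
  out <- .mk_model(.mkrq(all_n[, ord, drop = FALSE], all_d[, ord, drop = FALSE]),
                   model$metabolite_ids, all_ids[ord], all_rev[ord])
  step <- list(kind = "enzyme_subset_merge", merges = merges,
               blocked_subsets = blocked_sets)
  list(model = out, step = step)
}

#' Remove linearly dependent metabolite rows
#'
#' Conservation relations make some metabolite rows linear combinations of
#' earlier ones; exact elimination finds and removes them. The kernel of
#' `S` (hence the steady-state flux space) is unchanged.
#'
#' @param model `"MetabolicModel"`.
#' @return list with `model` and `step` (`dependent_row_removal` or `NULL`).
#' @export
remove_dependent_rows <- function(model) {
  m <- length(model$metabolite_ids)
  if (m <= 1) return(list(model = model, step = NULL))
  rr <- rq_rref(rq_t(model$S))      # pivot columns of S' = independent rows of S
  indep <- rr$pivots
  if (length(indep) == m) return(list(model = model, step = NULL))
  dep <- setdiff(seq_len(m), indep)
  bnd <- .subset_bounds(model, seq_along(model$reaction_ids))
  out <- .mk_model(rq_index(model$S, indep, seq_along(model$reaction_ids)),
                   model$metabolite_ids[indep], model$reaction_ids,
                   model$rev, bnd$lb, bnd$ub)
  list(model = out,
       step = list(kind = "dependent_row_removal",
                   removed_metabolites = model$metabolite_ids[dep]))
}

#' Compress a metabolic model losslessly
#'
#' Applies dead-end removal, kernel-blocked removal, enzyme-subset merging
#' and dependent-row removal, in that order, looping until a full pass
#' changes nothing. The returned record replays the steps in application
#' order and suffices to decompress any mode of the compressed model back
#' to the original reaction space exactly.
#'
#' @param model `"MetabolicModel"`.
#' @return list with `model` (compressed) and `record`
#'   (`"CompressionRecord"`).
#' @export
compress_model <- function(model) {
  stopifnot(inherits(model, "MetabolicModel"))
  original_ids <- model$reaction_ids
  steps <- list()
  repeat {
    changed <- FALSE
    for (f in list(remove_deadend_metabolites, remove_blocked_by_kernel,
                   merge_enzyme_subsets, remove_dependent_rows)) {
      r <- f(model)
      if (!is.null(r$step)) {
        steps[[length(steps) + 1L]] <- r$step
        model <- r$model
        changed <- TRUE
      }
    }
    if (!changed) break
    if (length(model$reaction_ids) == 0) break
  }
  if (length(model$reaction_ids) == 0) {
    warning("model compresses to emptiness (no reaction can carry flux)")
  }
  record <- structure(list(steps = steps,
                           original_reaction_ids = original_ids),
                      class = "CompressionRecord")
  list(model = model, record = record)
}

#' Translate a bounds table through a compression record
#'
#' Rewrites bounds over original reaction ids into the compressed
#' namespace: a bound on a merged member `j` with `v_j = c_j v_rep` becomes
#' a bound on the representative with value `val / c_j` (relation flipped
#' when `c_j < 0`); a bound on a removed (always-zero) reaction is dropped
#' if satisfied by zero flux and is an error otherwise.
#'
#' @param bounds `"BoundsTable"` over original ids.
#' @param record `"CompressionRecord"`.
#' @return `"BoundsTable"` over compressed ids.
#' @export
translate_bounds <- function(bounds, record) {
  ids <- bounds$reaction_id
  rel <- bounds$relation
  vals <- lapply(seq_along(ids), function(i) rq_index(bounds$value, i))
  drop_zero <- function(i) {
    v <- vals[[i]]
    bad <- (rel[i] == ">=" && rq_sign(v) > 0) || (rel[i] == "<=" && rq_sign(v) < 0)
    if (bad) stop("bound on blocked reaction ", ids[i],
                  " is infeasible at zero flux", call. = FALSE)
    TRUE
  }
  for (step in record$steps) {
    removed <- character(0)
    if (step$kind %in% c("deadend_removal", "kernel_blocked_removal")) {
      removed <- step$removed_reactions
    } else if (step$kind == "enzyme_subset_merge") {
      removed <- unlist(step$blocked_subsets)
      for (mg in step$merges) {
        coef <- rq_parse(mg$coefficients)
        for (i in seq_along(ids)) {
          pos <- match(ids[i], mg$members)
          if (is.na(pos)) next
          cj <- rq_index(coef, pos)
          vals[[i]] <- rq_div(vals[[i]], cj)
          if (rq_sign(cj) < 0) rel[i] <- if (rel[i] == ">=") "<=" else ">="
          ids[i] <- mg$representative
        }
      }
    }
    if (length(removed)) {
      hit <- which(ids %in% removed)
      keep <- setdiff(seq_along(ids), hit[vapply(hit, drop_zero, logical(1))])
      ids <- ids[keep]; rel <- rel[keep]; vals <- vals[keep]
    }
  }
  if (!length(ids)) return(bounds_table(character(0), character(0), rq_zeros(0)))
  bounds_table(ids, rel, do.call(rq_c, vals))
}

#' Decompress modes to the original reaction space
#'
#' Inverts the compression record in reverse step order: merged reactions
#' distribute their flux to members as `c_j * v`, and reactions removed as
#' blocked or dead-end reappear with flux 0. Mode kinds are preserved.
#'
#' @param modes `"ModeSet"` over compressed reaction ids.
#' @param record `"CompressionRecord"` from [compress_model()] (with
#'   `original_reaction_ids` set, as [compress_model()] on the original
#'   model produces via the pipeline wrappers) or the original model's
#'   reaction ids in `original_ids`.
#' @param original_ids optional explicit original reaction id vector.
#' @return `"ModeSet"` over the original reaction ids.
#' @export
decompress_modes <- function(modes, record, original_ids = NULL) {
  stopifnot(inherits(modes, "ModeSet"), inherits(record, "CompressionRecord"))
  ids <- modes$reaction_ids
  k <- mode_count(modes)
  vals <- lapply(seq_len(k), function(i) rq_row(modes$values, i))
  for (step in rev(record$steps)) {
    if (step$kind == "enzyme_subset_merge") {
      for (mg in rev(step$merges)) {
        pos <- match(mg$representative, ids)
        if (is.na(pos)) stop("mode set references unknown compressed id: ",
                             mg$representative)
        coef <- rq_parse(mg$coefficients)
        before <- if (pos > 1) ids[1:(pos - 1)] else character(0)
        after <- if (pos < length(ids)) ids[(pos + 1):length(ids)] else character(0)
        ids <- c(before, mg$members, after)
        vals <- lapply(vals, function(v) {
          vm <- rq_index(v, pos)
          expanded <- rq_mul(coef, vm)
          rq_c(if (pos > 1) rq_index(v, 1:(pos - 1)) else rq_zeros(0),
               expanded,
               if (pos <= length(v$n) - 1) rq_index(v, (pos + 1):length(v$n))
               else rq_zeros(0))
        })
      }
      for (bs in step$blocked_subsets) {
        ids <- c(ids, bs)
        vals <- lapply(vals, function(v) rq_c(v, rq_zeros(length(bs))))
      }
    } else if (step$kind %in% c("deadend_removal", "kernel_blocked_removal")) {
      rr <- step$removed_reactions
      if (length(rr)) {
        ids <- c(ids, rr)
        vals <- lapply(vals, function(v) rq_c(v, rq_zeros(length(rr))))
      }
    }
    # dependent_row_removal does not touch reactions
  }
  target <- if (!is.null(original_ids)) original_ids else record$original_reaction_ids
  if (is.null(target)) target <- ids
  missing <- setdiff(target, ids)
  if (length(missing)) stop("record does not restore reaction(s): ",
                            paste(missing, collapse = ", "))
  perm <- match(target, ids)
  vals <- lapply(seq_along(vals), function(i) {
    v <- rq_index(vals[[i]], perm)
    # fractional merge coefficients can leave a ray on a rational scale;
    # rescale such rays to coprime integers (orientation is already fixed,
    # and integer-valued rays pass through unchanged)
    if (modes$kind[i] == "efm" && any(v$d != 1)) rq_int_normalize(v) else v
  })
  out <- mode_set(vals, target, modes$kind)
  out
}

# ---- record serialization --------------------------------------------------

#' Write a compression record as JSON
#' @param record `"CompressionRecord"`.
#' @param path file path.
#' @export
write_compression_record <- function(record, path) {
  stopifnot(inherits(record, "CompressionRecord"))
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a compression record from JSON
#' @param path file path.
#' @return `"CompressionRecord"`.
#' @export
read_compression_record <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  steps <- lapply(x$steps, function(s) {
    s$kind <- as.character(s$kind)
    s
  })
  structure(list(steps = steps,
                 original_reaction_ids = unlist(x$original_reaction_ids)),
            class = "CompressionRecord")
}
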