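# Post-processing of raw enumerator output: two-cycle removal, merging of
# split reversible pairs back to signed fluxes, exact deduplication with a
# multiplicity report, and the downstream analytics (yields, support
# distances).

#' Remove two-cycle modes
#'
#' Drops exactly those modes whose support equals the `{forward, reverse}`
#' pair of one split reversible reaction — the artifactual futile cycles
#' introduced by reversible splitting. A genuine two-reaction cycle between
#' different reactions is retained.
#'
#' @param modes `"ModeSet"` over the split reaction space.
#' @param record `"TransformRecord"` from [split_reversible()].
#' @return `"ModeSet"` without two-cycle modes.
#' @export
filter_two_cycles <- function(modes, record) {
  stopifnot(inherits(modes, "ModeSet"), inherits(record, "TransformRecord"))
  pair_keys <- vapply(record$split_pairs, function(p) {
    if (is.na(p["rev"])) NA_character_ else
      paste(sort(c(p["fwd"], p["rev"])), collapse = ",")
  }, character(1))
  pair_keys <- pair_keys[!is.na(pair_keys)]
  keep <- vapply(seq_len(mode_count(modes)), function(i) {
    supp <- which(modes$values$n[i, ] != 0)
    !(length(supp) == 2 && paste(supp, collapse = ",") %in% pair_keys)
  }, logical(1))
  mode_set(rq_index(modes$values, which(keep)), modes$reaction_ids,
           modes$kind[keep])
}

#' Merge split reaction pairs back to signed fluxes
#'
#' Maps modes over the split (all-irreversible) space back to the original
#' signed reaction space: original value = forward - reverse. Since an
#' elementary mode uses at most one direction of a reversible reaction,
#' both halves positive in one mode signals an enumerator inconsistency
#' (after two-cycle filtering) and raises an error.
#'
#' @param modes `"ModeSet"` over split reaction ids (two-cycles already
#'   filtered).
#' @param record `"TransformRecord"` from [split_reversible()].
#' @return `"ModeSet"` over original reaction ids, signed values.
#' @export
merge_split_pairs <- function(modes, record) {
  stopifnot(inherits(modes, "ModeSet"), inherits(record, "TransformRecord"))
  orig <- record$original_ids
  k <- mode_count(modes)
  vals <- vector("list", k)
  for (i in seq_len(k)) {
    v <- rq_row(modes$values, i)
    out <- rq_zeros(length(orig))
    for (t in seq_along(orig)) {
      p <- record$split_pairs[[orig[t]]]
      fwd <- rq_index(v, p[["fwd"]])
      if (!is.na(p[["rev"]])) {
        rev_ <- rq_index(v, p[["rev"]])
        if (rq_sign(fwd) > 0 && rq_sign(rev_) > 0) {
          stop("mode ", i, " uses both directions of reaction ", orig[t],
               " (not a two-cycle); enumerator inconsistency", call. = FALSE)
        }
        out <- rq_set(out, t, NULL, rq_sub(fwd, rev_))
      } else {
        out <- rq_set(out, t, NULL, fwd)
      }
    }
    vals[[i]] <- out
  }
  mode_set(vals, orig, modes$kind)
}

#' Deduplicate modes with a multiplicity report
#'
#' Removes exact duplicates (identical rational vectors) and reports the
#' emission count of each unique mode plus the overall mean multiplicity —
#' the quantity that distinguishes the polyhedron formulation (duplicates
#' possible) from the cone formulations (unique output).
#'
#' @param modes `"ModeSet"`.
#' @return list with `modes` (unique `"ModeSet"`) and `report` (data.frame
#'   `mode`/`count` plus attribute-free `mean_multiplicity` entry in a
#'   list).
#' @export
dedupe_modes <- function(modes) {
  keys <- mode_keys(modes)
  k <- length(keys)
  if (k == 0) {
    return(list(modes = modes,
                report = list(counts = integer(0), mean_multiplicity = NA_real_)))
  }
  first <- !duplicated(keys)
  counts <- as.integer(table(factor(keys, levels = keys[first])))
  uniq <- mode_set(rq_index(modes$values, which(first)),
                   modes$reaction_ids, modes$kind[first])
  list(modes = uniq,
       report = list(counts = counts,
                     mean_multiplicity = k / sum(first)))
}

#' Per-mode yields of a target on a substrate
#'
#' `yield_i = value(target) / value(substrate)` for every mode with nonzero
#' substrate flux; modes with zero substrate flux are excluded and counted.
#' Yields are exact rationals; binning for a histogram is left to the
#' caller.
#'
#' @param modes `"ModeSet"`.
#' @param substrate_id,target_id reaction ids (e.g. glucose uptake and
#'   biomass).
#' @return list with `yields` (data.frame: mode index, yield string, yield
#'   numeric) and `excluded` (count of zero-substrate modes).
#' @export
compute_yields <- function(modes, substrate_id, target_id) {
  s <- match(substrate_id, modes$reaction_ids)
  t <- match(target_id, modes$reaction_ids)
  if (is.na(s)) stop("unknown substrate id: ", substrate_id)
  if (is.na(t)) stop("unknown target id: ", target_id)
  idx <- integer(0); ystr <- character(0); ynum <- numeric(0)
  excluded <- 0L
  for (i in seq_len(mode_count(modes))) {
    sv <- rq_elt(modes$values, i, s)
    if (sv$n == 0) { excluded <- excluded + 1L; next }
    y <- rq_div(rq_elt(modes$values, i, t), sv)
    idx <- c(idx, i); ystr <- c(ystr, rq_format(y)); ynum <- c(ynum, rq_to_double(y))
  }
  list(yields = data.frame(mode = idx, yield = ystr, value = ynum,
                           stringsAsFactors = FALSE),
       excluded = excluded)
}

#' Pairwise support distances between modes
#'
#' Entry `(i, j)` is the size of the symmetric difference of the supports
#' of modes `i` and `j` — the number of reactions in which they differ —
#' as visualized in similarity heat maps of near-identical high-yield EFMs.
#'
#' @param modes `"ModeSet"`.
#' @return symmetric integer matrix with zero diagonal.
#' @export
support_distance_matrix <- function(modes) {
  k <- mode_count(modes)
  S <- modes$values$n != 0
  D <- matrix(0L, k, k)
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      d <- sum(xor(S[i, ], S[j, ]))
      D[i, j] <- d; D[j, i] <- d
    }
  }
  D
}
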