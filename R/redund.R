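# Redundancy removal: drop inequality rows whose removal provably leaves
# the feasible set unchanged (the function lrs ships as `redund`).

#' Remove redundant inequality rows
#'
#' An inequality row `a x >= b` is redundant iff minimizing `a x` subject
#' to all *other* constraints still yields an optimum `>= b`. Rows are
#' scanned in ascending index order, each test running against the
#' surviving set, so duplicated rows lose exactly one copy per pass and
#' the result is deterministic. Equality (linearity) rows and the implicit
#' nonnegativity block of a `"PolyhedronH"` are never candidates.
#'
#' @param obj `"GeneralHRep"`, `"ConeH"` or `"PolyhedronH"`.
#' @return list with `object` (same class, redundant rows removed) and
#'   `removed` (indices into the object's inequality rows).
#' @export
remove_redundant_rows <- function(obj) {
  h <- .as_hview(obj)
  A <- h$A; b <- h$b; lin <- h$linearity
  k <- nrow(A$n); l <- ncol(A$n)
  # candidate rows: the object's explicit inequality rows
  cand <- if (inherits(obj, "GeneralHRep")) {
    setdiff(seq_len(k), lin)
  } else if (inherits(obj, "ConeH")) {
    nrow(obj$G$n) + seq_len(nrow(obj$H$n))
  } else {       # PolyhedronH: only the E block
    nrow(obj$C$n) + seq_len(nrow(obj$E$n))
  }

  # feasibility up front: an infeasible system is an error, never emptied
  feas <- rq_lp(rq_zeros(l),
                A_ge = rq_index(A, setdiff(seq_len(k), lin), seq_len(l)),
                b_ge = rq_index(b, setdiff(seq_len(k), lin)),
                A_eq = if (length(lin)) rq_index(A, lin, seq_len(l)) else NULL,
                b_eq = if (length(lin)) rq_index(b, lin) else NULL,
                nonneg = FALSE)
  if (feas$status == "infeasible") {
    stop("system is infeasible; refusing to remove rows", call. = FALSE)
  }

  alive <- rep(TRUE, k)
  removed <- integer(0)
  for (i in cand) {
    others <- setdiff(which(alive), i)
    ineq <- setdiff(others, lin)
    r <- rq_lp(rq_row(A, i),
               A_ge = if (length(ineq)) rq_index(A, ineq, seq_len(l)) else NULL,
               b_ge = if (length(ineq)) rq_index(b, ineq) else NULL,
               A_eq = if (length(lin)) rq_index(A, lin, seq_len(l)) else NULL,
               b_eq = if (length(lin)) rq_index(b, lin) else NULL,
               nonneg = FALSE, maximize = FALSE)
    if (r$status == "optimal" && rq_cmp(r$value, rq_index(b, i)) >= 0) {
      alive[i] <- FALSE
      removed <- c(removed, i)
    }
  }

  if (!length(removed)) return(list(object = obj, removed = integer(0)))

  if (inherits(obj, "GeneralHRep")) {
    keep <- which(alive)
    newlin <- match(lin, keep)
    out <- general_hrep(rq_index(A, keep, seq_len(l)), rq_index(b, keep),
                        linearity = newlin[!is.na(newlin)])
    rem_rel <- removed
  } else if (inherits(obj, "ConeH")) {
    ng <- nrow(obj$G$n)
    keepH <- which(alive[ng + seq_len(nrow(obj$H$n))])
    out <- cone_hrep(obj$G, rq_index(obj$H, keepH, seq_len(l)),
                     var_ids = obj$var_ids, zeta_index = obj$zeta_index)
    rem_rel <- removed - ng
  } else {
    k1 <- nrow(obj$C$n)
    keepE <- which(alive[k1 + seq_len(nrow(obj$E$n))])
    out <- polyhedron_hrep(obj$C, obj$d,
                           if (length(keepE)) rq_index(obj$E, keepE,
                                                       seq_len(length(obj$nonneg)))
                           else NULL,
                           if (length(keepE)) rq_index(obj$f, keepE) else NULL,
                           var_ids = obj$var_ids)
    rem_rel <- removed - k1
  }
  list(object = out, removed = rem_rel)
}
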