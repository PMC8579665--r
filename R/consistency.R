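# Flux-variability-style consistency preprocessing: remove reactions that
# can never carry flux at steady state, fix the direction of reversible
# reactions that only ever run one way, drop orphaned metabolites.

#' Make a model consistent
#'
#' For every reaction the pair of linear programs max/min `v_i` subject to
#' `S v = 0` and box bounds (defaults `[0, M]` for irreversible, `[-M, M]`
#' for reversible reactions, intersected with any finite model bounds) is
#' solved with the package's exact rational simplex. Reactions whose flux
#' range is exactly `{0}` are removed (blocked); reversible reactions with
#' minimum 0 become irreversible forward; reversible reactions with maximum
#' 0 have their column sign flipped and become irreversible. Metabolites
#' left without any incident reaction are dropped.
#'
#' Because the LPs are solved exactly, `tol` plays no role in the decisions;
#' it is retained in the interface for compatibility with float-LP
#' implementations of the same preprocessing.
#'
#' @param model `"MetabolicModel"`.
#' @param M box constant bounding all fluxes in the LPs (default 1000).
#' @param tol unused by the exact implementation; kept for interface
#'   stability.
#' @return list with `model` (the consistent model) and `report` (lists of
#'   `removed_reactions`, `made_irreversible`, `flipped`,
#'   `removed_metabolites`).
#' @export
make_consistent <- function(model, M = 1000, tol = 1e-9) {
  stopifnot(inherits(model, "MetabolicModel"))
  n <- length(model$reaction_ids); m <- length(model$metabolite_ids)
  Mq <- rq(M)

  lo <- rq_zeros(n); hi <- rq_zeros(n)
  for (j in seq_len(n)) {
    l <- if (model$rev[j]) rq_neg(Mq) else rq(0)
    if (model$lb_finite[j] && rq_cmp(rq_index(model$lb, j), l) > 0) {
      l <- rq_index(model$lb, j)
    }
    h <- Mq
    if (model$ub_finite[j] && rq_cmp(rq_index(model$ub, j), h) < 0) {
      h <- rq_index(model$ub, j)
    }
    lo <- rq_set(lo, j, NULL, l); hi <- rq_set(hi, j, NULL, h)
  }

  # inequalities: v >= lo  and  -v >= -hi
  A_ge <- rq_rbind(rq_eye(n), rq_neg(rq_eye(n)))
  b_ge <- rq_c(lo, rq_neg(hi))
  zer <- rq_zeros(m)

  vmax <- rq_zeros(n); vmin <- rq_zeros(n)
  for (j in seq_len(n)) {
    obj <- rq_zeros(n); obj <- rq_set(obj, j, NULL, rq(1))
    for (sense in c(TRUE, FALSE)) {
      r <- tryCatch(
        rq_lp(obj, A_ge = A_ge, b_ge = b_ge, A_eq = model$S, b_eq = zer,
              nonneg = FALSE, maximize = sense),
        error = function(e) stop("LP failure for reaction ",
                                 model$reaction_ids[j], ": ",
                                 conditionMessage(e), call. = FALSE))
      if (r$status != "optimal") {
        stop("LP for reaction ", model$reaction_ids[j],
             " returned status '", r$status, "' (box-bounded LP must be optimal)",
             call. = FALSE)
      }
      if (sense) vmax <- rq_set(vmax, j, NULL, r$value)
      else vmin <- rq_set(vmin, j, NULL, r$value)
    }
  }

  blocked <- rq_is_zero(vmax) & rq_is_zero(vmin)
  fwd_only <- model$rev & !blocked & (rq_sign(vmin) >= 0)
  bwd_only <- model$rev & !blocked & (rq_sign(vmax) <= 0) & !fwd_only

  keep <- which(!blocked)
  S2 <- rq_index(model$S, seq_len(m), keep)
  rev2 <- model$rev[keep]
  lb2 <- rq_index(model$lb, keep); ub2 <- rq_index(model$ub, keep)
  lbf2 <- model$lb_finite[keep]; ubf2 <- model$ub_finite[keep]
  ids2 <- model$reaction_ids[keep]

  for (k in seq_along(keep)) {
    j <- keep[k]
    if (fwd_only[j]) {
      rev2[k] <- FALSE
      if (!lbf2[k] || rq_sign(rq_index(lb2, k)) < 0) {
        lb2 <- rq_set(lb2, k, NULL, rq(0)); lbf2[k] <- TRUE
      }
    } else if (bwd_only[j]) {
      # flip column sign: flux runs only backwards, re-orient forward
      S2 <- rq_set(S2, seq_len(m), k, rq_neg(rq_index(S2, seq_len(m), k)))
      rev2[k] <- FALSE
      old_lb <- rq_index(lb2, k); old_ub <- rq_index(ub2, k)
      old_lbf <- lbf2[k]; old_ubf <- ubf2[k]
      lb2 <- rq_set(lb2, k, NULL, if (old_ubf) rq_neg(old_ub) else rq(0))
      lbf2[k] <- TRUE
      ub2 <- rq_set(ub2, k, NULL, if (old_lbf) rq_neg(old_lb) else rq(0))
      ubf2[k] <- old_lbf
      if (!old_ubf || rq_sign(rq_index(lb2, k)) < 0) {
        lb2 <- rq_set(lb2, k, NULL, rq(0))
      }
    }
  }

  incident <- rowSums(S2$n != 0) > 0
  met_keep <- which(incident)
  S3 <- rq_index(S2, met_keep, seq_along(keep))
  attr(lb2, "finite") <- lbf2
  attr(ub2, "finite") <- ubf2
  out <- metabolic_model(S3, model$metabolite_ids[met_keep], ids2, rev2,
                         lb = lb2, ub = ub2,
                         objective_id = if (!is.null(model$objective_id) &&
                                            model$objective_id %in% ids2)
                           model$objective_id else NULL)
  report <- list(
    removed_reactions = model$reaction_ids[blocked],
    made_irreversible = model$reaction_ids[fwd_only],
    flipped = model$reaction_ids[bwd_only],
    removed_metabolites = model$metabolite_ids[!incident]
  )
  list(model = out, report = report)
}
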