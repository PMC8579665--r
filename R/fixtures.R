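# Programmatic test fixtures: classic polytopes with known vertex counts,
# a toy branched metabolic network, seeded random flux cones, and nested
# uptake-series model families. Identical parameters always reproduce
# bit-identical fixtures.

#' Permutahedron H-representation
#'
#' The order-`n` permutahedron: points in `R^n` whose coordinates are
#' permutations of `1..n`. One linearity row fixes the total coordinate sum
#' to `n(n+1)/2`; every proper nonempty subset `S` of coordinates yields the
#' facet inequality `sum_{i in S} x_i >= 1 + 2 + ... + |S|`. Vertex count is
#' `n!` and the polytope is simple. Subset rows are generated in ascending
#' bitmask order so the file layout is deterministic.
#'
#' @param n order, between 2 and 10.
#' @return `"GeneralHRep"` with `2^n - 2` inequalities plus one linearity.
#' @export
permutahedron <- function(n) {
  if (!(n >= 2 && n <= 10)) stop("permutahedron order must be in 2..10")
  nsub <- 2^n - 2
  An <- matrix(0, nsub + 1, n)
  bn <- numeric(nsub + 1)
  for (mask in seq_len(nsub)) {
    members <- which(bitwAnd(mask, bitwShiftL(1, 0:(n - 1))) != 0)
    An[mask, members] <- 1
    k <- length(members)
    bn[mask] <- k * (k + 1) / 2
  }
  An[nsub + 1, ] <- 1
  bn[nsub + 1] <- n * (n + 1) / 2
  general_hrep(rq(An), rq(bn), linearity = nsub + 1L)
}

#' Birkhoff polytope H-representation
#'
#' The polytope of `n x n` doubly stochastic matrices: `n^2` nonnegative
#' variables (row-major order `x_11, x_12, ...`), with `2n` linearity rows
#' forcing each row sum and column sum to 1. By Birkhoff-von Neumann its
#' vertices are exactly the `n!` permutation matrices. Highly degenerate
#' for `n >= 3`.
#'
#' @param n matrix order, between 2 and 7.
#' @return `"GeneralHRep"` with `n^2` nonnegativity rows and `2n` linearities.
#' @export
birkhoff <- function(n) {
  if (!(n >= 2 && n <= 7)) stop("birkhoff order must be in 2..7")
  nv <- n * n
  idx <- function(i, j) (i - 1) * n + j
  An <- rbind(diag(nv), matrix(0, 2 * n, nv))
  bn <- c(numeric(nv), rep(1, 2 * n))
  for (i in seq_len(n)) An[nv + i, idx(i, seq_len(n))] <- 1       # row sums
  for (j in seq_len(n)) An[nv + n + j, idx(seq_len(n), j)] <- 1   # col sums
  general_hrep(rq(An), rq(bn), linearity = nv + seq_len(2 * n))
}

#' Toy branched metabolic network
#'
#' Three metabolites A, B, C and five reactions: an uptake `R1: -> A`, two
#' branches `R2: A -> B` (irreversible) and `R3: A <-> C` (reversible), and
#' two exports `R4: B ->`, `R5: C ->`. After two-cycle removal the network
#' has exactly two EFMs: `{R1, R2, R4}` and `{R1, R3, R5}`.
#'
#' @return `"MetabolicModel"`.
#' @export
toy_branch <- function() {
  S <- matrix(c(
    #R1 R2  R3  R4  R5
     1, -1, -1,  0,  0,   # A
     0,  1,  0, -1,  0,   # B
     0,  0,  1,  0, -1    # C
  ), nrow = 3, byrow = TRUE)
  metabolic_model(rq(S), c("A", "B", "C"), paste0("R", 1:5),
                  rev = c(FALSE, FALSE, TRUE, FALSE, FALSE))
}

#' Seeded random flux cone
#'
#' Sparse integer stoichiometry with entries in `{-3..3}`, reproducible from
#' the seed. Every row and column is guaranteed at least one nonzero entry
#' so the instance is not trivially empty. Reactions are all irreversible
#' (the flux-cone setting); degeneracy varies across seeds.
#'
#' @param m metabolites (rows), `m < n`.
#' @param n reactions (columns), at most 14.
#' @param density expected fraction of nonzero entries.
#' @param seed integer seed.
#' @return `"FluxCone"`.
#' @export
random_flux_cone <- function(m, n, density = 0.4, seed = 1) {
  if (!(m < n && n <= 14 && m >= 1)) {
    stop("random_flux_cone requires m < n <= 14")
  }
  rng <- .fm_rng(seed)
  N <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    if (rng() < density) {
      v <- floor(rng() * 7) - 3  # in -3..3
      N[i, j] <- v
    }
  }
  # ensure no all-zero row/column (deterministic repair)
  for (i in seq_len(m)) if (all(N[i, ] == 0)) {
    j <- 1 + (i - 1) %% n
    N[i, j] <- 1
    N[i, 1 + j %% n] <- -1
  }
  for (j in seq_len(n)) if (all(N[, j] == 0)) {
    i <- 1 + (j - 1) %% m
    N[i, j] <- if (j %% 2 == 0) -1 else 1
  }
  flux_cone(rq(N), paste0("R", seq_len(n)))
}

# small deterministic PRNG (Park-Miller), independent of R's RNG state so
# fixtures never perturb or depend on the session RNG
.fm_rng <- function(seed) {
  state <- (as.numeric(seed) %% 2147483646) + 1
  function() {
    state <<- (state * 16807) %% 2147483647
    state / 2147483647
  }
}

#' Nested uptake-reaction model series
#'
#' Builds the family `model_0 .. model_k` where `model_0` removes all the
#' listed uptake reactions and `model_i` adds the first `i` of them back.
#' Each listed reaction must be an uptake: a column with exactly one
#' nonzero, positive stoichiometric entry. The EFM sets of successive
#' models are nested (zero-padded), since adding an uptake only enlarges
#' the feasible flux cone.
#'
#' @param model `"MetabolicModel"`.
#' @param ordered_uptake_ids character vector of uptake reaction ids.
#' @return list of `length(ordered_uptake_ids) + 1` models.
#' @export
nested_uptake_series <- function(model, ordered_uptake_ids) {
  stopifnot(inherits(model, "MetabolicModel"))
  ids <- as.character(ordered_uptake_ids)
  unknown <- setdiff(ids, model$reaction_ids)
  if (length(unknown)) stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  for (id in ids) {
    j <- match(id, model$reaction_ids)
    col <- model$S$n[, j]
    if (sum(col != 0) != 1 || col[col != 0] <= 0) {
      stop("reaction ", id, " is not an uptake (needs exactly one positive entry)")
    }
  }
  drop_cols <- function(m, drop_ids) {
    keep <- which(!(m$reaction_ids %in% drop_ids))
    lb <- rq_index(m$lb, keep); attr(lb, "finite") <- m$lb_finite[keep]
    ub <- rq_index(m$ub, keep); attr(ub, "finite") <- m$ub_finite[keep]
    metabolic_model(rq_index(m$S, seq_along(m$metabolite_ids), keep),
                    m$metabolite_ids, m$reaction_ids[keep], m$rev[keep],
                    lb = lb, ub = ub)
  }
  lapply(0:length(ids), function(i) {
    if (i == length(ids)) {
      if (i == 0) model else drop_cols(model, character(0))
    } else {
      drop_cols(model, ids[(i + 1):length(ids)])
    }
  })
}
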