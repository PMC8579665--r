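# Post-processing: two-cycle filtering, split merging, dedupe, analytics.

.toy_modes <- function() {
  sp <- split_reversible(toy_branch())
  fc <- flux_cone(sp$model$S, sp$model$reaction_ids)
  list(sp = sp, modes = enumerate_efms_ddm(fc))
}

test_that("filter_two_cycles removes exactly the split-pair mode", {
  x <- .toy_modes()
  filtered <- filter_two_cycles(x$modes, x$sp$record)
  expect_identical(mode_count(x$modes) - mode_count(filtered), 1L)
  expect_identical(mode_count(filtered), 2L)
  # model with no reversible reactions: identity
  m0 <- metabolic_model(rq(matrix(c(1, -1), 1, 2)), "A", c("a", "b"),
                        rev = c(FALSE, FALSE))
  sp0 <- split_reversible(m0)
  ms0 <- enumerate_efms_ddm(flux_cone(sp0$model$S, sp0$model$reaction_ids))
  expect_identical(mode_count(filter_two_cycles(ms0, sp0$record)),
                   mode_count(ms0))
})

test_that("a genuine 2-cycle between different reactions is retained", {
  # A -> B by r1, B -> A by r2: a real cycle, not a split pair
  m <- metabolic_model(rq(matrix(c(1, -1, -1, 1), 2, 2)), c("A", "B"),
                       c("r1", "r2"), rev = c(FALSE, FALSE))
  sp <- split_reversible(m)
  ms <- enumerate_efms_ddm(flux_cone(sp$model$S, sp$model$reaction_ids))
  expect_identical(mode_count(ms), 1L)
  expect_identical(mode_count(filter_two_cycles(ms, sp$record)), 1L)
})

test_that("merge_split_pairs signs reverse flux and detects inconsistency", {
  x <- .toy_modes()
  sp <- x$sp
  # reverse-direction mode: R3_rev = 2 -> original R3 = -2
  ms <- mode_set(list(rq(c(1, 0, 0, 2, 0, 2))), sp$model$reaction_ids, "efm",
                 canonicalize = FALSE)
  merged <- merge_split_pairs(ms, sp$record)
  expect_equal(as.vector(merged$values$n), c(1, 0, -2, 0, 2))
  # all-forward mode passes through unchanged
  ms2 <- mode_set(list(rq(c(1, 1, 0, 0, 1, 0))), sp$model$reaction_ids, "efm",
                  canonicalize = FALSE)
  expect_equal(as.vector(merge_split_pairs(ms2, sp$record)$values$n),
               c(1, 1, 0, 1, 0))
  # both directions positive: enumerator bug signalled
  bad <- mode_set(list(rq(c(1, 0, 1, 1, 0, 2))), sp$model$reaction_ids, "efm",
                  canonicalize = FALSE)
  expect_error(merge_split_pairs(bad, sp$record), "both directions")
  # end-to-end: 2 signed EFMs over the 5 original reactions
  full <- merge_split_pairs(filter_two_cycles(x$modes, sp$record), sp$record)
  expect_identical(mode_count(full), 2L)
  expect_identical(full$reaction_ids, paste0("R", 1:5))
})

test_that("dedupe_modes counts emission multiplicity", {
  base <- oracle_efms(toy_branch())
  doubled <- mode_set(rq_index(base$values, rep(seq_len(mode_count(base)), 2)),
                      base$reaction_ids,
                      rep(base$kind, 2), canonicalize = FALSE)
  dd <- dedupe_modes(doubled)
  expect_identical(mode_count(dd$modes), mode_count(base))
  expect_equal(dd$report$mean_multiplicity, 2)
  dd2 <- dedupe_modes(base)
  expect_equal(dd2$report$mean_multiplicity, 1)
})

test_that("yields are exact rationals with zero-substrate exclusion", {
  efms <- oracle_efms(toy_branch())
  y <- compute_yields(efms, "R1", "R4")
  expect_setequal(y$yields$yield, c("0", "1"))
  expect_identical(y$excluded, 0L)
  # mode with substrate 2, target 1 -> 1/2; zero substrate excluded
  ms <- mode_set(list(rq(c(2, 1)), rq(c(0, 3))), c("s", "t"), "efm",
                 canonicalize = FALSE)
  y2 <- compute_yields(ms, "s", "t")
  expect_identical(y2$yields$yield, "1/2")
  expect_identical(y2$excluded, 1L)
  expect_error(compute_yields(ms, "nope", "t"), "unknown")
})

test_that("support distances are symmetric-difference sizes", {
  ms <- mode_set(list(rq(c(1, 1, 1, 0)), rq(c(1, 1, 0, 1)), rq(c(1, 1, 1, 0))),
                 letters[1:4], "efm", canonicalize = FALSE)
  D <- support_distance_matrix(ms)
  expect_identical(diag(D), c(0L, 0L, 0L))
  expect_identical(D[1, 2], 2L)   # {a,b,c} vs {a,b,d}
  expect_identical(D[1, 3], 0L)
  expect_true(isSymmetric(D))
  # toy_branch's two EFMs differ in 4 reactions (R1 shared)
  efms <- oracle_efms(toy_branch())
  expect_identical(support_distance_matrix(efms)[1, 2], 4L)
})

test_that("modes TSV round trips exactly", {
  efms <- oracle_efms(toy_branch())
  p <- withr::local_tempfile(fileext = ".tsv")
  write_modes_tsv(efms, p)
  back <- read_modes_tsv(p)
  expect_true(mode_sets_equal(back, efms))
})
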