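# Loss-free compression steps and exact decompression.

test_that("rational_kernel satisfies the kernel contract", {
  K <- rational_kernel(rq(matrix(c(1, -1), 1, 2)))
  expect_equal(as.vector(K$n), c(1, 1))
  K2 <- rational_kernel(rq_zeros(2, 3))
  expect_identical(dim(K2$n), c(3L, 3L))
})

test_that("dead-end removal iterates to a fixpoint", {
  # D produced by R6 but never consumed -> R6 and D go
  m <- metabolic_model(rq(matrix(c(1, 0, -1, 0, 0, 1), 2, 3)),
                       c("A", "D"), c("R1", "R2", "R6"), rep(FALSE, 3))
  r <- remove_deadend_metabolites(m)
  expect_identical(r$step$removed_metabolites, "D")
  expect_identical(r$step$removed_reactions, "R6")
  # toy_branch: every metabolite has producer and consumer
  r2 <- remove_deadend_metabolites(toy_branch())
  expect_null(r2$step)
  # cascade: A -> B -> E, E unconsumed; removing E's producer orphans B
  S <- matrix(c(
    1, -1,  0,    # A: in, conv1
    0,  1, -1,    # B: conv1, conv2
    0,  0,  1     # E: conv2 (never consumed)
  ), 3, 3, byrow = TRUE)
  m3 <- metabolic_model(rq(S), c("A", "B", "E"),
                        c("in", "conv1", "conv2"), rep(FALSE, 3))
  r3 <- remove_deadend_metabolites(m3)
  expect_setequal(r3$step$removed_metabolites, c("A", "B", "E"))
  expect_identical(ncol(r3$model$S$n), 0L)
})

test_that("kernel-blocked reactions are removed", {
  # "dead" produces B which has no outlet: its kernel row is zero
  S <- matrix(c(
    1, -1,  1,
    0,  0,  1
  ), 2, 3, byrow = TRUE)
  m <- metabolic_model(rq(S), c("A", "B"), c("in", "out", "dead"),
                       rep(FALSE, 3))
  r <- remove_blocked_by_kernel(m)
  expect_identical(r$step$removed_reactions, "dead")
  # fully coupled toy_branch: nothing blocked
  expect_null(remove_blocked_by_kernel(toy_branch())$step)
  # trivial kernel: everything removed with a warning
  m2 <- metabolic_model(rq(matrix(c(1, 0, 0, 1), 2, 2)), c("A", "B"),
                        c("r1", "r2"), c(FALSE, FALSE))
  expect_warning(r2 <- remove_blocked_by_kernel(m2), "emptiness")
  expect_identical(ncol(r2$model$S$n), 0L)
})

test_that("enzyme subsets merge with exact ratios", {
  # linear chain: kernel = span{(1,1,1)} -> single merged reaction
  S <- matrix(c(
    1, -1,  0,
    0,  1, -1
  ), 2, 3, byrow = TRUE)
  m <- metabolic_model(rq(S), c("A", "B"), c("r1", "r2", "r3"), rep(FALSE, 3))
  r <- merge_enzyme_subsets(m)
  expect_length(r$step$merges, 1)
  expect_identical(r$step$merges[[1]]$coefficients, c("1", "1", "1"))
  expect_identical(ncol(r$model$S$n), 1L)
  # two irreversible reactions with ratio -1: both removed
  S2 <- matrix(c(1, 1), 1, 2)   # both produce A; kernel (1,-1)
  m2 <- metabolic_model(rq(S2), "A", c("f", "g"), c(FALSE, FALSE))
  expect_warning(r2 <- compress_model(m2), "emptiness")
  expect_identical(ncol(r2$model$S$n), 0L)
})

test_that("dependent metabolite rows are removed, kernel unchanged", {
  S <- matrix(c(
    1, -1, 0,
    0,  1, -1,
    1,  0, -1     # row3 = row1 + row2
  ), 3, 3, byrow = TRUE)
  m <- metabolic_model(rq(S), c("A", "B", "C"), c("r1", "r2", "r3"),
                       rep(FALSE, 3))
  r <- remove_dependent_rows(m)
  expect_identical(r$step$removed_metabolites, "C")
  expect_true(rq_identical(rq_kernel(m$S), rq_kernel(r$model$S)))
  # duplicated row: one removed
  S2 <- rbind(c(1, -1), c(1, -1))
  m2 <- metabolic_model(rq(S2), c("A", "A2"), c("a", "b"), c(FALSE, FALSE))
  expect_identical(remove_dependent_rows(m2)$step$removed_metabolites, "A2")
  # random models: kernel invariant
  for (seed in c(1, 6)) {
    m3 <- random_signed_model(4, 7, seed = seed)
    r3 <- remove_dependent_rows(m3)
    expect_true(rq_identical(rq_kernel(m3$S), rq_kernel(r3$model$S)))
  }
})

test_that("compress_model on toy_branch merges both branches", {
  cp <- compress_model(toy_branch())
  expect_lte(ncol(cp$model$S$n), 3L)
  nmerges <- sum(vapply(cp$record$steps, function(s) {
    if (s$kind == "enzyme_subset_merge") length(s$merges) else 0L
  }, integer(1)))
  expect_gte(nmerges, 2L)
})

test_that("compress_model is idempotent", {
  for (model in list(toy_branch(), random_signed_model(3, 7, seed = 5))) {
    cp <- compress_model(model)
    cp2 <- compress_model(cp$model)
    expect_length(cp2$record$steps, 0)
  }
})

test_that("decompression identities hold", {
  # empty record is the identity
  rec <- structure(list(steps = list(), original_reaction_ids = c("a", "b")),
                   class = "CompressionRecord")
  ms <- mode_set(list(rq(c(1, 2))), c("a", "b"), "efm")
  expect_true(mode_sets_equal(decompress_modes(ms, rec), ms))
  # chain merge c = (1,1,1): value 2 distributes to (2,2,2)
  S <- matrix(c(1, -1, 0, 0, 1, -1), 2, 3, byrow = TRUE)
  m <- metabolic_model(rq(S), c("A", "B"), c("r1", "r2", "r3"), rep(FALSE, 3))
  cp <- compress_model(m)
  cm <- mode_set(list(rq(2)), cp$model$reaction_ids, "efm")
  dec <- decompress_modes(cm, cp$record)
  expect_identical(dec$reaction_ids, c("r1", "r2", "r3"))
  expect_equal(as.vector(dec$values$n), c(2, 2, 2))
  # unknown compressed id is a key error
  bad <- mode_set(list(rq(1)), "nope", "efm")
  expect_error(decompress_modes(bad, cp$record), "unknown compressed id")
})

test_that("losslessness: compressed-model EFMs decompress to the originals", {
  models <- c(list(toy_branch()),
              lapply(c(2, 5, 8, 11, 17, 23), function(s)
                random_signed_model(3 + s %% 3, 6 + s %% 5, seed = s)))
  for (model in models) {
    direct <- oracle_efms(model)
    cp <- suppressWarnings(compress_model(model))
    if (ncol(cp$model$S$n) == 0) {
      expect_identical(mode_count(direct), 0L)
      next
    }
    comp_modes <- ddm_efms(cp$model)
    dec <- decompress_modes(comp_modes, cp$record)
    expect_true(mode_sets_equal(dec, direct))
    # EFM count invariant under compression
    expect_identical(mode_count(comp_modes), mode_count(direct))
  }
})

test_that("every compression step strictly shrinks rows + columns", {
  size <- function(m) nrow(m$S$n) + ncol(m$S$n)
  shrank <- 0L
  for (seed in c(3, 5, 19, 23)) {
    model <- random_signed_model(4, 8, seed = seed)
    cur <- model
    for (f in list(remove_deadend_metabolites, remove_blocked_by_kernel,
                   merge_enzyme_subsets, remove_dependent_rows)) {
      r <- suppressWarnings(f(cur))
      if (!is.null(r$step)) {
        expect_lt(size(r$model), size(cur))
        shrank <- shrank + 1L
      }
      cur <- r$model
    }
  }
  expect_gt(shrank, 0L)   # the corpus does exercise the steps
})

test_that("compression record serializes to JSON and back", {
  cp <- compress_model(toy_branch())
  p <- withr::local_tempfile(fileext = ".json")
  write_compression_record(cp$record, p)
  rec2 <- read_compression_record(p)
  expect_identical(length(rec2$steps), length(cp$record$steps))
  expect_identical(rec2$original_reaction_ids, cp$record$original_reaction_ids)
  # decompression through the reloaded record matches
  cm <- ddm_efms(cp$model)
  expect_true(mode_sets_equal(decompress_modes(cm, cp$record),
                              decompress_modes(cm, rec2)))
})

test_that("bounds translate through merges", {
  S <- matrix(c(1, -1, 0, 0, 1, -1), 2, 3, byrow = TRUE)
  m <- metabolic_model(rq(S), c("A", "B"), c("r1", "r2", "r3"), rep(FALSE, 3))
  cp <- compress_model(m)
  b <- bounds_table("r2", "<=", rq(5))
  tb <- translate_bounds(b, cp$record)
  expect_identical(tb$reaction_id, cp$model$reaction_ids[1])
  expect_equal(rq_format(tb$value), "5")
})
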