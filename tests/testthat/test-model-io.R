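# Model container, SBML round trips, efmtool inputs, bounds, consistency.

test_that("minimal SBML reads to the forced structure", {
  sbml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfSpecies>',
    '<species id="A" compartment="c" boundaryCondition="false" constant="false"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="R1" reversible="false"><listOfProducts>',
    '<speciesReference species="A" stoichiometry="1" constant="true"/>',
    '</listOfProducts></reaction>',
    '<reaction id="R2" reversible="false"><listOfReactants>',
    '<speciesReference species="A" stoichiometry="1" constant="true"/>',
    '</listOfReactants></reaction>',
    '</listOfReactions></model></sbml>')
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, p)
  m <- read_sbml(p)
  expect_identical(dim(m), c(1L, 2L))
  expect_identical(m$rev, c(FALSE, FALSE))
  expect_equal(rq_format(m$S)[1:2], c("1", "-1"))
})

test_that("fbc bounds drive reversibility; COBRA defaults treated unbounded", {
  sbml <- c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfSpecies>',
    '<species id="A" boundaryCondition="false"/></listOfSpecies>',
    '<listOfParameters>',
    '<parameter id="lbneg" value="-1000" constant="true"/>',
    '<parameter id="ubbig" value="1000" constant="true"/>',
    '<parameter id="lbz" value="0" constant="true"/>',
    '</listOfParameters>',
    '<listOfReactions>',
    '<reaction id="R1" reversible="false" lowerFluxBound="lbneg" upperFluxBound="ubbig">',
    '<listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts></reaction>',
    '<reaction id="R2" reversible="true" lowerFluxBound="lbz" upperFluxBound="ubbig">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants></reaction>',
    '</listOfReactions></model></sbml>')
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, p)
  m <- read_sbml(p)
  expect_true(m$rev[1])              # lb = -1000 < 0 => reversible
  expect_false(m$rev[2])             # lb = 0 => irreversible despite flag
  expect_false(any(m$ub_finite))     # |1000| bounds treated as unbounded
})

test_that("SBML round trip preserves the model exactly", {
  for (model in list(toy_branch(),
                     random_signed_model(3, 6, seed = 4))) {
    p <- withr::local_tempfile(fileext = ".xml")
    write_sbml(model, p)
    expect_true(model_identical(model, read_sbml(p)))
  }
})

test_that("invalid SBML produces a format error naming the problem", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines("this is not xml <", p)
  expect_error(read_sbml(p), "invalid SBML")
  writeLines(c('<?xml version="1.0"?>',
               '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core">',
               '<model id="m"><listOfReactions>',
               '<reaction id="R1"><listOfProducts>',
               '<speciesReference species="A" stoichiometry="twelve"/>',
               '</listOfProducts></reaction>',
               '</listOfReactions></model></sbml>'), p)
  expect_error(read_sbml(p), "non-numeric|unknown species")
})

test_that("efmtool input quadruple has the documented shape", {
  td <- withr::local_tempdir()
  paths <- write_efmtool_inputs(toy_branch(), td)
  expect_length(paths, 4)
  # reversibility line fixed by the fixture definition (R3 reversible)
  expect_identical(readLines(paths[2]), "0 0 1 0 0")
  srows <- readLines(paths[1])
  expect_length(srows, 3)
  expect_length(strsplit(srows[1], " ")[[1]], 5)
  expect_match(readLines(paths[3]), '"R1" "R2" "R3" "R4" "R5"', fixed = TRUE)
  # round trip through the dialect
  m2 <- read_efmtool_inputs(td)
  expect_true(rq_identical(m2$S, toy_branch()$S))
  expect_identical(m2$rev, toy_branch()$rev)
})

test_that("a single-metabolite model writes a 1 x 2 matrix file", {
  m <- metabolic_model(rq(matrix(c(1, -1), 1, 2)), "A", c("in", "out"),
                       rev = c(FALSE, FALSE))
  td <- withr::local_tempdir()
  paths <- write_efmtool_inputs(m, td)
  expect_length(readLines(paths[1]), 1)
})

test_that("empty reaction names are rejected", {
  expect_error(metabolic_model(rq(matrix(1, 1, 1)), "A", "", FALSE),
               "empty id")
})

test_that("apply_bounds tightens, never loosens, and is idempotent", {
  m <- toy_branch()
  b <- bounds_table(c("R1", "R4"), c("<=", ">="), rq_parse(c("10", "3.15")))
  m2 <- apply_bounds(m, b)
  expect_equal(rq_format(rq_index(m2$ub, 1)), "10")
  expect_true(m2$ub_finite[1])
  expect_equal(rq_format(rq_index(m2$lb, 4)), "63/20")   # 3.15 exactly
  # original untouched
  expect_false(m$ub_finite[1])
  # idempotent
  expect_true(model_identical(apply_bounds(m2, b), m2))
  # a looser bound is a no-op
  m3 <- apply_bounds(m2, bounds_table("R1", "<=", rq(100)))
  expect_true(model_identical(m3, m2))
  expect_error(apply_bounds(m, bounds_table("nope", "<=", rq(1))), "unknown")
  expect_error(apply_bounds(m2, bounds_table("R4", "<=", rq(1))), "lb > ub")
})

test_that("bounds TSV round trips", {
  b <- bounds_table(c("R_GlcUp", "R_ATPM"), c("<=", ">="),
                    rq_parse(c("10", "3.15")))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_bounds_tsv(b, p)
  b2 <- read_bounds_tsv(p)
  expect_identical(b2$reaction_id, b$reaction_id)
  expect_identical(b2$relation, b$relation)
  expect_true(all(rq_eq(b2$value, b$value)))
})

test_that("make_consistent removes blocked reactions and fixes directions", {
  # reaction producing a metabolite nothing consumes: removed
  m <- metabolic_model(rq(matrix(c(1, 0, -1, 0, 0, 1), 2, 3)),
                       c("A", "B"), c("R1", "R2", "R6"),
                       rev = c(FALSE, FALSE, FALSE))
  out <- make_consistent(m)
  expect_identical(out$report$removed_reactions, "R6")
  expect_identical(out$report$removed_metabolites, "B")
  # toy_branch: nothing removed; R3 can never run backwards -> direction fixed
  out2 <- make_consistent(toy_branch())
  expect_length(out2$report$removed_reactions, 0)
  expect_identical(out2$report$made_irreversible, "R3")
  # A <-> B where B is only consumable: LP forces forward irreversibility
  m3 <- metabolic_model(rq(matrix(c(1, 0, -1, 1, 0, -1), 2, 3)),
                        c("A", "B"), c("up", "conv", "out"),
                        rev = c(FALSE, TRUE, FALSE))
  out3 <- make_consistent(m3)
  expect_identical(out3$report$made_irreversible, "conv")
  expect_false(out3$model$rev[2])
})

test_that("make_consistent never changes the EFM set (zero-padded)", {
  for (seed in c(2, 9, 14)) {
    m <- random_signed_model(3, 7, seed = seed)
    out <- make_consistent(m)
    before <- oracle_efms(m)
    after <- oracle_efms(out$model)
    # pad the consistent model's EFMs with zeros at removed reactions;
    # flipped columns flip the sign back
    pad <- lapply(seq_len(mode_count(after)), function(i) {
      v <- rq_zeros(length(m$reaction_ids))
      vv <- rq_row(after$values, i)
      for (t in seq_along(after$reaction_ids)) {
        j <- match(after$reaction_ids[t], m$reaction_ids)
        val <- rq_index(vv, t)
        if (after$reaction_ids[t] %in% out$report$flipped) val <- rq_neg(val)
        v <- rq_set(v, j, NULL, val)
      }
      v
    })
    padded <- mode_set(pad, m$reaction_ids, "efm")
    expect_true(mode_sets_equal(padded, before))
  }
})
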