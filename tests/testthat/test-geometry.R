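# Geometric representations, transformations, redundancy removal, lrs files.

test_that("split_reversible doubles reversible columns in place", {
  sp <- split_reversible(toy_branch())
  m <- sp$model
  expect_identical(m$reaction_ids, c("R1", "R2", "R3", "R3_rev", "R4", "R5"))
  expect_false(any(m$rev))
  i3 <- match("R3", m$reaction_ids)
  expect_true(all(m$S$n[, i3 + 1] == -m$S$n[, i3]))
  expect_identical(sp$record$split_pairs$R3, c(fwd = 3L, rev = 4L))
  # all-irreversible model: identity transform
  m0 <- metabolic_model(rq(matrix(c(1, -1), 1, 2)), "A", c("a", "b"),
                        rev = c(FALSE, FALSE))
  sp0 <- split_reversible(m0)
  expect_identical(sp0$model$reaction_ids, c("a", "b"))
  expect_true(all(vapply(sp0$record$split_pairs,
                         function(p) is.na(p[["rev"]]), logical(1))))
  # column count arithmetic at network scale: 15 reversible of 71 -> 86
  mbig <- random_signed_model(6, 14, seed = 1)   # small stand-in for the law
  expect_identical(ncol(split_reversible(mbig)$model$S$n),
                   14L + sum(mbig$rev))
})

test_that("build_polyhedron encodes bounds as the documented rows", {
  sp <- split_reversible(toy_branch())
  # no bounds: E empty, polyhedron equals the flux cone
  P0 <- build_polyhedron(sp$model, NULL, sp$record)
  expect_identical(nrow(P0$E$n), 0L)
  # (R_ATPM-style) >= bound: unit row, f = value
  b <- bounds_table(c("R4", "R1"), c(">=", "<="), rq_parse(c("3.15", "10")))
  P <- build_polyhedron(sp$model, b, sp$record)
  expect_identical(nrow(P$E$n), 2L)
  i4 <- match("R4", sp$model$reaction_ids)
  expect_equal(P$E$n[1, i4], 1)
  expect_equal(rq_format(rq_index(P$f, 1)), "63/20")
  # <= bound: negated unit row, f = -value
  expect_equal(P$E$n[2, match("R1", sp$model$reaction_ids)], -1)
  expect_equal(rq_format(rq_index(P$f, 2)), "-10")
  # bound on a split reversible reaction: two-entry net-flux row
  b2 <- bounds_table("R3", "<=", rq(2))
  P2 <- build_polyhedron(sp$model, b2, sp$record)
  expect_equal(P2$E$n[1, 3:4], c(-1, 1))
})

test_that("homogenize produces the documented cone rows", {
  # P = {0 <= x <= 1}: rows x >= 0, -x + zeta >= 0, zeta >= 0
  P <- polyhedron_hrep(rq_zeros(0, 1), rq_zeros(0),
                       rq(matrix(-1, 1, 1)), rq(-1), var_ids = "x")
  C <- homogenize(P)
  expect_identical(nrow(C$G$n), 0L)
  expect_equal(C$H$n, matrix(c(-1, 1, 1, 0, 0, 1), 3, 2, byrow = TRUE))
  expect_identical(C$zeta_index, 2L)
  # setting zeta = 1 satisfies P: check on a vertex enumeration
  dh <- dehomogenize(enumerate_rays_ddm(C))
  expect_identical(sort(rq_to_double(dh$values)[, 1]), c(0, 1))
})

test_that("tetrahedron homogenizes to a 4-ray cone, all with zeta > 0", {
  A <- rbind(diag(3), c(-1, -1, -1)); b <- c(0, 0, 0, -1)
  tet <- general_hrep(rq(A), rq(b))
  dh <- dehomogenize(enumerate_rays_ddm(homogenize(tet)))
  expect_identical(sum(dh$kind == "efv"), 4L)
  expect_identical(sum(dh$kind == "efm"), 0L)
})

test_that("to_flux_cone has the block dimensions of the embedding", {
  C <- rq(matrix(sample(-2:2, 8, TRUE), 2, 4))
  E <- rq(matrix(sample(-2:2, 12, TRUE), 3, 4))
  P <- polyhedron_hrep(C, rq_zeros(2), E, rq(c(1, 1, 1)))
  fc <- to_flux_cone(P)
  expect_identical(dim(fc$cone$N$n), c(5L, 8L))       # (k1+k2) x (l+k2+1)
  expect_identical(fc$record$slack_columns, 5:7)
  expect_identical(fc$record$zeta_column, 8L)
  # flux-cone of a cone-shaped polyhedron: lone zeta column of zeros
  P0 <- polyhedron_hrep(C, rq_zeros(2), var_ids = paste0("v", 1:4))
  fc0 <- to_flux_cone(P0)
  expect_identical(dim(fc0$cone$N$n), c(2L, 5L))
  expect_true(all(fc0$cone$N$n[, 5] == 0))
})

test_that("flux-cone and polyhedral-cone routes enumerate identical modes", {
  set.seed(8)
  for (seed in c(3, 12, 27)) {
    model <- random_signed_model(3, 6, seed = seed)
    sp <- split_reversible(model)
    b <- bounds_table(model$reaction_ids[1], "<=", rq(4))
    P <- build_polyhedron(sp$model, b, sp$record)
    l <- length(P$var_ids)
    # route 1: homogenized polyhedral cone
    dh1 <- dehomogenize(enumerate_rays_ddm(homogenize(P)))
    # route 2: slack-embedded flux cone, restricted to (x, zeta)
    fc <- to_flux_cone(P)
    raw <- enumerate_rays_ddm(fc$cone)
    keep <- c(seq_len(l), fc$record$zeta_column)
    proj <- mode_set(rq_index(raw$values, seq_len(mode_count(raw)), keep),
                     c(P$var_ids, "zeta"), "efm")
    dh2 <- dehomogenize(dedupe_modes(proj)$modes)
    expect_true(mode_sets_equal(dh1, dh2))
  }
})

test_that("dehomogenize scales, classifies and rejects negative zeta", {
  ms <- mode_set(list(rq(c(2, 0, 2)), rq(c(1, 1, 0))), c("a", "b", "zeta"),
                 "efm", canonicalize = FALSE)
  dh <- dehomogenize(ms)
  expect_identical(sort(dh$kind), c("efm", "efv"))
  iv <- which(dh$kind == "efv")
  expect_equal(rq_to_double(rq_row(dh$values, iv)), c(1, 0))
  bad <- mode_set(list(rq(c(1, 1, -1))), c("a", "b", "zeta"), "efm",
                  canonicalize = FALSE)
  expect_error(dehomogenize(bad), "zeta < 0")
})

test_that("pointedness check names a lineality direction", {
  # free line: {x : 0 <= x1} in 2 vars has lineality along x2
  C <- cone_hrep(rq_zeros(0, 2), rq(matrix(c(1, 0), 1, 2)),
                 var_ids = c("x1", "zeta"))
  expect_error(assert_pointed(C), "lineality")
  expect_true(assert_pointed(flux_cone(rq(matrix(c(1, -1), 1, 2)))))
})

test_that("redundant rows are removed by the LP test, feasible set intact", {
  # {x >= 0, x <= 1, x <= 2}: the loose upper bound goes
  g <- general_hrep(rq(matrix(c(1, -1, -1), 3, 1)), rq(c(0, -1, -2)))
  r <- remove_redundant_rows(g)
  expect_identical(r$removed, 3L)
  # duplicated row: exactly one copy removed
  g2 <- general_hrep(rq(matrix(c(1, -1, -1), 3, 1)), rq(c(0, -1, -1)))
  r2 <- remove_redundant_rows(g2)
  expect_length(r2$removed, 1L)
  expect_identical(nrow(r2$object$A$n), 2L)
  # infeasible system: error, not silent emptying
  bad <- general_hrep(rq(matrix(c(1, -1), 2, 1)), rq(c(2, -1)))
  expect_error(remove_redundant_rows(bad), "infeasible")
  # random polytopes: vertex set unchanged (brute-force oracle)
  set.seed(13)
  for (i in 1:8) {
    d <- sample(2:3, 1); kx <- sample(3:6, 1)
    A <- rbind(matrix(sample(-2:2, kx * d, TRUE), kx, d), diag(d), -diag(d))
    b <- c(sample(-3:0, kx, TRUE), rep(-3, d), rep(-3, d))
    g3 <- general_hrep(rq(A), rq(b))
    r3 <- remove_redundant_rows(g3)
    expect_true(mode_sets_equal(brute_force_enumerate(g3)$vertices,
                                brute_force_enumerate(r3$object)$vertices))
  }
})

test_that("lrs .ine dialect matches the fixed encoding and round trips", {
  # 1-D polyhedron 0 <= x <= 1: body rows "0 1" and "1 -1"
  g <- general_hrep(rq(matrix(c(1, -1), 2, 1)), rq(c(0, -1)))
  p <- withr::local_tempfile(fileext = ".ine")
  write_lrs_ine(g, p, name = "unitseg")
  lines <- readLines(p)
  expect_identical(lines[1:4], c("unitseg", "H-representation", "begin",
                                 "2 2 rational"))
  expect_identical(lines[5:6], c("0 1", "1 -1"))
  expect_identical(lines[7], "end")
  g2 <- parse_lrs_ine(p)
  expect_true(rq_identical(g2$A, g$A))
  expect_true(rq_identical(g2$b, g$b))
  # linearity line is 1-based and round trips
  perm3 <- permutahedron(3)
  p2 <- withr::local_tempfile(fileext = ".ine")
  write_lrs_ine(perm3, p2)
  expect_match(readLines(p2)[3], "^linearity 1 7$")
  g3 <- parse_lrs_ine(p2)
  expect_identical(g3$linearity, perm3$linearity)
  expect_true(rq_identical(g3$A, perm3$A))
  # rational rows survive integer scaling
  gr <- general_hrep(rq(matrix(c(1, 3), 1, 2), c(2, 4)), rq_parse("1/6"))
  p3 <- withr::local_tempfile(fileext = ".ine")
  write_lrs_ine(gr, p3)
  g4 <- parse_lrs_ine(p3)
  # same halfspace up to positive scaling: compare normalized rows
  r1 <- rq_int_normalize(rq_c(rq_neg(gr$b), rq_row(gr$A, 1)))
  r2 <- rq_int_normalize(rq_c(rq_neg(g4$b), rq_row(g4$A, 1)))
  expect_true(all(rq_eq(r1, r2)))
})

test_that("lrs .ext parser classifies vertices and rays", {
  p <- withr::local_tempfile(fileext = ".ext")
  writeLines(c("test", "V-representation", "begin", "2 3 rational",
               "1 0 0", "0 1 1", "end"), p)
  v <- parse_lrs_ext(p)
  expect_identical(nrow(v$vertices$n), 1L)
  expect_identical(nrow(v$rays$n), 1L)
  expect_equal(v$rays$n[1, ], c(1, 1))
  # malformed arity reports the line number
  writeLines(c("test", "V-representation", "begin", "1 3 rational",
               "1 0", "end"), p)
  expect_error(parse_lrs_ext(p), "line 5")
})

test_that("write -> parse round trip preserves fixtures exactly", {
  for (obj in list(permutahedron(4), birkhoff(3))) {
    p <- withr::local_tempfile(fileext = ".ine")
    write_lrs_ine(obj, p)
    g <- parse_lrs_ine(p)
    expect_true(rq_identical(g$A, obj$A))
    expect_true(rq_identical(g$b, obj$b))
    expect_identical(g$linearity, obj$linearity)
  }
})

test_that("split then merge is the identity on one-sided flux vectors", {
  model <- toy_branch()
  sp <- split_reversible(model)
  # a flux with R3 running backwards at rate 2
  v_split <- rq(c(1, 0, 0, 2, 0, 2))
  ms <- mode_set(list(v_split), sp$model$reaction_ids, "efm",
                 canonicalize = FALSE)
  merged <- merge_split_pairs(ms, sp$record)
  expect_equal(rq_to_double(rq_row(merged$values, 1)), c(1, 0, -2, 0, 2))
})
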