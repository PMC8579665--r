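# Lexicographic reverse search engine.

test_that("classic small polytopes enumerate correctly", {
  # tetrahedron: 4 vertices, no rays, simple (one basis per vertex)
  tet <- general_hrep(rq(rbind(diag(3), c(-1, -1, -1))), rq(c(0, 0, 0, -1)))
  r <- enumerate_vertices_rs(tet)
  expect_equal(r$status, "ok")
  expect_identical(mode_count(r$vertices), 4L)
  expect_identical(mode_count(r$rays), 0L)
  expect_true(all(r$emissions$vertex_multiplicity == 1L))
  # square pyramid: 5 vertices, apex degenerate (4 tight facets in 3-D)
  pyr <- general_hrep(rq(rbind(c(0, 0, 1), c(-1, 0, -1), c(1, 0, -1),
                               c(0, -1, -1), c(0, 1, -1))),
                      rq(c(0, -1, -1, -1, -1)))
  r2 <- enumerate_vertices_rs(pyr)
  expect_identical(mode_count(r2$vertices), 5L)
  expect_gte(max(r2$emissions$vertex_multiplicity), 2L)  # apex basis cluster
  expect_true(mode_sets_equal(r2$vertices, brute_force_enumerate(pyr)$vertices))
  # unit square
  sq <- general_hrep(rq(rbind(diag(2), -diag(2))), rq(c(0, 0, -1, -1)))
  expect_identical(mode_count(enumerate_vertices_rs(sq)$vertices), 4L)
  # half line {x >= 0}: vertex {0}, ray {1}
  hl <- enumerate_vertices_rs(general_hrep(rq(matrix(1, 1, 1)), rq(0)))
  expect_identical(mode_count(hl$vertices), 1L)
  expect_equal(as.vector(hl$rays$values$n), 1)
})

test_that("infeasible and non-pointed inputs are reported as such", {
  inf <- general_hrep(rq(matrix(c(1, -1), 2, 1)), rq(c(2, -1)))
  expect_equal(enumerate_vertices_rs(inf)$status, "infeasible")
  # single halfspace in 2-D: lineality along the facet
  np <- general_hrep(rq(matrix(c(1, 0), 1, 2)), rq(0))
  expect_error(enumerate_vertices_rs(np), "lineality")
})

test_that("random bounded polyhedra agree with the brute-force oracle", {
  set.seed(42)
  for (it in 1:15) {
    d <- sample(2:4, 1); kx <- sample(2:6, 1)
    A <- rbind(matrix(sample(-3:3, kx * d, TRUE), kx, d), diag(d), -diag(d))
    b <- c(sample(-3:0, kx, TRUE), rep(-4, d), rep(-4, d))
    rep <- general_hrep(rq(A), rq(b))
    r <- enumerate_vertices_rs(rep)
    bf <- brute_force_enumerate(rep)
    expect_true(mode_sets_equal(r$vertices, bf$vertices))
    expect_true(mode_sets_equal(r$rays, bf$rays))
  }
})

test_that("random unbounded polyhedra recover their recession rays", {
  set.seed(7)
  for (it in 1:10) {
    d <- sample(2:3, 1); kx <- sample(2:5, 1)
    A <- rbind(matrix(sample(-2:2, kx * d, TRUE), kx, d), diag(d))
    b <- c(sample(-3:0, kx, TRUE), rep(0, d))
    rep <- general_hrep(rq(A), rq(b))
    r <- tryCatch(enumerate_vertices_rs(rep), error = function(e) e)
    if (inherits(r, "error")) {
      expect_match(conditionMessage(r), "lineality|pointed")
      next
    }
    if (r$status != "ok") next
    bf <- brute_force_enumerate(rep)
    expect_true(mode_sets_equal(r$vertices, bf$vertices))
    expect_true(mode_sets_equal(r$rays, bf$rays))
  }
})

test_that("a pointed flux cone yields origin plus the ddm ray set", {
  for (seed in c(9, 18, 33)) {
    fc <- random_flux_cone(3, 7, 0.5, seed = seed)
    r <- enumerate_vertices_rs(fc)
    expect_identical(mode_count(r$vertices), 1L)
    expect_true(all(r$vertices$values$n == 0))
    expect_true(mode_sets_equal(r$rays, enumerate_efms_ddm(fc)))
  }
})

test_that("emission order and counts are deterministic", {
  pyr <- general_hrep(rq(rbind(c(0, 0, 1), c(-1, 0, -1), c(1, 0, -1),
                               c(0, -1, -1), c(0, 1, -1))),
                      rq(c(0, -1, -1, -1, -1)))
  a <- enumerate_vertices_rs(pyr)
  b <- enumerate_vertices_rs(pyr)
  expect_identical(mode_keys(a$vertices), mode_keys(b$vertices))
  expect_identical(a$emissions, b$emissions)
})

test_that("linearity rows are eliminated by exact substitution", {
  # segment on the plane x + y = 1 within the unit box
  g <- general_hrep(rq(rbind(c(1, 1), diag(2), -diag(2))),
                    rq(c(1, 0, 0, -1, -1)), linearity = 1L)
  r <- enumerate_vertices_rs(g)
  expect_identical(mode_count(r$vertices), 2L)
  expect_setequal(apply(rq_to_double(r$vertices$values), 1, paste, collapse = ","),
                  c("0,1", "1,0"))
  # inconsistent linearities are infeasible
  g2 <- general_hrep(rq(matrix(c(1, 1), 2, 1)), rq(c(0, 1)),
                     linearity = c(1L, 2L))
  expect_equal(enumerate_vertices_rs(g2)$status, "infeasible")
})
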