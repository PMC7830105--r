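test_that("coupling grids evaluate the non-constant basis terms exactly", {
  b <- build_basis(2)
  cc <- numeric(b$n_terms); cc[1] <- 2 * pi
  g0 <- coupling_grid(cc, b, M = 32)
  expect_true(all(g0$values == 0))
  cc["sin(+0p1+1p2)" == b$terms$name] <- 1
  g <- coupling_grid(cc, b, M = 64)
  ang <- seq(0, 2 * pi, length.out = 65)[1:64]
  expect_close(g$values, matrix(sin(ang), 64, 64, byrow = TRUE), 1e-12)
  # torus mean of any single harmonic vanishes on the uniform grid
  for (nm in c("sin(+1p1-2p2)", "cos(+2p1+1p2)")) {
    c2 <- numeric(b$n_terms); c2[b$terms$name == nm] <- 1
    expect_lt(abs(mean(coupling_grid(c2, b, M = 48)$values)), 1e-10)
  }
  expect_error(coupling_grid(cc, b, M = 4), "at least 8")
})

test_that("the directionality index obeys its boundary and symmetry laws", {
  expect_equal(directionality(1.7, 0), -1)
  expect_equal(directionality(0, 0.3), 1)
  expect_equal(directionality(2, 2), 0)
  expect_equal(directionality(1, 3), 0.5)
  set.seed(2)
  c1 <- runif(10); c2 <- runif(10)
  expect_equal(directionality(c1, c2), -directionality(c2, c1))
  expect_error(directionality(0, 0), "undefined")
  expect_error(directionality(-1, 2), ">= 0")
})

test_that("coupling strength is the Euclidean norm", {
  expect_equal(coupling_strength(numeric(8)), 0)
  expect_equal(coupling_strength(-2.5), 2.5)
  expect_equal(coupling_strength(c(3, 4)), 5)
})

test_that("polar similarity measures form, not scale", {
  b <- build_basis(2)
  c_sin <- numeric(b$n_terms); c_sin[b$terms$name == "sin(+0p1+1p2)"] <- 1
  c_cos <- numeric(b$n_terms); c_cos[b$terms$name == "cos(+0p1+1p2)"] <- 1
  gs <- coupling_grid(c_sin, b, M = 100)
  gc <- coupling_grid(c_cos, b, M = 100)
  expect_equal(polar_similarity(gs, gs), 100)
  neg <- gs; neg$values <- -gs$values
  expect_equal(polar_similarity(gs, neg), 100)
  expect_lt(polar_similarity(gs, gc), 1e-8)
  # scale invariance
  mix <- coupling_grid(0.3 * c_sin + 0.2 * c_cos, b, M = 100)
  s1 <- polar_similarity(gs, mix)
  big <- mix; big$values <- -7 * mix$values
  expect_equal(polar_similarity(gs, big), s1, tolerance = 1e-12)
  flat <- coupling_grid(numeric(b$n_terms), b, M = 100)
  expect_error(polar_similarity(gs, flat), "constant grid")
  expect_error(polar_similarity(gs, coupling_grid(c_sin, b, M = 50)),
               "equal size")
})

test_that("stage aggregation follows the half-open midtime rule", {
  proto <- stage_protocol(c("A", "B"), c(0, 100), c(100, 200))
  expect_equal(unname(stage_aggregate(c(5, 5, 5), c(10, 50, 150), proto)),
               c(5, 5))
  expect_equal(unname(suppressWarnings(
    stage_aggregate(c(1, 2, 100), c(1, 2, 3), proto)))[1], 2)
  # midtime exactly at a stage start belongs to that stage
  agg <- stage_aggregate(c(1, 9), c(50, 100), proto)
  expect_equal(unname(agg), c(1, 9))
  expect_warning(out <- stage_aggregate(1, 50, proto), "no windows")
  expect_true(is.na(out["B"]))
  expect_equal(stage_of_midtime(c(0, 99.9, 100, 250), proto),
               c("A", "A", "B", NA))
})

test_that("group averaging of grids is the element-wise mean", {
  b <- build_basis(1)
  cc <- numeric(b$n_terms); cc[2] <- 0.5
  g <- coupling_grid(cc, b, M = 16)
  avg <- group_average_grid(list(g, g, g))
  expect_equal(avg$values, g$values)
  neg <- g; neg$values <- -g$values
  expect_close(group_average_grid(list(g, neg))$values, 0, 1e-14)
  # centering commutes with averaging (linearity)
  c2 <- numeric(b$n_terms); c2[3] <- 0.2; c2[1] <- 1
  g2 <- coupling_grid(c2, b, M = 16)
  m <- group_average_grid(list(g, g2))
  lhs <- m$values - mean(m$values)
  rhs <- ((g$values - mean(g$values)) + (g2$values - mean(g2$values))) / 2
  expect_close(lhs, rhs, 1e-12)
  expect_error(group_average_grid(list()), "empty")
})
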