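test_that("lattice graphs have the rook edge count and connectivity", {
  cases <- list(c(1, 2, 2, 1), c(2, 2, 4, 4), c(3, 3, 9, 12),
                c(19, 19, 361, 684))
  for (cs in cases) {
    g <- build_lattice_graph(cs[1], cs[2])
    expect_equal(g$n, cs[3])
    expect_equal(nrow(g$edges), cs[4])
    expect_equal(max(graph_components(g)), 1L)
  }
  # interior cells of a 3x3 lattice have 4 neighbors
  g <- build_lattice_graph(3, 3)
  deg <- tabulate(c(g$edges), nbins = 9)
  expect_equal(deg[5], 4)
  expect_error(build_lattice_graph(0, 3), "positive")
  expect_error(build_lattice_graph(1, 1), "at least 2")
})

test_that("graph constructor rejects malformed input", {
  expect_error(region_graph(3, rbind(c(1, 1))), "self-loop")
  expect_error(region_graph(3, rbind(c(1, 4))), "indices")
  # duplicate and reversed edges are canonicalized away
  g <- region_graph(3, rbind(c(2, 1), c(1, 2), c(2, 3)))
  expect_equal(nrow(g$edges), 2L)
})

test_that("edge-list and INLA-style graph files round-trip", {
  f <- withr::local_tempfile()
  writeLines(c("1 2", "2 3"), f)
  g <- read_graph(f, "edge_list")
  expect_equal(g$n, 3L)
  expect_equal(g$edges, cbind(1:2, 2:3), ignore_attr = TRUE)

  f2 <- withr::local_tempfile()
  writeLines(c("2", "1 1 2", "2 1 1"), f2)
  g2 <- read_graph(f2, "inla_graph")
  expect_equal(g2$n, 2L)
  expect_equal(nrow(g2$edges), 1L)

  for (fmt in c("edge_list", "inla_graph")) {
    lat <- build_lattice_graph(19, 19)
    f3 <- withr::local_tempfile()
    write_graph(lat, f3, fmt)
    back <- read_graph(f3, fmt)
    expect_equal(back$edges, lat$edges)
  }
})

test_that("asymmetric and out-of-range INLA graph files are rejected", {
  f <- withr::local_tempfile()
  writeLines(c("3", "1 1 2", "2 0", "3 0"), f)
  expect_error(read_graph(f, "inla_graph"), "asymmetric.*1 lists 2")
  f2 <- withr::local_tempfile()
  writeLines(c("2", "1 1 5", "2 0"), f2)
  expect_error(read_graph(f2, "inla_graph"), "out of range")
})

test_that("ICAR precision is the graph Laplacian with zero row sums", {
  Q <- icar_precision(path_graph(2))
  expect_equal(as.matrix(Q), rbind(c(1, -1), c(-1, 1)), ignore_attr = TRUE)
  Q3 <- icar_precision(path_graph(3))
  expect_equal(as.matrix(Q3),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)),
               ignore_attr = TRUE)
  expect_equal(Matrix::diag(icar_precision(build_lattice_graph(2, 2))),
               rep(2, 4))
  for (g in list(path_graph(5), build_lattice_graph(4, 6))) {
    Q <- icar_precision(g)
    expect_equal(as.numeric(Q %*% rep(1, g$n)), rep(0, g$n))
  }
})

test_that("scaling normalizes the generalized-inverse geometric mean", {
  # 2-node path: pseudo-inverse of [[1,-1],[-1,1]] has diagonal 0.25
  sp2 <- scale_icar(path_graph(2))
  expect_equal(sp2$scale_c, 0.25, tolerance = 1e-12)
  expect_equal(as.matrix(sp2$Q_star), 0.25 * as.matrix(sp2$Q),
               ignore_attr = TRUE)

  for (sp in list(sp_path3(), sp_lattice3(), sp_lattice19())) {
    expect_equal(exp(mean(log(sp$gen_inverse_diag))), 1, tolerance = 1e-8)
    # scaling idempotence: rescaling Q* gives c = 1
    expect_equal(scale_icar(sp$Q_star)$scale_c, 1, tolerance = 1e-8)
  }
})

test_that("scaled precision agrees with a dense pseudo-inverse oracle", {
  for (g in list(path_graph(3), build_lattice_graph(5, 10))) {
    sp <- scale_icar(g)
    pinv <- dense_pinv(icar_precision(g))
    c_oracle <- exp(mean(log(diag(pinv))))
    expect_equal(sp$scale_c, c_oracle, tolerance = 1e-8)
    expect_equal(sp$gen_inverse_diag, diag(pinv) / c_oracle,
                 tolerance = 1e-8)
  }
})

test_that("per-component scaling handles disconnected graphs, rejects islands", {
  # two disjoint path components
  g <- region_graph(5, rbind(c(1, 2), c(3, 4), c(4, 5)))
  sp <- scale_icar(g)
  expect_equal(length(sp$scale_c), 2L)
  for (k in 1:2) {
    idx <- sp$comp == k
    expect_equal(exp(mean(log(sp$gen_inverse_diag[idx]))), 1,
                 tolerance = 1e-8)
  }
  # isolated region
  g2 <- region_graph(3, rbind(c(1, 2)))
  expect_error(scale_icar(g2), "isolated")
})

test_that("structured effect draws honor constraint, seed and covariance", {
  sp <- sp_path3()
  u <- sample_structured(sp, 2, 42)
  expect_equal(sum(u), 0, tolerance = 1e-10)
  expect_identical(u, sample_structured(sp, 2, 42))
  expect_error(sample_structured(sp, -1, 1), "positive")

  # empirical covariance over many draws vs (1/tau) * (Q*)^-
  tau <- 2
  draws <- vapply(seq_len(20000),
                  function(s) sample_structured(sp, tau, s), numeric(3))
  emp <- tcrossprod(draws) / ncol(draws)
  expect_equal(max(abs(emp - dense_pinv(sp$Q_star) / tau)), 0,
               tolerance = 0.02)

  # per-component zero sums on a disconnected graph
  g <- region_graph(5, rbind(c(1, 2), c(3, 4), c(4, 5)))
  spd <- scale_icar(g)
  ud <- sample_structured(spd, 1, 7)
  expect_equal(sum(ud[1:2]), 0, tolerance = 1e-10)
  expect_equal(sum(ud[3:5]), 0, tolerance = 1e-10)
})
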