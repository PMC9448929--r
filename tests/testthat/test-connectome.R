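test_that("reading SC matrices validates shape, sign, symmetry and diagonal", {
  p3 <- uniform_parcellation(3)

  zero <- read_sc_matrix(write_matrix_file(matrix(0, 3, 3)), p3)
  expect_equal(zero$W, matrix(0, 3, 3))

  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 5; diag(W) <- 7
  cm <- read_sc_matrix(write_matrix_file(W), p3)
  expect_equal(diag(cm$W), rep(0, 3))
  expect_equal(cm$W[1, 2], 5)

  W[1, 2] <- 4  # asymmetric beyond tolerance
  expect_error(read_sc_matrix(write_matrix_file(W), p3), "asymmetry")

  expect_error(read_sc_matrix(write_matrix_file(matrix(1, 2, 3)), p3),
               "square")
  Wneg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(read_sc_matrix(write_matrix_file(Wneg),
                              uniform_parcellation(2)), "negative")
})

test_that("scaling to a target mean is exact and structure preserving", {
  W <- matrix(0, 3, 3)
  W[upper.tri(W)] <- c(2, 4, 6)
  W <- W + t(W)
  cm <- as_connectome(W)
  out <- scale_to_target_mean(cm, 1e-4)
  expect_equal(sort(out$W[upper.tri(out$W)]), c(0.5e-4, 1.0e-4, 1.5e-4))

  # fixed point: already at target
  again <- scale_to_target_mean(out, 1e-4)
  expect_equal(again$W, out$W, tolerance = 1e-15)

  # random matrices hit any target exactly; zeros stay zeros
  for (seed in 1:5) {
    W <- random_sc(10, density = 0.6, seed = seed)
    t <- runif(1, 1e-6, 10)
    out <- scale_to_target_mean(as_connectome(W), t)
    expect_equal(mean(out$W[upper.tri(out$W)]), t)
    expect_identical(out$W == 0, W == 0)
  }

  expect_error(scale_to_target_mean(as_connectome(matrix(0, 3, 3))),
               "degenerate")
})

test_that("reparcellation averages fine edges per system pair", {
  # nodes {1,2} -> S, {3,4} -> T
  p <- parcellation("p4", c("S", "S", "T", "T"))
  W <- matrix(0, 4, 4)
  W[1, 2] <- 2; W[3, 4] <- 4; W[1, 3] <- 1; W[1, 4] <- 3
  W[2, 3] <- 5; W[2, 4] <- 7
  W <- W + t(W)
  cm <- connectome(W, p)
  coarse <- reparcellate(cm)
  expect_equal(attr(coarse, "within"), c(S = 2, T = 4))
  expect_equal(coarse$W[1, 2], mean(c(1, 3, 5, 7)))
  expect_equal(diag(coarse$W), rep(0, 2))

  # constant off-diagonal matrix stays constant
  Wc <- matrix(3, 6, 6); diag(Wc) <- 0
  cc <- reparcellate(connectome(Wc, tiny_parcellation(6, 3)))
  expect_true(all(cc$W[upper.tri(cc$W)] == 3))
  expect_equal(unname(attr(cc, "within")), rep(3, 3))

  # identity mapping returns the input matrix (every system is a singleton,
  # so within-system means are flagged)
  W <- random_sc(5, seed = 42)
  cm <- as_connectome(W)
  expect_equal(suppressWarnings(reparcellate(cm))$W, W)

  # commutes with uniform scaling
  W <- random_sc(12, seed = 7)
  p12 <- tiny_parcellation(12, 3)
  r1 <- reparcellate(connectome(W * 3.7, p12))$W
  r2 <- reparcellate(connectome(W, p12))$W * 3.7
  expect_equal(r1, r2, tolerance = 1e-12)

  # singleton system: within entry is 0 with a warning
  p_single <- parcellation("ps", c("A", "A", "B"))
  expect_warning(out <- reparcellate(connectome(random_sc(3, seed = 1), p_single)),
                 "< 2 nodes")
  expect_equal(unname(attr(out, "within")["B"]), 0)
})

test_that("edge vectorization has the documented lengths and order", {
  expect_length(vectorize_edges(as_connectome(random_sc(100, seed = 1)))$values,
                4950)
  expect_length(vectorize_edges(as_connectome(random_sc(7, seed = 2)))$values,
                21)

  p <- parcellation("p5", c("A", "A", "A", "B", "B"))
  cm <- connectome(random_sc(5, seed = 3), p)
  expect_length(vectorize_edges(cm, edge_subset("within", "A"))$values, 3)
  expect_length(vectorize_edges(cm, edge_subset("between", "A", "B"))$values, 6)

  # row-major upper-triangle order
  W <- matrix(0, 3, 3)
  W[1, 2] <- 1; W[1, 3] <- 2; W[2, 3] <- 3
  W <- W + t(W)
  expect_equal(vectorize_edges(as_connectome(W))$values, c(1, 2, 3))

  # between-subsets are orientation invariant
  v1 <- vectorize_edges(cm, edge_subset("between", "A", "B"))$values
  v2 <- vectorize_edges(cm, edge_subset("between", "B", "A"))$values
  expect_identical(v1, v2)

  expect_error(vectorize_edges(cm, edge_subset("within", "Nope")), "unknown")

  # whole-vector length is n(n-1)/2 for a range of sizes
  for (n in c(3, 10, 37)) {
    expect_length(vectorize_edges(as_connectome(random_sc(n, seed = n)))$values,
                  n * (n - 1) / 2)
  }
})

test_that("coupling normalization sets the off-diagonal mean to 1", {
  # uniform weights become exactly 1
  W <- matrix(2, 4, 4); diag(W) <- 0
  C <- normalize_for_km(as_connectome(W))
  expect_true(all(C[row(C) != col(C)] == 1))

  # zeros count in the mean: unique weights {0, 2, 4} -> {0, 1, 2}
  W <- matrix(0, 3, 3); W[1, 2] <- 2; W[1, 3] <- 0; W[2, 3] <- 4
  W <- W + t(W)
  C <- normalize_for_km(as_connectome(W))
  expect_equal(sort(unique(C[upper.tri(C)])), c(0, 1, 2))

  # idempotent and scale invariant
  W <- random_sc(8, density = 0.7, seed = 5)
  C1 <- normalize_for_km(as_connectome(W))
  C2 <- normalize_for_km(as_connectome(W * 100))
  expect_equal(C1, C2, tolerance = 1e-12)
  expect_equal(normalize_for_km(as_connectome(C1)), C1, tolerance = 1e-12)

  expect_error(normalize_for_km(as_connectome(matrix(0, 3, 3))), "degenerate")
})

test_that("core operations preserve symmetry and nonnegativity", {
  for (seed in 1:5) {
    W <- random_sc(9, density = 0.5, seed = seed)
    cm <- connectome(W, tiny_parcellation(9, 3))
    for (M in list(scale_to_target_mean(cm, 0.5)$W,
                   reparcellate(cm)$W,
                   normalize_for_km(cm))) {
      expect_equal(M, t(M))
      expect_true(all(M >= 0))
      expect_true(all(diag(M) == 0))
    }
  }
})

test_that("parcellation round-trips through its TSV map", {
  p <- default_fine_parcellation()
  path <- tempfile(fileext = ".tsv")
  write_parcellation(p, path)
  q <- read_parcellation(path, name = p$name)
  expect_equal(q$systems, p$systems)
  expect_equal(q$n_nodes, 100L)
  expect_equal(length(system_labels(q)), 7L)
})
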