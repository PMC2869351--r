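test_that("deviation entries match the hand-computed two-atom case", {
  # two atoms at distance 1 nm then 3 nm: mean 2, |dev| = 1 each frame
  co <- array(0, dim = c(2, 2, 3))
  co[1, 2, 1] <- 1
  co[2, 2, 1] <- 3
  ens <- conf_ensemble(co)
  D_abs <- deviation_matrix(ens, "absolute")
  expect_equal(D_abs[1, 2], 1.0)
  expect_equal(D_abs[2, 1], 1.0)
  D_sq <- deviation_matrix(ens, "squared")
  expect_equal(D_sq[1, 2], 1.0)  # (1-2)^2 and (3-2)^2 average to 1 nm^2
})

test_that("rigid-body ensembles give an identically zero matrix", {
  base <- matrix(rnorm(15), 5, 3)
  co <- array(NA_real_, dim = c(6, 5, 3))
  set.seed(11)
  for (f in 1:6) {
    R <- random_rotation()
    co[f, , ] <- sweep(base %*% t(R), 2, rnorm(3), "+")
  }
  D <- deviation_matrix(conf_ensemble(co))
  expect_lt(max(abs(D)), 1e-12)
})

test_that("computed matrices satisfy symmetry, non-negativity, zero diagonal", {
  set.seed(3)
  for (rep in 1:5) {
    co <- array(rnorm(8 * 6 * 3), dim = c(8, 6, 3))
    D <- deviation_matrix(conf_ensemble(co))
    expect_identical(mat(D), t(mat(D)))
    expect_true(all(D >= 0))
    expect_identical(diag(mat(D)), rep(0, 6))
  }
})

test_that("D is invariant under frame permutation and per-frame rigid motion", {
  set.seed(5)
  gt <- small_hinged(seed = 5)
  D <- gt$D
  perm <- sample(gt$ensemble$n_frames)
  D_perm <- deviation_matrix(
    conf_ensemble(gt$ensemble$coords[perm, , , drop = FALSE],
                  gt$ensemble$atoms))
  expect_equal(mat(D_perm), mat(D), tolerance = 1e-12)
  D_rigid <- deviation_matrix(scramble_frames(gt$ensemble))
  expect_lt(max(abs(D_rigid - D)), 1e-10)
})

test_that("squared-mode entries dominate squared absolute-mode entries", {
  set.seed(9)
  co <- array(rnorm(10 * 5 * 3), dim = c(10, 5, 3))
  ens <- conf_ensemble(co)
  D_abs <- deviation_matrix(ens, "absolute")
  D_sq <- deviation_matrix(ens, "squared")
  expect_true(all(D_sq - unclass(D_abs)^2 >= -1e-12))  # Jensen
})

test_that("single-frame ensembles are rejected for deviation computation", {
  co <- array(rnorm(1 * 4 * 3), dim = c(1, 4, 3))
  expect_error(deviation_matrix(conf_ensemble(co)), ">= 2 conformations")
})

test_that("flexibility is the off-diagonal row mean", {
  a <- 0.7
  D <- as_deviation_matrix(matrix(a, 3, 3) - a * diag(3))
  expect_equal(atom_flexibility(D), rep(a, 3))
  D0 <- as_deviation_matrix(matrix(0, 4, 4))
  expect_equal(atom_flexibility(D0), rep(0, 4))
  expect_error(atom_flexibility(as_deviation_matrix(matrix(0, 1, 1))),
               "at least 2")
})

test_that("hinge-adjacent atoms are more flexible than rigid-core atoms", {
  gt <- small_hinged(sizes = c(5, 5), amplitude = 1, n_frames = 80, seed = 21)
  flex <- atom_flexibility(gt$D)
  # atoms far from the hinge swing most under a hinge rotation
  expect_gt(mean(flex), 0)
  # core atoms within one body: flexibility strictly below the per-body max
  expect_true(all(tapply(flex, gt$labels, function(v) diff(range(v)) > 0)))
})

test_that("symmetric-copy averaging reduces and preserves invariants", {
  gt <- small_hinged(sizes = c(4, 4), seed = 13)
  D <- gt$D
  # identity: one copy listing all atoms returns D unchanged
  expect_equal(mat(average_symmetric_copies(D, list(1:8))), mat(D))
  # two copies: element-wise mean of the sub-blocks
  avg <- average_symmetric_copies(D, list(1:4, 5:8))
  manual <- (mat(D)[1:4, 1:4] + mat(D)[5:8, 5:8]) / 2
  expect_equal(mat(avg), manual)
  expect_identical(mat(avg), t(mat(avg)))
  # errors
  expect_error(average_symmetric_copies(D, list(1:4, 5:7)), "same number")
  expect_error(average_symmetric_copies(D, list(1:4, 6:9)), "out of range")
  expect_error(average_symmetric_copies(D, list(1:4, 4:7)), "overlap")
})

test_that("CSV round-trip preserves the matrix and its invariants", {
  gt <- small_hinged(seed = 17)
  f <- withr::local_tempfile(fileext = ".csv")
  write_deviation_csv(gt$D, f)
  D2 <- read_deviation_csv(f)
  expect_equal(mat(D2), mat(gt$D), tolerance = 1e-12)
})
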