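test_that("clustering error matches hand-expanded values", {
  c_ <- 0.8
  D <- as_deviation_matrix(c_ * (matrix(1, 3, 3) - diag(3)))
  # perfectly rigid blocks -> zero error
  Dz <- toy_matrices()$two_zero_blocks
  expect_equal(clustering_error(Dz, hard_membership(c(1, 1, 2, 2), 2)), 0)
  # hard {1,2}|{3} on uniform off-diagonal c: the one co-clustered pair
  # contributes 2c
  expect_equal(clustering_error(D, hard_membership(c(1, 1, 2), 2)), 2 * c_)
  # uniform fuzzy memberships: E = 3c, strictly worse than the hard optimum
  expect_equal(clustering_error(D, matrix(0.5, 3, 2)), 3 * c_)
  expect_error(clustering_error(D, matrix(0.5, 4, 2)), "rows")
})

test_that("random initial memberships are feasible and reproducible", {
  P <- random_membership(3, 1, seed = 4)
  expect_equal(P, matrix(1, 3, 1))
  expect_identical(random_membership(7, 3, seed = 9),
                   random_membership(7, 3, seed = 9))
  for (case in list(c(5, 2), c(9, 4), c(12, 11))) {
    P <- random_membership(case[1], case[2], seed = sum(case))
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(rowSums(P), rep(1, case[1]), tolerance = 1e-12)
  }
  expect_error(random_membership(3, 4), "more domains")
})

test_that("solver finds the zero-error block partition from any start", {
  D <- toy_matrices()$two_zero_blocks
  for (s in 1:5) {
    res <- solve_memberships(D, 2, seed = s)
    expect_equal(res$E, 0)
    expect_true(same_partition(res$assignment, c(1, 1, 2, 2)))
  }
})

test_that("solver results are internally consistent and feasible", {
  gt <- small_hinged(sizes = c(4, 3), seed = 31)
  res <- solve_memberships(gt$D, 2, seed = 2)
  # E re-derivable from the membership it reports
  expect_equal(res$E, clustering_error(gt$D, res$membership),
               tolerance = 1e-8)
  expect_equal(res$assignment, max.col(res$membership, ties.method = "first"))
  expect_true(all(res$membership >= 0 & res$membership <= 1))
  expect_equal(rowSums(res$membership), rep(1, 7), tolerance = 1e-9)
  expect_error(solve_memberships(gt$D, 2, initial = matrix(0.6, 7, 2)),
               "sum to 1")
})

test_that("converged memberships are vertex solutions for generic matrices", {
  for (s in c(2, 7, 19)) {
    D <- random_instance(6, seed = s)
    res <- solve_memberships(D, 2, seed = s)
    expect_lt(max(pmin(res$membership, 1 - res$membership)), 1e-6)
  }
})

test_that("domain-label permutation leaves the error unchanged", {
  D <- random_instance(7, seed = 23)
  res <- solve_memberships(D, 3, seed = 1)
  for (rep in 1:3) {
    perm <- sample(3)
    expect_equal(clustering_error(D, res$membership[, perm]), res$E)
  }
})

test_that("best-over-restarts matches the exhaustive optimum", {
  for (s in 1:8) {
    n <- 5 + s %% 4
    M <- 2 + s %% 2
    D <- random_instance(n, seed = 100 + s)
    best <- best_over_restarts(D, M, restarts = 10, seed = s)
    orc <- brute_force_clustering(D, M)
    expect_equal(best$E, orc$best_E, tolerance = 1e-8)
  }
})

test_that("splitting the worst domain preserves feasibility and helps", {
  gt <- small_hinged(sizes = c(3, 3, 3), amplitude = 0.8, seed = 41)
  D <- gt$D
  res1 <- solve_memberships(D, 1, initial = matrix(1, 9, 1))
  P2 <- split_worst_domain(res1, D, seed = 1)
  expect_equal(dim(P2), c(9, 2))
  expect_equal(rowSums(P2), rep(1, 9), tolerance = 1e-12)
  expect_true(all(P2 >= 0 & P2 <= 1))
  # split-then-solve never exceeds the parent's error
  res2 <- solve_memberships(D, 2, initial = P2)
  expect_lte(res2$E, res1$E + 1e-12)
  expect_error(split_worst_domain(res1, D, fraction = 1), "between 0 and 1")
})

test_that("successive-restart series is monotone with the exact endpoints", {
  gt <- small_hinged(sizes = c(3, 2, 3), amplitude = 0.7, seed = 51)
  D <- gt$D
  n <- nrow(D)
  series <- solve_series(D, n, restarts = 5, seed = 2)
  E <- vapply(series, function(r) r$E, 0)
  expect_equal(E[1], sum(D))  # all-ones single domain
  expect_true(all(diff(E) <= 1e-10))
  expect_equal(E[n], 0)       # one atom per domain
  expect_equal(sort(series[[n]]$assignment), 1:n)
  # a two-zero-block matrix collapses to zero error from M = 2 onwards
  Dz <- toy_matrices()$two_zero_blocks
  Ez <- vapply(solve_series(Dz, 4, restarts = 5, seed = 3),
               function(r) r$E, 0)
  expect_equal(Ez[-1], rep(0, 3))
  expect_error(solve_series(D, n + 1), "exceeds")
})
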