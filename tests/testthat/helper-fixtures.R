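# shared fixtures: small ensembles, rigid transforms, random instances

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q %*% diag(c(1, 1, det(Q)))
}

# apply an independent random rigid transform (rotation + translation)
# to every frame of an ensemble
scramble_frames <- function(ensemble) {
  co <- ensemble$coords
  for (f in seq_len(ensemble$n_frames)) {
    R <- random_rotation()
    t_vec <- rnorm(3, sd = 5)
    co[f, , ] <- sweep(co[f, , , drop = TRUE] %*% t(R), 2, t_vec, "+")
  }
  conf_ensemble(co, ensemble$atoms)
}

# small articulated ensemble and its deviation matrix
small_hinged <- function(sizes = c(3, 3), amplitude = 1, n_frames = 40,
                         noise = 0.01, seed = 1) {
  gt <- generate_hinged_ensemble(synthetic_spec(
    bodies = sizes, hinges = rep(amplitude, length(sizes) - 1),
    n_frames = n_frames, noise_sigma = noise, seed = seed))
  gt$D <- deviation_matrix(gt$ensemble)
  gt
}

# random small deviation matrix from the generator (single-atom bodies,
# random hinge amplitudes -> generic, non-degenerate structure)
random_instance <- function(n, seed) {
  spec <- synthetic_spec(bodies = rep(1L, n),
                         hinges = withr::with_seed(seed, runif(n - 1, 0, 1)),
                         n_frames = 30, noise_sigma = 0.02, seed = seed)
  deviation_matrix(generate_hinged_ensemble(spec)$ensemble)
}

# bare numeric matrix (drop class and deviation attributes) for identity checks
mat <- function(D) {
  x <- unclass(D)
  attributes(x) <- list(dim = dim(x))
  x
}

best_over_restarts <- function(D, M, restarts = 10, seed = 0) {
  best <- NULL
  for (r in seq_len(restarts)) {
    res <- solve_memberships(D, M, seed = seed * 1000 + r)
    if (is.null(best) || res$E < best$E) best <- res
  }
  best
}
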