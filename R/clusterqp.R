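#' Clustering error of a fuzzy domain assignment
#'
#' The objective minimized by the domain decomposition: with membership
#' columns p_k (atom-to-domain probabilities) and distance-deviation matrix
#' D,
#' \deqn{E = \sum_{k=1}^{M} p_k^\top D\, p_k}
#' i.e. the membership-weighted sum of distance deviations between atoms
#' assigned to the same domain — the amount of internal motion neglected by
#' treating each domain as rigid. Each ordered pair (i, j), i != j, of hard
#' co-members contributes d_ij, so an unordered pair contributes 2 d_ij.
#'
#' The block structure of the quadratic form is exploited: the full
#' `NM x NM` Hessian (block diagonal with M copies of D) is never formed;
#' the objective and gradient are evaluated column-wise through `D %*% P`,
#' which reduces memory by a factor of M^2.
#'
#' @param D a `deviation_matrix` (or plain symmetric matrix)
#' @param P an `N x M` membership matrix; rows on the probability simplex
#' @return the non-negative clustering error E (units of `D`)
#' @export
clustering_error <- function(D, P) {
  P <- as.matrix(P)
  if (nrow(P) != nrow(D))
    stop("membership matrix has ", nrow(P), " rows but D is ", nrow(D),
         " x ", ncol(D))
  sum(P * (unclass(D) %*% P))
}

validate_membership <- function(P, tol = 1e-9) {
  if (any(P < -tol) || any(P > 1 + tol))
    stop("membership probabilities must lie in [0, 1]")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > tol))
    stop("membership rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  invisible(P)
}

#' Random feasible membership matrix
#'
#' Draws every membership probability uniformly in (0, 1) and normalizes
#' each atom's row to sum to one — the standard random initial condition
#' for the clustering solver.
#'
#' @param n_atoms N
#' @param n_domains M (requires `M <= N`)
#' @param seed optional integer seed; the global RNG state is restored
#'   afterwards
#' @return an `N x M` row-stochastic matrix
#' @export
random_membership <- function(n_atoms, n_domains, seed = NULL) {
  if (n_domains < 1L) stop("need at least one domain")
  if (n_domains > n_atoms)
    stop("more domains (", n_domains, ") than atoms (", n_atoms, ")")
  with_seed(seed, {
    P <- matrix(stats::runif(n_atoms * n_domains), n_atoms, n_domains)
    P / rowSums(P)
  })
}

# Euclidean projection of each row onto the probability simplex
# (sort-based algorithm; exact up to floating point).
project_rows_simplex <- function(P) {
  n <- nrow(P); m <- ncol(P)
  if (m == 1L) return(matrix(1, n, 1L))
  U <- t(apply(P, 1L, sort, decreasing = TRUE))
  css <- t(apply(U, 1L, cumsum)) - 1
  j <- matrix(seq_len(m), n, m, byrow = TRUE)
  cond <- U - css / j > 0
  rho <- max.col(cond, ties.method = "last")
  theta <- css[cbind(seq_len(n), rho)] / rho
  pmax(P - theta, 0)
}

# Exact row-wise coordinate descent to a vertex ("active-set polish").
# E is linear in each membership row because diag(D) = 0, so with the other
# rows fixed the optimal row i is the unit vector on argmin_k (D P)[i, k].
# Sweeping rows is monotone in E and terminates at a vertex local optimum;
# a pairwise-exchange phase then escapes vertices where no single-atom move
# improves but swapping two atoms between domains does.
polish_to_vertex <- function(D, P, max_sweeps = 200L) {
  D <- unclass(D)
  n <- nrow(P)
  assign <- max.col(P, ties.method = "first")
  m <- ncol(P)
  P <- matrix(0, n, m)
  P[cbind(seq_len(n), assign)] <- 1
  DP <- D %*% P

  move_atom <- function(i, to) {
    from <- assign[i]
    DP[, from] <<- DP[, from] - D[, i]
    DP[, to] <<- DP[, to] + D[, i]
    P[i, from] <<- 0; P[i, to] <<- 1
    assign[i] <<- to
  }
  single_move_sweeps <- function() {
    for (sweep in seq_len(max_sweeps)) {
      changed <- FALSE
      for (i in seq_len(n)) {
        costs <- DP[i, ]
        best <- which.min(costs)
        if (costs[best] < costs[assign[i]] - 1e-12) {
          move_atom(i, best)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }

  for (round in seq_len(max_sweeps)) {
    single_move_sweeps()
    if (m < 2L) break
    # exchange gain for atoms i, j in different domains:
    # dE/2 = DP[i, a_j] - DP[i, a_i] + DP[j, a_i] - DP[j, a_j] - 2 d_ij
    X <- DP[, assign, drop = FALSE]           # X[i, j] = DP[i, a_j]
    own <- DP[cbind(seq_len(n), assign)]
    gain <- X + t(X) - outer(own, own, "+") - 2 * D
    gain[outer(assign, assign, "==")] <- Inf
    best <- which.min(gain)
    if (!is.finite(gain[best]) || gain[best] >= -1e-12) break
    i <- (best - 1L) %% n + 1L
    j <- (best - 1L) %/% n + 1L
    ai <- assign[i]
    move_atom(i, assign[j])
    move_atom(j, ai)
  }
  P
}

#' Solve the constrained quadratic domain-assignment problem
#'
#' Minimizes the clustering error `E = sum_k p_k' D p_k` over membership
#' matrices whose rows lie on the probability simplex (each atom's
#' memberships are in \[0, 1\] and sum to 1). The quadratic program is
#' non-convex (D has zero trace), and its minima are in practice vertex
#' (0/1) solutions: each atom tilts over to the domain that adds the least
#' error.
#'
#' The solver runs two phases over feasible points: projected gradient
#' descent with backtracking line search and exact per-row simplex
#' projection, followed by a vertex-polish pass of exact row-wise
#' coordinate descent on the active bounds (E is linear in each row, so
#' each row's optimum given the others is a vertex). The objective never
#' increases along the iteration.
#'
#' @param D a `deviation_matrix`
#' @param n_domains number of domains M
#' @param initial optional feasible `N x M` starting membership matrix;
#'   default a random start from `seed`
#' @param seed integer seed used when `initial` is not given
#' @param tol convergence tolerance on the relative objective decrease
#' @param max_iter maximum projected-gradient iterations
#' @return an object of class `domain_clustering`: list with `membership`,
#'   `assignment` (argmax per row, ties to the lowest domain index), `E`,
#'   `E_N` (normalized error, see [normalized_error()]), `n_domains`
#'   (requested M), `n_effective` (non-empty domains), `converged`,
#'   `n_iterations`, and `seed`
#' @seealso [solve_series()], [select_num_domains()], [brute_force_clustering()]
#' @export
solve_memberships <- function(D, n_domains, initial = NULL, seed = NULL,
                              tol = 1e-10, max_iter = 5000L) {
  n <- nrow(D)
  if (n_domains < 1L) stop("need at least one domain")
  if (n_domains > n) stop("more domains (", n_domains, ") than atoms (", n, ")")
  if (tol <= 0) stop("tol must be positive")
  if (is.null(initial)) initial <- random_membership(n, n_domains, seed)
  P <- as.matrix(initial)
  if (nrow(P) != n || ncol(P) != n_domains)
    stop("initial membership must be ", n, " x ", n_domains)
  validate_membership(P, tol = 1e-7)
  Dm <- unclass(D)

  E <- clustering_error(Dm, P)
  step <- 1 / max(max(Dm), .Machine$double.eps)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    G <- 2 * (Dm %*% P)
    # backtracking line search on the projected step
    repeat {
      P_new <- project_rows_simplex(P - step * G)
      E_new <- clustering_error(Dm, P_new)
      if (E_new <= E + 1e-15 || step < 1e-14) break
      step <- step / 2
    }
    if (E_new > E) {  # no descent possible at machine precision
      converged <- TRUE
      break
    }
    dec <- E - E_new
    P <- P_new
    E <- E_new
    step <- step * 1.5  # cautious step growth between iterations
    if (dec <= tol * max(E, 1e-300)) {
      converged <- TRUE
      break
    }
  }

  P <- polish_to_vertex(Dm, P)
  E <- clustering_error(Dm, P)
  finish_clustering(D, P, n_domains, E, converged, iter, seed)
}

finish_clustering <- function(D, P, n_domains, E, converged, iter, seed) {
  assignment <- max.col(P, ties.method = "first")
  structure(
    list(
      membership = P,
      assignment = assignment,
      E = E,
      E_N = normalized_error(D, P),
      n_domains = n_domains,
      n_effective = length(unique(assignment)),
      converged = converged,
      n_iterations = iter,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    ),
    class = "domain_clustering"
  )
}

#' @export
print.domain_clustering <- function(x, ...) {
  cat("Domain clustering: M =", x$n_domains,
      sprintf("(%d non-empty), E = %.6g, E_N = %.6g\n",
              x$n_effective, x$E, x$E_N))
  cat("Domain sizes:",
      paste(tabulate(x$assignment, nbins = x$n_domains), collapse = " "), "\n")
  invisible(x)
}

#' Successive-restart initial condition: split the worst domain
#'
#' Builds a feasible starting membership for M + 1 domains from a converged
#' M-domain solution. The domain with the largest error per member,
#' \deqn{k^* = \arg\max_k \frac{p_k^\top D p_k}{\sum_i p_{ik}},}
#' is split: each member atom keeps its membership in k* or transfers it
#' entirely to the new domain M + 1 by an independent coin flip (probability
#' `fraction` for the new domain), so the two memberships always sum to the
#' original value and every row stays on the simplex. All other memberships
#' are unchanged, with zero in the new column.
#'
#' @param result a `domain_clustering` (a warning is issued if it did not
#'   converge)
#' @param D the `deviation_matrix` the result was computed from
#' @param seed optional integer seed for the coin flips
#' @param fraction probability that a member's weight moves to the new
#'   domain (strictly between 0 and 1)
#' @return an `N x (M + 1)` feasible membership matrix
#' @export
split_worst_domain <- function(result, D, seed = NULL, fraction = 0.5) {
  stopifnot(inherits(result, "domain_clustering"))
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be strictly between 0 and 1")
  if (!result$converged)
    warning("splitting a non-converged clustering result")
  P <- result$membership
  Dm <- unclass(D)
  col_mass <- colSums(P)
  per_domain_E <- colSums(P * (Dm %*% P))
  score <- ifelse(col_mass > 0, per_domain_E / col_mass, -Inf)
  if (all(!is.finite(score))) stop("all domains are empty; cannot split")
  k_star <- which.max(score)
  members <- which(P[, k_star] > 0)
  if (!length(members)) stop("worst domain is empty; cannot split")
  P_new <- cbind(P, 0)
  coin <- with_seed(seed, stats::runif(length(members)) < fraction)
  move <- members[coin]
  P_new[move, ncol(P_new)] <- P_new[move, k_star]
  P_new[move, k_star] <- 0
  P_new
}

#' Solve the clustering for a whole series of domain counts
#'
#' Runs the solver for M = 1, ..., `M_max`. For each M the best of several
#' candidate starts is kept: `restarts` random initial conditions, the
#' successive-restart start obtained by splitting the worst domain of the
#' best (M - 1)-domain solution, and that solution padded with an empty
#' domain (which realizes the parent partition exactly in M domains, so the
#' reported error series is non-increasing by construction). For M = N the
#' identity partition — one atom per domain, zero error — is seeded as a
#' further candidate, the known exact solution in that limit.
#'
#' @param D a `deviation_matrix`
#' @param M_max largest number of domains (at most N)
#' @param restarts random restarts per M
#' @param seed master seed; all per-M and per-restart seeds derive from it
#' @param tol,max_iter passed to [solve_memberships()]
#' @return list of `domain_clustering` objects, element M for M domains
#' @export
solve_series <- function(D, M_max, restarts = 10L, seed = 0L,
                         tol = 1e-10, max_iter = 5000L) {
  n <- nrow(D)
  if (M_max > n) stop("M_max (", M_max, ") exceeds the number of atoms (", n, ")")
  if (M_max < 1L) stop("M_max must be >= 1")
  results <- vector("list", M_max)

  # M = 1: the single feasible point
  P1 <- matrix(1, n, 1L)
  results[[1]] <- finish_clustering(D, P1, 1L, clustering_error(D, P1),
                                    TRUE, 0L, seed)
  for (M in seq_len(M_max)[-1]) {
    best <- NULL
    parent <- results[[M - 1]]
    starts <- list(
      split_worst_domain(parent, D, seed = child_seed(seed, M, 0L)),
      cbind(parent$membership, 0)  # parent partition realized in M domains
    )
    if (M == n) {
      starts <- c(starts, list(diag(n)))
    }
    for (r in seq_len(restarts)) {
      starts <- c(starts, list(random_membership(n, M, child_seed(seed, M, r))))
    }
    for (P0 in starts) {
      res <- solve_memberships(D, M, initial = P0, seed = seed,
                               tol = tol, max_iter = max_iter)
      if (is.null(best) || res$E < best$E) best <- res
    }
    results[[M]] <- best
  }
  results
}

# deterministic per-(M, restart) child seed, kept within 32-bit range
child_seed <- function(seed, M, r) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 100000L) * 10000L + M * 100L + r
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
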