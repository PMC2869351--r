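#' Normalized clustering error
#'
#' A physically interpretable quality measure for a domain decomposition:
#' the per-atom average deviation between an atom and the co-members of its
#' domains,
#' \deqn{e_i = \frac{\sum_k p_{ik} \sum_{j \ne i} p_{jk} d_{ij}}
#'                  {\sum_k p_{ik} \sum_{j \ne i} p_{jk}}, \qquad
#'       E_N = \frac{1}{N}\sum_i e_i.}
#' For a hard clustering, e_i is simply the mean deviation between atom i
#' and its same-domain partners. E_N is not what the solver optimizes; it
#' measures the mean distance deviation of pairs within domains and is
#' identically zero when the molecule consists of M perfectly rigid
#' domains. It carries length units: in absolute mode it is reported in nm
#' directly; in squared mode the square root of each e_i is taken first
#' (an RMSD per atom), so the reported value is always a length.
#'
#' An atom alone in its domain has no partners and contributes e_i = 0 by
#' convention, consistent with E_N tending to 0 as M approaches N.
#'
#' @param D a `deviation_matrix`
#' @param P an `N x M` membership matrix
#' @return E_N in nm
#' @export
normalized_error <- function(D, P) {
  P <- as.matrix(P)
  if (nrow(P) != nrow(D))
    stop("membership matrix has ", nrow(P), " rows but D is ", nrow(D),
         " x ", ncol(D))
  Dm <- unclass(D)
  num <- rowSums(P * (Dm %*% P))                       # diag(D)=0 excludes j=i
  den <- rowSums(P * sweep(-P, 2L, colSums(P), "+"))   # sum_k p_ik (m_k - p_ik)
  e <- ifelse(den > 1e-12, num / pmax(den, 1e-300), 0)
  if (dev_mode(D) == "squared") e <- sqrt(pmax(e, 0))
  mean(e)
}

#' Automatically select the number of domains
#'
#' Increases the number of domains M from `M_start`, computing the optimal
#' clustering for each M along the successive-restart series, and returns
#' the first clustering whose normalized error E_N falls at or below the
#' user-imposed bound `epsilon`. The bound has a direct physical reading:
#' the accepted decomposition leaves, on average, at most `epsilon` of
#' distance deviation between an atom and its domain co-members. If the
#' bound is never met up to `M_cap`, the `M_cap` result is returned flagged
#' as unsatisfied.
#'
#' @param D a `deviation_matrix`
#' @param epsilon maximum acceptable normalized error, nm (default 0.1 nm
#'   = 1 angstrom, a conventional rigidity scale)
#' @param M_start first number of domains tried (>= 2)
#' @param M_cap safety upper bound on M (default N)
#' @param restarts,seed,tol,max_iter passed to [solve_series()]
#' @return the selected `domain_clustering`, with extra fields `epsilon`,
#'   `satisfied`, and `series` (the `domain_clustering` list for
#'   M = 1..selected M)
#' @export
select_num_domains <- function(D, epsilon = 0.1, M_start = 2L, M_cap = nrow(D),
                               restarts = 10L, seed = 0L,
                               tol = 1e-10, max_iter = 5000L) {
  n <- nrow(D)
  if (epsilon <= 0) stop("epsilon must be positive")
  if (M_start < 2L || M_start > M_cap || M_cap > n)
    stop("need 2 <= M_start <= M_cap <= N")
  # grow the successive-restart series incrementally until the bound holds
  series <- solve_series(D, M_start, restarts = restarts, seed = seed,
                         tol = tol, max_iter = max_iter)
  M <- M_start
  while (series[[M]]$E_N > epsilon && M < M_cap) {
    M <- M + 1L
    series <- extend_series(D, series, M, restarts, seed, tol, max_iter)
  }
  out <- series[[M]]
  out$epsilon <- epsilon
  out$satisfied <- out$E_N <= epsilon
  out$series <- series
  out
}

# add the result for one more M to an existing successive-restart series
extend_series <- function(D, series, M, restarts, seed, tol, max_iter) {
  n <- nrow(D)
  parent <- series[[M - 1]]
  starts <- list(
    split_worst_domain(parent, D, seed = child_seed(seed, M, 0L)),
    cbind(parent$membership, 0)
  )
  if (M == n) starts <- c(starts, list(diag(n)))
  for (r in seq_len(restarts))
    starts <- c(starts, list(random_membership(n, M, child_seed(seed, M, r))))
  best <- NULL
  for (P0 in starts) {
    res <- solve_memberships(D, M, initial = P0, seed = seed,
                             tol = tol, max_iter = max_iter)
    if (is.null(best) || res$E < best$E) best <- res
  }
  series[[M]] <- best
  series
}

#' Rank domain counts by the error drop they achieve
#'
#' A user aid for choosing M by eye: for each step M - 1 -> M in a
#' clustering-error series, reports the gap E(M - 1) - E(M). A large gap
#' followed by a flat tail marks a natural number of domains.
#'
#' @param series list of `domain_clustering` results for consecutive M
#'   starting at M = 1 (as returned by [solve_series()])
#' @return `data.frame` with columns `M` (the step's endpoint) and `gap`,
#'   sorted by decreasing gap; ties keep increasing M order
#' @export
error_gap_report <- function(series) {
  if (length(series) < 2L) stop("need results for at least two values of M")
  E <- vapply(series, function(r) r$E, 0)
  M <- vapply(series, function(r) r$n_domains, 0L)
  if (any(diff(M) != 1L)) stop("series must cover consecutive M")
  gaps <- data.frame(M = M[-1], gap = E[-length(E)] - E[-1])
  gaps[order(-gaps$gap, gaps$M), , drop = FALSE]
}
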