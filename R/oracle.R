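#' Brute-force globally optimal hard clustering
#'
#' Enumerates every hard assignment of N atoms to at most M domain labels
#' and returns the minimum of the clustering error
#' `E = sum_k z_k' D z_k` over them — the exact integer optimum, used as
#' independent ground truth when validating the quadratic-programming
#' solver on small instances.
#'
#' Assignments are enumerated as restricted growth strings (atom 1 always
#' in domain 1, each new label introduced in increasing order), which
#' canonicalizes away the up-to-M! label permutations of every partition.
#' Enumeration order is lexicographic and the first minimum encountered is
#' kept, so ties break lexicographically.
#'
#' @param D a `deviation_matrix` (or plain symmetric matrix)
#' @param n_domains maximum number of domain labels M
#' @param limit refuse instances with more than `limit` raw assignments
#'   (`M^N`); default 1e7
#' @return list of class `oracle_result` with `best_assignment`, `best_E`
#'   and `n_evaluated` (number of canonical assignments enumerated)
#' @export
brute_force_clustering <- function(D, n_domains, limit = 1e7) {
  Dm <- unclass(as.matrix(D))
  n <- nrow(Dm)
  M <- as.integer(n_domains)
  if (M < 1L) stop("need at least one domain")
  if (M^n > limit)
    stop("instance too large for exhaustive enumeration: ", M, "^", n,
         " > ", format(limit, scientific = FALSE))
  state <- new.env(parent = emptyenv())
  state$best_E <- Inf
  state$best <- integer(0)
  state$count <- 0L
  assign_vec <- integer(n)

  # depth-first over restricted growth strings; cost accumulated
  # incrementally: placing atom i into label k adds 2 * sum_{j<i, a_j=k} d_ij
  recurse <- function(i, max_label, cost) {
    if (i > n) {
      state$count <- state$count + 1L
      if (cost < state$best_E) {
        state$best_E <- cost
        state$best <- assign_vec
      }
      return(invisible())
    }
    top <- min(max_label + 1L, M)
    for (k in seq_len(top)) {
      prev <- which(assign_vec[seq_len(i - 1L)] == k)
      add <- if (length(prev)) 2 * sum(Dm[prev, i]) else 0
      assign_vec[i] <<- k
      recurse(i + 1L, max(max_label, k), cost + add)
    }
    assign_vec[i] <<- 0L
  }
  recurse(1L, 0L, 0)
  structure(list(best_assignment = state$best, best_E = state$best_E,
                 n_evaluated = state$count),
            class = "oracle_result")
}

#' @export
print.oracle_result <- function(x, ...) {
  cat("Exhaustive optimum: E =", format(x$best_E), "over", x$n_evaluated,
      "canonical assignments\n")
  cat("Assignment:", paste(x$best_assignment, collapse = " "), "\n")
  invisible(x)
}

#' Hard membership matrix from an assignment vector
#'
#' @param assignment integer labels in `1..n_domains`
#' @param n_domains number of domains (default `max(assignment)`)
#' @return an `N x M` 0/1 membership matrix
#' @export
hard_membership <- function(assignment, n_domains = max(assignment)) {
  n <- length(assignment)
  P <- matrix(0, n, n_domains)
  P[cbind(seq_len(n), assignment)] <- 1
  P
}

#' Do two hard assignments describe the same partition?
#'
#' Compares two labelings up to permutation of the labels.
#'
#' @param a,b integer label vectors of equal length
#' @return TRUE if the induced partitions are identical
#' @export
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  identical(canonical_labels(a), canonical_labels(b))
}

canonical_labels <- function(a) {
  match(a, unique(a))
}
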