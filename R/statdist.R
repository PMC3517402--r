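# Indecomposable stationary distributions estimated from whole trajectories,
# and their clustering by support-overlap similarity.

#' Stationary-distribution estimate from one trajectory
#'
#' Time-average occupancy of each visited state over the whole horizon
#' `[0, T]`: `P[s0 = S] = (1/T) * time spent in S`.  For a trajectory that
#' has settled into an indecomposable stationary distribution this estimates
#' that distribution; early transient occupancy is not removed (choose the
#' horizon long enough that it is negligible).
#'
#' @param trajectory a `"bkmc_trajectory"` with positive horizon.
#' @param id optional trajectory identifier carried through to clustering.
#' @return an object of class `"bkmc_statdist_estimate"`: list with `states`
#'   (ids, sorted), `p` (occupancies, summing to 1) and `traj_id`.
#' @export
stationary_estimate <- function(trajectory, id = NA_integer_) {
  horizon <- trajectory$horizon
  if (is.null(horizon) || !is.finite(horizon) || horizon <= 0) stop("zero-length trajectory")
  len <- diff(c(trajectory$times, horizon))
  occ <- rowsum(len, trajectory$states)
  states <- as.numeric(rownames(occ))
  p <- as.numeric(occ) / horizon
  keep <- p > 0
  structure(list(states = states[keep], p = p[keep], traj_id = id,
                 n = trajectory$n, node_names = trajectory$node_names),
            class = "bkmc_statdist_estimate")
}

#' @export
print.bkmc_statdist_estimate <- function(x, ...) {
  cat(sprintf("Stationary-distribution estimate over %d state%s\n",
              length(x$states), if (length(x$states) == 1) "" else "s"))
  ord <- order(x$p, decreasing = TRUE)
  for (i in head(ord, 6L)) {
    cat(sprintf("  P[%s] = %.4g\n", state_label(x$states[i], x$node_names), x$p[i]))
  }
  if (length(ord) > 6L) cat(sprintf("  ... %d more\n", length(ord) - 6L))
  invisible(x)
}

#' Similarity of two stationary-distribution estimates
#'
#' The shared support is the set of states with strictly positive probability
#' in both estimates; the similarity is the product of the two total masses
#' carried on that shared support,
#' \eqn{D = (\sum_{S \in supp} \hat P_a[S]) (\sum_{S \in supp} \hat P_b[S])}.
#' `D` lies in `[0, 1]`, is symmetric, equals 1 for identical supports with
#' full mass, and 0 for disjoint supports.  Two estimates drawn from the same
#' indecomposable stationary distribution have `D -> 1` as the horizon grows
#' (indecomposable stationary distributions are identical iff they share
#' their support).
#'
#' @param a,b `"bkmc_statdist_estimate"` objects.
#' @return similarity coefficient in `[0, 1]`.
#' @export
statdist_similarity <- function(a, b) {
  i <- match(a$states, b$states)
  shared <- !is.na(i)
  if (!any(shared)) return(0)
  sum(a$p[shared]) * sum(b$p[i[shared]])
}

# Single-linkage clusters (connected components of the D >= alpha graph)
# from a similarity matrix; returns a membership integer vector.
cluster_from_similarity <- function(D, alpha) {
  m <- nrow(D)
  adj <- (D >= alpha)
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  igraph::components(g)$membership
}

#' Cluster stationary-distribution estimates
#'
#' Builds the graph on estimates with an edge wherever the similarity
#' [statdist_similarity()] is at least `alpha`, and takes connected
#' components (the minimal closure of the existential cluster definition
#' `C = {s0 | exists s0' in C with D(s0, s0') >= alpha}`).  Each cluster gets
#' an averaged distribution (plain mean of member probabilities) with
#' per-state errors `sqrt(Var / |C|)`, and a proportion `|C| / #estimates`.
#' Clusters are reported by descending proportion.
#'
#' This procedure only makes sense for a Markovian observable process, so the
#' caller must not have internal (marginalized) nodes; [bkmc()] enforces
#' this.
#'
#' @param estimates list of `"bkmc_statdist_estimate"`.
#' @param alpha similarity threshold in `(0, 1]`.
#' @return an object of class `"bkmc_cluster_set"`: list with `clusters`
#'   (each: `members`, `proportion`, `states`, `p`, `err`), `alpha`,
#'   `n_estimates` and the full similarity matrix `D`.
#' @export
statdist_cluster <- function(estimates, alpha) {
  if (!length(estimates)) stop("empty estimate set")
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  m <- length(estimates)
  D <- diag(1, m)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        D[i, j] <- D[j, i] <- statdist_similarity(estimates[[i]], estimates[[j]])
      }
    }
  }
  membership <- cluster_from_similarity(D, alpha)
  clusters <- lapply(sort(unique(membership)), function(cl) {
    members <- which(membership == cl)
    states <- sort(unique(unlist(lapply(estimates[members], `[[`, "states"))))
    pm <- matrix(0, length(members), length(states))
    for (k in seq_along(members)) {
      e <- estimates[[members[k]]]
      pm[k, match(e$states, states)] <- e$p
    }
    p <- colMeans(pm)
    err <- if (length(members) > 1L) {
      sqrt(apply(pm, 2L, var) / length(members))
    } else {
      rep(NA_real_, length(states))
    }
    list(members = members, proportion = length(members) / m,
         states = states, p = p, err = err)
  })
  ord <- order(vapply(clusters, `[[`, 0, "proportion"), decreasing = TRUE)
  structure(list(clusters = clusters[ord], alpha = alpha, n_estimates = m, D = D,
                 node_names = estimates[[1L]]$node_names),
            class = "bkmc_cluster_set")
}

#' @export
print.bkmc_cluster_set <- function(x, ...) {
  cat(sprintf("Stationary-distribution clusters: %d cluster%s from %d estimates (alpha = %g)\n",
              length(x$clusters), if (length(x$clusters) == 1) "" else "s",
              x$n_estimates, x$alpha))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  #%d: proportion %.3f, %d state%s in support\n", i, cl$proportion,
                length(cl$states), if (length(cl$states) == 1) "" else "s"))
    ord <- order(cl$p, decreasing = TRUE)
    for (j in head(ord, 4L)) {
      cat(sprintf("      P[%s] = %.4g\n",
                  state_label(cl$states[j], x$node_names), cl$p[j]))
    }
    if (length(ord) > 4L) cat(sprintf("      ... %d more\n", length(ord) - 4L))
  }
  invisible(x)
}

# Driver-side statdist path: errors if any node is internal.
statdist_estimates_from <- function(trajectories, internal) {
  if (any(internal)) {
    stop(paste("stationary-distribution clustering refuses to run with internal nodes:",
               "marginalizing nodes makes the observed process non-Markovian,",
               "so time-averages no longer estimate stationary distributions"),
         call. = FALSE)
  }
  lapply(seq_along(trajectories), function(j) stationary_estimate(trajectories[[j]], id = j))
}
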