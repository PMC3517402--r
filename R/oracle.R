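# Exact master-equation oracle for small networks: generator matrix, matrix
# exponentials, spectra, terminal strongly-connected components, and the
# asynchronous transition graph.  Ground truth for testing the stochastic
# engine; feasible up to ~2^12 states.

#' Build the master-equation generator matrix
#'
#' The generator `Q` is the `2^n x 2^n` rate matrix over all network states:
#' off-diagonal entries `Q[S, S'] = rho(S -> S')` (non-zero only when `S` and
#' `S'` differ in exactly one node) and diagonal `Q[S, S] = -rho_tot(S)`, so
#' every row sums to zero.  State indexing is deterministic: row `i`
#' corresponds to state id `i - 1`.  Instantaneous probabilities (as a row
#' vector) evolve by `dP/dt = P Q`.
#'
#' @param model a `"bkmc_model"`.
#' @param params parameter values (or a `"bkmc_config"`).
#' @param limit refuse models with more than `limit` nodes (dense-exponential
#'   feasibility guard).
#' @return a sparse `dgCMatrix` with `dimnames` the state ids.
#' @export
build_generator <- function(model, params = NULL, limit = 12L) {
  if (model$n > limit) {
    stop(sprintf("model has %d nodes; exact analysis is limited to %d (2^%d states)",
                 model$n, limit, limit))
  }
  ctx <- sim_context(model, params)
  m <- 2^model$n
  ii <- vector("list", m)
  jj <- vector("list", m)
  xx <- vector("list", m)
  for (s in seq_len(m)) {
    ts <- ctx_transitions(ctx, s - 1)
    k <- length(ts$target)
    ii[[s]] <- rep.int(s, k + 1L)
    jj[[s]] <- c(ts$target + 1, s)
    xx[[s]] <- c(ts$rate, -ts$total_rate)
  }
  Q <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(m, m),
                            dimnames = list(as.character(0:(m - 1)), as.character(0:(m - 1))))
  Q
}

#' Solve the master equation exactly
#'
#' Instantaneous probabilities `P(t) = P(0) exp(tQ)` via the matrix
#' exponential, for each requested time.  Entries are clamped at tiny
#' negative values produced by floating point; each returned row sums to 1
#' within 1e-9.
#'
#' @param generator generator matrix from [build_generator()].
#' @param p0 initial distribution over the `2^n` states (sums to 1).
#' @param times numeric vector of times (>= 0).
#' @return a `length(times) x 2^n` matrix of probabilities; rows named by
#'   time, columns by state id.
#' @export
solve_master <- function(generator, p0, times) {
  m <- nrow(generator)
  stopifnot(length(p0) == m)
  if (abs(sum(p0) - 1) > 1e-9) stop("initial distribution must sum to 1")
  out <- matrix(0, length(times), m,
                dimnames = list(format(times), colnames(generator)))
  for (k in seq_along(times)) {
    pt <- if (times[k] == 0) {
      as.numeric(p0)
    } else {
      as.numeric(matrix(p0, 1, m) %*% as.matrix(Matrix::expm(generator * times[k])))
    }
    out[k, ] <- pmax(pt, 0)
  }
  out
}

#' Exact window-averaged probabilities
#'
#' The window estimate targeted by the stochastic estimators is the time
#' average `(1/dt) * integral of P(t) over [tau*dt, (tau+1)*dt]`.  It is
#' computed exactly using the block-matrix identity
#' `expm([[Q, I], [0, 0]] dt) = [[A, J], [0, I]]` with `A = expm(Q dt)` and
#' `J = integral_0^dt expm(Q s) ds`, iterating `P -> P A` across windows.
#'
#' @inheritParams solve_master
#' @param timetick window width `dt`.
#' @param windows number of windows `K`.
#' @return a `K x 2^n` matrix of exact window-averaged probabilities.
#' @export
master_window_average <- function(generator, p0, timetick, windows) {
  m <- nrow(generator)
  stopifnot(length(p0) == m)
  M <- rbind(cbind(as.matrix(generator), diag(m)), matrix(0, m, 2 * m))
  E <- as.matrix(Matrix::expm(Matrix::Matrix(M) * timetick))
  A <- E[seq_len(m), seq_len(m), drop = FALSE]
  J <- E[seq_len(m), m + seq_len(m), drop = FALSE]
  out <- matrix(0, windows, m, dimnames = list(NULL, colnames(generator)))
  v <- matrix(p0, 1, m)
  for (tau in seq_len(windows)) {
    out[tau, ] <- (v %*% J) / timetick
    v <- v %*% A
  }
  pmax(out, 0)
}

#' Exact indecomposable stationary distributions
#'
#' Identifies the terminal strongly-connected components of the transition
#' graph (components with no outgoing edges); each carries exactly one
#' indecomposable stationary distribution, obtained from the null space of
#' the generator restricted to the component.  A single-state terminal
#' component is a fixed point (point mass); a terminal cycle yields a
#' distribution spread over its states.
#'
#' @param generator generator matrix from [build_generator()].
#' @return list of stationary distributions; each element is a list with
#'   `states` (ids) and `p` (probabilities summing to 1).
#' @export
stationary_analysis <- function(generator) {
  m <- nrow(generator)
  A <- generator
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  edges <- igraph::as_edgelist(g, names = FALSE)
  has_out <- rep(FALSE, comp$no)
  if (nrow(edges)) {
    cross <- memb[edges[, 1L]] != memb[edges[, 2L]]
    has_out[unique(memb[edges[cross, 1L]])] <- TRUE
  }
  terminal <- which(!has_out)
  lapply(terminal, function(cl) {
    states <- unname(which(memb == cl))
    k <- length(states)
    if (k == 1L) {
      return(list(states = states - 1, p = 1))
    }
    Qc <- as.matrix(generator[states, states, drop = FALSE])
    # terminal component: rows of the restricted generator sum to 0;
    # solve pi Qc = 0 with sum(pi) = 1
    sys <- rbind(t(Qc), rep(1, k))
    w <- pmax(unname(qr.solve(sys, c(rep(0, k), 1))), 0)
    list(states = states - 1, p = w / sum(w))
  })
}

#' Generator spectrum and damped-oscillation diagnosis
#'
#' A necessary condition for damped oscillations of instantaneous
#' probabilities is a non-real generator eigenvalue; when one is present
#' there is always an initial condition producing damped oscillations.
#' Reality is judged with the tolerance `|Im| > tol * max(1, |lambda|)`.
#'
#' Beyond the necessary condition, the result reports the *dominant decaying
#' mode*: the eigenvalue of largest real part among genuinely decaying modes
#' (`Re < -decay_tol`), after excluding quasi-stationary modes.  Whether that
#' mode is complex is a practical indicator of visible oscillation on the
#' simulation timescale: a real dominant mode relaxes monotonically at late
#' times even if faster complex modes exist.
#'
#' @param generator generator matrix from [build_generator()].
#' @param tol reality tolerance for eigenvalues.
#' @param decay_tol modes with `Re(lambda) >= -decay_tol` are treated as
#'   (quasi-)stationary and excluded from the dominant-mode diagnosis.
#' @return list with `values` (all eigenvalues), `has_nonreal`, `nonreal`
#'   (the non-real eigenvalues), `dominant_decaying` and
#'   `dominant_is_complex`.
#' @export
damped_oscillation_check <- function(generator, tol = 1e-9, decay_tol = 1e-3) {
  ev <- eigen(as.matrix(generator), only.values = TRUE)$values
  nonreal <- abs(Im(ev)) > tol * pmax(1, Mod(ev))
  decaying <- Re(ev) < -decay_tol
  dom <- if (any(decaying)) ev[decaying][which.max(Re(ev[decaying]))] else NA_complex_
  list(values = ev,
       has_nonreal = any(nonreal),
       nonreal = ev[nonreal],
       dominant_decaying = dom,
       dominant_is_complex = is.complex(dom) && !is.na(dom) &&
         abs(Im(dom)) > tol * max(1, Mod(dom)))
}

#' Asynchronous transition graph
#'
#' The directed graph on all `2^n` network states with an edge `S -> S'`
#' whenever `rho(S -> S') > 0`.  The out-degree of `S` equals `gamma(S)`, the
#' number of asynchronous transitions out of `S`.  Fixed points are the
#' states with no outgoing edge; cycles are reported as the strongly
#' connected components with more than one state.
#'
#' @param model a `"bkmc_model"` with at most `limit` nodes.
#' @param params parameter values (or a `"bkmc_config"`).
#' @param limit node-count guard.
#' @param restrict optional predicate `function(bits)` (named 0/1 vector);
#'   the graph is restricted to states satisfying it.  Useful for multi-level
#'   encodings where only consistent states (e.g. `B_h <= B`) are meaningful;
#'   the restriction must be forward-closed under the dynamics.
#' @return an object of class `"bkmc_transition_graph"`: list with `graph`
#'   (an igraph; vertex attribute `label`), `states` (ids), `fixed_points`
#'   (ids), `cycles` (list of id vectors, the SCCs with > 1 state) and
#'   `gamma` (out-degrees).
#' @export
transition_graph <- function(model, params = NULL, limit = 12L, restrict = NULL) {
  Q <- build_generator(model, params, limit = limit)
  m <- nrow(Q)
  states <- 0:(m - 1)
  keep <- rep(TRUE, m)
  if (!is.null(restrict)) {
    keep <- vapply(states, function(s) {
      bits <- setNames(state_bits(s, model$n), model$node_names)
      isTRUE(restrict(bits) != 0)
    }, TRUE)
  }
  A <- Q
  diag(A) <- 0
  A <- A[keep, keep, drop = FALSE]
  states <- states[keep]
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "directed")
  igraph::V(g)$name <- as.character(states)
  igraph::V(g)$label <- state_bitstring(states, model$node_names)
  deg <- igraph::degree(g, mode = "out")
  comp <- igraph::components(g, mode = "strong")
  cyc <- lapply(which(tabulate(comp$membership) > 1L), function(cl) {
    states[comp$membership == cl]
  })
  structure(list(graph = g, states = states,
                 fixed_points = states[deg == 0L],
                 cycles = cyc, gamma = setNames(as.integer(deg), as.character(states)),
                 model = model),
            class = "bkmc_transition_graph")
}

#' @export
print.bkmc_transition_graph <- function(x, ...) {
  cat(sprintf("Asynchronous transition graph: %d states, %d edges\n",
              length(x$states), igraph::ecount(x$graph)))
  nms <- x$model$node_names
  cat(sprintf("  fixed points (%d): %s\n", length(x$fixed_points),
              paste(state_bitstring(x$fixed_points, nms), collapse = ", ")))
  cat(sprintf("  cycles / SCCs with > 1 state: %d\n", length(x$cycles)))
  for (cy in x$cycles) {
    cat("    {", paste(state_bitstring(cy, nms), collapse = ", "), "}\n")
  }
  invisible(x)
}

#' Export a transition graph for external viewers
#'
#' Writes DOT or GraphML via igraph, for visual comparison with logical
#' modeling tools.
#'
#' @param tg a `"bkmc_transition_graph"`.
#' @param file output path.
#' @param format `"dot"` or `"graphml"`.
#' @return `file`, invisibly.
#' @export
export_transition_graph <- function(tg, file, format = c("dot", "graphml")) {
  format <- match.arg(format)
  igraph::write_graph(tg$graph, file, format = format)
  invisible(file)
}
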