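# Network states are carried as exact doubles: state id = sum_i bits_i 2^(i-1)
# with i the node declaration index.  Doubles represent these ids exactly up
# to n = 52 nodes.

state_pow2 <- function(n) 2^(0:(n - 1L))

#' Decompose a state id into per-node bits
#'
#' @param id state id (non-negative integer-valued double), or a vector of ids.
#' @param n number of nodes.
#' @return for a single id, an integer 0/1 vector of length `n` in node
#'   declaration order; for a vector of ids, an `length(id) x n` matrix.
#' @export
state_bits <- function(id, n) {
  p <- state_pow2(n)
  if (length(id) == 1L) return(as.integer(floor(id / p) %% 2))
  outer(id, p, function(a, b) floor(a / b) %% 2)
}

#' Compose a state id from per-node bits
#'
#' @param bits 0/1 vector in node declaration order (optionally named).
#' @return the state id as a double.
#' @export
state_id <- function(bits) {
  sum(as.numeric(bits) * state_pow2(length(bits)))
}

# Coerce user input (id, named vector, or unnamed bit vector) to a state id.
as_state_id <- function(state, model) {
  if (is.numeric(state) && length(state) == 1L && is.null(names(state))) {
    if (state < 0 || state >= 2^model$n || state != floor(state)) {
      stop(sprintf("state id %g out of range for a %d-node model", state, model$n))
    }
    return(as.numeric(state))
  }
  if (!is.null(names(state))) {
    miss <- setdiff(model$node_names, names(state))
    if (length(miss)) {
      stop(sprintf("state is missing node(s): %s", paste(miss, collapse = ", ")))
    }
    return(state_id(as.numeric(state[model$node_names]) != 0))
  }
  if (length(state) == model$n) return(state_id(as.numeric(state) != 0))
  stop("state must be a single id or a (named) 0/1 vector over all nodes")
}

#' Render a state as the list of its active nodes
#'
#' States are rendered by the names of their active nodes in declaration
#' order, joined by `" -- "`; the all-off state renders as `"<nil>"`.
#'
#' @param id state id, or vector of ids.
#' @param names node names defining bit order.
#' @return character vector of labels.
#' @examples
#' state_label(c(0, 5), c("A", "B", "C"))  # "<nil>", "A -- C"
#' @export
state_label <- function(id, names) {
  n <- length(names)
  vapply(id, function(s) {
    b <- state_bits(s, n)
    if (!any(b == 1L)) "<nil>" else paste(names[b == 1L], collapse = " -- ")
  }, "")
}

# "[ABC]=[101]" rendering used by print methods and reports.
state_bitstring <- function(id, names) {
  n <- length(names)
  vapply(id, function(s) {
    sprintf("[%s]=[%s]", paste(names, collapse = ""),
            paste(state_bits(s, n), collapse = ""))
  }, "")
}

# Map full-state ids to ids over a node subset (e.g. output nodes), by
# extracting the kept bits in declaration order.
project_state <- function(id, n, keep) {
  if (all(keep)) return(id)
  p <- state_pow2(n)[keep]
  q <- state_pow2(sum(keep))
  if (length(id) == 1L) return(sum((floor(id / p) %% 2) * q))
  as.numeric(outer(id, seq_along(p), function(a, j) floor(a / p[j]) %% 2 * q[j]) %*% rep(1, length(p)))
}
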