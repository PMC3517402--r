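# Small builders shared across test files.  All fixtures are built in code.

one_node_model <- function(up = "2.0", down = "0.0", name = "X") {
  parse_bnd(sprintf("node %s {\n  rate_up = %s;\n  rate_down = %s;\n}\n", name, up, down))
}

toy_model <- function(escape = 10) {
  fx <- make_fixture("toy", escape = escape)
  list(model = parse_bnd(fx$bnd), cfg = fx$cfg, params = c(escape = escape))
}

# 2-node pure 4-cycle with equal rates: 00 -> 10 -> 11 -> 01 -> 00.
four_cycle_model <- function() {
  parse_bnd(paste(
    "node A { rate_up = !B ? 1.0 : 0.0; rate_down = B ? 1.0 : 0.0; }",
    "node B { rate_up = A ? 1.0 : 0.0; rate_down = !A ? 1.0 : 0.0; }",
    sep = "\n"))
}

# Hand-built trajectory (for estimator arithmetic tests).
mk_traj <- function(times, states, horizon, names = c("A", "B", "C")) {
  structure(list(times = times, states = states, horizon = horizon,
                 n = length(names), node_names = names),
            class = "bkmc_trajectory")
}

# Hand-built stationary estimate.
mk_est <- function(states, p, names = c("A", "B", "C")) {
  structure(list(states = states, p = p, traj_id = NA_integer_,
                 n = length(names), node_names = names),
            class = "bkmc_statdist_estimate")
}

quick_config <- function(model, ...) ctboolnet:::new_config(model, ...)

# Marginal probability that `node` is on, per window.
node_marginal <- function(ws, node) {
  j <- match(node, ws$output_names)
  bits <- state_bits(ws$states, length(ws$output_names))
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1)
  on <- bits[, j] == 1
  rowSums(ws$prob[, on, drop = FALSE])
}
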