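# Stochastic engine: the four-step kinetic Monte-Carlo (Gillespie) iteration
# on the asynchronous Boolean state space.
#
# Rates depend only on the current state (time-independent Markov process), so
# per-state transition sets are memoized in a shared cache; memoization is
# bit-identical to re-evaluation by construction.

# Compiled evaluation context for a model + parameter assignment.
sim_context <- function(model, params = NULL) {
  params <- resolve_params(model, params)
  penv <- new.env(parent = baseenv())
  for (nm in names(params)) assign(paste0(".p_", nm), params[[nm]], envir = penv)
  up <- lapply(model$nodes, function(nd) expr_compile(nd$rate_up))
  down <- lapply(model$nodes, function(nd) expr_compile(nd$rate_down))
  list(model = model, params = params, penv = penv, up = up, down = down,
       pow2 = state_pow2(model$n), cache = new.env(parent = emptyenv()))
}

resolve_params <- function(model, params) {
  out <- model$parameters
  if (!is.null(params)) {
    if (inherits(params, "bkmc_config")) params <- params$parameters
    for (nm in names(params)) out[nm] <- as.numeric(params[[nm]])
  }
  out
}

# Build (and cache) the transition set of a state.
ctx_transitions <- function(ctx, id) {
  key <- as.character(id)
  ts <- ctx$cache[[key]]
  if (!is.null(ts)) return(ts)
  n <- ctx$model$n
  bits <- as.integer(floor(id / ctx$pow2) %% 2)
  senv <- new.env(parent = ctx$penv)
  nms <- ctx$model$node_names
  for (i in seq_len(n)) assign(nms[i], bits[i], envir = senv)
  rates <- numeric(n)
  for (i in seq_len(n)) {
    code <- if (bits[i] == 0L) ctx$up[[i]] else ctx$down[[i]]
    val <- tryCatch(as.numeric(eval(code, senv)), error = function(e) {
      stop(sprintf("rate evaluation failed for node '%s' in state %s: %s",
                   nms[i], state_bitstring(id, nms), conditionMessage(e)), call. = FALSE)
    })
    if (length(val) != 1L || !is.finite(val) || val < 0) {
      stop(sprintf("rate of node '%s' in state %s is not a finite non-negative number (got %s)",
                   nms[i], state_bitstring(id, nms), paste(val, collapse = ",")), call. = FALSE)
    }
    rates[i] <- val
  }
  keep <- which(rates > 0)
  rr <- rates[keep]
  targets <- id + ifelse(bits[keep] == 0L, ctx$pow2[keep], -ctx$pow2[keep])
  cum <- cumsum(rr)
  ts <- structure(list(from = id, node = keep, target = as.numeric(targets),
                       rate = rr, cum = cum,
                       total_rate = if (length(rr)) cum[length(cum)] else 0,
                       n = n, node_names = ctx$model$node_names),
                  class = "bkmc_transitions")
  assign(key, ts, envir = ctx$cache)
  ts
}

#' Enumerate the transitions leaving a network state
#'
#' For each node `i` the candidate transition flips bit `i`, with rate
#' `rate_up_i(S)` if the node is off and `rate_down_i(S)` if it is on;
#' zero-rate candidates are omitted.  Candidates are ordered by node
#' declaration index and each target differs from `state` in exactly one bit
#' (asynchronous transitions).
#'
#' @param model a `"bkmc_model"`.
#' @param state state id or named 0/1 vector.
#' @param params named parameter values (or a `"bkmc_config"`); merged over
#'   `model$parameters`.
#' @return an object of class `"bkmc_transitions"`: list with `node` (flipped
#'   node indices), `target` (state ids), `rate`, `cum` (cumulative rates) and
#'   `total_rate`.
#' @examples
#' toy <- parse_bnd(make_fixture("toy")$bnd)
#' transitions(toy, c(A = 0, B = 0, C = 1), params = c(escape = 10))
#' @export
transitions <- function(model, state, params = NULL) {
  ctx <- sim_context(model, params)
  ctx_transitions(ctx, as_state_id(state, model))
}

#' @export
print.bkmc_transitions <- function(x, ...) {
  cat(sprintf("Transitions leaving %s (total rate %g):\n",
              state_bitstring(x$from, x$node_names), x$total_rate))
  if (!length(x$node)) {
    cat("  none (absorbing state)\n")
  } else {
    for (k in seq_along(x$node)) {
      cat(sprintf("  flip %-8s -> %s  rate %g\n", x$node_names[x$node[k]],
                  state_bitstring(x$target[k], x$node_names), x$rate[k]))
    }
  }
  invisible(x)
}

#' One kinetic Monte-Carlo step
#'
#' Deterministic function of the transition set and two uniform variates:
#' the holding time is `-log(u) / total_rate`, and the `k`-th candidate (in
#' node-index order) is selected where
#' `sum(rate[1:(k-1)]) < u2 * total_rate <= sum(rate[1:k])`.
#'
#' @param tset a `"bkmc_transitions"` with positive total rate.
#' @param u,u2 uniform variates in `(0, 1]`.
#' @return list with `dt` (holding time), `state` (next state id) and `node`
#'   (index of the flipped node).
#' @examples
#' toy <- parse_bnd(make_fixture("toy")$bnd)
#' ts <- transitions(toy, c(A = 0, B = 0, C = 1), params = c(escape = 10))
#' gillespie_step(ts, u = exp(-ts$total_rate), u2 = 0.5)  # dt exactly 1
#' @export
gillespie_step <- function(tset, u, u2) {
  stopifnot(inherits(tset, "bkmc_transitions"))
  if (tset$total_rate <= 0) stop("gillespie_step called on an absorbing state (no transitions)")
  if (!(u > 0 && u <= 1) || !(u2 > 0 && u2 <= 1)) stop("u and u2 must lie in (0, 1]")
  dt <- -log(u) / tset$total_rate
  x <- u2 * tset$total_rate
  k <- sum(x > tset$cum) + 1L
  if (k > length(tset$cum)) k <- length(tset$cum)  # guard u2 = 1 rounding
  list(dt = dt, state = tset$target[k], node = tset$node[k])
}

#' Draw an initial network state
#'
#' Input nodes (those with a fixed `istate` in the configuration) take their
#' fixed values; all other nodes are independently 0/1 with probability 1/2.
#'
#' @param model a `"bkmc_model"`.
#' @param istate named vector of fixed initial values (`NA` = random), e.g.
#'   `config$istate`; `NULL` means all nodes random.
#' @return a state id.
#' @export
sample_initial_state <- function(model, istate = NULL) {
  n <- model$n
  if (is.null(istate)) istate <- rep(NA_real_, n)
  if (!is.null(names(istate))) istate <- istate[model$node_names]
  bits <- as.numeric(istate)
  free <- is.na(bits)
  if (any(free)) bits[free] <- as.numeric(runif(sum(free)) < 0.5)
  state_id(bits)
}

# Core loop.  `ctx` carries compiled rates and the shared state cache.
sim_one_trajectory <- function(ctx, istate, max_time) {
  id <- sample_initial_state(ctx$model, istate)
  cap <- 32L
  times <- numeric(cap)
  states <- numeric(cap)
  times[1L] <- 0
  states[1L] <- id
  m <- 1L
  t <- 0
  cache <- ctx$cache
  repeat {
    key <- as.character(id)
    ts <- cache[[key]]
    if (is.null(ts)) ts <- ctx_transitions(ctx, id)
    tot <- ts$total_rate
    if (tot <= 0) break                      # absorbing: state persists
    u <- runif(2L)
    t <- t - log(u[1L]) / tot
    if (t > max_time) break                  # truncated at the horizon
    x <- u[2L] * tot
    k <- sum(x > ts$cum) + 1L
    id <- ts$target[k]
    m <- m + 1L
    if (m > cap) {
      cap <- cap * 2L
      length(times) <- cap
      length(states) <- cap
    }
    times[m] <- t
    states[m] <- id
  }
  structure(list(times = times[seq_len(m)], states = states[seq_len(m)],
                 horizon = max_time, n = ctx$model$n,
                 node_names = ctx$model$node_names),
            class = "bkmc_trajectory")
}

# Per-trajectory substream seed: odd multiplier => bijective in j mod 2^31.
traj_seed <- function(seed, j) {
  (as.numeric(seed) + as.numeric(j) * 507111089) %% 2^31
}

#' Simulate one stochastic trajectory
#'
#' Repeats the kinetic Monte-Carlo step from a sampled initial state until the
#' horizon `max_time` is passed.  If a jump would exceed the horizon the
#' trajectory is truncated at `max_time` in the pre-jump state; in an
#' absorbing state (total rate 0) the state persists to the horizon.
#'
#' @param model a `"bkmc_model"`.
#' @param config a `"bkmc_config"` (only `max_time`, `parameters` and
#'   `istate` are used here).
#' @param seed optional integer; if given, the trajectory is reproducible
#'   from it alone (`set.seed` with Mersenne-Twister).
#' @return an object of class `"bkmc_trajectory"`: `times` (jump entry times,
#'   starting at 0, strictly increasing), `states` (ids entered at those
#'   times; consecutive states differ in exactly one bit) and `horizon`.
#' @export
simulate_trajectory <- function(model, config, seed = NULL) {
  ctx <- sim_context(model, config)
  if (!is.null(seed)) set.seed(as.integer(seed), kind = "Mersenne-Twister")
  sim_one_trajectory(ctx, config$istate, config$max_time)
}

#' @export
print.bkmc_trajectory <- function(x, ...) {
  cat(sprintf("Stochastic trajectory on [0, %g]: %d jump%s\n", x$horizon,
              length(x$times) - 1L, if (length(x$times) == 2L) "" else "s"))
  k <- min(length(x$times), 8L)
  for (i in seq_len(k)) {
    cat(sprintf("  t = %-10.4g %s\n", x$times[i], state_bitstring(x$states[i], x$node_names)))
  }
  if (length(x$times) > k) cat(sprintf("  ... %d more\n", length(x$times) - k))
  invisible(x)
}

#' Simulate an ensemble of trajectories
#'
#' Generates `config$sample_count` trajectories.  Trajectory `j` uses an RNG
#' substream derived from `(config$seed, j)` alone, so the ensemble is
#' bit-identical for any `parallel_degree`; with `parallel_degree > 1` the
#' work is forked over that many workers.
#'
#' @param model a `"bkmc_model"`.
#' @param config a `"bkmc_config"`.
#' @param sample_count optional override of `config$sample_count`.
#' @return a list of `"bkmc_trajectory"` objects, class `"bkmc_ensemble"`.
#' @export
run_ensemble <- function(model, config, sample_count = NULL) {
  ctx <- sim_context(model, config)
  N <- as.integer(sample_count %||% config$sample_count)
  one <- function(j) {
    set.seed(traj_seed(config$seed, j), kind = "Mersenne-Twister")
    sim_one_trajectory(ctx, config$istate, config$max_time)
  }
  deg <- config$parallel_degree
  trajs <- if (deg > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(N), one, mc.cores = deg, mc.set.seed = FALSE)
  } else {
    lapply(seq_len(N), one)
  }
  structure(trajs, class = "bkmc_ensemble")
}

#' @export
print.bkmc_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d trajectories (%d-node model)\n", length(x), x[[1]]$n))
  invisible(x)
}
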