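# Windowed observables estimated from trajectory ensembles.
#
# For a window [tau*dt, (tau+1)*dt] each trajectory contributes its occupancy
# fraction of every (projected) state; ensemble estimates are the mean over
# trajectories and errors are sqrt(Var/#trajectories).  The horizon is
# truncated down to an integer number of windows; a trailing partial window
# is discarded with a warning.

#' Shannon entropy of a probability distribution
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i}, in bits, with \eqn{0 \log_2 0 = 0}.
#' \eqn{2^H} estimates the number of states with non-negligible probability.
#'
#' @param p numeric vector of probabilities summing to 1 (within `tol`).
#' @param tol tolerance on the total probability.
#' @return entropy in bits.
#' @examples
#' shannon_entropy(c(0.5, 0.25, 0.25))  # 1.5
#' @export
shannon_entropy <- function(p, tol = 1e-6) {
  p <- as.numeric(p)
  if (any(p < -tol)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > tol) stop("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Number of full windows tiling [0, horizon]; warn when a partial window is
# dropped.
window_count <- function(horizon, dt, warn = TRUE) {
  K <- floor(horizon / dt + 1e-9)
  if (K < 1L) stop("horizon shorter than one timetick window")
  if (warn && K * dt < horizon - 1e-9 * max(1, horizon)) {
    warning(sprintf("horizon %g is not a multiple of timetick %g: trailing partial window discarded",
                    horizon, dt), call. = FALSE)
  }
  as.integer(K)
}

# Split a trajectory into (window, state, occupancy fraction) triples.
split_segments <- function(traj, dt, K, left_edges) {
  tmax <- dt * K
  tt <- traj$times
  ss <- traj$states
  keep <- tt < tmax
  tt <- tt[keep]
  ss <- ss[keep]
  cut <- sort(unique(c(tt, dt * seq_len(K))))
  cut <- cut[cut <= tmax + 1e-12 * max(1, tmax)]
  a <- cut[-length(cut)]
  b <- cut[-1L]
  mid <- (a + b) / 2
  list(win = findInterval(mid, left_edges),
       state = ss[findInterval(mid, tt)],
       frac = (b - a) / dt)
}

# Per-state derived quantities (projection onto output nodes, transition
# entropy, Hamming distance to the reference state), memoized per state id.
state_info_provider <- function(ctx, internal = NULL, refstate = NULL) {
  model <- ctx$model
  n <- model$n
  keep <- rep(TRUE, n)
  if (is.character(internal)) {
    keep <- !(model$node_names %in% internal)
  } else if (is.logical(internal) && !is.null(names(internal))) {
    keep <- !(model$node_names %in% names(internal)[internal])
  }
  if (!any(keep)) stop("all nodes are internal: no output nodes left to observe")
  has_internal <- any(!keep)
  refmask <- rep(FALSE, n)
  refbits <- rep(0L, n)
  if (!is.null(refstate)) {
    rs <- refstate[!is.na(refstate)]
    refmask <- model$node_names %in% names(rs)
    refbits[match(names(rs), model$node_names)] <- as.integer(rs)
  }
  cache <- new.env(parent = emptyenv())
  get1 <- function(id) {
    key <- as.character(id)
    v <- cache[[key]]
    if (!is.null(v)) return(v)
    ts <- ctx_transitions(ctx, id)
    th <- transition_entropy_from_tset(ts, keep, has_internal)
    bits <- state_bits(id, n)
    hd <- if (any(refmask)) sum(bits[refmask] != refbits[refmask]) else NA_real_
    v <- c(proj = project_state(id, n, keep), th = th, hd = hd)
    assign(key, v, envir = cache)
    v
  }
  list(get = get1, keep = keep, has_internal = has_internal,
       refmask = refmask, n_ref = sum(refmask))
}

# TH(S): entropy of the jump distribution.  With internal nodes, only
# candidates flipping an output node enter the normalization; if every
# candidate flips an internal node the transition entropy is zero.
transition_entropy_from_tset <- function(ts, keep, has_internal) {
  rates <- ts$rate
  if (has_internal) rates <- rates[keep[ts$node]]
  if (!length(rates)) return(0)
  p <- rates / sum(rates)
  -sum(p * log2(p))
}

# Streaming accumulator over trajectories for all windowed observables.
window_accumulator <- function(ctx, dt, K, internal = NULL, refstate = NULL) {
  info <- state_info_provider(ctx, internal, refstate)
  left_edges <- dt * (0:(K - 1L))
  acc <- new.env(parent = emptyenv())
  acc$ids <- numeric(0)          # projected state ids, column order
  acc$index <- new.env(parent = emptyenv())
  acc$sumP <- matrix(0, K, 0)
  acc$sumP2 <- matrix(0, K, 0)
  acc$sumTH <- numeric(K)
  acc$sumTH2 <- numeric(K)
  nhd <- if (info$n_ref > 0) info$n_ref + 1L else 0L
  acc$sumHD <- matrix(0, K, nhd)
  acc$sumHD2 <- matrix(0, K, nhd)
  acc$ntraj <- 0L

  col_of <- function(pids) {
    cols <- integer(length(pids))
    for (i in seq_along(pids)) {
      key <- as.character(pids[i])
      cl <- acc$index[[key]]
      if (is.null(cl)) {
        acc$ids <- c(acc$ids, pids[i])
        cl <- length(acc$ids)
        assign(key, cl, envir = acc$index)
        acc$sumP <- cbind(acc$sumP, 0)
        acc$sumP2 <- cbind(acc$sumP2, 0)
      }
      cols[i] <- cl
    }
    cols
  }

  add <- function(traj) {
    seg <- split_segments(traj, dt, K, left_edges)
    u <- unique(seg$state)
    im <- vapply(u, function(s) info$get(s), c(proj = 0, th = 0, hd = 0))
    iu <- match(seg$state, u)
    uproj <- unname(im["proj", ])
    proj <- uproj[iu]
    th <- unname(im["th", ])[iu]
    # state probabilities (projected)
    ucols <- col_of(uproj)
    col <- ucols[iu]
    g <- (col - 1) * K + seg$win
    f <- rowsum(seg$frac, g)
    gg <- as.numeric(rownames(f))
    c2 <- floor((gg - 1) / K) + 1
    w2 <- gg - (c2 - 1) * K
    ij <- cbind(w2, c2)
    acc$sumP[ij] <- acc$sumP[ij] + f
    acc$sumP2[ij] <- acc$sumP2[ij] + f^2
    # transition entropy
    thw <- rowsum(seg$frac * th, seg$win)
    wi <- as.numeric(rownames(thw))
    acc$sumTH[wi] <- acc$sumTH[wi] + thw
    acc$sumTH2[wi] <- acc$sumTH2[wi] + thw^2
    # Hamming distribution (column = HD + 1)
    if (nhd > 0L) {
      hd <- unname(im["hd", ])[iu]
      gh <- hd * K + seg$win
      fh <- rowsum(seg$frac, gh)
      ggh <- as.numeric(rownames(fh))
      ch <- floor((ggh - 1) / K) + 1
      wh <- ggh - (ch - 1) * K
      ijh <- cbind(wh, ch)
      acc$sumHD[ijh] <- acc$sumHD[ijh] + fh
      acc$sumHD2[ijh] <- acc$sumHD2[ijh] + fh^2
    }
    acc$ntraj <- acc$ntraj + 1L
    invisible(NULL)
  }

  finish <- function() {
    N <- acc$ntraj
    if (N == 0L) stop("no trajectories accumulated")
    mc_err <- function(s, s2, m) {
      if (N == 1L) return(array(NA_real_, dim = dim(as.matrix(s))))
      v <- (s2 - N * m^2) / (N - 1)
      sqrt(pmax(v, 0) / N)
    }
    ord <- order(acc$ids)
    P <- acc$sumP[, ord, drop = FALSE] / N
    Perr <- mc_err(acc$sumP[, ord, drop = FALSE], acc$sumP2[, ord, drop = FALSE], P)
    TH <- acc$sumTH / N
    THerr <- as.numeric(mc_err(acc$sumTH, acc$sumTH2, TH))
    out <- list(
      time = left_edges, dt = dt, K = K, n_traj = N,
      states = acc$ids[ord],
      labels = state_label(acc$ids[ord], ctx$model$node_names[info$keep]),
      output_names = ctx$model$node_names[info$keep],
      prob = P, prob_err = Perr,
      H = apply(P, 1L, function(p) shannon_entropy(p, tol = 1e-6)),
      th = TH, th_err = THerr,
      generalized_th = info$has_internal
    )
    if (nhd > 0L) {
      HD <- acc$sumHD / N
      out$hd <- HD
      out$hd_err <- mc_err(acc$sumHD, acc$sumHD2, HD)
      out$hd_values <- 0:(nhd - 1L)
    }
    class(out) <- "bkmc_window_stats"
    out
  }

  list(add = add, finish = finish)
}

check_traj_list <- function(trajectories) {
  if (inherits(trajectories, "bkmc_trajectory")) trajectories <- list(trajectories)
  if (!length(trajectories)) stop("empty trajectory set")
  trajectories
}

run_window_estimators <- function(trajectories, timetick, model, params = NULL,
                                  internal = NULL, refstate = NULL) {
  trajectories <- check_traj_list(trajectories)
  ctx <- sim_context(model, params)
  K <- window_count(trajectories[[1L]]$horizon, timetick)
  wacc <- window_accumulator(ctx, timetick, K, internal = internal, refstate = refstate)
  for (tr in trajectories) wacc$add(tr)
  wacc$finish()
}

#' Windowed network-state probabilities
#'
#' For each window `[tau*dt, (tau+1)*dt]`, each trajectory contributes the
#' fraction of the window it spends in every state; states are projected onto
#' the output (non-internal) nodes, i.e. internal-node bits are marginalized
#' by summation.  The ensemble estimate averages over trajectories; its error
#' is `sqrt(Var / n)`.  Per window, the probabilities sum to 1.
#'
#' @param trajectories a list of `"bkmc_trajectory"` (e.g. [run_ensemble()]).
#' @param timetick window width `dt` (> 0).
#' @param model the `"bkmc_model"` that produced the trajectories.
#' @param params parameter values (or a `"bkmc_config"`).
#' @param internal character vector of internal node names, or a named
#'   logical vector (e.g. `config$internal`).
#' @return a `"bkmc_window_stats"` object with `time` (window start times),
#'   `states`/`labels` (projected states observed), `prob` and `prob_err`
#'   (windows x states matrices), and the per-window entropy `H` in bits.
#'   With a single trajectory, errors are `NA` (a variance of one draw is
#'   meaningless).
#' @export
window_probabilities <- function(trajectories, timetick, model, params = NULL,
                                 internal = NULL) {
  run_window_estimators(trajectories, timetick, model, params, internal = internal)
}

#' Jump-chain transition probabilities of a state
#'
#' Normalizes the outgoing transition rates: `P(S -> S') = rho(S -> S') /
#' sum(rho(S -> .))`.  Absorbing states give an empty map.  When internal
#' nodes are declared, only candidates flipping an output node enter the
#' normalization, and the map is empty when every candidate flips an internal
#' node.
#'
#' @inheritParams window_probabilities
#' @param state state id or named 0/1 vector.
#' @return named numeric vector of probabilities (names = target state ids),
#'   with attribute `"labels"`; length 0 for absorbing states.
#' @export
transition_probabilities <- function(model, state, params = NULL, internal = NULL) {
  ts <- transitions(model, state, params)
  keep <- rep(TRUE, model$n)
  if (is.character(internal)) keep <- !(model$node_names %in% internal)
  if (is.logical(internal) && !is.null(names(internal))) {
    keep <- !(model$node_names %in% names(internal)[internal])
  }
  sel <- if (any(!keep)) keep[ts$node] else rep(TRUE, length(ts$node))
  rates <- ts$rate[sel]
  targ <- ts$target[sel]
  if (!length(rates)) return(setNames(numeric(0), character(0)))
  p <- setNames(rates / sum(rates), as.character(targ))
  attr(p, "labels") <- state_label(targ, model$node_names)
  p
}

#' Transition entropy of a single state
#'
#' The Shannon entropy (bits) of [transition_probabilities()]; 0 for states
#' with no transition.  A vanishing transition entropy means the next jump is
#' deterministic.
#'
#' @inheritParams transition_probabilities
#' @return transition entropy in bits.
#' @export
transition_entropy_state <- function(model, state, params = NULL, internal = NULL) {
  p <- transition_probabilities(model, state, params, internal)
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

#' Windowed transition entropy
#'
#' Per trajectory and window, `sum_S TH(S) * mu_S / dt` where `mu_S` is the
#' time spent in state `S` during the window; averaged over trajectories with
#' Monte-Carlo standard errors.  With internal nodes present the quantity is
#' a generalization of the Markovian transition entropy (flagged in the
#' result as `generalized_th`).
#'
#' @inheritParams window_probabilities
#' @return a `"bkmc_window_stats"` object; see `$th` and `$th_err`.
#' @export
transition_entropy_window <- function(trajectories, timetick, model, params = NULL,
                                      internal = NULL) {
  run_window_estimators(trajectories, timetick, model, params, internal = internal)
}

#' Windowed Hamming-distance distribution
#'
#' The Hamming distance of a state to the reference state counts the
#' reference nodes whose value differs.  Windowed occupancy estimation is as
#' for [window_probabilities()]; per window the distribution over distances
#' `0..#reference nodes` sums to 1.
#'
#' @inheritParams window_probabilities
#' @param refstate named vector giving the reference value (0/1) of each
#'   reference node (non-reference nodes omitted or `NA`).
#' @return a `"bkmc_window_stats"` object; see `$hd`, `$hd_err`, `$hd_values`.
#' @export
hamming_distribution <- function(trajectories, timetick, model, refstate,
                                 params = NULL, internal = NULL) {
  if (is.null(refstate) || !any(!is.na(refstate))) {
    stop("no reference nodes declared (refstate is empty)")
  }
  run_window_estimators(trajectories, timetick, model, params,
                        internal = internal, refstate = refstate)
}

#' @export
print.bkmc_window_stats <- function(x, ...) {
  cat(sprintf("Windowed estimates: %d windows of width %g, %d trajector%s\n",
              x$K, x$dt, x$n_traj, if (x$n_traj == 1) "y" else "ies"))
  cat(sprintf("  %d projected state%s observed over output nodes (%s)\n",
              length(x$states), if (length(x$states) == 1) "" else "s",
              paste(x$output_names, collapse = ", ")))
  last <- x$K
  cat(sprintf("  final window: H = %.4g bits, TH = %.4g bits\n", x$H[last], x$th[last]))
  top <- order(x$prob[last, ], decreasing = TRUE)[seq_len(min(4L, ncol(x$prob)))]
  for (j in top) {
    cat(sprintf("    P[%s] = %.4g\n", x$labels[j], x$prob[last, j]))
  }
  if (x$generalized_th) {
    cat("  note: internal nodes present; TH is the non-Markovian generalization\n")
  }
  invisible(x)
}
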