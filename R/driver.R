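# Main simulation driver: runs the trajectory ensemble, streams it through
# the windowed estimators, estimates and clusters stationary distributions,
# and returns a classed result.

#' Run a full stochastic simulation study
#'
#' Generates `sample_count` trajectories of the continuous-time Markov
#' process defined by `model` (kinetic Monte-Carlo), estimating per window:
#' network-state probabilities over the output nodes (with Monte-Carlo
#' errors), entropy `H`, transition entropy `TH`, and — when reference nodes
#' are declared — the Hamming-distance distribution.  The first
#' `statdist_traj_count` trajectories additionally yield stationary
#' distribution estimates, clustered by support-overlap similarity at the
#' configured threshold (skipped with a warning when internal nodes are
#' present, because the marginalized process is no longer Markovian).
#'
#' Trajectory `j` uses an RNG substream derived from `(seed, j)` alone, so
#' results are reproducible and independent of `parallel_degree`.
#'
#' @param model a `"bkmc_model"`, BND-style source text, or a file path.
#' @param config a `"bkmc_config"`, configuration text, or a file path.
#' @param seed optional override of `config$seed`.
#' @return an object of class `"bkmc"`: list with `windows` (the
#'   `"bkmc_window_stats"`), `probtraj` (a data frame, one row per window),
#'   `statdist` (a `"bkmc_cluster_set"` or `NULL`), `model`, `config`,
#'   `warnings`, `elapsed` (seconds) and `exact = FALSE`.
#' @seealso [run_ensemble()], [window_probabilities()], [statdist_cluster()],
#'   [bkmc_exact()], [bkmc_main()]
#' @examples
#' fx <- make_fixture("toy", sample_count = 200)
#' res <- bkmc(fx$bnd, fx$cfg)
#' summary(res)
#' @export
bkmc <- function(model, config, seed = NULL) {
  model <- as_bkmc_model(model)
  config <- as_bkmc_config(config, model)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  t0 <- proc.time()[["elapsed"]]
  warns <- character()
  note <- function(w) warns <<- unique(c(warns, w))

  K <- withCallingHandlers(
    window_count(config$max_time, config$timetick),
    warning = function(w) note(conditionMessage(w))
  )
  ctx <- sim_context(model, config)
  refstate <- if (any(!is.na(config$refstate))) config$refstate else NULL
  wacc <- window_accumulator(ctx, config$timetick, K,
                             internal = config$internal, refstate = refstate)
  if (any(config$internal)) {
    note("internal nodes present: TH is the non-Markovian generalization of the transition entropy")
  }
  want_sd <- config$statdist_traj_count
  if (want_sd > 0L && any(config$internal)) {
    note(paste("stationary-distribution clustering skipped: internal nodes make the",
               "observed process non-Markovian"))
    want_sd <- 0L
  }
  estimates <- vector("list", want_sd)

  N <- config$sample_count
  chunk <- 512L
  deg <- config$parallel_degree
  gen <- function(j) {
    set.seed(traj_seed(config$seed, j), kind = "Mersenne-Twister")
    sim_one_trajectory(ctx, config$istate, config$max_time)
  }
  done <- 0L
  while (done < N) {
    idx <- (done + 1L):min(done + chunk, N)
    trajs <- if (deg > 1L && .Platform$OS.type == "unix") {
      parallel::mclapply(idx, gen, mc.cores = deg, mc.set.seed = FALSE)
    } else {
      lapply(idx, gen)
    }
    for (k in seq_along(idx)) {
      j <- idx[k]
      wacc$add(trajs[[k]])
      if (j <= want_sd) estimates[[j]] <- stationary_estimate(trajs[[k]], id = j)
    }
    done <- idx[length(idx)]
  }

  ws <- wacc$finish()
  sd <- NULL
  if (want_sd > 0L) {
    sd <- statdist_cluster(estimates, config$statdist_cluster_threshold)
  }
  res <- structure(list(
    model = model, config = config,
    windows = ws,
    probtraj = probtraj_frame(ws),
    statdist = sd,
    warnings = warns,
    n_traj = N,
    exact = FALSE,
    elapsed = proc.time()[["elapsed"]] - t0
  ), class = "bkmc")
  for (w in warns) warning(w, call. = FALSE)
  res
}

as_bkmc_model <- function(model) {
  if (inherits(model, "bkmc_model")) return(model)
  if (is.character(model) && length(model) == 1L && !grepl("\n", model) && file.exists(model)) {
    return(parse_bnd(file = model))
  }
  parse_bnd(text = model)
}

as_bkmc_config <- function(config, model) {
  if (inherits(config, "bkmc_config")) return(config)
  if (is.character(config) && length(config) == 1L && !grepl("\n", config) && file.exists(config)) {
    return(parse_cfg(file = config, model = model))
  }
  parse_cfg(text = config, model = model)
}

# One row per window: time, TH +- err, H, per-state probability +- err,
# Hamming-distance columns when a reference state is declared.
probtraj_frame <- function(ws) {
  df <- data.frame(Time = ws$time, TH = ws$th, ErrTH = ws$th_err, H = ws$H,
                   check.names = FALSE)
  for (j in seq_along(ws$states)) {
    df[[paste0("Prob[", ws$labels[j], "]")]] <- ws$prob[, j]
    df[[paste0("ErrProb[", ws$labels[j], "]")]] <- ws$prob_err[, j]
  }
  if (!is.null(ws$hd)) {
    for (k in seq_along(ws$hd_values)) {
      df[[sprintf("HD=%d", ws$hd_values[k])]] <- ws$hd[, k]
      df[[sprintf("ErrHD=%d", ws$hd_values[k])]] <- ws$hd_err[, k]
    }
  }
  df
}

#' Solve a small model exactly instead of simulating
#'
#' Replaces the Monte-Carlo ensemble by the exact master-equation solution
#' (matrix exponential): window-averaged probabilities, exact entropy,
#' transition entropy and Hamming distribution, and the exact indecomposable
#' stationary distributions weighted by their absorption probabilities from
#' the configured initial condition.  Error columns are zero.
#'
#' @inheritParams bkmc
#' @param limit node-count guard for the dense exponential.
#' @return an object of class `"bkmc"` with `exact = TRUE`.
#' @export
bkmc_exact <- function(model, config, limit = 12L) {
  model <- as_bkmc_model(model)
  config <- as_bkmc_config(config, model)
  t0 <- proc.time()[["elapsed"]]
  warns <- character()
  K <- withCallingHandlers(
    window_count(config$max_time, config$timetick),
    warning = function(w) warns <<- unique(c(warns, conditionMessage(w)))
  )
  Q <- build_generator(model, config, limit = limit)
  p0 <- initial_distribution(model, config)
  avg <- master_window_average(Q, p0, config$timetick, K)
  ctx <- sim_context(model, config)
  refstate <- if (any(!is.na(config$refstate))) config$refstate else NULL
  info <- state_info_provider(ctx, config$internal, refstate)
  m <- ncol(avg)
  ids <- 0:(m - 1)
  trip <- vapply(ids, function(s) info$get(s), c(proj = 0, th = 0, hd = 0))
  # project probabilities onto output nodes
  pids <- sort(unique(trip["proj", ]))
  P <- matrix(0, K, length(pids))
  for (j in seq_len(m)) {
    cl <- match(trip["proj", j], pids)
    P[, cl] <- P[, cl] + avg[, j]
  }
  TH <- as.numeric(avg %*% trip["th", ])
  ws <- list(time = config$timetick * (0:(K - 1)), dt = config$timetick, K = K,
             n_traj = NA_integer_, states = pids,
             labels = state_label(pids, model$node_names[info$keep]),
             output_names = model$node_names[info$keep],
             prob = P, prob_err = matrix(0, K, length(pids)),
             H = apply(P, 1L, function(p) shannon_entropy(p / sum(p))),
             th = TH, th_err = rep(0, K),
             generalized_th = info$has_internal)
  if (!is.null(refstate)) {
    nhd <- info$n_ref + 1L
    HD <- matrix(0, K, nhd)
    for (j in seq_len(m)) {
      cl <- trip["hd", j] + 1L
      HD[, cl] <- HD[, cl] + avg[, j]
    }
    ws$hd <- HD
    ws$hd_err <- matrix(0, K, nhd)
    ws$hd_values <- 0:(nhd - 1L)
  }
  class(ws) <- "bkmc_window_stats"
  # exact stationary distributions, weighted by absorption probability
  stat <- stationary_analysis(Q)
  wts <- absorption_weights(Q, p0, lapply(stat, `[[`, "states"))
  clusters <- lapply(order(wts, decreasing = TRUE), function(i) {
    list(members = integer(0), proportion = wts[i],
         states = stat[[i]]$states, p = stat[[i]]$p,
         err = rep(0, length(stat[[i]]$states)))
  })
  sdist <- structure(list(clusters = clusters, alpha = NA_real_,
                          n_estimates = NA_integer_, D = NULL,
                          node_names = model$node_names),
                     class = "bkmc_cluster_set")
  structure(list(model = model, config = config, windows = ws,
                 probtraj = probtraj_frame(ws), statdist = sdist,
                 warnings = warns, n_traj = NA_integer_, exact = TRUE,
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "bkmc")
}

# Initial distribution implied by the configuration: input nodes fixed,
# free nodes independent fair coins.
initial_distribution <- function(model, config) {
  n <- model$n
  m <- 2^n
  istate <- config$istate
  p0 <- numeric(m)
  for (s in seq_len(m)) {
    bits <- state_bits(s - 1, n)
    pr <- 1
    for (i in seq_len(n)) {
      pr <- pr * if (is.na(istate[i])) 0.5 else as.numeric(bits[i] == istate[i])
    }
    p0[s] <- pr
  }
  p0
}

# P(absorption into each terminal class) from initial distribution p0.
absorption_weights <- function(Q, p0, classes) {
  m <- nrow(Q)
  cls_states <- lapply(classes, function(s) s + 1L)
  in_terminal <- sort(unlist(cls_states))
  transient <- setdiff(seq_len(m), in_terminal)
  vapply(seq_along(cls_states), function(ci) {
    h <- numeric(m)
    h[cls_states[[ci]]] <- 1
    if (length(transient)) {
      Qtt <- as.matrix(Q[transient, transient, drop = FALSE])
      rhs <- -as.matrix(Q[transient, cls_states[[ci]], drop = FALSE]) %*%
        rep(1, length(cls_states[[ci]]))
      h[transient] <- solve(Qtt, rhs)
    }
    sum(p0 * h)
  }, 0)
}

#' @export
print.bkmc <- function(x, ...) {
  cat("Continuous-time Boolean network simulation\n")
  cat(sprintf("  model: %d nodes (%s)\n", x$model$n, paste(x$model$node_names, collapse = ", ")))
  if (x$exact) {
    cat("  exact master-equation solution\n")
  } else {
    cat(sprintf("  %d trajectories, seed %d\n", x$n_traj, x$config$seed))
  }
  cat(sprintf("  %d windows of width %g on [0, %g]\n", x$windows$K, x$windows$dt,
              x$windows$K * x$windows$dt))
  last <- x$windows$K
  cat(sprintf("  final window: H = %.4g bits, TH = %.4g bits\n",
              x$windows$H[last], x$windows$th[last]))
  if (!is.null(x$statdist)) {
    cat(sprintf("  stationary distributions: %d cluster%s\n", length(x$statdist$clusters),
                if (length(x$statdist$clusters) == 1) "" else "s"))
  }
  invisible(x)
}

#' @export
summary.bkmc <- function(object, top = 6L, ...) {
  x <- object
  ws <- x$windows
  last <- ws$K
  cat("Continuous-time Boolean network simulation — summary\n\n")
  print(x$model)
  cat(sprintf("\nWindows: %d x %g; %s\n", ws$K, ws$dt,
              if (x$exact) "exact master equation" else sprintf("%d trajectories", x$n_traj)))
  cat(sprintf("Final-window entropy H = %.4g bits, transition entropy TH = %.4g bits\n",
              ws$H[last], ws$th[last]))
  ord <- order(ws$prob[last, ], decreasing = TRUE)
  cat("Final-window state probabilities:\n")
  for (j in head(ord, top)) {
    e <- ws$prob_err[last, j]
    cat(sprintf("  P[%s] = %.4g%s\n", ws$labels[j], ws$prob[last, j],
                if (is.na(e)) "" else sprintf(" +- %.2g", e)))
  }
  if (!is.null(x$statdist)) {
    cat("\n")
    print(x$statdist)
  }
  if (length(x$warnings)) {
    cat("\nWarnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

#' Plot windowed probabilities and entropies
#'
#' Two panels against time: selected state probabilities (by default the
#' most probable states of the final window), and the entropy/transition
#' entropy curves.
#'
#' @param x a `"bkmc"` result.
#' @param states character vector of state labels to plot (as in
#'   `x$windows$labels`); default picks the top `max_states` final-window
#'   states.
#' @param max_states number of states picked by default.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.bkmc <- function(x, states = NULL, max_states = 4L, ...) {
  ws <- x$windows
  tt <- ws$time + ws$dt / 2
  if (is.null(states)) {
    states <- ws$labels[order(ws$prob[ws$K, ], decreasing = TRUE)]
    states <- head(states, max_states)
  }
  j <- match(states, ws$labels)
  if (anyNA(j)) stop("unknown state label(s): ", paste(states[is.na(j)], collapse = ", "))
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(par(op))
  cols <- hcl.colors(length(j), "Dark 3")
  matplot(tt, ws$prob[, j, drop = FALSE], type = "l", lty = 1, col = cols,
          xlab = "time", ylab = "probability", ylim = c(0, 1), ...)
  legend("topright", legend = states, col = cols, lty = 1, bty = "n", cex = 0.8)
  matplot(tt, cbind(ws$H, ws$th), type = "l", lty = 1,
          col = c("black", "firebrick"), xlab = "time", ylab = "bits")
  legend("topright", legend = c("H", "TH"), col = c("black", "firebrick"),
         lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Simulate trajectories from a model
#'
#' `simulate()` method for `"bkmc_model"`: a thin wrapper over
#' [run_ensemble()].
#'
#' @param object a `"bkmc_model"`.
#' @param nsim number of trajectories.
#' @param seed RNG seed (overrides `config$seed`).
#' @param config a `"bkmc_config"` (or config text/path).
#' @param ... unused.
#' @return a list of `"bkmc_trajectory"` objects.
#' @export
simulate.bkmc_model <- function(object, nsim = 1, seed = NULL, config, ...) {
  config <- as_bkmc_config(config, object)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  run_ensemble(object, config, sample_count = nsim)
}
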