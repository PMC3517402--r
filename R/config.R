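# Simulation configuration: a key = value text dialect.
#
#   timetick = 0.1;             observable window width (required)
#   max_time = 4;               trajectory horizon (required)
#   sample_count = 50000;       number of trajectories (default 1000)
#   statdist_traj_count = 1000; trajectories kept for stationary estimates
#                               (default min(sample_count, 100))
#   statdist_cluster_threshold = 0.8;   similarity threshold alpha (default 0.8)
#   seed = 42;                  RNG seed (default 0)
#   parallel_degree = 1;        worker count (results independent of it)
#   $name = 0.5;                parameter value (constant expression)
#   NODE.is_internal = TRUE;    marginalize NODE out of all observables
#   NODE.istate = 0 | 1 | random;  fixed initial value makes NODE an input node
#   NODE.refstate = 0 | 1;      NODE enters the Hamming distance as reference
#
# Trailing semicolons are required after each statement; `//` and `#` comments
# and arbitrary whitespace are allowed.

CFG_SCALARS <- c("timetick", "max_time", "sample_count", "statdist_traj_count",
                 "statdist_cluster_threshold", "seed", "parallel_degree")

#' Parse a simulation configuration
#'
#' Reads the key/value configuration dialect documented above, resolving
#' node-scoped settings against `model`.  `timetick` and `max_time` have no
#' safe universal default and must be given explicitly; other settings
#' default as documented.
#'
#' @param text configuration source; or use `file`.
#' @param model the `"bkmc_model"` the configuration applies to.
#' @param file path to a configuration file.
#' @return an object of class `"bkmc_config"` with elements `timetick`,
#'   `max_time`, `sample_count`, `statdist_traj_count`,
#'   `statdist_cluster_threshold`, `seed`, `parallel_degree`, `parameters`
#'   (named numeric), and per-node vectors `internal` (logical), `istate`
#'   (0/1/`NA` = random) and `refstate` (0/1/`NA` = not a reference node).
#' @seealso [parse_bnd()], [bkmc()]
#' @export
parse_cfg <- function(text = NULL, model, file = NULL) {
  stopifnot(inherits(model, "bkmc_model"))
  if (is.null(text) == is.null(file)) stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) {
    if (!file.exists(file)) stop(sprintf("config file '%s' does not exist", file))
    text <- readLines(file, warn = FALSE)
  }
  toks <- dsl_tokenize(text)
  cur <- new_cursor(toks)
  set <- list(parameters = setNames(numeric(0), character(0)))
  internal <- setNames(rep(FALSE, model$n), model$node_names)
  istate <- setNames(rep(NA_real_, model$n), model$node_names)
  refstate <- setNames(rep(NA_real_, model$n), model$node_names)

  const_value <- function(what) {
    e <- parse_expr_toks(cur)
    if (length(expr_node_refs(e))) {
      stop(sprintf("value of %s must be a constant expression (node references not allowed)", what),
           call. = FALSE)
    }
    penv <- new.env(parent = baseenv())
    for (nm in names(set$parameters)) {
      assign(paste0(".p_", nm), set$parameters[[nm]], envir = penv)
    }
    val <- tryCatch(eval(expr_compile(e), penv), error = function(err) {
      stop(sprintf("cannot evaluate value of %s: %s", what, conditionMessage(err)), call. = FALSE)
    })
    as.numeric(val)
  }

  repeat {
    tk <- cur_peek(cur)
    if (tk$type == "eof") break
    if (tk$type == "param") {
      cur_next(cur)
      nm <- substring(tk$value, 2L)
      cur_expect(cur, value = "=")
      set$parameters[nm] <- const_value(sprintf("$%s", nm))
      cur_expect(cur, value = ";")
      next
    }
    key <- cur_expect(cur, type = "ident", what = "a setting name")
    nxt <- cur_peek(cur)
    if (nxt$type == "op" && nxt$value == ".") {
      # node-scoped setting
      cur_next(cur)
      if (!key$value %in% model$node_names) {
        stop(dsl_err(toks$text, key$pos, sprintf("unknown node '%s' in configuration", key$value)),
             call. = FALSE)
      }
      prop <- cur_expect(cur, type = "ident", what = "a node setting")
      cur_expect(cur, value = "=")
      if (prop$value == "is_internal") {
        internal[key$value] <- const_value(sprintf("%s.is_internal", key$value)) != 0
      } else if (prop$value == "istate") {
        vt <- cur_peek(cur)
        if (vt$type == "ident" && vt$value == "random") {
          cur_next(cur)
          istate[key$value] <- NA_real_
        } else {
          v <- const_value(sprintf("%s.istate", key$value))
          if (!v %in% c(0, 1)) {
            stop(sprintf("%s.istate must be 0, 1 or random", key$value), call. = FALSE)
          }
          istate[key$value] <- v
        }
      } else if (prop$value == "refstate") {
        v <- const_value(sprintf("%s.refstate", key$value))
        if (!v %in% c(0, 1)) stop(sprintf("%s.refstate must be 0 or 1", key$value), call. = FALSE)
        refstate[key$value] <- v
      } else {
        stop(dsl_err(toks$text, prop$pos,
                     sprintf("unknown node setting '%s' (expected is_internal, istate or refstate)",
                             prop$value)), call. = FALSE)
      }
      cur_expect(cur, value = ";")
      next
    }
    if (!key$value %in% CFG_SCALARS) {
      stop(dsl_err(toks$text, key$pos, sprintf("unknown configuration key '%s'", key$value)),
           call. = FALSE)
    }
    cur_expect(cur, value = "=")
    set[[key$value]] <- const_value(key$value)
    cur_expect(cur, value = ";")
  }

  for (req in c("timetick", "max_time")) {
    if (is.null(set[[req]])) {
      stop(sprintf("configuration must set '%s' explicitly (no universal default is safe)", req),
           call. = FALSE)
    }
  }
  cfg <- structure(list(
    timetick = set$timetick,
    max_time = set$max_time,
    sample_count = as.integer(set$sample_count %||% 1000L),
    statdist_traj_count = NA_integer_,
    statdist_cluster_threshold = set$statdist_cluster_threshold %||% 0.8,
    seed = as.integer(set$seed %||% 0L),
    parallel_degree = as.integer(set$parallel_degree %||% 1L),
    parameters = set$parameters,
    internal = internal,
    istate = istate,
    refstate = refstate
  ), class = "bkmc_config")
  cfg$statdist_traj_count <- as.integer(set$statdist_traj_count %||%
                                          min(cfg$sample_count, 100L))
  validate_config(cfg, model)
  cfg
}

validate_config <- function(cfg, model = NULL) {
  if (!is.finite(cfg$timetick) || cfg$timetick <= 0) stop("timetick must be > 0")
  if (!is.finite(cfg$max_time) || cfg$max_time <= 0) stop("max_time must be > 0")
  if (cfg$max_time < cfg$timetick) stop("max_time must be at least one timetick")
  if (cfg$sample_count < 1L) stop("sample_count must be >= 1")
  if (cfg$statdist_traj_count < 0L) stop("statdist_traj_count must be >= 0")
  if (cfg$statdist_traj_count > cfg$sample_count) {
    stop("statdist_traj_count must not exceed sample_count")
  }
  a <- cfg$statdist_cluster_threshold
  if (!is.finite(a) || a <= 0 || a > 1) {
    stop("statdist_cluster_threshold must be in (0, 1]")
  }
  if (cfg$parallel_degree < 1L) stop("parallel_degree must be >= 1")
  # parameters the model does not use are tolerated
  invisible(cfg)
}

# Build a config programmatically (used by fixtures and tests).
new_config <- function(model, timetick, max_time, sample_count = 1000L,
                       statdist_traj_count = NULL, statdist_cluster_threshold = 0.8,
                       seed = 0L, parallel_degree = 1L, parameters = numeric(),
                       internal = character(), istate = numeric(), refstate = numeric()) {
  cfg <- structure(list(
    timetick = timetick, max_time = max_time,
    sample_count = as.integer(sample_count),
    statdist_traj_count = as.integer(statdist_traj_count %||% min(sample_count, 100L)),
    statdist_cluster_threshold = statdist_cluster_threshold,
    seed = as.integer(seed), parallel_degree = as.integer(parallel_degree),
    parameters = parameters,
    internal = setNames(model$node_names %in% internal, model$node_names),
    istate = setNames(rep(NA_real_, model$n), model$node_names),
    refstate = setNames(rep(NA_real_, model$n), model$node_names)
  ), class = "bkmc_config")
  if (length(istate)) cfg$istate[names(istate)] <- istate
  if (length(refstate)) cfg$refstate[names(refstate)] <- refstate
  validate_config(cfg, model)
  cfg
}

#' @export
print.bkmc_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  timetick = %g, max_time = %g, sample_count = %d\n",
              x$timetick, x$max_time, x$sample_count))
  cat(sprintf("  statdist_traj_count = %d, statdist_cluster_threshold = %g\n",
              x$statdist_traj_count, x$statdist_cluster_threshold))
  cat(sprintf("  seed = %d, parallel_degree = %d\n", x$seed, x$parallel_degree))
  if (length(x$parameters)) {
    cat("  parameters:", paste(sprintf("$%s = %g", names(x$parameters), x$parameters),
                               collapse = ", "), "\n")
  }
  if (any(x$internal)) cat("  internal:", paste(names(x$internal)[x$internal], collapse = ", "), "\n")
  if (any(!is.na(x$istate))) {
    f <- !is.na(x$istate)
    cat("  input nodes:", paste(sprintf("%s=%d", names(x$istate)[f], as.integer(x$istate[f])),
                                collapse = ", "), "\n")
  }
  if (any(!is.na(x$refstate))) {
    f <- !is.na(x$refstate)
    cat("  reference state:", paste(sprintf("%s=%d", names(x$refstate)[f], as.integer(x$refstate[f])),
                                    collapse = ", "), "\n")
  }
  invisible(x)
}
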