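# Output writers mirroring the three run products (probability-trajectory
# CSV, stationary-distribution CSV, run report) and the command-line driver.
#
# CSV dialect: comma-separated, '.' decimal, scientific notation allowed;
# numbers are written with 17 significant digits so that reading a file back
# reproduces the in-memory estimates bit-exactly.  State probability columns
# are created lazily, only for states actually observed.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write the windowed-probability table
#'
#' One row per window: `Time` (window start), `TH`/`ErrTH`, `H`, then
#' `Prob[<label>]`/`ErrProb[<label>]` for every observed projected state
#' (labels are the active output-node names in declaration order, `"<nil>"`
#' for the all-off state), then `HD=k`/`ErrHD=k` columns when a reference
#' state was declared.  Numbers round-trip bit-exactly through
#' [read_probtraj()].
#'
#' @param x a `"bkmc"` result or the `probtraj` data frame itself.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_probtraj <- function(x, file) {
  df <- if (inherits(x, "bkmc")) x$probtraj else x
  stopifnot(is.data.frame(df))
  lines <- c(paste(names(df), collapse = ","),
             apply(vapply(df, fmt_num, character(nrow(df))), 1L, paste, collapse = ","))
  writeLines(lines, file)
  invisible(file)
}

#' Read back a windowed-probability table
#'
#' @param file path written by [write_probtraj()].
#' @return data frame with the original (numeric) columns.
#' @export
read_probtraj <- function(file) {
  df <- read.csv(file, check.names = FALSE, colClasses = "character")
  for (j in seq_along(df)) df[[j]] <- as.numeric(df[[j]])
  df
}

#' Write the stationary-distribution table
#'
#' Long-format CSV: rows with `Type = "cluster"` carry one state of one
#' cluster each (`Cluster`, `Proportion`, `State` label, `Prob`, `Err`);
#' rows with `Type = "similarity"` summarize the pairwise similarity
#' coefficients within and between clusters (`Cluster` = `"i-j"`, `Prob` =
#' mean D, `Err` = min/max spread half-width).  An empty run writes only the
#' header.
#'
#' @param x a `"bkmc"` result or a `"bkmc_cluster_set"` (or `NULL`).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_statdist <- function(x, file) {
  cs <- if (inherits(x, "bkmc")) x$statdist else x
  header <- "Type,Cluster,Proportion,State,Prob,Err"
  if (is.null(cs)) {
    writeLines(header, file)
    return(invisible(file))
  }
  lines <- header
  for (i in seq_along(cs$clusters)) {
    cl <- cs$clusters[[i]]
    ord <- order(cl$p, decreasing = TRUE)
    lines <- c(lines, sprintf("cluster,%d,%s,%s,%s,%s",
                              i, fmt_num(cl$proportion),
                              state_label(cl$states[ord], cs$node_names),
                              fmt_num(cl$p[ord]), fmt_num(cl$err[ord])))
  }
  if (!is.null(cs$D) && length(cs$clusters)) {
    memb <- integer(cs$n_estimates)
    for (i in seq_along(cs$clusters)) memb[cs$clusters[[i]]$members] <- i
    for (i in seq_along(cs$clusters)) {
      for (j in i:length(cs$clusters)) {
        block <- cs$D[memb == i, memb == j, drop = FALSE]
        vals <- if (i == j) {
          if (nrow(block) < 2L) next
          block[upper.tri(block)]
        } else {
          as.numeric(block)
        }
        if (!length(vals)) next
        lines <- c(lines, sprintf("similarity,%d-%d,NA,NA,%s,%s",
                                  i, j, fmt_num(mean(vals)),
                                  fmt_num((max(vals) - min(vals)) / 2)))
      }
    }
  }
  writeLines(lines, file)
  invisible(file)
}

model_digest <- function(model) {
  tf <- tempfile(fileext = ".bnd")
  on.exit(unlink(tf))
  writeLines(format_model(model), tf)
  unname(tools::md5sum(tf))
}

#' Write the run report
#'
#' Plain-text summary: model digest and size, configuration echo, trajectory
#' counts, wall-clock time and every warning emitted during the run (each
#' exactly once).
#'
#' @param x a `"bkmc"` result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_run_report <- function(x, file) {
  stopifnot(inherits(x, "bkmc"))
  cfg <- x$config
  lines <- c(
    "Continuous-time Boolean network simulation — run report",
    sprintf("package version: %s", as.character(packageVersion("ctboolnet"))),
    sprintf("method: %s", if (x$exact) "exact master equation" else "kinetic Monte-Carlo"),
    sprintf("model digest (md5 of canonical source): %s", model_digest(x$model)),
    sprintf("nodes (%d): %s", x$model$n, paste(x$model$node_names, collapse = ", ")),
    sprintf("timetick = %g; max_time = %g; windows = %d", cfg$timetick, cfg$max_time, x$windows$K),
    sprintf("sample_count = %d; statdist_traj_count = %d; statdist_cluster_threshold = %g",
            cfg$sample_count, cfg$statdist_traj_count, cfg$statdist_cluster_threshold),
    sprintf("seed = %d; parallel_degree = %d", cfg$seed, cfg$parallel_degree),
    if (length(cfg$parameters)) {
      sprintf("parameters: %s", paste(sprintf("$%s = %g", names(cfg$parameters), cfg$parameters),
                                      collapse = ", "))
    },
    if (any(cfg$internal)) {
      sprintf("internal nodes: %s", paste(names(cfg$internal)[cfg$internal], collapse = ", "))
    },
    if (any(!is.na(cfg$istate))) {
      f <- !is.na(cfg$istate)
      sprintf("input nodes: %s", paste(sprintf("%s=%d", names(cfg$istate)[f],
                                               as.integer(cfg$istate[f])), collapse = ", "))
    },
    if (any(!is.na(cfg$refstate))) {
      f <- !is.na(cfg$refstate)
      sprintf("reference state: %s", paste(sprintf("%s=%d", names(cfg$refstate)[f],
                                                   as.integer(cfg$refstate[f])), collapse = ", "))
    },
    sprintf("trajectories simulated: %s", if (x$exact) "0 (exact)" else format(x$n_traj)),
    sprintf("stationary-distribution clusters: %s",
            if (is.null(x$statdist)) "not computed" else format(length(x$statdist$clusters))),
    sprintf("wall-clock time: %.2f s", x$elapsed),
    if (length(x$warnings)) c("warnings:", paste0("  - ", x$warnings)) else "warnings: none"
  )
  writeLines(unlist(lines), file)
  invisible(file)
}

#' Command-line driver
#'
#' Runs a full simulation from a model file and a configuration file and
#' writes three outputs: `PREFIX_probtraj.csv`, `PREFIX_statdist.csv` and
#' `PREFIX_run.txt`.  Arguments may appear in any order:
#'
#' ```
#' ctboolnet -c model.cfg -o out model.bnd [--seed N] [--exact]
#' ```
#'
#' `--exact` routes small models (at most 12 nodes) through the exact
#' master-equation solver instead of the stochastic engine; `--seed`
#' overrides the configured seed.  Missing files and parse errors are
#' reported on stderr with a non-zero status.
#'
#' An executable `Rscript` wrapper is installed under
#' `system.file("exec", "ctboolnet", package = "ctboolnet")`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly (0 on success).
#' @export
bkmc_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: ctboolnet -c CONFIG.cfg -o PREFIX MODEL.bnd [--seed N] [--exact]"
  cfg_path <- NULL
  prefix <- NULL
  model_path <- NULL
  seed <- NULL
  exact <- FALSE
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "-c") {
      if (i == length(args)) { message("missing value after -c\n", usage); return(invisible(2L)) }
      cfg_path <- args[i + 1L]; i <- i + 2L
    } else if (a == "-o") {
      if (i == length(args)) { message("missing value after -o\n", usage); return(invisible(2L)) }
      prefix <- args[i + 1L]; i <- i + 2L
    } else if (a == "--seed") {
      if (i == length(args)) { message("missing value after --seed\n", usage); return(invisible(2L)) }
      seed <- as.integer(args[i + 1L]); i <- i + 2L
    } else if (a == "--exact") {
      exact <- TRUE; i <- i + 1L
    } else if (startsWith(a, "-")) {
      message(sprintf("unknown option '%s'\n%s", a, usage)); return(invisible(2L))
    } else {
      if (!is.null(model_path)) { message("more than one model file given\n", usage); return(invisible(2L)) }
      model_path <- a; i <- i + 1L
    }
  }
  if (is.null(cfg_path) || is.null(prefix) || is.null(model_path)) {
    message(usage)
    return(invisible(2L))
  }
  for (p in c(model_path, cfg_path)) {
    if (!file.exists(p)) {
      message(sprintf("error: file '%s' does not exist", p))
      return(invisible(1L))
    }
  }
  status <- tryCatch({
    model <- parse_bnd(file = model_path)
    config <- parse_cfg(file = cfg_path, model = model)
    if (!is.null(seed)) config$seed <- seed
    res <- withCallingHandlers(
      if (exact) bkmc_exact(model, config) else bkmc(model, config),
      warning = function(w) invokeRestart("muffleWarning")  # reported in the run report
    )
    write_probtraj(res, paste0(prefix, "_probtraj.csv"))
    write_statdist(res, paste0(prefix, "_statdist.csv"))
    write_run_report(res, paste0(prefix, "_run.txt"))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
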