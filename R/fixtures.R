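# Bundled example models, generated programmatically as model/config text.
#
# * toy: a 3-node single-cycle network (A activated by C and inhibited by B,
#   B activated by A, C activated by A or B).  All rates 1 except the escape
#   transition [ABC]=[001] -> [000] (inactivation of C when A and B are off),
#   exposed as $escape: 10 for the fast regime, 1e-5 for the slow one.
# * p53: a DNA-damage response network with a two-level p53 encoded by the
#   B/B_h Boolean pattern (5 Boolean nodes).  The logical rules are a
#   reconstruction (see the fixture text); the structural check is one fixed
#   point [p53 Mdm2C Mdm2N Dam] = [0010] plus two transition-graph cycles.
# * cellcycle: the published 10-node mammalian cell-cycle logic with a slow
#   (1) and a fast (10) rate class.
# * random: seeded random logic/rates for property testing.

#' Generate a bundled example model
#'
#' Returns BND-style model text and matching configuration text; parse with
#' [parse_bnd()] / [parse_cfg()] or run with [bkmc()].  All fixtures are
#' generated in code (no external files).
#'
#' @param name one of `"toy"`, `"p53"`, `"cellcycle"`, `"random"`.
#' @param escape (toy) escape-rate value: 10 = fast regime, 1e-5 = slow.
#' @param timetick,max_time,sample_count,statdist_traj_count,
#'   statdist_cluster_threshold,seed configuration overrides.
#' @param initial (cellcycle) `"g1"` starts from a G1 state with growth
#'   factors (CycD, p27, Cdh1 on, all else off and fixed); `"random"` leaves
#'   every node random, the setting used for stationary-distribution
#'   clustering.
#' @param n,rates (random) node count and rate style (`"random"` rates in
#'   `{0.5, 1, 2}`, `"unit"` all 1); the model is a deterministic function of
#'   `seed`.
#' @return list with elements `name`, `bnd` (model text) and `cfg`
#'   (configuration text).
#' @examples
#' fx <- make_fixture("toy", escape = 10)
#' model <- parse_bnd(fx$bnd)
#' config <- parse_cfg(fx$cfg, model)
#' @export
make_fixture <- function(name = c("toy", "p53", "cellcycle", "random"),
                         escape = 10, timetick = NULL, max_time = NULL,
                         sample_count = NULL, statdist_traj_count = NULL,
                         statdist_cluster_threshold = NULL, seed = NULL,
                         initial = c("g1", "random"), n = 5L, rates = c("random", "unit")) {
  name <- match.arg(name)
  switch(name,
    toy = fixture_toy(escape, timetick, max_time, sample_count,
                      statdist_traj_count, statdist_cluster_threshold, seed),
    p53 = fixture_p53(timetick, max_time, sample_count,
                      statdist_traj_count, statdist_cluster_threshold, seed),
    cellcycle = fixture_cellcycle(match.arg(initial), timetick, max_time, sample_count,
                                  statdist_traj_count, statdist_cluster_threshold, seed),
    random = fixture_random(n, seed %||% 1L, match.arg(rates))
  )
}

cfg_lines <- function(params = character(), timetick, max_time, sample_count,
                      statdist_traj_count, statdist_cluster_threshold, seed,
                      node_lines = character()) {
  c(params,
    sprintf("timetick = %s;", format(timetick, digits = 15)),
    sprintf("max_time = %s;", format(max_time, digits = 15)),
    sprintf("sample_count = %d;", as.integer(sample_count)),
    sprintf("statdist_traj_count = %d;", as.integer(statdist_traj_count)),
    sprintf("statdist_cluster_threshold = %s;", format(statdist_cluster_threshold, digits = 15)),
    sprintf("seed = %d;", as.integer(seed)),
    node_lines)
}

fixture_toy <- function(escape, timetick, max_time, sample_count,
                        statdist_traj_count, statdist_cluster_threshold, seed) {
  bnd <- paste(c(
    "// Single-cycle toy network:",
    "// A is activated by C and inhibited by B, B is activated by A,",
    "// C is activated by A or B.  All rates 1 except the escape",
    "// transition [ABC]=[001] -> [000] (inactivation of C), rate $escape.",
    "node A {",
    "  rate_up = (C & !B) ? 1.0 : 0.0;",
    "  rate_down = (C & !B) ? 0.0 : 1.0;",
    "}",
    "node B {",
    "  rate_up = A ? 1.0 : 0.0;",
    "  rate_down = A ? 0.0 : 1.0;",
    "}",
    "node C {",
    "  rate_up = (A | B) ? 1.0 : 0.0;",
    "  rate_down = (A | B) ? 0.0 : $escape;",
    "}"), collapse = "\n")
  cfg <- paste(cfg_lines(
    params = sprintf("$escape = %s;", format(escape, digits = 15)),
    timetick = timetick %||% 0.1,
    max_time = max_time %||% 4,
    sample_count = sample_count %||% 50000L,
    statdist_traj_count = statdist_traj_count %||% 0L,
    statdist_cluster_threshold = statdist_cluster_threshold %||% 0.8,
    seed = seed %||% 0L), collapse = "\n")
  list(name = "toy", bnd = paste0(bnd, "\n"), cfg = paste0(cfg, "\n"))
}

fixture_p53 <- function(timetick, max_time, sample_count,
                        statdist_traj_count, statdist_cluster_threshold, seed) {
  bnd <- paste(c(
    "// p53 response to DNA damage, two-level p53 via the B/B_h pattern.",
    "// Reconstructed rules: nuclear Mdm2 degrades p53; only high p53",
    "// (p53_h) transcribes cytoplasmic Mdm2; Mdm2 enters the nucleus from",
    "// the cytoplasm, p53 inhibits that translocation (basal entry when",
    "// p53 is off); DNA damage accelerates nuclear Mdm2 degradation; p53",
    "// promotes damage repair; damage is only set by the initial stress.",
    "node p53 {",
    "  rate_up = !Mdm2N ? $ap : 0.0;",
    "  rate_down = (p53_h | !Mdm2N) ? 0.0 : $dp;",
    "}",
    "node p53_h {",
    "  rate_up = (p53 & !Mdm2N) ? $ap : 0.0;",
    "  rate_down = Mdm2N ? $dp : 0.0;",
    "}",
    "node Mdm2C {",
    "  rate_up = p53_h ? $ac : 0.0;",
    "  rate_down = p53_h ? 0.0 : $dc;",
    "}",
    "node Mdm2N {",
    "  rate_up = (Mdm2C | !p53) ? $an : 0.0;",
    "  rate_down = !(Mdm2C | !p53) ? $dn : (Dam ? $dn : 0.0);",
    "}",
    "node Dam {",
    "  rate_up = 0.0;",
    "  rate_down = p53 ? $rep : 0.0;",
    "}"), collapse = "\n")
  cfg <- paste(cfg_lines(
    params = sprintf("$%s = 1.0;", c("ap", "dp", "ac", "dc", "an", "dn", "rep")),
    timetick = timetick %||% 0.2,
    max_time = max_time %||% 60,
    sample_count = sample_count %||% 20000L,
    statdist_traj_count = statdist_traj_count %||% 0L,
    statdist_cluster_threshold = statdist_cluster_threshold %||% 0.8,
    seed = seed %||% 0L,
    node_lines = c("p53.istate = 0;", "p53_h.istate = 0;", "Mdm2C.istate = random;",
                   "Mdm2N.istate = 1;", "Dam.istate = 1;")), collapse = "\n")
  list(name = "p53", bnd = paste0(bnd, "\n"), cfg = paste0(cfg, "\n"))
}

# Published 10-node mammalian cell-cycle logic; two rate classes
# ($slow synthesis/transcription-driven switches, $fast post-translational
# ones), mirroring the priority classes of the source model.
CELLCYCLE_LOGIC <- c(
  CycD = "CycD",
  Rb = "(!CycD & !CycE & !CycA & !CycB) | (p27 & !CycD & !CycB)",
  E2F = "(!Rb & !CycA & !CycB) | (p27 & !Rb & !CycB)",
  CycE = "E2F & !Rb",
  CycA = "(E2F & !Rb & !Cdc20 & !(Cdh1 & UbcH10)) | (CycA & !Rb & !Cdc20 & !(Cdh1 & UbcH10))",
  p27 = "(!CycD & !CycE & !CycA & !CycB) | (p27 & !(CycE & CycA) & !CycB & !CycD)",
  Cdc20 = "CycB",
  Cdh1 = "(!CycA & !CycB) | Cdc20 | (p27 & !CycB)",
  UbcH10 = "!Cdh1 | (Cdh1 & UbcH10 & (Cdc20 | CycA | CycB))",
  CycB = "!Cdc20 & !Cdh1"
)

# up/down rate class per node.  The fast class (10) is reserved for the
# purely phosphorylation-driven switch events — the inactivation of the
# CDK substrates Rb and p27 once cyclin/CDK complexes accumulate — while
# synthesis- and degradation-driven events form the slow class (1),
# mirroring the priority-class reasoning of the source model.  This
# assignment retains an oscillatory dominant generator mode, so the
# population-level cyclin probabilities show damped oscillations.
CELLCYCLE_RATES <- list(
  CycD = c("$slow", "$slow"),
  Rb = c("$slow", "$fast"),
  E2F = c("$slow", "$slow"),
  CycE = c("$slow", "$slow"),
  CycA = c("$slow", "$slow"),
  p27 = c("$slow", "$fast"),
  Cdc20 = c("$slow", "$slow"),
  Cdh1 = c("$slow", "$slow"),
  UbcH10 = c("$slow", "$slow"),
  CycB = c("$slow", "$slow")
)

fixture_cellcycle <- function(initial, timetick, max_time, sample_count,
                              statdist_traj_count, statdist_cluster_threshold, seed) {
  blocks <- vapply(names(CELLCYCLE_LOGIC), function(nm) {
    rr <- CELLCYCLE_RATES[[nm]]
    paste0("node ", nm, " {\n",
           "  rate_up = (", CELLCYCLE_LOGIC[[nm]], ") ? ", rr[1L], " : 0.0;\n",
           "  rate_down = (", CELLCYCLE_LOGIC[[nm]], ") ? 0.0 : ", rr[2L], ";\n",
           "}")
  }, "")
  bnd <- paste(c("// Mammalian cell-cycle logic (10 nodes), slow/fast rate classes.",
                 blocks), collapse = "\n")
  node_lines <- if (initial == "g1") {
    on <- c("CycD", "p27", "Cdh1")
    vapply(names(CELLCYCLE_LOGIC), function(nm) {
      sprintf("%s.istate = %d;", nm, as.integer(nm %in% on))
    }, "")
  } else {
    character()
  }
  cfg <- paste(cfg_lines(
    params = c("$slow = 1.0;", "$fast = 10.0;"),
    timetick = timetick %||% 0.5,
    max_time = max_time %||% (if (initial == "g1") 30 else 100),
    sample_count = sample_count %||% (if (initial == "g1") 2000L else 500L),
    statdist_traj_count = statdist_traj_count %||% (if (initial == "g1") 0L else 500L),
    statdist_cluster_threshold = statdist_cluster_threshold %||% 0.8,
    seed = seed %||% 0L,
    node_lines = node_lines), collapse = "\n")
  list(name = "cellcycle", bnd = paste0(bnd, "\n"), cfg = paste0(cfg, "\n"))
}

# Random n-node model: each node gets a random logic over <= 3 regulators in
# canonical form (rate_up = L ? ru : 0; rate_down = L ? 0 : rd).
fixture_random <- function(n, seed, rates) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  nms <- if (n <= 26L) LETTERS[seq_len(n)] else sprintf("N%02d", seq_len(n))
  rand_logic <- function() {
    k <- sample(1:min(3L, n), 1L)
    regs <- sample(nms, k)
    lits <- ifelse(runif(k) < 0.4, paste0("!", regs), regs)
    if (k == 1L) return(lits)
    ops <- sample(c("&", "|"), k - 1L, replace = TRUE)
    out <- lits[1L]
    for (i in seq_len(k - 1L)) out <- paste0("(", out, " ", ops[i], " ", lits[i + 1L], ")")
    out
  }
  rand_rate <- function() {
    if (rates == "unit") "1.0" else format(sample(c(0.5, 1, 2), 1L), nsmall = 1)
  }
  blocks <- vapply(nms, function(nm) {
    lg <- rand_logic()
    paste0("node ", nm, " {\n",
           "  rate_up = (", lg, ") ? ", rand_rate(), " : 0.0;\n",
           "  rate_down = (", lg, ") ? 0.0 : ", rand_rate(), ";\n",
           "}")
  }, "")
  bnd <- paste(c(sprintf("// Random %d-node model (seed %d).", n, as.integer(seed)), blocks),
               collapse = "\n")
  cfg <- paste(cfg_lines(
    params = character(),
    timetick = 0.25, max_time = 2, sample_count = 1000L,
    statdist_traj_count = 0L, statdist_cluster_threshold = 0.8,
    seed = seed), collapse = "\n")
  list(name = "random", bnd = paste0(bnd, "\n"), cfg = paste0(cfg, "\n"))
}
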