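# Rate-expression language: tokenizer, recursive-descent parser, evaluator and
# serializer.  The grammar is this package's documented dialect of the
# BND-style model language:
#
#   model      := node_block+
#   node_block := "node" IDENT "{" attr+ "}"
#   attr       := ("rate_up" | "rate_down") "=" expr ";"
#
# Expressions use C operator precedence:
#   ?:  <  ||  <  &&  <  |  <  ^  <  &  <  == !=  <  < <= > >=  <  + -  <  * /
#   < unary ! - +
# Leaves are node references, parameters ($name) and numeric literals.
# `//` and `#` start line comments.  Truthiness: a numeric value is true iff
# it is non-zero; Boolean results coerce to 1/0 in arithmetic context.

TOKEN_RE <- paste0(
  "(?://[^\n]*|#[^\n]*)",                                   # comments
  "|(?:[A-Za-z_][A-Za-z0-9_]*)",                            # identifier
  "|(?:\\$[A-Za-z_][A-Za-z0-9_]*)",                         # parameter
  "|(?:[0-9]+\\.?[0-9]*(?:[eE][+-]?[0-9]+)?|\\.[0-9]+(?:[eE][+-]?[0-9]+)?)", # number
  "|(?:&&|\\|\\||==|!=|<=|>=)",                             # two-char ops
  "|(?:[{}();=?:&|!^+*/<>.,-])",                            # one-char ops
  "|(?:[ \t\r\n]+)",                                        # whitespace
  "|(?:.)"                                                  # anything else: error
)

# Tokenize DSL source. Returns a data.frame-like list of type/value/pos.
dsl_tokenize <- function(text) {
  stopifnot(is.character(text))
  text <- paste(text, collapse = "\n")
  m <- gregexpr(TOKEN_RE, text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(list(type = character(), value = character(), pos = integer(), text = text))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  toks <- substring(text, starts, starts + lens - 1L)
  type <- character(length(toks))
  first <- substr(toks, 1L, 1L)
  type[grepl("^[A-Za-z_]", toks)] <- "ident"
  type[first == "$"] <- "param"
  type[grepl("^[0-9.]", toks) & grepl("[0-9]", toks)] <- "num"
  type[grepl("^(//|#)", toks)] <- "comment"
  type[toks %in% c("&&", "||", "==", "!=", "<=", ">=", "{", "}", "(", ")", ";",
                   "=", "?", ":", "&", "|", "!", "^", "+", "*", "/", "<", ">",
                   ".", ",", "-")] <- "op"
  type[grepl("^[ \t\r\n]+$", toks)] <- "ws"
  bad <- which(type == "")
  if (length(bad)) {
    stop(dsl_err(text, starts[bad[1]], sprintf("unexpected character '%s'", toks[bad[1]])),
         call. = FALSE)
  }
  keep <- !(type %in% c("ws", "comment"))
  list(type = type[keep], value = toks[keep], pos = starts[keep], text = text)
}

# Format "line L, column C: msg" for a character offset.
dsl_err <- function(text, pos, msg) {
  before <- substr(text, 1L, pos - 1L)
  line <- 1L + lengths(regmatches(before, gregexpr("\n", before, fixed = TRUE)))
  nl <- max(c(0L, gregexpr("\n", before, fixed = TRUE)[[1]]))
  col <- pos - nl
  sprintf("line %d, column %d: %s", line, col, msg)
}

# Parser state: a mutable cursor over the token stream.
new_cursor <- function(toks) {
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$i <- 1L
  env
}

cur_peek <- function(cur) {
  if (cur$i > length(cur$toks$type)) list(type = "eof", value = "<eof>", pos = nchar(cur$toks$text) + 1L)
  else list(type = cur$toks$type[cur$i], value = cur$toks$value[cur$i], pos = cur$toks$pos[cur$i])
}

cur_next <- function(cur) {
  tk <- cur_peek(cur)
  cur$i <- cur$i + 1L
  tk
}

cur_expect <- function(cur, value = NULL, type = NULL, what = NULL) {
  tk <- cur_next(cur)
  ok <- (is.null(value) || identical(tk$value, value)) && (is.null(type) || identical(tk$type, type))
  if (!ok) {
    want <- what %||% value %||% type
    stop(dsl_err(cur$toks$text, tk$pos,
                 sprintf("expected %s but found '%s'", want, tk$value)), call. = FALSE)
  }
  tk
}

`%||%` <- function(a, b) if (is.null(a)) b else a

BINARY_LEVELS <- list(
  "1" = "||", "2" = "&&", "3" = "|", "4" = "^", "5" = "&",
  "6" = c("==", "!="), "7" = c("<", "<=", ">", ">="),
  "8" = c("+", "-"), "9" = c("*", "/")
)

parse_expr_toks <- function(cur) {
  lhs <- parse_binary(cur, 1L)
  tk <- cur_peek(cur)
  if (tk$type == "op" && tk$value == "?") {
    cur_next(cur)
    yes <- parse_expr_toks(cur)
    cur_expect(cur, value = ":")
    no <- parse_expr_toks(cur)
    lhs <- list(type = "cond", cond = lhs, yes = yes, no = no)
  }
  lhs
}

parse_binary <- function(cur, level) {
  if (level > 9L) return(parse_unary(cur))
  ops <- BINARY_LEVELS[[as.character(level)]]
  lhs <- parse_binary(cur, level + 1L)
  repeat {
    tk <- cur_peek(cur)
    if (tk$type == "op" && tk$value %in% ops) {
      cur_next(cur)
      rhs <- parse_binary(cur, level + 1L)
      lhs <- list(type = "binary", op = tk$value, lhs = lhs, rhs = rhs)
    } else {
      return(lhs)
    }
  }
}

parse_unary <- function(cur) {
  tk <- cur_peek(cur)
  if (tk$type == "op" && tk$value %in% c("!", "-", "+")) {
    cur_next(cur)
    arg <- parse_unary(cur)
    if (tk$value == "+") return(arg)
    return(list(type = "unary", op = tk$value, arg = arg))
  }
  parse_primary(cur)
}

parse_primary <- function(cur) {
  tk <- cur_next(cur)
  if (tk$type == "num") return(list(type = "num", value = as.numeric(tk$value)))
  if (tk$type == "ident") {
    val <- toupper(tk$value)
    if (val %in% c("TRUE", "FALSE")) {
      return(list(type = "num", value = as.numeric(val == "TRUE")))
    }
    return(list(type = "node", name = tk$value))
  }
  if (tk$type == "param") return(list(type = "param", name = substring(tk$value, 2L)))
  if (tk$type == "op" && tk$value == "(") {
    e <- parse_expr_toks(cur)
    cur_expect(cur, value = ")")
    return(e)
  }
  stop(dsl_err(cur$toks$text, tk$pos,
               sprintf("expected an expression but found '%s'", tk$value)), call. = FALSE)
}

#' Parse a rate expression
#'
#' Parses a single expression in the model language (see [parse_bnd()] for the
#' grammar) into an abstract syntax tree of class `"bkmc_expr"`.
#'
#' @param text expression source, e.g. `"B ? $kb : (A ? $ka : 0.0)"`.
#' @return an object of class `"bkmc_expr"`.
#' @examples
#' e <- parse_rate_expr("B ? $kb : (A ? $ka : 0.0)")
#' evaluate_rate(e, c(A = 1, B = 0), c(kb = 2, ka = 0.5))
#' @export
parse_rate_expr <- function(text) {
  cur <- new_cursor(dsl_tokenize(text))
  ast <- parse_expr_toks(cur)
  tk <- cur_peek(cur)
  if (tk$type != "eof") {
    stop(dsl_err(cur$toks$text, tk$pos, sprintf("trailing input '%s'", tk$value)), call. = FALSE)
  }
  class(ast) <- c("bkmc_expr", class(ast))
  ast
}

# Node references appearing in an AST.
expr_node_refs <- function(ast) {
  switch(ast$type,
    num = character(),
    node = ast$name,
    param = character(),
    unary = expr_node_refs(ast$arg),
    binary = c(expr_node_refs(ast$lhs), expr_node_refs(ast$rhs)),
    cond = c(expr_node_refs(ast$cond), expr_node_refs(ast$yes), expr_node_refs(ast$no))
  )
}

expr_param_refs <- function(ast) {
  switch(ast$type,
    num = character(),
    node = character(),
    param = ast$name,
    unary = expr_param_refs(ast$arg),
    binary = c(expr_param_refs(ast$lhs), expr_param_refs(ast$rhs)),
    cond = c(expr_param_refs(ast$cond), expr_param_refs(ast$yes), expr_param_refs(ast$no))
  )
}

# Compile an AST to an R call.  Node references become variables, parameters
# become `.p_<name>` variables; Boolean operators apply non-zero truthiness.
expr_compile <- function(ast) {
  truthy <- function(x) if (is.call(x) && identical(x[[1L]], as.name("!="))) x else call("!=", x, 0)
  switch(ast$type,
    num = ast$value,
    node = as.name(ast$name),
    param = as.name(paste0(".p_", ast$name)),
    unary = {
      a <- expr_compile(ast$arg)
      if (ast$op == "!") call("!", truthy(a)) else call("-", a)
    },
    binary = {
      a <- expr_compile(ast$lhs)
      b <- expr_compile(ast$rhs)
      switch(ast$op,
        "|" = , "||" = call("||", truthy(a), truthy(b)),
        "&" = , "&&" = call("&&", truthy(a), truthy(b)),
        "^" = call("!=", truthy(a), truthy(b)),
        "==" = call("==", a, b),
        "!=" = call("!=", a, b),
        "<" = call("<", a, b),
        "<=" = call("<=", a, b),
        ">" = call(">", a, b),
        ">=" = call(">=", a, b),
        "+" = call("+", a, b),
        "-" = call("-", a, b),
        "*" = call("*", a, b),
        "/" = call("/", a, b)
      )
    },
    cond = call("if", expr_compile(ast$cond), expr_compile(ast$yes), expr_compile(ast$no))
  )
}

EXPR_PREC <- c("?:" = 0, "||" = 1, "&&" = 2, "|" = 3, "^" = 4, "&" = 5,
               "==" = 6, "!=" = 6, "<" = 7, "<=" = 7, ">" = 7, ">=" = 7,
               "+" = 8, "-" = 8, "*" = 9, "/" = 9)

# Render an AST back to DSL source with minimal parentheses.
expr_deparse <- function(ast) {
  prec_of <- function(a) {
    switch(a$type, cond = 0, binary = unname(EXPR_PREC[a$op]), unary = 10, 11)
  }
  wrap <- function(child, need) {
    s <- expr_deparse(child)
    if (need) paste0("(", s, ")") else s
  }
  switch(ast$type,
    num = format(ast$value, digits = 17, scientific = NA),
    node = ast$name,
    param = paste0("$", ast$name),
    unary = paste0(ast$op, wrap(ast$arg, prec_of(ast$arg) < 10)),
    binary = {
      p <- unname(EXPR_PREC[ast$op])
      paste0(wrap(ast$lhs, prec_of(ast$lhs) < p), " ", ast$op, " ",
             wrap(ast$rhs, prec_of(ast$rhs) <= p))
    },
    cond = paste0(wrap(ast$cond, ast$cond$type == "cond"), " ? ",
                  expr_deparse(ast$yes), " : ", expr_deparse(ast$no))
  )
}

#' @export
format.bkmc_expr <- function(x, ...) expr_deparse(x)

#' @export
print.bkmc_expr <- function(x, ...) {
  cat(expr_deparse(x), "\n")
  invisible(x)
}

#' Evaluate a rate expression against a network state
#'
#' Evaluates a parsed rate expression on a 0/1 assignment of node states and a
#' set of parameter values.  The result must be a finite, non-negative number
#' (units 1/time); anything else is an error.  The conditional operator
#' short-circuits, and a zero rate means the corresponding transition is
#' impossible.
#'
#' @param expr a `"bkmc_expr"` from [parse_rate_expr()], or a character string.
#' @param state named numeric/logical vector of node states (0/1).
#' @param params named numeric vector of parameter values.
#' @return a single non-negative number.
#' @examples
#' evaluate_rate("A ? 0.0 : 0.001", c(A = 1))
#' @export
evaluate_rate <- function(expr, state, params = numeric()) {
  if (is.character(expr)) expr <- parse_rate_expr(expr)
  penv <- new.env(parent = baseenv())
  if (length(params)) {
    for (nm in names(params)) assign(paste0(".p_", nm), as.numeric(params[[nm]]), envir = penv)
  }
  senv <- new.env(parent = penv)
  if (length(state)) {
    for (nm in names(state)) assign(nm, as.numeric(state[[nm]]), envir = senv)
  }
  code <- expr_compile(expr)
  val <- tryCatch(eval(code, senv), error = function(e) {
    stop(sprintf("rate evaluation failed for '%s': %s", expr_deparse(expr),
                 conditionMessage(e)), call. = FALSE)
  })
  check_rate_value(as.numeric(val), expr)
}

check_rate_value <- function(val, expr) {
  if (length(val) != 1L || !is.finite(val)) {
    stop(sprintf("rate expression '%s' evaluated to a non-finite value", expr_deparse(expr)),
         call. = FALSE)
  }
  if (val < 0) {
    stop(sprintf("rate expression '%s' evaluated to a negative value (%g)",
                 expr_deparse(expr), val), call. = FALSE)
  }
  val
}

#' Parse a BND-style model file
#'
#' Reads a model in the rate-annotated Boolean network language: one block per
#' node declaring activation (`rate_up`) and inactivation (`rate_down`) rate
#' expressions over node states and named `$parameters`.
#'
#' ```
#' node C {
#'   rate_up = B ? $kb : (A ? $ka : 0.0);
#'   rate_down = !(A & B) ? 1.0 : 0.0;
#' }
#' ```
#'
#' Declaration order defines the bit index of each node.  Parameters may be
#' left undefined at parse time and supplied later through the configuration
#' ([parse_cfg()]).  Syntax errors are reported with line/column positions;
#' duplicate node names and references to undeclared nodes are errors.
#'
#' @param text model source as a character string (possibly multi-line).
#' @param file path to a model file; exactly one of `text`/`file` is given.
#' @return an object of class `"bkmc_model"`: a list with elements `nodes`
#'   (per-node name and rate ASTs), `node_names`, `n` and `parameters`.
#' @seealso [format_model()] for the inverse, [parse_cfg()], [bkmc()].
#' @examples
#' m <- parse_bnd(make_fixture("toy")$bnd)
#' m$node_names
#' @export
parse_bnd <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) {
    if (!file.exists(file)) stop(sprintf("model file '%s' does not exist", file))
    text <- readLines(file, warn = FALSE)
  }
  toks <- dsl_tokenize(text)
  cur <- new_cursor(toks)
  nodes <- list()
  repeat {
    tk <- cur_peek(cur)
    if (tk$type == "eof") break
    kw <- cur_expect(cur, type = "ident", what = "'node'")
    if (kw$value != "node") {
      stop(dsl_err(toks$text, kw$pos, sprintf("expected 'node' but found '%s'", kw$value)),
           call. = FALSE)
    }
    nm <- cur_expect(cur, type = "ident", what = "a node name")
    if (nm$value %in% vapply(nodes, `[[`, "", "name")) {
      stop(dsl_err(toks$text, nm$pos, sprintf("duplicate node name '%s'", nm$value)),
           call. = FALSE)
    }
    cur_expect(cur, value = "{")
    spec <- list(name = nm$value, rate_up = NULL, rate_down = NULL)
    repeat {
      tk <- cur_peek(cur)
      if (tk$type == "op" && tk$value == "}") { cur_next(cur); break }
      at <- cur_expect(cur, type = "ident", what = "'rate_up' or 'rate_down'")
      if (!at$value %in% c("rate_up", "rate_down")) {
        stop(dsl_err(toks$text, at$pos,
                     sprintf("unknown node attribute '%s' (expected rate_up or rate_down)", at$value)),
             call. = FALSE)
      }
      cur_expect(cur, value = "=")
      e <- parse_expr_toks(cur)
      class(e) <- c("bkmc_expr", class(e))
      cur_expect(cur, value = ";")
      if (!is.null(spec[[at$value]])) {
        stop(dsl_err(toks$text, at$pos,
                     sprintf("attribute '%s' given twice for node '%s'", at$value, nm$value)),
             call. = FALSE)
      }
      spec[[at$value]] <- e
    }
    for (at in c("rate_up", "rate_down")) {
      if (is.null(spec[[at]])) {
        stop(sprintf("node '%s' is missing attribute '%s'", nm$value, at), call. = FALSE)
      }
    }
    nodes[[length(nodes) + 1L]] <- spec
  }
  if (!length(nodes)) stop("no nodes declared", call. = FALSE)
  node_names <- vapply(nodes, `[[`, "", "name")
  if (length(node_names) > 52L) {
    stop(sprintf("model has %d nodes; at most 52 are supported (exact double state ids)",
                 length(node_names)), call. = FALSE)
  }
  refs <- unique(unlist(lapply(nodes, function(nd) {
    c(expr_node_refs(nd$rate_up), expr_node_refs(nd$rate_down))
  })))
  unknown <- setdiff(refs, node_names)
  if (length(unknown)) {
    stop(sprintf("reference to undeclared node(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  params <- unique(unlist(lapply(nodes, function(nd) {
    c(expr_param_refs(nd$rate_up), expr_param_refs(nd$rate_down))
  })))
  structure(list(nodes = nodes, node_names = node_names, n = length(nodes),
                 parameters = setNames(numeric(0), character(0)),
                 param_names = params %||% character()),
            class = "bkmc_model")
}

#' Serialize a model back to BND-style source
#'
#' The output reparses to a structurally identical model
#' (`parse_bnd(format_model(m))`).
#'
#' @param model a `"bkmc_model"`.
#' @return a single character string of model source.
#' @export
format_model <- function(model) {
  stopifnot(inherits(model, "bkmc_model"))
  blocks <- vapply(model$nodes, function(nd) {
    paste0("node ", nd$name, " {\n",
           "  rate_up = ", expr_deparse(nd$rate_up), ";\n",
           "  rate_down = ", expr_deparse(nd$rate_down), ";\n",
           "}")
  }, "")
  paste0(paste(blocks, collapse = "\n\n"), "\n")
}

#' @export
print.bkmc_model <- function(x, ...) {
  cat(sprintf("Continuous-time Boolean network model: %d node%s\n", x$n, if (x$n == 1) "" else "s"))
  cat("  nodes:", paste(x$node_names, collapse = ", "), "\n")
  if (length(x$param_names)) {
    cat("  parameters:", paste(paste0("$", x$param_names), collapse = ", "), "\n")
  }
  invisible(x)
}
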