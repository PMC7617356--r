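# Expression trees for genetic-programming symbolic regression.
#
# A node is one of:
#   list(op = <name>, args = list(<children>))   operator node
#   list(feat = <column name>)                    feature leaf
#   list(const = <numeric>)                       constant leaf
#
# All operators are "protected": for finite inputs every operator returns a
# finite value, and each node's output is clamped to +/- CLAMP_LIMIT so that
# no chain of operations can overflow to Inf.

CLAMP_LIMIT <- 1e15

clamp_ <- function(x) {
  x[is.nan(x)] <- 0
  pmin(pmax(x, -CLAMP_LIMIT), CLAMP_LIMIT)
}

#' Operator set for expression trees
#'
#' Arithmetic from simple to complex, all protected so that finite inputs
#' always give finite outputs: `div` returns 1 where the denominator is 0,
#' `log` is `log(max(|x|, 1e-12))`, `exp` clamps its input to [-50, 50],
#' `sqrt` acts on `|x|`, `ifg(a,b,c,d)` returns `c` where `a > b` else `d`.
#'
#' @return Named list: each entry has `arity` and vectorised `fn`.
#' @export
operator_set <- function() {
  list(
    add  = list(arity = 2L, fn = function(a, b) a + b),
    sub  = list(arity = 2L, fn = function(a, b) a - b),
    mul  = list(arity = 2L, fn = function(a, b) a * b),
    div  = list(arity = 2L, fn = function(a, b) { r <- a / b; r[b == 0] <- 1; r }),
    neg  = list(arity = 1L, fn = function(a) -a),
    log  = list(arity = 1L, fn = function(a) log(pmax(abs(a), 1e-12))),
    exp  = list(arity = 1L, fn = function(a) exp(pmin(pmax(a, -50), 50))),
    sqrt = list(arity = 1L, fn = function(a) sqrt(abs(a))),
    min  = list(arity = 2L, fn = function(a, b) pmin(a, b)),
    max  = list(arity = 2L, fn = function(a, b) pmax(a, b)),
    ifg  = list(arity = 4L, fn = function(a, b, c, d) { r <- d; w <- a > b; r[w] <- c[w]; r })
  )
}

# leaf constructors
feat_node <- function(name) list(feat = name)
const_node <- function(value) list(const = value)
op_node <- function(op, ...) list(op = op, args = list(...))

is_leaf <- function(node) is.null(node$op)

#' Evaluate an expression tree on a feature matrix
#'
#' Vectorised over rows: each node is evaluated once as a length-n vector.
#'
#' @param tree Expression tree.
#' @param X Numeric matrix with named columns (or a `feature_matrix`).
#' @param ops Operator set (default [operator_set()]).
#' @return Numeric vector, one finite value per row.
#' @export
eval_tree <- function(tree, X, ops = operator_set()) {
  if (inherits(X, "feature_matrix")) X <- X$X
  n <- nrow(X)
  rec <- function(node) {
    if (!is.null(node$const)) return(rep(node$const, n))
    if (!is.null(node$feat)) {
      if (!node$feat %in% colnames(X))
        stop("unresolved feature reference: ", node$feat)
      return(X[, node$feat])
    }
    op <- ops[[node$op]]
    if (is.null(op)) stop("unknown operator: ", node$op)
    clamp_(do.call(op$fn, lapply(node$args, rec)))
  }
  rec(tree)
}

#' @rdname tree_utils
#' @export
tree_depth <- function(tree) {
  if (is_leaf(tree)) return(1L)
  1L + max(vapply(tree$args, tree_depth, integer(1)))
}

#' Tree utilities
#'
#' `tree_depth` counts levels (a leaf has depth 1); `tree_size` counts
#' nodes; `tree_features` lists the distinct feature columns referenced.
#'
#' @param tree Expression tree.
#' @name tree_utils
#' @export
tree_size <- function(tree) {
  if (is_leaf(tree)) return(1L)
  1L + sum(vapply(tree$args, tree_size, integer(1)))
}

#' @rdname tree_utils
#' @export
tree_features <- function(tree) {
  if (!is.null(tree$feat)) return(tree$feat)
  if (!is.null(tree$const)) return(character(0))
  unique(unlist(lapply(tree$args, tree_features)))
}

# preorder list of node paths; a path is an integer vector of child indices
node_paths <- function(tree) {
  out <- list(integer(0))
  if (!is_leaf(tree)) {
    for (i in seq_along(tree$args)) {
      for (p in node_paths(tree$args[[i]])) out[[length(out) + 1L]] <- c(i, p)
    }
  }
  out
}

get_node <- function(tree, path) {
  for (i in path) tree <- tree$args[[i]]
  tree
}

set_node <- function(tree, path, sub) {
  if (!length(path)) return(sub)
  tree$args[[path[1]]] <- set_node(tree$args[[path[1]]], path[-1], sub)
  tree
}

#' Generate a random expression tree
#'
#' `method = "full"` places operators at every level above `depth` 1;
#' `method = "grow"` chooses operators or terminals freely. Terminals are a
#' feature reference (probability 0.8) or a uniform constant.
#'
#' @param features Character vector of available feature columns.
#' @param max_depth Maximum tree depth (a single leaf has depth 1).
#' @param method `"grow"` or `"full"`.
#' @param const_range Length-2 numeric range for ephemeral constants.
#' @param ops Operator set.
#' @return An expression tree. Consumes the current RNG stream.
#' @export
random_tree <- function(features, max_depth, method = c("grow", "full"),
                        const_range = c(-2, 2), ops = operator_set()) {
  method <- match.arg(method)
  terminal <- function() {
    if (stats::runif(1) < 0.8 && length(features))
      feat_node(sample(features, 1))
    else const_node(stats::runif(1, const_range[1], const_range[2]))
  }
  rec <- function(depth) {
    pick_terminal <- depth >= max_depth ||
      (method == "grow" && depth > 1 && stats::runif(1) < 0.3)
    if (pick_terminal) return(terminal())
    nm <- sample(names(ops), 1)
    args <- lapply(seq_len(ops[[nm]]$arity), function(i) rec(depth + 1L))
    list(op = nm, args = args)
  }
  rec(1L)
}

#' Serialize an expression tree to its formula string
#'
#' Prefix grammar: `op(arg, ...)`, feature leaves by column name, constants
#' as decimal literals (17 significant digits, round-trip exact).
#'
#' @param tree Expression tree.
#' @return A single formula string.
#' @export
serialize_formula <- function(tree) {
  if (!is.null(tree$const)) return(sprintf("%.17g", tree$const))
  if (!is.null(tree$feat)) return(tree$feat)
  paste0(tree$op, "(",
         paste(vapply(tree$args, serialize_formula, character(1)),
               collapse = ", "), ")")
}

#' Parse a formula string back to an expression tree
#'
#' Rejects unknown operators and (when `features` is supplied) unknown
#' feature names; syntax errors report the character position.
#'
#' @param text Formula string in the prefix grammar.
#' @param features Optional character vector of legal feature names.
#' @param ops Operator set.
#' @return An expression tree.
#' @export
parse_formula <- function(text, features = NULL, ops = operator_set()) {
  pos <- 1L
  n <- nchar(text)
  peek <- function() if (pos > n) "" else substr(text, pos, pos)
  skip_ws <- function() while (pos <= n && peek() %in% c(" ", "\t")) pos <<- pos + 1L
  fail <- function(msg) stop(sprintf("parse error at position %d: %s", pos, msg))
  read_token <- function() {
    skip_ws()
    start <- pos
    if (grepl("[A-Za-z_]", peek())) {
      while (pos <= n && grepl("[A-Za-z0-9_]", peek())) pos <<- pos + 1L
      list(type = "ident", value = substr(text, start, pos - 1L))
    } else if (grepl("[-+0-9.]", peek())) {
      while (pos <= n && grepl("[-+0-9.eE]", peek())) pos <<- pos + 1L
      v <- suppressWarnings(as.numeric(substr(text, start, pos - 1L)))
      if (is.na(v)) fail(paste0("malformed number '", substr(text, start, pos - 1L), "'"))
      list(type = "num", value = v)
    } else fail(paste0("unexpected character '", peek(), "'"))
  }
  parse_expr <- function() {
    tok <- read_token()
    if (tok$type == "num") return(const_node(tok$value))
    skip_ws()
    if (peek() == "(") {
      op <- ops[[tok$value]]
      if (is.null(op)) fail(paste0("unknown operator '", tok$value, "'"))
      pos <<- pos + 1L
      args <- list()
      repeat {
        args[[length(args) + 1L]] <- parse_expr()
        skip_ws()
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        fail("expected ',' or ')'")
      }
      if (length(args) != op$arity)
        fail(sprintf("operator '%s' takes %d arguments, got %d",
                     tok$value, op$arity, length(args)))
      return(list(op = tok$value, args = args))
    }
    if (!is.null(features) && !tok$value %in% features)
      fail(paste0("unknown feature name '", tok$value, "'"))
    feat_node(tok$value)
  }
  out <- parse_expr()
  skip_ws()
  if (pos <= n) fail("trailing input")
  out
}
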