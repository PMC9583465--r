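# Expression trees: the shared genotype of the tree-GP engine and the
# phenotype of the grammatical-evolution mapper. Two dialects:
#   arithmetic — add/sub/mul/protected-div over crisp features and numeric
#     constants; the classifier score is sigmoid(raw value).
#   fuzzy — the fuzzy-pattern-tree operator set (max, min, WA, OWA with a
#     constant weight r in (0,1), dilator = sqrt, concentrator = square)
#     over fuzzy membership features; the raw value is the score, closed
#     in [0,1] by construction.

op_table <- list(
  arithmetic = list(add = 2L, sub = 2L, mul = 2L, div = 2L),
  fuzzy = list(max = 2L, min = 2L, WA = 2L, OWA = 2L,
               dilator = 1L, concentrator = 1L)
)

weighted_ops <- c("WA", "OWA")

node_op <- function(op, children, r = NULL)
  list(kind = "op", op = op, children = children, r = r)
node_feature <- function(name) list(kind = "feature", name = name)
node_const <- function(value) list(kind = "const", value = value)

#' Build an expression tree
#'
#' @param root the root node (use [parse_expression()] to build one from
#'   text).
#' @param dialect `"arithmetic"` or `"fuzzy"`.
#' @return An object of class `expression_tree`.
#' @export
expression_tree <- function(root, dialect = c("arithmetic", "fuzzy")) {
  dialect <- match.arg(dialect)
  tree <- structure(list(root = root, dialect = dialect),
                    class = "expression_tree")
  validate_tree(tree)
  tree
}

#' Validate expression-tree invariants
#'
#' Checks operator arities, dialect closure (a fuzzy tree uses only the
#' fuzzy operator set and feature terminals), weight constants in (0, 1),
#' and an optional depth cap.
#'
#' @param tree an `expression_tree`.
#' @param depth_cap maximum allowed depth (`Inf` to skip).
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_tree <- function(tree, depth_cap = Inf) {
  stopifnot(inherits(tree, "expression_tree"))
  ops <- op_table[[tree$dialect]]
  walk <- function(node) {
    switch(node$kind,
      op = {
        ar <- ops[[node$op]]
        if (is.null(ar))
          stop_oscml("operator '", node$op, "' is not in the ",
                     tree$dialect, " dialect")
        if (length(node$children) != ar)
          stop_oscml("operator '", node$op, "' expects ", ar, " children")
        if (node$op %in% weighted_ops) {
          if (is.null(node$r) || node$r <= 0 || node$r >= 1)
            stop_oscml(node$op, " weight r must lie in (0, 1)")
        }
        lapply(node$children, walk)
      },
      feature = NULL,
      const = {
        if (tree$dialect == "fuzzy")
          stop_oscml("fuzzy dialect admits only feature terminals")
        if (!is.finite(node$value)) stop_oscml("non-finite constant")
      },
      stop_oscml("unknown node kind '", node$kind, "'"))
    invisible(NULL)
  }
  walk(tree$root)
  if (tree_depth(tree) > depth_cap)
    stop_oscml("tree depth ", tree_depth(tree), " exceeds cap ", depth_cap)
  invisible(TRUE)
}

#' Tree depth
#'
#' A lone terminal has depth 0.
#' @param tree an `expression_tree` or a raw node.
#' @return Integer depth.
#' @export
tree_depth <- function(tree) {
  node <- if (inherits(tree, "expression_tree")) tree$root else tree
  if (node$kind != "op") return(0L)
  1L + max(vapply(node$children, tree_depth, 0L))
}

tree_size <- function(tree) {
  node <- if (inherits(tree, "expression_tree")) tree$root else tree
  if (node$kind != "op") return(1L)
  1L + sum(vapply(node$children, tree_size, 0L))
}

sigmoid <- function(v) 1 / (1 + exp(-v))

eval_node <- function(node, data) {
  switch(node$kind,
    feature = {
      col <- data[[node$name]]
      if (is.null(col))
        stop_oscml("record lacks terminal feature '", node$name, "'")
      as.numeric(col)
    },
    const = rep(node$value, nrow(data)),
    op = {
      a <- eval_node(node$children[[1]], data)
      b <- if (length(node$children) > 1) eval_node(node$children[[2]], data)
      switch(node$op,
        add = a + b,
        sub = a - b,
        mul = a * b,
        div = ifelse(abs(b) < 1e-6, 1, a / b),
        max = pmax(a, b),
        min = pmin(a, b),
        WA = node$r * a + (1 - node$r) * b,
        OWA = node$r * pmax(a, b) + (1 - node$r) * pmin(a, b),
        dilator = sqrt(a),
        concentrator = a^2,
        stop_oscml("unknown operator '", node$op, "'"))
    })
}

#' Evaluate an expression tree as a classifier score
#'
#' Arithmetic trees return `sigmoid(raw value)`; fuzzy trees return the raw
#' value, which the operator set keeps in \[0, 1\] whenever the inputs are
#' memberships in \[0, 1\].
#'
#' @param tree an `expression_tree`.
#' @param data data.frame whose columns include every terminal feature.
#' @return Numeric score vector in \[0, 1\], one per row of `data`.
#' @examples
#' tr <- parse_expression("OWA(concentrator(Rp_medium), Ax_medium, 0.6)",
#'                        dialect = "fuzzy")
#' evaluate_tree(tr, data.frame(Rp_medium = 0.5, Ax_medium = 0.3))
#' @export
evaluate_tree <- function(tree, data) {
  stopifnot(inherits(tree, "expression_tree"))
  data <- as.data.frame(data)
  raw <- eval_node(tree$root, data)
  if (tree$dialect == "arithmetic") sigmoid(raw) else raw
}

#' Render an expression tree as text
#'
#' Prefix notation, e.g. `"add(mul(Ax, 0.7), sub(Rt, Rm))"` or
#' `"OWA(concentrator(Rp_medium), Ax_medium, 0.6)"` (the WA/OWA weight is
#' printed as a trailing argument). The rendering parses back via
#' [parse_expression()].
#'
#' @param tree an `expression_tree` or node.
#' @return Single character string.
#' @export
render_tree <- function(tree) {
  node <- if (inherits(tree, "expression_tree")) tree$root else tree
  switch(node$kind,
    feature = node$name,
    const = format(node$value, digits = 15, scientific = FALSE,
                   trim = TRUE),
    op = {
      args <- vapply(node$children, render_tree, "")
      if (node$op %in% weighted_ops)
        args <- c(args, format(node$r, digits = 15, trim = TRUE))
      paste0(node$op, "(", paste(args, collapse = ", "), ")")
    })
}

#' @export
print.expression_tree <- function(x, ...) {
  cat(sprintf("<%s expression> %s\n", x$dialect, render_tree(x)))
  invisible(x)
}

#' Parse a prefix-notation expression
#'
#' Inverse of [render_tree()]: reads expressions such as
#' `"add(mul(Ax, 0.7), sub(Rt, Rm))"` into an `expression_tree`. For WA and
#' OWA the final numeric argument is the weight `r`.
#'
#' @param text expression string.
#' @param dialect `"arithmetic"` or `"fuzzy"`.
#' @return An `expression_tree`.
#' @export
parse_expression <- function(text, dialect = c("arithmetic", "fuzzy")) {
  dialect <- match.arg(dialect)
  ops <- op_table[[dialect]]
  src <- text
  pos <- 1L
  n <- nchar(src)
  peek <- function() if (pos > n) "" else substr(src, pos, pos)
  skip_ws <- function() while (pos <= n && grepl("[[:space:]]", peek())) pos <<- pos + 1L
  read_token <- function() {
    skip_ws()
    start <- pos
    while (pos <= n && grepl("[A-Za-z0-9_.+-]", peek())) pos <<- pos + 1L
    if (pos == start) stop_oscml("parse error near position ", pos, " in: ", text)
    substr(src, start, pos - 1L)
  }
  expect <- function(ch) {
    skip_ws()
    if (peek() != ch)
      stop_oscml("expected '", ch, "' at position ", pos, " in: ", text)
    pos <<- pos + 1L
  }
  parse_node <- function() {
    tok <- read_token()
    skip_ws()
    if (peek() == "(") {
      if (is.null(ops[[tok]]))
        stop_oscml("operator '", tok, "' is not in the ", dialect, " dialect")
      expect("(")
      args <- list()
      repeat {
        args[[length(args) + 1L]] <- parse_node()
        skip_ws()
        if (peek() == ",") { expect(",") } else break
      }
      expect(")")
      if (tok %in% weighted_ops) {
        rnode <- args[[length(args)]]
        if (rnode$kind != "const")
          stop_oscml(tok, " expects a numeric weight as its last argument")
        node_op(tok, args[-length(args)], r = rnode$value)
      } else {
        node_op(tok, args)
      }
    } else if (grepl("^[+-]?[0-9.]+$", tok)) {
      node_const(as.numeric(tok))
    } else {
      node_feature(tok)
    }
  }
  root <- parse_node()
  skip_ws()
  if (pos <= n) stop_oscml("trailing text after expression: ", text)
  expression_tree(root, dialect)
}

# --- random tree generation (grow / full), used by GP init and mutation ---

random_terminal <- function(dialect, terminals) {
  if (dialect == "arithmetic" && runif(1) < 0.2)
    node_const(round(runif(1, -1, 1), 3))
  else
    node_feature(sample(terminals, 1L))
}

random_op_node <- function(dialect, make_child) {
  ops <- op_table[[dialect]]
  op <- sample(names(ops), 1L)
  r <- if (op %in% weighted_ops) sample(seq(0.1, 0.9, by = 0.1), 1L) else NULL
  node_op(op, lapply(seq_len(ops[[op]]), function(i) make_child()),
          r = r)
}

random_node <- function(dialect, terminals, depth, method = c("grow", "full")) {
  method <- match.arg(method)
  if (depth <= 0L ||
      (method == "grow" && depth > 0L && runif(1) < 0.3))
    return(random_terminal(dialect, terminals))
  random_op_node(dialect,
                 function() random_node(dialect, terminals, depth - 1L, method))
}

#' Generate a random expression tree
#'
#' Grow or full method over the dialect's operator set and the given
#' terminal features (arithmetic trees may also draw ephemeral constants in
#' \[-1, 1\]). Used for GP initialization and subtree mutation; randomness
#' comes from the session RNG.
#'
#' @param dialect `"arithmetic"` or `"fuzzy"`.
#' @param terminals character vector of feature names.
#' @param depth maximum depth of the generated tree.
#' @param method `"grow"` (variable shape) or `"full"` (operators down to
#'   `depth`).
#' @return An `expression_tree`.
#' @export
random_tree <- function(dialect, terminals, depth,
                        method = c("grow", "full")) {
  expression_tree(random_node(dialect, terminals, depth, match.arg(method)),
                  dialect)
}

# Node addressing by child-index paths; path integer(0) is the root.
tree_paths <- function(node, prefix = integer(0)) {
  out <- list(prefix)
  if (node$kind == "op")
    for (i in seq_along(node$children))
      out <- c(out, tree_paths(node$children[[i]], c(prefix, i)))
  out
}

get_subtree <- function(node, path) {
  for (i in path) node <- node$children[[i]]
  node
}

replace_subtree <- function(node, path, replacement) {
  if (length(path) == 0L) return(replacement)
  node$children[[path[1]]] <-
    replace_subtree(node$children[[path[1]]], path[-1], replacement)
  node
}
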