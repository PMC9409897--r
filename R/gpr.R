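# Gene-protein-reaction (GPR) boolean expressions.
#
# Grammar: identifiers, parentheses, case-insensitive `and` / `or`.
#   expr   := term ( "or" term )*
#   term   := factor ( "and" factor )*
#   factor := identifier | "(" expr ")"
# NOT never occurs in GSMM gene associations and is not part of the grammar.

gpr_tokenize <- function(x) {
  x <- gsub("([()])", " \\1 ", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a gene-protein-reaction expression
#'
#' Parses a GPR string such as `"(g1 and g2) or g3"` into a nested expression
#' tree. Leaves are gene identifiers; internal nodes carry `op = "and"` or
#' `op = "or"`. An empty or whitespace-only string yields `NULL` (no gene
#' association).
#'
#' @param x GPR string. `and`/`or` are case-insensitive; parentheses group.
#' @return A parse tree (`NULL`, a character scalar leaf, or a
#'   `list(op =, args = )` node).
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(NULL)
  toks <- gpr_tokenize(x)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- toks[pos]
    pos <<- pos + 1L
    t
  }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed GPR '", x, "': unexpected end of expression", call. = FALSE)
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (is.na(peek()) || peek() != ")") {
        stop("malformed GPR '", x, "': missing closing parenthesis", call. = FALSE)
      }
      advance()
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) {
      stop("malformed GPR '", x, "': dangling connective or parenthesis near '", t, "'",
        call. = FALSE
      )
    }
    advance()
  }
  tree <- parse_expr()
  if (pos <= length(toks)) {
    stop("malformed GPR '", x, "': trailing tokens from '", toks[pos], "'", call. = FALSE)
  }
  tree
}

#' Genes referenced by a GPR expression
#'
#' @param x GPR string or parse tree.
#' @return Character vector of unique gene ids (empty for no association).
#' @export
gpr_genes <- function(x) {
  tree <- if (is.character(x)) parse_gpr(x) else x
  walk <- function(node) {
    if (is.null(node)) return(character())
    if (is.character(node)) return(node)
    unlist(lapply(node$args, walk))
  }
  unique(walk(tree))
}

#' Evaluate a GPR expression
#'
#' Boolean mode treats AND as conjunction and OR as disjunction (enzyme
#' complexes require all subunits; isozymes require any). Numeric mode is the
#' standard expression-overlay convention: AND = min, OR = max, so a complex
#' is limited by its least-expressed subunit and isozymes by the strongest.
#'
#' Genes absent from `gene_values` are taken as absent (`FALSE` / `NA`) with a
#' warning. An empty GPR means "no gene association": the reaction is treated
#' as present (`TRUE` in boolean mode, `NA` in numeric mode) and the result
#' carries attribute `no_gene_association = TRUE`.
#'
#' @param gpr GPR string or parse tree.
#' @param gene_values Named logical (boolean mode) or numeric (numeric mode)
#'   vector keyed by gene id.
#' @param mode `"boolean"` or `"numeric"`.
#' @param quiet Suppress the missing-gene warning.
#' @return Logical or numeric scalar.
#' @examples
#' evaluate_gpr("(g1 or g2) and g3", c(g1 = 2, g2 = 5, g3 = 1.5), mode = "numeric")
#' @export
evaluate_gpr <- function(gpr, gene_values, mode = c("boolean", "numeric"),
                         quiet = FALSE) {
  mode <- match.arg(mode)
  tree <- if (is.character(gpr) || is.null(gpr)) parse_gpr(if (is.null(gpr)) "" else gpr) else gpr
  if (is.null(tree)) {
    out <- if (mode == "boolean") TRUE else NA_real_
    attr(out, "no_gene_association") <- TRUE
    return(out)
  }
  leaves <- gpr_genes(tree)
  missing <- setdiff(leaves, names(gene_values))
  if (length(missing) && !quiet) {
    warning("GPR genes absent from gene_values, treated as absent: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  eval_node <- function(node) {
    if (is.character(node)) {
      if (!node %in% names(gene_values)) {
        return(if (mode == "boolean") FALSE else NA_real_)
      }
      v <- gene_values[[node]]
      return(if (mode == "boolean") isTRUE(as.logical(v)) else as.numeric(v))
    }
    vals <- vapply(
      node$args, eval_node,
      if (mode == "boolean") logical(1) else numeric(1)
    )
    if (mode == "boolean") {
      if (node$op == "and") all(vals) else any(vals)
    } else {
      vals <- vals[!is.na(vals)]
      if (!length(vals)) return(NA_real_)
      if (node$op == "and") min(vals) else max(vals)
    }
  }
  eval_node(tree)
}

# Canonical string form of a parse tree (used by writers and diffing).
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    s <- deparse_gpr(a)
    if (!is.character(a) && a$op != tree$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}
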