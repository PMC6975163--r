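# Gene-protein-reaction (GPR) rule parsing and evaluation.
#
# Grammar: identifiers, `and`, `or`, parentheses; keywords are
# case-insensitive; an empty rule means the reaction is spontaneous or has
# no known gene (always active).

tokenize_rule <- function(rule) {
  tokens <- list()
  i <- 1L
  n <- nchar(rule)
  while (i <= n) {
    ch <- substr(rule, i, i)
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch == "(" || ch == ")") {
      tokens[[length(tokens) + 1L]] <- list(type = ch, pos = i)
      i <- i + 1L
    } else {
      m <- regmatches(substr(rule, i, n),
                      regexpr("^[A-Za-z0-9_.:-]+", substr(rule, i, n)))
      if (length(m) == 0L)
        stop(sprintf("gene rule parse error at position %d: unexpected '%s'",
                     i, ch), call. = FALSE)
      word <- m[[1L]]
      lw <- tolower(word)
      type <- if (lw == "and") "and" else if (lw == "or") "or" else "ident"
      tokens[[length(tokens) + 1L]] <- list(type = type, value = word, pos = i)
      i <- i + nchar(word)
    }
  }
  tokens
}

#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean GPR expression (`and`/`or`/parentheses, case-insensitive
#' keywords) into an AST usable by [gene_rule_active()]. An empty or
#' whitespace-only rule parses to `NULL`, meaning "always active".
#'
#' @param rule character scalar GPR expression.
#' @return parse tree (nested lists) or `NULL` for an empty rule.
#' @export
parse_gene_rule <- function(rule) {
  if (is.null(rule) || length(rule) == 0L || !nzchar(trimws(rule)))
    return(NULL)
  tokens <- tokenize_rule(rule)
  pos <- 1L

  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() {
    t <- tokens[[pos]]
    pos <<- pos + 1L
    t
  }
  expect_err <- function(what) {
    t <- peek()
    at <- if (is.null(t)) nchar(rule) + 1L else t$pos
    stop(sprintf("gene rule parse error at position %d: expected %s", at,
                 what), call. = FALSE)
  }

  parse_factor <- function() {
    t <- peek()
    if (is.null(t)) expect_err("gene id or '('")
    if (t$type == "ident") {
      advance()
      return(list(op = "gene", id = t$value))
    }
    if (t$type == "(") {
      advance()
      node <- parse_expr()
      t2 <- peek()
      if (is.null(t2) || t2$type != ")") expect_err("')'")
      advance()
      return(node)
    }
    expect_err("gene id or '('")
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      node <- list(op = "and", lhs = node, rhs = parse_factor())
    }
    node
  }
  parse_expr <- function() {
    node <- parse_term()
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      node <- list(op = "or", lhs = node, rhs = parse_term())
    }
    node
  }

  ast <- parse_expr()
  if (!is.null(peek()))
    stop(sprintf("gene rule parse error at position %d: unexpected token",
                 peek()$pos), call. = FALSE)
  ast
}

eval_rule_ast <- function(ast, knocked_out) {
  if (is.null(ast)) return(TRUE)
  switch(ast$op,
    gene = !(ast$id %in% knocked_out),
    and = eval_rule_ast(ast$lhs, knocked_out) &&
          eval_rule_ast(ast$rhs, knocked_out),
    or = eval_rule_ast(ast$lhs, knocked_out) ||
         eval_rule_ast(ast$rhs, knocked_out),
    stop("invalid gene rule AST"))
}

#' Evaluate whether a reaction's gene rule is satisfied under knockouts
#'
#' Knocked-out genes evaluate to FALSE, all other genes to TRUE. An empty
#' rule is always active.
#'
#' @param rule GPR string or a parse tree from [parse_gene_rule()].
#' @param knocked_out character vector of knocked-out gene ids.
#' @return logical scalar.
#' @export
gene_rule_active <- function(rule, knocked_out = character()) {
  ast <- if (is.character(rule) || is.null(rule)) parse_gene_rule(rule) else rule
  eval_rule_ast(ast, knocked_out)
}

rule_genes_ast <- function(ast) {
  if (is.null(ast)) return(character())
  if (ast$op == "gene") return(ast$id)
  c(rule_genes_ast(ast$lhs), rule_genes_ast(ast$rhs))
}

#' Extract the gene ids referenced by a gene rule
#' @param rule GPR string or parse tree.
#' @return character vector of unique gene ids.
#' @export
gene_rule_genes <- function(rule) {
  ast <- if (is.character(rule) || is.null(rule)) parse_gene_rule(rule) else rule
  unique(rule_genes_ast(ast))
}
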