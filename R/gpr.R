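# Gene-protein-reaction (GPR) boolean rules.
#
# Rules are stored as strings over gene identifiers with the operators
# `and` / `or` (case-insensitive) and parentheses.  `and` encodes a protein
# complex (all subunits required), `or` isoenzymes (any suffices).  An empty
# rule means the reaction has no genetic requirement (orphan/spontaneous).

gpr_tokenise <- function(gpr) {
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(character())
  # identifiers may contain letters, digits, '_', '-', '.'
  toks <- regmatches(gpr, gregexpr("[A-Za-z0-9_.:-]+|\\(|\\)", gpr))[[1]]
  toks
}

#' Extract the gene ids referenced by a GPR rule
#' @param gpr rule string.
#' @return character vector of gene ids (empty for orphan reactions).
#' @export
gpr_genes <- function(gpr) {
  toks <- gpr_tokenise(gpr)
  toks <- toks[!(tolower(toks) %in% c("and", "or", "(", ")"))]
  unique(toks)
}

# Recursive-descent parse into nested list AST:
#   gene leaf: list(op = "gene", gene = id)
#   node:      list(op = "and"/"or", args = list(...))
gpr_parse <- function(gpr) {
  toks <- gpr_tokenise(gpr)
  if (!length(toks)) return(NULL)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed GPR rule: ", gpr)
    if (t == "(") {
      take()
      e <- parse_expr()
      if (is.na(peek()) || take() != ")") stop("unbalanced parentheses in GPR: ", gpr)
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("malformed GPR rule: ", gpr)
    list(op = "gene", gene = take())
  }
  out <- parse_expr()
  if (pos <= length(toks)) stop("trailing tokens in GPR rule: ", gpr)
  out
}

gpr_eval_ast <- function(ast, off) {
  if (is.null(ast)) return(TRUE)
  switch(ast$op,
         gene = !(ast$gene %in% off),
         and = all(vapply(ast$args, gpr_eval_ast, logical(1), off = off)),
         or = any(vapply(ast$args, gpr_eval_ast, logical(1), off = off)),
         stop("bad GPR node"))
}

#' Evaluate a GPR rule under a set of gene knockouts
#'
#' @param gpr rule string; an empty rule always evaluates `TRUE`.
#' @param off character vector of deleted (inactive) genes.
#' @return logical: can the reaction still be catalysed?
#' @export
gpr_eval <- function(gpr, off = character()) {
  gpr_eval_ast(gpr_parse(gpr), off)
}

# Canonical string form (sorted operands) used for model comparison.
gpr_ast_string <- function(ast) {
  if (is.null(ast)) return("")
  if (ast$op == "gene") return(ast$gene)
  parts <- sort(vapply(ast$args, gpr_ast_string, character(1)))
  paste0(ast$op, "(", paste(parts, collapse = ","), ")")
}

gpr_normalise <- function(gpr) {
  vapply(gpr, function(g) gpr_ast_string(gpr_parse(g)), character(1),
         USE.NAMES = FALSE)
}
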