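#' Gene-protein-reaction (GPR) rules
#'
#' GPR rules are boolean expressions over gene identifiers with `and`
#' (complex: all subunits required) and `or` (isozymes: any suffices),
#' e.g. `"(g1 and g2) or g3"`. They are parsed into a tree of nested lists:
#' a gene is a character scalar, a node is `list(op = "and"|"or",
#' args = list(...))`.
#'
#' @param text GPR string; `NA` or `""` yields `NULL` (no rule).
#' @return parse tree, or `NULL`.
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text) || trimws(text) == "") {
    return(NULL)
  }
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("trailing input in GPR rule near '", st$toks[st$pos], "'", call. = FALSE)
  }
  tree
}

gpr_tokenize <- function(text) {
  text <- gsub("(", " ( ", gsub(")", " ) ", text, fixed = TRUE), fixed = TRUE)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[toks != ""]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_and(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_atom(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok)) stop("unexpected end of GPR rule", call. = FALSE)
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")")) stop("unbalanced parentheses in GPR rule", call. = FALSE)
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    stop("unexpected token '", tok, "' in GPR rule", call. = FALSE)
  }
  st$pos <- st$pos + 1L
  tok
}

#' Genes referenced by a GPR tree
#' @param tree GPR parse tree (see [parse_gpr()]).
#' @return character vector of gene ids (unique, in order of appearance).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Evaluate a GPR tree with a set of knocked-out genes
#'
#' @param tree GPR parse tree; `NULL` evaluates `TRUE` (no rule, reaction
#'   always available).
#' @param knocked character vector of deleted gene ids.
#' @return logical: is the reaction still catalysable?
#' @export
eval_gpr <- function(tree, knocked = character(0)) {
  if (is.null(tree)) return(TRUE)
  if (is.character(tree)) return(!(tree %in% knocked))
  vals <- vapply(tree$args, eval_gpr, logical(1), knocked = knocked)
  if (tree$op == "and") all(vals) else any(vals)
}

#' Render a GPR tree back to a rule string
#' @param tree GPR parse tree.
#' @return GPR string (`NA` for `NULL` trees).
#' @export
deparse_gpr <- function(tree) {
  if (is.null(tree)) return(NA_character_)
  if (is.character(tree)) return(tree)
  sep <- paste0(" ", tree$op, " ")
  parts <- vapply(tree$args, function(a) {
    s <- deparse_gpr(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, "")
  paste(parts, collapse = sep)
}
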