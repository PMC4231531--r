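# Gene-protein-reaction (GPR) boolean rules.
#
# A GPR is a boolean tree over gene-id leaves with AND (enzyme complex) and
# OR (isozyme) internal nodes. The empty rule (NULL) means the reaction has
# no gene association and can never be disabled by a gene deletion.

#' Parse a gene-protein-reaction rule
#'
#' Parses text such as `"(g1 and g2) or g3"` into a boolean expression tree.
#' `and`/`or` are case-insensitive; any other token is a gene identifier.
#' Blank or empty text yields the empty rule (`NULL`).
#'
#' @param text a single character string.
#' @return an object of class `gpr` (a nested list with nodes
#'   `list(op = "and"|"or", args = ...)` and leaves
#'   `list(op = "gene", gene = <id>)`), or `NULL` for an empty rule.
#' @examples
#' parse_gpr("g1 and g2")
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L) return(NULL)
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(NULL)

  ## tokenize, remembering character positions for error messages
  pat <- "\\(|\\)|[^()[:space:]]+"
  mm <- gregexpr(pat, text)[[1]]
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  pos <- as.integer(mm)
  i <- 1L
  ntok <- length(toks)

  peek <- function() if (i <= ntok) toks[i] else NA_character_
  bail <- function(msg, at = if (i <= ntok) pos[i] else nchar(text) + 1L) {
    stop(sprintf("GPR parse error at position %d: %s", at, msg), call. = FALSE)
  }

  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      i <<- i + 1L
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      i <<- i + 1L
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    tk <- peek()
    if (is.na(tk)) bail("unexpected end of rule")
    if (tk == "(") {
      open_at <- pos[i]
      i <<- i + 1L
      node <- parse_expr()
      if (is.na(peek()) || peek() != ")") {
        bail("unbalanced parenthesis", at = open_at)
      }
      i <<- i + 1L
      return(node)
    }
    if (tk == ")") bail("unexpected ')'")
    if (tolower(tk) %in% c("and", "or")) bail(sprintf("dangling operator '%s'", tk))
    i <<- i + 1L
    list(op = "gene", gene = tk)
  }

  root <- parse_expr()
  if (!is.na(peek())) bail(sprintf("unexpected token '%s'", peek()))
  structure(root, class = "gpr")
}

#' Serialize a GPR tree to its string form
#'
#' The output reparses to an equivalent tree: `and` binds tighter than `or`,
#' and `or` children of an `and` node are parenthesized.
#'
#' @param gpr a `gpr` object or `NULL`.
#' @return a character string (`""` for the empty rule).
#' @export
gpr_to_string <- function(gpr) {
  if (is.null(gpr)) return("")
  rec <- function(node, parent_op) {
    if (node$op == "gene") return(node$gene)
    parts <- vapply(node$args, rec, character(1), parent_op = node$op)
    s <- paste(parts, collapse = paste0(" ", node$op, " "))
    if (node$op == "or" && identical(parent_op, "and")) paste0("(", s, ")") else s
  }
  rec(unclass(gpr), NA_character_)
}

#' Genes referenced by a GPR rule
#'
#' @param gpr a `gpr` object or `NULL`.
#' @return character vector of distinct gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  out <- character(0)
  rec <- function(node) {
    if (node$op == "gene") {
      out[[length(out) + 1L]] <<- node$gene
    } else {
      for (a in node$args) rec(a)
    }
  }
  rec(unclass(gpr))
  unique(out)
}

#' Evaluate a GPR rule under a gene deletion
#'
#' @param gpr a `gpr` object or `NULL`.
#' @param deleted character vector of deleted gene ids.
#' @return `TRUE` if the reaction's enzyme remains available. The empty rule
#'   always evaluates `TRUE`.
#' @export
gpr_eval <- function(gpr, deleted = character(0)) {
  if (is.null(gpr)) return(TRUE)
  rec <- function(node) {
    switch(node$op,
      gene = !(node$gene %in% deleted),
      and = all(vapply(node$args, rec, logical(1))),
      or = any(vapply(node$args, rec, logical(1))),
      stop("corrupt GPR node"))
  }
  rec(unclass(gpr))
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", gpr_to_string(x), "\n", sep = "")
  invisible(x)
}

## coerce user input (string or tree) to a gpr tree
as_gpr <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "gpr")) return(x)
  if (is.character(x)) return(parse_gpr(x))
  stop("gpr must be a string, a 'gpr' object, or NULL")
}
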