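#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are Boolean expressions over gene identifiers in which `and`
#' encodes subunits of a complex (all genes required) and `or` encodes
#' isozymes (any gene suffices). The grammar accepted here matches the usual
#' SBML/FBC serialisations: case-insensitive `and`/`or` keywords,
#' parentheses, and gene ids being any other token. `and` binds tighter than
#' `or`; chains of the same operator are flattened into a single n-ary node.
#' The empty string parses to the empty association (no genes required).
#'
#' @param text character scalar, e.g. `"(g1 and g2) or g3"`; `""` and `NA`
#'   give the empty association.
#' @return An object of class `gpr`: either the empty association, a leaf
#'   (gene id), or a list node with `op` (`"and"`/`"or"`) and `args`.
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' parse_gpr("")
#' @export
parse_gpr <- function(text) {
  if (length(text) != 1L) stop("parse_gpr() expects a single string")
  if (is.na(text) || !nzchar(trimws(text))) {
    return(structure(list(kind = "empty"), class = "gpr"))
  }
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- gpr_parse_or(st, text)
  if (st$pos <= length(st$toks)) {
    tk <- st$toks[[st$pos]]
    stop(sprintf("GPR parse error at offset %d: unexpected token '%s'",
                 tk$offset, tk$text))
  }
  structure(expr, class = "gpr")
}

# Tokens: "(" ")" and/or keywords (case-insensitive) and gene ids. Offsets
# are 1-based character positions into the original string, kept for error
# messages.
gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) return(list())
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    txt <- substr(text, starts[k], starts[k] + lens[k] - 1L)
    low <- tolower(txt)
    type <- if (txt == "(") "lparen" else if (txt == ")") "rparen"
      else if (low %in% c("and", "&", "&&")) "and"
      else if (low %in% c("or", "|", "||")) "or"
      else "gene"
    out[[k]] <- list(type = type, text = txt, offset = starts[k])
  }
  out
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks)) NULL else st$toks[[st$pos]]
}

# flatten children carrying the same operator, so "a op b op c" and any
# parenthesisation of it yield one n-ary node
gpr_flatten <- function(op, args) {
  out <- list()
  for (a in args) {
    if (is.list(a) && identical(a$kind, "op") && a$op == op) out <- c(out, a$args)
    else out <- c(out, list(a))
  }
  if (length(out) == 1L) out[[1]] else list(kind = "op", op = op, args = out)
}

gpr_parse_or <- function(st, text) {
  args <- list(gpr_parse_and(st, text))
  while (!is.null(tk <- gpr_peek(st)) && tk$type == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st, text)))
  }
  gpr_flatten("or", args)
}

gpr_parse_and <- function(st, text) {
  args <- list(gpr_parse_atom(st, text))
  while (!is.null(tk <- gpr_peek(st)) && tk$type == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st, text)))
  }
  gpr_flatten("and", args)
}

gpr_parse_atom <- function(st, text) {
  tk <- gpr_peek(st)
  if (is.null(tk)) {
    stop(sprintf("GPR parse error at offset %d: unexpected end of rule",
                 nchar(text) + 1L))
  }
  if (tk$type == "lparen") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st, text)
    cl <- gpr_peek(st)
    if (is.null(cl) || cl$type != "rparen") {
      stop(sprintf("GPR parse error at offset %d: unbalanced parenthesis",
                   tk$offset))
    }
    st$pos <- st$pos + 1L
    # unwrap: parenthesised subexpression keeps its own structure
    if (inherits(inner, "gpr")) unclass(inner) else inner
  } else if (tk$type == "gene") {
    st$pos <- st$pos + 1L
    list(kind = "gene", gene = tk$text)
  } else {
    stop(sprintf("GPR parse error at offset %d: unexpected token '%s'",
                 tk$offset, tk$text))
  }
}

#' Evaluate a GPR rule under a set of deleted genes
#'
#' A reaction stays catalysable when its rule evaluates to `TRUE` with every
#' deleted gene set to `FALSE` and every other gene `TRUE`. The empty
#' association (spontaneous or orphan reaction) is always active.
#'
#' @param gpr a `gpr` object from [parse_gpr()] (a plain rule string is also
#'   accepted and parsed on the fly).
#' @param deleted character vector of deleted gene ids.
#' @return logical scalar.
#' @examples
#' gpr_active(parse_gpr("(g1 and g2) or g3"), deleted = "g1")
#' @export
gpr_active <- function(gpr, deleted = character()) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  stopifnot(inherits(gpr, "gpr") || is.list(gpr))
  node <- if (inherits(gpr, "gpr")) unclass(gpr) else gpr
  switch(node$kind,
    empty = TRUE,
    gene = !(node$gene %in% deleted),
    op = {
      vals <- vapply(node$args, gpr_active, logical(1), deleted = deleted)
      if (node$op == "and") all(vals) else any(vals)
    },
    stop("malformed GPR node")
  )
}

#' Genes referenced by a GPR rule
#'
#' @param gpr a `gpr` object or rule string.
#' @return character vector of unique gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(gpr) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  node <- if (inherits(gpr, "gpr")) unclass(gpr) else gpr
  switch(node$kind,
    empty = character(),
    gene = node$gene,
    op = unique(unlist(lapply(node$args, gpr_genes))),
    stop("malformed GPR node")
  )
}

#' Serialise a GPR rule to canonical text
#'
#' Produces a string that [parse_gpr()] parses back to an identical tree:
#' lower-case keywords, `and`-chains parenthesised inside `or` only where
#' precedence requires it.
#'
#' @param gpr a `gpr` object.
#' @return character scalar (empty string for the empty association).
#' @export
gpr_to_string <- function(gpr) {
  node <- if (inherits(gpr, "gpr")) unclass(gpr) else gpr
  switch(node$kind,
    empty = "",
    gene = node$gene,
    op = {
      parts <- vapply(node$args, function(a) {
        s <- gpr_to_string(a)
        # parenthesise an or-child inside an and-parent
        if (node$op == "and" && is.list(a) && identical(a$kind, "op") &&
            a$op == "or") paste0("(", s, ")") else s
      }, character(1))
      paste(parts, collapse = paste0(" ", node$op, " "))
    },
    stop("malformed GPR node")
  )
}

#' @export
print.gpr <- function(x, ...) {
  s <- gpr_to_string(x)
  cat("<gpr> ", if (nzchar(s)) s else "(no gene association)", "\n", sep = "")
  invisible(x)
}
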