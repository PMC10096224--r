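# Boolean gene-reaction rule handling.
#
# Rules follow the COBRA string convention: gene ids combined with "and"/"or"
# (case-insensitive; "&"/"|" accepted) and parentheses. Rules are parsed into
# nested lists: a leaf is a character scalar, an internal node is
# list(op = "and"|"or", args = list(...)).

tokenizeRule <- function(rule) {
  rule <- gsub("&&?", " and ", rule)
  rule <- gsub("\\|\\|?", " or ", rule)
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

parseGeneRule <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- tokenizeRule(rule)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L; toks[pos - 1L] }
  parseExpr <- function() {
    args <- list(parseTerm())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args <- c(args, list(parseTerm()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parseTerm <- function() {
    args <- list(parseFactor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args <- c(args, list(parseFactor()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parseFactor <- function() {
    tok <- peek()
    if (is.na(tok)) stop("malformed gene rule: ", rule, call. = FALSE)
    if (tok == "(") {
      advance()
      e <- parseExpr()
      if (is.na(peek()) || peek() != ")")
        stop("unbalanced parentheses in gene rule: ", rule, call. = FALSE)
      advance()
      return(e)
    }
    if (tok %in% c(")") || tolower(tok) %in% c("and", "or"))
      stop("malformed gene rule: ", rule, call. = FALSE)
    advance()
  }
  out <- parseExpr()
  if (pos <= length(toks))
    stop("trailing tokens in gene rule: ", rule, call. = FALSE)
  out
}

deparseGeneRule <- function(tree, parentOp = NULL) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, deparseGeneRule, character(1),
                  parentOp = tree$op)
  joined <- paste(parts, collapse = paste0(" ", tree$op, " "))
  # parenthesise "or" nested under "and" to keep precedence explicit
  if (!is.null(parentOp) && parentOp == "and" && tree$op == "or")
    joined <- paste0("(", joined, ")")
  joined
}

ruleGenes <- function(rule) {
  tree <- parseGeneRule(rule)
  collect <- function(t) {
    if (is.null(t)) return(character())
    if (is.character(t)) return(t)
    unlist(lapply(t$args, collect))
  }
  unique(collect(tree))
}

# Remove a gene from a rule tree, simplifying as it goes: a node that loses
# all children vanishes; a node with one child collapses to that child.
dropGeneFromTree <- function(tree, gene) {
  if (is.null(tree)) return(NULL)
  if (is.character(tree)) return(if (identical(tree, gene)) NULL else tree)
  args <- lapply(tree$args, dropGeneFromTree, gene = gene)
  args <- args[!vapply(args, is.null, logical(1))]
  if (length(args) == 0L) return(NULL)
  if (length(args) == 1L) return(args[[1L]])
  list(op = tree$op, args = args)
}
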