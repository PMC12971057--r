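#' Parse a detection-rule expression
#'
#' Parses the boolean rule language used to describe biosynthetic gene
#' cluster detection rules. The language has identifiers (profile names:
#' letters, digits, `_` and `-`), the keywords `and`, `or` and `not`
#' (precedence `not` > `and` > `or`, binary operators left-associative),
#' parentheses, and a single-gene scope `cds(...)`: an expression wrapped in
#' `cds()` must be satisfied by the hits of one single gene, whereas outside
#' `cds()` an identifier is true if any gene in the region carries a
#' significant hit to it. `cds()` may not be nested. Lines starting with `#`
#' are comments; whitespace and newlines are insignificant.
#'
#' @param text A single string containing one rule expression.
#' @return A `rule_expr` object: a recursive list with a `kind` field, one of
#'   `"identifier"` (field `name`), `"not"` (field `child`), `"and"`/`"or"`
#'   (fields `left`, `right`), or `"cds"` (field `child`).
#' @examples
#' parse_rule("cds(Condensation and AMP-binding)")
#' parse_rule("A or B and not C")  # parsed as A or (B and (not C))
#' @seealso [format.rule_expr()], [evaluate_rule()], [list_identifiers()]
#' @export
parse_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  # strip comment lines before tokenizing
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\s*#", lines)]
  text <- paste(lines, collapse = "\n")
  toks <- tokenize_rule(text)
  if (nrow(toks) == 0L) {
    stop("empty rule expression", call. = FALSE)
  }
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  st$in_cds <- FALSE
  expr <- parse_or(st)
  if (st$pos <= nrow(st$toks)) {
    tok <- st$toks[st$pos, ]
    stop(sprintf("unexpected token '%s' at position %d", tok$text, tok$at),
         call. = FALSE)
  }
  expr
}

# Token table: columns type (ident, lparen, rparen, kw_and, kw_or, kw_not,
# kw_cds), text, at (character offset, for error messages).
tokenize_rule <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  types <- character(0)
  texts <- character(0)
  ats <- integer(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
      next
    }
    if (ch == "(") {
      types <- c(types, "lparen"); texts <- c(texts, "("); ats <- c(ats, i)
      i <- i + 1L
    } else if (ch == ")") {
      types <- c(types, "rparen"); texts <- c(texts, ")"); ats <- c(ats, i)
      i <- i + 1L
    } else if (grepl("^[A-Za-z0-9_-]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_-]$", chars[j])) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      type <- switch(word,
        "and" = "kw_and", "or" = "kw_or", "not" = "kw_not", "cds" = "kw_cds",
        "ident")
      types <- c(types, type); texts <- c(texts, word); ats <- c(ats, i)
      i <- j
    } else {
      stop(sprintf("unknown token '%s' at position %d", ch, i), call. = FALSE)
    }
  }
  data.frame(type = types, text = texts, at = ats, stringsAsFactors = FALSE)
}

tok_peek <- function(st) {
  if (st$pos > nrow(st$toks)) NULL else st$toks[st$pos, ]
}

tok_take <- function(st, type, what) {
  tok <- tok_peek(st)
  if (is.null(tok)) {
    stop(sprintf("unexpected end of rule: expected %s", what), call. = FALSE)
  }
  if (tok$type != type) {
    stop(sprintf("expected %s but found '%s' at position %d",
                 what, tok$text, tok$at), call. = FALSE)
  }
  st$pos <- st$pos + 1L
  tok
}

rule_node <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "rule_expr")
}

parse_or <- function(st) {
  left <- parse_and(st)
  repeat {
    tok <- tok_peek(st)
    if (is.null(tok) || tok$type != "kw_or") return(left)
    st$pos <- st$pos + 1L
    right <- parse_and(st)
    left <- rule_node("or", left = left, right = right)
  }
}

parse_and <- function(st) {
  left <- parse_not(st)
  repeat {
    tok <- tok_peek(st)
    if (is.null(tok) || tok$type != "kw_and") return(left)
    st$pos <- st$pos + 1L
    right <- parse_not(st)
    left <- rule_node("and", left = left, right = right)
  }
}

parse_not <- function(st) {
  tok <- tok_peek(st)
  if (!is.null(tok) && tok$type == "kw_not") {
    st$pos <- st$pos + 1L
    rule_node("not", child = parse_not(st))
  } else {
    parse_primary(st)
  }
}

parse_primary <- function(st) {
  tok <- tok_peek(st)
  if (is.null(tok)) {
    stop("unexpected end of rule: expected identifier, '(' or 'cds('",
         call. = FALSE)
  }
  if (tok$type == "ident") {
    st$pos <- st$pos + 1L
    return(rule_node("identifier", name = tok$text))
  }
  if (tok$type == "lparen") {
    st$pos <- st$pos + 1L
    expr <- parse_or(st)
    tok_take(st, "rparen", "')'")
    return(expr)
  }
  if (tok$type == "kw_cds") {
    if (st$in_cds) {
      stop(sprintf("cds() may not be nested (at position %d)", tok$at),
           call. = FALSE)
    }
    st$pos <- st$pos + 1L
    tok_take(st, "lparen", "'(' after cds")
    st$in_cds <- TRUE
    child <- parse_or(st)
    st$in_cds <- FALSE
    tok_take(st, "rparen", "')'")
    return(rule_node("cds", child = child))
  }
  stop(sprintf("unexpected token '%s' at position %d", tok$text, tok$at),
       call. = FALSE)
}

#' Pretty-print a rule expression
#'
#' Renders a parsed rule back to rule-language text. The output reparses to
#' an identical abstract syntax tree: `parse_rule(format(parse_rule(s)))`
#' equals `parse_rule(s)`.
#'
#' @param x A `rule_expr`.
#' @param ... Ignored.
#' @return A single string.
#' @export
format.rule_expr <- function(x, ...) {
  fmt <- function(node, parent_prec) {
    # precedence ranks: or=1, and=2, not=3, atoms=4
    switch(node$kind,
      identifier = node$name,
      cds = paste0("cds(", fmt(node$child, 1L), ")"),
      "not" = {
        s <- paste0("not ", fmt(node$child, 3L))
        if (parent_prec > 3L) paste0("(", s, ")") else s
      },
      "and" = {
        s <- paste(fmt(node$left, 2L), "and", fmt(node$right, 3L))
        if (parent_prec > 2L) paste0("(", s, ")") else s
      },
      "or" = {
        s <- paste(fmt(node$left, 1L), "or", fmt(node$right, 2L))
        if (parent_prec > 1L) paste0("(", s, ")") else s
      },
      stop("unknown rule node kind: ", node$kind))
  }
  fmt(x, 1L)
}

#' @export
print.rule_expr <- function(x, ...) {
  cat("<rule>", format(x), "\n")
  invisible(x)
}

#' List identifiers of a rule by polarity
#'
#' Walks the abstract syntax tree and partitions identifier names by the
#' parity of enclosing `not` operators: an identifier under an even number of
#' negations occurs positively, under an odd number negatively. A name can
#' appear in both partitions if it occurs in both polarities.
#'
#' @param rule A `rule_expr`.
#' @return A list with sorted character vectors `positive` and `negated`.
#' @examples
#' r <- parse_rule("A and not (B or not C)")
#' list_identifiers(r)  # positive: A, C; negated: B
#' @export
list_identifiers <- function(rule) {
  positive <- character(0)
  negated <- character(0)
  walk <- function(node, neg) {
    switch(node$kind,
      identifier = {
        if (neg) negated <<- c(negated, node$name)
        else positive <<- c(positive, node$name)
      },
      "not" = walk(node$child, !neg),
      "and" = { walk(node$left, neg); walk(node$right, neg) },
      "or" = { walk(node$left, neg); walk(node$right, neg) },
      cds = walk(node$child, neg))
    invisible(NULL)
  }
  walk(rule, FALSE)
  list(positive = sort(unique(positive)), negated = sort(unique(negated)))
}

#' The canonical NRP-metallophore detection rule
#'
#' Returns the bundled chelator-based detection rule: a region is called an
#' NRP metallophore BGC if it carries one of the metallophore-specific NRPS
#' condensation-domain subtypes (VibH-like or tandem heterocyclization), or
#' if a single gene carries both a condensation and an adenylation
#' (AMP-binding) domain and the region additionally carries a chelator
#' biosynthesis marker: beta-hydroxyaspartate or beta-hydroxyhistidine
#' hydroxylases (with the syringomycin-family SBH_Asp veto), salicylate
#' (IPL or SalSyn), 2,3-DHB catechol (EntA and EntC), graminine (GrbD and
#' GrbE), Dmaq (FbnL and FbnM), the pyoverdine chromophore (PvdO or PvdP),
#' or a hydroxamate pathway (ornithine/lysine N-monooxygenase, with KtzT and
#' MetRS-like piperazate/hydrazine vetoes, or the vicibactin epimerase VbsL).
#'
#' @param parsed If `TRUE` (default) return the parsed `rule_expr`;
#'   otherwise return the rule text.
#' @return A `rule_expr`, or a string when `parsed = FALSE`.
#' @export
nrp_metallophore_rule <- function(parsed = TRUE) {
  path <- system.file("extdata", "nrp_metallophore.rule",
                      package = "metallominer", mustWork = TRUE)
  txt <- paste(readLines(path), collapse = "\n")
  if (parsed) parse_rule(txt) else txt
}

#' Read a rule from a file
#'
#' Reads a plain-text rule file (one rule per file, `#` comment lines
#' allowed) and parses it.
#'
#' @param path Path to a rule file.
#' @return A `rule_expr`.
#' @export
read_rule <- function(path) {
  parse_rule(paste(readLines(path), collapse = "\n"))
}
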