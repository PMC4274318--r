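## Atom-selection mini-language.
##
## Grammar (case-insensitive keywords, XPLOR-flavoured):
##   expr    := term ( "or" term )*
##   term    := factor ( "and" factor )*
##   factor  := "not" factor | "(" expr ")" | primary
##   primary := "segid" VALUE | "chain" VALUE | "resname" VALUE
##            | "resid" INT | "resid" INT:INT | "name" GLOB
##            | "all" | "none"
## Atom-name globs use "*" (any suffix), e.g. "name N*" matches N001...N190.
## Evaluation is deterministic and order-preserving (ascending atom index).

sel_tokenize <- function(text) {
  text <- gsub("∗", "*", text)   # tolerate the typographic asterisk
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws2(text), "\\s+")[[1]]
  toks[toks != ""]
}

#' Parse an atom-selection expression
#'
#' @param text selection string, e.g. `"segid S and resid 1 and name N*"` or
#'   `"name CA and resid 10:225 and not resid 129:136"`.
#' @return a `selection` object (parse tree) reusable across structures.
#' @export
parse_selection <- function(text) {
  if (inherits(text, "selection")) return(text)
  toks <- sel_tokenize(text)
  if (length(toks) == 0) stop("empty selection expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- peek(); pos <<- pos + 1L; t }
  kw <- function(t) tolower(t)

  parse_expr <- function() {
    node <- parse_term()
    while (!is.na(peek()) && kw(peek()) == "or") {
      advance()
      node <- list(op = "or", a = node, b = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.na(peek()) && kw(peek()) == "and") {
      advance()
      node <- list(op = "and", a = node, b = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of selection expression")
    if (kw(t) == "not") {
      advance()
      return(list(op = "not", a = parse_factor()))
    }
    if (t == "(") {
      advance()
      node <- parse_expr()
      if (is.na(peek()) || peek() != ")") stop("missing ')' in selection")
      advance()
      return(node)
    }
    parse_primary()
  }
  parse_primary <- function() {
    t <- kw(advance())
    if (t == "all") return(list(op = "all"))
    if (t == "none") return(list(op = "none"))
    if (!t %in% c("segid", "chain", "resname", "resid", "name")) {
      stop("unknown field in selection expression: '", t, "'")
    }
    v <- advance()
    if (is.na(v)) stop("missing value after '", t, "'")
    if (t == "resid") {
      if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
        rng <- as.integer(strsplit(v, ":")[[1]])
        return(list(op = "resid", lo = min(rng), hi = max(rng)))
      }
      if (!grepl("^-?[0-9]+$", v)) stop("bad resid value: '", v, "'")
      return(list(op = "resid", lo = as.integer(v), hi = as.integer(v)))
    }
    list(op = t, value = v)
  }

  tree <- parse_expr()
  if (!is.na(peek())) stop("trailing tokens in selection: '", peek(), "'")
  structure(list(tree = tree, text = text), class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat("selection:", x$text, "\n")
  invisible(x)
}

sel_eval <- function(node, atoms) {
  switch(node$op,
    all = rep(TRUE, nrow(atoms)),
    none = rep(FALSE, nrow(atoms)),
    and = sel_eval(node$a, atoms) & sel_eval(node$b, atoms),
    or = sel_eval(node$a, atoms) | sel_eval(node$b, atoms),
    not = !sel_eval(node$a, atoms),
    segid = toupper(atoms$segid) == toupper(node$value),
    chain = toupper(atoms$chain) == toupper(node$value),
    resname = toupper(atoms$resname) == toupper(node$value),
    resid = atoms$resid >= node$lo & atoms$resid <= node$hi,
    name = {
      pat <- utils::glob2rx(toupper(node$value))
      grepl(pat, toupper(atoms$name))
    },
    stop("unknown selection node: ", node$op)
  )
}

#' Select atoms of a structure
#'
#' @param s a `pdb_structure`.
#' @param sel a selection string or a parsed `selection`.
#' @return ordered (ascending) integer indices of matching atoms.
#' @examples
#' \dontrun{
#' select_atoms(s, "segid S and resid 1 and name N*")
#' }
#' @export
select_atoms <- function(s, sel) {
  sel <- parse_selection(sel)
  which(sel_eval(sel$tree, s$atoms))
}
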