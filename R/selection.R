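## Atom-selection mini-language.
##
## Grammar:
##   expr     := or_expr
##   or_expr  := and_expr ('or' and_expr)*
##   and_expr := unary ('and' unary)*
##   unary    := 'not' unary | '(' expr ')' | term
##   term     := 'name' WORD | 'resname' WORD | 'resid' N[:M]
##             | 'segid' WORD | 'element' WORD | 'protein' | 'water'
##
## `protein` matches the 20 standard amino-acid residue names; `water`
## matches TIP3/HOH/WAT/SPC/TIP4.  Evaluation returns a sorted integer
## vector of 1-based atom indices; an empty result is not an error.

tokenize_selection <- function(text) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1L) stop("empty selection expression")
  tokens <- regmatches(text, gregexpr(pat, text))[[1]]
  positions <- as.integer(m)
  list(tokens = tokens, positions = positions)
}

#' Parse and evaluate an atom selection expression
#'
#' @param text selection expression string.
#' @param atoms an [atom_table()].
#' @return sorted integer vector of 1-based atom indices (possibly empty).
#' @export
parse_selection <- function(text, atoms) {
  tk <- tokenize_selection(text)
  toks <- tk$tokens
  pos <- tk$positions
  i <- 1L
  n_tok <- length(toks)

  peek <- function() if (i <= n_tok) toks[i] else NA_character_
  advance <- function() {
    t <- toks[i]
    i <<- i + 1L
    t
  }
  perr <- function(msg) {
    at <- if (i <= n_tok) pos[i] else nchar(text) + 1L
    stop("selection parse error at position ", at, ": ", msg)
  }

  n_atoms <- nrow(atoms)

  term <- function() {
    t <- peek()
    if (is.na(t)) perr("unexpected end of expression")
    if (t == "(") {
      advance()
      v <- or_expr()
      if (is.na(peek()) || peek() != ")") perr("expected ')'")
      advance()
      return(v)
    }
    advance()
    switch(tolower(t),
      "protein" = atoms$resname %in% .standard_amino_acids,
      "water"   = atoms$resname %in% .water_resnames,
      "name"    = ,
      "resname" = ,
      "segid"   = ,
      "element" = {
        val <- peek()
        if (is.na(val) || val %in% c("and", "or", "not", "(", ")")) {
          perr(paste0("keyword '", t, "' needs a value"))
        }
        advance()
        field <- switch(tolower(t), name = atoms$name, resname = atoms$resname,
                        segid = atoms$segid, element = toupper(atoms$element))
        field == if (tolower(t) == "element") toupper(val) else val
      },
      "resid" = {
        val <- peek()
        if (is.na(val) || !grepl("^-?[0-9]+(:-?[0-9]+)?$", val)) {
          perr("'resid' needs N or N:M")
        }
        advance()
        rng <- as.integer(strsplit(val, ":", fixed = TRUE)[[1]])
        if (length(rng) == 1L) atoms$resid == rng
        else atoms$resid >= rng[1] & atoms$resid <= rng[2]
      },
      perr(paste0("unknown keyword '", t, "'"))
    )
  }

  unary <- function() {
    if (!is.na(peek()) && tolower(peek()) == "not") {
      advance()
      return(!unary())
    }
    term()
  }

  and_expr <- function() {
    v <- unary()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      v <- v & unary()
    }
    v
  }

  or_expr <- function() {
    v <- and_expr()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      v <- v | and_expr()
    }
    v
  }

  mask <- or_expr()
  if (i <= n_tok) perr(paste0("unexpected token '", peek(), "'"))
  which(mask)
}
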