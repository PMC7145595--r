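#' Select atoms with a small expression language
#'
#' The mini-language supports `resid` ranges (inclusive, e.g.
#' `resid 205-209`), `name`, `resname` and `chain` keywords with one or more
#' values, the keywords `all` and `backbone` (N, CA, C, O), and the boolean
#' operators `and`, `or`, `not` with parentheses. `and` binds tighter than
#' `or`; `not` binds tightest.
#'
#' @param topology A [topology()].
#' @param expression Selection string, e.g. `"resid 205-209 and name CA"`.
#' @return A `selection`: the ordered atom-id vector (topology order) with the
#'   defining expression attached.
#' @export
#' @examples
#' top <- topology(data.frame(id = 1:4, name = c("CA","CB","CA","CA"),
#'                            element = "C", resid = c(1, 1, 2, 3)))
#' select_atoms(top, "resid 1-2 and name CA")
select_atoms <- function(topology, expression) {
  stopifnot(inherits(topology, "topology"))
  if (!is.character(expression) || length(expression) != 1 ||
      !nzchar(trimws(expression))) {
    stop_usage("`expression` must be a non-empty string.")
  }
  toks <- sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- sel_parse_or(st, topology)
  if (st$pos <= length(st$toks)) {
    sel_error(st, "unexpected trailing input")
  }
  ids <- topology$atoms$id[mask]
  if (length(ids) == 0) {
    stop_selection(sprintf("selection '%s' matches no atoms.", expression))
  }
  structure(list(ids = ids, expression = expression), class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("<selection> %d atoms: \"%s\"\n", length(x$ids), x$expression))
  invisible(x)
}

# Map a selection (or raw ids / expression string) to atom row indices.
selection_rows <- function(topology, sel) {
  if (inherits(sel, "selection")) {
    ids <- sel$ids
  } else if (is.character(sel)) {
    ids <- select_atoms(topology, sel)$ids
  } else if (is.numeric(sel)) {
    ids <- as.integer(sel)
  } else {
    stop_usage("selections must be a selection object, expression string, or id vector.")
  }
  rows <- match(ids, topology$atoms$id)
  if (anyNA(rows)) {
    stop_selection(sprintf("unknown atom id(s): %s",
                           paste(head(ids[is.na(rows)], 5), collapse = ", ")))
  }
  rows
}

sel_tokenize <- function(expression) {
  pat <- "\\(|\\)|[A-Za-z][A-Za-z0-9'*_]*|[0-9]+-[0-9]+|[0-9]+"
  m <- gregexpr(pat, expression)[[1]]
  if (m[1] == -1) stop_parameter(sprintf("cannot tokenize '%s'.", expression))
  toks <- regmatches(expression, gregexpr(pat, expression))[[1]]
  covered <- sum(attr(m, "match.length"))
  rest <- gsub("\\s", "", gsub(pat, "", expression))
  if (nzchar(rest)) {
    stop_parameter(sprintf("selection parse error near '%s' in '%s'.",
                           substr(rest, 1, 8), expression))
  }
  tibble(text = toks, at = as.integer(m))
}

sel_error <- function(st, msg) {
  pos <- if (st$pos <= nrow(st$toks)) st$toks$at[st$pos] else NA_integer_
  stop_parameter(sprintf("selection parse error at position %s: %s.",
                         ifelse(is.na(pos), "end", pos), msg))
}

sel_peek <- function(st) {
  if (st$pos > nrow(st$toks)) NA_character_ else st$toks$text[st$pos]
}

sel_take <- function(st) {
  t <- sel_peek(st)
  st$pos <- st$pos + 1L
  t
}

sel_parse_or <- function(st, top) {
  mask <- sel_parse_and(st, top)
  while (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "or") {
    sel_take(st)
    mask <- mask | sel_parse_and(st, top)
  }
  mask
}

sel_parse_and <- function(st, top) {
  mask <- sel_parse_unary(st, top)
  while (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "and") {
    sel_take(st)
    mask <- mask & sel_parse_unary(st, top)
  }
  mask
}

sel_parse_unary <- function(st, top) {
  t <- sel_peek(st)
  if (is.na(t)) sel_error(st, "unexpected end of expression")
  if (tolower(t) == "not") {
    sel_take(st)
    return(!sel_parse_unary(st, top))
  }
  sel_parse_primary(st, top)
}

sel_is_value <- function(t) {
  !is.na(t) && !(tolower(t) %in% c("and", "or", "not", "resid", "name",
                                   "resname", "chain", "all", "backbone")) &&
    t != "(" && t != ")"
}

sel_parse_primary <- function(st, top) {
  at <- top$atoms
  t <- sel_take(st)
  if (is.na(t)) sel_error(st, "unexpected end of expression")
  lt <- tolower(t)
  if (t == "(") {
    mask <- sel_parse_or(st, top)
    if (is.na(sel_peek(st)) || sel_take(st) != ")") sel_error(st, "expected ')'")
    return(mask)
  }
  if (lt == "all") return(rep(TRUE, nrow(at)))
  if (lt == "backbone") return(at$name %in% c("N", "CA", "C", "O"))
  if (lt == "resid") {
    vals <- character(0)
    while (sel_is_value(sel_peek(st)) &&
           grepl("^[0-9]+(-[0-9]+)?$", sel_peek(st))) {
      vals <- c(vals, sel_take(st))
    }
    if (length(vals) == 0) sel_error(st, "'resid' needs numbers or ranges")
    resids <- unlist(lapply(vals, function(v) {
      if (grepl("-", v)) {
        ab <- as.integer(strsplit(v, "-")[[1]])
        seq(ab[1], ab[2])
      } else as.integer(v)
    }))
    return(at$resid %in% resids)
  }
  if (lt %in% c("name", "resname", "chain")) {
    vals <- character(0)
    while (sel_is_value(sel_peek(st))) vals <- c(vals, sel_take(st))
    if (length(vals) == 0) sel_error(st, sprintf("'%s' needs at least one value", lt))
    col <- switch(lt, name = at$name, resname = at$resname, chain = at$chain)
    return(col %in% vals)
  }
  sel_error(st, sprintf("unknown keyword '%s'", t))
}
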