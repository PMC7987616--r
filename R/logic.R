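#' Parse an exposure-combination expression
#'
#' Expressions combine declared inclusion entity names with `and`/`or`
#' (case-insensitive) and parentheses; `and` binds tighter than `or`.
#' Negation is not part of the grammar — disqualification is expressed
#' through exclusion code entities instead.  Parsing is by recursive
#' descent:
#'
#' ```
#' expr   := term ("or" term)*
#' term   := factor ("and" factor)*
#' factor := NAME | "(" expr ")"
#' ```
#'
#' @param text the expression, e.g. `"Type2Diabetes and Metformin"`.
#' @param declared_entities character vector of known inclusion entity
#'   names; any other NAME is an error.
#' @return a `logic_ast`: nested nodes of shape `list(op = "ref", name =)`
#'   or `list(op = "and"/"or", left =, right =)`.
#' @seealso [format_logic()], [evaluate_loose()], [evaluate_strict()]
#' @export
parse_logic <- function(text, declared_entities) {
  if (inherits(text, "logic_ast")) return(text)
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text))) {
    abort("expression must be a non-empty string")
  }
  toks <- tokenize_logic(text)
  pos <- 1L
  peek <- function() if (pos <= nrow(toks)) toks$type[pos] else "eof"
  take <- function() {
    t <- toks[pos, ]
    pos <<- pos + 1L
    t
  }
  fail <- function(msg, at = if (pos <= nrow(toks)) toks$at[pos] else nchar(text) + 1L) {
    abort(paste0("parse error at position ", at, ": ", msg))
  }

  parse_factor <- function() {
    tt <- peek()
    if (tt == "name") {
      t <- take()
      if (!t$text %in% declared_entities) {
        abort(paste0("undeclared entity '", t$text, "' at position ", t$at))
      }
      list(op = "ref", name = t$text)
    } else if (tt == "lparen") {
      take()
      e <- parse_expr()
      if (peek() != "rparen") fail("expected ')'")
      take()
      e
    } else {
      fail(if (tt == "eof") "unexpected end of input" else "expected entity name or '('")
    }
  }
  parse_term <- function() {
    node <- parse_factor()
    while (peek() == "and") {
      take()
      node <- list(op = "and", left = node, right = parse_factor())
    }
    node
  }
  parse_expr <- function() {
    node <- parse_term()
    while (peek() == "or") {
      take()
      node <- list(op = "or", left = node, right = parse_term())
    }
    node
  }

  ast <- parse_expr()
  if (peek() != "eof") fail("unexpected trailing input")
  class(ast) <- "logic_ast"
  ast
}

tokenize_logic <- function(text) {
  pat <- "\\(|\\)|[A-Za-z_][A-Za-z0-9_]*"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) abort("parse error at position 1: no tokens found")
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  # anything between tokens other than whitespace is illegal
  covered <- rep(FALSE, nchar(text))
  for (i in seq_along(starts)) covered[seq(starts[i], length.out = lens[i])] <- TRUE
  chars <- strsplit(text, "")[[1]]
  stray <- which(!covered & !grepl("^\\s$", chars))
  if (length(stray)) {
    abort(paste0("parse error at position ", stray[1], ": unexpected character '",
      chars[stray[1]], "'"))
  }
  txt <- substring(text, starts, starts + lens - 1L)
  type <- dplyr::case_when(
    txt == "(" ~ "lparen",
    txt == ")" ~ "rparen",
    tolower(txt) == "and" ~ "and",
    tolower(txt) == "or" ~ "or",
    TRUE ~ "name"
  )
  tibble(type = type, text = txt, at = starts)
}

#' Render a parsed expression back to canonical text
#'
#' Produces the canonical form (lowercase keywords, parentheses only where
#' precedence requires them); `parse_logic(format_logic(ast))` returns an
#' identical tree.
#'
#' @param ast a `logic_ast` from [parse_logic()].
#' @return a single string.
#' @export
format_logic <- function(ast) {
  fmt <- function(node, parent, side) {
    if (node$op == "ref") return(node$name)
    s <- paste(fmt(node$left, node$op, "left"), node$op,
      fmt(node$right, node$op, "right"))
    need <- (node$op == "or" && parent == "and") ||
      # right-nested same-op chains keep their parentheses so the printed
      # form reparses to the identical tree (the parser is left-associative)
      (node$op == parent && side == "right")
    if (need) paste0("(", s, ")") else s
  }
  fmt(ast, "top", "left")
}

#' @export
print.logic_ast <- function(x, ...) {
  cat("<logic_ast> ", format_logic(x), "\n", sep = "")
  invisible(x)
}

logic_entities <- function(ast) {
  if (ast$op == "ref") return(ast$name)
  unique(c(logic_entities(structure(ast$left, class = "logic_ast")),
    logic_entities(structure(ast$right, class = "logic_ast"))))
}

as_date_matrix <- function(entity_dates) {
  # accepts a named list of Date vectors (one per entity, aligned over
  # patients) or a named list/vector of scalar dates; returns list of vectors
  stopifnot(!is.null(names(entity_dates)))
  lens <- vapply(entity_dates, length, 1L)
  n <- max(lens, 1L)
  stopifnot(all(lens %in% c(n)))
  lapply(entity_dates, function(d) as.Date(d, origin = "1970-01-01"))
}

#' Evaluate combination logic in loose mode
#'
#' Loose evaluation ignores the order in which entities occurred.  A
#' conjunction is satisfied when both operands are, and contributes the
#' later of their dates ("latest event date among the code entities"); a
#' disjunction is satisfied when either operand is, and contributes the
#' earliest date on which the whole criterion became true.  The result is
#' the candidate index date, or `NA` if the expression is unsatisfied.
#'
#' Vectorised: each entity maps to a `Date` vector aligned over patients
#' (`NA` = entity not found for that patient).
#'
#' @param ast a `logic_ast`; every referenced entity must be a name in
#'   `entity_dates`.
#' @param entity_dates named list of `Date` vectors (or scalars).
#' @return a `Date` vector of index dates (`NA` where unsatisfied).
#' @export
evaluate_loose <- function(ast, entity_dates) {
  ed <- as_date_matrix(entity_dates)
  check_logic_names(ast, names(ed))
  ev <- function(node) {
    if (node$op == "ref") return(ed[[node$name]])
    l <- ev(node$left)
    r <- ev(node$right)
    if (node$op == "and") {
      out <- pmax_date(l, r)
      out[is.na(l) | is.na(r)] <- NA
      out
    } else {
      pmin_date(l, r)
    }
  }
  ev(ast)
}

check_logic_names <- function(ast, known) {
  missing <- setdiff(logic_entities(ast), known)
  if (length(missing)) {
    abort(paste0("no dates supplied for entity(ies): ", paste(missing, collapse = ", ")))
  }
}

#' Evaluate combination logic in strict (order-sensitive) mode
#'
#' Strict evaluation accepts a patient only when the entities occurred in
#' the same left-to-right order as written: within every conjunction the
#' left operand's date must be on or before the right operand's (same-day
#' events count as in order).  Disjunction branches are alternatives; the
#' order constraint never crosses an `or`.  A patient whose entities
#' satisfy the expression in some order-respecting way gets the earliest
#' achievable qualifying date (the latest date of the qualifying
#' conjunction); a patient who satisfies the expression only out of order
#' is flagged `reject_order` (discarded, with the reason documented); a
#' patient missing a needed entity is `unsatisfied`.
#'
#' @inheritParams evaluate_loose
#' @return a tibble with columns `status` ("date", "reject_order",
#'   "unsatisfied") and `index_date` (`NA` unless status is "date").
#' @export
evaluate_strict <- function(ast, entity_dates) {
  ed <- as_date_matrix(entity_dates)
  check_logic_names(ast, names(ed))
  n <- length(ed[[1]])
  na_date <- as.Date(rep(NA_real_, n), origin = "1970-01-01")

  # Each node yields: a list of order-respecting "interpretations", each a
  # pair of aligned Date vectors (date of the first and last entity used,
  # NA where that interpretation is unavailable), plus the vector of
  # patients for whom the node is boolean-satisfied by mere presence.
  ev <- function(node) {
    if (node$op == "ref") {
      d <- ed[[node$name]]
      return(list(interps = list(list(first = d, last = d)), present = !is.na(d)))
    }
    l <- ev(node$left)
    r <- ev(node$right)
    if (node$op == "or") {
      list(interps = c(l$interps, r$interps), present = l$present | r$present)
    } else {
      combos <- list()
      for (li in l$interps) {
        for (ri in r$interps) {
          ok <- !is.na(li$last) & !is.na(ri$first) & li$last <= ri$first
          f <- li$first
          f[!ok] <- NA
          la <- ri$last
          la[!ok] <- NA
          combos[[length(combos) + 1L]] <- list(first = f, last = la)
        }
      }
      list(interps = combos, present = l$present & r$present)
    }
  }
  res <- ev(ast)
  # qualifying index date: earliest over interpretations of the last date
  idx <- na_date
  for (it in res$interps) idx <- pmin_date(idx, it$last)
  status <- dplyr::case_when(
    !is.na(idx) ~ "date",
    res$present ~ "reject_order",
    TRUE ~ "unsatisfied"
  )
  idx[status != "date"] <- NA
  tibble(status = status, index_date = idx)
}
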