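# Brute-force oracles, kept deliberately independent of the package's
# evaluators: they enumerate subsets of entities and check boolean
# satisfaction directly.

bool_eval <- function(ast, present) {
  switch(ast$op,
    ref = isTRUE(present[[ast$name]]),
    and = bool_eval(ast$left, present) && bool_eval(ast$right, present),
    or = bool_eval(ast$left, present) || bool_eval(ast$right, present)
  )
}

leaves_in_order <- function(ast) {
  if (ast$op == "ref") return(ast$name)
  c(leaves_in_order(ast$left), leaves_in_order(ast$right))
}

all_subsets <- function(xs) {
  n <- length(xs)
  lapply(seq_len(2^n) - 1L, function(m) xs[bitwAnd(m, 2^(seq_len(n) - 1L)) > 0])
}

# loose oracle: earliest date over satisfying subsets of the present
# entities, where a subset's date is the latest date it contains
oracle_loose <- function(ast, dates) {
  ents <- unique(leaves_in_order(ast))
  present <- ents[!is.na(unlist(dates[ents]))]
  best <- NA
  for (s in all_subsets(present)) {
    sat <- bool_eval(ast, setNames(as.list(ents %in% s), ents))
    if (sat) {
      cand <- if (length(s)) max(vapply(dates[s], as.numeric, 0)) else -Inf
      if (is.na(best) || cand < best) best <- cand
    }
  }
  if (is.na(best)) as.Date(NA_real_, origin = "1970-01-01")
  else as.Date(best, origin = "1970-01-01")
}

# strict oracle: a minimal satisfying subset, taken in the textual order of
# the expression's leaves, qualifies iff all its entities are present with
# non-decreasing dates; result is the earliest qualifying clause date
oracle_strict <- function(ast, dates) {
  ord <- leaves_in_order(ast)
  ents <- unique(ord)
  subsets <- Filter(
    function(s) bool_eval(ast, setNames(as.list(ents %in% s), ents)),
    all_subsets(ents))
  minimal <- Filter(function(s) {
    !any(vapply(subsets, function(t) length(t) < length(s) && all(t %in% s), TRUE))
  }, subsets)
  best <- NA
  any_present <- FALSE
  for (s in minimal) {
    seqd <- unlist(dates[ord[ord %in% s]])
    if (any(is.na(seqd))) next
    any_present <- TRUE
    if (all(diff(as.numeric(seqd)) >= 0) || length(seqd) == 1) {
      cand <- max(as.numeric(seqd))
      if (is.na(best) || cand < best) best <- cand
    }
  }
  if (!is.na(best)) {
    list(status = "date", date = as.Date(best, origin = "1970-01-01"))
  } else if (any_present) {
    list(status = "reject_order", date = as.Date(NA_real_, origin = "1970-01-01"))
  } else {
    list(status = "unsatisfied", date = as.Date(NA_real_, origin = "1970-01-01"))
  }
}

# random expression trees with distinct leaves
random_ast <- function(entities, depth) {
  build <- function(pool, d) {
    if (d == 0 || length(pool) == 1) {
      return(list(node = list(op = "ref", name = pool[1]), used = pool[1]))
    }
    k <- sample(seq_len(length(pool) - 1), 1)
    l <- build(pool[seq_len(k)], d - 1)
    r <- build(pool[-seq_len(k)], d - 1)
    list(node = list(op = sample(c("and", "or"), 1), left = l$node, right = r$node),
      used = c(l$used, r$used))
  }
  n <- sample(seq_along(entities), 1)
  out <- build(sample(entities, n), depth)$node
  class(out) <- "logic_ast"
  out
}
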