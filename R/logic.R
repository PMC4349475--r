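# Boolean logic expression trees.
#
# An expression is a nested list with a `type` field:
#   list(type = "var",   name = <locus id>)
#   list(type = "const", value = TRUE/FALSE)
#   list(type = "not",   a = <expr>)
#   list(type = "and",   a = <expr>, b = <expr>)
#   list(type = "or",    a = <expr>, b = <expr>)
# Gates are binary; n-ary conjunctions are right-nested trees.

logic_var <- function(name) list(type = "var", name = name)
logic_const <- function(value) list(type = "const", value = isTRUE(value))
logic_not <- function(a) list(type = "not", a = a)
logic_and <- function(a, b) list(type = "and", a = a, b = b)
logic_or <- function(a, b) list(type = "or", a = a, b = b)

#' Variables referenced by a logic expression
#'
#' @param expr a logic expression tree.
#' @return character vector of distinct locus ids, sorted.
#' @export
logic_vars <- function(expr) {
  out <- character(0)
  walk <- function(e) {
    switch(e$type,
      var = out[[length(out) + 1L]] <<- e$name,
      const = NULL,
      not = walk(e$a),
      { walk(e$a); walk(e$b) }
    )
    invisible(NULL)
  }
  walk(expr)
  sort(unique(out))
}

#' Evaluate a logic expression against a named state
#'
#' @param expr logic expression tree.
#' @param state named logical vector; must cover every variable in `expr`.
#' @return logical scalar.
#' @export
eval_logic <- function(expr, state) {
  switch(expr$type,
    var = {
      i <- match(expr$name, names(state))
      if (is.na(i) || is.na(state[[i]])) {
        stop("state does not cover variable '", expr$name, "'")
      }
      state[[i]]
    },
    const = expr$value,
    not = !eval_logic(expr$a, state),
    and = eval_logic(expr$a, state) && eval_logic(expr$b, state),
    or = eval_logic(expr$a, state) || eval_logic(expr$b, state),
    stop("unknown logic node type: ", expr$type)
  )
}

#' Canonical string form of a logic expression
#'
#' Parenthesized infix with `AND`, `OR`, `NOT`; operands of commutative gates
#' are sorted by their own canonical string, so structurally equal expressions
#' (up to operand order) serialize identically. This string is the allele
#' equality key and the on-disk logic format.
#'
#' @param expr logic expression tree.
#' @return character scalar.
#' @export
logic_to_string <- function(expr) {
  switch(expr$type,
    var = expr$name,
    const = if (expr$value) "TRUE" else "FALSE",
    not = paste0("(NOT ", logic_to_string(expr$a), ")"),
    {
      a <- logic_to_string(expr$a)
      b <- logic_to_string(expr$b)
      if (b < a) { tmp <- a; a <- b; b <- tmp }
      paste0("(", a, " ", toupper(expr$type), " ", b, ")")
    }
  )
}

#' Parse the canonical logic grammar
#'
#' Inverse of [logic_to_string()]. Accepts `TRUE`/`FALSE`, variable names
#' (anything not containing whitespace or parentheses), `(NOT x)`,
#' `(x AND y)`, `(x OR y)`.
#'
#' @param s character scalar.
#' @return logic expression tree.
#' @export
logic_from_string <- function(s) {
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()[:space:]]+", s))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_expr <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of logic string: ", s)
    if (t == "(") {
      if (identical(peek(), "NOT")) {
        take()
        a <- parse_expr()
        if (!identical(take(), ")")) stop("expected ')' in: ", s)
        return(logic_not(a))
      }
      a <- parse_expr()
      op <- take()
      if (!op %in% c("AND", "OR")) stop("expected AND/OR, got '", op, "' in: ", s)
      b <- parse_expr()
      if (!identical(take(), ")")) stop("expected ')' in: ", s)
      return(if (op == "AND") logic_and(a, b) else logic_or(a, b))
    }
    if (t == ")") stop("unexpected ')' in: ", s)
    if (t == "TRUE") return(logic_const(TRUE))
    if (t == "FALSE") return(logic_const(FALSE))
    logic_var(t)
  }
  out <- parse_expr()
  if (pos <= length(toks)) stop("trailing tokens in logic string: ", s)
  out
}

#' Generate a random logic expression over a fixed variable set
#'
#' Builds a random binary AND/OR tree whose variable set is exactly `vars`:
#' the set is split recursively into two non-empty groups joined by a gate
#' drawn from `gate_probs`; each variable leaf is negated independently with
#' probability `p_negate`. With zero variables a random constant is returned.
#'
#' @param vars character vector of input locus ids (possibly empty).
#' @param gate_probs named numeric, probabilities for the `and` and `or` gate
#'   templates (normalized internally).
#' @param p_negate probability that a variable leaf is wrapped in NOT.
#' @return logic expression tree with `logic_vars()` equal to `sort(unique(vars))`.
#' @export
random_logic <- function(vars, gate_probs = c(and = 0.5, or = 0.5), p_negate = 0.25) {
  vars <- unique(vars)
  if (length(vars) == 0L) return(logic_const(stats::runif(1) < 0.5))
  if (length(vars) == 1L) {
    leaf <- logic_var(vars)
    if (stats::runif(1) < p_negate) leaf <- logic_not(leaf)
    return(leaf)
  }
  k <- sample(seq_len(length(vars) - 1L), 1L)
  idx <- sample(length(vars), k)
  a <- random_logic(vars[idx], gate_probs, p_negate)
  b <- random_logic(vars[-idx], gate_probs, p_negate)
  gate <- sample(c("and", "or"), 1L, prob = gate_probs[c("and", "or")])
  if (gate == "and") logic_and(a, b) else logic_or(a, b)
}

# Structurally remove every occurrence of variable `v`. Gates with one dead
# child collapse onto the surviving child; returns NULL when nothing survives.
logic_remove_var <- function(expr, v) {
  switch(expr$type,
    var = if (expr$name == v) NULL else expr,
    const = expr,
    not = {
      a <- logic_remove_var(expr$a, v)
      if (is.null(a)) NULL else logic_not(a)
    },
    {
      a <- logic_remove_var(expr$a, v)
      b <- logic_remove_var(expr$b, v)
      if (is.null(a)) b else if (is.null(b)) a
      else if (expr$type == "and") logic_and(a, b) else logic_or(a, b)
    }
  )
}

# Substitute variables by expressions: subs is a named list of replacement
# trees; variables absent from subs are kept as-is.
logic_substitute <- function(expr, subs) {
  switch(expr$type,
    var = if (!is.null(subs[[expr$name]])) subs[[expr$name]] else expr,
    const = expr,
    not = logic_not(logic_substitute(expr$a, subs)),
    and = logic_and(logic_substitute(expr$a, subs), logic_substitute(expr$b, subs)),
    or = logic_or(logic_substitute(expr$a, subs), logic_substitute(expr$b, subs))
  )
}

# Total substitution: variables absent from subs become constant FALSE
# (references to loci lost from the genome evaluate as OFF).
logic_substitute_total <- function(expr, subs) {
  switch(expr$type,
    var = subs[[expr$name]] %||% FALSE_CONST,
    const = expr,
    not = logic_not(logic_substitute_total(expr$a, subs)),
    and = logic_and(logic_substitute_total(expr$a, subs),
                    logic_substitute_total(expr$b, subs)),
    or = logic_or(logic_substitute_total(expr$a, subs),
                  logic_substitute_total(expr$b, subs))
  )
}

FALSE_CONST <- list(type = "const", value = FALSE)

# Allele-level postfix bytecode over the allele's own input list:
# op 1 LOAD (arg = 1-based index into `inputs`), 2 CONST (arg = 0/1),
# 3 NOT, 4 AND, 5 OR. Cached on the allele; the genome assembler rewrites
# LOADs to phenotype-node indices (expanding heterozygous references).
compile_logic <- function(expr, inputs) {
  op <- integer(0); arg <- integer(0)
  emit <- function(e) {
    switch(e$type,
      var = { op[[length(op) + 1L]] <<- 1L
              arg[[length(arg) + 1L]] <<- match(e$name, inputs) },
      const = { op[[length(op) + 1L]] <<- 2L
                arg[[length(arg) + 1L]] <<- as.integer(e$value) },
      not = { emit(e$a); op[[length(op) + 1L]] <<- 3L
              arg[[length(arg) + 1L]] <<- 0L },
      and = { emit(e$a); emit(e$b); op[[length(op) + 1L]] <<- 4L
              arg[[length(arg) + 1L]] <<- 0L },
      or = { emit(e$a); emit(e$b); op[[length(op) + 1L]] <<- 5L
             arg[[length(arg) + 1L]] <<- 0L }
    )
    invisible(NULL)
  }
  emit(expr)
  list(op = op, arg = arg)
}

# Number of subtrees (internal + leaf nodes).
logic_size <- function(expr) {
  switch(expr$type,
    var = 1L,
    const = 1L,
    not = 1L + logic_size(expr$a),
    1L + logic_size(expr$a) + logic_size(expr$b)
  )
}

# Return the k-th subtree in preorder (1 = whole expression).
logic_subtree <- function(expr, k) {
  res <- NULL
  cnt <- 0L
  walk <- function(e) {
    if (!is.null(res)) return(invisible(NULL))
    cnt <<- cnt + 1L
    if (cnt == k) { res <<- e; return(invisible(NULL)) }
    switch(e$type, var = NULL, const = NULL, not = walk(e$a), { walk(e$a); walk(e$b) })
    invisible(NULL)
  }
  walk(expr)
  res
}

# Replace the k-th subtree in preorder with `repl`.
logic_replace_subtree <- function(expr, k, repl) {
  cnt <- 0L
  walk <- function(e) {
    cnt <<- cnt + 1L
    if (cnt == k) return(repl)
    switch(e$type,
      var = e,
      const = e,
      not = { e$a <- walk(e$a); e },
      { e$a <- walk(e$a); if (cnt < k) e$b <- walk(e$b); e }
    )
  }
  walk(expr)
}

# Count var leaves in preorder.
logic_count_vars <- function(expr) {
  switch(expr$type,
    var = 1L,
    const = 0L,
    not = logic_count_vars(expr$a),
    logic_count_vars(expr$a) + logic_count_vars(expr$b)
  )
}

# Toggle negation on the k-th var leaf (preorder): a var directly under a NOT
# loses the NOT; a bare var gains one.
logic_toggle_not <- function(expr, k) {
  cnt <- 0L
  walk <- function(e) {
    switch(e$type,
      var = {
        cnt <<- cnt + 1L
        if (cnt == k) logic_not(e) else e
      },
      const = e,
      not = {
        if (e$a$type == "var") {
          cnt <<- cnt + 1L
          if (cnt == k) return(e$a)
          return(e)
        }
        e$a <- walk(e$a)
        e
      },
      { e$a <- walk(e$a); e$b <- walk(e$b); e }
    )
  }
  walk(expr)
}
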