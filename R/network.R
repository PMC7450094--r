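# Boolean network representation and the BoolNet-style .bnet text format.
#
# A BooleanNetwork stores the declared component order and, per component,
# a Boolean expression over component names built from NOT (!), AND (&),
# OR (|), parentheses and the constants 0/1. Expressions are held as R
# language objects restricted to that grammar; a per-component compiled form
# (input indices, truth table, influence signs) is cached lazily in an
# environment carried by the object.

new_boolean_network <- function(components, functions) {
  stopifnot(length(components) >= 1L, length(components) == length(functions))
  bn <- list(components = components,
             functions = functions,
             cache = new.env(parent = emptyenv()))
  class(bn) <- "BooleanNetwork"
  bn
}

#' Number of components of a Boolean network
#'
#' @param bn A `BooleanNetwork`.
#' @return The number of components, an integer.
#' @export
bn_size <- function(bn) length(bn$components)

stop_parse <- function(msg, line = NA) {
  if (!is.na(line)) msg <- sprintf("line %d: %s", line, msg)
  stop("bnet parse error: ", msg, call. = FALSE)
}

valid_name <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_.]*$", x)

# Restrict an R expression to the .bnet grammar: symbols, constants 0/1,
# !, &, | (and their doubled forms, normalized). `(` nodes are dropped so
# that serialize/parse round-trips compare equal.
normalize_expr <- function(e, line = NA) {
  if (is.symbol(e)) return(e)
  if (is.logical(e) && length(e) == 1L && !is.na(e)) return(e)
  if (is.numeric(e) && length(e) == 1L) {
    if (e == 0) return(FALSE)
    if (e == 1) return(TRUE)
    stop_parse(sprintf("constant must be 0 or 1, got %s", format(e)), line)
  }
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "(") return(normalize_expr(e[[2L]], line))
    if (op == "!") return(call("!", normalize_expr(e[[2L]], line)))
    if (op %in% c("&", "&&"))
      return(call("&", normalize_expr(e[[2L]], line), normalize_expr(e[[3L]], line)))
    if (op %in% c("|", "||"))
      return(call("|", normalize_expr(e[[2L]], line), normalize_expr(e[[3L]], line)))
    stop_parse(sprintf("unsupported operator '%s'", op), line)
  }
  stop_parse("malformed expression", line)
}

expr_vars <- function(e) {
  if (is.symbol(e)) return(as.character(e))
  if (is.call(e)) return(unique(unlist(lapply(as.list(e)[-1L], expr_vars))))
  character(0)
}

#' Parse a Boolean network from BoolNet-style text
#'
#' The accepted dialect is the de-facto interchange format of logical
#' modeling tools: an optional `targets, factors` header, one declaration
#' per line of the form `name, expression`, expressions over the operators
#' `!`, `&`, `|`, parentheses and the constants `0`/`1`, comments starting
#' with `#`, and case-sensitive component names. Component order is the
#' declaration order; configuration strings are read left to right in that
#' order.
#'
#' @param text A character scalar holding the full file contents, or a
#'   character vector of lines.
#' @return A `BooleanNetwork` object.
#' @seealso [read_bnet()], [serialize_bnet()]
#' @examples
#' bn <- parse_bnet("targets, factors\nx1, !x2\nx2, !x1\nx3, x2 & !x1")
#' bn
#' @export
parse_bnet <- function(text) {
  if (!is.character(text) || length(text) == 0L)
    stop_parse("input must be non-empty text")
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  clean <- trimws(sub("#.*$", "", lines))
  keep <- which(nzchar(clean))
  if (length(keep) == 0L) stop_parse("no component declarations found")
  if (grepl("^targets[[:space:]]*,[[:space:]]*factors$", clean[keep[1L]],
            ignore.case = TRUE))
    keep <- keep[-1L]
  if (length(keep) == 0L) stop_parse("no component declarations found")

  comps <- character(0)
  exprs <- list()
  for (ln in keep) {
    line <- clean[ln]
    ci <- regexpr(",", line, fixed = TRUE)
    if (ci < 0L) stop_parse("expected 'name, expression'", ln)
    nm <- trimws(substr(line, 1L, ci - 1L))
    rhs <- trimws(substr(line, ci + 1L, nchar(line)))
    if (!valid_name(nm)) stop_parse(sprintf("invalid component name '%s'", nm), ln)
    if (nm %in% comps) stop_parse(sprintf("duplicate component '%s'", nm), ln)
    if (!nzchar(rhs)) stop_parse(sprintf("missing expression for '%s'", nm), ln)
    e <- tryCatch(str2lang(rhs), error = function(err)
      stop_parse(sprintf("malformed expression '%s'", rhs), ln))
    exprs[[length(exprs) + 1L]] <- normalize_expr(e, ln)
    comps <- c(comps, nm)
  }
  for (j in seq_along(exprs)) {
    undeclared <- setdiff(expr_vars(exprs[[j]]), comps)
    if (length(undeclared))
      stop_parse(sprintf("undeclared variable '%s' in function of '%s'",
                         undeclared[1L], comps[j]))
  }
  new_boolean_network(comps, exprs)
}

#' @rdname parse_bnet
#' @param path Path to a `.bnet` file.
#' @export
read_bnet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parse_bnet(readLines(path, warn = FALSE))
}

deparse_bnet_expr <- function(e, parent_prec = 0L, right = FALSE) {
  prec <- function(x) {
    if (!is.call(x)) return(4L)
    switch(as.character(x[[1L]]), `|` = 1L, `&` = 2L, `!` = 3L, 4L)
  }
  if (is.symbol(e)) return(as.character(e))
  if (is.logical(e)) return(if (e) "1" else "0")
  op <- as.character(e[[1L]])
  p <- prec(e)
  out <- if (op == "!") {
    paste0("!", deparse_bnet_expr(e[[2L]], p))
  } else {
    lhs <- deparse_bnet_expr(e[[2L]], p)
    rhs <- deparse_bnet_expr(e[[3L]], p, right = TRUE)
    paste(lhs, op, rhs)
  }
  # parenthesize when binding looser than the context, or when a same-
  # precedence operator appears as a right operand (left-associativity)
  if (p < parent_prec || (p == parent_prec && right && p < 3L))
    out <- paste0("(", out, ")")
  out
}

#' Serialize a Boolean network to BoolNet-style text
#'
#' @param bn A `BooleanNetwork`.
#' @return A character scalar; parsing it back yields an identical network.
#' @export
serialize_bnet <- function(bn) {
  lines <- c("targets, factors",
             vapply(seq_along(bn$components), function(i) {
               paste0(bn$components[i], ", ", deparse_bnet_expr(bn$functions[[i]]))
             }, character(1)))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @rdname serialize_bnet
#' @param path Path of the file to write.
#' @export
write_bnet <- function(bn, path) {
  writeLines(sub("\n$", "", serialize_bnet(bn)), path)
  invisible(path)
}

#' @export
print.BooleanNetwork <- function(x, ...) {
  cat(sprintf("Boolean network with %d components\n", bn_size(x)))
  for (i in seq_along(x$components))
    cat(sprintf("  %s <- %s\n", x$components[i],
                deparse_bnet_expr(x$functions[[i]])))
  invisible(x)
}

# ---- compiled per-component form ------------------------------------------

# Truth table of `e` over `vars` (in that order); input j toggles with bit
# 2^(j-1). Evaluation is a single vectorized eval over all 2^k assignments.
eval_truth_table <- function(e, vars) {
  k <- length(vars)
  N <- 2L^k
  env <- new.env(parent = baseenv())
  idx <- 0:(N - 1L)
  for (j in seq_len(k))
    assign(vars[j], bitwAnd(idx, 2L^(j - 1L)) > 0L, envir = env)
  val <- eval(e, env)
  if (length(val) == 1L) val <- rep(val, N)
  as.logical(val)
}

# semantic sign of each input from the truth table:
# 0 = no influence, 1 = activator, -1 = inhibitor, 2 = both signs
tt_signs <- function(tt, k) {
  if (k == 0L) return(integer(0))
  N <- 2L^k
  idx <- 0:(N - 1L)
  vapply(seq_len(k), function(j) {
    bit <- 2L^(j - 1L)
    lo <- which(bitwAnd(idx, bit) == 0L)
    hi <- tt[lo + bit]
    lo <- tt[lo]
    act <- any(hi & !lo)
    inh <- any(!hi & lo)
    if (act && inh) 2L else if (act) 1L else if (inh) -1L else 0L
  }, integer(1))
}

# syntactic polarity on negation normal form; sound but may report 2 (both)
# for variables that are semantically single-signed or non-influential
syntactic_signs <- function(e, vars) {
  pol <- matrix(FALSE, nrow = length(vars), ncol = 2L,
                dimnames = list(vars, c("pos", "neg")))
  walk <- function(x, positive) {
    if (is.symbol(x)) {
      nm <- as.character(x)
      pol[nm, if (positive) "pos" else "neg"] <<- TRUE
    } else if (is.call(x)) {
      op <- as.character(x[[1L]])
      if (op == "!") walk(x[[2L]], !positive)
      else { walk(x[[2L]], positive); walk(x[[3L]], positive) }
    }
  }
  walk(e, TRUE)
  ifelse(pol[, 1L] & pol[, 2L], 2L, ifelse(pol[, 1L], 1L, ifelse(pol[, 2L], -1L, 0L)))
}

# Exhaustive analysis is bounded by function arity; beyond TT_MAX_INPUTS the
# compiled form keeps only the expression and syntactic signs.
TT_MAX_INPUTS <- 16L

bn_compiled <- function(bn, i) {
  key <- paste0("c", i)
  cmp <- bn$cache[[key]]
  if (!is.null(cmp)) return(cmp)
  e <- bn$functions[[i]]
  vars <- sort(match(expr_vars(e), bn$components))
  k <- length(vars)
  if (k <= TT_MAX_INPUTS) {
    tt <- eval_truth_table(e, bn$components[vars])
    cmp <- list(vars = vars, k = k, tt = tt, signs = tt_signs(tt, k),
                exact = TRUE, expr = e)
  } else {
    cmp <- list(vars = vars, k = k, tt = NULL,
                signs = unname(syntactic_signs(e, bn$components[vars])),
                exact = FALSE, expr = e)
  }
  bn$cache[[key]] <- cmp
  cmp
}

tt_index <- function(z) {
  if (length(z) == 0L) return(1L)
  as.integer(sum(z * 2^(seq_along(z) - 1L)) + 1)
}

# f_i on a full Boolean input vector for component i's inputs (internal)
eval_compiled <- function(bn, cmp, z) {
  if (!is.null(cmp$tt)) return(as.integer(cmp$tt[tt_index(z)]))
  env <- new.env(parent = baseenv())
  for (j in seq_along(cmp$vars))
    assign(bn$components[cmp$vars[j]], as.logical(z[j]), envir = env)
  as.integer(eval(cmp$expr, env))
}

#' Evaluate one local function of a Boolean network
#'
#' Computes the value toward which component `i` evolves in configuration
#' `x`, i.e. \eqn{f_i(x)}.
#'
#' @param bn A `BooleanNetwork`.
#' @param i Component index (1-based, in declaration order).
#' @param x A configuration: binary string such as `"010"` or an integer
#'   vector over \{0,1\}.
#' @return 0 or 1 (integer).
#' @examples
#' bn <- parse_bnet("x1, !x2\nx2, !x1\nx3, x2 & !x1")
#' evaluate_component(bn, 3, "010")
#' @export
evaluate_component <- function(bn, i, x) {
  n <- bn_size(bn)
  if (i < 1L || i > n) stop("component index out of bounds", call. = FALSE)
  x <- as_config(x, n)
  cmp <- bn_compiled(bn, i)
  eval_compiled(bn, cmp, x[cmp$vars])
}

# f(x) as an integer vector (internal hot path)
update_all <- function(bn, x) {
  vapply(seq_len(bn_size(bn)), function(i) {
    cmp <- bn_compiled(bn, i)
    eval_compiled(bn, cmp, x[cmp$vars])
  }, integer(1))
}

# components whose functions read component i (cached)
bn_dependents <- function(bn) {
  dep <- bn$cache$dependents
  if (!is.null(dep)) return(dep)
  n <- bn_size(bn)
  dep <- vector("list", n)
  for (j in seq_len(n)) dep[[j]] <- integer(0)
  for (i in seq_len(n)) {
    for (v in bn_compiled(bn, i)$vars) dep[[v]] <- c(dep[[v]], i)
  }
  bn$cache$dependents <- dep
  dep
}

#' Signed influence graph of a Boolean network
#'
#' An edge `(source, target, "+")` is reported when there exists a
#' configuration in which switching the source from 0 to 1 increases the
#' target's function, and dually for `"-"`; a regulator acting with both
#' signs yields two rows. Signs are computed exhaustively from the truth
#' table for functions with at most 16 inputs; beyond that a
#' sound syntactic approximation on negation normal form is used and the
#' affected rows are flagged with `exact = FALSE`.
#'
#' @param bn A `BooleanNetwork`.
#' @return A data frame with columns `source`, `target`, `sign` (`"+"` or
#'   `"-"`) and `exact` (logical).
#' @examples
#' influence_signs(parse_bnet("x1, !x2\nx2, !x1\nx3, x2 & !x1"))
#' @export
influence_signs <- function(bn) {
  rows <- list()
  for (i in seq_len(bn_size(bn))) {
    cmp <- bn_compiled(bn, i)
    for (j in seq_along(cmp$vars)) {
      s <- cmp$signs[j]
      if (s == 0L) next
      src <- bn$components[cmp$vars[j]]
      tgt <- bn$components[i]
      if (s %in% c(1L, 2L))
        rows[[length(rows) + 1L]] <- data.frame(source = src, target = tgt,
                                                sign = "+", exact = cmp$exact)
      if (s %in% c(-1L, 2L))
        rows[[length(rows) + 1L]] <- data.frame(source = src, target = tgt,
                                                sign = "-", exact = cmp$exact)
    }
  }
  if (!length(rows))
    return(data.frame(source = character(0), target = character(0),
                      sign = character(0), exact = logical(0)))
  out <- do.call(rbind, rows)
  out[order(out$target, out$source, out$sign), , drop = FALSE]
}

#' Is every local function monotonic in each of its inputs?
#'
#' A network is locally monotonic when no regulator both activates and
#' inhibits the same target. This is the standard assumption for biological
#' networks under which most-permissive reads, and hence reachability, are
#' decided in polynomial time. The check first tries the linear-time
#' syntactic route (single polarity per variable in negation normal form,
#' which is sound); functions failing it are decided exactly from their
#' truth table when the arity permits.
#'
#' @param bn A `BooleanNetwork`.
#' @return `TRUE` or `FALSE`.
#' @export
is_locally_monotonic <- function(bn) {
  for (i in seq_len(bn_size(bn))) {
    e <- bn$functions[[i]]
    vars <- expr_vars(e)
    syn <- syntactic_signs(e, vars)
    if (!any(syn == 2L)) next
    cmp <- bn_compiled(bn, i)
    if (!cmp$exact) return(FALSE)  # cannot certify beyond table arity
    if (any(cmp$signs == 2L)) return(FALSE)
  }
  TRUE
}
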