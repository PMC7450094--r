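# Trap spaces. A trap space is a subcube closed under f: the image of every
# vertex stays inside the subcube. Minimal trap spaces (those containing no
# smaller trap space) are exactly the attractors of the Most Permissive
# semantics.
#
# Two complete enumeration routes are provided. The exhaustive route scans
# all 3^n subcube patterns and is the small-n oracle. The scalable route
# rests on a prime-implicant characterization: a pattern is a trap space
# iff each of its fixed literals (i, v) is supported by a prime implicant
# of f_i = v whose literals are all fixed by the pattern; minimal trap
# spaces are then the maximal consistent self-supported literal sets,
# enumerated by branch-and-prune over conflicting literals.

# does some vertex of the pattern map position i outside the pattern?
pattern_ctx <- function(pattern) {
  ctx <- pattern
  ctx[is.na(ctx)] <- MP_UP   # free positions read as dynamic
  ctx
}

can_escape <- function(bn, pattern, i) {
  can_read_int(bn, i, pattern_ctx(pattern), 1L - pattern[i])
}

#' Is a subcube a trap space?
#'
#' @param bn A `BooleanNetwork`.
#' @param pattern A subcube pattern (string over `0`, `1`, `*`, or integer
#'   vector with NA for free positions).
#' @return `TRUE` iff `f` maps every vertex of the subcube into it.
#' @examples
#' bn <- parse_bnet("x1, !x2\nx2, !x1\nx3, x2 & !x1")
#' is_trap_space(bn, "01*")
#' is_trap_space(bn, "1**")
#' @export
is_trap_space <- function(bn, pattern) {
  pattern <- as_subcube(pattern, bn_size(bn))
  for (i in which(!is.na(pattern))) {
    if (can_escape(bn, pattern, i)) return(FALSE)
  }
  TRUE
}

#' Smallest trap space containing a configuration
#'
#' Percolates the pattern starting from `x`: while some fixed position can
#' be mapped outside the current subcube by one of its vertices, that
#' position is freed. The least fixed point of this operator is the
#' smallest trap space containing `x`; a configuration belongs to a Most
#' Permissive attractor exactly when this trap space is minimal.
#'
#' @param bn A `BooleanNetwork`.
#' @param x A Boolean configuration.
#' @return A subcube pattern string over `0`, `1`, `*`.
#' @examples
#' bn <- parse_bnet("x1, !x2\nx2, !x1\nx3, x2 & !x1")
#' smallest_trap_space(bn, "011")
#' smallest_trap_space(bn, "000")
#' @export
smallest_trap_space <- function(bn, x) {
  n <- bn_size(bn)
  pattern <- as_config(x, n)
  dep <- bn_dependents(bn)
  queue <- seq_len(n)
  inq <- rep(TRUE, n)
  pos <- 1L
  while (pos <= length(queue)) {
    i <- queue[pos]; pos <- pos + 1L
    inq[i] <- FALSE
    if (is.na(pattern[i])) next
    if (can_escape(bn, pattern, i)) {
      pattern[i] <- NA_integer_
      for (j in dep[[i]]) {
        if (!is.na(pattern[j]) && !inq[j]) {
          queue <- c(queue, j)
          inq[j] <- TRUE
        }
      }
    }
  }
  format_subcube(pattern)
}

# ---- prime implicants ------------------------------------------------------

PI_MAX_INPUTS <- 14L

# All prime implicants of (f == v) by iterative term merging (Quine-
# McCluskey without the covering step). Terms are (mask, val) integer pairs
# over the k inputs of the truth table; bit j of mask marks a cared input.
qm_primes <- function(tt, k, v) {
  want <- which(tt == (v == 1L)) - 1L
  if (!length(want)) return(list())
  if (k == 0L) return(list(c(mask = 0L, val = 0L)))
  full <- 2L^k - 1L
  cur_mask <- rep(full, length(want))
  cur_val <- want
  primes_mask <- integer(0)
  primes_val <- integer(0)
  while (length(cur_val)) {
    keys <- paste(cur_mask, cur_val)
    have <- new.env(parent = emptyenv(), size = length(keys))
    for (s in keys) assign(s, TRUE, envir = have)
    merged <- rep(FALSE, length(cur_val))
    nxt_mask <- integer(0)
    nxt_val <- integer(0)
    for (t in seq_along(cur_val)) {
      mask <- cur_mask[t]; val <- cur_val[t]
      for (j in seq_len(k)) {
        bit <- 2L^(j - 1L)
        if (bitwAnd(mask, bit) == 0L) next
        partner <- bitwXor(val, bit)
        if (exists(paste(mask, partner), envir = have, inherits = FALSE)) {
          merged[t] <- TRUE
          if (bitwAnd(val, bit) == 0L) {   # emit each merged pair once
            nxt_mask <- c(nxt_mask, bitwAnd(mask, bitwNot(bit)))
            nxt_val <- c(nxt_val, val)
          }
        }
      }
    }
    primes_mask <- c(primes_mask, cur_mask[!merged])
    primes_val <- c(primes_val, cur_val[!merged])
    if (length(nxt_val)) {
      dup <- duplicated(paste(nxt_mask, nxt_val))
      cur_mask <- nxt_mask[!dup]
      cur_val <- nxt_val[!dup]
    } else {
      cur_mask <- integer(0)
      cur_val <- integer(0)
    }
  }
  dup <- duplicated(paste(primes_mask, primes_val))
  Map(function(m, w) c(mask = m, val = w), primes_mask[!dup], primes_val[!dup])
}

lit_id <- function(i, v, n) i + n * v

# Prime implicants of f_i = v as literal-id vectors, optionally after
# substituting fixed values for some components (used when searching inside
# a trap space). Implicants touching a permanently-free component are
# dropped by the caller via `allowed`.
component_implicants <- function(bn, i, v, fixed = NULL) {
  n <- bn_size(bn)
  cmp <- bn_compiled(bn, i)
  if (is.null(cmp$tt))
    stop("implicant-based trap space analysis requires function arities of ",
         "at most ", TT_MAX_INPUTS, " inputs ('", bn$components[i], "')",
         call. = FALSE)
  vars <- cmp$vars
  tt <- cmp$tt
  if (!is.null(fixed)) {
    sub <- which(!is.na(fixed[vars]))
    if (length(sub)) {
      keep_idx <- 0:(2L^cmp$k - 1L)
      for (j in sub)
        keep_idx <- keep_idx[bitwAnd(keep_idx %/% 2L^(j - 1L), 1L) == fixed[vars[j]]]
      free_j <- setdiff(seq_along(vars), sub)
      tt <- tt[keep_idx + 1L]
      vars <- vars[free_j]
      # re-index surviving assignments onto the reduced variable set: keep_idx
      # enumerates free bits in ascending order, so tt is already ordered
    }
  }
  k <- length(vars)
  if (k > PI_MAX_INPUTS)
    stop("function of '", bn$components[i], "' has ", k, " free inputs, above ",
         "the prime-implicant bound of ", PI_MAX_INPUTS, call. = FALSE)
  lapply(qm_primes(tt, k, v), function(term) {
    bits <- which(bitwAnd(term[["mask"]], 2L^(seq_len(k) - 1L)) > 0L)
    vals <- bitwAnd(term[["val"]] %/% 2L^(bits - 1L), 1L)
    lit_id(vars[bits], vals, n)
  })
}

# ---- maximal self-supported literal sets -----------------------------------

# A literal set S (over ids 1..2n) is stable when every literal has an
# implicant contained in S. gs() computes the greatest stable subset by
# worklist pruning; rev_index maps a literal to the (owner, implicant)
# pairs that mention it.
build_support <- function(bn, members, fixed = NULL) {
  n <- bn_size(bn)
  pis <- vector("list", 2L * n)
  for (i in members) {
    for (v in c(0L, 1L)) {
      imps <- component_implicants(bn, i, v, fixed)
      # implicants mentioning non-member components can never be supported
      ok <- vapply(imps, function(P) {
        comps <- ifelse(P > n, P - n, P)
        all(comps %in% members)
      }, logical(1))
      pis[[lit_id(i, v, n)]] <- imps[ok]
    }
  }
  pis
}

greatest_stable <- function(S, pis, rev_index) {
  supported <- function(l) {
    for (P in pis[[l]]) if (all(S[P])) return(TRUE)
    FALSE
  }
  queue <- which(S)
  pos <- 1L
  while (pos <= length(queue)) {
    l <- queue[pos]; pos <- pos + 1L
    if (!S[l]) next
    if (!supported(l)) {
      S[l] <- FALSE
      for (o in rev_index[[l]]) if (S[o]) queue <- c(queue, o)
    }
  }
  S
}

# Enumerate all maximal consistent stable literal sets by branching on a
# component carrying both literals. `first_only` turns the search into an
# existence check for a nonempty stable consistent set.
enumerate_stable_sets <- function(bn, members, fixed = NULL,
                                  node_limit = 100000L, first_only = FALSE) {
  n <- bn_size(bn)
  pis <- build_support(bn, members, fixed)
  rev_index <- vector("list", 2L * n)
  for (l in seq_len(2L * n)) {
    for (P in pis[[l]]) {
      for (m in P) rev_index[[m]] <- unique(c(rev_index[[m]], l))
    }
  }
  S0 <- logical(2L * n)
  S0[c(members, members + n)] <- TRUE
  S0 <- greatest_stable(S0, pis, rev_index)
  results <- list()
  seen <- new.env(parent = emptyenv())
  nodes <- 0L
  found_nonempty <- FALSE
  rec <- function(S) {
    if (first_only && found_nonempty) return(invisible(NULL))
    key <- paste0("k", paste(which(S), collapse = ","))
    if (exists(key, envir = seen, inherits = FALSE)) return(invisible(NULL))
    assign(key, TRUE, envir = seen)
    nodes <<- nodes + 1L
    if (nodes > node_limit)
      stop("trap space search exceeded the branching budget (",
           node_limit, " nodes); the network has too many candidate trap spaces",
           call. = FALSE)
    conflict <- which(S[seq_len(n)] & S[seq_len(n) + n])
    if (!length(conflict)) {
      if (any(S)) found_nonempty <<- TRUE
      results[[length(results) + 1L]] <<- S
      return(invisible(NULL))
    }
    c0 <- conflict[1L]
    for (drop in c(lit_id(c0, 0L, n), lit_id(c0, 1L, n))) {
      S2 <- S
      S2[drop] <- FALSE
      rec(greatest_stable(S2, pis, rev_index))
    }
  }
  rec(S0)
  if (first_only) return(found_nonempty)
  # keep only maximal sets (minimal subcubes): drop any result strictly
  # contained in another
  keep <- rep(TRUE, length(results))
  for (a in seq_along(results)) {
    if (!keep[a]) next
    for (b in seq_along(results)) {
      if (a == b) next
      if (all(!results[[a]] | results[[b]]) && any(results[[b]] & !results[[a]])) {
        keep[a] <- FALSE
        break
      }
    }
  }
  results[keep]
}

stable_set_to_pattern <- function(S, n, base = NULL) {
  pattern <- if (is.null(base)) rep(NA_integer_, n) else base
  pattern[which(S[seq_len(n)])] <- 0L
  pattern[which(S[seq_len(n) + n])] <- 1L
  pattern
}

# ---- SCC decomposition -----------------------------------------------------

# Strongly connected blocks of the dependency graph restricted to `members`,
# in topological order of the condensation (regulator blocks first).
# Minimal trap spaces factorize over this order: the restriction of a
# minimal trap space to the blocks processed so far is itself minimal, and
# given that restriction the next block can be solved independently, with
# upstream fixed values substituted and upstream free components acting as
# permanently-free inputs (implicants mentioning them are unsupportable).
scc_blocks <- function(bn, members) {
  if (!length(members)) return(list())
  idx <- match(members, members)
  from <- integer(0); to <- integer(0)
  for (i in members) {
    for (v in intersect(bn_compiled(bn, i)$vars, members)) {
      from <- c(from, match(v, members))
      to <- c(to, match(i, members))
    }
  }
  g <- igraph::make_empty_graph(n = length(members), directed = TRUE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g, mode = "strong")$membership
  cond <- igraph::contract(g, memb)
  cond <- igraph::simplify(cond)
  ord <- as.integer(igraph::topo_sort(cond, mode = "out"))
  lapply(ord, function(b) members[memb == b])
}

# Minimal trap spaces of the network restricted to `base` (fixed values
# substituted, other components candidates), by block-wise enumeration.
# Returns a list of full patterns extending `base`.
mts_decomposed <- function(bn, base, node_limit) {
  n <- bn_size(bn)
  members <- which(is.na(base))
  partial <- list(base)
  for (block in scc_blocks(bn, members)) {
    nxt <- list()
    for (pat in partial) {
      sets <- enumerate_stable_sets(bn, block, fixed = pat,
                                    node_limit = node_limit)
      for (S in sets)
        nxt[[length(nxt) + 1L]] <- stable_set_to_pattern(S, n, base = pat)
      if (length(nxt) > node_limit)
        stop("more than ", node_limit, " candidate trap spaces; raise ",
             "node_limit if this is intended", call. = FALSE)
    }
    partial <- nxt
  }
  partial
}

# ---- minimal trap spaces ---------------------------------------------------

enumerate_trap_spaces_exhaustive <- function(bn) {
  n <- bn_size(bn)
  out <- list()
  for (code in 0:(3L^n - 1L)) {
    digits <- (code %/% 3L^(0:(n - 1L))) %% 3L
    pattern <- ifelse(digits == 2L, NA_integer_, digits)
    if (is_trap_space(bn, pattern)) out[[length(out) + 1L]] <- pattern
  }
  out
}

minimal_patterns <- function(patterns) {
  keep <- rep(TRUE, length(patterns))
  for (a in seq_along(patterns)) {
    if (!keep[a]) next
    for (b in seq_along(patterns)) {
      if (a == b) next
      if (subcube_contains(patterns[[a]], patterns[[b]]) &&
          !identical(patterns[[a]], patterns[[b]])) {
        keep[a] <- FALSE
        break
      }
    }
  }
  patterns[keep]
}

#' Minimal trap spaces (Most Permissive attractors)
#'
#' Enumerates the complete, pairwise non-nested set of minimal trap spaces
#' of the network. These subcubes are exactly the attractors of the Most
#' Permissive semantics. Two complete methods are available:
#' `"exhaustive"` scans all 3^n subcube patterns (the small-n oracle),
#' `"implicants"` enumerates maximal self-supported consistent literal sets
#' from the prime implicants of each local function and scales to networks
#' with hundreds to thousands of components. `"auto"` picks `"exhaustive"`
#' up to 8 components.
#'
#' @param bn A `BooleanNetwork`.
#' @param method `"auto"`, `"exhaustive"` or `"implicants"`.
#' @param node_limit Branching budget for the implicant search.
#' @return Sorted character vector of patterns over `0`, `1`, `*`.
#' @examples
#' bn <- parse_bnet("x1, !x2\nx2, !x1\nx3, x2 & !x1")
#' minimal_trap_spaces(bn)
#' @export
minimal_trap_spaces <- function(bn, method = c("auto", "exhaustive", "implicants"),
                                node_limit = 100000L) {
  method <- match.arg(method)
  n <- bn_size(bn)
  if (method == "auto") method <- if (n <= 8L) "exhaustive" else "implicants"
  if (method == "exhaustive") {
    if (n > 12L)
      stop("exhaustive trap space enumeration scans 3^n patterns; use ",
           "method = \"implicants\" beyond 12 components", call. = FALSE)
    pats <- minimal_patterns(enumerate_trap_spaces_exhaustive(bn))
  } else {
    pats <- mts_decomposed(bn, rep(NA_integer_, n), node_limit)
  }
  sort(vapply(pats, format_subcube, character(1)))
}

#' Is a trap space minimal?
#'
#' @param bn A `BooleanNetwork`.
#' @param pattern A trap space pattern; an error is raised if it is not a
#'   trap space.
#' @param method `"auto"` uses the exhaustive sub-pattern scan when the
#'   pattern has at most 8 free positions and the implicant-based existence
#'   check otherwise.
#' @return `TRUE` iff no strictly smaller trap space is contained in it.
#' @examples
#' bn <- parse_bnet("x1, !x2\nx2, !x1\nx3, x2 & !x1")
#' is_minimal_trap_space(bn, "011")
#' is_minimal_trap_space(bn, "***")
#' @export
is_minimal_trap_space <- function(bn, pattern,
                                  method = c("auto", "exhaustive", "implicants")) {
  method <- match.arg(method)
  n <- bn_size(bn)
  pattern <- as_subcube(pattern, n)
  if (!is_trap_space(bn, pattern))
    stop("pattern ", format_subcube(pattern), " is not a trap space", call. = FALSE)
  free <- which(is.na(pattern))
  if (!length(free)) return(TRUE)
  if (method == "auto") method <- if (length(free) <= 8L) "exhaustive" else "implicants"
  if (method == "exhaustive") {
    f <- length(free)
    if (f > 12L)
      stop("exhaustive minimality check scans 3^f sub-patterns; use ",
           "method = \"implicants\"", call. = FALSE)
    for (code in 0:(3L^f - 1L)) {
      digits <- (code %/% 3L^(0:(f - 1L))) %% 3L
      if (all(digits == 2L)) next   # the pattern itself
      q <- pattern
      q[free] <- ifelse(digits == 2L, NA_integer_, digits)
      if (is_trap_space(bn, q)) return(FALSE)
    }
    return(TRUE)
  }
  # a smaller trap space exists iff some dependency block of the free
  # components carries a nonempty self-supported consistent literal set
  for (block in scc_blocks(bn, free)) {
    if (enumerate_stable_sets(bn, block, fixed = pattern, first_only = TRUE))
      return(FALSE)
  }
  TRUE
}

#' Does a configuration belong to a Most Permissive attractor?
#'
#' A configuration is in an attractor exactly when the smallest trap space
#' containing it is minimal.
#'
#' @inheritParams smallest_trap_space
#' @return `TRUE` or `FALSE`.
#' @examples
#' bn <- parse_bnet("x1, !x2\nx2, !x1\nx3, x2 & !x1")
#' in_attractor(bn, "011")
#' in_attractor(bn, "000")
#' @export
in_attractor <- function(bn, x) {
  is_minimal_trap_space(bn, smallest_trap_space(bn, x))
}

#' Attractors reachable from a configuration
#'
#' Computes the minimal trap spaces of the network and keeps those whose
#' subcube is Most Permissive-reachable from `x`. Both steps avoid explicit
#' state-space construction, so the analysis scales to large networks.
#'
#' @inheritParams smallest_trap_space
#' @param method Passed to [minimal_trap_spaces()].
#' @param node_limit Branching budget for the implicant search.
#' @return Sorted character vector of reachable minimal trap space patterns.
#' @examples
#' bn <- parse_bnet("x1, !x2\nx2, !x1\nx3, x2 & !x1")
#' reachable_attractors(bn, "000")
#' reachable_attractors(bn, "100")
#' @export
reachable_attractors <- function(bn, x, method = c("auto", "exhaustive", "implicants"),
                                 node_limit = 100000L) {
  mts <- minimal_trap_spaces(bn, method = method, node_limit = node_limit)
  mts[vapply(mts, function(p) mp_reach_subcube(bn, x, p), logical(1))]
}
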