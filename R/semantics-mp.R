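# Most Permissive semantics. Components take four states: inactive (0),
# active (1), increasing ('+') and decreasing ('-'). A component in a
# dynamic state is read non-deterministically as 0 or 1 by its targets,
# which abstracts away unknown interaction thresholds: the set of admissible
# Boolean interpretations gamma(x) fixes Boolean components and frees
# dynamic ones.
#
# Reachability between Boolean configurations admits a polynomial shortcut
# for locally monotonic networks: a three-phase trajectory (Boolean ->
# dynamic, dynamic flips, dynamic -> Boolean) of at most 3n transitions,
# found by saturation with a blacklist of components that cannot restore
# their starting value.

# can_read over internal codes; x uses 0/1 for Boolean and 2/3 for dynamic
can_read_int <- function(bn, i, x, v) {
  cmp <- bn_compiled(bn, i)
  k <- cmp$k
  if (k == 0L) return(eval_compiled(bn, cmp, integer(0)) == v)
  xv <- x[cmp$vars]
  dyn <- xv > 1L
  if (!any(dyn)) return(eval_compiled(bn, cmp, xv) == v)
  s <- cmp$signs
  if (!any(s[dyn] == 2L)) {
    # monotone fast path: dynamic activators read as v, inhibitors as 1-v
    z <- xv
    zd <- s[dyn]
    z[dyn] <- ifelse(zd == 1L, v, ifelse(zd == -1L, 1L - v, 0L))
    return(eval_compiled(bn, cmp, z) == v)
  }
  if (is.null(cmp$tt))
    stop("cannot decide a most-permissive read: function of '",
         bn$components[i], "' is not syntactically monotone and has more ",
         "than ", TT_MAX_INPUTS, " inputs", call. = FALSE)
  # exhaustive over the dynamic inputs of f_i
  d <- which(dyn)
  base <- 0L
  fixed <- which(!dyn)
  if (length(fixed)) base <- sum(xv[fixed] * 2L^(fixed - 1L))
  combos <- 0:(2L^length(d) - 1L)
  idx <- rep(base, length(combos))
  for (j in seq_along(d))
    idx <- idx + bitwAnd(combos %/% 2L^(j - 1L), 1L) * 2L^(d[j] - 1L)
  any(cmp$tt[idx + 1L] == (v == 1L))
}

#' Can a component read a Boolean value from an MP configuration?
#'
#' Decides whether some Boolean interpretation `z` of the most-permissive
#' configuration `x` (Boolean components fixed, dynamic components free)
#' satisfies `f_i(z) = v`. For functions that are monotonic in every input
#' the answer is obtained in linear time by substituting dynamic activators
#' with `v` and dynamic inhibitors with `1 - v`; otherwise the dynamic
#' inputs of `f_i` are enumerated exhaustively (which requires the function
#' to have at most 16 inputs).
#'
#' @param bn A `BooleanNetwork`.
#' @param i Component index.
#' @param x An MP configuration: string over `0`, `1`, `+` (increasing),
#'   `-` (decreasing), or an integer vector over codes 0:3.
#' @param v Target Boolean value, 0 or 1.
#' @return `TRUE` or `FALSE`.
#' @examples
#' bn <- parse_bnet("x1, 1\nx2, x1\nx3, x2 & !x1")
#' can_read(bn, 3, "++0", 1)  # read x1 as 0 and x2 as 1
#' can_read(bn, 3, "1+0", 1)  # impossible: x1 is fixed at 1
#' @export
can_read <- function(bn, i, x, v) {
  n <- bn_size(bn)
  if (i < 1L || i > n) stop("component index out of bounds", call. = FALSE)
  v <- as.integer(v)
  if (!v %in% c(0L, 1L)) stop("v must be 0 or 1", call. = FALSE)
  can_read_int(bn, i, as_mp_config(x, n), v)
}

mp_successors_int <- function(bn, x) {
  out <- list()
  for (i in seq_along(x)) {
    s <- x[i]
    if (s == 0L || s == MP_DOWN) {       # may start increasing
      if (can_read_int(bn, i, x, 1L)) {
        y <- x; y[i] <- MP_UP
        out[[length(out) + 1L]] <- y
      }
    }
    if (s == 1L || s == MP_UP) {         # may start decreasing
      if (can_read_int(bn, i, x, 0L)) {
        y <- x; y[i] <- MP_DOWN
        out[[length(out) + 1L]] <- y
      }
    }
    if (s == MP_UP) {                    # settle at 1, unconditionally
      y <- x; y[i] <- 1L
      out[[length(out) + 1L]] <- y
    }
    if (s == MP_DOWN) {                  # settle at 0, unconditionally
      y <- x; y[i] <- 0L
      out[[length(out) + 1L]] <- y
    }
  }
  out
}

#' One-step Most Permissive transitions
#'
#' All single-component state changes allowed by the Most Permissive
#' semantics: a component may change to increasing from 0 or decreasing
#' whenever it can read its function as true, to decreasing from 1 or
#' increasing whenever it can read it as false, and a dynamic component may
#' settle at its direction's Boolean endpoint at any time.
#'
#' @inheritParams can_read
#' @return Sorted character vector of successor MP configuration strings.
#' @examples
#' bn <- parse_bnet("x1, !x2\nx2, !x1\nx3, x2 & !x1")
#' mp_successors(bn, "000")
#' @export
mp_successors <- function(bn, x) {
  x <- as_mp_config(x, bn_size(bn))
  sort(vapply(mp_successors_int(bn, x), format_mp_config, character(1)))
}

enc_mp <- function(x) as.integer(sum(x * 4^(seq_along(x) - 1L)) + 1)

dec_mp <- function(code, n) {
  as.integer((code - 1L) %/% 4^(0:(n - 1L))) %% 4L
}

# BFS over the full four-state transition graph; returns visit flags
mp_bfs_int <- function(bn, x0, visited = NULL) {
  n <- length(x0)
  if (is.null(visited)) visited <- logical(4L^n)
  queue <- list(x0)
  visited[enc_mp(x0)] <- TRUE
  pos <- 1L
  while (pos <= length(queue)) {
    cur <- queue[[pos]]; pos <- pos + 1L
    for (y in mp_successors_int(bn, cur)) {
      code <- enc_mp(y)
      if (!visited[code]) {
        visited[code] <- TRUE
        queue[[length(queue) + 1L]] <- y
      }
    }
  }
  visited
}

#' Brute-force Most Permissive reachability oracle
#'
#' Enumerates the full four-state transition graph (4^n states) by
#' breadth-first search and returns every Boolean configuration reachable
#' from `x`. This is the ground-truth oracle against which the polynomial
#' reachability procedure [mp_reach()] is validated; it is only usable at
#' small n.
#'
#' @inheritParams can_read
#' @param max_n Oracle bound; the search allocates 4^n visit flags.
#' @return Sorted character vector of reachable Boolean configurations
#'   (always contains `x` itself).
#' @export
mp_reachable_boolean_set_oracle <- function(bn, x, max_n = 8L) {
  n <- bn_size(bn)
  if (n > max_n)
    stop(sprintf("network has %d components, above the MP oracle bound of %d (4^n states)",
                 n, max_n), call. = FALSE)
  x <- as_config(x, n)
  visited <- mp_bfs_int(bn, x)
  codes <- which(visited)
  out <- character(0)
  for (code in codes) {
    s <- dec_mp(code, n)
    if (all(s <= 1L)) out <- c(out, format_config(s))
  }
  sort(out)
}

# Full Boolean-to-Boolean MP reachability table at small n (internal, used
# by the randomized validation suite): one pass building the 4^n adjacency,
# then one BFS per Boolean start over integer adjacency.
mp_boolean_reach_table <- function(bn, max_n = 8L) {
  n <- bn_size(bn)
  if (n > max_n) stop("above MP oracle bound", call. = FALSE)
  N <- 4L^n
  adj <- vector("list", N)
  for (code in seq_len(N)) {
    cur <- dec_mp(code, n)
    succ <- mp_successors_int(bn, cur)
    adj[[code]] <- vapply(succ, enc_mp, integer(1))
  }
  bool_codes <- integer(2L^n)
  for (b in seq_len(2L^n))
    bool_codes[b] <- enc_mp(dec_config(b, n))
  is_bool <- logical(N)
  is_bool[bool_codes] <- TRUE
  bool_rank <- integer(N)
  bool_rank[bool_codes] <- seq_len(2L^n)
  reach <- matrix(FALSE, nrow = 2L^n, ncol = 2L^n)
  for (b in seq_len(2L^n)) {
    visited <- logical(N)
    queue <- bool_codes[b]
    visited[queue] <- TRUE
    pos <- 1L
    while (pos <= length(queue)) {
      code <- queue[pos]; pos <- pos + 1L
      for (nx in adj[[code]]) {
        if (!visited[nx]) {
          visited[nx] <- TRUE
          queue <- c(queue, nx)
        }
      }
    }
    reach[b, ] <- visited[bool_codes]
  }
  reach
}

# ---- polynomial reachability ----------------------------------------------

# Phase-1 saturation: the largest set of non-blacklisted components that can
# enter a dynamic state, each tested in the context where the members found
# so far are dynamic and the rest sit at x. The closure is monotone (more
# dynamic components can only enable more reads), so the result does not
# depend on insertion order.
mp_saturate <- function(bn, x, blacklist) {
  n <- length(x)
  dep <- bn_dependents(bn)
  ctx <- x
  M <- integer(0)
  queue <- seq_len(n)
  inq <- rep(TRUE, n)
  pos <- 1L
  while (pos <= length(queue)) {
    i <- queue[pos]; pos <- pos + 1L
    inq[i] <- FALSE
    if (ctx[i] > 1L || blacklist[i]) next
    if (can_read_int(bn, i, ctx, 1L - x[i])) {
      ctx[i] <- if (x[i] == 0L) MP_UP else MP_DOWN
      M <- c(M, i)
      for (j in dep[[i]]) {
        if (ctx[j] <= 1L && !blacklist[j] && !inq[j]) {
          queue <- c(queue, j)
          inq[j] <- TRUE
        }
      }
    }
  }
  list(M = M, ctx = ctx)
}

# Shared exploration for Boolean and subcube targets. `target` is an integer
# vector with NA marking positions exempt from the flip-back requirement.
mp_reach_core <- function(bn, x, target) {
  n <- length(x)
  blacklist <- logical(n)
  repeat {
    sat <- mp_saturate(bn, x, blacklist)
    inM <- logical(n)
    inM[sat$M] <- TRUE
    changed <- which(!is.na(target) & target != x)
    if (!all(inM[changed])) return(list(ok = FALSE))
    flip_back <- sat$M[!is.na(target[sat$M]) & target[sat$M] == x[sat$M]]
    fails <- flip_back[!vapply(flip_back, function(i)
      can_read_int(bn, i, sat$ctx, x[i]), logical(1))]
    if (!length(fails))
      return(list(ok = TRUE, sat = sat, flip_back = flip_back))
    # a component that cannot restore its value in the maximal context can
    # never do so; exclude all such components and re-saturate
    blacklist[fails] <- TRUE
  }
}

new_mp_witness <- function(reachable, states = character(0), phases = character(0)) {
  structure(list(reachable = reachable, states = states, phases = phases),
            class = "mp_witness")
}

mp_witness_build <- function(x, target, core) {
  cur <- x
  states <- list(cur)
  phases <- character(0)
  for (i in core$sat$M) {
    cur[i] <- if (x[i] == 0L) MP_UP else MP_DOWN
    states[[length(states) + 1L]] <- cur
    phases <- c(phases, "P1")
  }
  for (i in core$flip_back) {
    cur[i] <- if (cur[i] == MP_UP) MP_DOWN else MP_UP
    states[[length(states) + 1L]] <- cur
    phases <- c(phases, "P2")
  }
  for (i in core$sat$M) {
    cur[i] <- if (cur[i] == MP_UP) 1L else 0L
    states[[length(states) + 1L]] <- cur
    phases <- c(phases, "P3")
  }
  new_mp_witness(TRUE,
                 vapply(states, format_mp_config, character(1)),
                 phases)
}

#' @export
print.mp_witness <- function(x, ...) {
  if (!x$reachable) {
    cat("not reachable\n")
    return(invisible(x))
  }
  cat("Most Permissive trajectory (", length(x$states) - 1L, " transitions)\n",
      sep = "")
  cat("  ", x$states[1L], "\n", sep = "")
  for (k in seq_along(x$phases))
    cat("  ", x$states[k + 1L], "  [", x$phases[k], "]\n", sep = "")
  invisible(x)
}

#' Most Permissive reachability between Boolean configurations
#'
#' Decides whether `to` is reachable from `from` under the Most Permissive
#' semantics, using the polynomial three-phase exploration: saturate the
#' set of components that can enter a dynamic state, require every changing
#' component to be in that set, require every non-changing dynamic
#' component to be able to flip back toward its starting value in the
#' saturated context, and blacklist-and-restart (at most n times) when a
#' flip-back fails. For locally monotonic networks every step is linear
#' time; non-monotonic functions are handled by enumerative reads over
#' their dynamic inputs.
#'
#' On success a witness trajectory visiting at most `3n + 1` configurations
#' can be returned, with each transition annotated by its phase: `P1`
#' (Boolean to dynamic), `P2` (dynamic flip), `P3` (dynamic to Boolean).
#'
#' @param bn A `BooleanNetwork`.
#' @param from,to Boolean configurations (strings or integer vectors).
#' @param witness If `TRUE`, return an `mp_witness` object instead of a
#'   logical.
#' @return A logical, or an `mp_witness` when `witness = TRUE`.
#' @examples
#' bn <- parse_bnet("x1, !x2\nx2, !x1\nx3, x2 & !x1")
#' mp_reach(bn, "000", "111")
#' mp_reach(bn, "000", "111", witness = TRUE)
#' @export
mp_reach <- function(bn, from, to, witness = FALSE) {
  n <- bn_size(bn)
  x <- as_config(from, n)
  y <- as_config(to, n)
  if (identical(x, y)) {
    if (!witness) return(TRUE)
    return(new_mp_witness(TRUE, format_mp_config(x), character(0)))
  }
  core <- mp_reach_core(bn, x, y)
  if (!core$ok) {
    if (!witness) return(FALSE)
    return(new_mp_witness(FALSE))
  }
  if (!witness) return(TRUE)
  mp_witness_build(x, y, core)
}

#' Most Permissive reachability of a subcube
#'
#' Decides whether some vertex of the subcube `target` is reachable from
#' `from`. The exploration is the one of [mp_reach()], except that
#' components free in the target are exempt from the flip-back requirement
#' (they may settle on either side). With `target` a minimal trap space,
#' this is the reachable-attractor test.
#'
#' @inheritParams mp_reach
#' @param target A subcube pattern over `0`, `1`, `*` (string such as
#'   `"**1"`, or an integer vector with NA for free positions).
#' @return A logical, or an `mp_witness` when `witness = TRUE`.
#' @examples
#' bn <- parse_bnet("x1, 1\nx2, x1\nx3, x2 & !x1")
#' mp_reach_subcube(bn, "000", "**1")
#' @export
mp_reach_subcube <- function(bn, from, target, witness = FALSE) {
  n <- bn_size(bn)
  x <- as_config(from, n)
  tg <- as_subcube(target, n)
  fixed <- which(!is.na(tg))
  if (all(tg[fixed] == x[fixed])) {
    if (!witness) return(TRUE)
    return(new_mp_witness(TRUE, format_mp_config(x), character(0)))
  }
  core <- mp_reach_core(bn, x, tg)
  if (!core$ok) {
    if (!witness) return(FALSE)
    return(new_mp_witness(FALSE))
  }
  if (!witness) return(TRUE)
  mp_witness_build(x, tg, core)
}
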