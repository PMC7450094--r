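# Classical execution semantics of Boolean networks: synchronous, fully
# asynchronous, and generalized asynchronous. These are explicit-state
# procedures over the 2^n configuration space; they serve as ground-truth
# oracles at small n, not as the scalable analysis path.

match_semantics <- function(mode) {
  match.arg(mode, c("general", "asynchronous", "synchronous"))
}

enc_config <- function(x) as.integer(sum(x * 2^(seq_along(x) - 1L)) + 1)

dec_config <- function(code, n) {
  as.integer((code - 1L) %/% 2^(0:(n - 1L))) %% 2L
}

check_state_bound <- function(n, max_n) {
  if (n > max_n)
    stop(sprintf(paste0("network has %d components, above the explicit-state ",
                        "bound of %d; these routines enumerate 2^n states and ",
                        "are meant as small-n oracles (raise max_n at your own ",
                        "risk)"), n, max_n), call. = FALSE)
}

# integer-coded successor computation shared by the exported front ends
successors_int <- function(bn, x, mode) {
  fx <- update_all(bn, x)
  unstable <- which(fx != x)
  if (length(unstable) == 0L) return(list())
  if (mode == "synchronous") return(list(fx))
  if (mode == "asynchronous") {
    return(lapply(unstable, function(i) { y <- x; y[i] <- fx[i]; y }))
  }
  # generalized: any nonempty subset of unstable components updates at once
  k <- length(unstable)
  if (k > 20L)
    stop("more than 20 simultaneously unstable components; generalized ",
         "successor enumeration would be too large", call. = FALSE)
  lapply(seq_len(2L^k - 1L), function(mask) {
    y <- x
    sel <- unstable[bitwAnd(mask, 2L^(seq_len(k) - 1L)) > 0L]
    y[sel] <- fx[sel]
    y
  })
}

#' Successor configurations under a classical semantics
#'
#' Implements the one-step transition relations: synchronous (all components
#' update together, giving the unique successor `f(x)` when it differs from
#' `x`), fully asynchronous (exactly one unstable component updates), and
#' generalized asynchronous (any nonempty subset of unstable components
#' updates simultaneously). The identity transition is never emitted, so
#' fixed points have no successors.
#'
#' @param bn A `BooleanNetwork`.
#' @param x A configuration (binary string or integer vector).
#' @param mode One of `"general"`, `"asynchronous"`, `"synchronous"`.
#' @return A sorted character vector of successor configuration strings.
#' @examples
#' bn <- parse_bnet("x1, !x2\nx2, !x1\nx3, x2 & !x1")
#' successors(bn, "000", "general")
#' @export
successors <- function(bn, x, mode = c("general", "asynchronous", "synchronous")) {
  mode <- match_semantics(mode)
  x <- as_config(x, bn_size(bn))
  sort(vapply(successors_int(bn, x, mode), format_config, character(1)))
}

#' Reachable set of a configuration
#'
#' Breadth-first closure of the chosen transition relation, including the
#' starting configuration itself.
#'
#' @inheritParams successors
#' @param max_n Explicit-state bound; networks with more components are
#'   rejected since the search allocates 2^n visit flags.
#' @return Sorted character vector of reachable configuration strings.
#' @examples
#' bn <- parse_bnet("x1, !x2\nx2, !x1\nx3, x2 & !x1")
#' reachable_set(bn, "000", "general")
#' @export
reachable_set <- function(bn, x, mode = c("general", "asynchronous", "synchronous"),
                          max_n = 20L) {
  mode <- match_semantics(mode)
  n <- bn_size(bn)
  check_state_bound(n, max_n)
  x <- as_config(x, n)
  visited <- logical(2L^n)
  queue <- list(x)
  visited[enc_config(x)] <- TRUE
  pos <- 1L
  while (pos <= length(queue)) {
    cur <- queue[[pos]]; pos <- pos + 1L
    for (y in successors_int(bn, cur, mode)) {
      code <- enc_config(y)
      if (!visited[code]) {
        visited[code] <- TRUE
        queue[[length(queue) + 1L]] <- y
      }
    }
  }
  sort(vapply(which(visited), function(code) format_config(dec_config(code, n)),
              character(1)))
}

#' Attractors under a classical semantics
#'
#' Attractors are the smallest nonempty sets of configurations from which
#' the dynamics cannot escape, i.e. the terminal strongly connected
#' components of the full transition digraph. Each returned set `A`
#' satisfies `reachable_set(z) == A` for every `z` in `A`.
#'
#' @inheritParams reachable_set
#' @return A list of sorted character vectors, one per attractor, ordered by
#'   their first configuration.
#' @examples
#' bn <- parse_bnet("x1, !x2\nx2, !x1\nx3, x2 & !x1")
#' attractors(bn, "asynchronous")
#' @export
attractors <- function(bn, mode = c("general", "asynchronous", "synchronous"),
                       max_n = 20L) {
  mode <- match_semantics(mode)
  n <- bn_size(bn)
  check_state_bound(n, max_n)
  N <- 2L^n
  from <- integer(0); to <- integer(0)
  for (code in seq_len(N)) {
    x <- dec_config(code, n)
    succ <- successors_int(bn, x, mode)
    if (length(succ)) {
      from <- c(from, rep(code, length(succ)))
      to <- c(to, vapply(succ, enc_config, integer(1)))
    }
  }
  g <- igraph::make_empty_graph(n = N, directed = TRUE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g, mode = "strong")$membership
  terminal <- rep(TRUE, max(memb))
  cross <- memb[from] != memb[to]
  terminal[unique(memb[from[cross]])] <- FALSE
  out <- lapply(which(terminal), function(comp) {
    sort(vapply(which(memb == comp),
                function(code) format_config(dec_config(code, n)), character(1)))
  })
  out[order(vapply(out, `[`, character(1), 1L))]
}

#' Fixed points of a Boolean network
#'
#' Configurations `z` with `f(z) = z`. Found by a backtracking search over
#' partial configurations with constraint propagation (a component whose
#' function can no longer attain one Boolean value is forced to the other),
#' so the search scales well beyond explicit state-space enumeration.
#'
#' @param bn A `BooleanNetwork`.
#' @return Sorted character vector of fixed-point configuration strings
#'   (possibly empty).
#' @examples
#' fixed_points(parse_bnet("x1, !x2\nx2, !x1\nx3, x2 & !x1"))
#' @export
fixed_points <- function(bn) {
  n <- bn_size(bn)
  res <- character(0)
  rec <- function(ctx) {
    repeat {
      progress <- FALSE
      for (i in seq_len(n)) {
        if (ctx[i] <= 1L) {
          if (!can_read_int(bn, i, ctx, ctx[i])) return(invisible(NULL))
        } else {
          r1 <- can_read_int(bn, i, ctx, 1L)
          r0 <- can_read_int(bn, i, ctx, 0L)
          if (r1 && r0) next
          ctx[i] <- if (r1) 1L else 0L
          progress <- TRUE
        }
      }
      if (!progress) break
    }
    free <- which(ctx > 1L)
    if (!length(free)) {
      res[[length(res) + 1L]] <<- format_config(ctx)
      return(invisible(NULL))
    }
    i <- free[1L]
    for (v in c(0L, 1L)) {
      ctx2 <- ctx
      ctx2[i] <- v
      rec(ctx2)
    }
  }
  rec(rep(MP_UP, n))
  sort(res)
}
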