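# Multivalued networks (MNs) and the refinement relation to Boolean
# networks. An MN over levels 0..m maps every multivalued configuration to
# a per-component tendency in {-1, 0, +1} (decrease, steady, increase).
# The refinement criterion goes through the binarization operator: level 0
# reads as Boolean 0, level m as 1, intermediate levels as either value.

mv_enc <- function(x, m) as.integer(sum(x * (m + 1)^(seq_along(x) - 1L)) + 1)

mv_dec <- function(code, n, m) {
  as.integer((code - 1L) %/% (m + 1)^(0:(n - 1L))) %% (m + 1L)
}

as_mv_config <- function(x, n, m) {
  if (is.character(x)) {
    if (length(x) != 1L)
      stop("a multivalued configuration string must be a single character value",
           call. = FALSE)
    ch <- strsplit(x, "", fixed = TRUE)[[1L]]
    if (!all(ch %in% as.character(0:9)))
      stop("multivalued configuration strings must be digit strings", call. = FALSE)
    x <- as.integer(ch)
  }
  x <- as.integer(x)
  if (length(x) != n)
    stop(sprintf("configuration has length %d but the network has %d components",
                 length(x), n), call. = FALSE)
  if (anyNA(x) || any(x < 0L) || any(x > m))
    stop("multivalued configuration values must lie in 0..m", call. = FALSE)
  x
}

format_mv_config <- function(x) paste(x, collapse = "")

#' Construct a multivalued network
#'
#' A multivalued network of dimension `n` with uniform maximum level `m` is
#' defined by a tendency function mapping each configuration in
#' `{0..m}^n` to a per-component tendency in `{-1, 0, 1}`. The tendency is
#' materialized as an explicit table over all `(m+1)^n` configurations.
#'
#' @param n Number of components.
#' @param m Maximum level (all components range over `0..m`).
#' @param tendency Either a function taking an integer configuration vector
#'   and returning an integer vector of tendencies, or a ready-made
#'   `(m+1)^n` by `n` integer matrix (row order follows [mv_configs()]).
#' @param max_states Capacity guard on the table size.
#' @return A `MultivaluedNetwork` object.
#' @export
multivalued_network <- function(n, m, tendency, max_states = 2L^20L) {
  stopifnot(n >= 1L, m >= 1L)
  N <- (m + 1L)^n
  if (N > max_states)
    stop("tendency table would have ", N, " rows, above the capacity of ",
         max_states, call. = FALSE)
  if (is.function(tendency)) {
    tab <- matrix(0L, nrow = N, ncol = n)
    for (code in seq_len(N))
      tab[code, ] <- as.integer(tendency(mv_dec(code, n, m)))
  } else {
    tab <- tendency
    storage.mode(tab) <- "integer"
    if (!is.matrix(tab) || nrow(tab) != N || ncol(tab) != n)
      stop("tendency table must be a (m+1)^n by n matrix", call. = FALSE)
  }
  if (!all(tab %in% c(-1L, 0L, 1L)))
    stop("tendencies must be -1, 0 or 1", call. = FALSE)
  structure(list(n = n, m = m, tendency = tab), class = "MultivaluedNetwork")
}

#' All configurations of a multivalued network, in table row order
#'
#' @param mn A `MultivaluedNetwork`.
#' @return A `(m+1)^n` by `n` integer matrix; row `k` is the configuration
#'   whose tendency is row `k` of the network's table.
#' @export
mv_configs <- function(mn) {
  N <- (mn$m + 1L)^mn$n
  t(vapply(seq_len(N), function(code) mv_dec(code, mn$n, mn$m),
           integer(mn$n)))
}

#' @export
print.MultivaluedNetwork <- function(x, ...) {
  cat(sprintf("Multivalued network: %d components, levels 0..%d (%d configurations)\n",
              x$n, x$m, nrow(x$tendency)))
  invisible(x)
}

#' Tendency table as a data frame
#'
#' One row per multivalued configuration with its per-component tendency,
#' for inspection and plain-text export.
#'
#' @param x A `MultivaluedNetwork`.
#' @param row.names,optional,... Ignored; present for the generic.
#' @return A data frame with a `configuration` column and one tendency
#'   column per component.
#' @export
as.data.frame.MultivaluedNetwork <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  cfg <- apply(mv_configs(x), 1L, format_mv_config)
  out <- data.frame(configuration = cfg, x$tendency)
  names(out)[-1L] <- paste0("d", seq_len(x$n))
  out
}

mn_successors_int <- function(mn, x, mode) {
  d <- mn$tendency[mv_enc(x, mn$m), ]
  movers <- which(d != 0L & x + d >= 0L & x + d <= mn$m)
  if (!length(movers)) return(list())
  if (mode == "synchronous") {
    y <- x
    y[movers] <- y[movers] + d[movers]
    return(list(y))
  }
  if (mode == "asynchronous") {
    return(lapply(movers, function(i) { y <- x; y[i] <- y[i] + d[i]; y }))
  }
  k <- length(movers)
  if (k > 20L) stop("too many simultaneous movers", call. = FALSE)
  lapply(seq_len(2L^k - 1L), function(mask) {
    sel <- movers[bitwAnd(mask, 2L^(seq_len(k) - 1L)) > 0L]
    y <- x
    y[sel] <- y[sel] + d[sel]
    y
  })
}

#' Successors of a multivalued configuration
#'
#' Components step by their tendency (one component for the asynchronous
#' mode, any nonempty subset for the generalized mode, all for the
#' synchronous mode); a step that would leave the `0..m` range is
#' suppressed rather than truncated.
#'
#' @param mn A `MultivaluedNetwork`.
#' @param x A multivalued configuration (digit string or integer vector).
#' @param mode `"asynchronous"`, `"general"` or `"synchronous"`.
#' @return Sorted character vector of successor configuration strings.
#' @export
mn_successors <- function(mn, x, mode = c("asynchronous", "general", "synchronous")) {
  mode <- match.arg(mode)
  x <- as_mv_config(x, mn$n, mn$m)
  sort(vapply(mn_successors_int(mn, x, mode), format_mv_config, character(1)))
}

#' Reachable set of a multivalued configuration
#'
#' @inheritParams mn_successors
#' @param max_states Explicit-state capacity guard.
#' @return Sorted character vector of reachable configurations, including
#'   `x` itself.
#' @export
mn_reachable_set <- function(mn, x, mode = c("asynchronous", "general", "synchronous"),
                             max_states = 2L^20L) {
  mode <- match.arg(mode)
  N <- (mn$m + 1L)^mn$n
  if (N > max_states) stop("state space too large", call. = FALSE)
  x <- as_mv_config(x, mn$n, mn$m)
  visited <- logical(N)
  visited[mv_enc(x, mn$m)] <- TRUE
  queue <- list(x)
  pos <- 1L
  while (pos <= length(queue)) {
    cur <- queue[[pos]]; pos <- pos + 1L
    for (y in mn_successors_int(mn, cur, mode)) {
      code <- mv_enc(y, mn$m)
      if (!visited[code]) {
        visited[code] <- TRUE
        queue[[length(queue) + 1L]] <- y
      }
    }
  }
  sort(vapply(which(visited), function(code)
    format_mv_config(mv_dec(code, mn$n, mn$m)), character(1)))
}

#' Admissible binarizations of a multivalued configuration
#'
#' Level 0 is forced to Boolean 0, the maximum level `m` to 1, and
#' intermediate levels are free, so a configuration with `k` strictly
#' intermediate levels has `2^k` binarizations. For example with `m = 2`,
#' the configuration `012` binarizes to `{001, 011}`.
#'
#' @param x A multivalued configuration (digit string or integer vector).
#' @param m Maximum level.
#' @return Sorted character vector of Boolean configuration strings.
#' @examples
#' binarizations("012", m = 2)
#' @export
binarizations <- function(x, m) {
  if (is.character(x)) x <- as.integer(strsplit(x, "", fixed = TRUE)[[1L]])
  x <- as.integer(x)
  if (anyNA(x) || any(x < 0L) || any(x > m))
    stop("configuration values must lie in 0..m", call. = FALSE)
  n <- length(x)
  base <- ifelse(x == 0L, 0L, ifelse(x == m, 1L, NA_integer_))
  free <- which(is.na(base))
  k <- length(free)
  out <- character(2L^k)
  for (mask in 0:(2L^k - 1L)) {
    y <- base
    if (k) y[free] <- bitwAnd(mask %/% 2L^(seq_len(k) - 1L), 1L)
    out[mask + 1L] <- format_config(y)
  }
  sort(out)
}

# MP context encoding a multivalued configuration's binarization freedom
mv_to_mp_ctx <- function(x, m) {
  ifelse(x == 0L, 0L, ifelse(x == m, 1L, MP_UP))
}

#' Is a multivalued network a refinement of a Boolean network?
#'
#' The refinement criterion: a component's value may decrease (increase)
#' at a configuration only if some binarization of that configuration sets
#' its Boolean function to 0 (to 1). Checked exhaustively over the full
#' tendency table.
#'
#' @param mn A `MultivaluedNetwork`.
#' @param bn A `BooleanNetwork` of the same dimension.
#' @return `TRUE` or `FALSE`, with a `violation` attribute (configuration,
#'   component, tendency) on failure.
#' @export
is_refinement <- function(mn, bn) {
  if (bn_size(bn) != mn$n)
    stop("networks have different dimensions", call. = FALSE)
  N <- (mn$m + 1L)^mn$n
  for (code in seq_len(N)) {
    x <- mv_dec(code, mn$n, mn$m)
    ctx <- mv_to_mp_ctx(x, mn$m)
    d <- mn$tendency[code, ]
    for (i in which(d != 0L)) {
      v <- if (d[i] > 0L) 1L else 0L
      if (!can_read_int(bn, i, ctx, v)) {
        out <- FALSE
        attr(out, "violation") <- list(configuration = format_mv_config(x),
                                       component = i, tendency = d[i])
        return(out)
      }
    }
  }
  TRUE
}

# MP configurations compatible with a multivalued configuration: extremes
# are Boolean, intermediate levels may be increasing or decreasing
compatible_mp <- function(x, m) {
  base <- ifelse(x == 0L, 0L, ifelse(x == m, 1L, NA_integer_))
  free <- which(is.na(base))
  k <- length(free)
  lapply(0:(2L^k - 1L), function(mask) {
    h <- base
    if (k) h[free] <- ifelse(bitwAnd(mask %/% 2L^(seq_len(k) - 1L), 1L) == 1L,
                             MP_DOWN, MP_UP)
    h
  })
}

#' Executable completeness check of the Most Permissive abstraction
#'
#' For a refinement `mn` of `bn`, every asynchronous multivalued trajectory
#' must have a Most Permissive counterpart: for every reachable pair
#' `(x, y)` and every MP configuration compatible with `x`, the MP
#' configuration compatible with `y` and consistent with the changes
#' between `x` and `y` (increasing where the level went up short of the
#' maximum, decreasing where it went down short of zero, Boolean at the
#' extremes, unchanged elsewhere) must be reachable in the full MP
#' transition graph. This instantiates the completeness guarantee at
#' enumerable sizes.
#'
#' @param mn A `MultivaluedNetwork`, a refinement of `bn`.
#' @param bn A `BooleanNetwork`.
#' @param max_n Bound on the Boolean dimension (the check walks the 4^n MP
#'   graph).
#' @return `TRUE`, or `FALSE` with a `counterexample` attribute.
#' @export
completeness_check <- function(mn, bn, max_n = 6L) {
  if (!isTRUE(is_refinement(mn, bn)))
    stop("mn is not a refinement of bn; the completeness guarantee only ",
         "applies to refinements", call. = FALSE)
  n <- mn$n
  if (n > max_n)
    stop("completeness check is enumerative and bounded to ", max_n,
         " components", call. = FALSE)
  m <- mn$m
  reach_cache <- new.env(parent = emptyenv())
  mp_reach_from <- function(xhat) {
    key <- paste(xhat, collapse = "")
    got <- reach_cache[[key]]
    if (!is.null(got)) return(got)
    visited <- mp_bfs_int(bn, xhat)
    reach_cache[[key]] <- visited
    visited
  }
  N <- (m + 1L)^n
  for (code in seq_len(N)) {
    x <- mv_dec(code, n, m)
    for (ystr in mn_reachable_set(mn, x, "asynchronous")) {
      y <- as_mv_config(ystr, n, m)
      if (identical(x, y)) next
      for (xhat in compatible_mp(x, m)) {
        yhat <- integer(n)
        for (i in seq_len(n)) {
          yhat[i] <- if (y[i] == x[i]) xhat[i]
          else if (y[i] == 0L) 0L
          else if (y[i] == m) 1L
          else if (y[i] > x[i]) MP_UP
          else MP_DOWN
        }
        visited <- mp_reach_from(xhat)
        if (!visited[enc_mp(yhat)]) {
          out <- FALSE
          attr(out, "counterexample") <- list(
            x = format_mv_config(x), y = format_mv_config(y),
            xhat = format_mp_config(xhat), yhat = format_mp_config(yhat))
          return(out)
        }
      }
    }
  }
  TRUE
}
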