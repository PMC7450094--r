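# Worked-example fixtures and random generators used for property-based
# validation and scalability runs.

#' Incoherent feed-forward loop of type 3 (I3-FFL)
#'
#' Three components: a signal held on (constant-true input), a relay
#' activated by the signal, and an output requiring the relay to be active
#' and the signal to be absent. Under synchronous or asynchronous
#' semantics the output can never activate from the all-inactive
#' configuration, although quantitative models of the same logic show a
#' transient activation; the Most Permissive semantics recovers it.
#'
#' @return A `BooleanNetwork` with functions `x1 = 1`, `x2 = x1`,
#'   `x3 = x2 & !x1`.
#' @examples
#' bn <- fixture_i3ffl()
#' reachable_set(bn, "000", "asynchronous")   # x3 never active
#' mp_reach_subcube(bn, "000", "**1")         # transient activation
#' @export
fixture_i3ffl <- function() {
  parse_bnet(c("targets, factors",
               "x1, 1",
               "x2, x1",
               "x3, x2 & !x1"))
}

#' Three-component toggle-switch example with a multivalued refinement
#'
#' A mutual-inhibition switch between components 1 and 2, with component 3
#' activated by 2 and inhibited by 1. The companion multivalued network
#' refines the Boolean logic with three levels per component (0, 1, 2):
#' inhibitions act only at the top level, and an intermediate level of
#' component 2 already suffices to activate component 3 provided component
#' 1 is not high. The refinement exhibits a simultaneous activation of all
#' three components that the classical Boolean semantics miss.
#'
#' @return A list with elements `bn` (a `BooleanNetwork` with `x1 = !x2`,
#'   `x2 = !x1`, `x3 = x2 & !x1`) and `mn` (a `MultivaluedNetwork` with
#'   `m = 2` refining it).
#' @examples
#' fx <- fixture_switch3()
#' reachable_set(fx$bn, "000", "general")
#' is_refinement(fx$mn, fx$bn)
#' @export
fixture_switch3 <- function() {
  bn <- parse_bnet(c("targets, factors",
                     "x1, !x2",
                     "x2, !x1",
                     "x3, x2 & !x1"))
  tendency <- function(x) {
    target <- c(if (x[2] == 2L) 0L else 2L,
                if (x[1] == 2L) 0L else 2L,
                if (x[2] >= 1L && x[1] <= 1L) 2L else 0L)
    as.integer(sign(target - x))
  }
  list(bn = bn, mn = multivalued_network(3L, 2L, tendency))
}

# random monotone expression over regulators with fixed polarities
random_monotone_expr <- function(literals) {
  if (length(literals) == 1L) return(literals[[1L]])
  split <- sample.int(length(literals) - 1L, 1L)
  op <- sample(c("&", "|"), 1L)
  call(op,
       random_monotone_expr(literals[seq_len(split)]),
       random_monotone_expr(literals[-seq_len(split)]))
}

#' Random locally monotonic scale-free Boolean network
#'
#' Samples a network with heavy-tailed connectivity: in-degrees follow a
#' truncated power law and regulators are drawn with probability
#' proportional to Pareto-distributed per-node weights, giving a few hub
#' regulators with very high out-degree. Each regulator is assigned a
#' fixed polarity (activator or inhibitor) and the local function is a
#' random AND/OR tree over those literals, so every sampled network is
#' locally monotonic by construction. Self-regulation is excluded.
#' Generation is deterministic for a given seed; the caller's RNG state is
#' left untouched.
#'
#' @param n Number of components.
#' @param seed Integer seed.
#' @param gamma Power-law exponent for the degree model.
#' @param max_inputs Cap on the number of regulators per component.
#' @return A `BooleanNetwork` with components `x1 .. xn`.
#' @examples
#' bn <- random_scale_free_bn(10, seed = 1)
#' is_locally_monotonic(bn)
#' @export
random_scale_free_bn <- function(n, seed, gamma = 2.5, max_inputs = 5L) {
  stopifnot(n >= 1L, max_inputs >= 1L, gamma > 1)
  with_seed(seed, {
    comps <- paste0("x", seq_len(n))
    # Pareto weights drive hub formation among regulators
    weights <- (1 - stats::runif(n))^(-1 / (gamma - 1))
    kmax <- min(max_inputs, max(1L, n - 1L))
    pk <- (1:kmax)^(-gamma)
    exprs <- vector("list", n)
    for (i in seq_len(n)) {
      if (n == 1L) {
        exprs[[i]] <- TRUE   # degenerate single-node network: held on
        next
      }
      k <- sample.int(kmax, 1L, prob = pk)
      pool <- setdiff(seq_len(n), i)
      regs <- if (length(pool) == 1L) pool
      else sample(pool, min(k, length(pool)), prob = weights[pool])
      lits <- lapply(regs, function(r) {
        sym <- as.symbol(comps[r])
        if (stats::runif(1) < 0.5) sym else call("!", sym)
      })
      exprs[[i]] <- random_monotone_expr(lits)
    }
    new_boolean_network(comps, exprs)
  })
}

#' Random multivalued refinement of a Boolean network
#'
#' Builds a tendency table where each entry is drawn uniformly among the
#' tendencies permitted by the refinement criterion at that configuration
#' and component: 0 is always permitted, +1 only if some binarization of
#' the configuration makes the local function true, and -1 only if some
#' binarization makes it false. The output therefore satisfies
#' [is_refinement()] by construction.
#'
#' @param bn A `BooleanNetwork`.
#' @param m Maximum level of the refinement.
#' @param seed Integer seed (the caller's RNG state is preserved).
#' @param maximal If `TRUE`, take the largest permitted magnitude instead
#'   of sampling (preferring +1 when both signs are permitted). With
#'   `m = 1` this reproduces the Boolean asynchronous dynamics exactly.
#' @param max_states Capacity guard on the table size.
#' @return A `MultivaluedNetwork`.
#' @export
random_refinement <- function(bn, m, seed, maximal = FALSE, max_states = 2L^20L) {
  n <- bn_size(bn)
  N <- (m + 1L)^n
  if (N > max_states)
    stop("tendency table would have ", N, " rows, above capacity", call. = FALSE)
  with_seed(seed, {
    tab <- matrix(0L, nrow = N, ncol = n)
    for (code in seq_len(N)) {
      x <- mv_dec(code, n, m)
      ctx <- mv_to_mp_ctx(x, m)
      for (i in seq_len(n)) {
        allowed <- 0L
        if (can_read_int(bn, i, ctx, 1L)) allowed <- c(allowed, 1L)
        if (can_read_int(bn, i, ctx, 0L)) allowed <- c(allowed, -1L)
        tab[code, i] <- if (maximal) {
          if (1L %in% allowed) 1L else if (-1L %in% allowed) -1L else 0L
        } else if (length(allowed) == 1L) allowed else sample(allowed, 1L)
      }
    }
    multivalued_network(n, m, tab)
  })
}
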