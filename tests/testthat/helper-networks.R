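# Shared fixtures and slow-but-simple reference implementations used as
# independent oracles in the tests. These deliberately avoid the package's
# compiled truth-table path: expressions are interpreted recursively, one
# configuration at a time.

switch3 <- function() fixture_switch3()$bn
i3ffl <- function() fixture_i3ffl()

xor2_bn <- function() {
  parse_bnet(c("x1, (x1 & !x2) | (!x1 & x2)",
               "x2, x2"))
}

eval_expr_ref <- function(e, env) {
  if (is.symbol(e)) return(env[[as.character(e)]])
  if (is.logical(e)) return(as.integer(e))
  op <- as.character(e[[1L]])
  if (op == "!") return(1L - eval_expr_ref(e[[2L]], env))
  a <- eval_expr_ref(e[[2L]], env)
  b <- eval_expr_ref(e[[3L]], env)
  if (op == "&") as.integer(a == 1L && b == 1L) else as.integer(a == 1L || b == 1L)
}

# f_i(x) by direct recursive interpretation of the stored expression
eval_component_ref <- function(bn, i, x) {
  env <- as.list(as.integer(x))
  names(env) <- bn$components
  eval_expr_ref(bn$functions[[i]], env)
}

all_configs <- function(n) {
  lapply(0:(2^n - 1), function(code) (code %/% 2^(0:(n - 1))) %% 2)
}

# brute-force gamma enumeration: some Boolean completion of the MP
# configuration (dynamic components free) evaluates f_i to v
can_read_ref <- function(bn, i, mp, v) {
  n <- length(bn$components)
  dyn <- which(mp > 1)
  fixed <- mp
  fixed[dyn] <- 0L
  for (mask in 0:(2^length(dyn) - 1)) {
    z <- fixed
    if (length(dyn)) z[dyn] <- (mask %/% 2^(seq_along(dyn) - 1)) %% 2
    if (eval_component_ref(bn, i, z) == v) return(TRUE)
  }
  FALSE
}

config_in_pattern <- function(x, pattern) {
  p <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  all(p == "*" | p == ch)
}
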