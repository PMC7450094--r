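# Coercion helpers between user-facing string encodings and internal integer
# vectors. Internally, Boolean configurations are integer vectors over {0,1},
# most-permissive (MP) configurations use the codes 0, 1, 2 (increasing) and
# 3 (decreasing), and subcube patterns use NA for free positions.

MP_UP <- 2L
MP_DOWN <- 3L

as_config <- function(x, n) {
  if (is.character(x)) {
    if (length(x) != 1L)
      stop("a configuration string must be a single character value", call. = FALSE)
    ch <- strsplit(x, "", fixed = TRUE)[[1L]]
    if (!all(ch %in% c("0", "1")))
      stop("configuration strings may only contain '0' and '1': ", x, call. = FALSE)
    x <- as.integer(ch == "1")
  }
  x <- as.integer(x)
  if (length(x) != n)
    stop(sprintf("configuration has length %d but the network has %d components",
                 length(x), n), call. = FALSE)
  if (anyNA(x) || !all(x %in% c(0L, 1L)))
    stop("configuration values must be 0 or 1", call. = FALSE)
  x
}

format_config <- function(x) paste(x, collapse = "")

MP_CHARS <- c(`0` = 0L, `1` = 1L, `+` = 2L, `-` = 3L)

as_mp_config <- function(x, n) {
  if (is.character(x)) {
    if (length(x) != 1L)
      stop("an MP configuration string must be a single character value", call. = FALSE)
    ch <- strsplit(x, "", fixed = TRUE)[[1L]]
    if (!all(ch %in% names(MP_CHARS)))
      stop("MP configuration strings may only contain '0', '1', '+' and '-': ",
           x, call. = FALSE)
    x <- unname(MP_CHARS[ch])
  }
  x <- as.integer(x)
  if (length(x) != n)
    stop(sprintf("MP configuration has length %d but the network has %d components",
                 length(x), n), call. = FALSE)
  if (anyNA(x) || !all(x %in% 0:3))
    stop("MP configuration codes must be in 0:3", call. = FALSE)
  x
}

format_mp_config <- function(x) paste(names(MP_CHARS)[x + 1L], collapse = "")

as_subcube <- function(x, n) {
  if (is.character(x)) {
    if (length(x) != 1L)
      stop("a subcube pattern must be a single character value", call. = FALSE)
    ch <- strsplit(x, "", fixed = TRUE)[[1L]]
    if (!all(ch %in% c("0", "1", "*")))
      stop("subcube patterns may only contain '0', '1' and '*': ", x, call. = FALSE)
    x <- ifelse(ch == "*", NA_integer_, as.integer(ch == "1"))
  }
  x <- as.integer(x)
  if (length(x) != n)
    stop(sprintf("subcube pattern has length %d but the network has %d components",
                 length(x), n), call. = FALSE)
  if (!all(is.na(x) | x %in% c(0L, 1L)))
    stop("subcube values must be 0, 1 or NA (free)", call. = FALSE)
  x
}

format_subcube <- function(x) {
  paste(ifelse(is.na(x), "*", as.character(x)), collapse = "")
}

# pattern q is contained in pattern p (as sets of vertices)
subcube_contains <- function(p, q) {
  all(is.na(p) | (!is.na(q) & q == p))
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
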