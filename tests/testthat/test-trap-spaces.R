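test_that("trap space membership follows closure under f", {
  bn <- switch3()
  expect_true(is_trap_space(bn, "01*"))
  expect_false(is_trap_space(bn, "1**"))
  expect_true(is_trap_space(bn, "***"))
  expect_true(is_trap_space(bn, "011"))
})

test_that("smallest_trap_space percolates to the enclosing trap space", {
  bn <- switch3()
  expect_equal(smallest_trap_space(bn, "011"), "011")
  expect_equal(smallest_trap_space(bn, "000"), "***")
  for (fp in fixed_points(bn))
    expect_equal(smallest_trap_space(bn, fp), fp)
})

test_that("minimality distinguishes singletons, nests and the full cube", {
  bn <- switch3()
  expect_true(is_minimal_trap_space(bn, "100"))
  expect_false(is_minimal_trap_space(bn, "01*"))   # contains {011}
  expect_false(is_minimal_trap_space(bn, "***"))
  expect_error(is_minimal_trap_space(bn, "1**"), "not a trap space")
})

test_that("minimal trap spaces of the fixtures match both methods", {
  bn <- switch3()
  expect_equal(minimal_trap_spaces(bn), c("011", "100"))
  expect_equal(minimal_trap_spaces(bn, method = "implicants"), c("011", "100"))
  expect_equal(minimal_trap_spaces(i3ffl()), "110")
  expect_equal(minimal_trap_spaces(parse_bnet("x1, !x1")), "*")
})

test_that("implicant enumeration equals the exhaustive subcube oracle", {
  for (s in 1:25) {
    n <- sample(3:7, 1)
    bn <- random_scale_free_bn(n, seed = 1100 + s, max_inputs = 4)
    expect_equal(minimal_trap_spaces(bn, method = "implicants"),
                 minimal_trap_spaces(bn, method = "exhaustive"),
                 info = paste("seed", 1100 + s))
  }
})

test_that("in_attractor equals membership in a minimal trap space", {
  for (s in 1:10) {
    n <- sample(3:5, 1)
    bn <- random_scale_free_bn(n, seed = 1200 + s, max_inputs = 3)
    mts <- minimal_trap_spaces(bn)
    for (x in all_configs(n)) {
      xs <- paste(as.integer(x), collapse = "")
      member <- any(vapply(mts, function(p) config_in_pattern(xs, p), logical(1)))
      expect_equal(in_attractor(bn, xs), member,
                   info = paste("seed", 1200 + s, xs))
    }
  }
})

test_that("fixed points are exactly the singleton minimal trap spaces", {
  for (s in 1:10) {
    n <- sample(3:6, 1)
    bn <- random_scale_free_bn(n, seed = 1300 + s, max_inputs = 3)
    mts <- minimal_trap_spaces(bn)
    singletons <- sort(mts[!grepl("*", mts, fixed = TRUE)])
    expect_equal(singletons, fixed_points(bn), info = paste("seed", 1300 + s))
  }
})

test_that("every minimal trap space contains an asynchronous attractor", {
  for (s in 1:10) {
    n <- sample(3:6, 1)
    bn <- random_scale_free_bn(n, seed = 1400 + s, max_inputs = 3)
    att <- attractors(bn, "asynchronous")
    for (p in minimal_trap_spaces(bn)) {
      inside <- vapply(att, function(A)
        all(vapply(A, config_in_pattern, logical(1), pattern = p)), logical(1))
      expect_true(any(inside), info = paste("seed", 1400 + s, p))
    }
  }
})

test_that("reachable attractors filter trap spaces by MP reachability", {
  bn <- switch3()
  expect_equal(reachable_attractors(bn, "000"), c("011", "100"))
  expect_equal(reachable_attractors(bn, "100"), "100")
  expect_equal(reachable_attractors(i3ffl(), "000"), "110")
})
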