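test_that("binarizations force extremes and free intermediate levels", {
  expect_equal(binarizations("012", m = 2), c("001", "011"))
  expect_equal(binarizations("000", m = 2), "000")
  expect_equal(binarizations("111", m = 2),
               sort(vapply(all_configs(3), function(x)
                 paste(as.integer(x), collapse = ""), character(1))))
  # 2^(number of strictly intermediate levels) binarizations
  for (m in 2:3) {
    for (trial in 1:10) {
      x <- sample(0:m, 4, replace = TRUE)
      k <- sum(x > 0 & x < m)
      got <- binarizations(x, m)
      expect_length(got, 2^k)
      forced0 <- which(x == 0)
      forced1 <- which(x == m)
      for (g in got) {
        ch <- strsplit(g, "")[[1]]
        expect_true(all(ch[forced0] == "0") && all(ch[forced1] == "1"))
      }
    }
  }
})

test_that("multivalued steps follow tendencies with bound suppression", {
  mn <- fixture_switch3()$mn
  expect_equal(mn_successors(mn, "000"), c("010", "100"))
  expect_true("111" %in% mn_successors(mn, "110"))
  # steady configurations have no successors
  steady <- multivalued_network(2, 1, function(x) c(0L, 0L))
  expect_length(mn_successors(steady, "01"), 0L)
  expect_equal(mn_reachable_set(steady, "01"), "01")
  # a +1 tendency at the top level is suppressed, not truncated
  up <- multivalued_network(1, 2, function(x) 1L)
  expect_equal(mn_successors(up, "2"), character(0))
})

test_that("the switch refinement reaches simultaneous full activity", {
  fx <- fixture_switch3()
  reach <- mn_reachable_set(fx$mn, "000")
  expect_true("111" %in% reach)
  expect_true(any(vapply(strsplit(reach, ""), function(ch)
    all(as.integer(ch) >= 1), logical(1))))
})

test_that("the refinement criterion accepts the fixture and flags violations", {
  fx <- fixture_switch3()
  expect_true(isTRUE(is_refinement(fx$mn, fx$bn)))
  # force an unjustifiable increase: with x2 at level 2, beta fixes x2' = 1
  # and f1 = !x2 can never read 1
  tab <- fx$mn$tendency
  bad_code <- mpbnet:::mv_enc(c(0L, 2L, 0L), 2L)
  tab[bad_code, 1] <- 1L
  mn_bad <- multivalued_network(3, 2, tab)
  res <- is_refinement(mn_bad, fx$bn)
  expect_false(isTRUE(res))
  expect_equal(attr(res, "violation")$component, 1L)
  # an all-steady network refines anything of matching dimension
  zero <- multivalued_network(3, 2, function(x) c(0L, 0L, 0L))
  expect_true(isTRUE(is_refinement(zero, fx$bn)))
})

test_that("random refinements are refinements and deterministic per seed", {
  for (s in 1:10) {
    bn <- random_scale_free_bn(sample(2:4, 1), seed = 1500 + s, max_inputs = 3)
    mn1 <- random_refinement(bn, m = 2, seed = s)
    mn2 <- random_refinement(bn, m = 2, seed = s)
    expect_identical(mn1$tendency, mn2$tendency)
    expect_true(isTRUE(is_refinement(mn1, bn)))
  }
})

test_that("maximal m=1 refinements reproduce asynchronous BN dynamics", {
  for (s in 1:8) {
    n <- sample(2:4, 1)
    bn <- random_scale_free_bn(n, seed = 1600 + s, max_inputs = 3)
    mn <- random_refinement(bn, m = 1, seed = s, maximal = TRUE)
    for (x in all_configs(n)) {
      xs <- paste(as.integer(x), collapse = "")
      expect_equal(mn_reachable_set(mn, xs, "asynchronous"),
                   reachable_set(bn, xs, "asynchronous"),
                   info = paste("seed", 1600 + s, xs))
    }
  }
})

test_that("completeness holds on the fixture and fails only off-criterion", {
  fx <- fixture_switch3()
  expect_true(isTRUE(completeness_check(fx$mn, fx$bn)))
  # a non-refinement is rejected up front: the guarantee does not apply
  tab <- fx$mn$tendency
  tab[mpbnet:::mv_enc(c(0L, 2L, 0L), 2L), 1] <- 1L
  expect_error(completeness_check(multivalued_network(3, 2, tab), fx$bn),
               "not a refinement")
})

test_that("m=1 refinement asynchronous steps are generalized BN steps", {
  for (s in 1:8) {
    n <- sample(2:4, 1)
    bn <- random_scale_free_bn(n, seed = 1700 + s, max_inputs = 3)
    mn <- random_refinement(bn, m = 1, seed = s)
    for (x in all_configs(n)) {
      xs <- paste(as.integer(x), collapse = "")
      succ <- mn_successors(mn, xs, "asynchronous")
      gen <- successors(bn, xs, "general")
      expect_true(all(succ %in% gen), info = paste("seed", 1700 + s, xs))
    }
  }
})
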