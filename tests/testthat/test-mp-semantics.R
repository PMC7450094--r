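test_that("can_read frees dynamic components and fixes Boolean ones", {
  bn <- i3ffl()
  expect_true(can_read(bn, 3, "++0", 1))   # x1 read as 0, x2 as 1
  expect_false(can_read(bn, 3, "1+0", 1))  # x1 fixed at 1 blocks f3
  # all-Boolean states reduce to plain evaluation
  for (x in c("000", "010", "110", "111")) {
    for (i in 1:3) {
      expect_equal(can_read(bn, i, x, 1),
                   evaluate_component(bn, i, x) == 1L)
    }
  }
})

test_that("monotone fast-path reads equal exhaustive gamma enumeration", {
  for (s in 1:12) {
    n <- sample(2:5, 1)
    bn <- random_scale_free_bn(n, seed = 600 + s, max_inputs = 4)
    for (code in 0:(4^n - 1)) {
      mp <- (code %/% 4^(0:(n - 1))) %% 4
      for (i in seq_len(n)) {
        for (v in 0:1) {
          expect_equal(can_read(bn, i, mp, v), can_read_ref(bn, i, mp, v),
                       info = sprintf("seed %d state %d i %d v %d",
                                      600 + s, code, i, v))
        }
      }
    }
  }
})

test_that("non-monotone reads fall back to enumeration correctly", {
  bn <- xor2_bn()
  n <- 2
  for (code in 0:(4^n - 1)) {
    mp <- (code %/% 4^(0:(n - 1))) %% 4
    for (i in 1:2) {
      for (v in 0:1) {
        expect_equal(can_read(bn, i, mp, v), can_read_ref(bn, i, mp, v))
      }
    }
  }
})

test_that("MP transitions follow the four-state change rules", {
  bn <- switch3()
  expect_equal(mp_successors(bn, "000"), c("+00", "0+0"))
  # while 1 is increasing and 2 is active, the output can start increasing
  expect_true("+1+" %in% mp_successors(bn, "+10"))
  expect_length(mp_successors(bn, "100"), 0L)
  # dynamic components may always settle at their direction's endpoint
  succ <- mp_successors(bn, "+-0")
  expect_true(all(c("1-0", "+00") %in% succ))
})

test_that("the MP oracle explores the full four-state graph", {
  bn <- switch3()
  expect_equal(mp_reachable_boolean_set_oracle(bn, "000"),
               sort(vapply(all_configs(3), function(x)
                 paste(as.integer(x), collapse = ""), character(1))))
  expect_equal(mp_reachable_boolean_set_oracle(i3ffl(), "110"), "110")
  one <- parse_bnet("x1, x1")
  expect_equal(mp_reachable_boolean_set_oracle(one, "0"), "0")
  expect_error(mp_reachable_boolean_set_oracle(random_scale_free_bn(12, 1),
                                               paste(rep("0", 12), collapse = "")),
               "oracle bound")
})

test_that("mp_reach decides the figure-anchored reachability questions", {
  expect_true(mp_reach(switch3(), "000", "111"))
  expect_true(mp_reach(i3ffl(), "000", "111"))
  expect_true(mp_reach(switch3(), "010", "010"))   # reflexivity
  expect_false(mp_reach(i3ffl(), "110", "000"))
  expect_true(mp_reach_subcube(i3ffl(), "000", "**1"))
  expect_true(mp_reach_subcube(switch3(), "000", "011"))
  expect_true(mp_reach_subcube(switch3(), "011", "0*1"))  # containment
})

test_that("witnesses are phase-ordered three-stage trajectories", {
  bn <- switch3()
  w <- mp_reach(bn, "000", "111", witness = TRUE)
  expect_s3_class(w, "mp_witness")
  expect_true(w$reachable)
  expect_lte(length(w$states), 3 * 3 + 1)
  expect_false(is.unsorted(match(w$phases, c("P1", "P2", "P3"))))
  expect_equal(w$states[1], "000")
  expect_equal(w$states[length(w$states)], "111")
  # consecutive states differ in exactly one component
  for (k in seq_along(w$phases)) {
    a <- strsplit(w$states[k], "")[[1]]
    b <- strsplit(w$states[k + 1], "")[[1]]
    expect_equal(sum(a != b), 1L)
  }
  w0 <- mp_reach(bn, "010", "010", witness = TRUE)
  expect_true(w0$reachable)
  expect_length(w0$phases, 0L)
})

test_that("polynomial mp_reach agrees with the brute-force oracle", {
  for (s in 1:25) {
    n <- sample(3:5, 1)
    bn <- random_scale_free_bn(n, seed = 700 + s, max_inputs = 3)
    oracle <- mpbnet:::mp_boolean_reach_table(bn, max_n = 6)
    for (a in seq_len(2^n)) {
      xa <- mpbnet:::dec_config(a, n)
      for (b in seq_len(2^n)) {
        expect_equal(mp_reach(bn, xa, mpbnet:::dec_config(b, n)),
                     oracle[a, b],
                     info = sprintf("seed %d %d->%d", 700 + s, a, b))
      }
    }
  }
})

test_that("classical generalized dynamics are contained in MP dynamics", {
  for (s in 1:15) {
    n <- sample(3:5, 1)
    bn <- random_scale_free_bn(n, seed = 800 + s, max_inputs = 3)
    for (x in all_configs(n)) {
      xs <- paste(as.integer(x), collapse = "")
      mp <- mp_reachable_boolean_set_oracle(bn, xs)
      expect_true(all(reachable_set(bn, xs, "general") %in% mp),
                  info = paste("seed", 800 + s, "from", xs))
    }
  }
})

test_that("phase-1 saturation is order-independent", {
  for (s in 1:8) {
    n <- sample(3:6, 1)
    bn <- random_scale_free_bn(n, seed = 900 + s, max_inputs = 3)
    perm <- sample(n)
    lines <- vapply(perm, function(i)
      paste0(bn$components[i], ", ",
             mpbnet:::deparse_bnet_expr(bn$functions[[i]])), character(1))
    bn2 <- parse_bnet(lines)
    for (x in all_configs(n)) {
      sat1 <- mpbnet:::mp_saturate(bn, as.integer(x), rep(FALSE, n))
      sat2 <- mpbnet:::mp_saturate(bn2, as.integer(x)[perm], rep(FALSE, n))
      expect_setequal(bn$components[sat1$M], bn2$components[sat2$M])
    }
  }
})
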