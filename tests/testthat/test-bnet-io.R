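test_that("parse_bnet builds the declared components and functions", {
  bn <- parse_bnet("targets, factors\nx1, !x2\nx2, !x1\nx3, x2 & !x1")
  expect_s3_class(bn, "BooleanNetwork")
  expect_equal(bn$components, c("x1", "x2", "x3"))
  expect_equal(evaluate_component(bn, 1, "010"), 0L)
  expect_equal(evaluate_component(bn, 3, "010"), 1L)
  expect_equal(evaluate_component(bn, 3, "110"), 0L)
  expect_equal(evaluate_component(bn, 3, "000"), 0L)

  # header is optional, comments and blank lines are ignored
  bn2 <- parse_bnet(c("# comment", "", "x1, !x2", "x2, !x1", "x3, x2 & !x1"))
  expect_equal(serialize_bnet(bn2), serialize_bnet(bn))
})

test_that("constants and single-component networks parse", {
  bn <- parse_bnet("targets, factors\nx1, 1")
  expect_equal(evaluate_component(bn, 1, "0"), 1L)
  expect_equal(evaluate_component(bn, 1, "1"), 1L)
  bn0 <- parse_bnet("x1, 0")
  expect_equal(evaluate_component(bn0, 1, "1"), 0L)
})

test_that("parse errors carry the offending variable or line", {
  expect_error(parse_bnet("targets, factors\nx1, !x9"), "x9")
  expect_error(parse_bnet("x1, 1\nx1, 0"), "duplicate")
  expect_error(parse_bnet("x1, x1 &"), "line 1")
  expect_error(parse_bnet("x1"), "expected")
  expect_error(parse_bnet("x1, x1 + 1"), "operator")
})

test_that("serialize/parse round-trips the internal representation", {
  texts <- c(
    "x1, (x1 & !x2) | (!x1 & x2)\nx2, x2",
    "a, a & (b | !c)\nb, !(a & c)\nc, 1",
    "n1, n2 | n3 & !n1\nn2, 0\nn3, n1"
  )
  for (txt in texts) {
    bn <- parse_bnet(txt)
    bn2 <- parse_bnet(serialize_bnet(bn))
    expect_equal(bn$components, bn2$components)
    expect_equal(bn$functions, bn2$functions)
  }
  for (s in 1:20) {
    bn <- random_scale_free_bn(sample(2:12, 1), seed = s)
    bn2 <- parse_bnet(serialize_bnet(bn))
    expect_equal(bn$functions, bn2$functions, info = paste("seed", s))
  }
})

test_that("read_bnet loads the shipped fixtures", {
  path <- system.file("extdata", "switch3.bnet", package = "mpbnet")
  bn <- read_bnet(path)
  expect_equal(bn$components, c("x1", "x2", "x3"))
  expect_equal(fixed_points(bn), c("011", "100"))
})

test_that("evaluation agrees with a recursive reference interpreter", {
  for (s in 1:10) {
    n <- sample(2:6, 1)
    bn <- random_scale_free_bn(n, seed = 100 + s, max_inputs = 4)
    for (x in all_configs(n)) {
      for (i in seq_len(n)) {
        expect_equal(evaluate_component(bn, i, x),
                     eval_component_ref(bn, i, x),
                     info = sprintf("seed %d i %d x %s", s, i,
                                    paste(x, collapse = "")))
      }
    }
  }
})

test_that("influence signs match an exhaustive toggle check", {
  bn <- switch3()
  sg <- influence_signs(bn)
  got <- sprintf("%s->%s%s", sg$source, sg$target, sg$sign)
  expect_setequal(got, c("x2->x1-", "x1->x2-", "x2->x3+", "x1->x3-"))
  expect_true(all(sg$exact))

  # brute-force reference on random networks
  for (s in 1:5) {
    n <- sample(2:5, 1)
    bn <- random_scale_free_bn(n, seed = 200 + s, max_inputs = 3)
    sg <- influence_signs(bn)
    for (src in seq_len(n)) {
      for (tgt in seq_len(n)) {
        act <- inh <- FALSE
        for (x in all_configs(n)) {
          if (x[src] == 1) next
          y <- x; y[src] <- 1
          lo <- eval_component_ref(bn, tgt, x)
          hi <- eval_component_ref(bn, tgt, y)
          if (hi > lo) act <- TRUE
          if (hi < lo) inh <- TRUE
        }
        rows <- sg[sg$source == bn$components[src] & sg$target == bn$components[tgt], ]
        expect_equal("+" %in% rows$sign, act)
        expect_equal("-" %in% rows$sign, inh)
      }
    }
  }
})

test_that("XOR inputs carry both signs and break local monotonicity", {
  bn <- xor2_bn()
  sg <- influence_signs(bn)
  x1rows <- sg[sg$target == "x1", ]
  expect_setequal(paste0(x1rows$source, x1rows$sign),
                  c("x1+", "x1-", "x2+", "x2-"))
  expect_false(is_locally_monotonic(bn))
  expect_true(is_locally_monotonic(switch3()))
  expect_true(is_locally_monotonic(parse_bnet("x1, 1")))
})

test_that("a constant function has no incoming influence edges", {
  sg <- influence_signs(i3ffl())
  expect_equal(nrow(sg[sg$target == "x1", ]), 0L)
})

test_that("locally monotonic networks never show dual-signed edges", {
  for (s in 1:20) {
    bn <- random_scale_free_bn(sample(2:8, 1), seed = 300 + s)
    expect_true(is_locally_monotonic(bn))
    sg <- influence_signs(bn)
    key <- paste(sg$source, sg$target)
    expect_false(any(duplicated(key)), info = paste("seed", 300 + s))
  }
})
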