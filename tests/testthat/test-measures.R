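# Point-estimate behaviour of every interaction measure, against hand and
# brute-force oracles.

test_that("two-factor RERI matches hand evaluation and handles null grids", {
  expect_equal(reri2(rr_grid(c("A", "B"), c("10" = 2, "01" = 3, "11" = 6)))$estimate,
               2)  # 6 - 2 - 3 + 1
  expect_equal(reri2(rr_grid(c("A", "B"), c("10" = 2, "01" = 3, "11" = 4)))$estimate,
               0)
  expect_equal(reri2(rr_grid(c("A", "B"), c("10" = 1, "01" = 1, "11" = 1)))$estimate,
               0)
  expect_error(reri2(table2_grid()), class = "rerin_dimensionality_error")
})

test_that("total RERI matches the worked example and direct formula evaluation", {
  expect_equal(tot_reri(table2_grid())$estimate, 1.1790388, tolerance = 1e-6)
  # within two-decimal coefficient rounding of the printed 1.20
  expect_equal(tot_reri(table2_grid())$estimate, 1.20, tolerance = 0.03)

  g <- additive_grid(c(1, 2, 0.5))
  expect_equal(tot_reri(g)$estimate, 0, tolerance = 1e-12)

  # 4-factor grid with RR(S) = 2^|S|: 16 - 4*2 + 3 = 11
  pats <- rerin:::patterns_canonical(4)
  g4 <- rr_grid(paste0("F", 1:4),
                vapply(pats, function(p) 2^length(rerin:::indices_from_pattern(p)),
                       numeric(1)))
  expect_equal(tot_reri(g4)$estimate, 11)
})

test_that("top-order RERI is the inclusion-exclusion sum over all patterns", {
  expect_equal(reri_top(table2_grid())$estimate, 1.9698227, tolerance = 1e-6)
  expect_equal(reri_top(table2_grid())$estimate, 1.98, tolerance = 0.03)

  # brute-force oracle on RR(S) = 2^|S|: sum_k (-1)^(4-k) C(4,k) 2^k = 1
  pats <- rerin:::patterns_canonical(4)
  rrv <- vapply(pats, function(p) 2^length(rerin:::indices_from_pattern(p)),
                numeric(1))
  brute <- sum(vapply(pats, function(p) {
    k <- length(rerin:::indices_from_pattern(p))
    (-1)^(4 - k) * 2^k
  }, numeric(1)))
  expect_equal(brute, 1)
  expect_equal(reri_top(rr_grid(paste0("F", 1:4), rrv))$estimate, brute)

  g2 <- rr_grid(c("A", "B"), c("10" = 2, "01" = 3, "11" = 6))
  expect_identical(reri_top(g2)$estimate, reri2(g2)$estimate)
})

test_that("conditional RERI re-references by the stratum baseline", {
  g <- table2_grid()
  expect_equal(conditional_reri(g, c("lowMD", "highBMI"), c(smoker = 0))$estimate,
               -0.30, tolerance = 0.03)
  expect_equal(conditional_reri(g, c("lowMD", "highBMI"), c(smoker = 1))$estimate,
               1.11, tolerance = 0.03)
  # hand oracle for the present stratum
  rr <- g$rr
  expect_equal(conditional_reri(g, c("lowMD", "highBMI"), c(smoker = 1))$estimate,
               (rr[["111"]] - rr[["101"]] - rr[["011"]] + rr[["001"]]) / rr[["001"]],
               tolerance = 1e-12)

  g2 <- rr_grid(c("A", "B"), c("10" = 2, "01" = 3, "11" = 6))
  expect_equal(conditional_reri(g2, c("A", "B"))$estimate, reri2(g2)$estimate)

  expect_error(conditional_reri(g, c("lowMD", "highBMI"), c(lowMD = 1)),
               class = "rerin_specification_error")
  expect_error(conditional_reri(g, c("lowMD", "highBMI"), numeric(0)),
               class = "rerin_specification_error")
  expect_error(conditional_reri(g, "lowMD", c(highBMI = 0, smoker = 0)),
               class = "rerin_dimensionality_error")
})

test_that("decomposition components sum to the total RERI", {
  d <- decompose(table2_grid())
  expect_length(d, 4L)
  expect_equal(attr(d, "total"), tot_reri(table2_grid())$estimate,
               tolerance = 1e-12)

  expect_true(all(abs(vapply(decompose(additive_grid(c(1, 2, 0.5))),
                             `[[`, numeric(1), "estimate")) < 1e-12))

  set.seed(42)
  g4 <- random_grid(4)
  d4 <- decompose(g4)
  expect_length(d4, 1 + choose(4, 3) + choose(4, 2))  # 11 components
  expect_equal(attr(d4, "total"), tot_reri(g4)$estimate, tolerance = 1e-10)
})

test_that("multiplicative index is the joint-to-product RR ratio", {
  expect_equal(multiplicative_index(rr_grid(c("A", "B"),
               c("10" = 2, "01" = 3, "11" = 6)))$estimate, 1)
  expect_equal(multiplicative_index(rr_grid(c("A", "B"),
               c("10" = 2, "01" = 3, "11" = 12)))$estimate, 2)
  expect_equal(multiplicative_index(rr_grid(c("A", "B"),
               c("10" = 1, "01" = 1, "11" = 1)))$estimate, 1)
  expect_error(multiplicative_index(table2_grid(), "lowMD"),
               class = "rerin_dimensionality_error")
})

test_that("classification follows the sign convention and flags the CI", {
  m <- interaction_measure("RERI_top", c("A", "B", "C"), estimate = 1.98,
                           se = 1.01, lower = 0.00, upper = 3.96)
  expect_equal(as.character(classify(m)), "super-additive")
  expect_false(attr(classify(m), "ci_excludes_zero"))  # CI touches 0

  expect_equal(as.character(classify(interaction_measure("RERI_top", c("A", "B"),
                                                         estimate = 0))),
               "additive")
  m2 <- interaction_measure("RERI_conditional", c("A", "B"), c(C = 0),
                            estimate = -0.30, se = 0.17,
                            lower = -0.64, upper = 0.03)
  expect_equal(as.character(classify(m2)), "sub-additive")
  expect_false(attr(classify(m2), "ci_excludes_zero"))

  m3 <- interaction_measure("RERI_conditional", c("A", "B"), c(C = 1),
                            estimate = 1.31, lower = 0.05, upper = 2.58)
  expect_true(attr(classify(m3), "ci_excludes_zero"))

  expect_error(classify(multiplicative_index(table2_grid())),
               class = "rerin_kind_error")
  # with a tolerance, small departures count as additive
  expect_equal(as.character(classify(interaction_measure("RERI_top", c("A", "B"),
                                                         estimate = 0.05), 0.1)),
               "additive")
})
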