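# Algebraic identities of the measures, exercised on random positive grids.

test_that("decomposition identity holds on random grids (n = 2..6)", {
  set.seed(101)
  for (n in 2:6) {
    for (rep in 1:25) {
      g <- random_grid(n)
      d <- decompose(g)
      expect_equal(attr(d, "total"), tot_reri(g)$estimate,
                   tolerance = 1e-10)
    }
  }
})

test_that("recursion identity links the n-way RERI to (n-1)-way strata", {
  # RERI_n = RERI_{n-1}(.. | X_i = 1) * RR(only i) - RERI_{n-1}(.. | X_i = 0)
  set.seed(202)
  for (n in 3:6) {
    for (rep in 1:10) {
      g <- random_grid(n)
      top <- reri_top(g)$estimate
      for (i in seq_len(n)) {
        others <- setdiff(seq_len(n), i)
        rr_i <- g$rr[[rerin:::pattern_from_indices(i, n)]]
        hi <- conditional_reri(g, others,
                               stats::setNames(1, g$factors[i]))$estimate
        lo <- conditional_reri(g, others,
                               stats::setNames(0, g$factors[i]))$estimate
        expect_equal(hi * rr_i - lo, top, tolerance = 1e-10)
      }
    }
  }
})

test_that("total RERI equals the subset sum of all-absent conditional RERIs", {
  # brute-force oracle: evaluate each component from raw RRs, independent of
  # measure_coef
  set.seed(303)
  for (n in 2:5) {
    g <- random_grid(n)
    brute <- 0
    for (k in 2:n) {
      for (S in utils::combn(n, k, simplify = FALSE)) {
        s_sum <- 0
        for (j in 0:k) {
          subs <- if (j == 0) list(integer(0)) else utils::combn(S, j, simplify = FALSE)
          for (s in subs) {
            s_sum <- s_sum + (-1)^(k - j) *
              g$rr[[rerin:::pattern_from_indices(s, n)]]
          }
        }
        brute <- brute + s_sum
      }
    }
    expect_equal(brute, tot_reri(g)$estimate, tolerance = 1e-10)
  }
})

test_that("n = 2 collapses: reri_top = tot_reri = reri2", {
  set.seed(404)
  for (rep in 1:20) {
    g <- random_grid(2)
    expect_identical(reri_top(g)$estimate, reri2(g)$estimate)
    expect_equal(tot_reri(g)$estimate, reri2(g)$estimate, tolerance = 1e-12)
  }
})

test_that("exactly additive grids yield zero for every RERI measure", {
  set.seed(505)
  for (n in 2:5) {
    e <- stats::runif(n, 0.2, 3)
    g <- additive_grid(e)
    expect_lt(abs(tot_reri(g)$estimate), 1e-12)
    for (m in decompose(g)) expect_lt(abs(m$estimate), 1e-12)
  }
})

test_that("super-multiplicative effects imply super-additive effects", {
  # for grids with all single-factor RRs >= 1:
  #   multiplicative index >= 1 => corresponding RERI >= 0, and
  #   RERI <= 0 => multiplicative index <= 1 (contrapositive)
  set.seed(606)
  checked <- 0L
  for (rep in 1:400) {
    n <- sample(2:4, 1)
    singles <- exp(stats::runif(n, 0, 1))       # all >= 1
    pats <- rerin:::patterns_canonical(n)
    rr <- vapply(pats, function(p) {
      idx <- rerin:::indices_from_pattern(p)
      if (length(idx) == 0) 1
      else if (length(idx) == 1) singles[idx]
      else prod(singles[idx]) * exp(stats::rnorm(1, 0, 0.5))
    }, numeric(1))
    g <- rr_grid(paste0("F", seq_len(n)), rr)
    I <- multiplicative_index(g)$estimate
    tot <- tot_reri(g)$estimate
    if (I >= 1) {
      expect_gte(tot, -1e-12)
      checked <- checked + 1L
    }
    if (tot <= 0) expect_lte(I, 1 + 1e-12)
  }
  expect_gt(checked, 50L)  # the implication was actually exercised
})

test_that("relabelling factors permutes measures and fixes the symmetric ones", {
  set.seed(707)
  for (rep in 1:10) {
    n <- sample(3:5, 1)
    g <- random_grid(n)
    perm <- sample(n)
    # permuted grid: factor j of g2 is factor perm[j] of g
    pats <- names(g$rr)
    new_rr <- stats::setNames(numeric(length(pats)), pats)
    for (p in pats) {
      bits <- as.integer(strsplit(p, "", fixed = TRUE)[[1]])
      old_bits <- integer(n)
      old_bits[perm] <- bits                 # g2 bit j is g bit perm[j]
      new_rr[p] <- g$rr[[paste(old_bits, collapse = "")]]
    }
    g2 <- rr_grid(g$factors[perm], new_rr)
    expect_equal(tot_reri(g2)$estimate, tot_reri(g)$estimate, tolerance = 1e-12)
    expect_equal(reri_top(g2)$estimate, reri_top(g)$estimate, tolerance = 1e-12)
    # a conditional measure maps to the corresponding relabelled one
    S2 <- c(1L, 2L)
    rest2 <- setdiff(seq_len(n), S2)
    z <- stats::setNames(rep(0, length(rest2)), g2$factors[rest2])
    m2 <- conditional_reri(g2, S2, z)$estimate
    S1 <- perm[S2]
    rest1 <- setdiff(seq_len(n), S1)
    z1 <- stats::setNames(rep(0, length(rest1)), g$factors[rest1])
    expect_equal(m2, conditional_reri(g, S1, z1)$estimate, tolerance = 1e-12)
  }
})

test_that("reorientation is an involution that restores risk orientation", {
  g <- rr_grid(c("drugA", "drugB"),
               c("10" = 0.25, "01" = 0.25, "11" = 0.1))
  flagged <- check_risk_orientation(g)
  expect_setequal(flagged$factor, c("drugA", "drugB"))
  expect_equal(flagged$rr, c(0.25, 0.25))

  g2 <- reorient(g, c("drugA", "drugB"))
  expect_equal(unname(g2$rr[c("00", "10", "01", "11")]), c(1, 2.5, 2.5, 10))
  expect_equal(g2$factors, c("no_drugA", "no_drugB"))
  expect_equal(reri2(g2)$estimate, 6)
  expect_identical(nrow(check_risk_orientation(g2)), 0L)

  # involution (flipping back warns: the restored grid is protective again)
  g3 <- suppressWarnings(reorient(g2, c("no_drugA", "no_drugB")))
  expect_equal(g3$factors, g$factors)
  expect_equal(g3$rr, g$rr, tolerance = 1e-12)

  expect_identical(reorient(g, character(0)), g)
  expect_identical(nrow(check_risk_orientation(table2_grid())), 0L)

  set.seed(808)
  for (rep in 1:10) {
    n <- sample(2:4, 1)
    g <- random_grid(n)
    flip <- sample(g$factors, sample(n, 1))
    g2 <- suppressWarnings(reorient(g, flip))
    expect_equal(unname(g2$rr[strrep("0", n)]), 1)
    g3 <- suppressWarnings(reorient(g2, paste0("no_", flip)))
    expect_equal(g3$rr, g$rr, tolerance = 1e-12)
    expect_equal(g3$factors, g$factors)
  }
})
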