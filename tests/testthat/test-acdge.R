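test_that("conditional count pmf matches its closed forms", {
  for (N in c(10, 1000, 125456)) {
    expect_equal(ac_pmf(0, 0, N, N), 0.5)
    expect_equal(ac_pmf(1, 1, N, N), 0.25)
  }
  # factorial form vs negative-binomial form, direct evaluation of both
  expect_equal(ac_pmf(3, 5, 1000, 2000), dnbinom(3, size = 6, prob = 1/3),
               tolerance = 1e-12)
  ys <- 0:50
  expect_equal(ac_pmf(ys, 17, 99632, 125456),
               dnbinom(ys, size = 18, prob = 99632/225088),
               tolerance = 1e-12)
  expect_error(ac_pmf(1, 1, 0, 10), "positive")
  expect_error(ac_pmf(-1, 1, 10, 10), "non-negative")
})

test_that("pmf sums to one over its support", {
  for (x in c(0, 3, 25, 100)) {
    for (r in c(1, 2, 125456 / 99632)) {
      Y <- ceiling(50 * (x + 1) * max(1 / r, 1))
      s <- sum(ac_pmf(0:Y, x, 125456, 125456 / r))
      expect_equal(s, 1, tolerance = 1e-12)
    }
  }
})

test_that("one-tailed test conditions on the larger count and handles edges", {
  # closed form: x = 2, y = 0, equal totals -> (1/2)^3
  r <- ac_test(2, 0, 100, 100)
  expect_equal(r$p_value, 0.125)
  expect_identical(r$direction, "down")

  # degenerate zero-zero contig
  z <- ac_test(0, 0, 100, 200)
  expect_equal(z$p_value, 1)
  expect_identical(z$direction, "tie")
  expect_equal(z$ratio, 1)
  expect_false(z$significant)

  # zero on one side: infinite ratio, direction from relative frequencies
  i <- ac_test(0, 5, 125456, 99632)
  expect_identical(r$direction, "down")
  expect_identical(i$direction, "up")
  expect_equal(i$ratio, Inf)
  expect_equal(i$rel_d, 0)
})

test_that("relative frequencies and ratios follow their definitions", {
  tot <- physarum_library_totals()
  r <- ac_test(40, 1, tot["n_d"], tot["n_l"])
  expect_equal(r$rel_d, 40 / 125456)
  expect_equal(r$rel_l, 1 / 99632)
  expect_equal(r$ratio, (40 / 125456) / (1 / 99632))
  u <- ac_test(1, 37, tot["n_d"], tot["n_l"])
  expect_equal(u$ratio, (37 / 99632) / (1 / 125456))
})

test_that("extreme imbalance stays finite on the log scale", {
  tot <- physarum_library_totals()
  r <- ac_test(23, 813, tot["n_d"], tot["n_l"])
  expect_gt(r$p_value, 0)
  expect_equal(r$log10_p, -249.2693864337893, tolerance = 1e-10)
  # far below double underflow the linear value is 0 but log10_p is exact
  h <- ac_test(1, 5000, 125456, 99632)
  expect_identical(h$p_value, 0)
  expect_true(is.finite(h$log10_p))
  expect_lt(h$log10_p, -320)
})

test_that("log-space tail agrees with high-precision reference values", {
  # frozen from 60-digit arbitrary-precision direct summation of the pmf
  ref <- list(
    list(x = 40, y = 1, n1 = 125456, n2 = 99632, l10 = -9.12617220947545680),
    list(x = 68, y = 2, n1 = 125456, n2 = 99632, l10 = -14.81336559584223468),
    list(x = 813, y = 23, n1 = 99632, n2 = 125456, l10 = -249.26938643378929960),
    list(x = 100, y = 100, n1 = 1000, n2 = 500, l10 = -2.401974091921997455e-7),
    list(x = 200, y = 0, n1 = 100, n2 = 100, l10 = -60.50702912846022024),
    list(x = 5, y = 3, n1 = 1000, n2 = 2000, l10 = -1.37240481699335985),
    list(x = 171, y = 3, n1 = 99632, n2 = 125456, l10 = -55.69210733215203604))
  for (cs in ref) {
    got <- dgepair:::ac_logp_tail(cs$y, cs$x, cs$n1, cs$n2) / log(10)
    if (abs(cs$l10) > 1e-3) {
      expect_lt(abs(got - cs$l10) / abs(cs$l10), 1e-9)
    } else {
      # p ~ 1: the log is smaller than double cancellation error, so
      # compare on the probability scale instead
      expect_equal(10^got, 10^cs$l10, tolerance = 1e-12)
    }
  }
})

test_that("library swap flips direction and preserves the p-value exactly", {
  set.seed(11)
  a <- rpois(300, 20); b <- rpois(300, 10)
  r1 <- suppressWarnings(ac_test(a, b, 5000, 4000))
  r2 <- suppressWarnings(ac_test(b, a, 4000, 5000))
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$log10_p, r2$log10_p)
  flip <- c(down = "up", up = "down", tie = "tie")
  expect_identical(unname(flip[r1$direction]), r2$direction)
})

test_that("the tail p-value decreases as the minority count drops", {
  p <- ac_test(rep(100, 11), 0:10, 10000, 10000)$p_value
  expect_true(all(diff(p) > 0))
})

test_that("significance is a strict inequality at alpha", {
  de <- ac_test(2, 0, 100, 100)  # p = 0.125 exactly
  expect_false(classify_de(de, alpha = 0.125)$significant)
  expect_true(classify_de(de, alpha = 0.1250001)$significant)
  expect_error(classify_de(de, alpha = 0))
})

test_that("raw-count vs relative-frequency disagreement warns, ties do not", {
  expect_warning(ac_test(5, 4, 125456, 99632), "different libraries")
  expect_no_warning(ac_test(2, 2, 125456, 99632))
  expect_no_warning(ac_test(10, 2, 125456, 99632))
})

test_that("counts exceeding their library total are rejected", {
  expect_error(ac_test(101, 0, 100, 100), "exceeds")
  expect_error(ac_test(1, 2, 100, 1), "exceeds")
})
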