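test_that("longest flanking match equals the longest common substring", {
  expect_identical(longest_flanking_match("AAAA", "CCCC"), 0L)
  expect_identical(longest_flanking_match("ACGT", "CGTA"), 3L)
  ten <- strrep("ACGTACGTAC", 1)
  expect_identical(longest_flanking_match(ten, ten), 10L)
  expect_error(longest_flanking_match("", "ACGT"), "empty window")
})

test_that("flanking match agrees with a dynamic-programming oracle on an
           exhaustive reduced-alphabet set", {
  lcs_dp <- function(a, b) {
    A <- strsplit(a, NULL)[[1]]; B <- strsplit(b, NULL)[[1]]
    best <- 0L; prev <- integer(length(B))
    for (i in seq_along(A)) {
      cur <- integer(length(B))
      for (j in seq_along(B)) {
        if (A[i] == B[j]) cur[j] <- (if (j > 1) prev[j - 1] else 0L) + 1L
      }
      best <- max(best, cur); prev <- cur
    }
    best
  }
  mers <- do.call(paste0, expand.grid(rep(list(c("A", "C")), 6)))
  set.seed(2)
  pairs <- cbind(sample(mers, 1500, TRUE), sample(mers, 1500, TRUE))
  for (r in seq_len(nrow(pairs))) {
    expect_identical(longest_flanking_match(pairs[r, 1], pairs[r, 2]),
                     lcs_dp(pairs[r, 1], pairs[r, 2]))
  }
})

test_that("microhomology window splits n around the cut site", {
  q <- microhomology_query("AACCGGTTAACC", cut = 6, n = 8)
  expect_identical(q$left_flank, "CCGG")
  expect_identical(q$right_flank, "TTAA")
  expect_identical(q$M, longest_flanking_match("CCGG", "TTAA"))
})

test_that("closed-form bounds evaluate and clamp correctly", {
  expect_equal(p_upper_bound_M_le_L(100, 1, 0.25), 0.00306, tolerance = 1e-2)
  # p^(2 log_{1/p} n) = n^-2 analytically; check against the identity
  p <- 0.25; n <- 100; L <- 1
  lg <- log(n) / log(1 / p)
  expect_equal(p_upper_bound_M_le_L(n, L, p),
               (1 + p) / (1 - p) * (1 - 2 * lg / n)^(-2) * n^(-2) * p^(-L - 1))
  expect_identical(p_upper_bound_M_le_L(4, 1, 0.25), 1)   # raw value > 1
  expect_equal(p_lower_bound_M_le_L(100, 10, 0.25), 0.99762, tolerance = 1e-4)
  expect_identical(p_lower_bound_M_le_L(100, 1, 0.25), 0)  # raw value < 0
  # at very small p the exponent 2 log_{1/p}(n) - L - 1 goes negative and
  # the raw bound diverges; the clamp keeps it a probability
  expect_identical(p_upper_bound_M_le_L(100, 1, 0.01), 1)
  expect_error(p_upper_bound_M_le_L(1, 1, 0.25), "bound undefined")
})

test_that("MMEJ lower bound reaches 99.7% at 100 bp and grows with n", {
  expect_identical(signif(mmej_probability_lower_bound(100), 3), 0.997)
  vals <- mmej_probability_lower_bound(20:300)
  expect_true(all(diff(vals) >= -1e-12))
  # where the P(M<=1) upper bound clamps to 1, the MMEJ bound collapses to 0
  expect_identical(mmej_probability_lower_bound(6), 0)
})

test_that("the curve is the element-wise scalar bound", {
  ns <- c(20, 50, 100, 200)
  cv <- mmej_curve(ns)
  expect_s3_class(cv, "mmej_curve")
  expect_equal(cv$p_mmej, vapply(ns, mmej_probability_lower_bound, 1))
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("Monte-Carlo ratio behaves at small n and in degenerate cases", {
  r <- simulate_M_ratio(16, reps = 200, seed = 3)
  expect_gt(r$mean_ratio, 0)
  expect_true(is.finite(r$se_ratio))
  # p = 1: single-letter alphabet, M is the whole flank
  d <- simulate_M_ratio(16, reps = 100, seed = 3, p = 1, flank_len = 8)
  expect_equal(d$mean_M, 8)
  # determinism
  expect_identical(simulate_M_ratio(64, 150, seed = 9),
                   simulate_M_ratio(64, 150, seed = 9))
})

test_that("larger regions push the ratio toward the limit of 2", {
  r1 <- simulate_M_ratio(2^8, reps = 200, seed = 4)
  r2 <- simulate_M_ratio(2^12, reps = 200, seed = 4)
  expect_lt(abs(r2$mean_ratio - 2), abs(r1$mean_ratio - 2))
})
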