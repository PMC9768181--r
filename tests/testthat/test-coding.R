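# Discretization, incremental/dummy coding, coding-matrix recovery.

test_that("discretization maps values into half-open bins with clamping", {
  v <- qc_variable("age", "continuous-discretized",
                   bin_edges = c(18, 35, 50, 65, 120))
  expect_identical(discretize(40, v), 2L)
  expect_identical(discretize(35, v), 2L)      # interior edge -> upper bin
  expect_identical(discretize(c(20, 70), v), c(1L, 4L))
  expect_identical(discretize(c(18, 119.9, 120), v), c(1L, 4L, 4L))
  expect_warning(lo <- discretize(10, v), "clamped")
  expect_identical(lo, 1L)
  expect_warning(hi <- discretize(150, v), "clamped")
  expect_identical(hi, 4L)
  expect_error(discretize(c(30, NA), v), "row 2")
  expect_error(discretize(Inf, v), "non-finite")
})

test_that("incremental coding rows and bounds follow the constraint case", {
  inc_pos <- encode_incremental(1:4, 4, qc_constraint("increasing", "positive"))
  expect_equal(inc_pos$ref_end, 1L)
  expect_equal(unname(inc_pos$Z[1, ]), c(0, 0, 0))   # reference end: zero row
  expect_equal(unname(inc_pos$Z[3, ]), c(1, 1, 0))
  expect_equal(inc_pos$bounds, c("ge", "ge", "ge"))

  dec_neg <- encode_incremental(1:4, 4, qc_constraint("decreasing", "negative"))
  expect_equal(dec_neg$ref_end, 1L)
  expect_equal(unname(dec_neg$Z[4, ]), c(1, 1, 1))
  expect_equal(dec_neg$bounds, c("le", "le", "le"))

  # sign-monotonicity combinations force the reference end
  inc_neg <- encode_incremental(1:4, 4, qc_constraint("increasing", "negative"))
  expect_equal(inc_neg$ref_end, 4L)
  expect_equal(unname(inc_neg$Z[4, ]), c(0, 0, 0))
  expect_error(
    encode_incremental(1:4, 4, qc_constraint("increasing", "positive"),
                       reference = 4),
    "requires the reference")

  # monotone-unrestricted: first step free
  inc_un <- encode_incremental(1:4, 4, qc_constraint("increasing", "unrestricted"))
  expect_equal(inc_un$bounds, c("free", "ge", "ge"))
  expect_error(encode_incremental(1:2, 1, qc_constraint("increasing", "positive")))
})

test_that("dummy coding is one-hot minus reference with shared sign bound", {
  d <- encode_dummy(c(1, 3, 2), 3, reference = 1, sign = "positive")
  expect_equal(unname(d$Z[1, ]), c(0, 0))
  expect_equal(unname(d$Z[2, ]), c(0, 1))
  expect_equal(d$bounds, c("ge", "ge"))
  d2 <- encode_dummy(1:3, 3, reference = 2)
  expect_equal(unname(d2$Z[2, ]), c(0, 0))
  expect_equal(d2$non_ref, c(1L, 3L))
})

test_that("coefficients recover through the coding matrix (cumsum oracle)", {
  A <- step_coding_matrix(4, 1L)            # lower-triangular ones
  expect_equal(recover_coefficients(c(1, 2, 3), A), c(1, 3, 6))
  expect_equal(recover_coefficients(c(0, 0, 0), A), c(0, 0, 0))
  set.seed(3)
  for (K in 2:6) for (ref in c(1L, K)) {
    A <- step_coding_matrix(K, ref)
    zeta <- rnorm(K - 1)
    beta <- recover_coefficients(zeta, A)
    expect_equal(solve(A, beta), zeta, tolerance = 1e-12)
  }
  expect_error(recover_coefficients(c(1, 2), step_coding_matrix(4, 1L)),
               "does not match")
})

test_that("every Table-style case yields curves with the declared shape and sign", {
  set.seed(11)
  for (case in all_monotone_cases()) {
    for (K in 2:6) {
      enc <- encode_incremental(1:K, K, case)
      for (r in 1:40) {
        zeta <- random_feasible_zeta(K, enc$bounds)
        e <- curve_from_beta(recover_coefficients(zeta, enc$A), K, enc$ref_end)
        # independent enumeration oracle for the curve
        expect_equal(e, curve_by_enumeration(zeta, K, enc$ref_end),
                     tolerance = 1e-12)
        lev <- setdiff(seq_len(K), enc$ref_end)
        non_ref <- e[lev]
        if (case$sign != "unrestricted") {
          # full-curve monotonicity (reference included)
          if (case$monotonicity == "increasing") {
            expect_true(all(diff(e) >= -1e-12))
          } else {
            expect_true(all(diff(e) <= 1e-12))
          }
          if (case$sign == "positive") expect_true(all(e >= -1e-12))
          if (case$sign == "negative") expect_true(all(e <= 1e-12))
        } else {
          # monotone over the non-reference levels; position free
          dd <- diff(non_ref[order(lev)])
          if (case$monotonicity == "increasing") {
            expect_true(all(dd >= -1e-12))
          } else {
            expect_true(all(dd <= 1e-12))
          }
        }
      }
    }
  }
})

test_that("monotone signed step curves are exactly representable (reverse map)", {
  set.seed(12)
  for (case in all_monotone_cases()[1:4]) {
    for (K in 2:6) {
      enc <- encode_incremental(1:K, K, case)
      # build a random curve with the declared shape/sign, pinned at ref
      steps <- runif(K - 1, 0, 1.5)
      if (case$monotonicity == "decreasing") steps <- -steps
      e <- c(0, cumsum(steps))                # increasing or decreasing from 0
      if (case$sign == "positive" && case$monotonicity == "increasing")
        e <- e                                # ref first
      if (case$sign == "negative" && case$monotonicity == "decreasing")
        e <- e
      if (enc$ref_end == K) e <- e - e[K]     # pin at last level instead
      beta <- e[setdiff(seq_len(K), enc$ref_end)]
      zeta <- solve(enc$A, beta)
      ok <- (enc$bounds == "free") |
        (enc$bounds == "ge" & zeta >= -1e-12) |
        (enc$bounds == "le" & zeta <= 1e-12)
      expect_true(all(ok))
    }
  }
})

test_that("unconstrained dummy and incremental codings span the same space", {
  dat <- tiny_survey(n = 120, seed = 5)
  v <- qc_variable("x1", "ordinal", n_levels = 3)
  lev <- dat$x1
  Zd <- encode_dummy(lev, 3, reference = 1)$Z
  Zi <- encode_incremental(lev, 3, qc_constraint("increasing", "unrestricted"))$Z
  # identical column spans => identical OLS fitted values
  f1 <- lm.fit(cbind(1, Zd), dat$z)$fitted.values
  f2 <- lm.fit(cbind(1, Zi), dat$z)$fitted.values
  expect_equal(f1, f2, tolerance = 1e-10)
})
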