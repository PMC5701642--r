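test_that("localization picks the maximal node with a deterministic tie-break", {
  sc <- data.frame(
    node_id = 1:4, x = c(0, 1, 2, 3), y = 0, z = 0,
    constraint = "unit_array_gain",
    variance_output = c(1, 5, 3, 2), kurtosis_output = c(0, 1, 4, 4),
    ori_x = 1, ori_y = 0, ori_z = 0, skipped = FALSE
  )
  lv <- localize(sc, "variance", truth = c(1, 0, 0))
  expect_equal(lv$estimated_node, 2)
  expect_equal(lv$error, 0)
  expect_false(lv$tie)
  lk <- localize(sc, "kurtosis")
  expect_equal(lk$estimated_node, 3) # tie with node 4: lowest index wins
  expect_true(lk$tie)
  sc$skipped <- TRUE
  expect_error(localize(sc, "variance"), "degenerate")
  # skipped nodes never win
  sc$skipped <- c(FALSE, TRUE, FALSE, FALSE)
  expect_equal(localize(sc, "variance")$estimated_node, 3)
})

test_that("localization error is the symmetric Euclidean distance", {
  expect_equal(localization_error(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(localization_error(c(1, 1, 1), c(1, 1, 1)), 0)
  a <- c(2, -1, 7); b <- c(-3, 0.5, 2)
  expect_equal(localization_error(a, b), localization_error(b, a))
})

test_that("the error summary follows the median-anchored whisker rule", {
  s <- tukey_summary(1:9)
  expect_equal(s$median, 5)
  expect_equal(s$q1, 3) # type-7 linear interpolation
  expect_equal(s$q3, 7)
  expect_equal(s$whisker_low, 1) # fences 5 +/- 6 cover everything
  expect_equal(s$whisker_high, 9)
  expect_length(s$outliers, 0)

  s2 <- tukey_summary(rep(4.2, 6))
  expect_equal(c(s2$q1, s2$median, s2$q3), rep(4.2, 3))
  expect_length(s2$outliers, 0)

  # a far point is an outlier and only its display value is capped
  e <- c(4, 4, 5, 5, 5, 6, 6, 120)
  s3 <- tukey_summary(e)
  expect_true(120 %in% s3$outliers)
  expect_equal(max(s3$outliers_capped), 40)
  expect_equal(max(s3$outliers), 120) # stored statistics never capped
  # conservation: outliers + in-whisker points = n
  inside <- sum(e >= s3$whisker_low & e <= s3$whisker_high)
  expect_equal(inside + length(s3$outliers), length(e))

  # the conventional quartile-anchored rule is available and differs:
  # with q1=3, median=5, q3=7, the value 12 sits between median+1.5*IQR (11)
  # and q3+1.5*IQR (13)
  e2 <- c(1, 2, 3, 4, 5, 6, 7, 8, 12)
  sm <- tukey_summary(e2, whisker_anchor = "median")
  sq <- tukey_summary(e2, whisker_anchor = "quartile")
  expect_equal(sm$outliers, 12)
  expect_length(sq$outliers, 0)
  expect_error(tukey_summary(numeric(0)), "non-empty")
})
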