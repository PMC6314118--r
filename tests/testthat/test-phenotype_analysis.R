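test_that("fatty acid shorthand parses strictly", {
  fa <- fatty_acid("18:3Δ9,12,15")
  expect_equal(fa$chain, 18)
  expect_equal(fa$bonds, c(9L, 12L, 15L))
  expect_equal(fatty_acid("16:1d9")$bonds, 9L)
  expect_equal(fatty_acid("17:0")$bonds, integer(0))
  expect_error(fatty_acid("18:2Δ9"), "does not match")
  expect_error(fatty_acid("18:2Δ12,9"), "cannot parse|increasing")
  expect_error(fatty_acid("18:1Δ18"), "outside")
  expect_error(fatty_acid("banana"), "cannot parse")
})

test_that("quantify implements internal-standard normalization", {
  pt <- peak_table("s", a600 = 1,
                   species = c("18:2Δ9,12", "17:0"),
                   area = c(2000, 1000), istd_mass = 5)
  res <- quantify(pt)
  expect_equal(unname(res$yields[["18:2Δ9,12"]]), 10)  # 2 x 5 ug / 1 A600
  expect_equal(res$product_activity, 10)

  # all product areas zero
  pt0 <- peak_table("z", 1, c("18:2Δ9,12", "18:3Δ9,12,15", "17:0"),
                    c(0, 0, 1000))
  expect_equal(quantify(pt0)$product_activity, 0)

  # monoene and saturates are not products by default
  pt1 <- peak_table("m", 2, c("16:0", "18:1Δ9", "18:2Δ9,12", "17:0"),
                    c(500, 800, 400, 1000))
  res1 <- quantify(pt1)
  expect_equal(res1$product_activity,
               unname(res1$yields[["18:2Δ9,12"]]))

  expect_error(quantify(peak_table("b", 1, c("18:2Δ9,12", "17:0"),
                                   c(10, 0))), "internal-standard area")
  expect_error(peak_table("b", 0, c("17:0"), 10), "positive")
  expect_error(peak_table("b", 1, c("18:2Δ9,12"), 10),
               "internal-standard row")
})

test_that("quantify is invariant to a common area scale factor", {
  pt <- peak_table("s", 1.7, c("16:0", "18:2Δ9,12", "18:3Δ9,12,15", "17:0"),
                   c(300, 123, 456, 789))
  base <- quantify(pt)
  for (k in c(0.01, 3, 1e4)) {
    scaled <- peak_table("s", 1.7,
                         c("16:0", "18:2Δ9,12", "18:3Δ9,12,15", "17:0"),
                         k * c(300, 123, 456, 789))
    got <- quantify(scaled)
    expect_equal(got$yields, base$yields, tolerance = 1e-12)
    expect_equal(got$ala_fraction, base$ala_fraction, tolerance = 1e-12)
  }
})

test_that("ala_fraction is the ALA/(ALA+LA) ratio with an undefined flag", {
  expect_equal(ala_fraction(86, 14), 0.86)
  expect_equal(ala_fraction(0, 5), 0)
  expect_true(is.na(ala_fraction(0, 0)))
  expect_error(ala_fraction(-1, 5))
  # monotone in both arguments
  set.seed(3)
  for (rep in 1:20) {
    a <- runif(1, 0, 10); l <- runif(1, 0.1, 10); d <- runif(1, 0.1, 2)
    expect_gt(ala_fraction(a + d, l), ala_fraction(a, l))
    expect_lt(ala_fraction(a, l + d), ala_fraction(a, l))
    expect_true(ala_fraction(a, l) >= 0 && ala_fraction(a, l) <= 1)
  }
})

test_that("classify_variant applies the activity and ratio thresholds", {
  mk <- function(total, frac) {
    pt <- peak_table("x", 1, c("18:2Δ9,12", "18:3Δ9,12,15", "17:0"),
                     c(total * (1 - frac) * 100, total * frac * 100, 500))
    quantify(pt)
  }
  ref <- mk(10, 0.86)
  expect_equal(classify_variant(mk(25, 0.86), ref), "increased_activity")
  expect_equal(classify_variant(mk(10, 0.40), ref), "ratio_shifted")
  lof <- quantify(peak_table("lof", 1,
                             c("18:2Δ9,12", "18:3Δ9,12,15", "17:0"),
                             c(0, 0, 500)))
  expect_true("loss_of_function" %in% classify_variant(lof, ref))
  expect_equal(classify_variant(mk(11, 0.80), ref), character(0))
})

test_that("predict_product implements v+3 and omega-3 counting", {
  expect_equal(predict_product("18:1Δ9", "v_plus_3")$shorthand, "18:2Δ9,12")
  expect_equal(predict_product("16:2Δ9,12", "v_plus_3")$shorthand,
               "16:3Δ9,12,15")
  expect_equal(predict_product("16:2Δ9,12", "omega3")$shorthand,
               "16:3Δ9,12,13")
  expect_equal(predict_product("18:2Δ9,12", "omega3")$shorthand,
               "18:3Δ9,12,15")
  expect_error(predict_product("18:0", "v_plus_3"), "existing double bond")
  # infeasible: position occupied or beyond the chain
  expect_error(predict_product("16:1Δ13", "omega3"), class = "fadscan_infeasible")
  expect_error(predict_product("16:1Δ14", "v_plus_3"),
               class = "fadscan_infeasible")
})

test_that("infer_rule discriminates the two counting mechanisms", {
  expect_equal(infer_rule("18:2Δ9,12", "18:3Δ9,12,15"), "ambiguous")
  expect_equal(infer_rule("16:2Δ9,12", "16:3Δ9,12,15"), "v_plus_3")
  expect_equal(infer_rule("16:2Δ9,12", "16:3Δ9,12,13"), "omega3")
  # a bond neither rule predicts is reported as matching neither
  expect_equal(infer_rule("16:2Δ9,12", "16:3Δ8,9,12"), "none")
  expect_error(infer_rule("16:2Δ9,12", "18:3Δ9,12,15"), "derivative")
  expect_error(infer_rule("16:2Δ9,12", "16:2Δ9,13"), "derivative")
})

test_that("rule round trip: ambiguity exactly when last bond is chain - 6", {
  set.seed(10)
  for (rep in 1:100) {
    chain <- sample(c(14, 16, 18, 20, 22), 1)
    last <- sample(4:(chain - 5), 1)
    sub <- new_sub <- sprintf("%d:1Δ%d", chain, last)
    for (rule in c("v_plus_3", "omega3")) {
      prod <- tryCatch(predict_product(sub, rule),
                       fadscan_infeasible = function(e) NULL)
      if (is.null(prod)) next
      got <- infer_rule(sub, prod)
      if (last == chain - 6) {
        expect_equal(got, "ambiguous", info = sub)
      } else {
        expect_equal(got, rule, info = paste(sub, rule))
      }
    }
  }
})

test_that("peak tables round-trip through CSV", {
  demo <- fm1_demo(seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_tables(demo$tables, path)
  back <- read_peak_tables(path)
  expect_equal(length(back), length(demo$tables))
  for (id in names(demo$tables)) {
    expect_equal(back[[id]]$rows$area, demo$tables[[id]]$rows$area,
                 tolerance = 1e-6)
    expect_equal(quantify(back[[id]])$product_activity,
                 quantify(demo$tables[[id]])$product_activity,
                 tolerance = 1e-6)
  }
})
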