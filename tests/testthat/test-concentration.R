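test_that("parse_concentration recognizes the published dialects", {
  r <- parse_concentration("0.50% of essential oil")
  expect_true(r$determined)
  expect_equal(c(r$low, r$high), c(0.5, 0.5))
  expect_identical(r$unit, "percent_w_w")
  expect_identical(r$basis, "essential oil")

  r2 <- parse_concentration("0.018 to 0.64 mg/g of oil")
  expect_equal(c(r2$low, r2$high), c(0.018, 0.64))
  expect_identical(r2$unit, "mg_per_g")
  expect_identical(r2$basis, "oil")

  expect_false(parse_concentration("ND")$determined)
  expect_false(parse_concentration("Not determined")$determined)
  expect_false(parse_concentration("not determined")$determined)
})

test_that("en dash, hyphen and 'to' all separate ranges", {
  for (s in c("109–135 ppm of gel", "109-135 ppm of gel",
              "109 to 135 ppm of gel", "109-135ppm of gel")) {
    r <- parse_concentration(s)
    expect_equal(c(r$low, r$high), c(109, 135), info = s)
    expect_identical(r$unit, "ppm", info = s)
    expect_identical(r$basis, "gel", info = s)
  }
})

test_that("unrecognized reports fail loudly, naming the text", {
  expect_error(parse_concentration("plenty of it"), "plenty of it")
  expect_error(parse_concentration("5 mol/L of sap"), "5 mol/L")
})

test_that("to_ppm applies the declared conversion factors", {
  expect_equal(to_ppm(parse_concentration("0.50% of essential oil"))$value,
               5000)
  expect_equal(to_ppm(parse_concentration("1.1–2.0 mg/g of rhizome"))$value,
               1550)
  expect_equal(to_ppm(parse_concentration("109–135 ppm of gel"))$value, 122)
  expect_identical(
    to_ppm(parse_concentration("109–135 ppm of gel"))$provenance,
    "range_midpoint")
  expect_identical(to_ppm(parse_concentration("97.32% of oil"))$provenance,
                   "point")
  expect_true(is_undetermined(to_ppm(parse_concentration("ND"))))
})

test_that("X percent converts identically to 10 X mg/g, and ppm is identity", {
  set.seed(11)
  for (x in round(10^runif(20, -2, 1.5), 4)) {
    pct <- to_ppm(hm_concentration("x", TRUE, x, x, "percent_w_w"))$value
    mgg <- to_ppm(hm_concentration("x", TRUE, 10 * x, 10 * x,
                                   "mg_per_g"))$value
    expect_equal(pct, mgg)
  }
  expect_equal(to_ppm(hm_concentration("x", TRUE, 37.5, 37.5, "ppm"))$value,
               37.5)
})

test_that("conversion is monotone in the rubric's concentration points", {
  set.seed(23)
  units <- c("percent_w_w", "mg_per_g", "ppm")
  reports <- lapply(1:60, function(i) {
    lo <- 10^runif(1, -4, 2)
    hi <- lo * runif(1, 1, 3)
    hm_concentration("x", TRUE, lo, hi, sample(units, 1))
  })
  mids <- vapply(reports, function(r) to_ppm(r)$value, 0)
  pts <- vapply(reports, function(r) {
    v <- to_ppm(r)$value
    as.integer(v >= 5) + as.integer(v >= 50)
  }, 0L)
  ord <- order(mids)
  expect_true(all(diff(pts[ord]) >= 0))
})

test_that("fixture concentration strings survive parse-format-parse", {
  fx <- hm_fixture_dataset()
  for (rec in fx$compounds) {
    r1 <- rec$concentration
    r2 <- parse_concentration(format_concentration(r1))
    expect_identical(r2$determined, r1$determined, info = rec$compound_id)
    expect_equal(r2$low, r1$low, info = rec$compound_id)
    expect_equal(r2$high, r1$high, info = rec$compound_id)
    expect_identical(r2$unit, r1$unit, info = rec$compound_id)
    expect_identical(r2$basis, r1$basis, info = rec$compound_id)
  }
})
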