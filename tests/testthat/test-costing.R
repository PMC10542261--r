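test_that("unit costs divide price by pack size, half-up to one decimal", {
  expect_equal(unit_cost("x", hm_standard_listing("S", "~95%", 0.5, "mg",
                                                  249))$rounded, 498.0)
  uc <- unit_cost("x", hm_standard_listing("S", ">=95%", 100, "mg", 63.9))
  expect_equal(uc$cost_per_unit, 0.639)
  expect_equal(uc$rounded, 0.6)
  expect_equal(unit_cost("x", hm_standard_listing("S", ">=98%", 5, "mg",
                                                  70))$rounded, 14.0)
  # half-up, not banker's: 12.65 -> 12.7
  expect_equal(unit_cost("x", hm_standard_listing("S", "p", 20, "mg",
                                                  253))$rounded, 12.7)
  expect_error(unit_cost("x", hm_standard_listing("S", "g", 0, "mg", 10)),
               "pack_value")
})

test_that("the denomination follows the listing's own pack unit", {
  uc <- unit_cost("x", hm_standard_listing("S", ">=95%", 10, "g", 68.3))
  expect_identical(uc$unit, "g")
  expect_equal(uc$rounded, 6.8)
})

test_that("cost_summary pools listings, with sane degenerate behaviour", {
  plant <- test_plant()
  two <- record_for(1, 0, 0, 0, 1, 0)
  two$standards <- list(hm_standard_listing("A", "g", 1, "mg", 10),
                        hm_standard_listing("B", "g", 1, "mg", 20))
  doc <- hm_dataset(plants = list(plant), compounds = list(two))
  cs <- cost_summary(doc)
  expect_identical(cs$n, 2L)
  expect_equal(cs$mean, 15.0)
  expect_equal(cs$sd, sqrt(50), tolerance = 1e-12)

  one <- two
  one$standards <- one$standards[1]
  cs1 <- cost_summary(hm_dataset(plants = list(plant),
                                 compounds = list(one)))
  expect_identical(cs1$n, 1L)
  expect_true(cs1$single_listing)
  expect_equal(cs1$sd, 0)
  expect_equal(cs1$mean, 10)

  none <- two
  none$standards <- list()
  expect_error(cost_summary(hm_dataset(plants = list(plant),
                                       compounds = list(none))),
               "no priced listings")
})

test_that("scaling every price by k scales the unrounded summary by k", {
  fx <- hm_fixture_dataset()
  base <- cost_summary(fx, use_rounded = FALSE)
  k <- 3.7
  scaled_doc <- fx
  scaled_doc$compounds <- lapply(fx$compounds, function(rec) {
    rec$standards <- lapply(rec$standards, function(s) {
      s$price_eur <- s$price_eur * k
      s
    })
    rec
  })
  scaled <- cost_summary(scaled_doc, use_rounded = FALSE)
  expect_equal(scaled$minimum, k * base$minimum)
  expect_equal(scaled$maximum, k * base$maximum)
  expect_equal(scaled$mean, k * base$mean)
  expect_equal(scaled$sd, k * base$sd)
})

test_that("fixture summary matches a listing-by-listing recomputation", {
  fx <- hm_fixture_dataset()
  # independent spreadsheet-style oracle: walk the raw listings directly
  vals <- c()
  owner <- c()
  for (rec in fx$compounds) {
    for (s in rec$standards) {
      vals <- c(vals, floor(s$price_eur / s$pack_value * 10 + 0.5) / 10)
      owner <- c(owner, rec$compound_id)
    }
  }
  cs <- cost_summary(fx)
  expect_identical(cs$n, length(vals))
  expect_equal(cs$minimum, min(vals))
  expect_equal(cs$maximum, max(vals))
  expect_equal(cs$mean, mean(vals))
  expect_equal(cs$sd, sd(vals))
  expect_identical(cs$argmin, owner[which.min(vals)])
  expect_identical(cs$argmax, owner[which.max(vals)])
  # the per-denomination breakdown partitions the pooled listings
  expect_identical(sum(cs$by_unit$n), cs$n)
})
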