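test_that("rubric totals match the published verdicts for key dossiers", {
  fx <- hm_fixture_dataset()
  expect_identical(score_components(fixture_record(fx, "EG02"))$total, 8L)
  expect_identical(score_components(fixture_record(fx, "AV05"))$total, 3L)
  # all-zero case
  empty <- record_for(0, 0, 0, 0, 0, 0, id = "Z0")
  expect_identical(score_components(empty)$total, 0L)
})

test_that("concentration thresholds are inclusive and d implies c", {
  at50 <- record_for(1, 0, 1, 1, 0, 0)
  at50$concentration <- parse_concentration("50 ppm of leaf")
  cc <- score_components(at50)
  expect_identical(c(cc$c, cc$d), c(1L, 1L))

  at5 <- record_for(1, 0, 1, 0, 0, 0)
  at5$concentration <- parse_concentration("5 ppm of leaf")
  cc5 <- score_components(at5)
  expect_identical(c(cc5$c, cc5$d), c(1L, 0L))

  below <- record_for(1, 0, 0, 0, 0, 0)
  below$concentration <- parse_concentration("4.9 ppm of leaf")
  ccb <- score_components(below)
  expect_identical(c(ccb$c, ccb$d), c(0L, 0L))
})

test_that("component B counts distinct symptoms, capped at three", {
  rec <- record_for(1, 0, 0, 0, 0, 0)
  rec$activities <- list(
    hm_activity("a1", c("symptom one", "symptom two")),
    hm_activity("a2", c("Symptom Two ", "symptom three", "symptom four")))
  expect_identical(score_components(rec, plant = test_plant())$b, 3L)
  # irrelevant activities never count
  rec$activities <- list(
    hm_activity("a1", "symptom one", relevant_to_indication = FALSE))
  expect_identical(score_components(rec)$b, 0L)
})

test_that("score_components agrees with the exhaustive component-space oracle", {
  space <- enumerate_component_space()
  expect_identical(nrow(space), 96L)
  for (i in seq_len(nrow(space))) {
    row <- space[i, ]
    rec <- record_for(row$a, row$b, row$c, row$d, row$e, row$f,
                      id = sprintf("O%03d", i))
    got <- score_components(rec, plant = test_plant())
    expect_identical(unlist(got[c("a", "b", "c", "d", "e", "f")]),
                     unlist(row[c("a", "b", "c", "d", "e", "f")]),
                     info = sprintf("vector %d", i))
    # independent brute-force sum, not the scorer's own total
    expect_identical(got$total,
                     row$a + row$b + row$c + row$d + row$e + row$f)
  }
  expect_identical(range(space$total), c(0L, 8L))
})

test_that("adding evidence never decreases any component", {
  set.seed(41)
  space <- enumerate_component_space()
  for (i in sample(nrow(space), 25)) {
    row <- space[i, ]
    rec <- record_for(row$a, row$b, row$c, row$d, row$e, row$f)
    base <- score_components(rec, plant = test_plant())

    plus_act <- rec
    plus_act$activities <- c(plus_act$activities,
                             list(hm_activity("extra", "symptom four")))
    plus_std <- rec
    plus_std$standards <- c(plus_std$standards,
                            list(hm_standard_listing("V", "g", 1, "mg", 10)))
    plus_met <- rec
    plus_met$methods <- c(plus_met$methods,
                          list(hm_method_listing("TLC", "leaf", "x")))
    plus_conc <- rec
    plus_conc$concentration <- parse_concentration("1000 ppm of leaf")

    for (variant in list(plus_act, plus_std, plus_met, plus_conc)) {
      after <- score_components(variant, plant = test_plant())
      for (k in c("a", "b", "c", "d", "e", "f", "total")) {
        expect_gte(after[[k]], base[[k]])
      }
    }
  }
})

test_that("suitability needs 5 points plus standard and method", {
  fx <- hm_fixture_dataset()
  # epicatechin: 5 points but no analytical standard
  epi <- assess_compound(fixture_record(fx, "MI03"))
  expect_identical(epi$components$total, 5L)
  expect_false(epi$suitable)
  at <- assess_compound(fixture_record(fx, "EG02"))
  expect_true(at$suitable)
  expect_identical(at$role, "quantitative")
  # 5+ points with a method but no standard, built synthetically
  rec <- record_for(1, 3, 1, 1, 0, 1)
  expect_false(assess_compound(rec, plant = test_plant())$suitable)
})

test_that("toxicants are flagged for mandatory screening whatever they score", {
  rec <- record_for(1, 1, 0, 0, 0, 0, toxic = TRUE)
  asmt <- assess_compound(rec, plant = test_plant())
  expect_identical(asmt$components$total, 2L)
  expect_true(asmt$must_screen)
  expect_false(assess_compound(record_for(1, 1, 0, 0, 0, 0),
                               plant = test_plant())$must_screen)
})

test_that("analytical role splits at 50 ppm, boundary to quantitative", {
  expect_identical(assign_role(hm_ppm(5000)), "quantitative")
  expect_identical(assign_role(hm_ppm(10)), "qualitative")
  expect_identical(assign_role(hm_ppm(50)), "quantitative")
  expect_identical(assign_role(to_ppm(parse_concentration("ND"))),
                   "unassigned")
})

test_that("regulatory limits are inclusive maxima; zero tolerates nothing", {
  isc <- hm_regulatory_limit("ISC", "total anthraquinone glycosides", 10)
  ema <- hm_regulatory_limit("EMA", "total anthraquinone glycosides", 0)
  expect_identical(check_regulatory_compliance(9.9, isc), "compliant")
  expect_identical(check_regulatory_compliance(10.0, isc), "compliant")
  expect_identical(check_regulatory_compliance(10.1, isc), "non_compliant")
  expect_identical(check_regulatory_compliance(0.5, ema), "non_compliant")
  expect_identical(check_regulatory_compliance(0, ema), "compliant")
  expect_identical(check_regulatory_compliance(NA, isc), "not_evaluable")
})

test_that("aloin dossiers carry negative-marker verdicts", {
  fx <- hm_fixture_dataset()
  aloin <- assess_compound(fixture_record(fx, "AV01"))
  expect_identical(nrow(aloin$compliance), 3L)
  # 3500 ppm midpoint exceeds all limits
  expect_true(all(aloin$compliance$verdict == "non_compliant"))
  # suitability of the positive-marker role is unaffected
  expect_true(aloin$suitable)
})

test_that("suitable implies standard, method and five points on synthetic data", {
  sim <- generate_dataset(simulation_config(n_compounds = 300, seed = 99,
                                            p_standard = 0.5,
                                            p_method = 0.5))
  plant <- sim$dataset$plants[[1]]
  for (rec in sim$dataset$compounds) {
    asmt <- assess_compound(rec, plant = plant)
    if (asmt$suitable) {
      cc <- asmt$components
      expect_true(cc$total >= 5L && cc$e == 1L && cc$f == 1L)
    }
  }
})
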