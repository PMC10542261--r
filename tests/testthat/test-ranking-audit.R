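test_that("ranking is total-descending with deterministic name tie-breaks", {
  fx <- hm_fixture_dataset()
  tabs <- assess_dataset(fx)
  euc <- tabs[["Eucalyptus globulus"]]
  expect_identical(vapply(euc$rows, `[[`, "", "name"),
                   c("1,8-cineol", "α-terpineol", "aromadendrine",
                     "globulol"))
  expect_identical(vapply(euc$rows, function(a) a$components$total, 0L),
                   c(8L, 8L, 7L, 6L))
})

test_that("empty and all-tied inputs rank deterministically", {
  plant <- test_plant()
  expect_length(rank_compounds(plant, list())$rows, 0L)

  recs <- lapply(c("cetin", "atin", "btin"), function(nm) {
    r <- record_for(1, 1, 0, 0, 0, 0, id = nm)
    r$name <- nm
    r
  })
  asmts <- lapply(recs, assess_compound, plant = plant)
  ranked <- rank_compounds(plant, asmts)
  expect_identical(vapply(ranked$rows, `[[`, "", "name"),
                   c("atin", "btin", "cetin"))
})

test_that("ranking refuses assessments from another plant", {
  fx <- hm_fixture_dataset()
  asmt <- assess_compound(fixture_record(fx, "EG02"))
  expect_error(rank_compounds(test_plant(), list(asmt)), "belong")
})

test_that("marker selection reproduces the published per-plant marker sets", {
  fx <- hm_fixture_dataset()
  tabs <- assess_dataset(fx)
  markers <- lapply(tabs, function(t)
    vapply(select_markers(t), `[[`, "", "name"))

  expect_length(markers[["Warburgia ugandensis"]], 0L)
  expect_setequal(markers[["Eucalyptus globulus"]],
                  c("aromadendrine", "α-terpineol", "globulol",
                    "1,8-cineol"))
  expect_setequal(markers[["Aloe vera"]],
                  c("aloin A", "aloin B", "aloe emodin", "acemannan"))
  expect_setequal(markers[["Mangifera indica"]],
                  c("mangiferin", "catechin", "quercetin", "gallic acid"))
  expect_false("epicatechin" %in% markers[["Mangifera indica"]])
  expect_setequal(markers[["Zingiber officinale"]],
                  c("6-gingerol", "8-gingerol", "10-gingerol", "6-shogaol"))
  # threshold above the rubric maximum selects nothing, for any plant
  for (t in tabs) expect_length(select_markers(t, threshold = 9L), 0L)
})

test_that("select_markers at threshold 8 keeps only perfect scorers", {
  fx <- hm_fixture_dataset()
  tabs <- assess_dataset(fx)
  top <- select_markers(tabs[["Eucalyptus globulus"]], 8L)
  expect_identical(vapply(top, `[[`, "", "name"),
                   c("1,8-cineol", "α-terpineol"))
})

test_that("the fixture audit surfaces the table's own inconsistencies", {
  fx <- hm_fixture_dataset()
  f <- audit_dataset(fx)
  expect_identical(attr(f, "skipped"), 0L)

  sums <- f[f$kind == "sum_mismatch", ]
  expect_gte(nrow(sums), 1L)
  expect_true("polygodial" %in% sums$name)

  der <- f[f$kind == "derivation_mismatch", ]
  expect_gte(nrow(der), 1L)
  expect_true(any(der$name == "12-gingerol" & der$field == "d"))

  # rows that must audit clean on the sum check
  clean_ids <- c("EG01", "EG02", "EG03", "EG04", "AV01", "AV02", "AV03",
                 "AV04", "AV05", "AC01", "AC02", "AC03", "AC04", "MI01",
                 "MI02", "MI03", "MI04", "MI05", "AI01", "AI02", "ZO02",
                 "ZO03", "ZO04", "WU01", "WU02", "WU04", "WU06")
  expect_length(clean_ids, 27L)
  expect_length(intersect(clean_ids, sums$compound_id), 0L)
})

test_that("records without recorded scores are skipped, not audited", {
  plant <- test_plant()
  recs <- list(record_for(1, 1, 0, 0, 0, 0, id = "N1"),
               record_for(1, 2, 1, 1, 1, 1, id = "N2"))
  doc <- hm_dataset(plants = list(plant), compounds = recs)
  f <- audit_dataset(doc)
  expect_identical(nrow(f), 0L)
  expect_identical(attr(f, "skipped"), 2L)
})

test_that("a self-consistent scored record audits clean", {
  plant <- test_plant()
  rec <- record_for(1, 2, 1, 1, 1, 1, id = "C1")
  rec$recorded_components <- score_components(rec, plant = plant)
  rec$recorded_total <- rec$recorded_components$total
  doc <- hm_dataset(plants = list(plant), compounds = list(rec))
  expect_identical(nrow(audit_dataset(doc)), 0L)
})
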