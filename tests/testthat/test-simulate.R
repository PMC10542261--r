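test_that("generation is fully deterministic for a fixed seed", {
  cfg <- simulation_config(n_compounds = 100, seed = 42, corrupt_k = 3)
  s1 <- generate_dataset(cfg)
  s2 <- generate_dataset(cfg)
  expect_identical(s1, s2)
  # and does not disturb the session RNG stream
  set.seed(7); before <- runif(3)
  set.seed(7); invisible(generate_dataset(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("forcing every availability and a high concentration maxes at 5 + b", {
  cfg <- simulation_config(
    n_compounds = 400, seed = 7, p_constituent = 1,
    symptom_count_distribution = c(0, 0, 0, 1),
    p_concentration_determined = 1, ppm_log_range = c(2, 4),
    p_standard = 1, p_method = 1)
  sim <- generate_dataset(cfg)
  totals <- vapply(sim$dataset$compounds,
                   function(r) score_components(r)$total, 0L)
  expect_true(all(totals == 8L))
})

test_that("recomputed components equal the generator's ground truth exactly", {
  sim <- generate_dataset(simulation_config(n_compounds = 500, seed = 13))
  plant <- sim$dataset$plants[[1]]
  truth <- sim$truth$components
  for (i in seq_along(sim$dataset$compounds)) {
    got <- score_components(sim$dataset$compounds[[i]], plant = plant)
    expect_identical(
      unlist(got[c("a", "b", "c", "d", "e", "f", "total")]),
      unlist(truth[i, c("a", "b", "c", "d", "e", "f", "total")]),
      info = truth$compound_id[i])
  }
})

test_that("planted corruptions are recovered exactly by the auditor", {
  sim <- generate_dataset(simulation_config(n_compounds = 50, seed = 3,
                                            corrupt_k = 5))
  expect_identical(nrow(sim$truth$ledger), 5L)
  f <- audit_dataset(sim$dataset)
  expect_identical(nrow(f), 5L)
  got <- f[order(f$compound_id), c("compound_id", "field", "kind")]
  want <- sim$truth$ledger[order(sim$truth$ledger$compound_id),
                           c("compound_id", "field", "kind")]
  expect_equal(as.data.frame(got), as.data.frame(want),
               ignore_attr = TRUE)
  # recorded value in the findings equals the planted corrupted value
  merged <- merge(as.data.frame(f), as.data.frame(sim$truth$ledger),
                  by = c("compound_id", "field"))
  expect_identical(nrow(merged), 5L)
  expect_identical(merged$recorded, merged$corrupted)
})

test_that("uncorrupted synthetic datasets audit clean", {
  sim <- generate_dataset(simulation_config(n_compounds = 80, seed = 21,
                                            corrupt_k = 0))
  f <- audit_dataset(sim$dataset)
  expect_identical(nrow(f), 0L)
  expect_identical(attr(f, "skipped"), 80L)
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(n_compounds = 3, corrupt_k = 5),
               "corrupt_k")
  expect_error(simulation_config(symptom_count_distribution =
                                   c(0.5, 0.5, 0.5, 0.5)))
  expect_error(simulation_config(ppm_log_range = c(4, 1)))
  expect_error(simulation_config(p_standard = 1.4))
})

test_that("the component space enumerates 96 admissible vectors", {
  space <- enumerate_component_space()
  expect_identical(nrow(space), 96L)
  expect_false(any(space$d > space$c))
  expect_true(any(space$a == 1 & space$b == 3 & space$c == 1 &
                    space$d == 1 & space$e == 1 & space$f == 1 &
                    space$total == 8))
  expect_true(any(space$total == 0))
  expect_false(anyDuplicated(space[c("a", "b", "c", "d", "e", "f")]) > 0)
})

test_that("synthetic documents round-trip like real ones", {
  sim <- generate_dataset(simulation_config(n_compounds = 20, seed = 5,
                                            corrupt_k = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_dataset(sim$dataset, path, "json")
  expect_equal(read_dataset(path, "json"), sim$dataset)
})
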