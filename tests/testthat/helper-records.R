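# Shared builders for one-off synthetic records used across the suite.

test_plant <- function() {
  hm_plant(
    "Testa exempli", "Testaceae", "cultivated",
    part_used = "leaf", dosage_forms = "syrup",
    indications = list(
      hm_indication("test condition",
                    c("symptom one", "symptom two", "symptom three",
                      "symptom four"))
    )
  )
}

# a record engineered to produce the given components under the rubric
record_for <- function(a = 1L, b = 0L, c = 0L, d = 0L, e = 0L, f = 0L,
                       id = "T001", toxic = FALSE) {
  stopifnot(d <= c)
  syms <- c("symptom one", "symptom two", "symptom three")[seq_len(min(b, 3))]
  conc <- if (c == 0L) {
    hm_concentration("ND", determined = FALSE)
  } else if (d == 0L) {
    parse_concentration("10 ppm of leaf")
  } else {
    parse_concentration("100 ppm of leaf")
  }
  hm_compound_record(
    compound_id = id, name = paste0("testin ", id), plant = "Testa exempli",
    documented_constituent = a == 1L,
    activities = if (b > 0L)
      list(hm_activity("test activity", syms)) else list(),
    concentration = conc,
    standards = if (e == 1L)
      list(hm_standard_listing("TestChem", "analytical", 10, "mg", 100))
      else list(),
    methods = if (f == 1L)
      list(hm_method_listing("HPLC-UV", "leaf", "T1")) else list(),
    toxic = toxic
  )
}

fixture_record <- function(fx, id) {
  ids <- vapply(fx$compounds, `[[`, "", "compound_id")
  fx$compounds[[match(id, ids)]]
}

fixture_totals <- function(fx) {
  out <- vapply(fx$compounds, function(r) score_components(r)$total, 0L)
  names(out) <- vapply(fx$compounds, `[[`, "", "compound_id")
  out
}
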