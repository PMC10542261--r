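#' Score the six Herb MaRS components for a compound record
#'
#' Computes the additive rubric from the record's evidence:
#'
#' * `a = 1` iff the compound is a documented constituent of the material;
#' * `b = min(3, n)` where `n` is the number of distinct indication symptoms
#'   covered by activities flagged relevant to the indication (1 point for
#'   one symptom, 2 for two, 3 for three and more);
#' * `(c, d)` from the ppm-normalized concentration: undetermined or
#'   `< 5 ppm` gives `(0, 0)`; `>= 5 ppm` gives `c = 1`; `>= 50 ppm`
#'   additionally gives `d = 1` (so `d <= c` always);
#' * `e = 1` iff at least one analytical reference standard is listed;
#' * `f = 1` iff at least one assay method is listed;
#' * `total` is the plain sum, in 0..8.
#'
#' @param record An [hm_compound_record()] that passes [validate_record()].
#' @param plant Optional owning [hm_plant()]; when supplied, symptoms counted
#'   for component B are additionally restricted to the plant's indication
#'   symptoms (a no-op on validated records, where coverage is an invariant).
#' @return An [hm_component_scores()] object.
#' @export
#' @examples
#' fx <- hm_fixture_dataset()
#' score_components(fx$compounds[[2]])  # alpha-terpineol: total 8
score_components <- function(record, plant = NULL) {
  viol <- validate_record(record, plant = plant)
  if (length(viol)) {
    stop(sprintf("invalid record '%s': %s", record$compound_id %||% "?",
                 paste(viol, collapse = "; ")), call. = FALSE)
  }
  a <- as.integer(isTRUE(record$documented_constituent))

  covered <- character()
  for (act in record$activities) {
    if (isTRUE(act$relevant_to_indication))
      covered <- c(covered, norm_symptom(act$symptoms_addressed))
  }
  covered <- unique(covered)
  if (!is.null(plant)) covered <- intersect(covered, plant_symptoms(plant))
  b <- min(3L, length(covered))

  ppm <- to_ppm(record$concentration)
  if (is_undetermined(ppm)) {
    c_pt <- 0L; d_pt <- 0L
  } else {
    c_pt <- as.integer(ppm$value >= 5)
    d_pt <- as.integer(ppm$value >= 50)
  }

  e <- as.integer(length(record$standards) > 0L)
  f <- as.integer(length(record$methods) > 0L)
  hm_component_scores(a, b, c_pt, d_pt, e, f)
}

#' Assign the analytical role of a marker from its concentration
#'
#' Markers at or above 50 ppm are quantified (`"quantitative"` role); those
#' below 50 ppm are monitored for identity only (`"qualitative"`); a marker
#' whose concentration was never determined is `"unassigned"`.  The 50 ppm
#' boundary itself resolves to the quantitative arm, consistent with
#' component D's "at least 50 ppm" rule.
#'
#' @param ppm An `hm_ppm` object (see [to_ppm()]) or a plain non-negative
#'   number in ppm; `NA` counts as undetermined.
#' @return `"quantitative"`, `"qualitative"` or `"unassigned"`.
#' @export
assign_role <- function(ppm) {
  val <- if (inherits(ppm, "hm_ppm")) ppm$value else as.numeric(ppm)
  if (is.null(val) || length(val) == 0L || is.na(val)) return("unassigned")
  if (val >= 50) "quantitative" else "qualitative"
}

#' Check a measured concentration against a regulatory maximum
#'
#' A measurement is compliant iff it does not exceed the limit; the limit is
#' an inclusive maximum, so a 10 ppm measurement satisfies a 10 ppm limit,
#' while a 0 ppm limit makes any positive measurement non-compliant.
#'
#' @param measured_ppm Non-negative measured concentration in ppm; `NA` for
#'   a concentration that cannot be evaluated.
#' @param limit An [hm_regulatory_limit()].
#' @return `"compliant"`, `"non_compliant"` or `"not_evaluable"`.
#' @export
#' @examples
#' isc <- hm_regulatory_limit("ISC", "total anthraquinone glycosides", 10)
#' check_regulatory_compliance(9.9, isc)
check_regulatory_compliance <- function(measured_ppm, limit) {
  if (is.null(measured_ppm) || is.na(measured_ppm)) return("not_evaluable")
  stopifnot(measured_ppm >= 0)
  if (measured_ppm <= limit$limit_ppm) "compliant" else "non_compliant"
}

#' Assess a compound as a candidate marker
#'
#' Runs the full rubric on one record and derives the decision layer:
#'
#' * `suitable` -- total of at least 5 points *and* both a reference
#'   standard (E = 1) and an assay method (F = 1) available.  The score
#'   threshold alone is not enough: a compound without a standard or method
#'   cannot be used in routine quality control however well it scores.
#' * `role` -- via [assign_role()] on the normalized concentration.
#' * `must_screen` -- `TRUE` for toxic-flagged compounds, regardless of
#'   score: toxicants are screened mandatorily.
#' * `compliance` -- one verdict per attached negative-marker limit, via
#'   [check_regulatory_compliance()] on the ppm midpoint (`not_evaluable`
#'   when the concentration is undetermined).
#'
#' @inheritParams score_components
#' @return An `hm_assessment` object: list with `compound_id`, `name`,
#'   `plant`, `components`, `ppm`, `suitable`, `role`, `must_screen` and a
#'   `compliance` tibble.
#' @export
assess_compound <- function(record, plant = NULL) {
  comps <- score_components(record, plant = plant)
  ppm <- to_ppm(record$concentration)
  suitable <- comps$total >= 5L && comps$e == 1L && comps$f == 1L
  role <- assign_role(ppm)

  limits <- record$negative_marker_limits
  compliance <- tibble(
    authority = vapply(limits, `[[`, "", "authority"),
    analyte = vapply(limits, `[[`, "", "analyte"),
    limit_ppm = vapply(limits, `[[`, 0, "limit_ppm"),
    verdict = vapply(limits, function(l) {
      check_regulatory_compliance(ppm$value, l)
    }, "")
  )

  structure(
    list(
      compound_id = record$compound_id,
      name = record$name,
      plant = record$plant,
      components = comps,
      ppm = ppm,
      suitable = suitable,
      role = role,
      must_screen = isTRUE(record$toxic),
      compliance = compliance
    ),
    class = "hm_assessment"
  )
}

#' @export
print.hm_assessment <- function(x, ...) {
  cc <- x$components
  cat(sprintf("<hm_assessment> %s (%s)\n", x$name, x$compound_id))
  cat(sprintf("  A=%d B=%d C=%d D=%d E=%d F=%d  total %d/8\n",
              cc$a, cc$b, cc$c, cc$d, cc$e, cc$f, cc$total))
  cat(sprintf("  suitable: %s | role: %s | must_screen: %s\n",
              x$suitable, x$role, x$must_screen))
  if (nrow(x$compliance)) {
    cat(sprintf("  limits: %s\n",
                paste(sprintf("%s %g ppm -> %s", x$compliance$authority,
                              x$compliance$limit_ppm, x$compliance$verdict),
                      collapse = "; ")))
  }
  invisible(x)
}

#' @export
print.hm_component_scores <- function(x, ...) {
  cat(sprintf("<hm_component_scores> A=%d B=%d C=%d D=%d E=%d F=%d total=%d\n",
              x$a, x$b, x$c, x$d, x$e, x$f, x$total))
  invisible(x)
}
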