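#' Evidence-model constructors
#'
#' Light-weight typed containers (classed lists) for the evidence a marker
#' assessment consumes: the plant material and its indications, per-compound
#' bioactivity evidence, concentration reports, reference-standard and assay
#' listings, regulatory limits, and the full compound dossier.  Constructors
#' coerce types but do not reject inconsistent content; use
#' [validate_record()] / [validate_dataset()] for that.
#'
#' @name evidence_model
NULL

#' @param condition Name of the disease condition.
#' @param symptoms Character vector of symptoms; deduplicated and lower-cased.
#' @rdname evidence_model
#' @export
hm_indication <- function(condition, symptoms = character()) {
  structure(
    list(
      condition = as.character(condition),
      symptoms = unique(norm_symptom(as.character(symptoms)))
    ),
    class = "hm_indication"
  )
}

#' @param botanical_name Botanical name, e.g. `"Eucalyptus globulus"`.
#' @param family Botanical family.
#' @param source One of `"wild"`, `"cultivated"`, `"both"`.
#' @param part_used Character vector of plant parts used.
#' @param dosage_forms Character vector of product dosage forms.
#' @param indications List of [hm_indication()] objects.
#' @rdname evidence_model
#' @export
hm_plant <- function(botanical_name, family = "", source = "both",
                     part_used = character(), dosage_forms = character(),
                     indications = list()) {
  structure(
    list(
      botanical_name = as.character(botanical_name),
      family = as.character(family),
      source = as.character(source),
      part_used = as.character(part_used),
      dosage_forms = as.character(dosage_forms),
      indications = indications
    ),
    class = "hm_plant"
  )
}

#' @param activity_name Name of the documented bioactivity.
#' @param symptoms_addressed Symptoms of the plant's indications this
#'   activity treats or alleviates.
#' @param relevant_to_indication Whether the activity is relevant to the
#'   plant's commercial indication (only relevant activities count toward
#'   component B).
#' @param mechanism Free-text mechanism of action.
#' @param citations Character vector of citation keys.
#' @rdname evidence_model
#' @export
hm_activity <- function(activity_name, symptoms_addressed = character(),
                        relevant_to_indication = TRUE, mechanism = "",
                        citations = character()) {
  structure(
    list(
      activity_name = as.character(activity_name),
      symptoms_addressed = norm_symptom(as.character(symptoms_addressed)),
      relevant_to_indication = isTRUE(relevant_to_indication),
      mechanism = as.character(mechanism),
      citations = as.character(citations)
    ),
    class = "hm_activity"
  )
}

#' @param raw_text The report as printed, e.g. `"0.50% of essential oil"`.
#' @param determined Whether a concentration was ever determined.
#' @param low,high Lower/upper bound of the reported range (equal for a
#'   point report), in `unit`.
#' @param unit One of `"percent_w_w"`, `"mg_per_g"`, `"ppm"`.
#' @param basis Matrix the concentration refers to (e.g. `"essential oil"`).
#' @rdname evidence_model
#' @export
hm_concentration <- function(raw_text, determined = TRUE, low = NULL,
                             high = NULL, unit = NULL, basis = NULL) {
  structure(
    list(
      raw_text = as.character(raw_text),
      determined = isTRUE(determined),
      low = if (is.null(low)) NULL else as.numeric(low),
      high = if (is.null(high)) NULL else as.numeric(high),
      unit = if (is.null(unit)) NULL else as.character(unit),
      basis = if (is.null(basis)) NULL else as.character(basis)
    ),
    class = "hm_concentration"
  )
}

#' @param vendor Vendor name.
#' @param grade Grade / quality descriptor of the listing.
#' @param pack_value Numeric size of the smallest commercial pack.
#' @param pack_unit One of `"mg"`, `"mL"`, `"g"`.
#' @param price_eur Price of the pack in euro.
#' @rdname evidence_model
#' @export
hm_standard_listing <- function(vendor, grade, pack_value, pack_unit,
                                price_eur) {
  structure(
    list(
      vendor = as.character(vendor),
      grade = as.character(grade),
      pack_value = as.numeric(pack_value),
      pack_unit = as.character(pack_unit),
      price_eur = as.numeric(price_eur)
    ),
    class = "hm_standard_listing"
  )
}

#' @param technique Analytical technique, e.g. `"HPLC-UV"`.
#' @param matrix Matrix the method was developed for.
#' @param citation Citation key for the method.
#' @rdname evidence_model
#' @export
hm_method_listing <- function(technique, matrix = "", citation = "") {
  structure(
    list(
      technique = as.character(technique),
      matrix = as.character(matrix),
      citation = as.character(citation)
    ),
    class = "hm_method_listing"
  )
}

#' @param authority Issuing authority, e.g. `"EMA"`.
#' @param analyte Regulated analyte the limit refers to.
#' @param limit_ppm Maximum permitted concentration in ppm (0 allowed).
#' @param direction Only `"maximum"` limits are modelled.
#' @rdname evidence_model
#' @export
hm_regulatory_limit <- function(authority, analyte, limit_ppm,
                                direction = "maximum") {
  structure(
    list(
      authority = as.character(authority),
      analyte = as.character(analyte),
      limit_ppm = as.numeric(limit_ppm),
      direction = as.character(direction)
    ),
    class = "hm_regulatory_limit"
  )
}

#' @param a,b,c,d,e,f Integer rubric components (A in 0/1, B in 0..3,
#'   C, D, E, F in 0/1).
#' @param total Integer total; defaults to the component sum.
#' @rdname evidence_model
#' @export
hm_component_scores <- function(a, b, c, d, e, f,
                                total = a + b + c + d + e + f) {
  structure(
    list(
      a = as.integer(a), b = as.integer(b), c = as.integer(c),
      d = as.integer(d), e = as.integer(e), f = as.integer(f),
      total = as.integer(total)
    ),
    class = "hm_component_scores"
  )
}

#' @param compound_id Identifier, unique within a dataset.
#' @param name Compound name as printed (UTF-8; e.g. `"α-terpineol"`).
#' @param plant Botanical name of the owning [hm_plant()] (a reference, not
#'   an embedded object).
#' @param documented_constituent Whether the compound is a documented
#'   constituent of the material (the basis of component A; kept separate
#'   from `activities` because a compound can be documented without any
#'   listed bioactivity).
#' @param activities List of [hm_activity()] objects.
#' @param concentration An [hm_concentration()] report.
#' @param standards List of [hm_standard_listing()] objects.
#' @param methods List of [hm_method_listing()] objects.
#' @param toxic Whether the compound is a known toxicant (mandatory
#'   screening applies regardless of score).
#' @param negative_marker_limits List of [hm_regulatory_limit()] objects.
#' @param recorded_components Optional [hm_component_scores()] as printed in
#'   a source table, kept verbatim for auditing.
#' @param recorded_total Optional printed total (0..8), kept for auditing.
#' @rdname evidence_model
#' @export
hm_compound_record <- function(compound_id, name, plant,
                               documented_constituent = TRUE,
                               activities = list(),
                               concentration = hm_concentration("ND",
                                                                determined = FALSE),
                               standards = list(), methods = list(),
                               toxic = FALSE,
                               negative_marker_limits = list(),
                               recorded_components = NULL,
                               recorded_total = NULL) {
  structure(
    list(
      compound_id = as.character(compound_id),
      name = as.character(name),
      plant = as.character(plant),
      documented_constituent = isTRUE(documented_constituent),
      activities = activities,
      concentration = concentration,
      standards = standards,
      methods = methods,
      toxic = isTRUE(toxic),
      negative_marker_limits = negative_marker_limits,
      recorded_components = recorded_components,
      recorded_total = if (is.null(recorded_total)) NULL
                       else as.integer(recorded_total)
    ),
    class = "hm_compound_record"
  )
}

#' Validate a compound record
#'
#' Checks every evidence-model invariant for one [hm_compound_record()] and
#' returns a character vector of human-readable violations (empty when the
#' record is fully valid).  Never raises on bad content; structural problems
#' (missing mandatory fields) are themselves reported as violations.
#'
#' @param record An [hm_compound_record()].
#' @param plant Optional owning [hm_plant()]; when supplied, the
#'   symptom-coverage invariant (symptoms addressed by relevant activities
#'   must be indication symptoms of the plant) is also checked.
#' @return Character vector of violations; `character(0)` if valid.
#' @export
#' @examples
#' rec <- hm_compound_record("X1", "examplin", "Examplus plantus")
#' validate_record(rec)
validate_record <- function(record, plant = NULL) {
  v <- character()
  say <- function(field, rule) sprintf("%s: %s", field, rule)

  for (fld in c("compound_id", "name", "plant")) {
    val <- record[[fld]]
    if (is.null(val) || !nzchar(val %||% ""))
      v <- c(v, say(fld, "mandatory field missing or empty"))
  }
  if (is.null(record$concentration)) {
    v <- c(v, say("concentration", "mandatory field missing or empty"))
  } else {
    conc <- record$concentration
    if (isTRUE(conc$determined)) {
      if (is.null(conc$unit))
        v <- c(v, say("unit", "determined report must state a unit"))
      else if (!conc$unit %in% c("percent_w_w", "mg_per_g", "ppm"))
        v <- c(v, say("unit", sprintf("unknown unit '%s'", conc$unit)))
      if (is.null(conc$low) || is.null(conc$high)) {
        v <- c(v, say("low/high", "determined report must state low and high"))
      } else {
        if (conc$low < 0)
          v <- c(v, say("low", "concentration must be non-negative"))
        if (conc$low > conc$high)
          v <- c(v, say("low/high", "low must not exceed high"))
      }
    } else {
      if (!is.null(conc$low) || !is.null(conc$high) || !is.null(conc$unit))
        v <- c(v, say("low/high/unit",
                      "undetermined report must not carry values or a unit"))
    }
  }

  for (i in seq_along(record$standards)) {
    s <- record$standards[[i]]
    tag <- sprintf("standards[%d]", i)
    if (is.null(s$pack_value) || is.na(s$pack_value) || s$pack_value <= 0)
      v <- c(v, say(paste0(tag, ".pack_value"), "must be > 0"))
    if (is.null(s$price_eur) || is.na(s$price_eur) || s$price_eur <= 0)
      v <- c(v, say(paste0(tag, ".price_eur"), "must be > 0"))
    if (!is.null(s$pack_unit) && !s$pack_unit %in% c("mg", "mL", "g"))
      v <- c(v, say(paste0(tag, ".pack_unit"),
                    sprintf("unknown pack unit '%s'", s$pack_unit)))
  }
  for (i in seq_along(record$methods)) {
    m <- record$methods[[i]]
    if (is.null(m$technique) || !nzchar(m$technique))
      v <- c(v, say(sprintf("methods[%d].technique", i), "must be non-empty"))
  }
  for (i in seq_along(record$negative_marker_limits)) {
    l <- record$negative_marker_limits[[i]]
    if (is.null(l$limit_ppm) || is.na(l$limit_ppm) || l$limit_ppm < 0)
      v <- c(v, say(sprintf("negative_marker_limits[%d].limit_ppm", i),
                    "must be >= 0"))
  }

  if (!is.null(record$recorded_total) &&
      (record$recorded_total < 0L || record$recorded_total > 8L))
    v <- c(v, say("recorded_total", "must lie in [0, 8]"))
  if (!is.null(record$recorded_components)) {
    rc <- record$recorded_components
    rng <- list(a = 0:1, b = 0:3, c = 0:1, d = 0:1, e = 0:1, f = 0:1)
    for (k in names(rng)) {
      if (is.null(rc[[k]]) || !rc[[k]] %in% rng[[k]])
        v <- c(v, say(paste0("recorded_components.", k),
                      sprintf("must lie in [%d, %d]", min(rng[[k]]),
                              max(rng[[k]]))))
    }
  }

  if (!is.null(plant)) {
    pool <- plant_symptoms(plant)
    for (i in seq_along(record$activities)) {
      act <- record$activities[[i]]
      if (isTRUE(act$relevant_to_indication)) {
        extra <- setdiff(norm_symptom(act$symptoms_addressed), pool)
        if (length(extra))
          v <- c(v, say(sprintf("activities[%d].symptoms_addressed", i),
                        sprintf("not indication symptoms of the plant: %s",
                                paste(extra, collapse = ", "))))
      }
    }
  }
  v
}

# union of all indication symptoms of a plant, canonical form
plant_symptoms <- function(plant) {
  unique(norm_symptom(unlist(lapply(plant$indications, `[[`, "symptoms"),
                             use.names = FALSE) %||% character()))
}

#' Validate a dataset document
#'
#' Validates every record of a [hm_dataset()] (including the per-plant
#' symptom-coverage invariant), plus dataset-level invariants: unique
#' compound ids and referential integrity of plant references.
#'
#' @param doc A [hm_dataset()] document.
#' @return Character vector of violations, prefixed by compound id (or
#'   `dataset:` for dataset-level problems); `character(0)` if valid.
#' @export
validate_dataset <- function(doc) {
  v <- character()
  ids <- vapply(doc$compounds, `[[`, "", "compound_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    v <- c(v, sprintf("dataset: duplicate compound_id '%s'", dup))
  plant_names <- vapply(doc$plants, `[[`, "", "botanical_name")
  for (rec in doc$compounds) {
    if (!rec$plant %in% plant_names) {
      v <- c(v, sprintf("%s: plant '%s' not present in the dataset",
                        rec$compound_id, rec$plant))
      plant <- NULL
    } else {
      plant <- doc$plants[[match(rec$plant, plant_names)]]
    }
    rv <- validate_record(rec, plant = plant)
    if (length(rv)) v <- c(v, sprintf("%s: %s", rec$compound_id, rv))
  }
  v
}

#' @export
print.hm_compound_record <- function(x, ...) {
  cat(sprintf("<hm_compound_record> %s (%s; plant: %s)\n", x$name,
              x$compound_id, x$plant))
  cat(sprintf("  constituent: %s | activities: %d | standards: %d | methods: %d\n",
              x$documented_constituent, length(x$activities),
              length(x$standards), length(x$methods)))
  cat(sprintf("  concentration: %s\n", x$concentration$raw_text))
  invisible(x)
}
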