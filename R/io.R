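#' Dataset documents
#'
#' A dataset document bundles the plants, compound dossiers and any
#' dataset-level regulatory limits under a schema version.  JSON is the
#' canonical on-disk format (schema published in
#' `inst/extdata/herbmars-dataset.schema.json`); YAML and CSV are
#' convenience dialects carrying identical content.
#'
#' @param plants List of [hm_plant()] objects.
#' @param compounds List of [hm_compound_record()] objects.
#' @param limits List of dataset-level [hm_regulatory_limit()] objects.
#' @param schema_version Schema version string.
#' @return An `hm_dataset` object.
#' @export
hm_dataset <- function(plants = list(), compounds = list(), limits = list(),
                       schema_version = "1.0") {
  structure(
    list(schema_version = as.character(schema_version), plants = plants,
         compounds = compounds, limits = limits),
    class = "hm_dataset"
  )
}

#' @export
print.hm_dataset <- function(x, ...) {
  cat(sprintf("<hm_dataset> schema %s: %d plants, %d compounds, %d limits\n",
              x$schema_version, length(x$plants), length(x$compounds),
              length(x$limits)))
  invisible(x)
}

#' The packaged evidence dataset
#'
#' Loads the evidence dataset shipped with the package: seven medicinal
#' plants widely used in Ugandan herbal manufacturing (*Eucalyptus
#' globulus*, *Aloe vera*, *Albizia coriaria*, *Mangifera indica*,
#' *Azadirachta indica*, *Zingiber officinale*, *Warburgia ugandensis*) and
#' 35 candidate-marker dossiers with documented bioactivities, reported
#' concentrations, reference-standard listings, assay methods and the
#' scores as printed in the source ranking table (kept verbatim for
#' auditing).
#'
#' @return An `hm_dataset` document.
#' @export
#' @examples
#' fx <- hm_fixture_dataset()
#' length(fx$compounds)
hm_fixture_dataset <- function() {
  read_dataset(system.file("extdata", "herbmars-tables.json",
                           package = "herbmars", mustWork = TRUE), "json")
}

# ---- plain (serializable) representation ------------------------------------

drop_null <- function(x) x[!vapply(x, is.null, TRUE)]

plain_dataset <- function(doc) {
  list(
    schema_version = doc$schema_version,
    plants = lapply(doc$plants, function(p) {
      list(
        botanical_name = p$botanical_name, family = p$family,
        source = p$source, part_used = as.list(p$part_used),
        dosage_forms = as.list(p$dosage_forms),
        indications = lapply(p$indications, function(ind) {
          list(condition = ind$condition, symptoms = as.list(ind$symptoms))
        })
      )
    }),
    compounds = lapply(doc$compounds, plain_record),
    limits = lapply(doc$limits, unclass)
  )
}

plain_record <- function(rec) {
  conc <- rec$concentration
  drop_null(list(
    compound_id = rec$compound_id, name = rec$name, plant = rec$plant,
    documented_constituent = rec$documented_constituent,
    activities = lapply(rec$activities, function(a) {
      list(activity_name = a$activity_name,
           symptoms_addressed = as.list(a$symptoms_addressed),
           relevant_to_indication = a$relevant_to_indication,
           mechanism = a$mechanism, citations = as.list(a$citations))
    }),
    concentration = drop_null(list(
      raw_text = conc$raw_text, determined = conc$determined,
      low = conc$low, high = conc$high, unit = conc$unit, basis = conc$basis
    )),
    standards = lapply(rec$standards, unclass),
    methods = lapply(rec$methods, unclass),
    toxic = rec$toxic,
    negative_marker_limits = lapply(rec$negative_marker_limits, unclass),
    recorded_components = if (is.null(rec$recorded_components)) NULL else
      unclass(rec$recorded_components)[c("a", "b", "c", "d", "e", "f")],
    recorded_total = rec$recorded_total
  ))
}

unplain_dataset <- function(x) {
  chr1 <- function(v) as.character(unlist(v, use.names = FALSE) %||%
                                     character())
  hm_dataset(
    schema_version = x$schema_version %||% "1.0",
    plants = lapply(x$plants %||% list(), function(p) {
      hm_plant(p$botanical_name, p$family %||% "", p$source %||% "both",
               chr1(p$part_used), chr1(p$dosage_forms),
               lapply(p$indications %||% list(), function(ind) {
                 hm_indication(ind$condition, chr1(ind$symptoms))
               }))
    }),
    compounds = lapply(x$compounds %||% list(), function(r) {
      conc <- r$concentration
      hm_compound_record(
        compound_id = r$compound_id, name = r$name, plant = r$plant,
        documented_constituent = isTRUE(r$documented_constituent),
        activities = lapply(r$activities %||% list(), function(a) {
          hm_activity(a$activity_name, chr1(a$symptoms_addressed),
                      isTRUE(a$relevant_to_indication), a$mechanism %||% "",
                      chr1(a$citations))
        }),
        concentration = hm_concentration(
          raw_text = conc$raw_text, determined = isTRUE(conc$determined),
          low = conc$low, high = conc$high, unit = conc$unit,
          basis = conc$basis
        ),
        standards = lapply(r$standards %||% list(), function(s) {
          hm_standard_listing(s$vendor, s$grade %||% "", s$pack_value,
                              s$pack_unit, s$price_eur)
        }),
        methods = lapply(r$methods %||% list(), function(m) {
          hm_method_listing(m$technique, m$matrix %||% "",
                            m$citation %||% "")
        }),
        toxic = isTRUE(r$toxic),
        negative_marker_limits = lapply(r$negative_marker_limits %||% list(),
                                        function(l) {
          hm_regulatory_limit(l$authority, l$analyte, l$limit_ppm,
                              l$direction %||% "maximum")
        }),
        recorded_components = if (is.null(r$recorded_components)) NULL else
          with(r$recorded_components, hm_component_scores(a, b, c, d, e, f)),
        recorded_total = r$recorded_total
      )
    }),
    limits = lapply(x$limits %||% list(), function(l) {
      hm_regulatory_limit(l$authority, l$analyte, l$limit_ppm,
                          l$direction %||% "maximum")
    })
  )
}

# ---- readers / writers ------------------------------------------------------

#' Read a dataset document
#'
#' @param path File path (JSON or YAML) or directory path (CSV dialect).
#' @param format `"json"`, `"yaml"` or `"csv"`; guessed from the path
#'   extension when omitted.
#' @return An `hm_dataset` document.  Schema violations raise one error
#'   listing every offending field, not just the first.
#' @export
read_dataset <- function(path, format = c("json", "yaml", "csv")) {
  format <- if (missing(format)) guess_format(path) else match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such path: %s", path),
                               call. = FALSE)
  plain <- switch(format,
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    yaml = yaml::read_yaml(path),
    csv = csv_to_plain(path)
  )
  doc <- unplain_dataset(plain)
  viol <- validate_dataset(doc)
  if (length(viol)) {
    stop(sprintf("dataset at '%s' violates the schema:\n%s", path,
                 paste0("  - ", viol, collapse = "\n")), call. = FALSE)
  }
  doc
}

#' Write a dataset document
#'
#' @param doc An `hm_dataset` document.
#' @param path Target file (JSON, YAML) or directory (CSV dialect; created
#'   if absent, populated with `dataset.csv`, `plants.csv`,
#'   `indications.csv`, `compounds.csv`, `activities.csv`, `standards.csv`,
#'   `methods.csv` and `limits.csv`).
#' @inheritParams read_dataset
#' @return `path`, invisibly.  Reading the written file(s) back yields a
#'   document equal to `doc`, for all three formats.
#' @export
write_dataset <- function(doc, path, format = c("json", "yaml", "csv")) {
  format <- if (missing(format)) guess_format(path) else match.arg(format)
  plain <- plain_dataset(doc)
  switch(format,
    json = jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    yaml = yaml::write_yaml(plain, path, precision = 15L),
    csv = plain_to_csv(doc, path)
  )
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = "json", yaml = "yaml", yml = "yaml", csv = "csv",
         if (dir.exists(path) || ext == "") "csv" else
           stop(sprintf("cannot guess dataset format from '%s'", path),
                call. = FALSE))
}

# ---- CSV dialect ------------------------------------------------------------
# One row per compound; list-valued scalar fields are ';'-joined; activities,
# standards, methods, indications and limits live in companion tables keyed
# by compound_id / plant.

SJ <- function(x) paste(x, collapse = "; ")
SPLIT <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else
    stringi::stri_trim_both(stringi::stri_split_fixed(x, ";")[[1]])
}
na2empty <- function(x) ifelse(is.na(x), "", x)

plain_to_csv <- function(doc, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) readr::write_csv(df, file.path(dir, name), na = "")

  w(tibble(schema_version = doc$schema_version), "dataset.csv")

  w(dplyr::bind_rows(lapply(doc$plants, function(p) tibble(
    botanical_name = p$botanical_name, family = p$family, source = p$source,
    part_used = SJ(p$part_used), dosage_forms = SJ(p$dosage_forms)
  ))), "plants.csv")

  ind <- list()
  for (p in doc$plants) for (i in p$indications) {
    ind[[length(ind) + 1L]] <- tibble(plant = p$botanical_name,
                                      condition = i$condition,
                                      symptoms = SJ(i$symptoms))
  }
  w(if (length(ind)) dplyr::bind_rows(ind) else
      tibble(plant = character(), condition = character(),
             symptoms = character()), "indications.csv")

  w(dplyr::bind_rows(lapply(doc$compounds, function(r) {
    conc <- r$concentration
    rc <- r$recorded_components
    tibble(
      compound_id = r$compound_id, name = r$name, plant = r$plant,
      documented_constituent = r$documented_constituent,
      conc_raw = conc$raw_text, conc_determined = conc$determined,
      conc_low = conc$low %||% NA_real_, conc_high = conc$high %||% NA_real_,
      conc_unit = conc$unit %||% NA_character_,
      conc_basis = conc$basis %||% NA_character_,
      toxic = r$toxic,
      rec_a = if (is.null(rc)) NA_integer_ else rc$a,
      rec_b = if (is.null(rc)) NA_integer_ else rc$b,
      rec_c = if (is.null(rc)) NA_integer_ else rc$c,
      rec_d = if (is.null(rc)) NA_integer_ else rc$d,
      rec_e = if (is.null(rc)) NA_integer_ else rc$e,
      rec_f = if (is.null(rc)) NA_integer_ else rc$f,
      rec_total = r$recorded_total %||% NA_integer_
    )
  })), "compounds.csv")

  tab <- function(items, build) {
    rows <- list()
    for (r in doc$compounds) for (it in r[[items]]) {
      rows[[length(rows) + 1L]] <- build(r$compound_id, it)
    }
    rows
  }
  act <- tab("activities", function(id, a) tibble(
    compound_id = id, activity_name = a$activity_name,
    symptoms_addressed = SJ(a$symptoms_addressed),
    relevant_to_indication = a$relevant_to_indication,
    mechanism = a$mechanism, citations = SJ(a$citations)))
  w(if (length(act)) dplyr::bind_rows(act) else
      tibble(compound_id = character(), activity_name = character(),
             symptoms_addressed = character(),
             relevant_to_indication = logical(), mechanism = character(),
             citations = character()), "activities.csv")

  std <- tab("standards", function(id, s) tibble(
    compound_id = id, vendor = s$vendor, grade = s$grade,
    pack_value = s$pack_value, pack_unit = s$pack_unit,
    price_eur = s$price_eur))
  w(if (length(std)) dplyr::bind_rows(std) else
      tibble(compound_id = character(), vendor = character(),
             grade = character(), pack_value = numeric(),
             pack_unit = character(), price_eur = numeric()),
    "standards.csv")

  met <- tab("methods", function(id, m) tibble(
    compound_id = id, technique = m$technique, matrix = m$matrix,
    citation = m$citation))
  w(if (length(met)) dplyr::bind_rows(met) else
      tibble(compound_id = character(), technique = character(),
             matrix = character(), citation = character()), "methods.csv")

  lim <- tab("negative_marker_limits", function(id, l) tibble(
    scope = id, authority = l$authority, analyte = l$analyte,
    limit_ppm = l$limit_ppm, direction = l$direction))
  for (l in doc$limits) {
    lim[[length(lim) + 1L]] <- tibble(scope = "dataset",
                                      authority = l$authority,
                                      analyte = l$analyte,
                                      limit_ppm = l$limit_ppm,
                                      direction = l$direction)
  }
  w(if (length(lim)) dplyr::bind_rows(lim) else
      tibble(scope = character(), authority = character(),
             analyte = character(), limit_ppm = numeric(),
             direction = character()), "limits.csv")
  invisible(dir)
}

csv_to_plain <- function(dir) {
  rd <- function(name, types) {
    readr::read_csv(file.path(dir, name), col_types = types,
                    locale = readr::locale(encoding = "UTF-8"),
                    progress = FALSE)
  }
  ds <- rd("dataset.csv", "c")
  plants <- rd("plants.csv", "ccccc")
  indic <- rd("indications.csv", "ccc")
  comp <- rd("compounds.csv", "ccclclddccliiiiiii")
  act <- rd("activities.csv", "ccclcc")
  std <- rd("standards.csv", "cccdcd")
  met <- rd("methods.csv", "cccc")
  lim <- rd("limits.csv", "cccdc")

  lim_for <- function(scope) {
    rows <- lim[lim$scope == scope, , drop = FALSE]
    lapply(seq_len(nrow(rows)), function(i) list(
      authority = rows$authority[i], analyte = rows$analyte[i],
      limit_ppm = rows$limit_ppm[i], direction = rows$direction[i]))
  }

  list(
    schema_version = ds$schema_version[1],
    plants = lapply(seq_len(nrow(plants)), function(i) {
      nm <- plants$botanical_name[i]
      ind <- indic[indic$plant == nm, , drop = FALSE]
      list(
        botanical_name = nm, family = na2empty(plants$family[i]),
        source = plants$source[i],
        part_used = as.list(SPLIT(plants$part_used[i])),
        dosage_forms = as.list(SPLIT(plants$dosage_forms[i])),
        indications = lapply(seq_len(nrow(ind)), function(j) list(
          condition = ind$condition[j],
          symptoms = as.list(SPLIT(ind$symptoms[j]))))
      )
    }),
    compounds = lapply(seq_len(nrow(comp)), function(i) {
      id <- comp$compound_id[i]
      a <- act[act$compound_id == id, , drop = FALSE]
      s <- std[std$compound_id == id, , drop = FALSE]
      m <- met[met$compound_id == id, , drop = FALSE]
      determined <- isTRUE(comp$conc_determined[i])
      list(
        compound_id = id, name = comp$name[i], plant = comp$plant[i],
        documented_constituent = isTRUE(comp$documented_constituent[i]),
        activities = lapply(seq_len(nrow(a)), function(j) list(
          activity_name = a$activity_name[j],
          symptoms_addressed = as.list(SPLIT(a$symptoms_addressed[j])),
          relevant_to_indication = isTRUE(a$relevant_to_indication[j]),
          mechanism = na2empty(a$mechanism[j]),
          citations = as.list(SPLIT(a$citations[j])))),
        concentration = list(
          raw_text = comp$conc_raw[i], determined = determined,
          low = if (determined) comp$conc_low[i] else NULL,
          high = if (determined) comp$conc_high[i] else NULL,
          unit = if (determined) comp$conc_unit[i] else NULL,
          basis = if (determined && !is.na(comp$conc_basis[i]))
            comp$conc_basis[i] else NULL
        ),
        standards = lapply(seq_len(nrow(s)), function(j) list(
          vendor = s$vendor[j], grade = na2empty(s$grade[j]),
          pack_value = s$pack_value[j], pack_unit = s$pack_unit[j],
          price_eur = s$price_eur[j])),
        methods = lapply(seq_len(nrow(m)), function(j) list(
          technique = m$technique[j], matrix = na2empty(m$matrix[j]),
          citation = na2empty(m$citation[j]))),
        toxic = isTRUE(comp$toxic[i]),
        negative_marker_limits = lim_for(id),
        recorded_components = if (is.na(comp$rec_a[i])) NULL else list(
          a = comp$rec_a[i], b = comp$rec_b[i], c = comp$rec_c[i],
          d = comp$rec_d[i], e = comp$rec_e[i], f = comp$rec_f[i]),
        recorded_total = if (is.na(comp$rec_total[i])) NULL else
          comp$rec_total[i]
      )
    }),
    limits = lim_for("dataset")
  )
}
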