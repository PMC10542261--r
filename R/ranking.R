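#' Rank assessed compounds for one plant
#'
#' Orders assessments by total score, descending; ties are broken by
#' compound name, ascending, after Unicode NFC normalization and case
#' folding, compared byte-wise (C locale) so the ordering is deterministic
#' across platforms.  Unsuitable compounds are kept (flagged), as published
#' ranking tables list them too.
#'
#' @param plant The [hm_plant()] the assessments belong to.
#' @param assessments List of `hm_assessment` objects (see
#'   [assess_compound()]); all must reference `plant`.
#' @return An `hm_ranked_table`: list with `plant` and ordered `rows`.
#' @export
rank_compounds <- function(plant, assessments) {
  if (length(assessments)) {
    owners <- vapply(assessments, `[[`, "", "plant")
    if (!all(owners == plant$botanical_name)) {
      stop("all assessments must belong to the plant being ranked",
           call. = FALSE)
    }
    totals <- vapply(assessments, function(a) a$components$total, 0L)
    keys <- name_sort_key(vapply(assessments, `[[`, "", "name"))
    ord <- order(-totals, keys, method = "radix")
    assessments <- assessments[ord]
  }
  structure(list(plant = plant, rows = assessments),
            class = "hm_ranked_table")
}

#' Select suitable markers from a ranked table
#'
#' Keeps rows that are suitable (total of at least 5 with standard and
#' method available; see [assess_compound()]) and reach the score
#' threshold, preserving rank order.
#'
#' @param table An `hm_ranked_table` from [rank_compounds()].
#' @param threshold Minimum total score, in 0..8 (default 5).
#' @return List of `hm_assessment` rows, in rank order.
#' @export
select_markers <- function(table, threshold = 5L) {
  stopifnot(threshold >= 0)
  Filter(function(a) a$suitable && a$components$total >= threshold,
         table$rows)
}

#' Assess and rank every compound in a dataset
#'
#' Convenience wrapper: assesses each compound against its own plant and
#' returns one ranked table per plant, in dataset plant order.
#'
#' @param dataset A [hm_dataset()] document.
#' @return Named list of `hm_ranked_table` objects (names are botanical
#'   names).
#' @export
assess_dataset <- function(dataset) {
  plant_names <- vapply(dataset$plants, `[[`, "", "botanical_name")
  tables <- list()
  for (i in seq_along(dataset$plants)) {
    plant <- dataset$plants[[i]]
    recs <- Filter(function(r) r$plant == plant$botanical_name,
                   dataset$compounds)
    assessments <- lapply(recs, assess_compound, plant = plant)
    tables[[plant$botanical_name]] <- rank_compounds(plant, assessments)
  }
  tables
}

#' Audit recorded scores against the rubric
#'
#' Compares the scores recorded in a dataset (e.g. as printed in a source
#' table) with what the rubric derives from the records' own evidence, and
#' reports every inconsistency.  Three kinds of finding:
#'
#' * `sum_mismatch` -- the recorded components do not add up to the
#'   recorded total;
#' * `derivation_mismatch` -- a recorded component A--D differs from the
#'   component recomputed from the evidence (e.g. a "at least 50 ppm" point
#'   granted to a concentration below 50 ppm);
#' * `availability_mismatch` -- recorded E or F contradicts the standards
#'   or methods lists actually attached to the record.
#'
#' The auditor reports and never repairs: recorded values stay
#' authoritative in the dataset.  Records carrying no recorded scores are
#' skipped; their count is attached as the `"skipped"` attribute.
#'
#' @param dataset A [hm_dataset()] document (or plain list of records, in
#'   which case the plant-restricted symptom count is not applied).
#' @return A tibble of findings: `compound_id`, `name`, `kind`, `field`,
#'   `recorded`, `recomputed`, `detail`; zero rows when fully consistent.
#' @export
audit_dataset <- function(dataset) {
  compounds <- dataset_compounds(dataset)
  plants <- if (is.list(dataset) && !is.null(dataset$plants))
    dataset$plants else list()
  plant_names <- vapply(plants, `[[`, "", "botanical_name")

  findings <- list()
  skipped <- 0L
  emit <- function(rec, kind, field, recorded, recomputed, rule) {
    findings[[length(findings) + 1L]] <<- tibble(
      compound_id = rec$compound_id, name = rec$name, kind = kind,
      field = field, recorded = as.integer(recorded),
      recomputed = as.integer(recomputed),
      detail = sprintf("%s: recorded %s=%d, recomputed %d (%s)",
                       rec$name, toupper(field), recorded, recomputed, rule)
    )
  }

  for (rec in compounds) {
    has_rc <- !is.null(rec$recorded_components)
    has_rt <- !is.null(rec$recorded_total)
    if (!has_rc && !has_rt) {
      skipped <- skipped + 1L
      next
    }
    plant <- if (rec$plant %in% plant_names)
      plants[[match(rec$plant, plant_names)]] else NULL
    derived <- score_components(rec, plant = plant)

    if (has_rc && has_rt) {
      rc <- rec$recorded_components
      s <- rc$a + rc$b + rc$c + rc$d + rc$e + rc$f
      if (s != rec$recorded_total) {
        emit(rec, "sum_mismatch", "total", rec$recorded_total, s,
             "recorded components do not sum to the recorded total")
      }
    }
    if (has_rc) {
      rc <- rec$recorded_components
      for (k in c("a", "b", "c", "d")) {
        if (rc[[k]] != derived[[k]]) {
          emit(rec, "derivation_mismatch", k, rc[[k]], derived[[k]],
               "component derived from the evidence differs")
        }
      }
      if (rc$e != derived$e) {
        emit(rec, "availability_mismatch", "e", rc$e, derived$e,
             sprintf("%d standard listing(s) attached",
                     length(rec$standards)))
      }
      if (rc$f != derived$f) {
        emit(rec, "availability_mismatch", "f", rc$f, derived$f,
             sprintf("%d assay method(s) attached", length(rec$methods)))
      }
    }
  }

  out <- if (length(findings)) dplyr::bind_rows(findings) else
    tibble(compound_id = character(), name = character(), kind = character(),
           field = character(), recorded = integer(), recomputed = integer(),
           detail = character())
  attr(out, "skipped") <- skipped
  out
}

#' @export
print.hm_ranked_table <- function(x, ...) {
  cat(sprintf("<hm_ranked_table> %s (%d compounds)\n",
              x$plant$botanical_name, length(x$rows)))
  for (a in x$rows) {
    cat(sprintf("  %d/8  %-24s %s%s\n", a$components$total, a$name,
                a$role, if (a$suitable) "  [marker]" else ""))
  }
  invisible(x)
}

#' Ranked table as a tibble
#'
#' @param x An `hm_ranked_table`.
#' @param ... Unused.
#' @return Tibble with one row per assessed compound in rank order.
#' @method as_tibble hm_ranked_table
#' @export
as_tibble.hm_ranked_table <- function(x, ...) {
  rows <- lapply(x$rows, function(asmt) {
    cc <- asmt$components
    ppm_val <- if (is_undetermined(asmt$ppm)) NA_real_ else asmt$ppm$value
    tibble(
      plant = x$plant$botanical_name, compound_id = asmt$compound_id,
      name = asmt$name, a = cc$a, b = cc$b, c = cc$c, d = cc$d, e = cc$e,
      f = cc$f, total = cc$total, ppm = ppm_val,
      suitable = asmt$suitable, role = asmt$role,
      must_screen = asmt$must_screen
    )
  })
  if (!length(rows)) {
    return(tibble(plant = character(), compound_id = character(),
                  name = character(), a = integer(), b = integer(),
                  c = integer(), d = integer(), e = integer(), f = integer(),
                  total = integer(), ppm = numeric(), suitable = logical(),
                  role = character(), must_screen = logical()))
  }
  dplyr::bind_rows(rows)
}
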