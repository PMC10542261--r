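#' Parse a free-text concentration report
#'
#' Recognizes the report dialects that occur in published marker tables:
#' `"ND"` / `"Not determined"`; point values and ranges in percent w/w
#' (`"0.50% of essential oil"`), mg/g (`"1.1–2.0 mg/g of rhizome"`) and ppm
#' (`"109–135 ppm of gel"`).  En dash, em dash, hyphen and the word `"to"`
#' are all accepted as range separators; the matrix after `"of"` is captured
#' verbatim as the `basis`.
#'
#' @param raw Non-empty report text.
#' @return An [hm_concentration()] report; `determined = FALSE` for
#'   not-determined reports.
#' @seealso [to_ppm()], [format_concentration()]
#' @export
#' @examples
#' parse_concentration("0.50% of essential oil")
#' parse_concentration("0.018 to 0.64 mg/g of oil")
#' parse_concentration("ND")
parse_concentration <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(trimws(raw)))
  txt <- stringi::stri_trim_both(raw)

  if (stringi::stri_detect_regex(txt, "^(ND|N\\.D\\.?|not\\s+determined)$",
                                 case_insensitive = TRUE)) {
    return(hm_concentration(raw_text = txt, determined = FALSE))
  }

  num <- "([0-9]+(?:\\.[0-9]+)?)"
  sep <- "\\s*(?:–|—|-|to)\\s*"
  unit_re <- "(%|ppm|mg/g)"
  pat <- paste0("^", num, "(?:", sep, num, ")?\\s*", unit_re,
                "(?:\\s+of\\s+(.+))?$")
  m <- stringi::stri_match_first_regex(txt, pat)
  if (is.na(m[1, 1])) {
    stop(sprintf("unrecognized concentration report: '%s'", txt),
         call. = FALSE)
  }
  low <- as.numeric(m[1, 2])
  high <- if (is.na(m[1, 3])) low else as.numeric(m[1, 3])
  unit <- switch(m[1, 4],
                 "%" = "percent_w_w",
                 "ppm" = "ppm",
                 "mg/g" = "mg_per_g")
  basis <- if (is.na(m[1, 5])) NULL else m[1, 5]
  hm_concentration(raw_text = txt, determined = TRUE, low = low, high = high,
                   unit = unit, basis = basis)
}

#' Render a concentration report as canonical text
#'
#' Inverse of [parse_concentration()] up to formatting: parsing the rendered
#' text yields a report with identical `determined`, `low`, `high`, `unit`
#' and `basis`.
#'
#' @param report An [hm_concentration()] report.
#' @return A single string.
#' @export
format_concentration <- function(report) {
  if (!isTRUE(report$determined)) return("ND")
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)
  unit <- switch(report$unit,
                 percent_w_w = "%",
                 ppm = " ppm",
                 mg_per_g = " mg/g")
  val <- if (report$low == report$high) fmt(report$low) else
    paste0(fmt(report$low), "–", fmt(report$high))
  out <- paste0(val, unit)
  if (!is.null(report$basis)) out <- paste0(out, " of ", report$basis)
  out
}

#' Normalize a concentration report to parts per million
#'
#' Converts a determined report to a single scalar in ppm (mass fraction,
#' w/w): percent w/w is multiplied by 10,000, mg/g by 1,000, ppm by 1.
#' Ranges collapse to the arithmetic midpoint of the converted bounds
#' (`provenance = "range_midpoint"`); point reports keep
#' `provenance = "point"`.  Not-determined reports return the undetermined
#' sentinel (`hm_ppm` with `NA` value and `provenance = "undetermined"`).
#' The basis (oil, leaf, gel, ...) is carried as metadata and never rescales
#' the value.
#'
#' @param report An [hm_concentration()] report.
#' @return An `hm_ppm` object: list with `value` (ppm), `provenance`
#'   (`"point"`, `"range_midpoint"` or `"undetermined"`) and `basis`.
#' @export
#' @examples
#' to_ppm(parse_concentration("0.50% of essential oil"))  # 5000 ppm
#' to_ppm(parse_concentration("1.1-2.0 mg/g of rhizome")) # 1550 ppm
#' is_undetermined(to_ppm(parse_concentration("ND")))
to_ppm <- function(report) {
  if (!isTRUE(report$determined)) {
    return(hm_ppm(NA_real_, "undetermined", report$basis %||% NA_character_))
  }
  factor <- switch(report$unit,
                   percent_w_w = 1e4,
                   mg_per_g = 1e3,
                   ppm = 1,
                   stop(sprintf("unknown concentration unit '%s'",
                                report$unit), call. = FALSE))
  lo <- report$low * factor
  hi <- report$high * factor
  if (report$low == report$high) {
    hm_ppm(lo, "point", report$basis %||% NA_character_)
  } else {
    hm_ppm((lo + hi) / 2, "range_midpoint", report$basis %||% NA_character_)
  }
}

#' @param value Concentration in ppm (mass basis).
#' @param provenance `"point"`, `"range_midpoint"` or `"undetermined"`.
#' @param basis Matrix the value refers to.
#' @rdname to_ppm
#' @export
hm_ppm <- function(value, provenance = "point", basis = NA_character_) {
  structure(
    list(value = as.numeric(value), provenance = as.character(provenance),
         basis = basis),
    class = "hm_ppm"
  )
}

#' @param x An `hm_ppm` object (or numeric ppm value).
#' @rdname to_ppm
#' @export
is_undetermined <- function(x) {
  if (inherits(x, "hm_ppm"))
    return(identical(x$provenance, "undetermined") || is.na(x$value))
  is.null(x) || all(is.na(x))
}

#' @export
print.hm_ppm <- function(x, ...) {
  if (is_undetermined(x)) {
    cat("<hm_ppm> undetermined\n")
  } else {
    cat(sprintf("<hm_ppm> %s ppm (%s%s)\n", format(x$value), x$provenance,
                if (is.na(x$basis %||% NA)) "" else paste0(", ", x$basis)))
  }
  invisible(x)
}
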