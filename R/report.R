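#' Render a plain-text ranking report
#'
#' One section per plant (compound, components A--F, total, suitability,
#' role, cheapest unit cost), followed by a footer with the
#' reference-standard cost summary and audit counts.  Output is
#' deterministic for fixed input; the only non-deterministic element, a
#' timestamp, is confined to the optional header line.
#'
#' @param tables List of `hm_ranked_table` objects (see [rank_compounds()]
#'   or [assess_dataset()]).
#' @param cost Optional `hm_cost_summary` (see [cost_summary()]).
#' @param findings Optional findings tibble from [audit_dataset()].
#' @param header Emit a header line (with timestamp)?  Disable for
#'   byte-reproducible output.
#' @return The report as a single string.
#' @export
render_ranking_report <- function(tables = list(), cost = NULL,
                                  findings = NULL, header = FALSE) {
  out <- character()
  if (header) {
    out <- c(out, sprintf("# Herb MaRS ranking report (%s)",
                          format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")))
  }
  out <- c(out,
           "Modified Herb MaRS rubric: total /8 = A+B+C+D+E+F",
           paste("A constituent documented; B symptoms covered (max 3);",
                 "C >=5 ppm; D >=50 ppm; E standard; F method"),
           "")

  hdr <- sprintf("%-26s %2s %2s %2s %2s %2s %2s %5s  %-8s %-12s %s",
                 "compound", "A", "B", "C", "D", "E", "F", "total",
                 "marker", "role", "min cost")
  for (tbl in tables) {
    out <- c(out, sprintf("== %s ==", tbl$plant$botanical_name), hdr,
             strrep("-", nchar(hdr)))
    for (a in tbl$rows) {
      cc <- a$components
      min_cost <- ""
      if (!is.null(cost)) {
        mine <- cost$costs[cost$costs$compound_id == a$compound_id, ]
        if (nrow(mine)) {
          i <- which.min(mine$rounded)
          min_cost <- sprintf("%.1f EUR/%s", mine$rounded[i],
                              mine$pack_unit[i])
        }
      }
      out <- c(out, sprintf(
        "%-26s %2d %2d %2d %2d %2d %2d %5d  %-8s %-12s %s",
        a$name, cc$a, cc$b, cc$c, cc$d, cc$e, cc$f, cc$total,
        if (a$suitable) "yes" else "no", a$role, min_cost))
    }
    out <- c(out, "")
  }

  if (!is.null(cost)) {
    out <- c(out, sprintf(
      paste0("Reference-standard costs (EUR per pack unit, over %d priced",
             " listings): min %.1f (%s), max %.1f (%s), mean %.1f, sd %.1f"),
      cost$n, cost$minimum, cost$argmin, cost$maximum, cost$argmax,
      cost$mean, cost$sd))
  }
  if (!is.null(findings)) {
    counts <- table(factor(findings$kind,
                           levels = c("sum_mismatch", "derivation_mismatch",
                                      "availability_mismatch")))
    out <- c(out, sprintf(
      paste0("Audit: %d finding(s) -- %d sum, %d derivation, ",
             "%d availability; %d record(s) without recorded scores."),
      nrow(findings), counts[["sum_mismatch"]],
      counts[["derivation_mismatch"]], counts[["availability_mismatch"]],
      attr(findings, "skipped") %||% 0L))
  }
  paste(out, collapse = "\n")
}
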