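#' Unit cost of one reference-standard listing
#'
#' Normalizes a pack price to the cost of the smallest denomination: the
#' pack price divided by the numeric pack size, in euro per mg, per mL or
#' per g according to the listing's own pack unit (no cross-unit
#' conversion).  One mg or mL is taken as sufficient for a single external
#' calibration.  The published convention rounds the column to one decimal
#' place, half away from zero; both the exact and the rounded value are
#' returned.
#'
#' @param compound_id Identifier of the owning compound.
#' @param listing An [hm_standard_listing()].
#' @return An `hm_unit_cost` object: list with `compound_id`, `listing`,
#'   `cost_per_unit`, `unit` (`"mg"`, `"mL"` or `"g"`) and `rounded`.
#' @export
#' @examples
#' unit_cost("AI01", hm_standard_listing("Sigma-Aldrich", "~95%",
#'                                       0.5, "mg", 249))$rounded  # 498
unit_cost <- function(compound_id, listing) {
  if (is.null(listing$pack_value) || is.na(listing$pack_value) ||
      listing$pack_value <= 0) {
    stop("invalid listing: pack_value must be > 0", call. = FALSE)
  }
  if (is.null(listing$price_eur) || is.na(listing$price_eur) ||
      listing$price_eur <= 0) {
    stop("invalid listing: price_eur must be > 0", call. = FALSE)
  }
  cpu <- listing$price_eur / listing$pack_value
  structure(
    list(
      compound_id = as.character(compound_id),
      listing = listing,
      cost_per_unit = cpu,
      unit = listing$pack_unit,
      rounded = round_half_up(cpu, 1)
    ),
    class = "hm_unit_cost"
  )
}

#' Unit costs of every priced listing in a dataset
#'
#' @param dataset A [hm_dataset()] document or plain list of
#'   [hm_compound_record()] objects.
#' @return A tibble with one row per priced listing: `compound_id`, `name`,
#'   `vendor`, `grade`, `pack_value`, `pack_unit`, `price_eur`,
#'   `cost_per_unit`, `rounded`.
#' @export
unit_costs <- function(dataset) {
  compounds <- dataset_compounds(dataset)
  rows <- list()
  for (rec in compounds) {
    for (s in rec$standards) {
      uc <- unit_cost(rec$compound_id, s)
      rows[[length(rows) + 1L]] <- tibble(
        compound_id = rec$compound_id, name = rec$name,
        vendor = s$vendor, grade = s$grade,
        pack_value = s$pack_value, pack_unit = s$pack_unit,
        price_eur = s$price_eur,
        cost_per_unit = uc$cost_per_unit, rounded = uc$rounded
      )
    }
  }
  if (!length(rows)) {
    return(tibble(compound_id = character(), name = character(),
                  vendor = character(), grade = character(),
                  pack_value = numeric(), pack_unit = character(),
                  price_eur = numeric(), cost_per_unit = numeric(),
                  rounded = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Summarize reference-standard costs across a dataset
#'
#' Pools the per-unit costs of every priced listing (one value per listing,
#' not per compound) across denominations, exactly as a single published
#' cost column does, and reports minimum, maximum, mean and sample standard
#' deviation together with the owning compounds of the extremes.  By
#' default the summary is computed over the one-decimal rounded costs (the
#' printed-column convention); set `use_rounded = FALSE` for the exact
#' variant.  A per-denomination breakdown is attached as `by_unit` since
#' pooling euro/mg with euro/g is a deliberate fidelity choice, not a
#' physically meaningful aggregate.
#'
#' @param dataset A [hm_dataset()] or list of records with at least one
#'   priced listing.
#' @param use_rounded Summarize rounded (default) or exact unit costs.
#' @return An `hm_cost_summary`: list with `n`, `minimum`, `maximum`,
#'   `mean`, `sd` (sample, `n - 1` denominator; 0 with `single_listing =
#'   TRUE` when `n = 1`), `argmin`, `argmax`, `single_listing`, `by_unit`
#'   (tibble) and the underlying `costs` tibble.
#' @export
cost_summary <- function(dataset, use_rounded = TRUE) {
  costs <- unit_costs(dataset)
  if (!nrow(costs)) stop("no priced listings in the dataset", call. = FALSE)
  vals <- if (use_rounded) costs$rounded else costs$cost_per_unit
  n <- length(vals)
  by_unit <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(costs, .val = vals), .data$pack_unit),
    n = dplyr::n(), minimum = min(.data$.val), maximum = max(.data$.val),
    mean = mean(.data$.val), .groups = "drop"
  )
  structure(
    list(
      n = n,
      minimum = min(vals),
      maximum = max(vals),
      mean = mean(vals),
      sd = if (n > 1L) sd(vals) else 0,
      argmin = costs$compound_id[which.min(vals)],
      argmax = costs$compound_id[which.max(vals)],
      single_listing = n == 1L,
      by_unit = by_unit,
      costs = costs
    ),
    class = "hm_cost_summary"
  )
}

#' @export
print.hm_cost_summary <- function(x, ...) {
  cat(sprintf(
    "<hm_cost_summary> n=%d  min=%.1f (%s)  max=%.1f (%s)  mean=%.1f  sd=%.1f\n",
    x$n, x$minimum, x$argmin, x$maximum, x$argmax, x$mean, x$sd))
  invisible(x)
}

# accept either a dataset document or a bare list of records
dataset_compounds <- function(dataset) {
  if (inherits(dataset, "hm_dataset") ||
      (is.list(dataset) && !is.null(dataset$compounds))) {
    dataset$compounds
  } else {
    dataset
  }
}
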