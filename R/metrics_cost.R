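# Accuracy metrics (PPV, sensitivity, macro averages), road-length clipping,
# and the mileage/trip/dollar cost model.

#' Positive predictive value
#'
#' `tp / (tp + fp)`: the probability that a listed store exists, is open,
#' and is an eligible food outlet.  Undefined (NA) when the list is empty
#' (`tp + fp == 0`); never reported as zero in that case.
#'
#' @param counts a [confusion_counts()] object, or a data frame with `tp`
#'   and `fp` columns (one row per site).
#' @return numeric value (or vector) in `[0, 1]`, NA where undefined.
#' @export
ppv <- function(counts) {
  tp <- counts$tp
  fp <- counts$fp
  ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
}

#' Sensitivity
#'
#' `tp / (tp + fn)`: the probability that an open eligible store appears on
#' the list.  Undefined (NA) when there are no open stores.
#'
#' @param counts a [confusion_counts()] object, or a data frame with `tp`
#'   and `fn` columns.
#' @return numeric value (or vector) in `[0, 1]`, NA where undefined.
#' @export
sensitivity <- function(counts) {
  tp <- counts$tp
  fn <- counts$fn
  ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
}

#' Macro-average of per-site metric values
#'
#' The arithmetic mean of the per-site values — the aggregation used for the
#' headline accuracy figures, as opposed to pooling counts across sites.
#' NA (undefined) values are excluded with a warning; an all-NA input
#' returns NA.
#'
#' @param values numeric vector of per-site metric values.
#' @return the mean of the defined values.
#' @export
macro_average <- function(values) {
  if (length(values) == 0L || all(is.na(values))) {
    return(NA_real_)
  }
  if (anyNA(values)) {
    warning("undefined (NA) metric values excluded from macro average",
            call. = FALSE)
  }
  mean(values, na.rm = TRUE)
}

#' Road length inside the canvass zones
#'
#' Sums the length of the geometric intersection of every road segment with
#' the pooled buffer union of all zones.  Exact (interval arithmetic on the
#' member discs), not a polygon approximation.
#'
#' @param network a `road_network` (see [generate_road_network()]).
#' @param zones a `zone_set` from [build_zones()].
#' @return clipped road length in metres.
#' @export
road_length_in_zones <- function(network, zones) {
  stopifnot(inherits(network, "road_network"), inherits(zones, "zone_set"))
  centers <- zone_centers(zones)
  if (nrow(centers) == 0L || length(network$segments) == 0L) {
    return(0)
  }
  sum(vapply(network$segments, polyline_length_in_discs, numeric(1),
             centers = centers, radius = zones$radius))
}

#' Metres-to-miles conversion constant
#' @format A number: metres per statute mile (1609.344).
#' @export
METERS_PER_MILE <- 1609.344

#' Per-site cost inputs
#'
#' One row per site of the field-cost model.  `driven_miles` is the actual
#' odometer mileage where it was measured; leave it `NA` to estimate it as
#' `road_miles * backtrack_factor` (back-tracking to reach every corner of a
#' road network inflates network miles into driven miles, by about 27 % in
#' town/rural canvassing).
#'
#' @param site character site labels.
#' @param road_miles miles of road within each site's network (or within its
#'   canvass zones, for the modified protocol).
#' @param trips number of day trips to the site.
#' @param round_trip_miles to/from mileage of one trip.
#' @param driven_miles measured canvass mileage; `NA` to estimate.
#' @return tibble of validated cost inputs.
#' @export
cost_inputs <- function(site, road_miles, trips, round_trip_miles,
                        driven_miles = NA_real_) {
  x <- tibble::tibble(site = as.character(site),
                      road_miles = as.numeric(road_miles),
                      trips = as.numeric(trips),
                      round_trip_miles = as.numeric(round_trip_miles),
                      driven_miles = as.numeric(driven_miles))
  if (any(x$road_miles < 0, na.rm = TRUE) || any(x$trips < 0) ||
      any(x$round_trip_miles < 0)) {
    stop("cost inputs must be non-negative", call. = FALSE)
  }
  x
}

#' Mileage and dollar cost report
#'
#' Computes, per site and in total, canvass miles driven, to/from transit
#' miles, total miles, and the corresponding dollar costs, for the
#' traditional and modified protocols, plus the savings the modified
#' protocol would realise.  All arithmetic uses unrounded values; rounding
#' to display precision happens only in [render_table2()].
#'
#' @param traditional,modified [cost_inputs()] tibbles with matching sites.
#' @param backtrack_factor multiplier converting road-network miles into
#'   miles actually driven (default 1.27, i.e. 27 % extra).
#' @param rate_per_mile reimbursement rate in dollars per mile
#'   (default 0.565).
#' @return a `cost_report` object: list with `per_site` (long tibble),
#'   `totals`, and `savings` (amount and percent per metric).
#' @export
cost_report <- function(traditional, modified,
                        backtrack_factor = 1.27, rate_per_mile = 0.565) {
  stopifnot(backtrack_factor >= 1, rate_per_mile >= 0)
  if (!identical(sort(traditional$site), sort(modified$site))) {
    stop("traditional and modified inputs must cover the same sites",
         call. = FALSE)
  }
  expand <- function(x, scenario) {
    driven <- ifelse(is.na(x$driven_miles),
                     x$road_miles * backtrack_factor, x$driven_miles)
    to_from <- x$trips * x$round_trip_miles
    tibble::tibble(
      site = x$site, scenario = scenario,
      road_miles = x$road_miles,
      driven_miles = driven,
      to_from_miles = to_from,
      total_miles = driven + to_from,
      trips = x$trips,
      mileage_cost = driven * rate_per_mile,
      total_cost = (driven + to_from) * rate_per_mile
    )
  }
  per_site <- dplyr::bind_rows(expand(traditional, "traditional"),
                               expand(modified, "modified"))
  totals <- per_site |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(dplyr::across(
      c("road_miles", "driven_miles", "to_from_miles", "total_miles",
        "trips", "mileage_cost", "total_cost"), sum), .groups = "drop")
  tr <- totals[totals$scenario == "traditional", ]
  mo <- totals[totals$scenario == "modified", ]
  metrics <- c("road_miles", "driven_miles", "to_from_miles", "total_miles",
               "trips", "mileage_cost", "total_cost")
  savings <- tibble::tibble(
    metric = metrics,
    traditional = as.numeric(tr[1, metrics]),
    modified = as.numeric(mo[1, metrics])
  )
  savings$amount <- savings$traditional - savings$modified
  savings$pct <- ifelse(savings$traditional > 0,
                        100 * savings$amount / savings$traditional, NA_real_)
  structure(list(per_site = per_site, totals = totals, savings = savings,
                 backtrack_factor = backtrack_factor,
                 rate_per_mile = rate_per_mile),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat("<cost_report>\n")
  print(x$savings)
  invisible(x)
}

#' Round half away from zero
#'
#' Display rounding for report tables (the convention used for printed
#' miles, dollars, and 2-dp metrics), as opposed to R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
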