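# Reading and writing store tables, geometries, configuration, and the
# rendered report tables.  CSV dialect: comma, ".", no thousands separators,
# UTF-8, header row; coordinates at full precision; metrics rounded only at
# render time.

read_csv_checked <- function(path, required, numeric_cols = c("x", "y")) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("", "NA")))
    if (length(bad) > 0L) {
      stop("schema error in ", basename(path), ": non-numeric value '",
           df[[col]][bad[1]], "' in column '", col, "', row ", bad[1],
           call. = FALSE)
    }
    df[[col]] <- v
  }
  dup <- which(duplicated(df$id))
  if (length(dup) > 0L) {
    stop("schema error in ", basename(path), ": duplicate id '",
         df$id[dup[1]], "' in row ", dup[1], call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write one site's tables and geometries
#'
#' Writes `census.csv`, `listing.csv`, and `roads.geojson` into `dir`.
#' Hidden generator columns (`truth_status`, `census_id`) are written when
#' present so a written synthetic site round-trips losslessly.
#'
#' @param bundle a `site_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_site_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "site_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(census = file.path(dir, "census.csv"),
             listing = file.path(dir, "listing.csv"),
             roads = file.path(dir, "roads.geojson"))
  utils::write.csv(bundle$census, paths["census"], row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  utils::write.csv(bundle$listing, paths["listing"], row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  write_roads_geojson(bundle$roads, paths["roads"])
  invisible(paths)
}

#' Read one site's tables and geometries
#'
#' Validates the schema (required columns, numeric coordinates, unique ids)
#' and reports the offending row and field on failure.
#'
#' @param census_path,listing_path,roads_path file paths.
#' @param site_id site label for the bundle.
#' @return a `site_bundle`.
#' @export
read_site_bundle <- function(census_path, listing_path, roads_path,
                             site_id = "site") {
  census <- read_csv_checked(census_path,
                             c("id", "name", "category", "x", "y", "eligible"))
  census$eligible <- census$eligible %in% c("TRUE", "true", "1")
  if ("listed_id" %in% names(census)) {
    census$listed_id[census$listed_id == ""] <- NA_character_
  }
  listing <- read_csv_checked(listing_path,
                              c("id", "name", "category", "x", "y"))
  if ("census_id" %in% names(listing)) {
    listing$census_id[listing$census_id == ""] <- NA_character_
  }
  roads <- read_roads_geojson(roads_path)
  site_bundle(site_id, roads, census, listing)
}

#' Write a road network as GeoJSON LineStrings
#'
#' @param roads a `road_network`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_roads_geojson <- function(roads, path) {
  stopifnot(inherits(roads, "road_network"))
  features <- lapply(seq_along(roads$segments), function(i) {
    m <- roads$segments[[i]]
    list(type = "Feature",
         properties = list(segment = i, length_m = roads$lengths[i]),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(m)),
                                              function(r) c(m[r, 1], m[r, 2]))))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a road network from GeoJSON
#'
#' @param path a GeoJSON file of LineString features with planar metre
#'   coordinates.
#' @return a `road_network`.
#' @export
read_roads_geojson <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("schema error in ", basename(path), ": not a FeatureCollection",
         call. = FALSE)
  }
  segments <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "LineString")) {
      stop("schema error in ", basename(path),
           ": roads must be LineString features", call. = FALSE)
    }
    coords <- f$geometry$coordinates
    if (length(coords) < 2L) {
      stop("schema error in ", basename(path),
           ": LineString with fewer than 2 vertices", call. = FALSE)
    }
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    dimnames(m) <- NULL
    m
  })
  road_network(segments, town_centers = NULL)
}

#' Write cluster zones as GeoJSON polygons
#'
#' Each zone becomes one Polygon feature (outer ring plus any holes) whose
#' rings discretise the exact buffer-union boundary arcs; `member_ids` and
#' the exact area ride along as properties.
#'
#' @param zones a `zone_set`.
#' @param path output file.
#' @param segments_per_quarter arc-export resolution (vertices per quarter
#'   circle).
#' @return invisibly, `path`.
#' @export
write_zones_geojson <- function(zones, path, segments_per_quarter = 64) {
  stopifnot(inherits(zones, "zone_set"))
  features <- lapply(zones$zones, function(z) {
    rings <- disc_union_rings(z$centers, z$radius, segments_per_quarter)
    areas <- vapply(rings, ring_signed_area, numeric(1))
    rings <- rings[order(-areas)]  # outer ring (largest positive) first
    coords <- lapply(rings, function(r) {
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature",
         properties = list(member_ids = as.list(z$member_ids),
                           radius_m = z$radius, area_m2 = z$area),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a classification as CSV
#'
#' @param cls a `classification` from [match_records()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_classification_csv <- function(cls, path) {
  stopifnot(inherits(cls, "classification"))
  utils::write.csv(cls$records, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a validated store list as CSV
#'
#' @param validated a `validated_list` from [simulate_modified()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_validated_csv <- function(validated, path) {
  stopifnot(inherits(validated, "validated_list"))
  utils::write.csv(validated$entries, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Render the accuracy table
#'
#' Lays out per-site confusion counts, PPV, and sensitivity in the wide
#' reference format: one column per site and list, a Total column per list
#' with pooled counts, and the macro (per-site mean) metric values in the
#' Total column.  Counts render as integers; metrics to 2 decimal places,
#' half up.  Missing sites render as NA cells, never silent zeros.
#'
#' @param confusions tibble with columns `site`, `list`, `tp`, `fp`, `fn`
#'   (as from [reference_confusion_counts()] or the pipeline).
#' @return a character data frame ready for [utils::write.csv()].
#' @export
render_accuracy_table <- function(confusions) {
  cc <- tibble::as_tibble(confusions)
  lists <- unique(cc$list)
  sites <- sort(unique(cc$site))
  rows <- c("stores_on_list", "true_positives", "false_positives",
            "false_negatives", "ppv", "sensitivity")
  out <- data.frame(metric = rows, stringsAsFactors = FALSE)
  fmt2 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", round_half_up(x, 2)))
  for (lst in lists) {
    sub <- cc[cc$list == lst, , drop = FALSE]
    vals <- matrix(NA_real_, length(rows), length(sites) + 1L)
    for (j in seq_along(sites)) {
      r <- sub[sub$site == sites[j], , drop = FALSE]
      if (nrow(r) == 1L) {
        vals[, j] <- c(r$tp + r$fp, r$tp, r$fp, r$fn,
                       ppv(r), sensitivity(r))
      }
    }
    vals[1:4, length(sites) + 1L] <- rowSums(vals[1:4, seq_along(sites),
                                                  drop = FALSE])
    # NA cells are rendered explicitly, so the exclusion warning is redundant
    vals[5, length(sites) + 1L] <-
      suppressWarnings(macro_average(vals[5, seq_along(sites)]))
    vals[6, length(sites) + 1L] <-
      suppressWarnings(macro_average(vals[6, seq_along(sites)]))
    cols <- paste0(lst, "_", c(sites, "total"))
    for (j in seq_along(cols)) {
      col <- vals[, j]
      out[[cols[j]]] <- c(ifelse(is.na(col[1:4]), "NA",
                                 format(col[1:4], trim = TRUE)),
                          fmt2(col[5:6]))
    }
  }
  out
}

#' Render the cost table
#'
#' Per-site and total mileage, trip, and dollar rows for both protocols,
#' with miles and dollars rounded half up to whole numbers and savings
#' percentages to whole percent.
#'
#' @param report a [cost_report()].
#' @return a character data frame ready for [utils::write.csv()].
#' @export
render_cost_table <- function(report) {
  stopifnot(inherits(report, "cost_report"))
  ps <- report$per_site
  sites <- unique(ps$site)
  metrics <- c(road_miles = "miles_of_road", driven_miles = "miles_driven",
               mileage_cost = "canvass_mileage_cost",
               to_from_miles = "miles_to_from", total_miles = "total_miles",
               total_cost = "total_mileage_cost", trips = "trips")
  out <- data.frame(metric = unname(metrics), stringsAsFactors = FALSE)
  for (scen in c("traditional", "modified")) {
    sub <- ps[ps$scenario == scen, , drop = FALSE]
    for (s in sites) {
      r <- sub[sub$site == s, , drop = FALSE]
      out[[paste0(scen, "_", s)]] <-
        as.character(round_half_up(as.numeric(r[1, names(metrics)])))
    }
    tot <- report$totals[report$totals$scenario == scen, ]
    out[[paste0(scen, "_total")]] <-
      as.character(round_half_up(as.numeric(tot[1, names(metrics)])))
  }
  sv <- report$savings
  idx <- match(names(metrics), sv$metric)
  out$savings_amount <- as.character(round_half_up(sv$amount[idx]))
  out$savings_pct <- ifelse(is.na(sv$pct[idx]), "NA",
                            as.character(round_half_up(sv$pct[idx])))
  out
}

#' Write the rendered report tables
#'
#' @param results list with elements `accuracy` (confusion tibble) and
#'   optionally `cost` (a [cost_report()]).
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_report_tables <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(results$accuracy)) {
    p <- file.path(dir, "accuracy_table.csv")
    utils::write.csv(render_accuracy_table(results$accuracy), p,
                     row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, accuracy = p)
  }
  if (!is.null(results$cost)) {
    p <- file.path(dir, "cost_table.csv")
    utils::write.csv(render_cost_table(results$cost), p,
                     row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, cost = p)
  }
  if (length(paths) == 0L) {
    stop("no results to write: need at least one of accuracy or cost",
         call. = FALSE)
  }
  invisible(paths)
}
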