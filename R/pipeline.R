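# End-to-end orchestration: generate (or load) sites, classify the listing,
# build cluster zones, simulate both modified scenarios, compute metrics and
# costs, and write the report tables plus a run manifest.

#' Read and validate a pipeline configuration
#'
#' Configurations are YAML or JSON documents (or plain R lists) with fields:
#' `sites` (`"reference"` for the deterministic three-site fixture, or a
#' number of synthetic sites), `seed`, `buffer_radius` (m), optional
#' `linkage_distance` (m, default twice the radius), `assumptions`
#' (subset of `"assume_open"`, `"assume_closed"`), `match_mode`
#' (`"id"` or `"fuzzy"`), `backtrack_factor`, `rate_per_mile`, and an
#' optional `synth` block of [synth_config()] overrides.
#'
#' @param config a file path or a named list.
#' @return a validated configuration list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) {
    stop("config error: configuration must be a list or a YAML/JSON file",
         call. = FALSE)
  }
  defaults <- list(sites = "reference", seed = 20140601,
                   buffer_radius = 200, linkage_distance = NULL,
                   assumptions = c("assume_open", "assume_closed"),
                   match_mode = "id", backtrack_factor = 1.27,
                   rate_per_mile = 0.565, synth = list())
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("config error: unknown field(s) ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$linkage_distance)) {
    cfg$linkage_distance <- 2 * cfg$buffer_radius
  }
  if (!is.numeric(cfg$buffer_radius) || cfg$buffer_radius <= 0) {
    stop("config error: field 'buffer_radius' must be positive",
         call. = FALSE)
  }
  if (!is.numeric(cfg$linkage_distance) || cfg$linkage_distance <= 0) {
    stop("config error: field 'linkage_distance' must be positive",
         call. = FALSE)
  }
  if (!all(cfg$assumptions %in% c("assume_open", "assume_closed")) ||
      length(cfg$assumptions) < 1L) {
    stop("config error: field 'assumptions' must be a non-empty subset of ",
         "assume_open, assume_closed", call. = FALSE)
  }
  if (!cfg$match_mode %in% c("id", "fuzzy")) {
    stop("config error: field 'match_mode' must be 'id' or 'fuzzy'",
         call. = FALSE)
  }
  if (!(identical(cfg$sites, "reference") ||
        (is.numeric(cfg$sites) && cfg$sites >= 1))) {
    stop("config error: field 'sites' must be \"reference\" or a positive ",
         "number of synthetic sites", call. = FALSE)
  }
  cfg
}

# Build the site bundles a config asks for.
pipeline_sites <- function(cfg) {
  if (identical(cfg$sites, "reference")) {
    stats::setNames(lapply(c("A", "B", "C"), make_reference_fixture),
                    c("A", "B", "C"))
  } else {
    n <- as.integer(cfg$sites)
    ids <- sprintf("S%d", seq_len(n))
    stats::setNames(lapply(seq_len(n), function(i) {
      args <- cfg$synth
      args$seed <- cfg$seed + (i - 1L) * 1000L
      generate_site(do.call(synth_config, args), ids[i])
    }), ids)
  }
}

#' Evaluate one site through the full protocol comparison
#'
#' Classifies the listing against the census, builds cluster zones from the
#' listing, simulates the requested modified scenarios, and returns the
#' confusion counts for the commercial list and each scenario, plus the
#' zones and intermediate objects.
#'
#' @param bundle a `site_bundle`.
#' @param buffer_radius zone buffer radius in metres.
#' @param linkage_distance cluster linkage distance in metres.
#' @param assumptions scenarios to simulate.
#' @param policy a [match_policy()].
#' @return list with `confusions` tibble (`site`, `list`, `tp`, `fp`, `fn`),
#'   `classification`, `zones`, and the `validated` lists.
#' @export
evaluate_site <- function(bundle, buffer_radius = 200,
                          linkage_distance = 2 * buffer_radius,
                          assumptions = c("assume_open", "assume_closed"),
                          policy = match_policy()) {
  stopifnot(inherits(bundle, "site_bundle"))
  cls <- match_records(bundle$listing, bundle$census, policy)
  zones <- build_zones(
    link_components(bundle$listing, linkage_distance),
    bundle$listing, buffer_radius)
  conf <- list(tibble::tibble(site = bundle$site_id, list = "commercial",
                              tp = confusion_from_classification(cls)$tp,
                              fp = confusion_from_classification(cls)$fp,
                              fn = confusion_from_classification(cls)$fn))
  validated <- list()
  for (a in assumptions) {
    vl <- simulate_modified(bundle$census, bundle$listing, zones, a, cls)
    cc <- confusion_vs_census(vl, bundle$census)
    conf[[length(conf) + 1L]] <- tibble::tibble(
      site = bundle$site_id, list = a, tp = cc$tp, fp = cc$fp, fn = cc$fn)
    validated[[a]] <- vl
  }
  list(confusions = dplyr::bind_rows(conf), classification = cls,
       zones = zones, validated = validated)
}

#' Run the full pipeline
#'
#' Generates or loads the configured sites, evaluates each one, computes
#' road-mileage costs from the synthetic road networks, writes every stage
#' output (site tables, zone GeoJSON, classification and validated-list
#' CSVs, rendered report tables), and records a run manifest.  A stage
#' failure aborts with the failing stage named.
#'
#' @param config a configuration (path or list); see
#'   [read_pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, the manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  files <- character(0)
  message("stage sites: building site bundles")
  sites <- stage("sites", pipeline_sites(cfg))
  message(sprintf("stage sites: %d site(s)", length(sites)))
  policy <- match_policy(cfg$match_mode)
  confusions <- list()
  trad_rows <- list()
  mod_rows <- list()
  for (sid in names(sites)) {
    b <- sites[[sid]]
    sdir <- file.path(out_dir, paste0("site_", sid))
    files <- c(files, stage("write_site", write_site_bundle(b, sdir)))
    res <- stage("evaluate", evaluate_site(
      b, cfg$buffer_radius, cfg$linkage_distance, cfg$assumptions, policy))
    message(sprintf(
      "stage evaluate [%s]: %d census, %d listed, %d zone(s)",
      sid, nrow(b$census), nrow(b$listing), length(res$zones$zones)))
    zp <- file.path(sdir, "zones.geojson")
    stage("zones", write_zones_geojson(res$zones, zp))
    cp <- file.path(sdir, "classification.csv")
    write_classification_csv(res$classification, cp)
    files <- c(files, zp, cp)
    for (a in names(res$validated)) {
      vp <- file.path(sdir, paste0("validated_", a, ".csv"))
      write_validated_csv(res$validated[[a]], vp)
      files <- c(files, vp)
    }
    confusions[[sid]] <- res$confusions
    road_mi <- b$roads$total_length / METERS_PER_MILE
    zone_mi <- road_length_in_zones(b$roads, res$zones) / METERS_PER_MILE
    trad_rows[[sid]] <- cost_inputs(sid, road_mi, trips = 1,
                                    round_trip_miles = 0)
    mod_rows[[sid]] <- cost_inputs(sid, zone_mi, trips = 1,
                                   round_trip_miles = 0)
  }
  confusions <- dplyr::bind_rows(confusions)
  cost <- stage("cost", cost_report(dplyr::bind_rows(trad_rows),
                                    dplyr::bind_rows(mod_rows),
                                    cfg$backtrack_factor, cfg$rate_per_mile))
  files <- c(files, stage("report", write_report_tables(
    list(accuracy = confusions, cost = cost), out_dir)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("groundtruthr")),
    config = cfg[setdiff(names(cfg), "synth")],
    synth = cfg$synth,
    config_hash = rlang::hash(cfg),
    seed = cfg$seed,
    files = unname(files)
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  message("pipeline complete: ", length(files) + 1L, " files in ", out_dir)
  invisible(manifest)
}
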