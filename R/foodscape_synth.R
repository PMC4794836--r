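# Synthetic town/rural foodscapes: road networks, ground-truth store
# censuses, and error-laden commercial listings with the spatial and error
# structure of small-town food environments, plus a deterministic three-site
# reference fixture with known confusion-count strata.

STORE_CATEGORIES <- c("supermarket", "grocery", "convenience", "gas",
                      "dollar", "restaurant", "pharmacy", "other")

DEFAULT_CATEGORY_PROBS <- c(supermarket = 0.05, grocery = 0.10,
                            convenience = 0.20, gas = 0.15, dollar = 0.05,
                            restaurant = 0.30, pharmacy = 0.05, other = 0.10)

#' Synthetic foodscape configuration
#'
#' Defaults emulate one town/rural study site: a listing of roughly 45-60
#' records, about a third of the true stores missing from the listing,
#' roughly 40 % of listed records that are phantoms or ineligible, nearly
#' all stores concentrated in town-centre clusters, and a small minority
#' (about 7 % of open stores) isolated in the countryside.
#'
#' @param n_town_centers number of town centres (each gets a street grid and
#'   a store cluster).
#' @param grid_lines streets per direction in each town grid.
#' @param grid_spacing street spacing in metres.
#' @param n_rural_roads extra rural connector roads beyond the town-to-town
#'   chain.
#' @param n_clustered_stores open eligible stores placed in clusters,
#'   total across centres.
#' @param n_isolated_stores open eligible stores placed far from any
#'   cluster.
#' @param cluster_dispersion isotropic (per-axis Gaussian) dispersion of
#'   clustered stores around their centre, metres.
#' @param omission_prob probability that a true store is missing from the
#'   commercial listing (such stores surface in the field as new stores).
#' @param phantom_in_zone phantom listing records placed inside clusters.
#' @param phantom_out_zone phantom listing records placed isolated.
#' @param ineligible_count listed establishments that exist but are not
#'   eligible food stores.
#' @param jitter_sd positional error of listed coordinates, metres.
#' @param name_noise_prob probability a listed name is perturbed (an owner
#'   name prefixed, or an operating-company alias substituted).
#' @param isolation_min_separation minimum distance (m) between isolated
#'   placements and every other store, keeping them outside any
#'   default-radius cluster zone.
#' @param area_extent side of the square study area, metres.
#' @param max_placement_retries rejection-sampling cap for isolated
#'   placements.
#' @param seed integer seed; the same config and seed reproduce identical
#'   outputs byte for byte.
#' @return a validated `synth_config` object.
#' @export
synth_config <- function(n_town_centers = 2,
                         grid_lines = 3,
                         grid_spacing = 1000,
                         n_rural_roads = 2,
                         n_clustered_stores = 40,
                         n_isolated_stores = 3,
                         cluster_dispersion = 150,
                         omission_prob = 0.34,
                         phantom_in_zone = 14,
                         phantom_out_zone = 3,
                         ineligible_count = 2,
                         jitter_sd = 15,
                         name_noise_prob = 0.15,
                         isolation_min_separation = 1000,
                         area_extent = 10000,
                         max_placement_retries = 1000,
                         seed = 20140601) {
  cfg <- list(n_town_centers = n_town_centers, grid_lines = grid_lines,
              grid_spacing = grid_spacing, n_rural_roads = n_rural_roads,
              n_clustered_stores = n_clustered_stores,
              n_isolated_stores = n_isolated_stores,
              cluster_dispersion = cluster_dispersion,
              omission_prob = omission_prob,
              phantom_in_zone = phantom_in_zone,
              phantom_out_zone = phantom_out_zone,
              ineligible_count = ineligible_count,
              jitter_sd = jitter_sd, name_noise_prob = name_noise_prob,
              isolation_min_separation = isolation_min_separation,
              area_extent = area_extent,
              max_placement_retries = max_placement_retries,
              seed = seed)
  counts <- c("n_town_centers", "grid_lines", "n_rural_roads",
              "n_clustered_stores", "n_isolated_stores", "phantom_in_zone",
              "phantom_out_zone", "ineligible_count", "max_placement_retries")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != floor(v)) {
      stop(sprintf("config field '%s' must be a non-negative integer", f),
           call. = FALSE)
    }
  }
  for (f in c("omission_prob", "name_noise_prob")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("config field '%s' must be a probability in [0, 1]", f),
           call. = FALSE)
    }
  }
  for (f in c("grid_spacing", "cluster_dispersion", "jitter_sd",
              "isolation_min_separation", "area_extent")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop(sprintf("config field '%s' must be positive", f), call. = FALSE)
    }
  }
  if (cfg$grid_lines < 2) {
    stop("config field 'grid_lines' must be at least 2", call. = FALSE)
  }
  if (!is.numeric(cfg$seed) || cfg$seed != floor(cfg$seed)) {
    stop("config field 'seed' must be an integer", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  for (f in names(unclass(x))) cat(sprintf("  %s: %s\n", f, x[[f]]))
  invisible(x)
}

# Construct a road_network object from a list of polyline matrices.
road_network <- function(segments, town_centers) {
  lengths <- vapply(segments, polyline_length, numeric(1))
  structure(list(segments = segments, lengths = lengths,
                 total_length = sum(lengths)),
            town_centers = town_centers, class = "road_network")
}

#' Length of a polyline
#'
#' @param coords two-column matrix of vertices (metres).
#' @return sum of consecutive vertex-to-vertex Euclidean distances.
#' @export
polyline_length <- function(coords) {
  if (nrow(coords) < 2L) {
    return(0)
  }
  sum(sqrt(rowSums(diff(coords)^2)))
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d segments, total %.2f km (%.1f mi)\n",
              length(x$segments), x$total_length / 1000,
              x$total_length / METERS_PER_MILE))
  invisible(x)
}

#' Generate a synthetic road network
#'
#' Lays a rectangular street grid around each town centre, chains
#' consecutive town centres with straight rural roads, and adds
#' `n_rural_roads` extra rural spurs.  Town centres are placed in the
#' central half of the study square with enough mutual separation that the
#' grids do not overlap.
#'
#' @param config a [synth_config()].
#' @return a `road_network`: list of polyline segments with per-segment and
#'   total lengths; town centres attached as an attribute.
#' @export
generate_road_network <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_town_centers < 1) {
    stop("invalid config: at least one town centre is required",
         call. = FALSE)
  }
  set.seed(config$seed)
  ext <- config$area_extent
  span <- (config$grid_lines - 1) * config$grid_spacing
  min_sep <- span + 1000
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(centers) < config$n_town_centers) {
    cand <- stats::runif(2, 0.25 * ext, 0.75 * ext)
    ok <- nrow(centers) == 0L ||
      all(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >=
            min_sep)
    if (ok) centers <- rbind(centers, cand)
    tries <- tries + 1
    if (tries > config$max_placement_retries) {
      stop("could not place town centres: minimum separation ", min_sep,
           " m not attainable in the study area", call. = FALSE)
    }
  }
  segments <- list()
  half <- span / 2
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    for (k in seq_len(config$grid_lines) - 1L) {
      y <- cy - half + k * config$grid_spacing
      segments[[length(segments) + 1L]] <-
        cbind(c(cx - half, cx + half), c(y, y))
      x <- cx - half + k * config$grid_spacing
      segments[[length(segments) + 1L]] <-
        cbind(c(x, x), c(cy - half, cy + half))
    }
  }
  if (nrow(centers) > 1L) {
    for (i in seq_len(nrow(centers) - 1L)) {
      segments[[length(segments) + 1L]] <-
        rbind(centers[i, ], centers[i + 1L, ])
    }
  }
  if (config$n_rural_roads > 0) {
    for (k in seq_len(config$n_rural_roads)) {
      i <- sample.int(nrow(centers), 1)
      start <- centers[i, ] +
        c(sample(c(-half, half), 1), sample(c(-half, half), 1))
      end <- stats::runif(2, 0, ext)
      segments[[length(segments) + 1L]] <- rbind(start, end)
    }
  }
  segments <- lapply(segments, function(m) {
    m <- unname(as.matrix(m)); dimnames(m) <- NULL; m
  })
  road_network(segments, centers)
}

# Deterministic synthetic store names.
NAME_PLACES <- c("Maple", "Prairie", "Lakeside", "North Star", "Golden",
                 "Cedar", "Valley", "Riverside", "Sunset", "Twin Pines",
                 "Oak Grove", "Main Street")
NAME_TYPES <- list(
  supermarket = c("Supermarket", "Family Foods"),
  grocery = c("Grocery", "Market"),
  convenience = c("Quick Stop", "Corner Store"),
  gas = c("Gas & Go", "Fuel Stop"),
  dollar = c("Dollar Store", "Bargain Mart"),
  restaurant = c("Diner", "Cafe", "Pizza Co"),
  pharmacy = c("Pharmacy", "Drug Store"),
  other = c("Trading Post", "General Store")
)
NAME_OWNERS <- c("Olson", "Johnson", "Nguyen", "Garcia", "Miller", "Zhang")

make_store_names <- function(categories) {
  vapply(categories, function(cat) {
    paste(sample(NAME_PLACES, 1), sample(NAME_TYPES[[cat]], 1))
  }, character(1))
}

#' Generate a ground-truth store census
#'
#' Clustered stores are drawn around each town centre with isotropic
#' Gaussian dispersion; isolated stores are rejection-sampled uniformly,
#' at least twice the dispersion from every centre and at least
#' `isolation_min_separation` from every other store.  A handful of
#' ineligible establishments (listed but not food stores) are also placed in
#' the clusters with `eligible = FALSE`.
#'
#' @param config a [synth_config()].
#' @param roads the [generate_road_network()] output for the same config
#'   (supplies the town centres).
#' @return tibble of census stores: `id`, `name`, `category`, `x`, `y`,
#'   `eligible`.
#' @export
generate_census <- function(config, roads) {
  stopifnot(inherits(config, "synth_config"), inherits(roads, "road_network"))
  set.seed(config$seed + 1L)
  centers <- attr(roads, "town_centers")
  ext <- config$area_extent
  nc <- config$n_clustered_stores
  per <- rep(nc %/% nrow(centers), nrow(centers))
  if (nc %% nrow(centers) > 0) {
    per[seq_len(nc %% nrow(centers))] <- per[seq_len(nc %% nrow(centers))] + 1L
  }
  draw_clustered <- function(center, n) {
    if (n == 0L) return(matrix(numeric(0), ncol = 2))
    pts <- matrix(NA_real_, n, 2)
    for (k in seq_len(n)) {
      repeat {
        p <- center + stats::rnorm(2, sd = config$cluster_dispersion)
        if (all(p >= 0 & p <= ext)) break
      }
      pts[k, ] <- p
    }
    pts
  }
  xy <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    draw_clustered(centers[i, ], per[i])
  }))
  if (is.null(xy)) xy <- matrix(numeric(0), ncol = 2)
  # isolated stores: far from all centres and from everything placed so far
  n_iso <- config$n_isolated_stores
  if (n_iso > 0) {
    for (k in seq_len(n_iso)) {
      tries <- 0
      repeat {
        p <- stats::runif(2, 0, ext)
        far_centers <- all(sqrt((centers[, 1] - p[1])^2 +
                                  (centers[, 2] - p[2])^2) >=
                             2 * config$cluster_dispersion)
        far_stores <- nrow(xy) == 0L ||
          all(sqrt((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2) >=
                config$isolation_min_separation)
        if (far_centers && far_stores) break
        tries <- tries + 1
        if (tries > config$max_placement_retries) {
          stop("could not place isolated store ", k,
               ": separation constraints (>= 2 x dispersion from centres, ",
               "isolation_min_separation between stores) not satisfiable",
               call. = FALSE)
        }
      }
      xy <- rbind(xy, p)
    }
  }
  # ineligible establishments, clustered like ordinary stores
  n_inel <- config$ineligible_count
  if (n_inel > 0) {
    which_center <- sample.int(nrow(centers), n_inel, replace = TRUE)
    for (i in which_center) {
      xy <- rbind(xy, draw_clustered(centers[i, ], 1L))
    }
  }
  n <- nrow(xy)
  if (n == 0L) {
    return(tibble::tibble(id = character(0), name = character(0),
                          category = character(0), x = numeric(0),
                          y = numeric(0), eligible = logical(0)))
  }
  categories <- sample(names(DEFAULT_CATEGORY_PROBS), n, replace = TRUE,
                       prob = DEFAULT_CATEGORY_PROBS)
  tibble::tibble(
    id = sprintf("S%03d", seq_len(n)),
    name = make_store_names(categories),
    category = categories,
    x = xy[, 1], y = xy[, 2],
    eligible = rep(c(TRUE, FALSE), c(n - n_inel, n_inel))
  )
}

#' Generate an error-laden commercial listing from a census
#'
#' Each eligible census store appears on the listing with probability
#' `1 - omission_prob`; omitted stores become the field's "new stores".
#' Ineligible establishments are always listed.  Phantom records (stores
#' that will not be found) are added both inside clusters and isolated, and
#' every listed coordinate is jittered by `jitter_sd`.  The hidden columns
#' `truth_status` (open / not_found / ineligible) and `census_id` carry the
#' generator's ground truth for oracle checks; use
#' [link_census_listing()] to transfer the linkage onto the census.
#'
#' @param census a [generate_census()] tibble.
#' @param config the same [synth_config()].
#' @return tibble of listing records: `id`, `name`, `category`, `x`, `y`,
#'   `truth_status`, `census_id`.
#' @export
generate_listing <- function(census, config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 2L)
  cen <- tibble::as_tibble(census)
  ext <- config$area_extent

  rows <- list()
  eligible <- cen[cen$eligible, , drop = FALSE]
  listed <- stats::runif(nrow(eligible)) >= config$omission_prob
  if (any(listed)) {
    src <- eligible[listed, , drop = FALSE]
    name <- src$name
    noisy <- stats::runif(nrow(src)) < config$name_noise_prob
    for (i in which(noisy)) {
      if (stats::runif(1) < 2 / 3) {
        name[i] <- paste(sample(NAME_OWNERS, 1), name[i])
      } else {
        name[i] <- make_store_names(src$category[i])
      }
    }
    rows$open <- tibble::tibble(
      name = name, category = src$category,
      x = src$x + stats::rnorm(nrow(src), sd = config$jitter_sd),
      y = src$y + stats::rnorm(nrow(src), sd = config$jitter_sd),
      truth_status = "open", census_id = src$id)
  }
  inel <- cen[!cen$eligible, , drop = FALSE]
  if (nrow(inel) > 0L) {
    rows$ineligible <- tibble::tibble(
      name = inel$name, category = inel$category,
      x = inel$x + stats::rnorm(nrow(inel), sd = config$jitter_sd),
      y = inel$y + stats::rnorm(nrow(inel), sd = config$jitter_sd),
      truth_status = "ineligible", census_id = inel$id)
  }
  if (config$phantom_in_zone > 0 && nrow(eligible) > 0L) {
    anchor <- eligible[sample.int(nrow(eligible), config$phantom_in_zone,
                                  replace = TRUE), , drop = FALSE]
    categories <- sample(names(DEFAULT_CATEGORY_PROBS),
                         config$phantom_in_zone, replace = TRUE,
                         prob = DEFAULT_CATEGORY_PROBS)
    rows$phantom_in <- tibble::tibble(
      name = make_store_names(categories), category = categories,
      x = anchor$x + stats::rnorm(nrow(anchor), sd = 40),
      y = anchor$y + stats::rnorm(nrow(anchor), sd = 40),
      truth_status = "not_found", census_id = NA_character_)
  }
  if (config$phantom_out_zone > 0) {
    placed <- cbind(c(cen$x, if (!is.null(rows$phantom_in)) rows$phantom_in$x),
                    c(cen$y, if (!is.null(rows$phantom_in)) rows$phantom_in$y))
    pts <- matrix(NA_real_, 0, 2)
    for (k in seq_len(config$phantom_out_zone)) {
      tries <- 0
      repeat {
        p <- stats::runif(2, 0, ext)
        ok <- (nrow(placed) == 0L ||
                 all(sqrt((placed[, 1] - p[1])^2 +
                            (placed[, 2] - p[2])^2) >=
                       config$isolation_min_separation)) &&
          (nrow(pts) == 0L ||
             all(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >=
                   config$isolation_min_separation))
        if (ok) break
        tries <- tries + 1
        if (tries > config$max_placement_retries) {
          stop("could not place out-of-zone phantom ", k,
               ": isolation_min_separation not satisfiable", call. = FALSE)
        }
      }
      pts <- rbind(pts, p)
    }
    categories <- sample(names(DEFAULT_CATEGORY_PROBS),
                         config$phantom_out_zone, replace = TRUE,
                         prob = DEFAULT_CATEGORY_PROBS)
    rows$phantom_out <- tibble::tibble(
      name = make_store_names(categories), category = categories,
      x = pts[, 1], y = pts[, 2],
      truth_status = "not_found", census_id = NA_character_)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(id = character(0), name = character(0),
                          category = character(0), x = numeric(0),
                          y = numeric(0), truth_status = character(0),
                          census_id = character(0)))
  }
  out$id <- sprintf("L%03d", seq_len(nrow(out)))
  out[, c("id", "name", "category", "x", "y", "truth_status", "census_id")]
}

#' Transfer the generator's listing linkage onto the census
#'
#' Fills the census `listed_id` column from the listing's hidden
#' `census_id` column: an absent `listed_id` marks a store the field crew
#' will discover as new.
#'
#' @param census a census tibble.
#' @param listing the matching [generate_listing()] tibble.
#' @return the census with a `listed_id` column.
#' @export
link_census_listing <- function(census, listing) {
  cen <- tibble::as_tibble(census)
  cen$listed_id <- listing$id[match(cen$id, listing$census_id)]
  cen
}

#' Bundle one site's roads, census, and listing
#'
#' @param site_id site label.
#' @param roads a `road_network`.
#' @param census census tibble.
#' @param listing listing tibble.
#' @return a validated `site_bundle` object.
#' @export
site_bundle <- function(site_id, roads, census, listing) {
  stopifnot(inherits(roads, "road_network"))
  if (anyDuplicated(census$id)) {
    stop("duplicate census ids in site ", site_id, call. = FALSE)
  }
  if (anyDuplicated(listing$id)) {
    stop("duplicate listing ids in site ", site_id, call. = FALSE)
  }
  structure(list(site_id = site_id, roads = roads,
                 census = tibble::as_tibble(census),
                 listing = tibble::as_tibble(listing)),
            class = "site_bundle")
}

#' @export
print.site_bundle <- function(x, ...) {
  cat(sprintf("<site_bundle> %s: %d census stores (%d eligible), %d listing records\n",
              x$site_id, nrow(x$census), sum(x$census$eligible),
              nrow(x$listing)))
  invisible(x)
}

#' Generate a full synthetic site
#'
#' Runs the three generators in sequence (roads, census, listing) under the
#' config's seed and returns the linked bundle.
#'
#' @param config a [synth_config()].
#' @param site_id site label.
#' @return a `site_bundle`.
#' @export
generate_site <- function(config, site_id = "S1") {
  roads <- generate_road_network(config)
  census <- generate_census(config, roads)
  listing <- generate_listing(census, config)
  census <- link_census_listing(census, listing)
  site_bundle(site_id, roads, census, listing)
}

# Per-site strata of the deterministic reference fixture: counts of listed
# open stores in/out of the cluster zone, bad listings (not found or
# ineligible) in/out, and new (unlisted) stores in/out.  These are the
# unique strata consistent with the reference study's per-site confusion
# counts for all three list comparisons.
reference_strata <- function() {
  list(
    A = c(loi = 7,  loo = 0, bi = 6,  bo = 1,  ni = 7,  no = 0),
    B = c(loi = 45, loo = 3, bi = 17, bo = 9,  ni = 21, no = 3),
    C = c(loi = 32, loo = 3, bi = 17, bo = 11, ni = 14, no = 1)
  )
}

#' Reference per-site confusion counts
#'
#' The published three-site confusion counts that the deterministic fixture
#' reproduces end-to-end: one row per site and list.  List `"commercial"`
#' is the raw commercial listing judged against full ground-truthing;
#' `"assume_open"` and `"assume_closed"` are the two modified
#' ground-truthing scenarios.
#'
#' @return tibble with columns `site`, `list`, `tp`, `fp`, `fn`.
#' @export
reference_confusion_counts <- function() {
  tibble::tibble(
    site = rep(c("A", "B", "C"), times = 3),
    list = rep(c("commercial", "assume_open", "assume_closed"), each = 3),
    tp = c(7, 48, 35, 14, 69, 49, 14, 66, 46),
    fp = c(7, 26, 28, 1, 9, 11, 0, 0, 0),
    fn = c(7, 24, 15, 0, 3, 1, 0, 6, 4)
  )
}

#' Reference mileage and trip cost inputs
#'
#' The published per-site cost inputs for the traditional protocol (road
#' miles in the network, actual odometer miles driven, day trips, round-trip
#' transit miles) and the modified protocol (road miles inside cluster
#' zones, one trip per site).
#'
#' @return list with `traditional` and `modified` [cost_inputs()] tibbles.
#' @export
reference_cost_inputs <- function() {
  list(
    traditional = cost_inputs(
      site = c("A", "B", "C"),
      road_miles = c(80, 236, 248),
      trips = c(1, 2, 3),
      round_trip_miles = c(124, 136, 132),
      driven_miles = c(100, 262, 356)
    ),
    modified = cost_inputs(
      site = c("A", "B", "C"),
      road_miles = c(10, 32, 25),
      trips = c(1, 1, 1),
      round_trip_miles = c(124, 136, 132)
    )
  )
}

#' Deterministic three-site reference fixture
#'
#' Builds one of three fixed sites (A, B, C) whose stratum counts — listed
#' open stores in/out of the central cluster, bad listings in/out, new
#' stores in/out — are the unique values consistent with
#' [reference_confusion_counts()].  The geometry guarantees that zone
#' construction on the listing (200 m buffers, 400 m linkage) recovers
#' exactly the intended in/out partition: in-zone records sit on one tight
#' grid; every out-of-zone record is over 3 km from all other listed
#' records; new out-of-zone stores are far outside every zone.  Running the
#' full pipeline on the fixture therefore reproduces every reference
#' confusion-count cell exactly.
#'
#' @param site `"A"`, `"B"`, or `"C"`.
#' @return a `site_bundle`.
#' @export
make_reference_fixture <- function(site = c("A", "B", "C")) {
  site <- match.arg(site)
  s <- reference_strata()[[site]]
  ctr <- c(5000, 5000)

  grid_xy <- function(k) {
    # 8-column grid, 60 m pitch, anchored near the cluster centre
    col <- (k - 1L) %% 8L
    row <- (k - 1L) %/% 8L
    cbind(4800 + 60 * col, 4800 + 60 * row)
  }
  out_slot <- function(m, radius = 4000, offset = 0) {
    th <- 2 * pi * (m + offset) / 16
    cbind(ctr[1] + radius * cos(th), ctr[2] + radius * sin(th))
  }
  categories <- function(n, start = 0) {
    STORE_CATEGORIES[(start + seq_len(n) - 1L) %% length(STORE_CATEGORIES) + 1L]
  }

  n_in_listed <- s[["loi"]] + s[["bi"]]
  in_listed <- grid_xy(seq_len(n_in_listed))
  loo_xy <- if (s[["loo"]] > 0) out_slot(seq_len(s[["loo"]]) - 1L) else
    matrix(numeric(0), ncol = 2)
  bo_xy <- if (s[["bo"]] > 0)
    out_slot(s[["loo"]] + seq_len(s[["bo"]]) - 1L) else
      matrix(numeric(0), ncol = 2)
  ni_xy <- if (s[["ni"]] > 0)
    grid_xy(seq_len(s[["ni"]])) + 30 else matrix(numeric(0), ncol = 2)
  no_xy <- if (s[["no"]] > 0)
    out_slot(seq_len(s[["no"]]) - 1L, radius = 4500, offset = 0.5) else
      matrix(numeric(0), ncol = 2)

  # listing: open in-zone, open out-of-zone, bad in-zone, bad out-of-zone
  lst_xy <- rbind(in_listed[seq_len(s[["loi"]]), , drop = FALSE], loo_xy,
                  if (s[["bi"]] > 0)
                    in_listed[s[["loi"]] + seq_len(s[["bi"]]), ,
                              drop = FALSE] else matrix(numeric(0), ncol = 2),
                  bo_xy)
  n_lst <- nrow(lst_xy)
  n_open <- s[["loi"]] + s[["loo"]]
  listing <- tibble::tibble(
    id = sprintf("%s-L%02d", site, seq_len(n_lst)),
    name = sprintf("Fixture Store %s-%02d", site, seq_len(n_lst)),
    category = categories(n_lst),
    x = lst_xy[, 1], y = lst_xy[, 2],
    truth_status = rep(c("open", "not_found"),
                       c(n_open, s[["bi"]] + s[["bo"]])),
    census_id = c(sprintf("%s-C%02d", site, seq_len(n_open)),
                  rep(NA_character_, s[["bi"]] + s[["bo"]]))
  )

  # census: the open listed stores (same coordinates and names as their
  # records), then new stores in and out of the zone
  cen_xy <- rbind(in_listed[seq_len(s[["loi"]]), , drop = FALSE], loo_xy,
                  ni_xy, no_xy)
  n_cen <- nrow(cen_xy)
  census <- tibble::tibble(
    id = sprintf("%s-C%02d", site, seq_len(n_cen)),
    name = c(listing$name[seq_len(n_open)],
             sprintf("Fixture New Store %s-%02d", site,
                     seq_len(s[["ni"]] + s[["no"]]))),
    category = c(listing$category[seq_len(n_open)],
                 categories(s[["ni"]] + s[["no"]], start = 3)),
    x = cen_xy[, 1], y = cen_xy[, 2],
    eligible = TRUE
  )
  census <- link_census_listing(census, listing)

  # simple fixed street grid around the cluster centre
  half <- 1000
  segments <- list()
  for (k in 0:2) {
    y <- ctr[2] - half + k * 1000
    segments[[length(segments) + 1L]] <- cbind(c(ctr[1] - half,
                                                 ctr[1] + half), c(y, y))
    x <- ctr[1] - half + k * 1000
    segments[[length(segments) + 1L]] <- cbind(c(x, x), c(ctr[2] - half,
                                                          ctr[2] + half))
  }
  roads <- road_network(segments, matrix(ctr, ncol = 2))
  site_bundle(site, roads, census, listing)
}
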