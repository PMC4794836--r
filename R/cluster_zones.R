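# Central commercial clusters: groups of >= 2 listed stores whose buffers
# form the canvass area of the modified ground-truthing protocol.

#' Link listed store locations into cluster components
#'
#' Builds the graph joining points whose pairwise distance is at most
#' `linkage_distance` and returns its connected components of size two or
#' more.  With the default linkage of twice the buffer radius, two stores are
#' linked exactly when their buffers touch or overlap, so each component's
#' buffer union is a single connected canvass area.  Singletons are
#' discarded: an isolated listed store seeds no cluster.
#'
#' @param points data frame with columns `id`, `x`, `y` (one row per listed
#'   store; coordinates in metres).
#' @param linkage_distance maximum distance (m) at which two stores are
#'   considered part of the same cluster. Must be positive.
#' @return list of character vectors of member ids, each sorted, the list
#'   ordered by smallest member id.
#' @export
link_components <- function(points, linkage_distance) {
  stopifnot(is.data.frame(points), all(c("id", "x", "y") %in% names(points)))
  if (!is.numeric(linkage_distance) || linkage_distance <= 0) {
    stop("linkage_distance must be a positive number", call. = FALSE)
  }
  n <- nrow(points)
  if (n < 2L) {
    return(list())
  }
  d <- as.matrix(stats::dist(cbind(points$x, points$y)))
  adj <- d <= linkage_distance
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  ids <- as.character(points$id)
  groups <- split(ids, comp)
  groups <- Filter(function(g) length(g) >= 2L, groups)
  groups <- lapply(groups, function(g) sort(g))
  groups <- unname(groups)
  if (length(groups) == 0L) {
    return(list())
  }
  groups[order(vapply(groups, function(g) g[1], character(1)))]
}

#' Build buffer-union zones around store clusters
#'
#' Expands each cluster of listed stores into its canvass zone: the union of
#' discs of radius `radius` centred on the member stores.  Zones from
#' different clusters are kept separate even if their unions happen to
#' overlap; membership follows the linkage, not the geometry.
#'
#' @param clusters list of member-id vectors, as returned by
#'   [link_components()].
#' @param points the same listed-store data frame the clusters were built
#'   from (columns `id`, `x`, `y`).
#' @param radius buffer radius in metres. The protocol's figure is an eighth
#'   of a mile, stated as 200 m; use 201.168 for the exact conversion.
#' @return an object of class `zone_set`: a list with elements `zones` (each
#'   a list with `member_ids`, `centers`, `radius`, `area`) and `radius`.
#' @export
build_zones <- function(clusters, points, radius = 200) {
  stopifnot(is.numeric(radius), radius > 0)
  ids <- as.character(points$id)
  zones <- lapply(clusters, function(members) {
    idx <- match(members, ids)
    if (anyNA(idx)) {
      stop("cluster member id not present in points: ",
           paste(members[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    centers <- cbind(points$x[idx], points$y[idx])
    list(member_ids = members,
         centers = centers,
         radius = radius,
         area = disc_union_area(centers, radius))
  })
  structure(list(zones = zones, radius = radius), class = "zone_set")
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("<zone_set> %d zone(s), buffer radius %.1f m\n",
              length(x$zones), x$radius))
  for (i in seq_along(x$zones)) {
    z <- x$zones[[i]]
    cat(sprintf("  zone %d: %d members, area %.3f km^2\n",
                i, length(z$member_ids), z$area / 1e6))
  }
  invisible(x)
}

#' Test points against the canvass zones
#'
#' A point is inside the canvass area when it lies within the buffer radius
#' of any member store of any zone; the zone boundary counts as inside.
#'
#' @param x,y numeric vectors of point coordinates (metres).
#' @param zones a `zone_set` from [build_zones()].
#' @return logical vector, `TRUE` where the point falls in some zone.
#' @export
point_in_zones <- function(x, y, zones) {
  stopifnot(inherits(zones, "zone_set"))
  if (length(zones$zones) == 0L) {
    return(rep(FALSE, length(x)))
  }
  centers <- do.call(rbind, lapply(zones$zones, `[[`, "centers"))
  point_in_disc_union(x, y, centers, zones$radius)
}

#' Total canvass area of a zone set
#'
#' Pools every zone's member discs into one union before measuring, so
#' overlap between zones is not double-counted.
#'
#' @inheritParams point_in_zones
#' @return area in square metres.
#' @export
total_zone_area <- function(zones) {
  stopifnot(inherits(zones, "zone_set"))
  if (length(zones$zones) == 0L) {
    return(0)
  }
  centers <- do.call(rbind, lapply(zones$zones, `[[`, "centers"))
  disc_union_area(centers, zones$radius)
}

# All member centres of a zone set as one matrix (internal).
zone_centers <- function(zones) {
  if (length(zones$zones) == 0L) {
    return(matrix(numeric(0), ncol = 2))
  }
  do.call(rbind, lapply(zones$zones, `[[`, "centers"))
}
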