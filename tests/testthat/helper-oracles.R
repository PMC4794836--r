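# Independent oracles and small builders shared across tests.

# Brute-force single-linkage components over the full pairwise distance
# matrix, via hand-rolled union-find; singletons discarded; same ordering
# contract as link_components().
oracle_components <- function(points, linkage_distance) {
  n <- nrow(points)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        d <- sqrt((points$x[i] - points$x[j])^2 +
                    (points$y[i] - points$y[j])^2)
        if (d <= linkage_distance) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(as.character(points$id), roots)
  groups <- Filter(function(g) length(g) >= 2L, groups)
  groups <- lapply(unname(groups), sort)
  if (length(groups) == 0L) return(list())
  groups[order(vapply(groups, `[`, character(1), 1))]
}

# Fine-grid numerical area of a disc union (1 m cells, midpoint rule).
oracle_disc_union_area <- function(centers, radius, cell = 1) {
  xr <- range(centers[, 1]) + c(-radius, radius)
  yr <- range(centers[, 2]) + c(-radius, radius)
  xs <- seq(xr[1] + cell / 2, xr[2], by = cell)
  ys <- seq(yr[1] + cell / 2, yr[2], by = cell)
  g <- expand.grid(x = xs, y = ys)
  inside <- rep(FALSE, nrow(g))
  for (i in seq_len(nrow(centers))) {
    inside <- inside |
      ((g$x - centers[i, 1])^2 + (g$y - centers[i, 2])^2 <= radius^2)
  }
  sum(inside) * cell^2
}

# Riemann-sum length of a segment inside a disc union (dense midpoints).
oracle_segment_length <- function(p, q, centers, radius, n = 20000) {
  t <- (seq_len(n) - 0.5) / n
  xs <- p[1] + t * (q[1] - p[1])
  ys <- p[2] + t * (q[2] - p[2])
  inside <- rep(FALSE, n)
  for (i in seq_len(nrow(centers))) {
    inside <- inside |
      ((xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 <= radius^2)
  }
  mean(inside) * sqrt(sum((q - p)^2))
}

# A small, fast synthetic configuration for replicate batteries.
small_synth_config <- function(seed) {
  synth_config(n_town_centers = 1, n_clustered_stores = 24,
               n_isolated_stores = 2, phantom_in_zone = 6,
               phantom_out_zone = 2, ineligible_count = 1,
               n_rural_roads = 1, seed = seed)
}

# The six-store toy site from first principles: two open listed stores in a
# cluster, one in-cluster phantom, one open listed store far out, one far
# phantom, and one unlisted (new) store far out.
toy_site <- function() {
  listing <- tibble::tibble(
    id = c("L1", "L2", "L3", "L4", "L5"),
    name = c("Alpha Market", "Beta Grocery", "Ghost Mart",
             "Delta Gas", "Ghost Diner"),
    category = c("grocery", "grocery", "convenience", "gas", "restaurant"),
    x = c(0, 100, 50, 5000, 0),
    y = c(0, 0, 50, 0, 5000),
    truth_status = c("open", "open", "not_found", "open", "not_found"),
    census_id = c("C1", "C2", NA, "C3", NA)
  )
  census <- tibble::tibble(
    id = c("C1", "C2", "C3", "C4"),
    name = c("Alpha Market", "Beta Grocery", "Delta Gas", "New Cafe"),
    category = c("grocery", "grocery", "gas", "restaurant"),
    x = c(0, 100, 5000, 5000),
    y = c(0, 0, 0, 5000),
    eligible = TRUE
  )
  census <- link_census_listing(census, listing)
  list(census = census, listing = listing)
}

# Frozen printed accuracy values the fixture reproduces (per site and list).
printed_metrics <- function() {
  tibble::tibble(
    list = rep(c("commercial", "assume_open", "assume_closed"), each = 3),
    site = rep(c("A", "B", "C"), times = 3),
    ppv = c(0.50, 0.65, 0.56, 0.93, 0.88, 0.82, 1.00, 1.00, 1.00),
    sensitivity = c(0.50, 0.67, 0.70, 1.00, 0.96, 0.98, 1.00, 0.92, 0.92)
  )
}
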