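# Exact geometry for unions of equal-radius discs.
#
# Cluster zones are unions of circular buffers of one shared radius, so every
# geometric question the package asks (area, containment, length of a road
# segment inside the canvass area) has a closed-form answer on the discs
# themselves.  Polygons are produced only when exporting to GeoJSON.

#' Area of a union of equal-radius discs
#'
#' Computes the exact area of the union of discs of common radius `radius`
#' centred at the rows of `centers`, via Green's theorem applied to the
#' exposed boundary arcs.  Each disc contributes the arcs of its boundary not
#' covered by any other disc; traversing every exposed arc counter-clockwise
#' puts the union interior on the left, so outer boundaries and holes are
#' handled by the same line integral.
#'
#' @param centers two-column numeric matrix of disc centres (metres).
#' @param radius common disc radius in metres; must be positive.
#' @return area in square metres.
#' @examples
#' disc_union_area(matrix(c(0, 0), ncol = 2), 100) / (pi * 100^2) # 1
#' @export
disc_union_area <- function(centers, radius) {
  centers <- dedupe_centers(centers)
  arcs <- disc_exposed_arcs(centers, radius)
  if (nrow(arcs) == 0L) {
    return(0)
  }
  cx <- centers[arcs$circle, 1]
  cy <- centers[arcs$circle, 2]
  a <- arcs$theta1
  b <- arcs$theta2
  sum(0.5 * (cx * radius * (sin(b) - sin(a)) -
               cy * radius * (cos(b) - cos(a)) +
               radius^2 * (b - a)))
}

#' Point containment in a union of equal-radius discs
#'
#' @param x,y numeric vectors of point coordinates (metres).
#' @inheritParams disc_union_area
#' @param tol boundary tolerance in metres; points within `radius + tol` of a
#'   centre count as inside, so the boundary is inclusive.
#' @return logical vector, one element per point.
#' @export
point_in_disc_union <- function(x, y, centers, radius, tol = 1e-9) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0L) {
    return(logical(0))
  }
  if (is.null(centers) || nrow(centers) == 0L) {
    return(rep(FALSE, length(x)))
  }
  r2 <- (radius + tol)^2
  vapply(seq_along(x), function(i) {
    any((centers[, 1] - x[i])^2 + (centers[, 2] - y[i])^2 <= r2)
  }, logical(1))
}

#' Length of a segment inside a union of equal-radius discs
#'
#' Solves, for each disc, the quadratic giving the parameter interval of the
#' segment inside that disc, then sums the merged interval union.  Exact up
#' to floating point; no discretisation.
#'
#' @param p,q numeric length-2 vectors, the segment endpoints (metres).
#' @inheritParams disc_union_area
#' @return length of `p`--`q` lying inside the union, in metres.
#' @export
segment_length_in_discs <- function(p, q, centers, radius) {
  if (is.null(centers) || nrow(centers) == 0L) {
    return(0)
  }
  v <- q - p
  a <- sum(v * v)
  seg_len <- sqrt(a)
  if (seg_len == 0) {
    return(0)
  }
  ints <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(centers))) {
    w <- p - centers[i, ]
    b <- 2 * sum(w * v)
    cc <- sum(w * w) - radius^2
    disc <- b^2 - 4 * a * cc
    if (disc <= 0) next
    sq <- sqrt(disc)
    t1 <- max(0, (-b - sq) / (2 * a))
    t2 <- min(1, (-b + sq) / (2 * a))
    if (t2 > t1) ints <- rbind(ints, c(t1, t2))
  }
  if (nrow(ints) == 0L) {
    return(0)
  }
  ints <- ints[order(ints[, 1]), , drop = FALSE]
  total <- 0
  cur <- ints[1, ]
  for (i in seq_len(nrow(ints))[-1]) {
    if (ints[i, 1] <= cur[2]) {
      cur[2] <- max(cur[2], ints[i, 2])
    } else {
      total <- total + (cur[2] - cur[1])
      cur <- ints[i, ]
    }
  }
  total <- total + (cur[2] - cur[1])
  total * seg_len
}

#' Length of a polyline inside a union of equal-radius discs
#'
#' @param coords two-column matrix of polyline vertices.
#' @inheritParams disc_union_area
#' @return clipped length in metres.
#' @export
polyline_length_in_discs <- function(coords, centers, radius) {
  if (nrow(coords) < 2L) {
    return(0)
  }
  total <- 0
  for (i in seq_len(nrow(coords) - 1L)) {
    total <- total + segment_length_in_discs(coords[i, ], coords[i + 1L, ],
                                             centers, radius)
  }
  total
}

# Drop duplicate centres (within 1e-9 m); duplicates add nothing to the union
# and break the exposed-arc bookkeeping.
dedupe_centers <- function(centers) {
  if (is.null(centers)) return(matrix(numeric(0), ncol = 2))
  centers <- as.matrix(centers)
  if (nrow(centers) <= 1L) return(centers)
  key <- paste(round(centers[, 1], 9), round(centers[, 2], 9))
  centers[!duplicated(key), , drop = FALSE]
}

# Exposed boundary arcs of each disc in the union: for disc i, the parts of
# its boundary circle not strictly inside any other disc.  Equal radii: the
# arc of circle i inside circle j spans phi_ij +/- acos(d/(2r)) where phi_ij
# is the bearing from centre i to centre j.  Returns a data.frame
# (circle, theta1, theta2) with theta2 > theta1 (theta2 may exceed 2*pi when
# an arc wraps through angle 0).
disc_exposed_arcs <- function(centers, radius) {
  n <- nrow(centers)
  out <- vector("list", n)
  if (n == 0L) {
    return(data.frame(circle = integer(0), theta1 = numeric(0),
                      theta2 = numeric(0)))
  }
  for (i in seq_len(n)) {
    dx <- centers[, 1] - centers[i, 1]
    dy <- centers[, 2] - centers[i, 2]
    d <- sqrt(dx^2 + dy^2)
    nb <- which(d > 0 & d < 2 * radius)
    if (length(nb) == 0L) {
      out[[i]] <- data.frame(circle = i, theta1 = 0, theta2 = 2 * pi)
      next
    }
    phi <- atan2(dy[nb], dx[nb])
    alpha <- acos(pmin(1, d[nb] / (2 * radius)))
    keep <- alpha > 1e-12
    if (!any(keep)) {
      out[[i]] <- data.frame(circle = i, theta1 = 0, theta2 = 2 * pi)
      next
    }
    covered <- merge_circular_intervals(phi[keep] - alpha[keep],
                                        phi[keep] + alpha[keep])
    exposed <- complement_circular_intervals(covered)
    if (nrow(exposed) > 0L) {
      out[[i]] <- data.frame(circle = i, theta1 = exposed$lo,
                             theta2 = exposed$hi)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    data.frame(circle = integer(0), theta1 = numeric(0), theta2 = numeric(0))
  } else {
    res
  }
}

# Merge angular intervals [lo, hi] on the circle into disjoint intervals,
# normalised so each lies within [0, 4*pi) with lo in [0, 2*pi).
merge_circular_intervals <- function(lo, hi) {
  lo2 <- lo %% (2 * pi)
  hi2 <- lo2 + (hi - lo)
  # split intervals that wrap past 2*pi into two plain intervals on [0, 2*pi]
  plain_lo <- c()
  plain_hi <- c()
  for (k in seq_along(lo2)) {
    if (hi2[k] <= 2 * pi) {
      plain_lo <- c(plain_lo, lo2[k]); plain_hi <- c(plain_hi, hi2[k])
    } else {
      plain_lo <- c(plain_lo, lo2[k], 0)
      plain_hi <- c(plain_hi, 2 * pi, hi2[k] - 2 * pi)
    }
  }
  ord <- order(plain_lo)
  plain_lo <- plain_lo[ord]; plain_hi <- plain_hi[ord]
  mlo <- plain_lo[1]; mhi <- plain_hi[1]
  out_lo <- c(); out_hi <- c()
  for (k in seq_along(plain_lo)[-1]) {
    if (plain_lo[k] <= mhi + 1e-12) {
      mhi <- max(mhi, plain_hi[k])
    } else {
      out_lo <- c(out_lo, mlo); out_hi <- c(out_hi, mhi)
      mlo <- plain_lo[k]; mhi <- plain_hi[k]
    }
  }
  out_lo <- c(out_lo, mlo); out_hi <- c(out_hi, mhi)
  data.frame(lo = out_lo, hi = out_hi)
}

# Complement of merged intervals within [0, 2*pi); arcs wrapping through 0
# are returned with hi > 2*pi so theta2 > theta1 always holds.
complement_circular_intervals <- function(cov) {
  if (nrow(cov) == 0L) {
    return(data.frame(lo = 0, hi = 2 * pi))
  }
  lo <- c(); hi <- c()
  # gap before first interval joins gap after last (wrap)
  first_lo <- cov$lo[1]
  last_hi <- cov$hi[nrow(cov)]
  if (nrow(cov) > 1L) {
    for (k in seq_len(nrow(cov) - 1L)) {
      if (cov$lo[k + 1L] - cov$hi[k] > 1e-12) {
        lo <- c(lo, cov$hi[k]); hi <- c(hi, cov$lo[k + 1L])
      }
    }
  }
  wrap_gap <- (first_lo - 0) + (2 * pi - last_hi)
  if (wrap_gap > 1e-12) {
    if (last_hi >= 2 * pi - 1e-12) {
      lo <- c(lo, 0); hi <- c(hi, first_lo)
    } else {
      lo <- c(lo, last_hi); hi <- c(hi, 2 * pi + first_lo)
    }
  }
  if (length(lo) == 0L) {
    data.frame(lo = numeric(0), hi = numeric(0))
  } else {
    data.frame(lo = lo, hi = hi)
  }
}

# Boundary rings of the union, as closed coordinate rings for GeoJSON export.
# Exposed arcs are chained end-to-start; each closed chain becomes one ring.
# Rings with positive signed area are outer boundaries, negative are holes.
# segments_per_quarter controls export resolution only; area and containment
# never go through this discretisation.
disc_union_rings <- function(centers, radius, segments_per_quarter = 64) {
  centers <- dedupe_centers(centers)
  arcs <- disc_exposed_arcs(centers, radius)
  if (nrow(arcs) == 0L) {
    return(list())
  }
  pt_at <- function(i, theta) {
    c(centers[i, 1] + radius * cos(theta), centers[i, 2] + radius * sin(theta))
  }
  n_arc <- nrow(arcs)
  starts <- t(vapply(seq_len(n_arc),
                     function(k) pt_at(arcs$circle[k], arcs$theta1[k]),
                     numeric(2)))
  ends <- t(vapply(seq_len(n_arc),
                   function(k) pt_at(arcs$circle[k], arcs$theta2[k]),
                   numeric(2)))
  key <- function(p) paste(round(p[1], 6), round(p[2], 6))
  start_key <- apply(starts, 1, key)
  used <- rep(FALSE, n_arc)
  rings <- list()
  discretise <- function(k) {
    t1 <- arcs$theta1[k]; t2 <- arcs$theta2[k]
    nseg <- max(2L, ceiling((t2 - t1) / (pi / 2 / segments_per_quarter)))
    th <- seq(t1, t2, length.out = nseg + 1L)
    cbind(centers[arcs$circle[k], 1] + radius * cos(th),
          centers[arcs$circle[k], 2] + radius * sin(th))
  }
  for (k0 in seq_len(n_arc)) {
    if (used[k0]) next
    chain <- k0
    used[k0] <- TRUE
    # full-circle arc closes on itself
    if (arcs$theta2[k0] - arcs$theta1[k0] < 2 * pi - 1e-9) {
      cur_end <- key(ends[k0, ])
      repeat {
        nxt <- which(!used & start_key == cur_end)
        if (length(nxt) == 0L) break
        nxt <- nxt[1]
        chain <- c(chain, nxt)
        used[nxt] <- TRUE
        cur_end <- key(ends[nxt, ])
        if (cur_end == key(starts[k0, ])) break
      }
    }
    ring <- do.call(rbind, lapply(chain, discretise))
    # drop consecutive duplicates at arc joints, then close the ring
    dup <- c(FALSE, rowSums(abs(diff(ring))) < 1e-9)
    ring <- ring[!dup, , drop = FALSE]
    if (nrow(ring) >= 3L) {
      if (any(abs(ring[1, ] - ring[nrow(ring), ]) > 1e-9)) {
        ring <- rbind(ring, ring[1, ])
      }
      rings[[length(rings) + 1L]] <- ring
    }
  }
  rings
}

# Shoelace signed area of a closed ring (positive = counter-clockwise).
ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  0.5 * sum(x[-n] * y[-1] - x[-1] * y[-n])
}
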