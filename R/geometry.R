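# Planar geometry primitives for the overlay machinery.
#
# All polygons live in a projected CRS with metre units. A *ring* is an
# n x 2 numeric matrix of vertices, open (the closing vertex is NOT
# repeated). A *polygon* is a list of rings interpreted with the even-odd
# rule: ring 1 is the exterior, later rings are holes. Grid cells are always
# axis-aligned rectangles, so every intersection the pipeline needs is either
# rectangle-vs-rectangle (closed form) or polygon-vs-rectangle
# (Sutherland-Hodgman, exact for a convex clip window).

#' Signed and absolute polygon ring area
#'
#' Shoelace formula on an open ring (closing vertex not repeated).
#'
#' @param ring n x 2 numeric matrix of vertices.
#' @return Absolute area in squared CRS units.
#' @keywords internal
ring_area <- function(ring) {
  n <- nrow(ring)
  if (is.null(n) || n < 3L) return(0)
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

#' Area of a polygon (exterior minus holes)
#' @param poly list of rings (even-odd rule).
#' @keywords internal
poly_area <- function(poly) {
  if (length(poly) == 0L) return(0)
  a <- ring_area(poly[[1L]])
  if (length(poly) > 1L) {
    a <- a - sum(vapply(poly[-1L], ring_area, numeric(1)))
  }
  max(a, 0)
}

# Clip an open ring against one half-plane. side is one of "xmin","xmax",
# "ymin","ymax"; val the bound. Returns an open ring (possibly 0 rows).
clip_ring_halfplane <- function(ring, side, val) {
  n <- nrow(ring)
  if (is.null(n) || n == 0L) return(ring[0L, , drop = FALSE])
  inside <- switch(side,
    xmin = ring[, 1L] >= val,
    xmax = ring[, 1L] <= val,
    ymin = ring[, 2L] >= val,
    ymax = ring[, 2L] <= val,
    stop("unknown half-plane side: ", side)
  )
  ox <- numeric(2L * n); oy <- numeric(2L * n); m <- 0L
  horiz <- side %in% c("xmin", "xmax")
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- inside[i]; pj_in <- inside[j]
    if (pi_in) {
      m <- m + 1L; ox[m] <- ring[i, 1L]; oy[m] <- ring[i, 2L]
    }
    if (pi_in != pj_in) {
      # edge crosses the boundary: linear interpolation, exact on the bound
      if (horiz) {
        t <- (val - ring[i, 1L]) / (ring[j, 1L] - ring[i, 1L])
        m <- m + 1L; ox[m] <- val
        oy[m] <- ring[i, 2L] + t * (ring[j, 2L] - ring[i, 2L])
      } else {
        t <- (val - ring[i, 2L]) / (ring[j, 2L] - ring[i, 2L])
        m <- m + 1L; oy[m] <- val
        ox[m] <- ring[i, 1L] + t * (ring[j, 1L] - ring[i, 1L])
      }
    }
  }
  cbind(ox[seq_len(m)], oy[seq_len(m)])
}

#' Clip a ring to an axis-aligned rectangle (Sutherland-Hodgman)
#'
#' Exact for a convex clip window. Concave subject rings may come back with
#' degenerate zero-width bridges; these carry zero area and are harmless for
#' every downstream area computation.
#'
#' @param ring open n x 2 ring.
#' @param xmin,ymin,xmax,ymax rectangle bounds.
#' @return Open ring (possibly with 0 rows when disjoint).
#' @keywords internal
clip_ring_rect <- function(ring, xmin, ymin, xmax, ymax) {
  r <- clip_ring_halfplane(ring, "xmin", xmin)
  r <- clip_ring_halfplane(r, "xmax", xmax)
  r <- clip_ring_halfplane(r, "ymin", ymin)
  clip_ring_halfplane(r, "ymax", ymax)
}

#' Clip a polygon (with holes) to a rectangle
#' @return list of rings (even-odd) — exterior clip plus clipped holes.
#' @keywords internal
clip_poly_rect <- function(poly, xmin, ymin, xmax, ymax) {
  out <- lapply(poly, clip_ring_rect, xmin = xmin, ymin = ymin,
                xmax = xmax, ymax = ymax)
  out[vapply(out, nrow, integer(1)) >= 3L]
}

# Bounding box of a polygon: c(xmin, ymin, xmax, ymax).
poly_bbox <- function(poly) {
  xs <- unlist(lapply(poly, function(r) r[, 1L]), use.names = FALSE)
  ys <- unlist(lapply(poly, function(r) r[, 2L]), use.names = FALSE)
  c(min(xs), min(ys), max(xs), max(ys))
}

# Is the polygon a plain axis-aligned rectangle (single 4-vertex ring with
# exactly two distinct x and two distinct y)? Enables the closed-form
# rectangle-overlap fast path used for synthetic mosaics.
poly_is_rect <- function(poly) {
  if (length(poly) != 1L) return(FALSE)
  r <- poly[[1L]]
  nrow(r) == 4L &&
    length(unique(r[, 1L])) == 2L && length(unique(r[, 2L])) == 2L &&
    sum(r[, 1L] == min(r[, 1L])) == 2L && sum(r[, 2L] == min(r[, 2L])) == 2L
}

#' Exact area of the union of polygons by vertical slab decomposition
#'
#' Splits the x-axis at every vertex and every pairwise edge-crossing
#' abscissa; inside a slab no two edges cross, so the vertical order of edges
#' is constant and each polygon's even-odd y-intervals are bounded by linear
#' functions. The union of intervals is resolved at the slab midpoint and
#' integrated as trapezoids, which is exact.
#'
#' Used only where parcels genuinely overlap (same-class union, cross-class
#' overlap detection); the common non-overlapping path never calls it.
#'
#' @param polys list of polygons (each a list of even-odd rings).
#' @return Union area.
#' @keywords internal
union_area <- function(polys) {
  polys <- polys[vapply(polys, length, integer(1)) > 0L]
  if (length(polys) == 0L) return(0)
  # edge table: x1 y1 x2 y2 poly_id (all rings of a polygon share its id)
  ex1 <- c(); ey1 <- c(); ex2 <- c(); ey2 <- c(); pid <- c()
  for (p in seq_along(polys)) {
    for (ring in polys[[p]]) {
      n <- nrow(ring)
      if (n < 3L) next
      j <- c(seq_len(n)[-1L], 1L)
      ex1 <- c(ex1, ring[, 1L]); ey1 <- c(ey1, ring[, 2L])
      ex2 <- c(ex2, ring[j, 1L]); ey2 <- c(ey2, ring[j, 2L])
      pid <- c(pid, rep.int(p, n))
    }
  }
  if (length(ex1) == 0L) return(0)
  xs <- c(ex1, ex2)
  # pairwise proper crossings between non-parallel edges
  ne <- length(ex1)
  if (ne >= 2L) {
    for (a in seq_len(ne - 1L)) {
      dxa <- ex2[a] - ex1[a]; dya <- ey2[a] - ey1[a]
      for (b in (a + 1L):ne) {
        dxb <- ex2[b] - ex1[b]; dyb <- ey2[b] - ey1[b]
        den <- dxa * dyb - dya * dxb
        if (den == 0) next
        t <- ((ex1[b] - ex1[a]) * dyb - (ey1[b] - ey1[a]) * dxb) / den
        u <- ((ex1[b] - ex1[a]) * dya - (ey1[b] - ey1[a]) * dxa) / den
        if (t > 0 && t < 1 && u > 0 && u < 1) {
          xs <- c(xs, ex1[a] + t * dxa)
        }
      }
    }
  }
  xs <- sort(unique(xs))
  total <- 0
  for (s in seq_len(length(xs) - 1L)) {
    x1 <- xs[s]; x2 <- xs[s + 1L]
    w <- x2 - x1
    if (w <= 0) next
    xm <- (x1 + x2) / 2
    cross <- which(pmin(ex1, ex2) < xm & pmax(ex1, ex2) > xm)
    if (length(cross) == 0L) next
    tt <- (xm - ex1[cross]) / (ex2[cross] - ex1[cross])
    ym <- ey1[cross] + tt * (ey2[cross] - ey1[cross])
    t1 <- (x1 - ex1[cross]) / (ex2[cross] - ex1[cross])
    ya <- ey1[cross] + t1 * (ey2[cross] - ey1[cross])
    t2 <- (x2 - ex1[cross]) / (ex2[cross] - ex1[cross])
    yb <- ey1[cross] + t2 * (ey2[cross] - ey1[cross])
    gid <- pid[cross]
    # per polygon: even-odd pairing of crossings sorted by midpoint y
    lo_ym <- c(); hi_ym <- c(); lo_ya <- c(); hi_ya <- c()
    lo_yb <- c(); hi_yb <- c()
    for (p in unique(gid)) {
      k <- which(gid == p)
      o <- k[order(ym[k])]
      np <- length(o)
      if (np < 2L) next
      np <- np - (np %% 2L)
      lo <- o[seq(1L, np, by = 2L)]; hi <- o[seq(2L, np, by = 2L)]
      lo_ym <- c(lo_ym, ym[lo]); hi_ym <- c(hi_ym, ym[hi])
      lo_ya <- c(lo_ya, ya[lo]); hi_ya <- c(hi_ya, ya[hi])
      lo_yb <- c(lo_yb, yb[lo]); hi_yb <- c(hi_yb, yb[hi])
    }
    if (length(lo_ym) == 0L) next
    # merge intervals (order fixed within the slab, so midpoint order rules)
    o <- order(lo_ym)
    cur_lo <- o[1L]; cur_hi <- o[1L]
    flush <- function(loi, hii) {
      ((hi_ya[hii] - lo_ya[loi]) + (hi_yb[hii] - lo_yb[loi])) / 2 * w
    }
    for (i in o[-1L]) {
      if (lo_ym[i] <= hi_ym[cur_hi]) {
        if (hi_ym[i] > hi_ym[cur_hi]) cur_hi <- i
      } else {
        total <- total + flush(cur_lo, cur_hi)
        cur_lo <- i; cur_hi <- i
      }
    }
    total <- total + flush(cur_lo, cur_hi)
  }
  total
}

# Intersection area of two polygons via inclusion-exclusion with the exact
# union: |A ∩ B| = |A| + |B| - |A ∪ B|. Only used for overlap diagnostics.
poly_pair_intersection_area <- function(pa, pb) {
  max(poly_area(pa) + poly_area(pb) - union_area(list(pa, pb)), 0)
}

# Build a rectangle ring (counter-clockwise, open).
rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}
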