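# Independent oracles and small fixture builders used across the suite.

# Exhaustive-search natural breaks: enumerates every contiguous k-partition
# of the sorted values and returns the minimal total within-class SSD. The
# class cost uses the sum-of-squares identity on exact integer prefix sums,
# so for integer-valued inputs the returned SSD is bit-exact and directly
# comparable to the dynamic program.
brute_jenks_ssd <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  cost <- function(i, j) {  # 1-based inclusive segment
    s <- cs[j + 1L] - cs[i]
    q <- cs2[j + 1L] - cs2[i]
    q - s * s / (j - i + 1L)
  }
  best <- Inf
  splits <- utils::combn(n - 1L, k - 1L)
  for (c in seq_len(ncol(splits))) {
    b <- c(0L, splits[, c], n)
    tot <- 0
    for (g in seq_len(k)) tot <- tot + cost(b[g] + 1L, b[g + 1L])
    if (tot < best) best <- tot
  }
  best
}

# Rasterized-counting area oracle: counts 0.1 m pixel centers inside each
# rectangular parcel, per class, within one rectangular cell. Exact when
# parcel coordinates lie on the 0.1 m lattice (no pixel center can sit on a
# boundary).
raster_count_areas <- function(cell, rects, classes, res = 0.1) {
  px <- seq(cell[1] + res / 2, cell[3] - res / 2, by = res)
  py <- seq(cell[2] + res / 2, cell[4] - res / 2, by = res)
  gx <- rep(px, times = length(py))
  gy <- rep(py, each = length(px))
  counts <- numeric(0)
  for (cl in unique(classes)) {
    inside <- rep(FALSE, length(gx))
    for (p in which(classes == cl)) {
      r <- rects[[p]]
      inside <- inside | (gx > r[1] & gx < r[3] & gy > r[2] & gy < r[4])
    }
    counts[cl] <- sum(inside) * res^2
  }
  counts
}

# A cells table for a single rectangular cell, bypassing the raster layer.
one_cell <- function(xmin = 0, ymin = 0, xmax = 100, ymax = 100, pop = 0,
                     cell_id = 1L, crs = "LOCAL:synthetic-metre") {
  out <- data.frame(cell_id = cell_id, row = 1L, col = 1L,
                    xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax,
                    pop = pop, stratum = NA_character_)
  attr(out, "cell_size") <- xmax - xmin
  attr(out, "crs") <- crs
  out
}

# Rectangle parcels helper.
rect_parcels <- function(boxes, classes,
                         water_classes = default_water_classes(),
                         crs = "LOCAL:synthetic-metre") {
  land_parcels(
    geoms = lapply(boxes, function(b) {
      list(cbind(c(b[1], b[3], b[3], b[1]), c(b[2], b[2], b[4], b[4])))
    }),
    classes = classes, water_classes = water_classes, crs = crs
  )
}

# 2 x 2 grid with one nodata pixel: values [[10, NA], [0, 5]].
grid_2x2 <- function(crs = "LOCAL:synthetic-metre") {
  pop_grid(matrix(c(10, NA, 0, 5), 2, 2, byrow = TRUE),
           origin = c(0, 200), cell_size = 100, crs = crs)
}
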