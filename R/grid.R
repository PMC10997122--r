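# Coarse population grid container and vectorization.

#' Construct a coarse population grid
#'
#' An equal-area, axis-aligned square-cell raster of population counts, the
#' source surface to be refined. `values` is oriented like the printed
#' raster: row 1 is the northernmost row. `NA` marks nodata (non-land) cells,
#' which are dropped at vectorization; zero-population cells are kept.
#'
#' @param values Numeric matrix (nrows x ncols); `NA` = nodata; all other
#'   entries must be `>= 0`.
#' @param origin Length-2 numeric `c(x, y)`: the top-left corner of the grid
#'   in CRS units.
#' @param cell_size Cell side length in metres (`> 0`).
#' @param crs CRS identifier string (must be a projected, metre-unit CRS).
#' @return A `pop_grid` object.
#' @export
#' @examples
#' g <- pop_grid(matrix(c(10, NA, 0, 5), 2, 2, byrow = TRUE),
#'               origin = c(0, 200), cell_size = 100, crs = "EPSG:32649")
#' sum(g$values, na.rm = TRUE)
pop_grid <- function(values, origin, cell_size, crs) {
  stopifnot(is.matrix(values), is.numeric(values),
            length(origin) == 2L, is.finite(origin),
            length(cell_size) == 1L, cell_size > 0,
            is.character(crs), length(crs) == 1L, nzchar(crs))
  check_projected_crs(crs)
  neg <- which(!is.na(values) & values < 0)
  if (length(neg) > 0L) {
    stop("negative population at pixel index(es): ",
         paste(utils::head(neg, 10L), collapse = ", "), call. = FALSE)
  }
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size), crs = crs),
    class = "pop_grid"
  )
}

#' @export
print.pop_grid <- function(x, ...) {
  n_ok <- sum(!is.na(x$values))
  cat(sprintf(
    "<pop_grid> %d x %d cells of %g m, %d populated, total %.6g (%s)\n",
    nrow(x$values), ncol(x$values), x$cell_size, n_ok,
    sum(x$values, na.rm = TRUE), x$crs))
  invisible(x)
}

# Known geographic (degree-unit) CRS identifiers; grids must be projected.
GEOGRAPHIC_CRS <- c(
  "EPSG:4326", "EPSG:4490", "EPSG:4269", "EPSG:4258", "EPSG:4283",
  "EPSG:4610", "OGC:CRS84", "CRS84", "WGS84"
)

check_projected_crs <- function(crs) {
  if (toupper(crs) %in% toupper(GEOGRAPHIC_CRS) ||
      grepl("longlat|long/lat", crs, ignore.case = TRUE)) {
    stop("CRS '", crs, "' is geographic (degree units); ",
         "a projected metre-unit CRS is required", call. = FALSE)
  }
  invisible(TRUE)
}

check_same_crs <- function(crs_a, crs_b, what_a = "layer", what_b = "layer") {
  if (!identical(crs_a, crs_b)) {
    stop(sprintf("CRS mismatch: %s has '%s' but %s has '%s'",
                 what_a, crs_a, what_b, crs_b), call. = FALSE)
  }
  invisible(TRUE)
}

#' Vectorize a coarse grid into cell polygons
#'
#' Emits one record per non-nodata pixel with its square footprint and
#' population. Cell ids are assigned row-major from the top-left pixel of the
#' full grid (nodata pixels consume ids but emit no cell), so ids are
#' reproducible regardless of the nodata mask. Total population is conserved
#' exactly: `sum(out$pop) == sum(grid$values, na.rm = TRUE)`.
#'
#' @param grid A [pop_grid()].
#' @return A `data.frame` with columns `cell_id`, `row`, `col`, `xmin`,
#'   `ymin`, `xmax`, `ymax`, `pop`, `stratum` (NA until classified), plus
#'   attributes `cell_size` and `crs`.
#' @export
#' @examples
#' g <- pop_grid(matrix(c(10, NA, 0, 5), 2, 2, byrow = TRUE),
#'               origin = c(0, 200), cell_size = 100, crs = "EPSG:32649")
#' vectorize_grid(g)
vectorize_grid <- function(grid) {
  stopifnot(inherits(grid, "pop_grid"))
  v <- grid$values
  if (all(is.na(v))) stop("no populated cells (all pixels are nodata)",
                          call. = FALSE)
  nr <- nrow(v); nc <- ncol(v); s <- grid$cell_size
  idx <- which(!is.na(t(v)))           # row-major order over the full grid
  rr <- (idx - 1L) %/% nc + 1L
  cc <- (idx - 1L) %% nc + 1L
  out <- data.frame(
    cell_id = idx,
    row = rr, col = cc,
    xmin = grid$origin[1L] + (cc - 1L) * s,
    ymin = grid$origin[2L] - rr * s,
    xmax = grid$origin[1L] + cc * s,
    ymax = grid$origin[2L] - (rr - 1L) * s,
    pop = v[cbind(rr, cc)],
    stratum = NA_character_
  )
  attr(out, "cell_size") <- s
  attr(out, "crs") <- grid$crs
  class(out) <- c("pop_cells", "data.frame")
  out
}

cells_crs <- function(cells) attr(cells, "crs")
cells_size <- function(cells) attr(cells, "cell_size")
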