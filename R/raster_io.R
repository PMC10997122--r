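# Raster I/O: ESRI ASCII grid (.asc), the package's raster interchange
# format. Plain text, self-georeferenced (llcorner + cellsize header),
# lossless here because values are printed with 17 significant digits. The
# CRS travels in a .prj sidecar holding the CRS identifier string.

#' Read a coarse population raster
#'
#' Reads an ESRI ASCII grid plus its `.prj` sidecar. Nodata pixels are
#' masked (`NA`); all other values must be non-negative and are copied
#' bit-exactly. A geographic (degree-unit) CRS is a hard error, as are
#' negative populations.
#'
#' @param path Path to the `.asc` file.
#' @param band Band index; ASCII grids are single-band so only `1` is valid.
#' @param crs CRS identifier to use when no `.prj` sidecar exists.
#' @return A [pop_grid()].
#' @export
read_population_grid <- function(path, band = 1L, crs = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  if (band != 1L) stop("ASCII grids are single-band; band ", band,
                       " not present", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    key <- tolower(parts[1L])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                    "cellsize", "nodata_value")) break
    hdr[[key]] <- as.numeric(parts[2L])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[k]])) stop("malformed ASCII grid header: missing ", k,
                                call. = FALSE)
  }
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(body) != nr * nc) {
    stop("ASCII grid body has ", length(body), " values, expected ", nr * nc,
         call. = FALSE)
  }
  v <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) v[v == hdr$nodata_value] <- NA_real_
  prj <- paste0(tools::file_path_sans_ext(path), ".prj")
  if (file.exists(prj)) {
    crs <- trimws(readLines(prj, warn = FALSE)[1L])
  } else if (is.null(crs)) {
    stop("no .prj sidecar next to ", path,
         " and no crs argument supplied", call. = FALSE)
  }
  check_projected_crs(crs)
  neg <- which(!is.na(v) & v < 0)
  if (length(neg) > 0L) {
    stop("negative population at pixel index(es): ",
         paste(utils::head(neg, 10L), collapse = ", "), call. = FALSE)
  }
  if (all(is.na(v))) stop("no populated cells (raster is all nodata)",
                          call. = FALSE)
  pop_grid(v,
           origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
           cell_size = hdr$cellsize, crs = crs)
}

#' Write a population grid as an ESRI ASCII grid
#'
#' Values are printed at full double precision so a write/read round trip
#' reproduces the grid exactly. The CRS id is written to a `.prj` sidecar.
#'
#' @param grid A [pop_grid()].
#' @param path Output `.asc` path.
#' @param nodata Sentinel written for `NA` pixels.
#' @return `path`, invisibly.
#' @export
write_population_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "pop_grid"))
  v <- grid$values
  if (any(!is.na(v) & v == nodata)) {
    stop("nodata sentinel ", nodata, " collides with a data value",
         call. = FALSE)
  }
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", grid$origin[1L]),
    sprintf("yllcorner %.17g", grid$origin[2L] - nr * grid$cell_size),
    sprintf("cellsize %.17g", grid$cell_size),
    sprintf("NODATA_value %.17g", nodata)
  )
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  writeLines(grid$crs, paste0(tools::file_path_sans_ext(path), ".prj"))
  invisible(path)
}

#' Write fine-cell populations as a raster
#'
#' Assembles the refined fine-cell populations back into a regular grid and
#' writes it with [write_population_grid()]. Fine cells are located by their
#' polygon bounds; pixels with no fine cell become nodata.
#'
#' @param fine Fine-cell `data.frame` (from [downscale()]), columns
#'   `xmin,ymin,xmax,ymax,pop`.
#' @param path Output `.asc` path.
#' @param crs CRS identifier.
#' @return `path`, invisibly.
#' @export
write_fine_raster <- function(fine, path, crs) {
  stopifnot(all(c("xmin", "ymin", "xmax", "ymax", "pop") %in% names(fine)))
  s <- fine$xmax[1L] - fine$xmin[1L]
  x0 <- min(fine$xmin); y1 <- max(fine$ymax)
  cc <- as.integer(round((fine$xmin - x0) / s)) + 1L
  rr <- as.integer(round((y1 - fine$ymax) / s)) + 1L
  v <- matrix(NA_real_, nrow = max(rr), ncol = max(cc))
  v[cbind(rr, cc)] <- fine$pop
  write_population_grid(pop_grid(v, origin = c(x0, y1), cell_size = s,
                                 crs = crs), path)
}
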