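# Vector containers (land parcels, admin units) and GeoJSON / CSV I/O.

#' Construct a land-parcel set
#'
#' @param geoms List of polygons; each polygon is a list of open rings
#'   (n x 2 matrices), ring 1 the exterior, later rings holes.
#' @param classes Character vector of land classes, one per polygon; every
#'   class must belong to `taxonomy`.
#' @param taxonomy Ordered class list; defaults to [default_taxonomy()].
#' @param water_classes Classes treated as water by the zeroing rule.
#' @param crs CRS identifier (projected).
#' @return A `land_parcels` object.
#' @export
land_parcels <- function(geoms, classes, taxonomy = default_taxonomy(),
                         water_classes = default_water_classes(), crs) {
  stopifnot(is.list(geoms), length(geoms) == length(classes),
            is.character(crs), length(crs) == 1L)
  check_projected_crs(crs)
  check_taxonomy(classes, taxonomy)
  bad_water <- setdiff(water_classes, taxonomy)
  if (length(bad_water) > 0L) {
    stop("water class(es) not in taxonomy: ",
         paste(bad_water, collapse = ", "), call. = FALSE)
  }
  geoms <- lapply(seq_along(geoms), function(i) {
    repair_polygon(geoms[[i]], sprintf("parcel %d", i))
  })
  structure(
    list(geoms = geoms, class = as.character(classes), taxonomy = taxonomy,
         water_classes = water_classes, crs = crs),
    class = "land_parcels"
  )
}

#' @export
print.land_parcels <- function(x, ...) {
  cat(sprintf("<land_parcels> %d parcels, %d classes in use (%s)\n",
              length(x$geoms), length(unique(x$class)), x$crs))
  invisible(x)
}

#' Construct an administrative-unit set
#'
#' @param geoms List of polygons (see [land_parcels()] for the layout).
#' @param codes Character unit codes, unique within the set.
#' @param level Level tag: `"township"`, `"county"`, or `"city"`.
#' @param crs CRS identifier (projected).
#' @return An `admin_units` object.
#' @export
admin_units <- function(geoms, codes, level = "township", crs) {
  stopifnot(is.list(geoms), length(geoms) == length(codes))
  level <- match.arg(level, c("township", "county", "city"))
  check_projected_crs(crs)
  if (anyDuplicated(codes)) {
    stop("duplicate admin unit code(s): ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "),
         call. = FALSE)
  }
  geoms <- lapply(seq_along(geoms), function(i) {
    repair_polygon(geoms[[i]], sprintf("admin unit %s", codes[i]))
  })
  structure(
    list(geoms = geoms, code = as.character(codes), level = level, crs = crs),
    class = "admin_units"
  )
}

#' @export
print.admin_units <- function(x, ...) {
  cat(sprintf("<admin_units> %d %s-level units (%s)\n",
              length(x$geoms), x$level, x$crs))
  invisible(x)
}

# Light geometry repair: drop duplicated consecutive vertices and degenerate
# rings; reject rings that still self-intersect (land-use maps are supposed
# to partition space, so a bow-tie is a data error, not something to guess
# around).
repair_polygon <- function(poly, what) {
  if (is.matrix(poly)) poly <- list(poly)
  poly <- lapply(poly, function(ring) {
    ring <- as.matrix(ring)
    n <- nrow(ring)
    if (n >= 2L && all(ring[1L, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
    keep <- c(TRUE, rowSums(abs(diff(ring))) > 0)
    ring[keep, , drop = FALSE]
  })
  poly <- poly[vapply(poly, nrow, integer(1)) >= 3L]
  if (length(poly) == 0L) stop(what, ": degenerate geometry", call. = FALSE)
  for (ring in poly) {
    if (ring_self_intersects(ring)) {
      stop(what, ": self-intersecting ring after repair", call. = FALSE)
    }
  }
  poly
}

ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  if (n > 200L) return(FALSE)  # skip quadratic check on very dense rings
  j <- c(seq_len(n)[-1L], 1L)
  x1 <- ring[, 1L]; y1 <- ring[, 2L]; x2 <- ring[j, 1L]; y2 <- ring[j, 2L]
  for (a in seq_len(n - 2L)) {
    bs <- (a + 2L):n
    bs <- bs[!(a == 1L & bs == n)]     # skip adjacent (shared-vertex) edges
    for (b in bs) {
      dxa <- x2[a] - x1[a]; dya <- y2[a] - y1[a]
      dxb <- x2[b] - x1[b]; dyb <- y2[b] - y1[b]
      den <- dxa * dyb - dya * dxb
      if (den == 0) next
      t <- ((x1[b] - x1[a]) * dyb - (y1[b] - y1[a]) * dxb) / den
      u <- ((x1[b] - x1[a]) * dya - (y1[b] - y1[a]) * dxa) / den
      if (t > 0 && t < 1 && u > 0 && u < 1) return(TRUE)
    }
  }
  FALSE
}

#' Read polygons from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection of Polygon/MultiPolygon features into
#' either a [land_parcels()] or an [admin_units()] set. The CRS is taken
#' from the (legacy-style) top-level `crs` member, or from `crs=`. No
#' reprojection is ever attempted: supply co-registered layers.
#'
#' @param path GeoJSON file.
#' @param class_field Property holding the land class (`kind = "parcels"`)
#'   or the unit code (`kind = "admin"`).
#' @param kind `"parcels"` or `"admin"`.
#' @param taxonomy,water_classes Passed to [land_parcels()].
#' @param level Passed to [admin_units()].
#' @param crs Fallback CRS identifier when the file carries none.
#' @return A `land_parcels` or `admin_units` object.
#' @export
read_polygons <- function(path, class_field, kind = c("parcels", "admin"),
                          taxonomy = default_taxonomy(),
                          water_classes = default_water_classes(),
                          level = "township", crs = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("vector file not found: ", path, call. = FALSE)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop(path, " is not a FeatureCollection",
                                 call. = FALSE)
  file_crs <- tryCatch(gj$crs$properties$name, error = function(e) NULL)
  if (!is.null(file_crs)) crs <- file_crs
  if (is.null(crs)) {
    stop("GeoJSON file carries no crs member and no crs argument supplied",
         call. = FALSE)
  }
  geoms <- vector("list", length(gj$features))
  vals <- character(length(gj$features))
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    val <- f$properties[[class_field]]
    if (is.null(val)) {
      stop(sprintf("feature %d has no property '%s'", i, class_field),
           call. = FALSE)
    }
    vals[i] <- as.character(val)
    geoms[[i]] <- geojson_geometry_to_poly(f$geometry, i)
  }
  if (kind == "parcels") {
    land_parcels(geoms, vals, taxonomy = taxonomy,
                 water_classes = water_classes, crs = crs)
  } else {
    admin_units(geoms, vals, level = level, crs = crs)
  }
}

geojson_geometry_to_poly <- function(geom, i) {
  to_ring <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1L]], p[[2L]])))
    m
  }
  if (identical(geom$type, "Polygon")) {
    lapply(geom$coordinates, to_ring)
  } else if (identical(geom$type, "MultiPolygon")) {
    # flatten: all exteriors and holes of the parts form one even-odd set
    unlist(lapply(geom$coordinates, function(pp) lapply(pp, to_ring)),
           recursive = FALSE)
  } else {
    stop(sprintf("feature %d: unsupported geometry type '%s'", i, geom$type),
         call. = FALSE)
  }
}

#' Write a parcel or admin set to GeoJSON
#'
#' @param x A `land_parcels` or `admin_units` object.
#' @param path Output path.
#' @param class_field Property name for the class/code.
#' @return `path`, invisibly.
#' @export
write_polygons <- function(x, path, class_field = NULL) {
  if (inherits(x, "land_parcels")) {
    vals <- x$class
    if (is.null(class_field)) class_field <- "landuse"
  } else if (inherits(x, "admin_units")) {
    vals <- x$code
    if (is.null(class_field)) class_field <- "code"
  } else stop("x must be land_parcels or admin_units", call. = FALSE)
  feat <- lapply(seq_along(x$geoms), function(i) {
    rings <- lapply(x$geoms[[i]], function(r) {
      rc <- rbind(r, r[1L, ])            # GeoJSON rings are closed
      lapply(seq_len(nrow(rc)), function(k) c(rc[k, 1L], rc[k, 2L]))
    })
    props <- stats::setNames(list(vals[i]), class_field)
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = rings))
  })
  obj <- list(
    type = "FeatureCollection",
    crs = list(type = "name", properties = list(name = x$crs)),
    features = feat
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a census table from CSV
#'
#' @param path CSV file with a header row.
#' @param code_field Column holding the admin unit code.
#' @param pop_field Column holding the census population.
#' @return A `census_table` data.frame with columns `code`, `pop`.
#' @export
read_census_table <- function(path, code_field = "code", pop_field = "pop") {
  if (!file.exists(path)) stop("census file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (f in c(code_field, pop_field)) {
    if (!f %in% names(df)) {
      stop("census table has no column '", f, "'", call. = FALSE)
    }
  }
  census_table(df[[code_field]], df[[pop_field]])
}

#' Construct a census table
#'
#' @param codes Unit codes (unique).
#' @param pops Census populations (non-negative).
#' @return A `census_table` data.frame.
#' @export
census_table <- function(codes, pops) {
  codes <- as.character(codes)
  pops <- suppressWarnings(as.numeric(pops))
  if (anyDuplicated(codes)) {
    stop("duplicate census code(s): ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(pops))) stop("non-numeric census population(s)", call. = FALSE)
  if (any(pops < 0)) {
    stop("negative census population for code(s): ",
         paste(codes[pops < 0], collapse = ", "), call. = FALSE)
  }
  structure(data.frame(code = codes, pop = pops),
            class = c("census_table", "data.frame"))
}

#' Write a census table to CSV
#' @param census A `census_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census_table <- function(census, path) {
  utils::write.csv(as.data.frame(census)[, c("code", "pop")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
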