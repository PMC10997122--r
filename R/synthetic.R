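# Synthetic study areas with known ground truth: a rectangle-mosaic
# land-use landscape, a fine-scale truth population, the coarse raster
# aggregated from it, an administrative partition, and its census table.
# Every layer is consistent with the others by construction, so recovery
# and conservation can be tested without any external download.

#' Scenario configuration
#'
#' @param ncols,nrows Coarse grid shape.
#' @param cell_size Coarse cell side (m).
#' @param factor Refinement factor (fine cell side = `cell_size / factor`).
#' @param densities Named vector: true population per fully-covered *fine*
#'   cell for each land class in play. Water classes are forced to 0.
#' @param n_patches Number of rectangles in the landscape mosaic.
#' @param admin_kx,admin_ky Administrative partition shape (kx x ky
#'   rectangles, snapped to fine-cell boundaries).
#' @param noise_sigma Multiplicative lognormal sigma on truth cells (mean
#'   1, so expected totals are unchanged). 0 = exact scenario.
#' @param census_noise Multiplicative lognormal sigma on census counts.
#' @param taxonomy,water_classes Class taxonomy (defaults as elsewhere).
#' @param seed Integer RNG seed; identical seeds give identical scenarios.
#' @param crs CRS identifier stamped on all layers.
#' @param origin Top-left corner of the study area.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(ncols = 50L, nrows = 50L, cell_size = 100,
                            factor = 4L,
                            densities = c(residential = 50, commercial_service = 30,
                                          industrial_mining_storage = 10,
                                          cultivated = 5, water = 0),
                            n_patches = 120L,
                            admin_kx = 4L, admin_ky = 4L,
                            noise_sigma = 0, census_noise = 0,
                            taxonomy = default_taxonomy(),
                            water_classes = default_water_classes(),
                            seed = 1L, crs = "LOCAL:synthetic-metre",
                            origin = c(500000, 2500000)) {
  stopifnot(ncols >= 1L, nrows >= 1L, cell_size > 0, factor >= 2L,
            length(densities) >= 1L, !is.null(names(densities)),
            n_patches >= length(densities), admin_kx >= 1L, admin_ky >= 1L,
            noise_sigma >= 0, census_noise >= 0)
  check_taxonomy(names(densities), taxonomy)
  if (any(!is.finite(densities)) || any(densities < 0)) {
    stop("densities must be finite and non-negative", call. = FALSE)
  }
  densities[names(densities) %in% water_classes] <- 0
  if (all(densities == 0) && !all(names(densities) %in% water_classes)) {
    stop("all class densities are zero", call. = FALSE)
  }
  structure(list(
    ncols = as.integer(ncols), nrows = as.integer(nrows),
    cell_size = cell_size, factor = as.integer(factor),
    densities = densities, n_patches = as.integer(n_patches),
    admin_kx = as.integer(admin_kx), admin_ky = as.integer(admin_ky),
    noise_sigma = noise_sigma, census_noise = census_noise,
    taxonomy = taxonomy, water_classes = water_classes,
    seed = as.integer(seed), crs = crs, origin = origin
  ), class = "scenario_config")
}

#' Generate a synthetic scenario
#'
#' Builds, from one seed: (a) a land-use mosaic of axis-aligned rectangles
#' exactly tiling the study area (recursive random splits, so all patch
#' areas are exact and boundaries are shared coordinates); (b) truth fine
#' populations `P_I* = sum_j density_j * A(I,j) / fine_area * noise`;
#' (c) the coarse raster as the per-parent sum of truth (coarse and truth
#' are exactly consistent); (d) an admin partition snapped to fine-cell
#' boundaries and (e) its census, the per-unit sum of truth (optionally
#' perturbed).
#'
#' @param config A [scenario_config()].
#' @return List: `config`, `parcels` ([land_parcels()]), `grid`
#'   ([pop_grid()]), `truth` (fine table with `pop` = truth), `fine`
#'   (same table, `pop` unset), `admin` ([admin_units()]), `census`
#'   ([census_table()]), `admin_of_fine` (unit code per fine cell).
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  W <- config$ncols * config$cell_size
  H <- config$nrows * config$cell_size
  x0 <- config$origin[1L]; y1 <- config$origin[2L]

  # recursive random splits: always split the largest rectangle, at a
  # uniform position in the middle 60% of its longer axis
  rects <- data.frame(xmin = x0, ymin = y1 - H, xmax = x0 + W, ymax = y1)
  while (nrow(rects) < config$n_patches) {
    ar <- (rects$xmax - rects$xmin) * (rects$ymax - rects$ymin)
    i <- which.max(ar)
    r <- rects[i, ]
    wx <- r$xmax - r$xmin; wy <- r$ymax - r$ymin
    if (wx >= wy) {
      at <- r$xmin + wx * stats::runif(1L, 0.2, 0.8)
      new <- data.frame(xmin = c(r$xmin, at), ymin = r$ymin,
                        xmax = c(at, r$xmax), ymax = r$ymax)
    } else {
      at <- r$ymin + wy * stats::runif(1L, 0.2, 0.8)
      new <- data.frame(xmin = r$xmin, ymin = c(r$ymin, at),
                        xmax = r$xmax, ymax = c(at, r$ymax))
    }
    rects <- rbind(rects[-i, ], new)
  }
  classes <- names(config$densities)
  # every class appears at least once; the rest drawn uniformly
  lab <- c(classes,
           sample(classes, nrow(rects) - length(classes), replace = TRUE))
  lab <- sample(lab)
  parcels <- land_parcels(
    geoms = lapply(seq_len(nrow(rects)), function(i) {
      list(rect_ring(rects$xmin[i], rects$ymin[i],
                     rects$xmax[i], rects$ymax[i]))
    }),
    classes = lab, taxonomy = config$taxonomy,
    water_classes = config$water_classes, crs = config$crs
  )

  # full coarse cell table (no nodata in synthetic scenarios)
  zeros <- matrix(0, config$nrows, config$ncols)
  g0 <- pop_grid(zeros, origin = c(x0, y1), cell_size = config$cell_size,
                 crs = config$crs)
  cells <- vectorize_grid(g0)
  fine <- build_fine_grid(cells, config$factor)
  ffrag <- intersect_with_landuse(fine, parcels, sliver_tol = 0)

  fine_area <- (config$cell_size / config$factor)^2
  ft <- data.table::as.data.table(ffrag)
  ft[, dens := config$densities[class]]
  tr <- ft[, .(pop = sum(dens * area / fine_area)), by = cell_id]
  truth <- fine
  truth$pop <- 0
  truth$pop[match(tr$cell_id, truth$fine_id)] <- tr$pop
  if (config$noise_sigma > 0) {
    s <- config$noise_sigma
    truth$pop <- truth$pop *
      stats::rlnorm(nrow(truth), meanlog = -s^2 / 2, sdlog = s)
  }

  vals <- rowsum(truth$pop, truth$parent_id)
  v <- matrix(0, config$nrows, config$ncols)
  ids <- as.integer(rownames(vals))
  v[cbind((ids - 1L) %/% config$ncols + 1L,
          (ids - 1L) %% config$ncols + 1L)] <- vals[, 1L]
  grid <- pop_grid(v, origin = c(x0, y1), cell_size = config$cell_size,
                   crs = config$crs)

  # admin partition snapped to fine-cell boundaries, so each fine cell lies
  # in exactly one unit and the census is an exact sum of truth
  fs <- config$cell_size / config$factor
  nfx <- config$ncols * config$factor; nfy <- config$nrows * config$factor
  bx <- x0 + fs * round(seq(0, nfx, length.out = config$admin_kx + 1L))
  by <- (y1 - H) + fs * round(seq(0, nfy, length.out = config$admin_ky + 1L))
  geoms <- list(); codes <- character(0)
  for (iy in seq_len(config$admin_ky)) for (ix in seq_len(config$admin_kx)) {
    geoms <- c(geoms, list(list(rect_ring(bx[ix], by[iy],
                                          bx[ix + 1L], by[iy + 1L]))))
    codes <- c(codes, sprintf("T%02d%02d", ix, iy))
  }
  admin <- admin_units(geoms, codes, level = "township", crs = config$crs)
  cxm <- (truth$xmin + truth$xmax) / 2
  cym <- (truth$ymin + truth$ymax) / 2
  ux <- findInterval(cxm, bx, rightmost.closed = TRUE)
  uy <- findInterval(cym, by, rightmost.closed = TRUE)
  unit_of <- sprintf("T%02d%02d", ux, uy)
  cpop <- rowsum(truth$pop, unit_of)
  cen_pop <- stats::setNames(numeric(length(codes)), codes)
  cen_pop[rownames(cpop)] <- cpop[, 1L]
  if (config$census_noise > 0) {
    s <- config$census_noise
    cen_pop <- cen_pop * stats::rlnorm(length(cen_pop),
                                       meanlog = -s^2 / 2, sdlog = s)
  }
  census <- census_table(codes, as.numeric(cen_pop[codes]))

  list(config = config, parcels = parcels, grid = grid, truth = truth,
       fine = fine, admin = admin, census = census, admin_of_fine = unit_of)
}

#' Write a scenario's layers to disk
#'
#' Emits the same formats the readers consume, so fixtures exercise the
#' real I/O path: `grid.asc` (+`.prj`), `landuse.geojson`,
#' `admin.geojson`, `census.csv`, `truth.csv`.
#'
#' @param scenario A [generate_scenario()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_population_grid(scenario$grid, file.path(dir, "grid.asc"))
  write_polygons(scenario$parcels, file.path(dir, "landuse.geojson"),
                 class_field = "landuse")
  write_polygons(scenario$admin, file.path(dir, "admin.geojson"),
                 class_field = "code")
  write_census_table(scenario$census, file.path(dir, "census.csv"))
  utils::write.csv(
    data.frame(fine_id = scenario$truth$fine_id, pop = scenario$truth$pop),
    file.path(dir, "truth.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
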