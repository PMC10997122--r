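# End-to-end orchestration: vectorize -> overlay -> partition -> weights ->
# redistribute -> downscale -> water rule -> (optional) evaluate, with a
# machine-readable run report.

#' Refine a coarse population grid with land-use parcels
#'
#' Runs the full partition-dasymetric chain on in-memory objects and
#' returns every intermediate table plus a run report. This is the
#' function the file-driven [run_pipeline()] wraps.
#'
#' @param grid A [pop_grid()].
#' @param parcels A [land_parcels()] set in the same CRS.
#' @param k Number of density strata (default 3: low/medium/high).
#' @param factor Refinement factor (default 4).
#' @param sliver_tol Sliver tolerance for the overlay.
#' @param verbose Emit stage banners on `stderr`.
#' @return List with `cells`, `breaks`, `fragments`, `fractions`,
#'   `stratum_weights`, `weights`, `class_pops`, `fine`, `fine_fragments`,
#'   `water` (water-rule diagnostics) and `report`.
#' @export
refine_population <- function(grid, parcels, k = 3L, factor = 4L,
                              sliver_tol = 1e-6, verbose = FALSE) {
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "),
                                            sprintf(...))
  check_same_crs(grid$crs, parcels$crs, "grid", "parcels")

  say("[vectorize] %d x %d grid", nrow(grid$values), ncol(grid$values))
  cells <- vectorize_grid(grid)
  total_in <- sum(cells$pop)

  say("[overlay] %d cells x %d parcels", nrow(cells), length(parcels$geoms))
  fragments <- intersect_with_landuse(cells, parcels, sliver_tol)

  say("[partition] k = %d over %d cells", k, nrow(cells))
  breaks <- if (length(unique(cells$pop)) >= k) {
    jenks_breaks(cells$pop, k = k)
  } else NULL   # degenerate: all (or nearly all) populations equal
  cells <- classify_cells(cells, breaks)

  say("[weights]")
  fractions <- area_fractions(fragments)
  stratum_weights <- partition_class_weights(fractions, cells)
  weights <- composite_weights(fractions, stratum_weights, cells)

  say("[redistribute]")
  class_pops <- redistribute(cells, weights)
  unref <- attr(class_pops, "unrefined")

  say("[downscale] factor %d", factor)
  fine <- build_fine_grid(cells, factor)
  # the fine sliver fraction is scaled by factor^2 so the *absolute* area
  # threshold matches the coarse one: a fine fragment that survives then
  # always has a surviving coarse counterpart A(i,j) > 0
  fine_tol <- min(sliver_tol * factor^2, 0.01)
  fine_fragments <- intersect_with_landuse(fine, parcels, fine_tol)
  fine <- downscale(class_pops, fine, fine_fragments, fragments)

  say("[water rule]")
  water <- apply_water_rule(fine, fine_fragments,
                            water_classes = parcels$water_classes,
                            sliver_tol = max(sliver_tol, 1e-9))
  fine <- water$fine
  total_out <- sum(fine$pop)

  strata_counts <- table(cells$stratum)
  report <- list(
    total_in = total_in,
    total_out = total_out,
    conservation_rel_error = abs(total_out - total_in) / max(total_in, 1),
    n_cells = nrow(cells),
    n_fine = nrow(fine),
    breaks = if (is.null(breaks)) numeric(0) else breaks$breaks,
    strata_counts = as.list(strata_counts),
    stratum_weights = as.data.frame(stratum_weights),
    unrefined_cells = nrow(unref),
    unrefined_mass = sum(unref$pop),
    flagged_water_parents = water$flagged_parents,
    water_moved_mass = water$moved_mass,
    dropped_sliver_area = attr(fragments, "dropped_sliver_area") +
      attr(fine_fragments, "dropped_sliver_area")
  )
  say("[done] in %.6g, out %.6g, rel err %.3g", total_in, total_out,
      report$conservation_rel_error)

  list(cells = cells, breaks = breaks, fragments = fragments,
       fractions = fractions, stratum_weights = stratum_weights,
       weights = weights, class_pops = class_pops, fine = fine,
       fine_fragments = fine_fragments, water = water, report = report)
}

#' Run the pipeline from a config file or list
#'
#' The config (YAML file or equivalent list) either names input layers
#' (`grid`, `landuse`, `admin`, `census` paths) or a `synth` section with
#' [scenario_config()] fields. Outputs — refined raster, audit CSVs and a
#' JSON run report — are written to `out_dir` when given.
#'
#' Config keys: `grid`, `landuse` (+`class_field`), `admin`
#' (+`code_field`), `census` (+`census_code_field`, `census_pop_field`),
#' `synth` (list), `k`, `factor`, `sliver_tol`, `water_classes`,
#' `taxonomy`, `out_dir`, `evaluate` (logical), `verbose`.
#'
#' @param config Path to a YAML file, or a named list.
#' @return The [refine_population()] result, extended with `evaluation`
#'   (when requested) and the paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- function(key, default = NULL) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  k <- cfg("k", 3L); factor <- cfg("factor", 4L)
  sliver_tol <- cfg("sliver_tol", 1e-6)
  taxonomy <- cfg("taxonomy", default_taxonomy())
  water_classes <- cfg("water_classes", default_water_classes())
  verbose <- isTRUE(cfg("verbose", FALSE))

  truth <- NULL; admin <- NULL; census <- NULL
  if (!is.null(config$synth)) {
    sc <- do.call(scenario_config, config$synth)
    scen <- generate_scenario(sc)
    grid <- scen$grid; parcels <- scen$parcels
    admin <- scen$admin; census <- scen$census; truth <- scen$truth
  } else {
    for (key in c("grid", "landuse")) {
      if (is.null(config[[key]])) {
        stop("config must name '", key, "' (or a 'synth' section)",
             call. = FALSE)
      }
    }
    grid <- read_population_grid(config$grid)
    parcels <- read_polygons(config$landuse,
                             class_field = cfg("class_field", "landuse"),
                             kind = "parcels", taxonomy = taxonomy,
                             water_classes = water_classes)
    if (!is.null(config$admin)) {
      admin <- read_polygons(config$admin,
                             class_field = cfg("code_field", "code"),
                             kind = "admin", crs = parcels$crs)
    }
    if (!is.null(config$census)) {
      census <- read_census_table(config$census,
                                  code_field = cfg("census_code_field", "code"),
                                  pop_field = cfg("census_pop_field", "pop"))
    }
  }

  res <- refine_population(grid, parcels, k = k, factor = factor,
                           sliver_tol = sliver_tol, verbose = verbose)

  if (isTRUE(cfg("evaluate", !is.null(admin) && !is.null(census))) &&
      !is.null(admin) && !is.null(census)) {
    res$evaluation <- evaluate_surface(res$fine, admin, census)
    res$report$evaluation <- as.data.frame(res$evaluation)
  }

  out_dir <- cfg("out_dir")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fine_raster(res$fine, file.path(out_dir, "refined.asc"),
                      crs = grid$crs)
    write_fragments(res$fragments, file.path(out_dir, "fragments.csv"))
    write_stratum_weights(res$stratum_weights,
                          file.path(out_dir, "stratum_weights.csv"))
    write_class_populations(res$class_pops,
                            file.path(out_dir, "class_populations.csv"))
    if (!is.null(res$evaluation)) {
      utils::write.csv(as.data.frame(res$evaluation),
                       file.path(out_dir, "evaluation.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(res$report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$paths <- file.path(out_dir, c("refined.asc", "fragments.csv",
                                      "stratum_weights.csv",
                                      "class_populations.csv",
                                      "run_report.json"))
  }
  res$truth <- truth
  res
}

#' Uniform equal-split downscale (baseline)
#'
#' The no-ancillary-data baseline the partition-dasymetric surface is
#' judged against: every coarse cell's population is split equally over its
#' `factor^2` children.
#'
#' @param grid A [pop_grid()].
#' @param factor Refinement factor.
#' @return Fine table with `pop` set.
#' @export
uniform_downscale <- function(grid, factor = 4L) {
  cells <- vectorize_grid(grid)
  fine <- build_fine_grid(cells, factor)
  fine$pop <- cells$pop[match(fine$parent_id, cells$cell_id)] / factor^2
  fine
}
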