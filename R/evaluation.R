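# Accuracy metrics against census counts: standard deviation of the
# estimates, percent RMSE, and the coefficient of determination — the
# numbers from which a Taylor diagram of competing surfaces is drawn.

#' Compute the evaluation metric triple
#'
#' Aligns estimates and census counts by unit code and computes
#' \itemize{
#'   \item `sd` — population standard deviation of the estimates,
#'     `sqrt(mean((X - mean(X))^2))` (1/N, not 1/(N-1): the dispersion of
#'     the surface itself, the radial axis of a Taylor diagram);
#'   \item `pct_rmse` — `100 * sqrt(mean((X - Y)^2)) / mean(Y)`, RMSE as a
#'     percentage of the mean census count;
#'   \item `r2` — `1 - sum((Y - X)^2) / sum((Y - mean(Y))^2)`, which is 1
#'     for a perfect fit, 0 for the predict-the-mean baseline, and negative
#'     for anything worse.
#' }
#'
#' @param estimates Estimated population per unit: a data.frame with
#'   `code`, `pop` (e.g. `apportion_to_admin()$estimates`) or a named
#'   numeric vector.
#' @param census Census counts in the same form (e.g. a [census_table()]).
#' @param region Label stored in the output row.
#' @return One-row `data.frame`: `region`, `n`, `sd`, `pct_rmse`, `r2`,
#'   `mean_census`, `mean_estimate`.
#' @export
#' @examples
#' compute_metrics(c(T01 = 110, T02 = 190, T03 = 310),
#'                 c(T01 = 100, T02 = 200, T03 = 300))
compute_metrics <- function(estimates, census, region = "all") {
  x <- as_code_vector(estimates, "estimates")
  y <- as_code_vector(census, "census")
  only_x <- setdiff(names(x), names(y))
  only_y <- setdiff(names(y), names(x))
  if (length(only_x) > 0L || length(only_y) > 0L) {
    stop("unit codes do not match; only in estimates: [",
         paste(only_x, collapse = ", "), "], only in census: [",
         paste(only_y, collapse = ", "), "]", call. = FALSE)
  }
  y <- y[names(x)]
  n <- length(x)
  if (n < 2L) stop("need at least 2 units, have ", n, call. = FALSE)
  if (mean(y) <= 0) stop("mean census population is not positive",
                         call. = FALSE)
  data.frame(
    region = region,
    n = n,
    sd = sqrt(mean((x - mean(x))^2)),
    pct_rmse = 100 * sqrt(mean((x - y)^2)) / mean(y),
    r2 = 1 - sum((y - x)^2) / sum((y - mean(y))^2),
    mean_census = mean(y),
    mean_estimate = mean(x)
  )
}

as_code_vector <- function(obj, what) {
  if (is.data.frame(obj)) {
    if (!all(c("code", "pop") %in% names(obj))) {
      stop(what, " data.frame needs columns code, pop", call. = FALSE)
    }
    stats::setNames(obj$pop, as.character(obj$code))
  } else if (is.numeric(obj) && !is.null(names(obj))) {
    obj
  } else {
    stop(what, " must be a (code, pop) data.frame or a named numeric vector",
         call. = FALSE)
  }
}

#' Evaluate a population surface against a census table
#'
#' Aggregates the surface to administrative units by area-weighted
#' apportionment and computes the metric triple, for the whole study area
#' and (optionally) per region grouping of units — the per-county panels of
#' a Taylor-diagram comparison. The surface may be a fine-cell table or a
#' [pop_grid()]; both representations give identical metrics.
#'
#' @param surface Fine-cell table with `pop`, or a `pop_grid`.
#' @param admin An [admin_units()] set.
#' @param census A [census_table()] whose codes match the admin units.
#' @param regions Optional data.frame (`code`, `region`) grouping units into
#'   regions; each region with at least 2 units gets its own row.
#' @return `data.frame` of metric rows (see [compute_metrics()]) plus an
#'   `uncovered` attribute from the apportionment.
#' @export
evaluate_surface <- function(surface, admin, census, regions = NULL) {
  if (inherits(surface, "pop_grid")) {
    cells <- vectorize_grid(surface)
    surface <- data.frame(fine_id = cells$cell_id, parent_id = cells$cell_id,
                          xmin = cells$xmin, ymin = cells$ymin,
                          xmax = cells$xmax, ymax = cells$ymax,
                          pop = cells$pop)
    attr(surface, "crs") <- cells_crs(cells)
  }
  app <- apportion_to_admin(surface, admin)
  est <- app$estimates
  cen <- as.data.frame(census)
  missing_est <- setdiff(cen$code, est$code)
  if (length(missing_est) > 0L) {
    stop("census unit(s) with no estimate: ",
         paste(missing_est, collapse = ", "), call. = FALSE)
  }
  out <- compute_metrics(est[est$code %in% cen$code, ], cen, region = "all")
  if (!is.null(regions)) {
    for (rg in unique(regions$region)) {
      codes <- regions$code[regions$region == rg]
      if (sum(cen$code %in% codes) < 2L) next
      out <- rbind(out, compute_metrics(
        est[est$code %in% codes, ],
        cen[cen$code %in% codes, ], region = rg))
    }
  }
  attr(out, "uncovered") <- app$uncovered
  out
}
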