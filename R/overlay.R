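# Overlay: area bookkeeping between grid cells and land-use parcels, nested
# fine-grid construction, and apportionment of cell populations to
# administrative units. Cells are axis-aligned rectangles, so parcel-cell
# intersection is a Sutherland-Hodgman clip (closed-form for rectangular
# parcels); overlapping same-class parcels are unioned exactly before areas
# are summed, and overlaps between different classes are an error because a
# land-use map is expected to partition space.

#' Intersect grid cells with land-use parcels
#'
#' Computes, for every (cell, land class) pair, the intersected area
#' `A(i,j)` — the quantity all downstream weights are built from. Fragments
#' smaller than `sliver_tol` of the cell area are dropped (their total is
#' reported in the `dropped_sliver_area` attribute). Per-cell fragment
#' totals can never exceed the cell area beyond 1e-6 relative: same-class
#' overlaps are unioned first and cross-class overlaps raise an error.
#'
#' @param cells Cell table: columns `cell_id`, `xmin`, `ymin`, `xmax`,
#'   `ymax` (a [vectorize_grid()] result, or the fine table from
#'   [build_fine_grid()] with `fine_id` as id).
#' @param parcels A [land_parcels()] set in the same CRS.
#' @param sliver_tol Sliver threshold as a fraction of cell area, in
#'   `[0, 0.01]`.
#' @return `data.frame` with columns `cell_id`, `class`, `area` (m^2) and
#'   attribute `dropped_sliver_area`.
#' @export
intersect_with_landuse <- function(cells, parcels, sliver_tol = 1e-6) {
  stopifnot(inherits(parcels, "land_parcels"),
            sliver_tol >= 0, sliver_tol <= 0.01)
  cr <- cells_crs(cells)
  if (!is.null(cr)) check_same_crs(cr, parcels$crs, "cells", "parcels")
  id_col <- if ("fine_id" %in% names(cells)) "fine_id" else "cell_id"
  cxmin <- cells$xmin; cymin <- cells$ymin
  cxmax <- cells$xmax; cymax <- cells$ymax
  ids <- cells[[id_col]]
  cell_area <- (cxmax - cxmin) * (cymax - cymin)
  eps <- 1e-9 * sqrt(max(cell_area))

  pieces <- vector("list", length(parcels$geoms))
  geo_store <- new.env(parent = emptyenv())   # clipped geometries by piece key
  for (p in seq_along(parcels$geoms)) {
    poly <- parcels$geoms[[p]]
    bb <- poly_bbox(poly)
    cand <- which(cxmin < bb[3L] & cxmax > bb[1L] &
                  cymin < bb[4L] & cymax > bb[2L])
    if (length(cand) == 0L) next
    if (poly_is_rect(poly)) {
      ix1 <- pmax(cxmin[cand], bb[1L]); ix2 <- pmin(cxmax[cand], bb[3L])
      iy1 <- pmax(cymin[cand], bb[2L]); iy2 <- pmin(cymax[cand], bb[4L])
      a <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
      keep <- a > 0
      if (!any(keep)) next
      pieces[[p]] <- data.table::data.table(
        cell = cand[keep], parcel = p, area = a[keep],
        bx1 = ix1[keep], by1 = iy1[keep], bx2 = ix2[keep], by2 = iy2[keep],
        rect = TRUE)
    } else {
      rows <- vector("list", length(cand)); nr <- 0L
      for (ci in cand) {
        cp <- clip_poly_rect(poly, cxmin[ci], cymin[ci], cxmax[ci], cymax[ci])
        a <- poly_area(cp)
        if (a <= 0) next
        nr <- nr + 1L
        bb2 <- poly_bbox(cp)
        key <- paste0(p, "_", ci)
        assign(key, cp, envir = geo_store)
        rows[[nr]] <- data.table::data.table(
          cell = ci, parcel = p, area = a,
          bx1 = bb2[1L], by1 = bb2[2L], bx2 = bb2[3L], by2 = bb2[4L],
          rect = FALSE)
      }
      if (nr > 0L) pieces[[p]] <- data.table::rbindlist(rows[seq_len(nr)])
    }
  }
  pieces <- data.table::rbindlist(pieces[!vapply(pieces, is.null, logical(1))])
  if (nrow(pieces) == 0L) {
    out <- data.frame(cell_id = ids[0], class = character(0),
                      area = numeric(0))
    attr(out, "dropped_sliver_area") <- 0
    return(out)
  }
  pieces[, class := parcels$class[parcel]]

  # resolve overlaps cell by cell, but only where bounding boxes of two
  # pieces strictly overlap (shared edges in a clean mosaic never trigger
  # it). Plain grouped vectors keep this pass cheap on large fine grids.
  pc_cell <- pieces$cell; pc_parcel <- pieces$parcel
  pc_area <- pieces$area; pc_class <- pieces$class; pc_rect <- pieces$rect
  pc_x1 <- pieces$bx1; pc_y1 <- pieces$by1
  pc_x2 <- pieces$bx2; pc_y2 <- pieces$by2
  ord <- order(pc_cell)
  grp_end <- cumsum(rle(pc_cell[ord])$lengths)
  grp_start <- c(1L, grp_end[-length(grp_end)] + 1L)
  adjust <- list(); na <- 0L
  for (g in which(grp_end - grp_start >= 1L)) {
    kk <- ord[grp_start[g]:grp_end[g]]
    n <- length(kk)
    pr <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    qr <- sequence((n - 1L):1L) + pr
    a <- kk[pr]; b <- kk[qr]
    ov <- pc_x1[a] < pc_x2[b] - eps & pc_x2[a] > pc_x1[b] + eps &
          pc_y1[a] < pc_y2[b] - eps & pc_y2[a] > pc_y1[b] + eps
    if (!any(ov)) next
    ci <- pc_cell[kk[1L]]
    gets <- lapply(kk, function(k) {
      if (pc_rect[k]) {
        list(rect_ring(pc_x1[k], pc_y1[k], pc_x2[k], pc_y2[k]))
      } else {
        get(paste0(pc_parcel[k], "_", ci), envir = geo_store)
      }
    })
    # cross-class overlap is a data error
    for (w in which(ov)) {
      ka <- pr[w]; kb <- qr[w]
      if (pc_class[kk[ka]] == pc_class[kk[kb]]) next
      ia <- poly_pair_intersection_area(gets[[ka]], gets[[kb]])
      if (ia > eps^2 + 1e-9 * min(pc_area[kk[ka]], pc_area[kk[kb]])) {
        stop(sprintf(
          "parcels %d ('%s') and %d ('%s') of different classes overlap by %.6g m^2 in cell %d",
          pc_parcel[kk[ka]], pc_class[kk[ka]], pc_parcel[kk[kb]],
          pc_class[kk[kb]], ia, ids[ci]), call. = FALSE)
      }
    }
    # same-class overlap: replace the summed area by the exact union area
    ov_cls <- unique(pc_class[kk[c(pr[ov], qr[ov])]])
    for (cl in ov_cls) {
      k <- which(pc_class[kk] == cl)
      if (length(k) < 2L) next
      ua <- union_area(gets[k])
      if (ua < sum(pc_area[kk[k]]) - eps^2) {
        na <- na + 1L
        adjust[[na]] <- data.table::data.table(cell = ci, class = cl,
                                               uarea = ua)
      }
    }
  }

  frag <- pieces[, .(area = sum(area)), by = .(cell, class)]
  if (na > 0L) {
    adj <- data.table::rbindlist(adjust)
    frag[adj, on = c("cell", "class"), area := i.uarea]
  }
  frag[, cell_id := ids[cell]]
  frag[, carea := cell_area[cell]]
  tot <- frag[, .(t = sum(area), carea = carea[1L]), by = cell]
  over <- tot[t > carea * (1 + 1e-6)]
  if (nrow(over) > 0L) {
    stop("fragment areas exceed cell area for cell id(s): ",
         paste(utils::head(ids[over$cell], 10L), collapse = ", "),
         call. = FALSE)
  }
  sliver <- frag$area < sliver_tol * frag$carea
  dropped <- sum(frag$area[sliver])
  frag <- frag[!sliver]
  out <- data.frame(cell_id = frag$cell_id, class = frag$class,
                    area = frag$area)
  out <- out[order(out$cell_id, out$class), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_sliver_area") <- dropped
  out
}

#' Build the nested fine grid
#'
#' Tiles every coarse cell with `factor^2` congruent squares; the fine
#' polygons tile the parent exactly, so re-aggregating any per-fine quantity
#' by `parent_id` is the identity on per-coarse totals. Fine ids are
#' `(cell_id - 1) * factor^2 + k` with `k` row-major inside the parent.
#'
#' @param cells A [vectorize_grid()] cell table.
#' @param factor Integer refinement factor `>= 2` (default 4, i.e. 100 m to
#'   25 m).
#' @return `data.frame` with columns `fine_id`, `parent_id`, `xmin`, `ymin`,
#'   `xmax`, `ymax`, `pop` (NA until [downscale()]), carrying the parent
#'   table's `cell_size / factor` and `crs` attributes.
#' @export
build_fine_grid <- function(cells, factor = 4L) {
  if (length(factor) != 1L || factor != as.integer(factor) || factor < 2L) {
    stop("factor must be a single integer >= 2", call. = FALSE)
  }
  factor <- as.integer(factor)
  n <- nrow(cells)
  s <- cells$xmax[1L] - cells$xmin[1L]
  fs <- s / factor
  k <- factor * factor
  idx <- rep(seq_len(n), each = k)
  sub <- rep(seq_len(k), times = n)          # row-major inside the parent
  sr <- (sub - 1L) %/% factor                # 0-based sub-row from the top
  sc <- (sub - 1L) %% factor
  out <- data.frame(
    fine_id = (cells$cell_id[idx] - 1) * k + sub,
    parent_id = cells$cell_id[idx],
    xmin = cells$xmin[idx] + sc * fs,
    ymin = cells$ymax[idx] - (sr + 1) * fs,
    xmax = cells$xmin[idx] + (sc + 1) * fs,
    ymax = cells$ymax[idx] - sr * fs,
    pop = NA_real_
  )
  attr(out, "cell_size") <- fs
  attr(out, "crs") <- cells_crs(cells)
  out
}

#' Apportion fine-cell populations to administrative units
#'
#' A fine cell intersecting several units contributes to each in proportion
#' to intersected area; mass falling outside every unit is returned as the
#' `uncovered` diagnostic, so that
#' `sum(estimates$pop) + uncovered == sum(fine$pop)`.
#'
#' @param fine Fine-cell table with `pop` set.
#' @param admin An [admin_units()] set in the same CRS.
#' @return List with `estimates` (data.frame `code`, `pop`, one row per
#'   admin unit) and `uncovered` (population mass outside all units).
#' @export
apportion_to_admin <- function(fine, admin) {
  stopifnot(inherits(admin, "admin_units"))
  if (any(is.na(fine$pop))) stop("fine populations not set", call. = FALSE)
  cr <- cells_crs(fine)
  if (!is.null(cr)) check_same_crs(cr, admin$crs, "fine cells", "admin units")
  carea <- (fine$xmax - fine$xmin) * (fine$ymax - fine$ymin)
  est <- numeric(length(admin$geoms))
  assigned <- numeric(nrow(fine))
  for (u in seq_along(admin$geoms)) {
    poly <- admin$geoms[[u]]
    bb <- poly_bbox(poly)
    cand <- which(fine$xmin < bb[3L] & fine$xmax > bb[1L] &
                  fine$ymin < bb[4L] & fine$ymax > bb[2L])
    if (length(cand) == 0L) next
    if (poly_is_rect(poly)) {
      a <- pmax(pmin(fine$xmax[cand], bb[3L]) - pmax(fine$xmin[cand], bb[1L]), 0) *
           pmax(pmin(fine$ymax[cand], bb[4L]) - pmax(fine$ymin[cand], bb[2L]), 0)
    } else {
      a <- vapply(cand, function(ci) {
        poly_area(clip_poly_rect(poly, fine$xmin[ci], fine$ymin[ci],
                                 fine$xmax[ci], fine$ymax[ci]))
      }, numeric(1))
    }
    share <- fine$pop[cand] * a / carea[cand]
    est[u] <- sum(share)
    assigned[cand] <- assigned[cand] + share
  }
  uncovered <- sum(fine$pop) - sum(est)
  if (abs(uncovered) < 1e-9 * max(sum(fine$pop), 1)) uncovered <- 0
  list(
    estimates = data.frame(code = admin$code, pop = est),
    uncovered = uncovered
  )
}

#' Export a fragment table to CSV
#' @param fragments Result of [intersect_with_landuse()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  df <- data.frame(cell_id = fragments$cell_id, class = fragments$class,
                   area_m2 = fragments$area)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
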