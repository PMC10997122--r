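# Dasymetric downscaling of class populations to the nested fine grid, and
# the all-water zeroing rule.

#' Downscale class populations to the fine grid
#'
#' Each fine cell receives, for every class present in its parent,
#' `P_I = sum_j P(i,j) * A(I,j) / A(i,j)` — the parent's class population
#' times the fine cell's share of the parent's class area. Because the fine
#' cells tile the parent and both fragment tables come from the same parcel
#' set, per-parent totals reproduce `P_i`; the residual actually observed
#' (from dropped slivers) is returned as a diagnostic. Fine cells with no
#' fragments get 0 from the formula. Unrefined parents (no coarse
#' fragments) fall back to an equal split of `P_i` over their `factor^2`
#' children: conservation over invented structure.
#'
#' @param class_pops Class-population table from [redistribute()] (its
#'   `unrefined` attribute drives the fallback).
#' @param fine Fine-cell table from [build_fine_grid()].
#' @param fine_fragments Fragments of the fine cells
#'   ([intersect_with_landuse()] on `fine`), computed against the same
#'   parcel set as the coarse fragments.
#' @param fragments Coarse fragment table (provides `A(i,j)`).
#' @return The fine table with `pop` set; attribute `residual` is a
#'   data.frame (`cell_id`, `expected`, `got`) for parents whose children
#'   fail to reproduce `P_i` within 1e-9 relative.
#' @export
downscale <- function(class_pops, fine, fine_fragments, fragments) {
  cp <- data.table::as.data.table(class_pops)
  cf <- data.table::as.data.table(fragments)
  ff <- data.table::as.data.table(fine_fragments)
  data.table::setnames(ff, "cell_id", "fine_id")
  ff[, parent_id := fine$parent_id[match(fine_id, fine$fine_id)]]
  if (any(is.na(ff$parent_id))) {
    stop("fine fragments reference unknown fine ids", call. = FALSE)
  }
  ff <- merge(ff, cf[, .(parent_id = cell_id, class, A_ij = area)],
              by = c("parent_id", "class"), all.x = TRUE)
  bad <- is.na(ff$A_ij) | ff$A_ij <= 0
  if (any(bad)) {
    stop("fine fragment class with no coarse area A(i,j): parent id(s) ",
         paste(utils::head(unique(ff$parent_id[bad]), 10L), collapse = ", "),
         "; coarse and fine overlays are inconsistent", call. = FALSE)
  }
  ff <- merge(ff, cp[, .(parent_id = cell_id, class, P_ij = pop)],
              by = c("parent_id", "class"), all.x = TRUE)
  # a parent class with fragments but no redistributed population can only
  # happen for unrefined parents, which never have coarse fragments — so
  # anything left NA here is an internal inconsistency
  if (any(is.na(ff$P_ij))) {
    stop("fine fragments reference classes with no redistributed population",
         call. = FALSE)
  }
  contrib <- ff[, .(pop = sum(P_ij * area / A_ij)), by = fine_id]
  fine$pop <- 0
  fine$pop[match(contrib$fine_id, fine$fine_id)] <- contrib$pop
  # equal-split fallback for unrefined parents
  unref <- attr(class_pops, "unrefined")
  if (!is.null(unref) && nrow(unref) > 0L) {
    k <- sum(fine$parent_id == fine$parent_id[1L])
    m <- match(fine$parent_id, unref$cell_id)
    hit <- !is.na(m)
    fine$pop[hit] <- unref$pop[m[hit]] / k
  }
  # conservation audit per parent
  got <- rowsum(fine$pop, fine$parent_id)
  exp_tot <- rowsum(cp$pop, cp$cell_id)
  if (!is.null(unref) && nrow(unref) > 0L) {
    exp_tot <- rbind(exp_tot, matrix(unref$pop, ncol = 1L,
                                     dimnames = list(unref$cell_id, NULL)))
  }
  common <- intersect(rownames(got), rownames(exp_tot))
  g <- got[common, 1L]; e <- exp_tot[common, 1L]
  off <- abs(g - e) > 1e-9 * pmax(e, 1)
  attr(fine, "residual") <- data.frame(
    cell_id = as.integer(common[off]), expected = e[off], got = g[off],
    row.names = NULL)
  fine
}

#' Zero all-water fine cells and redistribute their mass within the parent
#'
#' A fine cell whose mapped area is entirely water (coverage of water
#' classes at least `1 - sliver_tol` of the cell area) is forced to zero
#' population; the mass it carried moves to its non-water siblings in
#' proportion to their pre-rule populations (equal shares if those are all
#' zero), so parent totals never change. A parent whose children are all
#' water but which carries population cannot satisfy both the rule and
#' conservation; the rule is skipped there and the parent is flagged.
#'
#' @param fine Fine table with `pop` set ([downscale()] output).
#' @param fine_fragments Fine fragment table.
#' @param water_classes Classes counted as water.
#' @param sliver_tol Coverage tolerance for "entirely water".
#' @return List: `fine` (adjusted table), `flagged_parents` (integer ids),
#'   `moved_mass` (total population moved off water cells).
#' @export
apply_water_rule <- function(fine, fine_fragments,
                             water_classes = default_water_classes(),
                             sliver_tol = 1e-6) {
  if (any(is.na(fine$pop))) stop("fine populations not set", call. = FALSE)
  ff <- data.table::as.data.table(fine_fragments)
  wat <- ff[class %in% water_classes, .(warea = sum(area)), by = cell_id]
  carea <- (fine$xmax - fine$xmin) * (fine$ymax - fine$ymin)
  wa <- numeric(nrow(fine))
  wa[match(wat$cell_id, fine$fine_id)] <- wat$warea
  is_water <- wa >= (1 - sliver_tol) * carea
  flagged <- integer(0)
  moved <- 0
  if (any(is_water)) {
    for (pid in unique(fine$parent_id[is_water])) {
      rows <- which(fine$parent_id == pid)
      wrows <- rows[is_water[rows]]
      drows <- rows[!is_water[rows]]
      mass <- sum(fine$pop[wrows])
      if (length(drows) == 0L) {
        if (sum(fine$pop[rows]) > 0) flagged <- c(flagged, pid)
        next
      }
      fine$pop[wrows] <- 0
      if (mass > 0) {
        base <- fine$pop[drows]
        share <- if (sum(base) > 0) base / sum(base)
                 else rep(1 / length(drows), length(drows))
        fine$pop[drows] <- base + mass * share
        moved <- moved + mass
      }
    }
  }
  list(fine = fine, flagged_parents = as.integer(flagged),
       moved_mass = moved)
}
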