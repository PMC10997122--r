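# Dual-constraint weighting: within-cell area weights, stratum land-class
# weights, and their normalized product, the composite weight that drives
# the reallocation.

#' Within-cell land-class area fractions
#'
#' For every cell with fragments, `WA(i,j) = A(i,j) / sum_j A(i,j)`: the
#' share of the cell's mapped area in class j. This one table plays both
#' roles in the model — it is the per-cell area weight and, cell by cell,
#' the unnormalized contribution to the stratum land-class weight.
#'
#' @param fragments Fragment table from [intersect_with_landuse()].
#' @return `data.frame` with columns `cell_id`, `class`, `wa`; rows sum to 1
#'   within each cell.
#' @export
area_fractions <- function(fragments) {
  dt <- data.table::as.data.table(fragments)
  if (nrow(dt) == 0L) {
    return(data.frame(cell_id = integer(0), class = character(0),
                      wa = numeric(0)))
  }
  dt[, wa := area / sum(area), by = cell_id]
  out <- data.frame(cell_id = dt$cell_id, class = dt$class, wa = dt$wa)
  out[order(out$cell_id, out$class), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Stratum land-class weights
#'
#' For each density stratum m, the normalized propensity of land class j to
#' carry population:
#' `D_mj = sum_{i in m} WA(i,j) / sum_{i in m} sum_j WA(i,j)`.
#' Because per-cell fractions sum to one, the denominator equals the number
#' of stratum-m cells with fragments and `D_mj` is the mean area fraction of
#' class j over those cells; both forms are computed and checked against
#' each other. A class absent from every cell of a stratum gets weight 0.
#'
#' @param fractions Output of [area_fractions()].
#' @param strata Either a classified cell table (with `cell_id`, `stratum`)
#'   or a data.frame with those two columns.
#' @return `data.frame` with columns `stratum`, `class`, `weight`; attribute
#'   `n_cells` (named integer vector: fragment-bearing cells per stratum).
#'   Rows sum to 1 within each stratum.
#' @export
partition_class_weights <- function(fractions, strata) {
  st <- data.frame(cell_id = strata$cell_id,
                   stratum = as.character(strata$stratum))
  if (any(is.na(st$stratum))) {
    stop("unclassified cell(s); run classify_cells first", call. = FALSE)
  }
  dt <- data.table::as.data.table(fractions)
  dt[, stratum := st$stratum[match(cell_id, st$cell_id)]]
  if (any(is.na(dt$stratum))) {
    stop("cell(s) in fractions without a stratum label: ",
         paste(utils::head(unique(dt$cell_id[is.na(dt$stratum)]), 5L),
               collapse = ", "), call. = FALSE)
  }
  empty <- setdiff(unique(st$stratum), unique(dt$stratum))
  if (length(empty) > 0L) {
    warning("stratum(s) without fragment-bearing cells omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  num <- dt[, .(num = sum(wa)), by = .(stratum, class)]
  den <- dt[, .(den = sum(wa), n = length(unique(cell_id))), by = stratum]
  # the normalizer of the stratum weight is exactly the cell count
  if (any(abs(den$den - den$n) > 1e-9 * pmax(den$n, 1))) {
    stop("internal error: stratum weight denominator != cell count",
         call. = FALSE)
  }
  tab <- merge(num, den, by = "stratum")
  tab[, weight := num / den]
  # second form: mean area fraction over stratum cells — must agree
  chk <- dt[, .(w2 = sum(wa)), by = .(stratum, class)]
  chk[den, on = "stratum", w2 := w2 / i.n]
  m <- merge(tab, chk, by = c("stratum", "class"))
  if (any(abs(m$weight - m$w2) > 1e-12)) {
    stop("internal error: stratum weight forms disagree", call. = FALSE)
  }
  # complete the (stratum x class) grid with zeros for absent classes
  grid <- data.table::CJ(stratum = unique(dt$stratum),
                         class = unique(dt$class))
  out <- merge(grid, tab[, .(stratum, class, weight)],
               by = c("stratum", "class"), all.x = TRUE)
  out[is.na(weight), weight := 0]
  res <- data.frame(stratum = out$stratum, class = out$class,
                    weight = out$weight)
  res <- res[order(res$stratum, res$class), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_cells") <- stats::setNames(den$n, den$stratum)
  res
}

#' Composite (dual-constraint) weights
#'
#' Combines the stratum land-class weight with the within-cell area weight:
#' `f(i,j) = D_mj * WA(i,j)`, renormalized per cell to
#' `F(i,j) = f(i,j) / sum_j f(i,j)`. For any cell with fragments the
#' normalizer is strictly positive — each class present in the cell
#' contributed to its own stratum weight, so `D_mj > 0` there — and this is
#' asserted rather than assumed.
#'
#' @param fractions Output of [area_fractions()].
#' @param stratum_weights Output of [partition_class_weights()].
#' @param strata Cell-to-stratum mapping (as in
#'   [partition_class_weights()]).
#' @return `data.frame` with columns `cell_id`, `class`, `f` (unnormalized)
#'   and `weight` (`F(i,j)`, summing to 1 per cell).
#' @export
composite_weights <- function(fractions, stratum_weights, strata) {
  dt <- data.table::as.data.table(fractions)
  st <- data.frame(cell_id = strata$cell_id,
                   stratum = as.character(strata$stratum))
  dt[, stratum := st$stratum[match(cell_id, st$cell_id)]]
  sw <- data.table::as.data.table(stratum_weights)
  dt <- merge(dt, sw, by = c("stratum", "class"), all.x = TRUE)
  if (any(is.na(dt$weight))) {
    stop("no stratum weight for some (stratum, class) pairs; ",
         "stratum/fraction tables mismatch", call. = FALSE)
  }
  dt[, f := weight * wa]
  tot <- dt[, .(s = sum(f)), by = cell_id]
  if (any(tot$s <= 0)) {
    stop("internal error: zero composite-weight normalizer for cell id(s): ",
         paste(utils::head(tot$cell_id[tot$s <= 0], 10L), collapse = ", "),
         call. = FALSE)
  }
  dt[, Fw := f / sum(f), by = cell_id]
  out <- data.frame(cell_id = dt$cell_id, class = dt$class, f = dt$f,
                    weight = dt$Fw)
  out <- out[order(out$cell_id, out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a stratum weight table to CSV
#' @param stratum_weights Output of [partition_class_weights()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stratum_weights <- function(stratum_weights, path) {
  utils::write.csv(as.data.frame(stratum_weights), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
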