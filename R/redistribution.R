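# Reallocation of each coarse cell's population across its land classes.

#' Redistribute cell populations across land classes
#'
#' `P(i,j) = P_i * F(i,j)`: the cell's population split by the composite
#' weight. Cells with no fragments ("unrefined" cells — no land-use
#' coverage) cannot be split; they keep their population, are excluded from
#' the table, and are returned in the `unrefined` attribute so the caller
#' can carry the mass forward. Mass is conserved exactly per cell.
#'
#' @param cells Classified cell table with `cell_id`, `pop`.
#' @param weights Composite weight table from [composite_weights()].
#' @param integerize If `TRUE`, round each cell's class populations to
#'   integers by the largest-remainder rule (per-cell totals become
#'   `round(P_i)`). Off by default: the model is defined on reals.
#' @return `data.frame` with columns `cell_id`, `class`, `pop`; attribute
#'   `unrefined` is a data.frame (`cell_id`, `pop`) of uncovered cells.
#' @export
redistribute <- function(cells, weights, integerize = FALSE) {
  if (any(cells$pop < 0)) {
    stop("negative cell population(s): cell id(s) ",
         paste(utils::head(cells$cell_id[cells$pop < 0], 10L),
               collapse = ", "), call. = FALSE)
  }
  dt <- data.table::as.data.table(weights)
  chk <- dt[, .(s = sum(weight)), by = cell_id]
  if (any(abs(chk$s - 1) > 1e-9)) {
    stop("composite weights do not sum to 1 for cell id(s): ",
         paste(utils::head(chk$cell_id[abs(chk$s - 1) > 1e-9], 10L),
               collapse = ", "), call. = FALSE)
  }
  dt[, cpop := cells$pop[match(cell_id, cells$cell_id)]]
  if (any(is.na(dt$cpop))) {
    stop("weights reference cell id(s) absent from the cell table",
         call. = FALSE)
  }
  dt[, pop := cpop * weight]
  if (integerize) {
    dt[, pop := largest_remainder(pop, round(cpop[1L])), by = cell_id]
  }
  unref <- !(cells$cell_id %in% dt$cell_id)
  out <- data.frame(cell_id = dt$cell_id, class = dt$class, pop = dt$pop)
  out <- out[order(out$cell_id, out$class), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unrefined") <- data.frame(cell_id = cells$cell_id[unref],
                                       pop = cells$pop[unref])
  out
}

# Largest-remainder integerization of a vector to a fixed integer total.
largest_remainder <- function(x, total) {
  if (sum(x) == 0) return(rep(0, length(x)))
  scaled <- x / sum(x) * total
  fl <- floor(scaled)
  left <- as.integer(round(total - sum(fl)))
  if (left > 0L) {
    o <- order(scaled - fl, decreasing = TRUE)[seq_len(left)]
    fl[o] <- fl[o] + 1
  }
  fl
}

#' Export a class-population table to CSV
#' @param class_pops Output of [redistribute()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_class_populations <- function(class_pops, path) {
  utils::write.csv(as.data.frame(class_pops), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
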