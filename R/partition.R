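# Density stratification by Fisher-Jenks optimal natural breaks.

#' Fisher-Jenks natural breaks
#'
#' Finds the contiguous k-partition of the sorted values minimizing the
#' total within-class sum of squared deviations from class means (the
#' "natural breakpoint" classifier), by exact dynamic programming — not the
#' heuristic reallocation variant. Breaks are the maxima of the lower `k-1`
#' classes; class membership is upper-closed (a value equal to a break
#' belongs to the lower class). Among equally optimal partitions the
#' lexicographically smallest break vector is returned.
#'
#' @param values Numeric vector; must contain at least `k` distinct values.
#' @param k Number of classes (`>= 2`; default 3 for low/medium/high).
#' @param labels Ordered class names, low to high; length `k`.
#' @return A `break_set`: list with `k`, `breaks` (length `k-1`, ascending),
#'   `labels`, and `ssd` (the optimal total within-class SSD).
#' @export
#' @examples
#' jenks_breaks(c(1, 2, 3, 20, 21, 22, 100, 101), k = 3)
jenks_breaks <- function(values, k = 3L,
                         labels = if (k == 3L) c("low", "medium", "high")
                                  else paste0("class", seq_len(k))) {
  stopifnot(is.numeric(values), length(k) == 1L, k >= 2L,
            length(labels) == k)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  x <- sort(values)
  n <- length(x)
  if (length(unique(x)) < k) {
    stop("need at least ", k, " distinct values, have ",
         length(unique(x)), call. = FALSE)
  }
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  # SSD of the sorted segment (i..j], i < j, both 0-based prefix indices
  seg_cost <- function(i, j) {
    s <- cs[j + 1L] - cs[i + 1L]
    q <- cs2[j + 1L] - cs2[i + 1L]
    m <- j - i
    pmax(q - s * s / m, 0)
  }
  # suffix DP: E[c, i] = optimal SSD of partitioning x[i..n] into c classes
  E <- matrix(Inf, nrow = k, ncol = n + 1L)
  E[1L, seq_len(n)] <- seg_cost(seq_len(n) - 1L, n)
  if (k > 1L) for (c in 2L:k) {
    # class count c needs at least c values in the suffix
    for (i in seq_len(n - c + 1L)) {
      ends <- i:(n - c + 1L)                 # last index of the first class
      E[c, i] <- min(seg_cost(i - 1L, ends) + E[c - 1L, ends + 1L])
    }
  }
  # greedy left-to-right reconstruction gives the lexicographically
  # smallest break vector among optimal partitions
  best <- E[k, 1L]
  breaks <- numeric(k - 1L)
  i <- 1L
  for (c in seq_len(k - 1L)) {
    rem <- k - c
    ends <- i:(n - rem)
    tot <- seg_cost(i - 1L, ends) + E[rem, ends + 1L]
    target <- min(tot)
    # prefer the smallest class maximum, i.e. the earliest optimal end
    e <- ends[which(tot <= target)[1L]]
    breaks[c] <- x[e]
    i <- e + 1L
  }
  structure(list(k = as.integer(k), breaks = breaks, labels = labels,
                 ssd = best),
            class = "break_set")
}

#' @export
print.break_set <- function(x, ...) {
  cat(sprintf("<break_set> k = %d, breaks = [%s], SSD = %.6g\n",
              x$k, paste(format(x$breaks), collapse = ", "), x$ssd))
  invisible(x)
}

#' Assign density strata to cells
#'
#' Labels every cell with its density stratum using upper-closed intervals:
#' `pop <= breaks[1]` is the lowest class, `breaks[1] < pop <= breaks[2]`
#' the next, and so on.
#'
#' @param cells A [vectorize_grid()] cell table.
#' @param breaks A `break_set` from [jenks_breaks()] (computed on these
#'   cells' populations), or `NULL` to place every cell in a single stratum
#'   (the degenerate fallback when all populations are equal).
#' @return The cell table with `stratum` filled in.
#' @export
classify_cells <- function(cells, breaks) {
  if (is.null(breaks)) {
    cells$stratum <- "all"
    return(cells)
  }
  stopifnot(inherits(breaks, "break_set"))
  idx <- rowSums(outer(cells$pop, breaks$breaks, ">")) + 1L
  cells$stratum <- breaks$labels[idx]
  cells
}
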