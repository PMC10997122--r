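# Overlay: fragment areas, fine-grid construction, admin apportionment.

test_that("a fully covered cell yields one fragment with the cell area", {
  cells <- one_cell(pop = 10)
  parcels <- rect_parcels(list(c(-10, -10, 110, 110)), "residential")
  frag <- intersect_with_landuse(cells, parcels)
  expect_equal(nrow(frag), 1L)
  expect_equal(frag$class, "residential")
  expect_equal(frag$area, 10000)
})

test_that("a 60/40 split produces 6000 and 4000 m2 fragments", {
  cells <- one_cell()
  parcels <- rect_parcels(list(c(0, 0, 60, 100), c(60, 0, 100, 100)),
                          c("residential", "water"))
  frag <- intersect_with_landuse(cells, parcels)
  frag <- frag[order(frag$class), ]
  expect_equal(frag$class, c("residential", "water"))
  expect_equal(frag$area, c(6000, 4000))
})

test_that("fragments below the sliver tolerance are dropped and logged", {
  cells <- one_cell()
  parcels <- rect_parcels(list(c(0, 0, 99.99, 100), c(99.99, 0, 100, 100)),
                          c("residential", "water"))
  frag <- intersect_with_landuse(cells, parcels, sliver_tol = 1e-3)
  expect_equal(frag$class, "residential")
  expect_equal(attr(frag, "dropped_sliver_area"), 1, tolerance = 1e-9)
})

test_that("overlapping same-class parcels are unioned, not double counted", {
  cells <- one_cell()
  parcels <- rect_parcels(list(c(0, 0, 60, 100), c(40, 0, 80, 100)),
                          c("residential", "residential"))
  frag <- intersect_with_landuse(cells, parcels)
  expect_equal(frag$area, 8000)
})

test_that("overlapping parcels of different classes are an error", {
  cells <- one_cell()
  parcels <- rect_parcels(list(c(0, 0, 60, 100), c(40, 0, 80, 100)),
                          c("residential", "water"))
  expect_error(intersect_with_landuse(cells, parcels),
               "different classes overlap")
})

test_that("fragment areas match the 0.1 m rasterized-counting oracle", {
  # coordinates on the 0.1 m lattice make the counting oracle exact
  set.seed(101)
  for (rep in 1:8) {
    n <- sample(2:5, 1)
    boxes <- replicate(n, {
      x <- sort(sample(seq(0, 200, by = 1), 2)) / 10
      y <- sort(sample(seq(0, 200, by = 1), 2)) / 10
      c(x[1], y[1], x[2], y[2])
    }, simplify = FALSE)
    classes <- sample(c("residential", "cultivated", "water"), n,
                      replace = TRUE)
    # drop boxes that strictly overlap an earlier different-class box
    keep <- rep(TRUE, n)
    for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
      if (!keep[j] || classes[i] == classes[j]) next
      if (boxes[[i]][1] < boxes[[j]][3] && boxes[[i]][3] > boxes[[j]][1] &&
          boxes[[i]][2] < boxes[[j]][4] && boxes[[i]][4] > boxes[[j]][2]) {
        keep[i] <- FALSE
      }
    }
    boxes <- boxes[keep]; classes <- classes[keep]
    if (length(boxes) == 0L) next
    cells <- one_cell(0, 0, 20, 20)
    frag <- intersect_with_landuse(cells, rect_parcels(boxes, classes),
                                   sliver_tol = 0)
    oracle <- raster_count_areas(c(0, 0, 20, 20), boxes, classes)
    for (cl in names(oracle)) {
      got <- sum(frag$area[frag$class == cl])
      if (oracle[[cl]] == 0) {
        expect_equal(got, 0)
      } else {
        expect_equal(got, oracle[[cl]], tolerance = 1e-9)
      }
    }
  }
})

test_that("fragment areas are independent of parcel input order", {
  set.seed(55)
  cells <- vectorize_grid(pop_grid(matrix(1, 3, 3), origin = c(0, 300),
                                   cell_size = 100,
                                   crs = "LOCAL:synthetic-metre"))
  boxes <- list(c(0, 0, 120, 300), c(120, 0, 300, 150), c(120, 150, 300, 300))
  classes <- c("residential", "water", "cultivated")
  f1 <- intersect_with_landuse(cells, rect_parcels(boxes, classes))
  o <- sample(3)
  f2 <- intersect_with_landuse(cells, rect_parcels(boxes[o], classes[o]))
  f1 <- f1[order(f1$cell_id, f1$class), ]
  f2 <- f2[order(f2$cell_id, f2$class), ]
  expect_equal(f2$area, f1$area, tolerance = 1e-9)
})

test_that("fine grid tiles each parent into factor^2 congruent squares", {
  cells <- one_cell(pop = 100)
  fine4 <- build_fine_grid(cells, 4L)
  expect_equal(nrow(fine4), 16L)
  areas <- (fine4$xmax - fine4$xmin) * (fine4$ymax - fine4$ymin)
  expect_equal(areas, rep(625, 16))
  fine2 <- build_fine_grid(cells, 2L)
  expect_equal(nrow(fine2), 4L)
  expect_equal((fine2$xmax - fine2$xmin) * (fine2$ymax - fine2$ymin),
               rep(2500, 4))
  # tiling: children cover the parent exactly, no overlap
  expect_equal(sum(areas), 10000)
  expect_equal(min(fine4$xmin), 0); expect_equal(max(fine4$xmax), 100)
  expect_equal(min(fine4$ymin), 0); expect_equal(max(fine4$ymax), 100)
  key <- paste(fine4$xmin, fine4$ymin)
  expect_equal(anyDuplicated(key), 0L)
  expect_error(build_fine_grid(cells, 2.5), "integer")
  expect_error(build_fine_grid(cells, 1L), "integer")
})

test_that("fine-then-aggregate is the identity on per-coarse totals", {
  set.seed(9)
  g <- pop_grid(matrix(runif(25) * 100, 5, 5), origin = c(0, 500),
                cell_size = 100, crs = "LOCAL:synthetic-metre")
  cells <- vectorize_grid(g)
  fine <- build_fine_grid(cells, 4L)
  fine$pop <- runif(nrow(fine))
  agg <- rowsum(fine$pop, fine$parent_id)
  direct <- tapply(fine$pop, fine$parent_id, sum)
  expect_equal(as.numeric(agg), as.numeric(direct))
  expect_equal(sort(unique(fine$parent_id)), sort(cells$cell_id))
})

test_that("apportionment splits straddling cells by area and conserves mass", {
  fine <- build_fine_grid(one_cell(), 2L)
  fine$pop <- c(8, 0, 0, 0)   # top-left 50 m sub-cell carries 8 people
  # units split that sub-cell 60/40 vertically
  admin <- admin_units(
    list(list(popfine:::rect_ring(0, 0, 30, 100)),
         list(popfine:::rect_ring(30, 0, 100, 100))),
    codes = c("T01", "T02"), crs = "LOCAL:synthetic-metre")
  app <- apportion_to_admin(fine, admin)
  expect_equal(app$estimates$pop[app$estimates$code == "T01"], 4.8)
  expect_equal(app$estimates$pop[app$estimates$code == "T02"], 3.2)
  expect_equal(app$uncovered, 0)
  # a single all-covering unit receives everything
  admin1 <- admin_units(list(list(popfine:::rect_ring(-10, -10, 110, 110))),
                        codes = "ALL", crs = "LOCAL:synthetic-metre")
  expect_equal(apportion_to_admin(fine, admin1)$estimates$pop, 8)
  # partial coverage: uncovered mass accounts for the rest
  adminp <- admin_units(list(list(popfine:::rect_ring(0, 50, 25, 100))),
                        codes = "HALF", crs = "LOCAL:synthetic-metre")
  app <- apportion_to_admin(fine, adminp)
  expect_equal(app$estimates$pop + app$uncovered, 8, tolerance = 1e-12)
  expect_equal(app$estimates$pop, 4)   # 25x50 of the 50x50 sub-cell
})
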