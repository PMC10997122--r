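# Dasymetric downscaling and the all-water zeroing rule.

test_that("a fully residential fine cell gets its area share of the class", {
  cells <- one_cell(pop = 100)
  # coarse: residential 6000, water 4000; class pops from the 6/7-1/7 split
  frag <- data.frame(cell_id = 1L, class = c("residential", "water"),
                     area = c(6000, 4000))
  cp <- data.frame(cell_id = 1L, class = c("residential", "water"),
                   pop = c(85.714286, 14.285714))
  attr(cp, "unrefined") <- data.frame(cell_id = integer(0), pop = numeric(0))
  fine <- build_fine_grid(cells, 4L)
  # one fine cell fully residential (625 m2), the rest unmapped
  ffrag <- data.frame(cell_id = fine$fine_id[1L], class = "residential",
                      area = 625)
  out <- downscale(cp, fine, ffrag, frag)
  expect_equal(out$pop[1L], 85.714286 * 625 / 6000, tolerance = 1e-9)
  expect_equal(out$pop[1L], 8.928571, tolerance = 1e-6)
  # fine cells with no fragments get zero before the water rule
  expect_equal(out$pop[-1L], rep(0, 15))
})

test_that("per-parent totals reproduce P_i on sliver-free fixtures", {
  scen <- generate_scenario(scenario_config(ncols = 8, nrows = 8,
                                            n_patches = 25, seed = 3))
  res <- refine_population(scen$grid, scen$parcels)
  agg <- rowsum(res$fine$pop, res$fine$parent_id)
  cells <- res$cells
  expect_equal(as.numeric(agg[match(cells$cell_id,
                                    as.integer(rownames(agg))), 1L]),
               cells$pop, tolerance = 1e-6)
  expect_equal(nrow(attr(res$fine, "residual")), 0L)
})

test_that("unrefined parents fall back to an equal split", {
  cells <- one_cell(pop = 48)
  cp <- data.frame(cell_id = integer(0), class = character(0),
                   pop = numeric(0))
  attr(cp, "unrefined") <- data.frame(cell_id = 1L, pop = 48)
  fine <- build_fine_grid(cells, 4L)
  out <- downscale(cp, fine,
                   data.frame(cell_id = integer(0), class = character(0),
                              area = numeric(0)),
                   data.frame(cell_id = integer(0), class = character(0),
                              area = numeric(0)))
  expect_equal(out$pop, rep(3, 16))
})

test_that("the water rule zeroes all-water cells and conserves parent totals", {
  cells <- one_cell(pop = 100)
  parcels <- rect_parcels(list(c(0, 0, 75, 100), c(75, 0, 100, 100)),
                          c("residential", "water"))
  frag <- intersect_with_landuse(cells, parcels)
  fr <- area_fractions(frag)
  st <- data.frame(cell_id = 1L, stratum = "all")
  cw <- composite_weights(fr, partition_class_weights(fr, st), st)
  cp <- redistribute(cells, cw)
  fine <- build_fine_grid(cells, 4L)
  ffrag <- intersect_with_landuse(fine, parcels)
  fine <- downscale(cp, fine, ffrag, frag)
  before <- sum(fine$pop)
  wr <- apply_water_rule(fine, ffrag)
  # the rightmost column of fine cells is entirely water -> exactly zero
  water_cells <- fine$fine_id[fine$xmin >= 75]
  expect_equal(wr$fine$pop[wr$fine$fine_id %in% water_cells], rep(0, 4))
  # parent total unchanged
  expect_equal(sum(wr$fine$pop), before, tolerance = 1e-9 * before)
  expect_gt(wr$moved_mass, 0)
  expect_length(wr$flagged_parents, 0)
})

test_that("the water rule is the identity when nothing is water", {
  cells <- one_cell(pop = 10)
  parcels <- rect_parcels(list(c(0, 0, 100, 100)), "residential")
  fine <- build_fine_grid(cells, 2L)
  ffrag <- intersect_with_landuse(fine, parcels)
  fine$pop <- c(1, 2, 3, 4)
  wr <- apply_water_rule(fine, ffrag)
  expect_equal(wr$fine$pop, c(1, 2, 3, 4))
  expect_equal(wr$moved_mass, 0)
})

test_that("an all-water populated parent is flagged and left untouched", {
  cells <- one_cell(pop = 100)
  parcels <- rect_parcels(list(c(0, 0, 100, 100)), "water")
  frag <- intersect_with_landuse(cells, parcels)
  fr <- area_fractions(frag)
  st <- data.frame(cell_id = 1L, stratum = "all")
  cw <- composite_weights(fr, partition_class_weights(fr, st), st)
  cp <- redistribute(cells, cw)
  fine <- build_fine_grid(cells, 2L)
  ffrag <- intersect_with_landuse(fine, parcels)
  fine <- downscale(cp, fine, ffrag, frag)
  wr <- apply_water_rule(fine, ffrag)
  expect_equal(wr$flagged_parents, 1L)
  expect_equal(wr$fine$pop, fine$pop)  # values retained
  expect_equal(sum(wr$fine$pop), 100, tolerance = 1e-9)
})

test_that("redistribution within the parent is proportional to pre-rule mass", {
  cells <- one_cell(pop = 100)
  fine <- build_fine_grid(cells, 2L)
  # bottom-right sub-cell [50,100]x[0,50] is water and carries 20
  ffrag <- data.frame(cell_id = fine$fine_id,
                      class = c("residential", "residential",
                                "residential", "water"),
                      area = rep(2500, 4))
  fine$pop <- c(40, 30, 10, 20)
  wr <- apply_water_rule(fine, ffrag)
  expect_equal(wr$fine$pop, c(40, 30, 10, 0) + c(40, 30, 10, 0) / 80 * 20)
  expect_equal(sum(wr$fine$pop), 100)
})
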