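# Area fractions, stratum land-class weights and composite weights.

frac_fixture <- function() {
  # cell 1: residential 6000 / water 4000; cell 2: residential only
  frag <- data.frame(cell_id = c(1L, 1L, 2L),
                     class = c("residential", "water", "residential"),
                     area = c(6000, 4000, 10000))
  area_fractions(frag)
}

strata_fixture <- function() {
  data.frame(cell_id = c(1L, 2L), stratum = "high")
}

test_that("area fractions are per-cell ratios that sum to one", {
  fr <- frac_fixture()
  expect_equal(fr$wa[fr$cell_id == 1 & fr$class == "residential"], 0.6)
  expect_equal(fr$wa[fr$cell_id == 1 & fr$class == "water"], 0.4)
  expect_equal(fr$wa[fr$cell_id == 2], 1.0)
  set.seed(8)
  frag <- data.frame(cell_id = rep(1:30, each = 3),
                     class = rep(c("residential", "water", "forest"), 30),
                     area = runif(90, 1, 5000))
  fr <- area_fractions(frag)
  sums <- tapply(fr$wa, fr$cell_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("stratum weights average the per-cell fractions (0.8/0.2 fixture)", {
  sw <- partition_class_weights(frac_fixture(), strata_fixture())
  expect_equal(sw$weight[sw$class == "residential"], 0.8)
  expect_equal(sw$weight[sw$class == "water"], 0.2)
  expect_equal(attr(sw, "n_cells")[["high"]], 2L)
})

test_that("an all-residential stratum has weight 1", {
  frag <- data.frame(cell_id = 1:3, class = "residential", area = c(1, 2, 3) * 1000)
  sw <- partition_class_weights(area_fractions(frag),
                                data.frame(cell_id = 1:3, stratum = "low"))
  expect_equal(sw$weight, 1)
})

test_that("stratum weight rows sum to 1 and the denominator is the cell count", {
  set.seed(77)
  scen <- generate_scenario(scenario_config(ncols = 12, nrows = 12,
                                            n_patches = 30, seed = 5))
  res <- refine_population(scen$grid, scen$parcels)
  sw <- res$stratum_weights
  sums <- tapply(sw$weight, sw$stratum, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  n_cells <- attr(sw, "n_cells")
  covered <- table(res$cells$stratum[res$cells$cell_id %in%
                                       res$fragments$cell_id])
  expect_identical(as.integer(n_cells[names(covered)]),
                   as.integer(covered))
  # a class has weight zero iff absent from every cell of the stratum
  fr <- merge(res$fractions,
              res$cells[, c("cell_id", "stratum")], by = "cell_id")
  for (r in seq_len(nrow(sw))) {
    present <- any(fr$stratum == sw$stratum[r] & fr$class == sw$class[r])
    expect_identical(sw$weight[r] > 0, present)
  }
})

test_that("composite weights follow the worked 6/7 - 1/7 example", {
  fr <- frac_fixture()
  sw <- partition_class_weights(fr, strata_fixture())
  cw <- composite_weights(fr, sw, strata_fixture())
  c1 <- cw[cw$cell_id == 1, ]
  expect_equal(c1$f[c1$class == "residential"], 0.48)
  expect_equal(c1$f[c1$class == "water"], 0.08)
  expect_equal(c1$weight[c1$class == "residential"], 6 / 7, tolerance = 1e-12)
  expect_equal(c1$weight[c1$class == "water"], 1 / 7, tolerance = 1e-12)
  # single-class cell: weight 1 regardless of the stratum weight
  expect_equal(cw$weight[cw$cell_id == 2], 1)
})

test_that("raising a class's stratum weight weakly raises its composite weight", {
  set.seed(12)
  for (rep in 1:20) {
    wa <- runif(3); wa <- wa / sum(wa)
    d <- runif(3); d <- d / sum(d)
    fr <- data.frame(cell_id = 1L, class = c("a", "b", "c"), wa = wa)
    st <- data.frame(cell_id = 1L, stratum = "m")
    mk <- function(dd) data.frame(stratum = "m", class = c("a", "b", "c"),
                                  weight = dd)
    f0 <- composite_weights(fr, mk(d), st)
    d2 <- d; d2[1] <- d2[1] * (1 + runif(1)); d2 <- d2  # others fixed
    f1 <- composite_weights(fr, mk(d2), st)
    expect_gte(f1$weight[f1$class == "a"] + 1e-12,
               f0$weight[f0$class == "a"])
  }
})

test_that("identical-composition cells make the composite weight WA-squared", {
  # one stratum, every cell 70/30 residential/forest: D = (0.7, 0.3), so
  # F(i,j) = WA^2 / sum(WA^2)
  frag <- data.frame(cell_id = rep(1:4, each = 2),
                     class = rep(c("residential", "forest"), 4),
                     area = rep(c(7000, 3000), 4))
  fr <- area_fractions(frag)
  st <- data.frame(cell_id = 1:4, stratum = "all")
  cw <- composite_weights(fr, partition_class_weights(fr, st), st)
  expect_equal(cw$weight[cw$class == "residential"],
               rep(0.49 / (0.49 + 0.09), 4), tolerance = 1e-12)
})

test_that("weight tables are invariant to uniform area rescaling", {
  frag <- data.frame(cell_id = c(1L, 1L, 2L, 2L),
                     class = c("residential", "water", "residential", "forest"),
                     area = c(1000, 3000, 2000, 500))
  st <- data.frame(cell_id = 1:2, stratum = "m")
  f1 <- area_fractions(frag)
  frag2 <- frag; frag2$area <- frag2$area * 12.34
  f2 <- area_fractions(frag2)
  expect_equal(f2$wa, f1$wa, tolerance = 1e-12)
  expect_equal(partition_class_weights(f2, st)$weight,
               partition_class_weights(f1, st)$weight, tolerance = 1e-12)
})
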