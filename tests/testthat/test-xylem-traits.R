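test_that("Mork's index arithmetic and boundary rule", {
  r <- morks_index(2.5, 30)
  expect_equal(r$mork_index, 1 / 3)
  expect_equal(r$portion, "ew")
  expect_equal(morks_index(5, 20)$portion, "lw")     # MI exactly 1
  expect_equal(morks_index(5, 20, boundary = "earlywood")$portion, "ew")
  r <- morks_index(6, 12)
  expect_equal(r$mork_index, 2)
  expect_equal(r$portion, "lw")
  expect_error(morks_index(2, 0), "degenerate")
  # mean-diameter variant
  r <- morks_index(3, 10, ld_tan_um = 14, diameter = "mean")
  expect_equal(r$mork_index, 1)
})

test_that("conduit reinforcement uses the thinner wall and its length", {
  expect_equal(conduit_reinforcement(2, 3, 20, 99), 0.04)
  # scale invariance under uniform linear rescaling
  expect_equal(conduit_reinforcement(4, 6, 40, 198), 0.04)
  # tie: radial side chosen
  expect_equal(conduit_reinforcement(2, 2, 10, 99), (4 / 10)^2)
  expect_error(conduit_reinforcement(2, 3, 0, 10), "positive")
})

test_that("anatomical density is the wall-area proportion", {
  expect_equal(anatomical_density(5, 5), 0.5)
  expect_equal(anatomical_density(300, 700), 0.3)
  expect_equal(anatomical_density(1, 1e-9), 1, tolerance = 1e-8)
  expect_equal(anatomical_density(200, 600), anatomical_density(2, 6))
  expect_error(anatomical_density(0, 0), "positive")
})

test_that("per-cell traits match a brute-force oracle on random cells", {
  set.seed(99)
  for (i in 1:40) {
    cell <- list(la_um2 = runif(1, 50, 2000),
                 ld_rad_um = runif(1, 5, 45),
                 cwt_rad_um = runif(1, 1, 8),
                 cwt_tan_um = runif(1, 1, 8),
                 cwa_um2 = runif(1, 50, 1500),
                 wall_len_rad_um = runif(1, 5, 50),
                 wall_len_tan_um = runif(1, 5, 50))
    ora <- cell_traits_oracle(cell)
    expect_identical(morks_index(cell$cwt_rad_um, cell$ld_rad_um)$portion,
                     ora$portion)
    expect_equal(conduit_reinforcement(cell$cwt_rad_um, cell$cwt_tan_um,
                                       cell$wall_len_rad_um,
                                       cell$wall_len_tan_um),
                 ora$tb2, tolerance = 1e-12)
    expect_equal(anatomical_density(cell$cwa_um2, cell$la_um2), ora$den,
                 tolerance = 1e-12)
  }
})

test_that("thickening walls never reclassifies latewood as earlywood", {
  set.seed(7)
  cwt <- runif(50, 1, 8)
  ld <- runif(50, 5, 45)
  base <- morks_index(cwt, ld)$portion
  for (c_mult in c(1, 1.3, 2, 5)) {
    up <- morks_index(cwt * c_mult, ld)$portion
    expect_false(any(base == "lw" & up == "ew"))
  }
})

test_that("chronologies are unweighted per-cell means by group", {
  cells <- data.frame(
    tree_id = "T1", year = 2000,
    la_um2 = c(500, 700), ld_rad_um = c(30, 32), ld_tan_um = c(25, 26),
    cwt_rad_um = c(2, 3), cwt_tan_um = c(2.5, 2.5),
    cwa_um2 = c(300, 350), wall_len_rad_um = c(30, 30),
    wall_len_tan_um = c(26, 27))
  chr <- build_chronology(cells)
  expect_equal(nrow(chr), 1L)            # both cells are earlywood
  expect_equal(chr$portion, "ew")
  expect_equal(chr$la, 600)
  expect_equal(chr$n_cells, 2L)
  expect_equal(chr$cwt, mean(c(2.25, 2.75)))

  # single cell: chronology equals the per-cell values
  one <- build_chronology(cells[1, ])
  expect_equal(one$la, 500)
  expect_equal(one$den, anatomical_density(300, 500))

  # all-earlywood ring yields no latewood row (and vice versa)
  expect_false("lw" %in% chr$portion)
  lw_cells <- cells
  lw_cells$cwt_rad_um <- c(9, 9)
  expect_false("ew" %in% build_chronology(lw_cells)$portion)
})

test_that("non-tracheid cells are dropped before any computation", {
  cells <- data.frame(
    tree_id = "T1", year = 2000,
    la_um2 = c(500, 700), ld_rad_um = c(30, 32), ld_tan_um = c(25, 26),
    cwt_rad_um = c(2, 3), cwt_tan_um = c(2.5, 2.5),
    cwa_um2 = c(300, 350), wall_len_rad_um = c(30, 30),
    wall_len_tan_um = c(26, 27), tracheid = c(TRUE, FALSE))
  expect_equal(build_chronology(cells)$la, 500)
})

test_that("ratio-of-sums density option differs predictably", {
  cells <- data.frame(
    tree_id = "T1", year = 2000,
    la_um2 = c(100, 900), ld_rad_um = c(30, 32), ld_tan_um = c(25, 26),
    cwt_rad_um = c(2, 3), cwt_tan_um = c(2.5, 2.5),
    cwa_um2 = c(100, 100), wall_len_rad_um = c(30, 30),
    wall_len_tan_um = c(26, 27))
  per_cell <- build_chronology(cells)$den
  ratio <- build_chronology(cells, den_method = "ratio_of_sums")$den
  expect_equal(per_cell, mean(c(0.5, 0.1)))
  expect_equal(ratio, 200 / 1200)
})

test_that("empty input gives an empty chronology", {
  chr <- build_chronology(data.frame())
  expect_equal(nrow(chr), 0L)
  expect_true(all(c("la", "tb2", "den", "cwt") %in% names(chr)))
})
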