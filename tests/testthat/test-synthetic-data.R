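test_that("climate generation is deterministic and has the right shape", {
  sites <- default_sites(2)
  a <- generate_climate(sites, 1970:2016, seed = 7)
  b <- generate_climate(sites, 1970:2016, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 3 * 47 * 12)
  expect_true(all(a$prcp_mm >= 0))
  d <- generate_climate(sites, 1970:2016, seed = 8)
  expect_false(identical(a$tmean_c, d$tmean_c))
  expect_error(generate_climate(sites, integer(0), seed = 1), "non-empty")
})

test_that("zero-noise climate reproduces the monthly normals exactly", {
  cfg <- site_config("X", monthly_temp_means = 1:12,
                     monthly_precip_means = rep(30, 12),
                     temp_sd = 0, precip_cv = 0, n_trees = 1)
  clim <- generate_climate(cfg, 2000:2004, seed = 1)
  jan <- clim[clim$month == 1, ]
  expect_true(all(jan$tmean_c == 1))
  expect_true(all(clim$tmean_c == clim$month))
  expect_true(all(clim$prcp_mm == 30))
})

test_that("tree generation respects allometry, flags and invertibility", {
  cfg <- default_sites(3)[["C-D"]]
  al <- default_allometries()[["C-D"]]
  ts <- generate_trees(cfg, al, seed = 3, missing_prob = 0,
                       height_noise_sd = 0)
  expect_false(any(ts$truth$missing$missing))
  expect_false(anyNA(ts$rings_observed$rw_mm))
  # noise-free heights sit exactly on the Weibull curve
  expect_equal(ts$trees$height_m,
               al$h_max * exp(al$a * ts$trees$dbh_cm^al$b), tolerance = 1e-12)
  # sampling DBH = 2 * cumulative ring width (pith offset 0)
  sums <- tapply(ts$truth$rings$rw_mm, ts$truth$rings$tree_id, sum)
  expect_equal(as.numeric(2 * sums[ts$trees$tree_id] / 10),
               ts$trees$dbh_cm, tolerance = 1e-12)
  expect_error(generate_trees(cfg, list(h_max = 10, a = -2, b = 0.5), 1),
               "rising")
  cfg0 <- cfg; cfg0$n_trees <- 0L
  expect_error(generate_trees(cfg0, al, 1), "positive")
})

test_that("generated ring widths decline with cambial age", {
  cfg <- default_sites(6)[["W-D"]]
  ts <- generate_trees(cfg, default_allometries()[["W-D"]], seed = 9,
                       missing_prob = 0)
  byage <- rings_by_cambial_age(ts$truth$rings)
  byage <- byage[byage$age <= 50, ]
  mean_rw <- tapply(byage$rw_mm, byage$age, mean)
  expect_lt(cor(as.numeric(names(mean_rw)), mean_rw, method = "spearman"), 0)
})

test_that("missing rings are deleted from observed series but kept in truth", {
  cfg <- default_sites(4)[["C-M"]]
  ts <- generate_trees(cfg, default_allometries()[["C-M"]], seed = 21,
                       missing_prob = 0.1)
  miss <- ts$truth$missing
  expect_gt(sum(miss$missing), 0)
  obs <- ts$rings_observed
  key_na <- paste(obs$tree_id, obs$year)[is.na(obs$rw_mm)]
  key_miss <- paste(miss$tree_id, miss$year)[miss$missing]
  expect_setequal(key_na, key_miss)
  expect_false(anyNA(ts$truth$rings$rw_mm))
})

test_that("Mork classifier recovers the generator's portion labels", {
  ds <- tiny_dataset(seed = 19)
  cls <- morks_index(ds$cells$cwt_rad_um, ds$cells$ld_rad_um)
  expect_identical(cls$portion, ds$cells$true_portion)
})

test_that("noise-free cells average exactly to the annual truth", {
  prof <- cell_geometry_profile(cells_per_ring = 24, noise_cv = 0)
  ds <- tiny_dataset(seed = 23, profile = prof)
  chr <- build_chronology(ds$cells)
  tg <- ds$truth_annual
  for (tr in c("la", "tb2", "den", "cwt")) {
    sub <- merge(chr, tg[tg$trait == tr, ],
                 by = c("tree_id", "year", "portion"))
    expect_equal(sub[[tr]], sub$value_natural, tolerance = 1e-9)
  }
})

test_that("a pure height signal is recovered by ordinary least squares", {
  truth <- default_truth()
  tt <- trait_truth("la", "ew", intercept = 600, beta_height = 1,
                    re_sd = c(0, 0, 0), phi = 0, sigma = 0)
  truth$la_ew <- tt
  amf <- annual_model_frame(list(la_ew = tt), seed = 31, n_trees = 6,
                            age_mean = 80)
  sl <- coef(lm(y ~ h, data = amf$data))["h"]
  expect_equal(unname(sl), 1, tolerance = 0.05)
})

test_that("AR1 residuals have the configured lag-1 autocorrelation", {
  tt <- trait_truth("la", "ew", intercept = 0, phi = 0.5, sigma = 1)
  cfg <- site_config("W-D", monthly_temp_means = rep(5, 12),
                     monthly_precip_means = rep(40, 12), n_trees = 1,
                     reference = TRUE)
  ts <- generate_trees(cfg, default_allometries()[["W-D"]], seed = 2,
                       sampling_year = 12000, age_mean = 10000,
                       age_jitter = 0, missing_prob = 0)
  clim <- generate_climate(cfg, 1999:12000, seed = 3)
  ann <- generate_annual_traits(list(la_ew = tt), ts, clim, seed = 4)
  tg <- ann$targets[order(ann$targets$year), ]
  eps <- tg$value_model
  r1 <- cor(eps[-1], eps[-length(eps)])
  expect_equal(r1, 0.5, tolerance = 0.03)
})

test_that("cell generation is deterministic and validates phi", {
  a <- tiny_dataset(seed = 4)
  b <- tiny_dataset(seed = 4)
  expect_identical(a$cells, b$cells)
  expect_error(trait_truth("la", "ew", intercept = 0, phi = 1.2),
               "phi")
})

test_that("cell geometry fields are mutually consistent", {
  ds <- tiny_dataset(seed = 6)
  cells <- ds$cells
  # lumen area equals the product of the two lumen diameters
  expect_equal(cells$la_um2, cells$ld_rad_um * cells$ld_tan_um,
               tolerance = 1e-12)
  # CWA back-solves the density identity
  expect_equal(cells$cwa_um2 / (cells$cwa_um2 + cells$la_um2),
               anatomical_density(cells$cwa_um2, cells$la_um2),
               tolerance = 1e-12)
  expect_true(all(cells$la_um2 > 0 & cells$cwa_um2 > 0 &
                    cells$wall_len_rad_um > 0 & cells$wall_len_tan_um > 0))
})

test_that("synthetic inputs round-trip through their exchange formats", {
  ds <- tiny_dataset(seed = 8)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_inputs(ds, dir)
  expect_true(all(file.exists(paths)))
  rings <- read_rwl(paths["rwl"])
  obs <- ds$tree_set$rings_observed
  obs <- obs[order(obs$tree_id, obs$year), ]
  expect_equal(rings$tree_id, obs$tree_id)
  expect_equal(rings$year, obs$year)
  # Tucson units are 0.01 mm, so agreement is to the rounding step
  expect_equal(rings$rw_mm, obs$rw_mm, tolerance = 0.0051)
  expect_identical(is.na(rings$rw_mm), is.na(obs$rw_mm))
})
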