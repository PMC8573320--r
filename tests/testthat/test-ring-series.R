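mk_series <- function(rw, coring = 1.3, dbh = NULL, height = 10,
                      start_year = 2000) {
  if (is.null(dbh)) dbh <- 2 * sum(rw, na.rm = TRUE) / 10 + 5
  ring_series("T1", start_year + seq_along(rw) - 1, rw,
              coring_height_m = coring, sampling_dbh_cm = dbh,
              sampling_height_m = height)
}

test_that("ring series constructor enforces its invariants", {
  expect_error(ring_series("T1", c(2000, 2002), c(1, 1), 1.3, 10, 5),
               "contiguous")
  expect_error(ring_series("T1", 2000:2001, c(1, -1), 1.3, 10, 5),
               "positive")
  s <- mk_series(c(1, 2, NA, 3))
  expect_s3_class(s, "ring_series")
  expect_equal(s$sampling_year, 2003)
})

test_that("imputation fills gaps with the pooled neighbor mean", {
  s <- mk_series(c(1, 1, NA, 1, 1))
  expect_equal(impute_missing_rings(s)$rw_mm[3], 1.0)

  # 10 values before (1..10), gap, then 12..21: (55 + 165) / 20 = 11
  s <- mk_series(c(1:10, NA, 12:21))
  out <- impute_missing_rings(s)
  expect_equal(out$rw_mm[11], 11.0)
  expect_true(out$imputed[11])
  expect_equal(sum(out$imputed), 1L)

  # edge gap in year 3: only 2 prior values, 10 following
  rw <- c(2, 4, NA, 5:14, 20, 30)
  s <- mk_series(rw)
  out <- impute_missing_rings(s)
  expect_equal(out$rw_mm[3], mean(c(2, 4, 5:14)))
})

test_that("consecutive gaps never feed on imputed values", {
  rw <- c(1, 2, NA, NA, 3, 4)
  out <- impute_missing_rings(mk_series(rw))
  expect_equal(out$rw_mm[3], mean(c(1, 2, 3, 4)))
  expect_equal(out$rw_mm[4], mean(c(1, 2, 3, 4)))
})

test_that("imputation matches the brute-force window oracle", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(15:60, 1)
    rw <- round(runif(n, 0.2, 4), 3)
    rw[sample(2:(n - 1), sample(1:5, 1))] <- NA
    s <- mk_series(rw)
    expect_equal(impute_missing_rings(s)$rw_mm, impute_oracle(rw),
                 tolerance = 1e-12)
  }
})

test_that("imputation errors are explicit", {
  expect_error(impute_missing_rings(mk_series(c(NA, NA, NA))), "all rings")
  s <- mk_series(c(NA, 1, 1))
  expect_silent(impute_missing_rings(s))
})

test_that("DBH recursion walks backwards from the sampling diameter", {
  # 5 rings of 1 cm each (10 mm), sampling DBH 10 cm
  s <- mk_series(rep(10, 5), dbh = 10)
  d <- reconstruct_dbh(s)
  expect_equal(d$dbh_cm, c(2, 4, 6, 8, 10))

  # telescoping identity on random series
  set.seed(1)
  rw <- runif(30, 0.3, 3)
  s <- mk_series(rw, dbh = 2 * sum(rw) / 10 + 1.5)
  d <- reconstruct_dbh(s)
  expect_equal(d$dbh_cm[1], s$sampling_dbh_cm - 2 * sum(rw[-1]) / 10,
               tolerance = 1e-12)
  expect_equal(min(d$dbh_cm) , s$sampling_dbh_cm - 2 * sum(rw) / 10 +
                 2 * rw[1] / 10, tolerance = 1e-12)
  expect_true(all(diff(d$dbh_cm) > 0))

  expect_error(reconstruct_dbh(mk_series(rep(10, 5), dbh = 3)), "smaller")
  expect_error(reconstruct_dbh(mk_series(c(1, NA, 1))), "impute")
})

test_that("height interpolation is linear in DBH with exact endpoints", {
  s <- ring_series("T1", 2001:2005, rep(8, 5), coring_height_m = 1.3,
                   sampling_dbh_cm = 8, sampling_height_m = 5.3)
  d <- reconstruct_dbh(s)
  h <- interpolate_height(s, d)
  expect_equal(attr(h, "slope"), 0.5)
  expect_equal(h$height_m[h$dbh_cm == 8], 5.3)
  # manual point: DBH 4 cm -> 1.3 + 0.5 * 4 = 3.3 m
  h4 <- interpolate_height(s, data.frame(tree_id = "T1", year = 2003,
                                         dbh_cm = c(0, 4), imputed = FALSE))
  expect_equal(h4$height_m, c(1.3, 3.3))
  bad <- s; bad$sampling_height_m <- 1.0
  expect_error(interpolate_height(bad, d), "below coring height")
})

test_that("reconstruction round-trips the generator truth exactly", {
  cfg <- default_sites(3)[["W-D"]]
  ts <- generate_trees(cfg, default_allometries()[["W-D"]], seed = 13,
                       missing_prob = 0)
  rec <- reconstruct_heights(ts$rings_observed, ts$trees)
  truth <- ts$truth$heights
  truth <- truth[order(truth$tree_id, truth$year), ]
  rec <- rec[order(rec$tree_id, rec$year), ]
  expect_equal(rec$dbh_cm, truth$dbh_cm, tolerance = 1e-12)
  expect_equal(rec$height_m, truth$height_m, tolerance = 1e-12)
  expect_false(any(rec$imputed))
})

test_that("reconstruction handles missing rings and flags them", {
  cfg <- default_sites(4)[["C-D"]]
  # a distance-to-pith allowance gives the headroom that imputed widths
  # need (imputation may slightly overshoot the deleted rings)
  ts <- generate_trees(cfg, default_allometries()[["C-D"]], seed = 17,
                       missing_prob = 0.08, pith_offset_cm = 0.5)
  rec <- reconstruct_heights(ts$rings_observed, ts$trees)
  miss <- ts$truth$missing
  expect_equal(sum(rec$imputed), sum(miss$missing))
  expect_true(all(tapply(rec$height_m, rec$tree_id,
                         function(x) all(diff(x) >= 0))))
  # imputation error stays small relative to the true widths
  truth <- ts$truth$heights
  j <- match(paste(rec$tree_id, rec$year), paste(truth$tree_id, truth$year))
  expect_lt(max(abs(rec$dbh_cm - truth$dbh_cm[j])), 1.0)
})
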