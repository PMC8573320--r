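test_that("restricted likelihood matches the dense oracle off-optimum", {
  for (k in 1:5) {
    df <- random_small_lmm(seed = 100 + k, n_tree = 4, n_yr = 7)
    spec <- small_spec()
    m <- length(unique(df$tree_id))
    set.seed(200 + k)
    theta <- c(rnorm(3, -1, 0.6), atanh(runif(1, -0.8, 0.8)),
               rnorm(m - 1, 0, 0.4))
    expect_equal(reml_loglik(df, spec, theta),
                 dense_reml_oracle(df, spec, theta), tolerance = 1e-10)
  }
})

test_that("degenerate structure reduces exactly to ordinary least squares", {
  df <- random_small_lmm(seed = 5, n_tree = 6, n_yr = 12)
  spec <- small_spec(include_re = FALSE, include_ar1 = FALSE,
                     include_weights = FALSE)
  fit <- fit_reml(df, spec)
  ols <- lm(y ~ site + h + h2 + temp_summer, data = df)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-6)
  expect_equal(fit$sigma, summary(ols)$sigma, tolerance = 1e-6)
  # REML loglik of the OLS reduction has a closed form
  expect_equal(fit$logLik, as.numeric(logLik(ols, REML = TRUE)),
               tolerance = 1e-6)
})

test_that("AR1-only fits equal closed-form generalized least squares", {
  set.seed(8)
  df <- random_small_lmm(seed = 8, n_tree = 5, n_yr = 15)
  # give the data genuine AR1 structure so phi_hat is interior
  for (tr in unique(df$tree_id)) {
    idx <- which(df$tree_id == tr)
    e <- as.numeric(arima.sim(list(ar = 0.6), length(idx)))
    df$y[idx] <- 0.5 * df$h[idx] + e
  }
  spec <- small_spec(include_re = FALSE, include_weights = FALSE)
  fit <- fit_reml(df, spec)
  X <- model.matrix(~ site + h + h2 + temp_summer, df)
  V <- matrix(0, nrow(df), nrow(df))
  for (tr in unique(df$tree_id)) {
    idx <- which(df$tree_id == tr)
    ti <- df$year[idx]
    V[idx, idx] <- outer(ti, ti, function(a, b) fit$phi^abs(a - b))
  }
  expect_equal(unname(fit$coefficients),
               as.numeric(gls_oracle(df$y, X, V)), tolerance = 1e-6)
})

test_that("estimates are invariant to tree order and year shifts", {
  amf <- annual_model_frame(default_truth()["la_ew"], seed = 44, n_trees = 2,
                            age_mean = 25, age_jitter = 3)
  df <- amf$data
  spec <- xylem_model_spec("la", "ew", log_transform = FALSE,
                           standardize_response = FALSE)
  f1 <- fit_reml(df, spec)
  f2 <- fit_reml(df[sample(nrow(df)), ], spec)     # shuffled rows
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-10)
  df3 <- df
  df3$year <- df3$year + 1000                       # only gaps matter
  f3 <- fit_reml(df3, spec)
  expect_equal(f1$logLik, f3$logLik, tolerance = 1e-8)
  expect_equal(f1$phi, f3$phi, tolerance = 1e-6)
})

test_that("the engine agrees with nlme on a moderate synthetic fit", {
  skip_if_not_installed("nlme")
  amf <- annual_model_frame(default_truth()["la_ew"], seed = 3, n_trees = 4,
                            age_mean = 40, age_jitter = 5)
  df <- amf$data
  spec <- xylem_model_spec("la", "ew", log_transform = FALSE,
                           standardize_response = FALSE)
  fit <- fit_reml(df, spec)
  preds <- xylemclim:::seasonal_predictors()
  fml <- stats::reformulate(c("site", preds, "h", "h2",
                              paste0("site:", preds)), response = "y")
  nf <- nlme::lme(fml, data = df,
                  random = list(tree_id = nlme::pdDiag(~ h + h2)),
                  correlation = nlme::corCAR1(form = ~ year | tree_id),
                  weights = nlme::varIdent(form = ~ 1 | tree_id),
                  method = "REML",
                  control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                             opt = "optim"))
  expect_equal(fit$logLik, as.numeric(logLik(nf)), tolerance = 1e-3)
  expect_equal(fit$phi,
               as.numeric(coef(nf$modelStruct$corStruct,
                               unconstrained = FALSE)), tolerance = 5e-3)
  expect_equal(fit$sigma, nf$sigma, tolerance = 1e-2)
  cf <- nlme::fixef(nf)[names(fit$coefficients)]
  expect_equal(unname(fit$coefficients), unname(cf), tolerance = 0.05)
})

test_that("degrees of freedom follow the inner-outer convention", {
  amf <- annual_model_frame(default_truth()["la_ew"], seed = 12, n_trees = 2,
                            age_mean = 20, age_jitter = 2)
  spec <- xylem_model_spec("la", "ew", log_transform = FALSE,
                           standardize_response = FALSE)
  fit <- fit_reml(amf$data, spec)
  N <- fit$n_obs; m <- fit$n_trees
  expect_equal(sum(fit$is_outer), 3L)                 # intercept + 2 sites
  expect_equal(fit$df_inner, N - m - 26L)
  expect_equal(fit$df_outer, m - 3L)
  expect_equal(unname(fit$df[names(fit$coefficients) == "h"]),
               fit$df_inner)
  spec_n <- xylem_model_spec("la", "ew", log_transform = FALSE,
                             standardize_response = FALSE,
                             df_method = "normal")
  fitn <- fit_reml(amf$data, spec_n)
  expect_true(all(is.infinite(fitn$df)))
})

test_that("a zero-variance random effect is reported, not an error", {
  tt <- trait_truth("la", "ew", intercept = 10, beta_height = 0.5,
                    re_sd = c(0, 0, 0), phi = 0, sigma = 1)
  amf <- annual_model_frame(list(la_ew = tt), seed = 9, n_trees = 2,
                            age_mean = 30, age_jitter = 2)
  spec <- xylem_model_spec("la", "ew", log_transform = FALSE,
                           standardize_response = FALSE,
                           include_weights = FALSE)
  fit <- fit_reml(amf$data, spec)
  expect_s3_class(fit, "xylem_lmm")
  expect_true(is.logical(fit$boundary))
  expect_lt(max(fit$sd_re) / fit$sigma, 0.25)
})

test_that("input validation catches unusable designs", {
  df <- random_small_lmm(seed = 1, n_tree = 1, n_yr = 8)
  expect_error(fit_reml(df, small_spec()), "at least 2 trees")
  df2 <- random_small_lmm(seed = 1, n_tree = 6, n_yr = 8)
  df2$h2 <- df2$h                                     # collinear
  expect_error(fit_reml(df2, small_spec()), "singular")
  df3 <- random_small_lmm(seed = 2, n_tree = 6, n_yr = 2)
  expect_error(fit_reml(df3, small_spec()), "3 years")
})
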