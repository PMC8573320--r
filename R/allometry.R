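#' Fit a modified Weibull height-diameter allometry
#'
#' Nonlinear least squares for `h = h_max * exp(a * DBH^b)` with `a < 0`,
#' `b > 0`: `h_max` is the asymptotic height and `a`, `b` modulate how the
#' asymptote is approached. Fitting uses Levenberg-Marquardt
#' (minpack.lm) from a data-driven start (`h_max = 1.05 * max(h)`, `a`
#' solving the mean point at `b = 1`), with 20 deterministic jittered
#' multistarts as fallback on non-convergence.
#'
#' @param dbh_cm DBH values, cm (one per tree).
#' @param height_m tree heights, m (> 0).
#' @param start optional list/vector with `h_max`, `a`, `b`.
#' @param site_id optional label carried in the result.
#' @return object of class `weibull_allometry` with elements `h_max`, `a`,
#'   `b`, `residual_sd`, `n`, `converged`, `site_id`.
#' @export
fit_weibull <- function(dbh_cm, height_m, start = NULL, site_id = NA_character_) {
  ok <- is.finite(dbh_cm) & is.finite(height_m)
  dbh_cm <- dbh_cm[ok]; height_m <- height_m[ok]
  if (length(unique(dbh_cm)) < 4L) {
    stop("need at least 4 distinct DBH values", call. = FALSE)
  }
  if (any(height_m <= 0)) stop("heights must be positive", call. = FALSE)
  df <- data.frame(d = dbh_cm, h = height_m)
  if (is.null(start)) {
    # a rising allometry (cor(h, d) > 0) needs a and b of equal sign;
    # start a so the curve passes through the mean point at the chosen b
    h_max0 <- 1.05 * max(height_m)
    b0 <- if (stats::cor(dbh_cm, height_m) >= 0) -0.7 else 0.7
    a0 <- log(mean(height_m) / h_max0) / max(mean(dbh_cm), 1e-6)^b0
    start <- list(h_max = h_max0, a = a0, b = b0)
  } else {
    start <- as.list(start)
  }
  try_fit <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(h ~ h_max * exp(a * d^b), data = df, start = st,
                        lower = c(h_max = 1e-6, a = -Inf, b = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- try_fit(start)
  if (is.null(fit)) {
    # deterministic jitter grid around the start (no RNG involvement)
    jit <- expand.grid(f1 = c(1, 1.2, 0.9, 1.5), f2 = c(1, 0.5, 2, 4, 0.25))
    for (k in seq_len(nrow(jit))) {
      st <- list(h_max = start$h_max * jit$f1[k], a = start$a * jit$f2[k],
                 b = start$b * jit$f2[k])
      fit <- try_fit(st)
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit)) {
    stop(sprintf(
      "Weibull fit failed to converge after multistart (n = %d, start h_max = %.2f)",
      length(dbh_cm), start$h_max), call. = FALSE)
  }
  cf <- coef(fit)
  structure(list(site_id = site_id,
                 h_max = unname(cf["h_max"]), a = unname(cf["a"]),
                 b = unname(cf["b"]),
                 residual_sd = sqrt(sum(residuals(fit)^2) /
                                      max(length(dbh_cm) - 3L, 1L)),
                 n = length(dbh_cm), converged = TRUE),
            class = "weibull_allometry")
}

#' Predict height from DBH under a fitted Weibull allometry
#'
#' @param object a `weibull_allometry`.
#' @param dbh_cm DBH values, cm.
#' @param ... unused.
#' @return predicted heights, m.
#' @export
predict.weibull_allometry <- function(object, dbh_cm, ...) {
  object$h_max * exp(object$a * dbh_cm^object$b)
}

#' @export
print.weibull_allometry <- function(x, ...) {
  cat(sprintf(
    "Weibull height-diameter allometry%s\n  h = %.3f * exp(%.4f * DBH^%.4f)\n  residual SD %.3f m on %d trees\n",
    if (is.na(x$site_id)) "" else paste0(" [", x$site_id, "]"),
    x$h_max, x$a, x$b, x$residual_sd, x$n))
  invisible(x)
}

#' Fit a regional curve: expected ring width as a function of cambial age
#'
#' Age-wise mean ring widths smoothed by a cubic smoothing spline. The
#' `span` parameter is the fraction of the maximum cambial age used as the
#' spline's effective bandwidth (df ~ 1/span); `span = 0` keeps the raw
#' age-wise means and `span = Inf` returns the global mean at every age.
#'
#' @param rw_age data.frame with columns `age` (cambial age, years) and
#'   `rw_mm`.
#' @param span smoothing span as a fraction of the maximum age (default
#'   0.1).
#' @return object of class `regional_curve`: data.frame `age`, `rw_mm`
#'   (smoothed, strictly positive) with attributes `span` and `site_id`.
#' @export
fit_regional_curve <- function(rw_age, span = 0.1, site_id = NA_character_) {
  stop_if_not_cols(rw_age, c("age", "rw_mm"), "ring-width-by-age table")
  rw_age <- rw_age[is.finite(rw_age$age) & is.finite(rw_age$rw_mm), ,
                   drop = FALSE]
  if (nrow(rw_age) == 0L) stop("empty ring-width-by-age table", call. = FALSE)
  means <- stats::aggregate(list(rw_mm = rw_age$rw_mm),
                            by = list(age = rw_age$age), mean)
  means <- means[order(means$age), , drop = FALSE]
  n_ages <- nrow(means)
  curve <- if (span <= 0 || n_ages < 4L) {
    means$rw_mm
  } else if (is.infinite(span)) {
    rep(mean(rw_age$rw_mm), n_ages)
  } else if (stats::var(means$rw_mm) < 1e-24) {
    means$rw_mm                       # constant input: spline is a no-op
  } else {
    df_target <- max(2, min(n_ages - 1L, 1 / span))
    sp <- smooth.spline(means$age, means$rw_mm, df = df_target)
    predict(sp, means$age)$y
  }
  out <- data.frame(age = means$age, rw_mm = pmax(curve, 1e-9))
  attr(out, "span") <- span
  attr(out, "site_id") <- site_id
  class(out) <- c("regional_curve", "data.frame")
  out
}

#' Cambial-age table from a long ring table
#'
#' Cambial age is the ring count from the innermost measured ring at the
#' coring height.
#'
#' @param rings long data.frame `tree_id`, `year`, `rw_mm`.
#' @return data.frame `tree_id`, `age`, `rw_mm`.
#' @export
rings_by_cambial_age <- function(rings) {
  stop_if_not_cols(rings, c("tree_id", "year", "rw_mm"), "ring table")
  parts <- lapply(split(rings, rings$tree_id), function(sub) {
    sub <- sub[order(sub$year), , drop = FALSE]
    data.frame(tree_id = sub$tree_id, age = seq_len(nrow(sub)),
               rw_mm = sub$rw_mm, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res
}

#' Ontogenetic age -> diameter -> height trajectory
#'
#' Composes a regional curve (cumulative double ring width gives the mean
#' diameter-age trajectory) with a Weibull height-diameter allometry from
#' the same site. Age 0 is included with diameter 0 and height
#' `h_max * exp(a)` evaluated at DBH = 0.
#'
#' @param curve a [fit_regional_curve()] result.
#' @param allom a [fit_weibull()] result.
#' @return data.frame `age`, `diameter_cm`, `height_m`.
#' @export
ontogenetic_trajectory <- function(curve, allom) {
  stopifnot(inherits(curve, "regional_curve"),
            inherits(allom, "weibull_allometry"))
  s1 <- attr(curve, "site_id"); s2 <- allom$site_id
  if (!is.na(s1) && !is.na(s2) && s1 != s2) {
    stop(sprintf("curve (%s) and allometry (%s) come from different sites",
                 s1, s2), call. = FALSE)
  }
  diameter_cm <- c(0, 2 * cumsum(mm_to_cm(curve$rw_mm)))
  data.frame(age = c(0, curve$age),
             diameter_cm = diameter_cm,
             height_m = predict(allom, diameter_cm))
}
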