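#' Construct a per-tree ring-width series
#'
#' @param tree_id series label.
#' @param years strictly increasing, contiguous calendar years.
#' @param rw_mm ring widths in mm; `NA` marks a missing ring.
#' @param coring_height_m height of the coring point (initial height at
#'   hypothetical DBH = 0), m.
#' @param sampling_dbh_cm DBH measured in the sampling year, cm.
#' @param sampling_height_m total tree height in the sampling year, m.
#' @param pith_offset_cm optional inside-bark distance-to-pith allowance
#'   added to the innermost diameter (default 0).
#' @return object of class `ring_series`.
#' @export
ring_series <- function(tree_id, years, rw_mm, coring_height_m,
                        sampling_dbh_cm, sampling_height_m,
                        pith_offset_cm = 0) {
  years <- as.integer(years)
  if (length(years) == 0L || length(years) != length(rw_mm)) {
    stop("'years' and 'rw_mm' must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(diff(years) != 1L)) {
    stop("'years' must be strictly increasing and contiguous", call. = FALSE)
  }
  if (any(rw_mm <= 0, na.rm = TRUE)) {
    stop("ring widths must be positive where present", call. = FALSE)
  }
  structure(list(tree_id = as.character(tree_id), years = years,
                 rw_mm = as.numeric(rw_mm),
                 imputed = rep(FALSE, length(years)),
                 coring_height_m = coring_height_m,
                 sampling_dbh_cm = sampling_dbh_cm,
                 sampling_height_m = sampling_height_m,
                 sampling_year = years[length(years)],
                 pith_offset_cm = pith_offset_cm),
            class = "ring_series")
}

#' Impute missing rings from neighboring ring widths
#'
#' Each missing ring is replaced by the arithmetic mean of the pooled
#' up-to-10 nearest non-missing ring widths before it and up-to-10 after
#' it. Only originally measured rings feed an imputation (imputed values
#' never feed other imputations), so consecutive gaps are filled jointly
#' and the result does not depend on fill order. At series ends, the
#' shorter available side is used as-is.
#'
#' @param series a [ring_series()].
#' @param window maximum non-missing neighbors used per side (default 10).
#' @return the series with all gaps filled; `$imputed` flags retained.
#' @export
impute_missing_rings <- function(series, window = 10L) {
  stopifnot(inherits(series, "ring_series"))
  rw <- series$rw_mm
  miss <- which(is.na(rw))
  if (length(miss) == 0L) return(series)
  if (all(is.na(rw))) {
    stop(sprintf("series %s: all rings missing, cannot impute",
                 series$tree_id), call. = FALSE)
  }
  filled <- rw
  for (i in miss) {
    before <- rw[seq_len(i - 1L)]
    before <- before[!is.na(before)]
    before <- tail(before, window)
    after <- if (i < length(rw)) rw[(i + 1L):length(rw)] else numeric(0)
    after <- after[!is.na(after)]
    after <- head(after, window)
    pool <- c(before, after)
    if (length(pool) == 0L) {
      stop(sprintf("series %s: no measured rings around year %d",
                   series$tree_id, series$years[i]), call. = FALSE)
    }
    filled[i] <- mean(pool)
  }
  series$rw_mm <- filled
  series$imputed[miss] <- TRUE
  series
}

#' Reconstruct annual DBH from a complete ring-width series
#'
#' DBH in the sampling year equals the measured DBH; walking backwards,
#' double the ring width of each year is subtracted cumulatively:
#' `DBH_(t-1) = DBH_t - 2 * rw_t`.
#'
#' @param series a complete (imputed) [ring_series()].
#' @param slack_cm tolerated shortfall of the sampling DBH against the
#'   cumulative double ring width (cm). Imputed rings can overshoot the
#'   true widths slightly; a shortfall within the slack is clamped to a
#'   DBH of 0 with a warning, a larger one is an error (inconsistent
#'   inputs).
#' @return data.frame with `tree_id`, `year`, `dbh_cm` (DBH at the end of
#'   each ring year) and `imputed`.
#' @export
reconstruct_dbh <- function(series, slack_cm = 1) {
  stopifnot(inherits(series, "ring_series"))
  if (anyNA(series$rw_mm)) {
    stop("series contains missing rings; run impute_missing_rings() first",
         call. = FALSE)
  }
  n <- length(series$rw_mm)
  step <- 2 * mm_to_cm(series$rw_mm)
  # dbh[t] = sampling DBH - sum of steps after t (telescoping backwards)
  dbh <- series$sampling_dbh_cm - (sum(step) - cumsum(step))
  innermost <- series$sampling_dbh_cm - sum(step)
  if (innermost < -slack_cm) {
    stop(sprintf(
      "series %s: sampling DBH (%.2f cm) smaller than cumulative ring width (%.2f cm)",
      series$tree_id, series$sampling_dbh_cm, sum(step)), call. = FALSE)
  }
  if (innermost < -1e-9) {
    warning(sprintf(
      "series %s: cumulative ring width exceeds sampling DBH by %.2f cm; innermost DBH clamped to 0",
      series$tree_id, -innermost), call. = FALSE)
  }
  data.frame(tree_id = series$tree_id, year = series$years,
             dbh_cm = pmax(dbh, 0), imputed = series$imputed,
             stringsAsFactors = FALSE)
}

#' Interpolate annual tree height linearly in DBH
#'
#' The coring height is the height at hypothetical DBH = 0 (the intercept)
#' and the measured sampling height anchors the slope:
#' `h_t = h_0 + a * DBH_t` with
#' `a = (sampling height - coring height) / sampling DBH`.
#'
#' @param series a [ring_series()] (supplies heights and sampling DBH).
#' @param dbh data.frame from [reconstruct_dbh()].
#' @return data.frame `tree_id`, `year`, `dbh_cm`, `height_m`, `imputed`,
#'   with the per-tree slope (m per cm) as attribute `"slope"`.
#' @export
interpolate_height <- function(series, dbh) {
  stopifnot(inherits(series, "ring_series"))
  if (series$sampling_dbh_cm <= 0) {
    stop("sampling DBH must be positive", call. = FALSE)
  }
  if (series$sampling_height_m < series$coring_height_m) {
    stop(sprintf("series %s: sampling height (%.2f m) below coring height (%.2f m)",
                 series$tree_id, series$sampling_height_m,
                 series$coring_height_m), call. = FALSE)
  }
  a <- (series$sampling_height_m - series$coring_height_m) /
    series$sampling_dbh_cm
  out <- dbh
  out$height_m <- series$coring_height_m + a * dbh$dbh_cm
  attr(out, "slope") <- a
  out
}

#' Reconstruct per-year DBH and height for a whole tree set
#'
#' Composes [impute_missing_rings()], [reconstruct_dbh()] and
#' [interpolate_height()] over a long ring table plus tree metadata.
#'
#' @param rings long data.frame `tree_id`, `year`, `rw_mm` (`NA` = missing).
#' @param trees metadata data.frame with `tree_id`, `coring_height_m`,
#'   `dbh_cm`, `height_m` (at sampling), `sampling_year`.
#' @param pith_offset_cm scalar or per-tree named vector (default 0).
#' @return data.frame `tree_id`, `year`, `dbh_cm`, `height_m`, `imputed`.
#' @export
reconstruct_heights <- function(rings, trees, pith_offset_cm = 0) {
  stop_if_not_cols(rings, c("tree_id", "year", "rw_mm"), "ring table")
  stop_if_not_cols(trees, c("tree_id", "coring_height_m", "dbh_cm",
                            "height_m", "sampling_year"), "tree metadata")
  out <- vector("list", nrow(trees))
  for (i in seq_len(nrow(trees))) {
    tr <- trees[i, ]
    sub <- rings[rings$tree_id == tr$tree_id, , drop = FALSE]
    sub <- sub[order(sub$year), , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop(sprintf("no rings found for tree %s", tr$tree_id), call. = FALSE)
    }
    po <- if (length(pith_offset_cm) > 1L) {
      pith_offset_cm[[tr$tree_id]]
    } else pith_offset_cm
    rs <- ring_series(tr$tree_id, sub$year, sub$rw_mm,
                      coring_height_m = tr$coring_height_m,
                      sampling_dbh_cm = tr$dbh_cm,
                      sampling_height_m = tr$height_m,
                      pith_offset_cm = po)
    if (rs$sampling_year != tr$sampling_year) {
      stop(sprintf("tree %s: last ring year (%d) != sampling year (%d)",
                   tr$tree_id, rs$sampling_year, tr$sampling_year),
           call. = FALSE)
    }
    rs <- impute_missing_rings(rs)
    out[[i]] <- interpolate_height(rs, reconstruct_dbh(rs))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
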