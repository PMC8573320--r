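#' Generate monthly climate series for synthetic sites
#'
#' Draws monthly mean temperature and precipitation sums around each site's
#' monthly normals. Temperature noise is Gaussian (`temp_sd`); precipitation
#' noise is Gaussian with SD `precip_cv * normal`, truncated at 0.
#'
#' @param sites a [site_config()] or list of them.
#' @param years integer vector of calendar years (need not be contiguous).
#' @param seed master integer seed.
#' @return data.frame with columns `site`, `year`, `month`, `tmean_c`,
#'   `prcp_mm`; one row per site x year x month.
#' @export
generate_climate <- function(sites, years, seed) {
  if (inherits(sites, "site_config")) sites <- list(sites)
  if (length(years) == 0L) stop("'years' must be non-empty", call. = FALSE)
  years <- sort(unique(as.integer(years)))
  seeds <- derive_seeds(seed, length(sites))
  out <- vector("list", length(sites))
  for (i in seq_along(sites)) {
    cfg <- sites[[i]]
    ny <- length(years)
    tab <- with_seed(seeds[i], {
      tmean <- rep(cfg$monthly_temp_means, times = ny) +
        rnorm(12L * ny, sd = cfg$temp_sd)
      pnorm_mm <- rep(cfg$monthly_precip_means, times = ny)
      prcp <- pmax(0, pnorm_mm + rnorm(12L * ny, sd = cfg$precip_cv * pnorm_mm))
      data.frame(site = cfg$site_id,
                 year = rep(years, each = 12L),
                 month = rep(1:12, times = ny),
                 tmean_c = tmean, prcp_mm = prcp,
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- tab
  }
  do.call(rbind, out)
}

#' Generate tree metadata and ring-width series for one site
#'
#' Ring widths follow a negative-exponential decline with cambial age times
#' lognormal noise. Sampling DBH is twice the cumulative ring width plus an
#' optional distance-to-pith allowance; sampling height follows the site's
#' Weibull height-diameter allometry plus Gaussian noise. Missing rings are
#' deleted from the observed series (value `NA`) but retained in the truth
#' output, so downstream imputation error is measurable.
#'
#' @param cfg a [site_config()] (supplies `n_trees` and the site label).
#' @param allometry list with `h_max` (m), `a` (< 0), `b` (> 0).
#' @param seed master integer seed.
#' @param sampling_year calendar year of coring (last ring).
#' @param age_mean,age_jitter mean ring count per tree and its half-range.
#' @param rw_start,rw_inf,rw_decay negative-exponential age trend of ring
#'   width, mm: `rw_inf + (rw_start - rw_inf) * exp(-rw_decay * age)`.
#' @param rw_sdlog lognormal noise SD of ring widths (0 = deterministic).
#' @param missing_prob per-ring probability of a missing ring (never the
#'   first or last ring).
#' @param coring_height_m height of the coring point, m.
#' @param height_noise_sd SD (m) of sampling-height noise around the
#'   allometric expectation.
#' @param pith_offset_cm inside-bark distance-to-pith allowance added to
#'   the innermost diameter (default 0, making DBH reconstruction exactly
#'   invertible).
#' @return list of class `xylem_tree_set` with elements `trees` (metadata),
#'   `rings_observed` (long, `rw_mm` is `NA` at missing rings) and `truth`
#'   (complete `rings`, per-year `heights`, and `missing` flags).
#' @export
generate_trees <- function(cfg, allometry, seed,
                           sampling_year = 2015, age_mean = 80,
                           age_jitter = 8, rw_start = 2.2, rw_inf = 0.4,
                           rw_decay = 0.03, rw_sdlog = 0.25,
                           missing_prob = 0.02, coring_height_m = 1.3,
                           height_noise_sd = 0.5, pith_offset_cm = 0) {
  stopifnot(inherits(cfg, "site_config"))
  if (cfg$n_trees <= 0) stop("n_trees must be positive", call. = FALSE)
  if (!(allometry$h_max > 0 && allometry$a < 0 &&
          allometry$a * allometry$b > 0)) {
    stop(paste("invalid Weibull parameters: need h_max > 0, a < 0 and a",
               "rising curve (a * b > 0, i.e. b < 0)"), call. = FALSE)
  }
  seeds <- derive_seeds(seed, cfg$n_trees)
  trees <- rings_true <- rings_obs <- heights <- missing <- list()
  for (k in seq_len(cfg$n_trees)) {
    tid <- sprintf("%s_T%02d", cfg$site_id, k)
    res <- with_seed(seeds[k], {
      n <- as.integer(round(age_mean + runif(1, -age_jitter, age_jitter)))
      n <- max(n, 5L)
      age <- seq_len(n)
      rw <- (rw_inf + (rw_start - rw_inf) * exp(-rw_decay * age))
      if (rw_sdlog > 0) rw <- rw * exp(rnorm(n, -rw_sdlog^2 / 2, rw_sdlog))
      yrs <- seq(sampling_year - n + 1L, sampling_year)
      miss <- rep(FALSE, n)
      if (missing_prob > 0 && n > 2L) {
        miss[2:(n - 1L)] <- runif(n - 2L) < missing_prob
      }
      dbh <- pith_offset_cm + 2 * cumsum(mm_to_cm(rw))
      dbh_samp <- dbh[n]
      h_exp <- allometry$h_max * exp(allometry$a * dbh_samp^allometry$b)
      h_samp <- h_exp + if (height_noise_sd > 0) {
        rnorm(1, sd = height_noise_sd)
      } else 0
      h_samp <- max(h_samp, coring_height_m + 0.2)
      slope <- (h_samp - coring_height_m) / dbh_samp
      list(yrs = yrs, rw = rw, miss = miss, dbh = dbh,
           dbh_samp = dbh_samp, h_samp = h_samp,
           h = coring_height_m + slope * dbh)
    })
    trees[[k]] <- data.frame(tree_id = tid, site = cfg$site_id,
                             coring_height_m = coring_height_m,
                             sampling_year = sampling_year,
                             dbh_cm = res$dbh_samp, height_m = res$h_samp,
                             stringsAsFactors = FALSE)
    rings_true[[k]] <- data.frame(tree_id = tid, year = res$yrs,
                                  rw_mm = res$rw, stringsAsFactors = FALSE)
    obs <- rings_true[[k]]
    obs$rw_mm[res$miss] <- NA_real_
    rings_obs[[k]] <- obs
    heights[[k]] <- data.frame(tree_id = tid, year = res$yrs,
                               dbh_cm = res$dbh, height_m = res$h,
                               stringsAsFactors = FALSE)
    missing[[k]] <- data.frame(tree_id = tid, year = res$yrs,
                               missing = res$miss, stringsAsFactors = FALSE)
  }
  structure(list(trees = do.call(rbind, trees),
                 rings_observed = do.call(rbind, rings_obs),
                 truth = list(rings = do.call(rbind, rings_true),
                              heights = do.call(rbind, heights),
                              missing = do.call(rbind, missing))),
            class = "xylem_tree_set")
}

# merge several per-site tree sets into one
combine_tree_sets <- function(sets) {
  structure(list(
    trees = do.call(rbind, lapply(sets, `[[`, "trees")),
    rings_observed = do.call(rbind, lapply(sets, `[[`, "rings_observed")),
    truth = list(
      rings = do.call(rbind, lapply(sets, function(s) s$truth$rings)),
      heights = do.call(rbind, lapply(sets, function(s) s$truth$heights)),
      missing = do.call(rbind, lapply(sets, function(s) s$truth$missing)))),
    class = "xylem_tree_set")
}

# Annual ground-truth trait means on the model scale for every
# tree x year x trait x portion, plus the standardized covariate frame.
# The truth linear predictor lives here; cells are drawn around it.
annual_truth_frame <- function(truth, tree_set, climate, seed) {
  stopifnot(inherits(tree_set, "xylem_tree_set"))
  for (tt in truth) {
    if (abs(tt$phi) >= 1) stop("phi must lie in (-1, 1)", call. = FALSE)
  }
  seasonal <- aggregate_seasons(climate,
                                years = unique(tree_set$truth$heights$year))
  mf <- merge(tree_set$truth$heights,
              tree_set$trees[, c("tree_id", "site")], by = "tree_id")
  mf <- merge(mf, seasonal, by = c("site", "year"))
  mf <- mf[order(mf$tree_id, mf$year), , drop = FALSE]
  rownames(mf) <- NULL
  if (nrow(mf) == 0L) {
    stop("trees and climate share no usable years", call. = FALSE)
  }

  preds <- seasonal_predictors()
  record <- list(center = numeric(0), scale = numeric(0))
  zscore <- function(x, nm) {
    mu <- mean(x); s <- sd(x)
    if (!is.finite(s) || s == 0) s <- 1
    record$center[nm] <<- mu; record$scale[nm] <<- s
    (x - mu) / s
  }
  mf$h_raw <- mf$height_m
  mf$h <- zscore(mf$height_m, "h")
  mf$h2 <- zscore(mf$height_m^2, "h2")
  for (p in preds) {
    mf[[paste0(p, "_raw")]] <- mf[[p]]
    mf[[p]] <- zscore(mf[[p]], p)
  }

  trees <- unique(mf$tree_id)
  seeds <- derive_seeds(seed, length(truth))
  targets <- vector("list", length(truth))
  re_out <- vector("list", length(truth))
  for (j in seq_along(truth)) {
    tt <- truth[[j]]
    res <- with_seed(seeds[j], {
      re <- matrix(rnorm(length(trees) * 3L), ncol = 3L) %*% diag(tt$re_sd)
      rownames(re) <- trees
      mult <- if (tt$sigma_tree_cv > 0) {
        sdl <- sqrt(log(1 + tt$sigma_tree_cv^2))
        exp(rnorm(length(trees), -sdl^2 / 2, sdl))
      } else rep(1, length(trees))
      names(mult) <- trees
      eps <- numeric(nrow(mf))
      for (tr in trees) {
        idx <- which(mf$tree_id == tr)
        s <- tt$sigma * mult[tr]
        n <- length(idx)
        e <- numeric(n)
        if (s > 0 && n > 0) {
          e[1] <- rnorm(1, sd = s)
          if (n > 1) {
            innov <- rnorm(n - 1, sd = s * sqrt(1 - tt$phi^2))
            for (t2 in 2:n) e[t2] <- tt$phi * e[t2 - 1] + innov[t2 - 1]
          }
        }
        eps[idx] <- e
      }
      list(re = re, mult = mult, eps = eps)
    })
    clim_beta <- matrix(rep(tt$beta_climate, each = nrow(mf)), nrow = nrow(mf))
    for (s2 in c("C-D", "C-M")) {
      rows <- mf$site == s2
      if (any(rows)) {
        clim_beta[rows, ] <- sweep(clim_beta[rows, , drop = FALSE], 2,
                                   tt$beta_climate_site[s2, ], `+`)
      }
    }
    clim_term <- rowSums(as.matrix(mf[, preds]) * clim_beta)
    site_off <- ifelse(mf$site == "C-D", tt$site_offsets["C-D"],
                       ifelse(mf$site == "C-M", tt$site_offsets["C-M"], 0))
    re_term <- res$re[mf$tree_id, 1] + res$re[mf$tree_id, 2] * mf$h +
      res$re[mf$tree_id, 3] * mf$h2
    value_model <- tt$intercept + site_off +
      tt$beta_height * mf$h + tt$beta_height2 * mf$h2 +
      clim_term + re_term + res$eps
    value_natural <- if (tt$log_scale) exp(value_model) else value_model
    if (tt$trait == "den") value_natural <- pmin(pmax(value_natural, 0.02), 0.98)
    targets[[j]] <- data.frame(tree_id = mf$tree_id, year = mf$year,
                               site = mf$site, trait = tt$trait,
                               portion = tt$portion,
                               value_model = value_model,
                               value_natural = value_natural,
                               stringsAsFactors = FALSE)
    re_out[[j]] <- list(trait = tt$trait, portion = tt$portion,
                        re = res$re, sigma_mult = res$mult)
  }
  names(re_out) <- names(truth)
  list(frame = mf, targets = do.call(rbind, targets),
       random_effects = re_out, standardization = record)
}

#' Generate annual trait chronologies directly from the ground truth
#'
#' Bypasses the cell layer: returns the annual earlywood/latewood trait
#' means exactly as defined by the truth linear predictor (fixed effects +
#' per-tree random effects + AR1 residual). Used for parameter-recovery
#' studies where the within-ring sampling layer is irrelevant.
#'
#' @inheritParams generate_cells
#' @return list with `chronology` (tree_id, year, portion, la, tb2, den,
#'   cwt on the natural scale), `frame` (standardized covariates per
#'   tree x year), `targets`, `random_effects`, `standardization`.
#' @export
generate_annual_traits <- function(truth, tree_set, climate, seed) {
  atf <- annual_truth_frame(truth, tree_set, climate, seed)
  tg <- atf$targets
  key <- unique(tg[, c("tree_id", "year", "portion")])
  for (tr in c("la", "tb2", "den", "cwt")) {
    sub <- tg[tg$trait == tr, c("tree_id", "year", "portion", "value_natural")]
    names(sub)[4] <- tr
    key <- merge(key, sub, by = c("tree_id", "year", "portion"),
                 all.x = TRUE, sort = FALSE)
  }
  key <- key[order(key$tree_id, key$year, key$portion), , drop = FALSE]
  rownames(key) <- NULL
  c(list(chronology = key), atf)
}

#' Generate a per-cell anatomy table around the annual ground truth
#'
#' Each ring contains `cells_per_ring` tracheids whose geometry follows the
#' within-ring profile (shrinking lumen, growing wall-to-lumen ratio). Cell
#' trait values are scaled so that, at zero within-ring noise, the
#' earlywood and latewood per-cell means of LA, TB2, DEN and mean CWT equal
#' the annual truth targets exactly; the radial lumen diameter is derived
#' from the profile's Mork ratio so the generator's earlywood/latewood
#' labels are recoverable by the Mork classifier.
#'
#' @param truth named list of [trait_truth()] objects covering all four
#'   traits in both portions (see [default_truth()]).
#' @param profile a [cell_geometry_profile()].
#' @param tree_set an `xylem_tree_set` (possibly combined across sites).
#' @param climate monthly climate table covering the ring years (including
#'   September of the year before the first ring).
#' @param seed master integer seed.
#' @return list with `cells` (one row per tracheid), `truth_annual` (the
#'   annual targets), `frame`, `random_effects`, `standardization`.
#' @export
generate_cells <- function(truth, profile, tree_set, climate, seed) {
  stopifnot(inherits(profile, "cell_geometry_profile"))
  seeds <- derive_seeds(seed, 2L)
  atf <- annual_truth_frame(truth, tree_set, climate, seeds[1])
  cur <- profile_curves(profile)
  n <- profile$cells_per_ring
  is_lw <- cur$mork >= 1
  shapes <- list(la = cur$la_shape, cwt = cur$cwt_shape,
                 den = cur$den_shape, tb2 = cur$tb2_shape)
  # normalize each shape to mean 1 within its portion
  shp <- lapply(shapes, function(s) {
    s[is_lw] <- s[is_lw] / mean(s[is_lw])
    s[!is_lw] <- s[!is_lw] / mean(s[!is_lw])
    s
  })

  tg <- atf$targets
  tgw <- stats::reshape(tg[, c("tree_id", "year", "trait", "portion",
                               "value_natural")],
                        idvar = c("tree_id", "year", "portion"),
                        timevar = "trait", direction = "wide")
  names(tgw) <- sub("^value_natural\\.", "", names(tgw))
  rows_ty <- unique(tgw[, c("tree_id", "year")])
  rows_ty <- rows_ty[order(rows_ty$tree_id, rows_ty$year), , drop = FALSE]

  noise_cv <- profile$noise_cv
  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  out <- vector("list", nrow(rows_ty))
  cell_seed <- derive_seeds(seeds[2], nrow(rows_ty))
  portion_chr <- ifelse(is_lw, "lw", "ew")
  for (i in seq_len(nrow(rows_ty))) {
    tid <- rows_ty$tree_id[i]; yr <- rows_ty$year[i]
    trow <- tgw[tgw$tree_id == tid & tgw$year == yr, , drop = FALSE]
    tgt <- function(trait) {
      v <- numeric(n)
      v[!is_lw] <- trow[trow$portion == "ew", trait]
      v[is_lw] <- trow[trow$portion == "lw", trait]
      v
    }
    vals <- with_seed(cell_seed[i], {
      noise <- function() {
        if (sdlog > 0) exp(rnorm(n, -sdlog^2 / 2, sdlog)) else rep(1, n)
      }
      la <- tgt("la") * shp$la * noise()
      cwt <- tgt("cwt") * shp$cwt * noise()
      den <- pmin(pmax(tgt("den") * shp$den * noise(), 0.02), 0.98)
      tb2 <- tgt("tb2") * shp$tb2 * noise()
      list(la = la, cwt = cwt, den = den, tb2 = tb2)
    })
    cwt_rad <- 1.1 * vals$cwt
    cwt_tan <- 0.9 * vals$cwt          # per-cell mean CWT stays exact
    ld_rad <- 4 * cwt_rad / cur$mork   # Mork ratio fixed by the profile
    ld_tan <- vals$la / ld_rad
    cwa <- vals$la * vals$den / (1 - vals$den)
    wall_len_tan <- 2 * cwt_tan / sqrt(vals$tb2)
    wall_len_rad <- ld_rad + 2 * cwt_tan
    out[[i]] <- data.frame(
      tree_id = tid, year = yr,
      la_um2 = vals$la, ld_rad_um = ld_rad, ld_tan_um = ld_tan,
      cwt_rad_um = cwt_rad, cwt_tan_um = cwt_tan, cwa_um2 = cwa,
      wall_len_rad_um = wall_len_rad, wall_len_tan_um = wall_len_tan,
      true_portion = portion_chr, stringsAsFactors = FALSE)
  }
  list(cells = do.call(rbind, out), truth_annual = tg,
       frame = atf$frame, random_effects = atf$random_effects,
       standardization = atf$standardization)
}

#' Generate a complete synthetic study with known ground truth
#'
#' Composes [generate_climate()], [generate_trees()] and [generate_cells()]
#' for the default (or supplied) three-site design.
#'
#' @param sites list of [site_config()]s (default [default_sites()]).
#' @param allometries per-site Weibull parameter lists
#'   (default [default_allometries()]).
#' @param truth trait ground truth (default [default_truth()]).
#' @param profile within-ring geometry (default [cell_geometry_profile()]).
#' @param seed master integer seed.
#' @param sampling_year last ring year.
#' @param age_mean mean ring count per tree.
#' @param ... further arguments passed to [generate_trees()].
#' @return list with `climate`, `tree_set`, `cells`, `truth_annual`,
#'   `frame`, `random_effects`, `standardization`, `seed`.
#' @export
generate_dataset <- function(sites = default_sites(),
                             allometries = default_allometries(),
                             truth = default_truth(),
                             profile = cell_geometry_profile(),
                             seed = 1, sampling_year = 2015,
                             age_mean = 80, ...) {
  seeds <- derive_seeds(seed, 2L + length(sites))
  year_min <- sampling_year - as.integer(age_mean) - 20L
  climate <- generate_climate(sites, (year_min - 1L):sampling_year, seeds[1])
  sets <- vector("list", length(sites))
  for (i in seq_along(sites)) {
    sid <- sites[[i]]$site_id
    sets[[i]] <- generate_trees(sites[[i]], allometries[[sid]],
                                seed = seeds[1L + i],
                                sampling_year = sampling_year,
                                age_mean = age_mean, ...)
  }
  tree_set <- combine_tree_sets(sets)
  cell_out <- generate_cells(truth, profile, tree_set, climate,
                             seed = seeds[length(seeds)])
  c(list(climate = climate, tree_set = tree_set, seed = seed), cell_out)
}

#' Write synthetic inputs in their on-disk exchange formats
#'
#' Writes `cells.csv`, `climate.csv`, `trees.csv`, `rings_long.csv`,
#' `rings.rwl` (Tucson decadal format, 0.01 mm units) and `truth.json`.
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_synthetic_inputs <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cells = file.path(dir, "cells.csv"),
             climate = file.path(dir, "climate.csv"),
             trees = file.path(dir, "trees.csv"),
             rings_long = file.path(dir, "rings_long.csv"),
             rwl = file.path(dir, "rings.rwl"),
             truth = file.path(dir, "truth.json"))
  cells <- dataset$cells
  cells$true_portion <- NULL   # labels live in the truth record only
  write.csv(cells, paths["cells"], row.names = FALSE)
  write.csv(dataset$climate, paths["climate"], row.names = FALSE)
  write.csv(dataset$tree_set$trees, paths["trees"], row.names = FALSE)
  write.csv(dataset$tree_set$rings_observed, paths["rings_long"],
            row.names = FALSE)
  write_rwl(dataset$tree_set$rings_observed, paths["rwl"])
  truth <- list(seed = dataset$seed,
                standardization = dataset$standardization,
                annual_targets = dataset$truth_annual,
                missing_rings = dataset$tree_set$truth$missing)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
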