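#' Site configuration for the synthetic generator
#'
#' Describes one treeline site: its monthly climate normals, interannual
#' dispersion, and how many trees to simulate. The three default sites
#' emulate contrasting boreal treeline regimes: one warm and dry
#' (drought-limited), one cold and dry, one cold and moist (both
#' temperature-limited).
#'
#' @param site_id character label, e.g. `"W-D"`.
#' @param monthly_temp_means 12 monthly mean temperatures, degC (Jan..Dec).
#' @param monthly_precip_means 12 monthly precipitation sums, mm.
#' @param temp_sd interannual SD of monthly temperature, degC.
#' @param precip_cv interannual coefficient of variation of monthly
#'   precipitation (draws are truncated at 0).
#' @param n_trees number of trees to simulate at this site.
#' @param reference logical; exactly one site acts as the model reference
#'   level for the site factor.
#' @return an object of class `site_config`.
#' @export
site_config <- function(site_id, monthly_temp_means, monthly_precip_means,
                        temp_sd = 1.2, precip_cv = 0.35, n_trees = 6,
                        reference = FALSE) {
  stopifnot(length(monthly_temp_means) == 12L,
            length(monthly_precip_means) == 12L,
            all(monthly_precip_means >= 0),
            temp_sd >= 0, precip_cv >= 0)
  if (n_trees <= 0) stop("n_trees must be positive", call. = FALSE)
  structure(list(site_id = as.character(site_id),
                 monthly_temp_means = as.numeric(monthly_temp_means),
                 monthly_precip_means = as.numeric(monthly_precip_means),
                 temp_sd = temp_sd, precip_cv = precip_cv,
                 n_trees = as.integer(n_trees),
                 reference = isTRUE(reference)),
            class = "site_config")
}

#' Default synthetic study sites
#'
#' Three sites with contrasting climates: `W-D` (warm-dry, the reference
#' level), `C-D` (cold-dry) and `C-M` (cold-moist). Monthly normals are
#' stylized continental boreal seasonal cycles: strongly continental
#' temperature at the dry sites, higher precipitation at the moist site,
#' all summer-peaked.
#'
#' @param n_trees trees per site (default 6, i.e. 18 trees in total).
#' @return named list of three [site_config()] objects.
#' @export
default_sites <- function(n_trees = 6) {
  mon <- 1:12
  seasonal <- function(mean_t, amp) mean_t - amp * cos(2 * pi * (mon - 1) / 12)
  list(
    `W-D` = site_config("W-D",
      monthly_temp_means = seasonal(-2.5, 19),
      monthly_precip_means = c(15, 11, 9, 8, 15, 35, 50, 45, 30, 25, 20, 15),
      temp_sd = 1.3, precip_cv = 0.4, n_trees = n_trees, reference = TRUE),
    `C-D` = site_config("C-D",
      monthly_temp_means = seasonal(-7.5, 18.5),
      monthly_precip_means = c(12, 10, 10, 8, 14, 30, 45, 40, 32, 24, 15, 12),
      temp_sd = 1.5, precip_cv = 0.4, n_trees = n_trees),
    `C-M` = site_config("C-M",
      monthly_temp_means = seasonal(-3.0, 14.5),
      monthly_precip_means = c(30, 25, 20, 18, 35, 65, 90, 85, 70, 60, 55, 45),
      temp_sd = 1.2, precip_cv = 0.3, n_trees = n_trees)
  )
}

#' Weibull height-diameter parameters used by the generator
#'
#' Height follows `h = h_max * exp(a * DBH^b)`. A curve that rises from 0
#' toward the asymptote `h_max` needs `a < 0` together with `b < 0` (the
#' exponent then decays to 0 as DBH grows). Defaults give a
#' faster-growing, taller-at-equal-diameter warm-dry site and two similar
#' cold sites.
#'
#' @return named list (per site) of lists with `h_max` (m), `a`, `b`.
#' @export
default_allometries <- function() {
  list(`W-D` = list(h_max = 18, a = -4.2, b = -0.70),
       `C-D` = list(h_max = 12, a = -3.6, b = -0.75),
       `C-M` = list(h_max = 14, a = -3.8, b = -0.72))
}

#' Names of the eight seasonal climate predictors
#'
#' Four seasons (previous fall, previous winter, spring, summer) by two
#' variables (mean temperature, precipitation sum), in the column order
#' used throughout the package.
#'
#' @return character vector of length 8.
#' @export
seasonal_predictors <- function() {
  c("temp_prev_fall", "temp_prev_winter", "temp_spring", "temp_summer",
    "prcp_prev_fall", "prcp_prev_winter", "prcp_spring", "prcp_summer")
}

#' Ground-truth linear predictor for one trait and ring portion
#'
#' Defines, on the model scale (natural log for TB2 and CWT), the annual
#' earlywood/latewood mean of a trait as
#' `intercept + site offset + bh*z(h) + bh2*z(h^2) + sum(bc*z(climate))
#'  + site-specific climate effects + per-tree random effects + AR1 noise`.
#' Heights and seasonal predictors enter standardized, so coefficients are
#' per standard deviation of the predictor.
#'
#' @param trait one of `"la"`, `"tb2"`, `"den"`, `"cwt"`.
#' @param portion `"ew"` or `"lw"`.
#' @param intercept grand mean on the model scale (log scale for TB2, CWT).
#' @param beta_height,beta_height2 height and squared-height coefficients.
#' @param beta_climate named length-8 vector over [seasonal_predictors()].
#' @param beta_climate_site 2 x 8 matrix (rows `C-D`, `C-M`) of
#'   site-specific climate coefficients added on top of `beta_climate`;
#'   defaults to zero.
#' @param site_offsets named length-2 vector (`C-D`, `C-M`) of level shifts
#'   versus the reference site.
#' @param re_sd length-3 vector of random-effect SDs (intercept, h, h2),
#'   diagonal covariance.
#' @param phi AR1 coefficient of the within-tree residual series, |phi| < 1.
#' @param sigma residual (innovation-marginal) SD on the model scale.
#' @param sigma_tree_cv dispersion of per-tree residual scale multipliers
#'   (lognormal CV; 0 = homoscedastic trees).
#' @return object of class `trait_truth`.
#' @export
trait_truth <- function(trait, portion, intercept,
                        beta_height = 0, beta_height2 = 0,
                        beta_climate = NULL, beta_climate_site = NULL,
                        site_offsets = c(`C-D` = 0, `C-M` = 0),
                        re_sd = c(0, 0, 0), phi = 0, sigma = 0,
                        sigma_tree_cv = 0) {
  trait <- match.arg(trait, c("la", "tb2", "den", "cwt"))
  portion <- match.arg(portion, c("ew", "lw"))
  preds <- seasonal_predictors()
  bc <- setNames(numeric(8), preds)
  if (!is.null(beta_climate)) bc[names(beta_climate)] <- beta_climate
  bcs <- matrix(0, 2, 8, dimnames = list(c("C-D", "C-M"), preds))
  if (!is.null(beta_climate_site)) {
    bcs[rownames(beta_climate_site), colnames(beta_climate_site)] <-
      beta_climate_site
  }
  if (abs(phi) >= 1) stop("phi must lie in (-1, 1)", call. = FALSE)
  stopifnot(all(re_sd >= 0), sigma >= 0, sigma_tree_cv >= 0)
  structure(list(trait = trait, portion = portion,
                 log_scale = trait %in% c("tb2", "cwt"),
                 intercept = intercept,
                 beta_height = beta_height, beta_height2 = beta_height2,
                 beta_climate = bc, beta_climate_site = bcs,
                 site_offsets = site_offsets,
                 re_sd = re_sd, phi = phi, sigma = sigma,
                 sigma_tree_cv = sigma_tree_cv),
            class = "trait_truth")
}

#' Default ground truth encoding the headline effect pattern
#'
#' Hydraulic traits (LA, TB2) respond to tree height, strongest in the
#' earlywood: height increases lumen area and decreases conduit
#' reinforcement. Structural traits (CWT, DEN) respond to temperature,
#' strongest in the latewood at the cold sites (via site-specific summer
#' temperature effects), with a weaker spring-temperature response at the
#' warm-dry reference site.
#'
#' @return named list of 8 [trait_truth()] objects, keyed `la_ew` ... `cwt_lw`.
#' @export
default_truth <- function() {
  cold <- rbind(`C-D` = c(temp_summer = 1), `C-M` = c(temp_summer = 1))
  out <- list(
    la_ew = trait_truth("la", "ew", intercept = 600,
      beta_height = 60, beta_height2 = -8,
      beta_climate = c(temp_summer = 12),
      site_offsets = c(`C-D` = 25, `C-M` = 40),
      re_sd = c(30, 10, 4), phi = 0.4, sigma = 40, sigma_tree_cv = 0.2),
    la_lw = trait_truth("la", "lw", intercept = 150,
      beta_height = 15, beta_height2 = -2,
      beta_climate = c(prcp_prev_winter = 4, prcp_spring = 4),
      site_offsets = c(`C-D` = 6, `C-M` = 10),
      re_sd = c(8, 3, 1), phi = 0.4, sigma = 12, sigma_tree_cv = 0.2),
    tb2_ew = trait_truth("tb2", "ew", intercept = log(0.04),
      beta_height = -0.22, beta_height2 = 0.03,
      beta_climate = c(prcp_summer = -0.04),
      beta_climate_site = 0.05 * cold,
      re_sd = c(0.10, 0.04, 0.015), phi = 0.35, sigma = 0.12,
      sigma_tree_cv = 0.2),
    tb2_lw = trait_truth("tb2", "lw", intercept = log(0.25),
      beta_height = -0.10, beta_height2 = 0.015,
      beta_climate = c(prcp_summer = -0.03),
      beta_climate_site = 0.04 * cold,
      re_sd = c(0.08, 0.03, 0.01), phi = 0.35, sigma = 0.10,
      sigma_tree_cv = 0.2),
    den_ew = trait_truth("den", "ew", intercept = 0.30,
      beta_height = 0.004, beta_climate = c(temp_summer = -0.006),
      site_offsets = c(`C-D` = -0.015, `C-M` = -0.010),
      re_sd = c(0.015, 0.005, 0.002), phi = 0.3, sigma = 0.018,
      sigma_tree_cv = 0.15),
    den_lw = trait_truth("den", "lw", intercept = 0.62,
      beta_height = -0.006,
      beta_climate = c(temp_spring = 0.004),
      beta_climate_site = 0.015 * cold,
      re_sd = c(0.02, 0.006, 0.002), phi = 0.3, sigma = 0.02,
      sigma_tree_cv = 0.15),
    cwt_ew = trait_truth("cwt", "ew", intercept = log(2.8),
      beta_height = 0.04,
      beta_climate = c(temp_spring = 0.02),
      re_sd = c(0.05, 0.02, 0.008), phi = 0.3, sigma = 0.06,
      sigma_tree_cv = 0.15),
    cwt_lw = trait_truth("cwt", "lw", intercept = log(5.5),
      beta_height = 0.015,
      beta_climate = c(temp_spring = 0.04, prcp_summer = -0.03),
      beta_climate_site = 0.12 * cold,
      re_sd = c(0.06, 0.02, 0.008), phi = 0.35, sigma = 0.08,
      sigma_tree_cv = 0.15)
  )
  out
}

#' Within-ring cell geometry profile
#'
#' Controls how individual tracheids are laid out across a ring. Lumen
#' diameter shrinks and the wall-to-lumen ratio grows monotonically from
#' ring start to ring end; the Mork ratio (4 x radial wall / radial lumen
#' diameter) crosses 1 exactly at `ew_fraction` of the ring, so the
#' earlywood/latewood labels implied by the geometry are recoverable by a
#' Mork classifier.
#'
#' @param cells_per_ring tracheids per ring.
#' @param ew_fraction proportion of the ring that is earlywood, in (0, 1).
#' @param ld_start,ld_end radial lumen diameter (um) at ring start/end of
#'   the *shape* profile (rescaled to hit the annual trait targets).
#' @param mork_start Mork ratio at ring start (< 1).
#' @param noise_cv multiplicative within-ring sampling noise (lognormal CV)
#'   applied independently per cell and trait; 0 gives exact annual means.
#' @return object of class `cell_geometry_profile`.
#' @export
cell_geometry_profile <- function(cells_per_ring = 40, ew_fraction = 0.6,
                                  ld_start = 30, ld_end = 12,
                                  mork_start = 0.28, noise_cv = 0.1) {
  stopifnot(cells_per_ring >= 2, ew_fraction > 0, ew_fraction < 1,
            ld_start > ld_end, ld_end > 0,
            mork_start > 0, mork_start < 1, noise_cv >= 0)
  structure(list(cells_per_ring = as.integer(cells_per_ring),
                 ew_fraction = ew_fraction,
                 ld_start = ld_start, ld_end = ld_end,
                 mork_start = mork_start, noise_cv = noise_cv),
            class = "cell_geometry_profile")
}

# positions and monotone shape curves of a profile, used by generate_cells()
profile_curves <- function(profile) {
  n <- profile$cells_per_ring
  pos <- (seq_len(n) - 0.5) / n
  rate <- log(1 / profile$mork_start) / profile$ew_fraction
  mork <- profile$mork_start * exp(rate * pos)
  ld <- profile$ld_start + (profile$ld_end - profile$ld_start) * pos
  list(pos = pos, mork = mork, ld = ld,
       la_shape = ld^2,                 # lumen area falls across the ring
       cwt_shape = mork * ld,           # wall thickness rises (rate > decay)
       den_shape = 0.85 + 0.3 * pos,    # density rises gently
       tb2_shape = 0.75 + 0.5 * pos)    # reinforcement rises gently
}
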