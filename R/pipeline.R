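#' Validate a pipeline run configuration
#'
#' A configuration (R list or YAML file) must name either the four input
#' tables (`inputs: cells, rings, climate, trees`) or a `synthetic` block
#' (generator settings), not neither. Optional fields: `traits` (list of
#' `"<trait>_<portion>"` strings, default all 8), `model` (options passed
#' to [xylem_model_spec()]), `out_dir`, `seed`.
#'
#' @param config list or path to a YAML file.
#' @return the validated config (with defaults filled in).
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path", call. = FALSE)
  has_inputs <- !is.null(config$inputs)
  has_synth <- !is.null(config$synthetic)
  if (!has_inputs && !has_synth) {
    stop("config must contain either 'inputs' or 'synthetic'", call. = FALSE)
  }
  if (has_inputs) {
    need <- c("cells", "rings", "climate", "trees")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss) > 0L) {
      stop(sprintf("config$inputs is missing field(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) config$out_dir <- "xylemclim_run"
  if (is.null(config$traits)) {
    config$traits <- as.vector(outer(c("la", "tb2", "den", "cwt"),
                                     c("ew", "lw"), paste, sep = "_"))
  }
  bad <- !grepl("^(la|tb2|den|cwt)_(ew|lw)$", unlist(config$traits))
  if (any(bad)) {
    stop(sprintf("invalid trait spec(s): %s",
                 paste(unlist(config$traits)[bad], collapse = ", ")),
         call. = FALSE)
  }
  config
}

read_pipeline_inputs <- function(config) {
  if (!is.null(config$inputs)) {
    rings_path <- config$inputs$rings
    rings <- if (grepl("\\.rwl$", rings_path, ignore.case = TRUE)) {
      read_rwl(rings_path)
    } else {
      read_rings_csv(rings_path)
    }
    list(cells = read.csv(config$inputs$cells, stringsAsFactors = FALSE),
         rings = rings,
         climate = read.csv(config$inputs$climate, stringsAsFactors = FALSE),
         trees = read.csv(config$inputs$trees, stringsAsFactors = FALSE),
         truth = NULL)
  } else {
    syn <- config$synthetic
    args <- list(seed = if (is.null(syn$seed)) config$seed else syn$seed)
    if (!is.null(syn$n_trees)) args$sites <- default_sites(syn$n_trees)
    if (!is.null(syn$age_mean)) args$age_mean <- syn$age_mean
    if (!is.null(syn$sampling_year)) args$sampling_year <- syn$sampling_year
    ds <- do.call(generate_dataset, args)
    cells <- ds$cells
    cells$true_portion <- NULL
    list(cells = cells, rings = ds$tree_set$rings_observed,
         climate = ds$climate, trees = ds$tree_set$trees, truth = ds)
  }
}

#' Run the full pipeline: reconstruct, derive, aggregate, fit, predict
#'
#' Stages: height/DBH reconstruction from ring widths, Mork-classified
#' earlywood/latewood trait chronologies from the cell table, seasonal
#' climate aggregation, one REML mixed model per requested trait x
#' portion, Tukey site contrasts and the two counterfactual prediction
#' experiments (height held at its mean; summer temperature held at its
#' mean). All artifacts are written under `config$out_dir` together with
#' a markdown report and a star-coded coefficient matrix.
#'
#' @param config run configuration (list or YAML path), see
#'   [validate_run_config()].
#' @return invisibly, a list with `heights`, `chronology`, `seasonal`,
#'   `fits`, `contrasts`, `predictions`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- read_pipeline_inputs(config)

  heights <- reconstruct_heights(inputs$rings, inputs$trees)
  write.csv(heights, file.path(out_dir, "heights.csv"), row.names = FALSE)

  chronology <- build_chronology(inputs$cells)
  write.csv(chronology, file.path(out_dir, "chronology.csv"),
            row.names = FALSE)

  seasonal <- suppressWarnings(aggregate_seasons(inputs$climate))
  write.csv(seasonal, file.path(out_dir, "seasonal.csv"), row.names = FALSE)

  model_opts <- if (is.null(config$model)) list() else config$model
  fits <- list(); contrasts <- list(); predictions <- list()
  tables <- list()
  for (tp in unlist(config$traits)) {
    parts <- strsplit(tp, "_")[[1]]
    spec <- do.call(xylem_model_spec,
                    c(list(trait = parts[1], portion = parts[2]), model_opts))
    md <- build_model_data(chronology, heights, seasonal, inputs$trees,
                           parts[1], parts[2])
    std <- standardize(md, spec)
    fit <- fit_reml(std$data, spec, record = std$record)
    fits[[tp]] <- fit
    ct <- site_contrasts(fit)
    contrasts[[tp]] <- ct
    pred_h <- counterfactual_predict(fit, "height")
    pred_t <- counterfactual_predict(fit, "summer_temperature")
    predictions[[tp]] <- data.frame(
      pred_h[, c("tree_id", "year", "site", "observed", "fitted")],
      predicted_height_held = pred_h$predicted,
      predicted_summer_temp_held = pred_t$predicted)
    tab <- coef_table(fit)
    tab$model <- tp
    tables[[tp]] <- tab
    jsonlite::write_json(
      list(model = tp, seed = config$seed,
           coefficients = tab,
           sigma = fit$sigma, sd_re = fit$sd_re, phi = fit$phi,
           tree_weights = as.list(fit$tree_weights),
           logLik = fit$logLik, boundary = fit$boundary),
      file.path(out_dir, paste0("fit_", tp, ".json")),
      auto_unbox = TRUE, digits = NA)
    write.csv(ct$contrasts, file.path(out_dir, paste0("contrasts_", tp, ".csv")),
              row.names = FALSE)
    write.csv(predictions[[tp]],
              file.path(out_dir, paste0("predictions_", tp, ".csv")),
              row.names = FALSE)
  }
  all_tab <- do.call(rbind, tables)
  write.csv(all_tab, file.path(out_dir, "table1.csv"), row.names = FALSE)

  write_run_report(config, inputs, fits, contrasts, out_dir)
  invisible(list(heights = heights, chronology = chronology,
                 seasonal = seasonal, fits = fits, contrasts = contrasts,
                 predictions = predictions, out_dir = out_dir))
}

# markdown report with a star-coded coefficient matrix and simple figures
write_run_report <- function(config, inputs, fits, contrasts, out_dir) {
  lines <- c("# xylemclim run report", "",
             sprintf("- seed: %s", config$seed),
             sprintf("- models: %s", paste(names(fits), collapse = ", ")),
             sprintf("- observations per model: %s",
                     paste(vapply(fits, function(f) f$n_obs, numeric(1)),
                           collapse = ", ")), "")
  terms <- names(fits[[1]]$coefficients)
  mat <- sapply(fits, function(f) {
    sprintf("%+.2f%s", f$coefficients, significance_stars(f$p_value))
  })
  lines <- c(lines, "## Coefficient matrix (star-coded)", "",
             paste0("| term | ", paste(names(fits), collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(fits) + 1L), collapse = "|"),
                    "|"),
             vapply(seq_along(terms), function(i) {
               paste0("| ", terms[i], " | ",
                      paste(mat[i, ], collapse = " | "), " |")
             }, character(1)), "")
  lines <- c(lines, "## Site contrasts", "")
  for (nm in names(contrasts)) {
    m <- contrasts[[nm]]$means
    lines <- c(lines, sprintf("- %s: %s", nm,
                              paste(sprintf("%s %.3f (%s)", m$site, m$emmean,
                                            m$letters), collapse = ", ")))
  }
  writeLines(lines, file.path(out_dir, "report.md"))

  # diameter-height trajectories per site (analogue of the allometry figure)
  ok <- tryCatch({
    grDevices::pdf(file.path(out_dir, "trajectories.pdf"), width = 6,
                   height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    trees <- inputs$trees
    plot(trees$dbh_cm, trees$height_m, xlab = "DBH (cm)",
         ylab = "height (m)", pch = 19,
         col = as.integer(factor(trees$site)))
    for (s in unique(trees$site)) {
      sub <- trees[trees$site == s, ]
      if (nrow(sub) >= 4 && length(unique(sub$dbh_cm)) >= 4) {
        al <- tryCatch(fit_weibull(sub$dbh_cm, sub$height_m, site_id = s),
                       error = function(e) NULL)
        if (!is.null(al)) {
          dd <- seq(0.5, max(sub$dbh_cm) * 1.2, length.out = 100)
          graphics::lines(dd, predict(al, dd),
                          col = as.integer(factor(s, unique(trees$site))))
        }
      }
    }
    TRUE
  }, error = function(e) FALSE)
  invisible(ok)
}

#' Repeated generate-and-refit study of the mixed-model estimator
#'
#' Draws `n_replicates` synthetic datasets at the annual-mean level (the
#' level where the ground truth lives), refits the trait model on each,
#' and summarizes per-coefficient bias, RMSE, Wald confidence-interval
#' coverage and rejection rate.
#'
#' @param truth trait ground truth, as [default_truth()].
#' @param trait,portion which response to study.
#' @param n_replicates number of replicates (>= 2).
#' @param seed master seed; each replicate derives its own substream.
#' @param n_trees trees per site.
#' @param age_mean mean ring count per tree.
#' @param n_starts optimizer starting points per fit (default 2; the
#'   profiled objective is well-conditioned at this design size).
#' @param conf_level coverage level of the Wald intervals.
#' @return list with `summary` (per-term truth, mean estimate, bias, RMSE,
#'   coverage, rejection rate) and `estimates` / `p_values` matrices
#'   (replicates x terms).
#' @export
parameter_recovery_study <- function(truth = default_truth(),
                                     trait = "la", portion = "ew",
                                     n_replicates = 50, seed = 1,
                                     n_trees = 6, age_mean = 80,
                                     n_starts = 2, conf_level = 0.95) {
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  tt <- truth[[paste(trait, portion, sep = "_")]]
  if (is.null(tt)) stop("truth does not cover the requested trait/portion",
                        call. = FALSE)
  spec <- xylem_model_spec(trait, portion, log_transform = FALSE,
                           standardize_response = FALSE)
  seeds <- derive_seeds(seed, n_replicates)
  est <- pv <- cov <- NULL
  truth_vec <- NULL
  for (r in seq_len(n_replicates)) {
    sub <- derive_seeds(seeds[r], 2L + 3L)
    sites <- default_sites(n_trees)
    sampling_year <- 2015
    year_min <- sampling_year - as.integer(age_mean) - 20L
    climate <- generate_climate(sites, (year_min - 1L):sampling_year, sub[1])
    allom <- default_allometries()
    sets <- lapply(seq_along(sites), function(i) {
      generate_trees(sites[[i]], allom[[sites[[i]]$site_id]],
                     seed = sub[1L + i], sampling_year = sampling_year,
                     age_mean = age_mean)
    })
    tree_set <- combine_tree_sets(sets)
    ann <- generate_annual_traits(truth[paste(trait, portion, sep = "_")],
                                  tree_set, climate, sub[5])
    df <- ann$frame
    tg <- ann$targets
    df$y <- tg$value_model[match(paste(df$tree_id, df$year),
                                 paste(tg$tree_id, tg$year))]
    df$site <- factor(df$site, levels = c("W-D", "C-D", "C-M"))
    fit <- fit_reml(df, spec, n_starts = n_starts)
    if (is.null(truth_vec)) {
      truth_vec <- truth_coefficients(tt, names(fit$coefficients))
      est <- pv <- cov <- matrix(NA_real_, n_replicates, length(truth_vec),
                                 dimnames = list(NULL, names(truth_vec)))
    }
    est[r, ] <- fit$coefficients
    pv[r, ] <- fit$p_value
    crit <- stats::qt(1 - (1 - conf_level) / 2, fit$df)
    cov[r, ] <- as.numeric(abs(fit$coefficients - truth_vec) <=
                             crit * fit$se)
  }
  summary <- data.frame(
    term = names(truth_vec), truth = unname(truth_vec),
    mean_estimate = colMeans(est),
    bias = colMeans(est) - truth_vec,
    mc_se = apply(est, 2, sd) / sqrt(n_replicates),
    rmse = sqrt(colMeans(sweep(est, 2, truth_vec)^2)),
    coverage = colMeans(cov),
    rejection_rate = colMeans(pv < 0.05),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(summary = summary, estimates = est, p_values = pv)
}

# expand a trait_truth into the 29-coefficient vector of the fitted model
truth_coefficients <- function(tt, term_names) {
  preds <- seasonal_predictors()
  out <- setNames(numeric(length(term_names)), term_names)
  out["(Intercept)"] <- tt$intercept
  for (s in c("C-D", "C-M")) {
    nm <- paste0("site", s)
    if (nm %in% term_names) out[nm] <- tt$site_offsets[s]
  }
  out["h"] <- tt$beta_height
  out["h2"] <- tt$beta_height2
  for (p in preds) {
    out[p] <- tt$beta_climate[p]
    for (s in c("C-D", "C-M")) {
      nm <- paste0("site", s, ":", p)
      if (nm %in% term_names) out[nm] <- tt$beta_climate_site[s, p]
    }
  }
  out
}
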