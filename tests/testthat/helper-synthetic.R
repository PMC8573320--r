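# Small synthetic setups shared across test files.

# reduced-size full study (cells included); ~2 trees/site x ~30 rings
tiny_dataset <- function(seed = 11, n_trees = 2, age_mean = 30,
                         profile = cell_geometry_profile(cells_per_ring = 20),
                         truth = default_truth()) {
  generate_dataset(sites = default_sites(n_trees), truth = truth,
                   profile = profile, seed = seed, age_mean = age_mean)
}

# annual-level data for one trait/portion, returning a ready model frame
annual_model_frame <- function(truth_one, seed = 5, n_trees = 6,
                               age_mean = 80, age_jitter = 8,
                               missing_prob = 0) {
  sites <- default_sites(n_trees)
  allom <- default_allometries()
  seeds <- xylemclim:::derive_seeds(seed, 2L + length(sites))
  sampling_year <- 2015
  year_min <- sampling_year - as.integer(age_mean) - 20L
  climate <- generate_climate(sites, (year_min - 1L):sampling_year, seeds[1])
  sets <- lapply(seq_along(sites), function(i) {
    generate_trees(sites[[i]], allom[[sites[[i]]$site_id]],
                   seed = seeds[1L + i], sampling_year = sampling_year,
                   age_mean = age_mean, age_jitter = age_jitter,
                   missing_prob = missing_prob)
  })
  tree_set <- xylemclim:::combine_tree_sets(sets)
  ann <- generate_annual_traits(truth_one, tree_set, climate,
                                seeds[length(seeds)])
  df <- ann$frame
  tg <- ann$targets
  df$y <- tg$value_model[match(paste(df$tree_id, df$year),
                               paste(tg$tree_id, tg$year))]
  df$site <- factor(df$site, levels = c("W-D", "C-D", "C-M"))
  list(data = df, annual = ann, tree_set = tree_set, climate = climate)
}
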