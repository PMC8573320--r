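# Independent brute-force oracles used throughout the suite. These are
# deliberately naive re-implementations (dense matrices, explicit loops)
# kept separate from the package's computational paths.

# Restricted log-likelihood via an explicitly assembled N x N covariance
# and generic solve()/determinant() calls (fixed effects and residual
# variance profiled out the same way the model defines them).
dense_reml_oracle <- function(data, spec, theta) {
  data <- data[order(data$tree_id, data$year), ]
  X <- model.matrix(xylemclim:::spec_formula(spec), data)
  trees <- unique(data$tree_id)
  m <- length(trees)
  q <- if (spec$include_re) 3L else 0L
  sd_re <- if (q > 0) exp(theta[seq_len(q)]) else numeric(0)
  i <- q
  phi <- 0
  if (spec$include_ar1) {
    phi <- tanh(theta[i + 1])
    i <- i + 1
  }
  wts <- rep(1, m)
  if (spec$include_weights) wts[-1] <- exp(theta[i + seq_len(m - 1)])
  N <- nrow(X)
  Lam <- matrix(0, N, N)
  for (k in seq_along(trees)) {
    idx <- which(data$tree_id == trees[k])
    ti <- data$year[idx]
    R <- outer(ti, ti, function(a, b) ifelse(a == b, 1, phi^abs(a - b)))
    V <- wts[k]^2 * R
    if (q > 0) {
      Zi <- cbind(1, data$h[idx], data$h2[idx])
      V <- V + Zi %*% diag(sd_re^2) %*% t(Zi)
    }
    Lam[idx, idx] <- V
  }
  y <- data$y
  p <- ncol(X)
  Li <- solve(Lam)
  XtLiX <- t(X) %*% Li %*% X
  beta <- solve(XtLiX, t(X) %*% Li %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Li %*% r)
  sig2 <- rss / (N - p)
  as.numeric(-0.5 * ((N - p) * log(2 * pi) + (N - p) * log(sig2) +
                       (N - p) + determinant(Lam)$modulus +
                       determinant(XtLiX)$modulus))
}

# GLS fixed effects for a given full covariance matrix (closed form)
gls_oracle <- function(y, X, V) {
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}

# windowed-mean imputation by explicit scanning
impute_oracle <- function(rw, window = 10L) {
  out <- rw
  for (i in which(is.na(rw))) {
    before <- c(); after <- c()
    j <- i - 1L
    while (j >= 1L && length(before) < window) {
      if (!is.na(rw[j])) before <- c(before, rw[j])
      j <- j - 1L
    }
    j <- i + 1L
    while (j <= length(rw) && length(after) < window) {
      if (!is.na(rw[j])) after <- c(after, rw[j])
      j <- j + 1L
    }
    out[i] <- mean(c(before, after))
  }
  out
}

# per-cell trait re-implementation, one cell at a time
cell_traits_oracle <- function(cell) {
  mi <- 4 * cell$cwt_rad_um / cell$ld_rad_um
  portion <- if (mi >= 1) "lw" else "ew"
  if (cell$cwt_rad_um <= cell$cwt_tan_um) {
    tb2 <- (2 * cell$cwt_rad_um / cell$wall_len_rad_um)^2
  } else {
    tb2 <- (2 * cell$cwt_tan_um / cell$wall_len_tan_um)^2
  }
  den <- cell$cwa_um2 / (cell$cwa_um2 + cell$la_um2)
  cwt <- (cell$cwt_rad_um + cell$cwt_tan_um) / 2
  list(mork = mi, portion = portion, tb2 = tb2, den = den, cwt = cwt)
}

# seasonal aggregation by explicit month picking
seasons_oracle <- function(monthly, site, ring_year, precip_stat = "sum") {
  pick <- function(yr, mo) {
    r <- monthly[monthly$site == site & monthly$year == yr &
                   monthly$month == mo, ]
    if (nrow(r) != 1L) stop("month missing")
    r
  }
  months <- list(
    prev_fall = Map(pick, ring_year - 1, 9:11),
    prev_winter = Map(pick, c(ring_year - 1, ring_year, ring_year),
                      c(12, 1, 2)),
    spring = Map(pick, rep(ring_year, 3), 3:5),
    summer = Map(pick, rep(ring_year, 3), 6:8))
  out <- list()
  for (nm in names(months)) {
    tm <- vapply(months[[nm]], function(r) r$tmean_c, numeric(1))
    pr <- vapply(months[[nm]], function(r) r$prcp_mm, numeric(1))
    out[[paste0("temp_", nm)]] <- mean(tm)
    out[[paste0("prcp_", nm)]] <- if (precip_stat == "sum") sum(pr) else
      mean(pr)
  }
  out
}

# random small mixed-model dataset with pure-noise response
random_small_lmm <- function(seed, n_tree = 5, n_yr = 8) {
  set.seed(seed)
  df <- expand.grid(year = 2001:(2000 + n_yr),
                    tree_id = sprintf("T%02d", seq_len(n_tree)),
                    stringsAsFactors = FALSE)
  df$site <- factor(rep_len(c("W-D", "C-D", "C-M"), n_tree)[
    match(df$tree_id, unique(df$tree_id))],
    levels = c("W-D", "C-D", "C-M"))
  df$h <- rnorm(nrow(df))
  df$h2 <- rnorm(nrow(df))
  df$temp_summer <- rnorm(nrow(df))
  df$y <- rnorm(nrow(df))
  df
}

small_spec <- function(...) {
  xylem_model_spec("la", "ew", log_transform = FALSE,
                   standardize_response = FALSE,
                   fixed = ~ site + h + h2 + temp_summer, ...)
}
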