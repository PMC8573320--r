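#' Tukey-adjusted pairwise site contrasts
#'
#' Marginal means per site are evaluated at the mean (i.e. zero) of every
#' standardized covariate, so the site x climate interaction terms drop
#' out and each site mean is `intercept + site offset`. Pairwise
#' differences use the fixed-effect covariance; p-values are adjusted with
#' the studentized-range distribution at the fit's between-tree degrees of
#' freedom, and a compact letter display summarizes the decisions.
#'
#' @param fit a `xylem_lmm`.
#' @param alpha significance level for the letter display (default 0.05).
#' @return list with `means` (site, emmean, se, letters) and `contrasts`
#'   (pair, estimate, se, t, df, p_adj).
#' @export
site_contrasts <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "xylem_lmm"))
  beta <- fit$coefficients
  V <- fit$vcov
  sites <- levels(fit$data$site)
  k <- length(sites)
  p <- length(beta)
  Lm <- matrix(0, k, p, dimnames = list(sites, names(beta)))
  Lm[, "(Intercept)"] <- 1
  for (s in sites[-1]) {
    col <- paste0("site", s)
    if (!col %in% names(beta)) {
      stop(sprintf("site coefficient '%s' not found", col), call. = FALSE)
    }
    Lm[s, col] <- 1
  }
  means <- drop(Lm %*% beta)
  se_means <- sqrt(diag(Lm %*% V %*% t(Lm)))

  pairs <- utils::combn(sites, 2)
  df <- fit$df_outer
  res <- data.frame(pair = apply(pairs, 2, paste, collapse = " - "),
                    estimate = NA_real_, se = NA_real_, t = NA_real_,
                    df = df, p_adj = NA_real_, stringsAsFactors = FALSE)
  sig <- matrix(FALSE, k, k, dimnames = list(sites, sites))
  for (j in seq_len(ncol(pairs))) {
    L <- Lm[pairs[1, j], ] - Lm[pairs[2, j], ]
    est <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    tval <- est / se
    padj <- ptukey(sqrt(2) * abs(tval), nmeans = k, df = df,
                   lower.tail = FALSE)
    res$estimate[j] <- est; res$se[j] <- se; res$t[j] <- tval
    res$p_adj[j] <- padj
    if (padj < alpha) {
      sig[pairs[1, j], pairs[2, j]] <- sig[pairs[2, j], pairs[1, j]] <- TRUE
    }
  }
  letters_vec <- compact_letters(sig, order(means))
  list(means = data.frame(site = sites, emmean = means, se = se_means,
                          letters = letters_vec, stringsAsFactors = FALSE),
       contrasts = res)
}

# insert-and-absorb compact letter display: groups sharing a letter are
# not significantly different
compact_letters <- function(sig, ord) {
  k <- nrow(sig)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      for (s in seq_along(sets)) {
        if (all(c(i, j) %in% sets[[s]])) {
          a <- setdiff(sets[[s]], i)
          b <- setdiff(sets[[s]], j)
          sets[[s]] <- a
          sets[[length(sets) + 1L]] <- b
        }
      }
      # absorb subsets
      keep <- rep(TRUE, length(sets))
      for (s in seq_along(sets)) {
        for (s2 in seq_along(sets)) {
          if (s != s2 && keep[s] && keep[s2] &&
                all(sets[[s]] %in% sets[[s2]])) {
            keep[s] <- FALSE
          }
        }
      }
      sets <- sets[keep]
    }
  }
  # order letter sets by the smallest mean they contain
  first <- vapply(sets, function(s) min(match(s, ord)), numeric(1))
  sets <- sets[order(first)]
  out <- character(k)
  for (s in seq_along(sets)) {
    for (g in sets[[s]]) out[g] <- paste0(out[g], letters[s])
  }
  out
}

#' Wald test of a linear combination of fixed effects
#'
#' Estimates `sum(L * beta)` with its standard error from the
#' fixed-effect covariance, e.g. the summer-temperature effect at a
#' non-reference site (main effect plus interaction).
#'
#' @param fit a `xylem_lmm`.
#' @param L named numeric vector of weights over coefficient names
#'   (unnamed terms get weight 0).
#' @return one-row data.frame with `estimate`, `se`, `t`, `df`, `p`.
#' @export
linear_combination <- function(fit, L) {
  stopifnot(inherits(fit, "xylem_lmm"))
  w <- setNames(numeric(length(fit$coefficients)), names(fit$coefficients))
  bad <- setdiff(names(L), names(w))
  if (length(bad) > 0L) {
    stop(sprintf("unknown coefficient(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  w[names(L)] <- L
  est <- sum(w * fit$coefficients)
  se <- sqrt(drop(t(w) %*% fit$vcov %*% w))
  df <- fit$df_inner
  tval <- est / se
  data.frame(estimate = est, se = se, t = tval, df = df,
             p = 2 * pt(abs(tval), df, lower.tail = FALSE))
}
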