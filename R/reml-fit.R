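# REML fitting of the trait mixed model. The likelihood kernel lives in
# src/reml.cpp; this file assembles design blocks, drives the optimizer on
# unconstrained transforms (log random-effect SDs, Fisher-z AR1, log
# per-tree relative SDs) and packages the fit.

fixed_formula <- function() {
  preds <- seasonal_predictors()
  stats::as.formula(paste("~ site +", paste(preds, collapse = " + "),
                          "+ h + h2 +",
                          paste(paste0("site:", preds), collapse = " + ")))
}

spec_formula <- function(spec) {
  if (is.null(spec$fixed)) fixed_formula() else spec$fixed
}

# split standardized data into per-tree blocks ordered by year
reml_blocks <- function(data, spec) {
  data <- data[order(data$tree_id, data$year), , drop = FALSE]
  if (anyDuplicated(data[, c("tree_id", "year")])) {
    stop("duplicate tree/year rows in model data", call. = FALSE)
  }
  X <- model.matrix(spec_formula(spec), data)
  if (qr(X)$rank < ncol(X)) {
    stop("singular fixed-effect design matrix", call. = FALSE)
  }
  trees <- unique(data$tree_id)
  q <- if (spec$include_re) 3L else 0L
  yl <- Xl <- Zl <- tl <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    idx <- which(data$tree_id == trees[i])
    yl[[i]] <- data$y[idx]
    Xl[[i]] <- X[idx, , drop = FALSE]
    Zl[[i]] <- if (q > 0) cbind(1, data$h[idx], data$h2[idx]) else
      matrix(0, length(idx), 0)
    tl[[i]] <- as.numeric(data$year[idx])
  }
  list(data = data, X = X, trees = trees, q = q,
       y_list = yl, X_list = Xl, Z_list = Zl, t_list = tl)
}

reml_objective <- function(blocks, spec) {
  function(theta) {
    reml_core(theta, blocks$y_list, blocks$X_list, blocks$Z_list,
              blocks$t_list, blocks$q, spec$include_ar1,
              spec$include_weights, FALSE)$deviance
  }
}

#' Fit the trait mixed model by restricted maximum likelihood
#'
#' Maximizes the restricted likelihood of the model described in
#' [xylem_model_spec()] over the variance parameters (3 log random-effect
#' SDs, Fisher-z AR1 coefficient, per-tree log relative SDs), with the 29
#' fixed effects and the residual variance profiled out by generalized
#' least squares at every step. Optimization starts from 5 deterministic
#' jittered points: the objective is evaluated at all of them, a bounded
#' quasi-Newton search runs from the best, and remaining starts serve as
#' fallbacks on non-convergence.
#'
#' Wald t tests use an inner-outer degrees-of-freedom heuristic:
#' within-tree terms get `N - m - p_inner` denominator df and
#' between-tree terms (intercept, site) get `m - p_outer`; set
#' `df_method = "normal"` in the spec for z tests instead.
#'
#' @param data standardized model frame (element `data` of
#'   [standardize()], or any frame with `tree_id`, `year`, `site`, `y`,
#'   `h`, `h2` and the standardized seasonal predictors).
#' @param spec a [xylem_model_spec()].
#' @param record optional `standardization_record` stored in the fit.
#' @param n_starts number of jittered starting points (default 5).
#' @return object of class `xylem_lmm`.
#' @export
fit_reml <- function(data, spec, record = NULL, n_starts = 5) {
  stopifnot(inherits(spec, "xylem_model_spec"))
  if (length(unique(data$tree_id)) < 2L) {
    stop("need at least 2 trees", call. = FALSE)
  }
  blocks <- reml_blocks(data, spec)
  m <- length(blocks$trees)
  n_per <- lengths(blocks$y_list)
  if (spec$include_ar1 && any(n_per < 3L)) {
    stop("AR1 needs at least 3 years per tree", call. = FALSE)
  }
  q <- blocks$q
  n_theta <- q + as.integer(spec$include_ar1) +
    if (spec$include_weights) m - 1L else 0L

  obj <- reml_objective(blocks, spec)
  lower <- c(rep(-8, q), if (spec$include_ar1) -5,
             rep(-4, if (spec$include_weights) m - 1L else 0L))
  upper <- c(rep(4, q), if (spec$include_ar1) 5,
             rep(4, if (spec$include_weights) m - 1L else 0L))

  base_start <- c(rep(log(0.4), q), if (spec$include_ar1) atanh(0.3),
                  rep(0, if (spec$include_weights) m - 1L else 0L))
  opt <- NULL
  if (n_theta == 0L) {
    opt <- list(par = numeric(0), value = obj(numeric(0)), convergence = 0L)
  } else {
    starts <- lapply(seq_len(max(1L, n_starts)), function(j) {
      if (j == 1L) base_start else
        base_start + 0.6 * sin(37 * j + 11 * seq_len(n_theta))
    })
    dev0 <- vapply(starts, obj, numeric(1))
    for (j in order(dev0)) {
      cand <- tryCatch(
        optim(starts[[j]], obj, method = "L-BFGS-B",
              lower = lower, upper = upper,
              control = list(maxit = 500, factr = 1e7)),
        error = function(e) NULL)
      if (!is.null(cand) && cand$convergence == 0L && cand$value < 1e9) {
        opt <- cand
        break
      }
      if (!is.null(cand) && is.null(opt) && cand$value < 1e9) opt <- cand
    }
    if (is.null(opt)) {
      stop(sprintf(
        "REML optimization failed from all %d starts (best objective %.4g)",
        length(starts), min(dev0)), call. = FALSE)
    }
  }

  full <- reml_core(opt$par, blocks$y_list, blocks$X_list, blocks$Z_list,
                    blocks$t_list, q, spec$include_ar1,
                    spec$include_weights, TRUE)
  if (!isTRUE(full$ok)) {
    stop("REML solution is numerically singular at the optimum", call. = FALSE)
  }
  beta <- drop(full$beta)
  names(beta) <- colnames(blocks$X)
  vcov_beta <- full$vcov_beta
  dimnames(vcov_beta) <- list(names(beta), names(beta))
  sigma <- sqrt(full$sigma2)
  sd_re_rel <- if (q > 0) drop(full$sd_re) else numeric(0)
  weights <- drop(full$weights)
  names(weights) <- blocks$trees

  N <- sum(n_per)
  # columns constant within every tree are "outer" (between-tree) terms
  is_outer <- vapply(seq_len(ncol(blocks$X)), function(jc) {
    all(vapply(blocks$X_list, function(Xi) {
      max(Xi[, jc]) - min(Xi[, jc]) < 1e-12
    }, logical(1)))
  }, logical(1))
  p_outer <- sum(is_outer)
  p_inner <- sum(!is_outer)
  df <- ifelse(is_outer, max(m - p_outer, 1L), max(N - m - p_inner, 1L))
  if (spec$df_method == "normal") df <- rep(Inf, length(beta))
  se <- sqrt(diag(vcov_beta))
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)

  boundary <- q > 0 && any(opt$par[seq_len(q)] <= lower[seq_len(q)] + 1e-2)

  # tree-level BLUPs and conditional fitted values
  blups <- matrix(0, m, max(q, 1L))
  fitted_marg <- fitted_cond <- numeric(N)
  pos <- 0L
  phi <- full$phi
  for (i in seq_len(m)) {
    ni <- n_per[i]
    idx <- pos + seq_len(ni)
    Xi <- blocks$X_list[[i]]
    fm <- drop(Xi %*% beta)
    fitted_marg[idx] <- fm
    if (q > 0) {
      Zi <- blocks$Z_list[[i]]
      ti <- blocks$t_list[[i]]
      Ri <- outer(ti, ti, function(a, b) phi^abs(a - b))
      if (phi == 0) Ri <- diag(ni)
      Li <- Zi %*% diag(sd_re_rel^2, q) %*% t(Zi) + weights[i]^2 * Ri
      bi <- diag(sd_re_rel^2, q) %*% t(Zi) %*%
        solve(Li, blocks$y_list[[i]] - fm)
      blups[i, ] <- bi
      fitted_cond[idx] <- fm + drop(Zi %*% bi)
    } else {
      fitted_cond[idx] <- fm
    }
    pos <- pos + ni
  }
  rownames(blups) <- blocks$trees

  structure(list(
    spec = spec, record = record,
    coefficients = beta, se = se, t_value = tval, df = df, p_value = pval,
    vcov = vcov_beta,
    sigma = sigma,
    sd_re = sigma * sd_re_rel,       # absolute random-effect SDs
    sd_re_names = c("intercept", "h", "h2")[seq_len(q)],
    phi = phi,
    tree_weights = weights,
    logLik = full$loglik,
    theta = opt$par,
    n_obs = N, n_trees = m,
    df_inner = max(N - m - p_inner, 1L), df_outer = max(m - p_outer, 1L),
    is_outer = is_outer,
    boundary = boundary,
    convergence = opt$convergence,
    data = blocks$data, X = blocks$X,
    trees = blocks$trees, blups = blups,
    fitted_marginal = fitted_marg, fitted_conditional = fitted_cond),
    class = "xylem_lmm")
}

#' Evaluate the restricted log-likelihood at given variance parameters
#'
#' Exposes the profiled REML criterion (fixed effects and residual
#' variance profiled out) for a standardized dataset, mainly for
#' validation against dense-matrix computations.
#'
#' @inheritParams fit_reml
#' @param theta unconstrained parameter vector: `q` log random-effect SDs,
#'   then Fisher-z AR1 (if enabled), then `m - 1` log relative SDs (if
#'   enabled).
#' @return restricted log-likelihood (scalar), or `-Inf` if the implied
#'   covariance is not positive definite.
#' @export
reml_loglik <- function(data, spec, theta) {
  blocks <- reml_blocks(data, spec)
  res <- reml_core(theta, blocks$y_list, blocks$X_list, blocks$Z_list,
                   blocks$t_list, blocks$q, spec$include_ar1,
                   spec$include_weights, TRUE)
  if (!isTRUE(res$ok)) return(-Inf)
  res$loglik
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Coefficient table of a fitted trait model
#'
#' @param fit a `xylem_lmm`.
#' @return data.frame with `term`, `estimate`, `se`, `df`, `t`, `p`,
#'   `stars` (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001).
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "xylem_lmm"))
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(fit$se), df = unname(fit$df),
             t = unname(fit$t_value), p = unname(fit$p_value),
             stars = significance_stars(unname(fit$p_value)),
             stringsAsFactors = FALSE)
}

#' @export
coef.xylem_lmm <- function(object, ...) object$coefficients

#' @export
vcov.xylem_lmm <- function(object, ...) object$vcov

#' @export
logLik.xylem_lmm <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) +
              length(object$theta) + 1L, class = "logLik")
}

#' @export
print.xylem_lmm <- function(x, ...) {
  cat(sprintf("Trait mixed model (REML): %s, %s\n", x$spec$trait,
              x$spec$portion))
  cat(sprintf("  %d obs, %d trees; logLik(REML) = %.3f%s\n", x$n_obs,
              x$n_trees, x$logLik,
              if (x$boundary) " [variance component on boundary]" else ""))
  cat(sprintf("  residual SD %.4f, AR1 phi %.3f\n", x$sigma, x$phi))
  if (length(x$sd_re) > 0) {
    cat("  random-effect SDs:",
        paste(sprintf("%s %.4f", x$sd_re_names, x$sd_re), collapse = ", "),
        "\n")
  }
  tab <- coef_table(x)
  tab$estimate <- signif(tab$estimate, 4)
  tab$se <- signif(tab$se, 3)
  tab$t <- signif(tab$t, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
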