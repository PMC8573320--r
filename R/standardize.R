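#' Model specification for one trait x ring-portion mixed model
#'
#' Fixed effects: intercept, site (reference first), standardized height
#' and squared height, 8 standardized seasonal climate predictors and the
#' 16 site x climate interactions (29 coefficients for 3 sites). Random
#' effects: per-tree intercept and slopes on height and squared height
#' with diagonal covariance. Errors: continuous-lag AR1 over calendar
#' years within tree, with one relative residual SD per tree (the first
#' tree fixed at 1).
#'
#' @param trait `"la"`, `"tb2"`, `"den"` or `"cwt"`.
#' @param portion `"ew"` or `"lw"`.
#' @param log_transform natural-log the response before standardization
#'   (default `TRUE` for TB2 and CWT, as their distributions are strongly
#'   right-skewed).
#' @param standardize_response z-score the (possibly logged) response
#'   (default `TRUE`); disable to keep coefficients in trait units.
#' @param include_re,include_ar1,include_weights structure switches;
#'   all `TRUE` by default.
#' @param reference_site reference level of the site factor.
#' @param df_method `"inner_outer"` (nlme-style two-level heuristic,
#'   default) or `"normal"` (z tests).
#' @param fixed optional one-sided formula overriding the default
#'   29-coefficient fixed-effect structure (useful for reduced designs).
#' @return object of class `xylem_model_spec`.
#' @export
xylem_model_spec <- function(trait, portion,
                             log_transform = trait %in% c("tb2", "cwt"),
                             standardize_response = TRUE,
                             include_re = TRUE, include_ar1 = TRUE,
                             include_weights = TRUE,
                             reference_site = "W-D",
                             df_method = c("inner_outer", "normal"),
                             fixed = NULL) {
  structure(list(trait = match.arg(trait, c("la", "tb2", "den", "cwt")),
                 portion = match.arg(portion, c("ew", "lw")),
                 fixed = fixed,
                 log_transform = isTRUE(log_transform),
                 standardize_response = isTRUE(standardize_response),
                 include_re = isTRUE(include_re),
                 include_ar1 = isTRUE(include_ar1),
                 include_weights = isTRUE(include_weights),
                 reference_site = reference_site,
                 df_method = match.arg(df_method)),
            class = "xylem_model_spec")
}

#' Assemble the model frame for one trait and ring portion
#'
#' Merges a trait chronology with reconstructed heights, tree metadata
#' (site) and seasonal climate into one row per tree x year.
#'
#' @param chronology output of [build_chronology()].
#' @param heights output of [reconstruct_heights()] (or generator truth).
#' @param seasonal output of [aggregate_seasons()].
#' @param trees tree metadata with `tree_id` and `site`.
#' @param trait,portion selection of the response.
#' @return data.frame with columns `tree_id`, `year`, `site`, `response`,
#'   `height_m` and the 8 seasonal predictors (raw units).
#' @export
build_model_data <- function(chronology, heights, seasonal, trees,
                             trait, portion) {
  trait <- match.arg(trait, c("la", "tb2", "den", "cwt"))
  portion <- match.arg(portion, c("ew", "lw"))
  chr <- chronology[chronology$portion == portion,
                    c("tree_id", "year", trait)]
  names(chr)[3] <- "response"
  mf <- merge(chr, heights[, c("tree_id", "year", "height_m")],
              by = c("tree_id", "year"))
  mf <- merge(mf, trees[, c("tree_id", "site")], by = "tree_id")
  mf <- merge(mf, seasonal, by = c("site", "year"))
  mf <- mf[complete.cases(mf), , drop = FALSE]
  mf <- mf[order(mf$tree_id, mf$year), , drop = FALSE]
  rownames(mf) <- NULL
  mf
}

#' Standardize model variables
#'
#' Applies the natural log to flagged responses, then z-scores the
#' response (optionally), height, squared height and all seasonal
#' predictors to mean 0, SD 1. The returned record allows exact
#' back-transformation.
#'
#' @param data output of [build_model_data()].
#' @param spec a [xylem_model_spec()].
#' @return list with `data` (columns `y`, `h`, `h2`, standardized
#'   predictors, plus the originals) and `record` (class
#'   `standardization_record`).
#' @export
standardize <- function(data, spec) {
  stopifnot(inherits(spec, "xylem_model_spec"))
  preds <- seasonal_predictors()
  stop_if_not_cols(data, c("tree_id", "year", "site", "response",
                           "height_m", preds), "model data")
  center <- numeric(0); scale <- numeric(0)
  zscore <- function(x, nm) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      stop(sprintf("variable '%s' has zero variance", nm), call. = FALSE)
    }
    mu <- mean(x)
    center[nm] <<- mu; scale[nm] <<- s
    (x - mu) / s
  }
  y <- data$response
  if (spec$log_transform) {
    if (any(y <= 0)) {
      stop(sprintf("log transform of '%s' requires positive values",
                   spec$trait), call. = FALSE)
    }
    y <- log(y)
  }
  out <- data
  out$y <- if (spec$standardize_response) zscore(y, "y") else y
  out$h <- zscore(data$height_m, "h")
  out$h2 <- zscore(data$height_m^2, "h2")
  for (p in preds) out[[p]] <- zscore(data[[p]], p)
  sites <- unique(data$site)
  if (!spec$reference_site %in% sites) {
    stop(sprintf("reference site '%s' absent from data",
                 spec$reference_site), call. = FALSE)
  }
  out$site <- factor(data$site,
                     levels = c(spec$reference_site,
                                sort(setdiff(sites, spec$reference_site))))
  rec <- structure(list(center = center, scale = scale,
                        log_response = spec$log_transform,
                        standardize_response = spec$standardize_response),
                   class = "standardization_record")
  list(data = out, record = rec)
}

#' Back-transform a standardized response to its natural scale
#'
#' @param record a `standardization_record` from [standardize()].
#' @param y_std values on the modeled scale.
#' @return values on the original trait scale.
#' @export
back_transform <- function(record, y_std) {
  stopifnot(inherits(record, "standardization_record"))
  y <- if (record$standardize_response) {
    unname(y_std * record$scale["y"] + record$center["y"])
  } else y_std
  if (record$log_response) exp(y) else y
}
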