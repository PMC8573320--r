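#' Derive reproducible sub-seeds from one master seed
#'
#' A single user-facing integer seed fans out to independent substreams
#' (climate, trees, cells, ...) so that regenerating one table never
#' perturbs another.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # Sub-seeds are drawn from a generator keyed by the master seed (state
  # restored afterwards). A multiplicative congruential chain is NOT used
  # here on purpose: nested derivations of such a chain continue the same
  # orbit, so substreams of different parents collide systematically.
  with_seed(seed, sample.int(2147483646L, n))
}

# run expr under a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ring widths are measured in mm, stem diameters carried in cm
mm_to_cm <- function(x) x / 10
cm_to_mm <- function(x) x * 10

stop_if_not_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
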