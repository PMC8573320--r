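#' Mork's index and earlywood/latewood classification
#'
#' The classical Mork criterion: a tracheid is latewood when double its
#' double radial wall thickness meets or exceeds its radial lumen
#' diameter, i.e. `MI = 4 * CWT_rad / LD_rad >= 1` (the historical
#' "wall >= lumen" rule puts the boundary case in the latewood). A variant
#' using the mean of radial and tangential lumen diameters is available.
#'
#' @param cwt_rad_um single radial cell-wall thickness, um.
#' @param ld_rad_um radial lumen diameter, um (> 0).
#' @param ld_tan_um tangential lumen diameter, um; only used when
#'   `diameter = "mean"`.
#' @param diameter `"radial"` (default) or `"mean"` lumen diameter.
#' @param boundary portion assigned at `MI == 1`; `"latewood"` (default)
#'   or `"earlywood"`.
#' @return data.frame with `mork_index` and `portion` (`"ew"`/`"lw"`).
#' @export
morks_index <- function(cwt_rad_um, ld_rad_um, ld_tan_um = NULL,
                        diameter = c("radial", "mean"),
                        boundary = c("latewood", "earlywood")) {
  diameter <- match.arg(diameter)
  boundary <- match.arg(boundary)
  ld <- if (diameter == "mean") {
    if (is.null(ld_tan_um)) {
      stop("ld_tan_um required for diameter = \"mean\"", call. = FALSE)
    }
    (ld_rad_um + ld_tan_um) / 2
  } else ld_rad_um
  if (any(ld <= 0)) {
    stop("degenerate cell: lumen diameter must be positive", call. = FALSE)
  }
  mi <- 4 * cwt_rad_um / ld
  lw <- if (boundary == "latewood") mi >= 1 else mi > 1
  data.frame(mork_index = mi, portion = ifelse(lw, "lw", "ew"),
             stringsAsFactors = FALSE)
}

#' Conduit reinforcement index (thickness-to-span ratio squared)
#'
#' `TB2 = (2 * CWT_s / wall_len_s)^2` where side `s` is the one with the
#' smaller single wall thickness (radial on ties) and `wall_len_s` the
#' length of that same wall.
#'
#' @param cwt_rad_um,cwt_tan_um single wall thicknesses, um.
#' @param wall_len_rad_um,wall_len_tan_um wall lengths, um.
#' @return numeric TB2 values (dimensionless).
#' @export
conduit_reinforcement <- function(cwt_rad_um, cwt_tan_um,
                                  wall_len_rad_um, wall_len_tan_um) {
  use_rad <- cwt_rad_um <= cwt_tan_um   # tie -> radial, deterministically
  cwt <- ifelse(use_rad, cwt_rad_um, cwt_tan_um)
  len <- ifelse(use_rad, wall_len_rad_um, wall_len_tan_um)
  if (any(len <= 0)) {
    stop("wall length on the selected side must be positive", call. = FALSE)
  }
  (2 * cwt / len)^2
}

#' Anatomical density of a tracheid
#'
#' Proportion of cell-wall area in the total cell area:
#' `DEN = CWA / (CWA + LA)`.
#'
#' @param cwa_um2 cell-wall area, um^2.
#' @param la_um2 lumen area, um^2.
#' @return numeric DEN values in (0, 1).
#' @export
anatomical_density <- function(cwa_um2, la_um2) {
  tot <- cwa_um2 + la_um2
  if (any(tot <= 0)) {
    stop("CWA + LA must be positive", call. = FALSE)
  }
  cwa_um2 / tot
}

#' Build annual earlywood/latewood trait chronologies from a cell table
#'
#' Computes per-cell traits (LA, TB2, DEN, mean CWT), classifies each cell
#' by Mork's index, and averages unweighted within tree x year x portion.
#' Cells flagged non-tracheid (optional logical column `tracheid` set to
#' `FALSE`) are dropped before any computation. Groups without cells are
#' simply absent from the output.
#'
#' @param cells data.frame with the columns of the cell exchange format
#'   (`tree_id`, `year`, `la_um2`, `ld_rad_um`, `ld_tan_um`, `cwt_rad_um`,
#'   `cwt_tan_um`, `cwa_um2`, `wall_len_rad_um`, `wall_len_tan_um`).
#' @param den_method `"per_cell"` (default; DEN averaged over cells, as
#'   annual means of a per-cell trait) or `"ratio_of_sums"`
#'   (`sum(CWA)/sum(CWA + LA)`) for sensitivity checks.
#' @param ... passed to [morks_index()] (`diameter`, `boundary`).
#' @return data.frame `tree_id`, `year`, `portion`, `la`, `tb2`, `den`,
#'   `cwt`, `n_cells`.
#' @export
build_chronology <- function(cells, den_method = c("per_cell", "ratio_of_sums"),
                             ...) {
  den_method <- match.arg(den_method)
  if (nrow(cells) == 0L) {
    return(data.frame(tree_id = character(0), year = integer(0),
                      portion = character(0), la = numeric(0),
                      tb2 = numeric(0), den = numeric(0), cwt = numeric(0),
                      n_cells = integer(0), stringsAsFactors = FALSE))
  }
  stop_if_not_cols(cells, c("tree_id", "year", "la_um2", "ld_rad_um",
                            "cwt_rad_um", "cwt_tan_um", "cwa_um2",
                            "wall_len_rad_um", "wall_len_tan_um"),
                   "cell table")
  if ("tracheid" %in% names(cells)) {
    cells <- cells[cells$tracheid %in% c(TRUE, NA), , drop = FALSE]
  }
  cls <- morks_index(cells$cwt_rad_um, cells$ld_rad_um, cells$ld_tan_um, ...)
  df <- data.frame(
    tree_id = cells$tree_id, year = cells$year, portion = cls$portion,
    la = cells$la_um2,
    tb2 = conduit_reinforcement(cells$cwt_rad_um, cells$cwt_tan_um,
                                cells$wall_len_rad_um, cells$wall_len_tan_um),
    den = anatomical_density(cells$cwa_um2, cells$la_um2),
    cwt = (cells$cwt_rad_um + cells$cwt_tan_um) / 2,
    cwa = cells$cwa_um2, tot = cells$cwa_um2 + cells$la_um2,
    stringsAsFactors = FALSE)
  agg <- stats::aggregate(df[, c("la", "tb2", "den", "cwt")],
                          by = df[, c("tree_id", "year", "portion")], mean)
  cnt <- stats::aggregate(list(n_cells = df$la),
                          by = df[, c("tree_id", "year", "portion")], length)
  agg <- merge(agg, cnt, by = c("tree_id", "year", "portion"))
  if (den_method == "ratio_of_sums") {
    dsum <- stats::aggregate(df[, c("cwa", "tot")],
                             by = df[, c("tree_id", "year", "portion")], sum)
    dsum$den <- dsum$cwa / dsum$tot
    agg$den <- dsum$den[match(paste(agg$tree_id, agg$year, agg$portion),
                              paste(dsum$tree_id, dsum$year, dsum$portion))]
  }
  agg <- agg[order(agg$tree_id, agg$year, agg$portion), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
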