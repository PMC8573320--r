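#' Read a Tucson (.rwl) ring-width file
#'
#' Parses the decadal Tucson layout: each line holds a series id, the
#' calendar year of the first value, and up to ten ring widths in 0.01 mm,
#' ending the series with a stop marker (`999` or `-9999`). A value of `0`
#' is interpreted as a missing (locally absent) ring and returned as `NA`.
#'
#' @param path path to the .rwl file.
#' @return long data.frame with columns `tree_id`, `year`, `rw_mm`.
#' @export
read_rwl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 3L) next
    id <- tok[1]
    yr0 <- suppressWarnings(as.integer(tok[2]))
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (is.na(yr0) || anyNA(vals)) {
      stop(sprintf("malformed .rwl line: %s", ln), call. = FALSE)
    }
    stop_i <- which(vals == 999 | vals == -9999)
    if (length(stop_i) > 0L) vals <- vals[seq_len(stop_i[1] - 1L)]
    if (length(vals) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      tree_id = id, year = yr0 + seq_along(vals) - 1L,
      rw_mm = ifelse(vals == 0, NA_real_, vals / 100),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop("no ring-width series found", call. = FALSE)
  res <- do.call(rbind, out)
  res <- res[order(res$tree_id, res$year), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write ring widths as a Tucson (.rwl) file
#'
#' Decadal layout, 0.01 mm units, series terminated with `999`; missing
#' rings are written as `0`.
#'
#' @param rings long data.frame with columns `tree_id`, `year`, `rw_mm`
#'   (`NA` marks a missing ring).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_rwl <- function(rings, path) {
  stop_if_not_cols(rings, c("tree_id", "year", "rw_mm"), "ring table")
  con <- file(path, "w")
  on.exit(close(con))
  for (id in unique(rings$tree_id)) {
    sub <- rings[rings$tree_id == id, , drop = FALSE]
    sub <- sub[order(sub$year), , drop = FALSE]
    if (any(diff(sub$year) != 1L)) {
      stop(sprintf("series %s has non-contiguous years", id), call. = FALSE)
    }
    vals <- ifelse(is.na(sub$rw_mm), 0L, as.integer(round(sub$rw_mm * 100)))
    yrs <- sub$year
    vals <- c(vals, 999L)            # stop marker occupies the next slot
    yrs <- c(yrs, yrs[length(yrs)] + 1L)
    i <- 1L
    while (i <= length(vals)) {
      decade_end <- (yrs[i] %/% 10) * 10 + 9
      j <- max(which(yrs <= decade_end))
      writeLines(sprintf("%-8s%6d%s", id, yrs[i],
                         paste0(sprintf("%6d", vals[i:j]), collapse = "")),
                 con)
      i <- j + 1L
    }
  }
  invisible(path)
}

#' Read ring widths from a long CSV
#'
#' @param path CSV with columns `tree_id`, `year`, `rw_mm`.
#' @return long data.frame `tree_id`, `year`, `rw_mm`.
#' @export
read_rings_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stop_if_not_cols(df, c("tree_id", "year", "rw_mm"), path)
  df[order(df$tree_id, df$year), c("tree_id", "year", "rw_mm")]
}
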