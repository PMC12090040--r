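# Readers and writers for the pipeline's tabular formats.

#' Read ring-width series
#'
#' Two dialects: a long CSV (`tree_id`, `year`, `width_mm`, optional `dbh`,
#' `bark`) and the Tucson decadal text format (series id + decade start
#' year, up to 10 values per line; end marker 999 for 0.01 mm units, -9999
#' for 0.001 mm units; values converted to mm).
#'
#' @param path File path.
#' @param dialect "csv" or "tucson".
#' @return data.frame `tree_id`, `year`, `width_mm` (plus any metadata
#'   columns for csv), years validated as consecutive per tree.
#' @export
read_ring_widths <- function(path, dialect = c("csv", "tucson")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  out <- if (dialect == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("tree_id", "year", "width_mm")
    miss <- setdiff(need, names(d))
    if (length(miss)) stop("ring-width CSV missing columns: ",
                           paste(miss, collapse = ", "))
    d
  } else {
    read_tucson(path)
  }
  for (id in unique(out$tree_id)) {
    y <- sort(out$year[out$tree_id == id])
    if (any(diff(y) != 1))
      stop("non-contiguous years for tree ", id, " at year ",
           y[which(diff(y) != 1)[1] + 1])
  }
  out
}

read_tucson <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- list()
  for (ln in lines) {
    id <- trimws(substr(ln, 1, 8))
    rest <- strsplit(trimws(substr(ln, 9, nchar(ln))), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(rest))
    if (length(vals) < 2 || any(is.na(vals))) stop("unparseable Tucson line: ", ln)
    decade <- vals[1]
    vals <- vals[-1]
    term <- which(vals == 999 | vals == -9999)
    divisor <- 100
    if (length(term)) {
      divisor <- if (vals[term[1]] == -9999) 1000 else 100
      vals <- vals[seq_len(term[1] - 1L)]
    }
    if (!length(vals)) next
    rows[[length(rows) + 1L]] <- data.frame(
      tree_id = id, year = decade + seq_along(vals) - 1L,
      width_mm = vals / divisor, divisor = divisor)
  }
  if (!length(rows)) stop("no series found in Tucson file")
  out <- do.call(rbind, rows)
  # the terminator (and thus the unit) appears on a series' last line only;
  # propagate it back over the series
  for (id in unique(out$tree_id)) {
    idx <- out$tree_id == id
    out$width_mm[idx] <- out$width_mm[idx] * out$divisor[idx] /
      out$divisor[idx][sum(idx)]
  }
  out$divisor <- NULL
  rownames(out) <- NULL
  out
}

#' Read a per-cell anatomy table
#'
#' Ingests a columnar cell-level export (one row per tracheid). Column
#' names are mapped through `column_map`; unknown columns are ignored with
#' a warning, rows failing validation (non-positive lumen geometry,
#' negative walls, position outside \[0,1\]) are dropped with a counted
#' warning.
#'
#' @param path CSV path.
#' @param column_map Named character vector mapping internal names
#'   (`tree_id`, `year`, `file_id`, `position`, `la`, `ld`, `cwt_r1`,
#'   `cwt_r2`, `cwt_t1`, `cwt_t2`, optional `cell_id`) to file column
#'   names. Default: identity.
#' @return Validated cell table data.frame.
#' @export
read_cell_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  internal <- c("tree_id", "year", "cell_id", "file_id", "position", "la",
                "ld", "cwt_r1", "cwt_r2", "cwt_t1", "cwt_t2")
  if (is.null(column_map)) column_map <- stats::setNames(internal, internal)
  mandatory <- setdiff(internal, "cell_id")
  miss <- mandatory[!column_map[mandatory] %in% names(d)]
  if (length(miss)) stop("cell table missing mandatory columns: ",
                         paste(column_map[miss], collapse = ", "))
  used <- intersect(unname(column_map[internal]), names(d))
  extra <- setdiff(names(d), used)
  if (length(extra))
    warning("ignoring unmapped columns: ", paste(extra, collapse = ", "))
  out <- d[, used]
  names(out) <- names(column_map)[match(used, column_map)]
  if (!"cell_id" %in% names(out))
    out$cell_id <- paste0(out$file_id, "_", stats::ave(
      seq_len(nrow(out)), out$tree_id, out$year, out$file_id, FUN = seq_along))
  ok <- is.finite(out$la) & out$la > 0 & is.finite(out$ld) & out$ld > 0 &
    out$position >= 0 & out$position <= 1 &
    out$cwt_r1 >= 0 & out$cwt_r2 >= 0 & out$cwt_t1 >= 0 & out$cwt_t2 >= 0
  ok[is.na(ok)] <- FALSE
  if (any(!ok))
    warning(sum(!ok), " invalid cell rows dropped")
  out <- out[ok, ]
  rownames(out) <- NULL
  out
}

#' Read a monthly climate CSV
#'
#' @param path CSV with columns `year`, `month`, `tmean`, `precip`
#'   (optional `tmax`, `tmin`).
#' @param latitude Site latitude (degrees), stored as attribute.
#' @return Validated climate data.frame.
#' @export
read_climate_csv <- function(path, latitude) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- check_climate(d)
  attr(d, "latitude") <- latitude
  d
}

#' Read a tree-ring isotope CSV
#'
#' @param path CSV with columns `tree_id`, `year_start`, `year_end`,
#'   `d13c_tree`; annual rows have `year_start == year_end`.
#' @return data.frame, blocks validated as non-overlapping per tree.
#' @export
read_isotope_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "year_start", "year_end", "d13c_tree")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("isotope CSV missing columns: ", paste(miss, collapse = ", "))
  if (any(d$year_end < d$year_start)) stop("year_end before year_start")
  for (id in unique(d$tree_id)) {
    sub <- d[d$tree_id == id, ]
    sub <- sub[order(sub$year_start), ]
    if (nrow(sub) > 1 && any(sub$year_start[-1] <= sub$year_end[-nrow(sub)]))
      stop("overlapping isotope blocks for tree ", id)
  }
  d
}

#' Write a data.frame as CSV (pipeline output convention)
#' @param x data.frame.
#' @param path Output path; directories are created.
#' @return `path`, invisibly.
#' @export
write_output_csv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
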