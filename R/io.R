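#' Read a component data matrix from CSV
#'
#' Expects a header row, one row per record, an id column and WGS84
#' latitude/longitude columns; every remaining numeric column is treated as
#' a component.  Errors report the offending id or line.
#'
#' @param path CSV path.
#' @param id_col,lat_col,lon_col Column names for the identifier and
#'   coordinates (the column-mapping configuration).
#' @return A [toxpi_data()] object; row order is preserved.
#' @export
read_data_csv <- function(path, id_col = "id", lat_col = "lat",
                          lon_col = "lon") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(id_col, lat_col, lon_col)) {
    if (!col %in% names(df)) {
      stop("mapped column '", col, "' not found in ", path,
           "; available: ", paste(names(df), collapse = ", "), call. = FALSE)
    }
  }
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate record id(s) in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  comp_cols <- setdiff(names(df), c(id_col, lat_col, lon_col))
  vals <- as.matrix(df[comp_cols])
  suppressWarnings(storage.mode(vals) <- "double")
  raw <- as.matrix(df[comp_cols])
  bad <- which(is.na(vals) & !(is.na(raw) | raw == "" | toupper(raw) == "NA"),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric value '", raw[bad[1, 1], bad[1, 2]], "' at line ",
         bad[1, 1] + 1L, ", column '", comp_cols[bad[1, 2]], "' of ", path,
         call. = FALSE)
  }
  lat <- suppressWarnings(as.numeric(df[[lat_col]]))
  lon <- suppressWarnings(as.numeric(df[[lon_col]]))
  if (any(is.na(lat)) || any(is.na(lon))) {
    i <- which(is.na(lat) | is.na(lon))[1]
    stop("missing or unparseable coordinate at line ", i + 1L, " of ", path,
         call. = FALSE)
  }
  toxpi_data(ids, lat, lon, vals)
}

#' Read pre-scored ToxPi results from CSV
#'
#' Accepts the output of an external ToxPi scoring run (e.g. a ToxPi GUI
#' results export adapted to this schema): an id column, latitude,
#' longitude, an overall-score column, and one column per model slice.
#' Unknown extra columns are ignored with a warning.  All scores are
#' validated against the \[0, 1\] invariants.
#'
#' @param path CSV path.
#' @param model A [toxpi_model()] naming the expected slice columns.
#' @param id_col,lat_col,lon_col,overall_col Column-mapping configuration.
#' @return A `toxpi_scores` data frame.
#' @export
read_prescored_csv <- function(path, model, id_col = "id", lat_col = "lat",
                               lon_col = "lon", overall_col = "overall") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  sn <- slice_names(model)
  needed <- c(id_col, lat_col, lon_col, overall_col, sn)
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "),
         "; expected slices: ", paste(sn, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), needed)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  }
  ss <- as.matrix(df[sn])
  storage.mode(ss) <- "double"
  if (any(!is.finite(ss)) || any(ss < 0) || any(ss > 1)) {
    bad <- which(!is.finite(ss) | ss < 0 | ss > 1, arr.ind = TRUE)[1, ]
    stop("slice score outside [0, 1] at line ", bad[1] + 1L, ", column '",
         sn[bad[2]], "' of ", path, call. = FALSE)
  }
  toxpi_scores(df[[id_col]], df[[lat_col]], df[[lon_col]], ss, model,
               overall = as.numeric(df[[overall_col]]))
}

#' Write ToxPi scores to CSV
#' @param scores A `toxpi_scores` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE)
  invisible(path)
}

#' Write hotspot results to CSV
#' @param hotspots Output of [hotspot_analysis()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hotspots_csv <- function(hotspots, path) {
  utils::write.csv(hotspots, path, row.names = FALSE)
  invisible(path)
}
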