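#' Construct a component data matrix
#'
#' One row per record (e.g. county) with a unique identifier, a WGS84
#' location and the raw numeric component values.
#'
#' @param ids Character vector of unique record identifiers.
#' @param lat,lon Numeric vectors of WGS84 decimal degrees.
#' @param values Numeric matrix (records x components) with column names;
#'   missing values are allowed.
#' @return An object of class `toxpi_data`.
#' @export
toxpi_data <- function(ids, lat, lon, values) {
  ids <- as.character(ids)
  n <- length(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (length(lat) != n || length(lon) != n) {
    stop("ids, lat and lon must have equal length", call. = FALSE)
  }
  bad_lat <- which(!is.finite(lat) | lat < -90 | lat > 90)
  if (length(bad_lat)) {
    stop("latitude out of range [-90, 90] for record(s): ",
         paste(ids[utils::head(bad_lat, 5)], collapse = ", "), call. = FALSE)
  }
  bad_lon <- which(!is.finite(lon) | lon < -180 | lon > 180)
  if (length(bad_lon)) {
    stop("longitude out of range [-180, 180] for record(s): ",
         paste(ids[utils::head(bad_lon, 5)], collapse = ", "), call. = FALSE)
  }
  values <- as.matrix(values)
  if (nrow(values) != n) {
    stop("values must have one row per record", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    stop("values must have column names (component names)", call. = FALSE)
  }
  storage.mode(values) <- "double"
  rownames(values) <- ids
  structure(list(ids = ids, lat = lat, lon = lon, values = values),
            class = "toxpi_data")
}

#' @export
print.toxpi_data <- function(x, ...) {
  cat("ToxPi data matrix: ", length(x$ids), " records x ",
      ncol(x$values), " components\n", sep = "")
  invisible(x)
}

# check every model component has a column; error names the missing ones
check_components_present <- function(data, model) {
  comp <- component_names(model)
  missing <- setdiff(comp, colnames(data$values))
  if (length(missing)) {
    stop("component column(s) missing from data matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Min-max scale the component columns of a data matrix
#'
#' Each component column is linearly scaled to \[0, 1\] over its non-missing
#' entries; `lower_is_worse` components are then inverted (`1 - scaled`) so
#' that, after scaling, larger always means a larger contribution to the
#' score.  Scaling is cohort-relative: the minimum and maximum are taken
#' from the supplied matrix itself.  Edge rules: a constant column maps to 0
#' for every record, and missing values are imputed as 0 after scaling (the
#' most conservative contribution); both cases emit a message.
#'
#' @param data A [toxpi_data()] matrix.
#' @param model A [toxpi_model()]; every model component must be a column.
#' @return A `toxpi_data` object whose component columns lie in \[0, 1\].
#' @export
scale_components <- function(data, model) {
  check_components_present(data, model)
  scaled <- data$values
  for (s in model$slices) {
    for (cc in s$components) {
      x <- data$values[, cc$name]
      ok <- is.finite(x)
      if (!any(ok)) {
        scaled[, cc$name] <- 0
        next
      }
      rng <- range(x[ok])
      if (rng[1] == rng[2]) {
        y <- rep(0, length(x))
        message("component '", cc$name, "' is constant; scaled to 0")
      } else {
        y <- (x - rng[1]) / (rng[2] - rng[1])
        if (cc$direction == "lower_is_worse") y <- 1 - y
      }
      if (any(!ok)) {
        y[!ok] <- 0
        message(sum(!ok), " missing value(s) in component '", cc$name,
                "' imputed as 0 after scaling")
      }
      scaled[, cc$name] <- y
    }
  }
  out <- data
  out$values <- scaled
  out
}

#' Compute per-record slice scores
#'
#' The score of slice *i* for a record is the weighted mean of its scaled
#' components, `s_i = sum_c(w_c * x_c) / sum_c(w_c)`, using the within-slice
#' component weights; each `s_i` lies in \[0, 1\].
#'
#' @param scaled A [toxpi_data()] matrix already passed through
#'   [scale_components()] (all component values in \[0, 1\]).
#' @param model A [toxpi_model()].
#' @return Numeric matrix (records x slices) of slice scores, with slice
#'   names as column names and record ids as row names.
#' @export
compute_slice_scores <- function(scaled, model) {
  check_components_present(scaled, model)
  v <- scaled$values
  if (any(v[is.finite(v)] < -1e-9 | v[is.finite(v)] > 1 + 1e-9)) {
    stop("scaled values must lie in [0, 1]; run scale_components() first",
         call. = FALSE)
  }
  out <- matrix(NA_real_, nrow = length(scaled$ids),
                ncol = length(model$slices),
                dimnames = list(scaled$ids, slice_names(model)))
  for (s in model$slices) {
    w <- vapply(s$components, `[[`, numeric(1), "weight")
    cols <- vapply(s$components, `[[`, character(1), "name")
    out[, s$name] <- as.vector(v[, cols, drop = FALSE] %*% w) / sum(w)
  }
  out
}

#' Combine slice scores into the normalized overall score
#'
#' `overall = sum_i(w_i * s_i) / sum_i(w_i)`; with slice scores in \[0, 1\]
#' the overall score is also in \[0, 1\] and is invariant under uniform
#' rescaling of the weights.
#'
#' @param slice_scores Numeric vector (one record) or matrix
#'   (records x slices) of slice scores.
#' @param weights Positive slice weights, one per slice.
#' @return Numeric overall score(s).
#' @export
compute_overall <- function(slice_scores, weights) {
  if (is.matrix(slice_scores)) {
    if (ncol(slice_scores) != length(weights)) {
      stop("number of slice-score columns (", ncol(slice_scores),
           ") does not match number of weights (", length(weights), ")",
           call. = FALSE)
    }
  } else if (length(slice_scores) != length(weights)) {
    stop("slice_scores and weights must have equal length", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("all slice weights must be positive and finite", call. = FALSE)
  }
  if (is.matrix(slice_scores)) {
    as.vector(slice_scores %*% weights) / sum(weights)
  } else {
    sum(slice_scores * weights) / sum(weights)
  }
}

#' Score a data matrix under a ToxPi model
#'
#' Runs the full scoring chain: min-max scaling with direction handling,
#' within-slice weighted means, and the weight-normalized overall score.
#'
#' @param data A [toxpi_data()] matrix of raw component values.
#' @param model A [toxpi_model()].
#' @return An object of class `toxpi_scores`: a data frame with columns
#'   `record_id`, `lat`, `lon`, `overall` and one column per slice, plus a
#'   `"model"` attribute.  Slice and overall scores lie in \[0, 1\].
#' @examples
#' m <- toxpi_model("demo", list(toxpi_slice("a", "x"), toxpi_slice("b", "y")))
#' d <- toxpi_data(c("r1", "r2", "r3"), lat = c(35, 36, 37),
#'                 lon = c(-80, -81, -82),
#'                 values = cbind(x = c(1, 2, 3), y = c(3, 2, 1)))
#' toxpi_score(d, m)
#' @export
toxpi_score <- function(data, model) {
  scaled <- scale_components(data, model)
  ss <- compute_slice_scores(scaled, model)
  overall <- compute_overall(ss, slice_weights(model))
  res <- data.frame(record_id = data$ids, lat = data$lat, lon = data$lon,
                    overall = overall, stringsAsFactors = FALSE)
  res <- cbind(res, as.data.frame(ss))
  rownames(res) <- NULL
  attr(res, "model") <- model
  class(res) <- c("toxpi_scores", "data.frame")
  res
}

#' Assemble a `toxpi_scores` object from already-computed scores
#'
#' Used when slice scores come from an external scoring run (for example a
#' ToxPi GUI results export) rather than from [toxpi_score()].
#'
#' @param record_id Character vector of unique ids.
#' @param lat,lon WGS84 coordinates.
#' @param slice_scores Matrix (records x slices) of slice scores in
#'   \[0, 1\], columns named after the model slices.
#' @param model A [toxpi_model()].
#' @param overall Optional overall scores; recomputed from the slice scores
#'   and model weights when omitted.
#' @return A `toxpi_scores` data frame; see [toxpi_score()].
#' @export
toxpi_scores <- function(record_id, lat, lon, slice_scores, model,
                         overall = NULL) {
  record_id <- as.character(record_id)
  if (anyDuplicated(record_id)) {
    stop("duplicate record id(s): ",
         paste(unique(record_id[duplicated(record_id)]), collapse = ", "),
         call. = FALSE)
  }
  sn <- slice_names(model)
  slice_scores <- as.matrix(slice_scores)
  missing <- setdiff(sn, colnames(slice_scores))
  if (length(missing)) {
    stop("missing slice-score column(s): ", paste(missing, collapse = ", "),
         "; expected slices: ", paste(sn, collapse = ", "), call. = FALSE)
  }
  slice_scores <- slice_scores[, sn, drop = FALSE]
  if (any(!is.finite(slice_scores)) ||
      any(slice_scores < -1e-9) || any(slice_scores > 1 + 1e-9)) {
    stop("slice scores must be finite and in [0, 1]", call. = FALSE)
  }
  if (is.null(overall)) {
    overall <- compute_overall(slice_scores, slice_weights(model))
  }
  if (any(overall < -1e-9) || any(overall > 1 + 1e-9)) {
    stop("overall scores must lie in [0, 1]", call. = FALSE)
  }
  res <- data.frame(record_id = record_id, lat = as.numeric(lat),
                    lon = as.numeric(lon), overall = as.numeric(overall),
                    stringsAsFactors = FALSE)
  res <- cbind(res, as.data.frame(slice_scores, row.names = NULL))
  attr(res, "model") <- model
  class(res) <- c("toxpi_scores", "data.frame")
  res
}

#' Slice-score matrix of a `toxpi_scores` object
#' @param scores A `toxpi_scores` data frame.
#' @return Numeric matrix (records x slices), rownames = record ids.
#' @export
score_matrix <- function(scores) {
  model <- attr(scores, "model")
  m <- as.matrix(scores[, slice_names(model), drop = FALSE])
  rownames(m) <- scores$record_id
  m
}

#' Aggregate records into per-group median ToxPi profiles
#'
#' For each group the per-slice median of the member slice scores is taken,
#' and the group overall score is recomputed from those median slice scores
#' via [compute_overall()] (so the group's glyph and its overall score stay
#' consistent).  Group locations default to the mean of member coordinates.
#'
#' @param scores A `toxpi_scores` data frame.
#' @param groups Character vector of group labels, one per record (or a
#'   named vector keyed by record id).
#' @return A `toxpi_scores` data frame with one row per group, ordered by
#'   group label, with a `group` column.
#' @export
aggregate_group_medians <- function(scores, groups) {
  model <- attr(scores, "model")
  if (!is.null(names(groups))) {
    groups <- groups[scores$record_id]
  }
  if (length(groups) != nrow(scores) || any(is.na(groups))) {
    stop("every record must be assigned to a group", call. = FALSE)
  }
  groups <- as.character(groups)
  labels <- sort(unique(groups))
  ss <- score_matrix(scores)
  med <- matrix(NA_real_, nrow = length(labels), ncol = ncol(ss),
                dimnames = list(labels, colnames(ss)))
  lat <- lon <- numeric(length(labels))
  for (k in seq_along(labels)) {
    idx <- which(groups == labels[k])
    if (!length(idx)) {
      warning("group '", labels[k], "' is empty; skipped")
      next
    }
    med[k, ] <- apply(ss[idx, , drop = FALSE], 2, stats::median)
    lat[k] <- mean(scores$lat[idx])
    lon[k] <- mean(scores$lon[idx])
  }
  keep <- stats::complete.cases(med)
  out <- toxpi_scores(labels[keep], lat[keep], lon[keep],
                      med[keep, , drop = FALSE], model)
  out$group <- labels[keep]
  out
}
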