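#' Define a ToxPi component
#'
#' A component is one input variable feeding a slice.  Its `direction`
#' states how the raw value relates to the quantity being prioritised:
#' `"higher_is_worse"` values are scaled so larger raw values give larger
#' contributions; `"lower_is_worse"` values are inverted after scaling.
#'
#' @param name Column name of the component in the data matrix.
#' @param direction One of `"higher_is_worse"` (default) or
#'   `"lower_is_worse"`.
#' @param weight Positive within-slice weight (default 1).  Components of a
#'   slice are combined as a weighted mean using these weights.
#' @return An object of class `toxpi_component`.
#' @export
toxpi_component <- function(name,
                            direction = c("higher_is_worse", "lower_is_worse"),
                            weight = 1) {
  direction <- match.arg(direction)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight <= 0) {
    stop("component '", name, "': weight must be a positive number",
         call. = FALSE)
  }
  structure(list(name = name, direction = direction,
                 weight = as.numeric(weight)),
            class = "toxpi_component")
}

#' Define a ToxPi slice
#'
#' A slice is one sector of the ToxPi glyph.  Its angular width is
#' proportional to `weight` and its radial length to the slice score in
#' \[0, 1\].  Slices are grouped into domains (colour families).
#'
#' @param name Slice name, unique within a model.
#' @param components List of [toxpi_component()] objects (or bare character
#'   names, taken as equally weighted `higher_is_worse` components).
#' @param weight Positive slice weight used for the overall score and the
#'   angular width.
#' @param domain Domain (colour-family) label.
#' @param color Hex colour for the slice.
#' @return An object of class `toxpi_slice`.
#' @export
toxpi_slice <- function(name, components, weight = 1, domain = name,
                        color = "#808080") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight <= 0) {
    stop("slice '", name, "': weight must be a positive number", call. = FALSE)
  }
  if (is.character(components)) {
    components <- lapply(components, toxpi_component)
  }
  if (length(components) < 1L) {
    stop("slice '", name, "' must contain at least one component",
         call. = FALSE)
  }
  comp_names <- vapply(components, `[[`, character(1), "name")
  if (anyDuplicated(comp_names)) {
    stop("slice '", name, "': duplicated component name(s): ",
         paste(unique(comp_names[duplicated(comp_names)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, domain = domain, weight = as.numeric(weight),
                 color = color, components = components),
            class = "toxpi_slice")
}

#' Define a ToxPi model
#'
#' The model is the analysis recipe: an ordered list of slices, each with a
#' weight, a domain, a colour and a set of weighted, directed components.
#'
#' @param name Model name.
#' @param slices List of [toxpi_slice()] objects.
#' @return An object of class `toxpi_model` with elements `name`, `slices`
#'   and the derived `domains` character vector.
#' @examples
#' m <- toxpi_model("demo", list(
#'   toxpi_slice("exposure", c("pm25", "ozone"), weight = 2),
#'   toxpi_slice("susceptibility", "age65", weight = 1)))
#' slice_names(m)
#' @export
toxpi_model <- function(name, slices) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(slices) < 1L) {
    stop("a ToxPi model needs at least one slice", call. = FALSE)
  }
  ok <- vapply(slices, inherits, logical(1), "toxpi_slice")
  if (!all(ok)) stop("all slices must be toxpi_slice objects", call. = FALSE)
  snames <- vapply(slices, `[[`, character(1), "name")
  if (anyDuplicated(snames)) {
    stop("duplicated slice name(s): ",
         paste(unique(snames[duplicated(snames)]), collapse = ", "),
         call. = FALSE)
  }
  comp <- unlist(lapply(slices, function(s)
    vapply(s$components, `[[`, character(1), "name")))
  if (anyDuplicated(comp)) {
    stop("component(s) assigned to more than one slice: ",
         paste(unique(comp[duplicated(comp)]), collapse = ", "),
         call. = FALSE)
  }
  domains <- unique(vapply(slices, `[[`, character(1), "domain"))
  structure(list(name = name, slices = slices, domains = domains),
            class = "toxpi_model")
}

#' @export
print.toxpi_model <- function(x, ...) {
  cat("ToxPi model '", x$name, "': ", length(x$slices), " slices in ",
      length(x$domains), " domains\n", sep = "")
  for (s in x$slices) {
    cat(sprintf("  %-28s domain=%-22s w=%-5g comps=%d\n",
                s$name, s$domain, s$weight, length(s$components)))
  }
  invisible(x)
}

#' Slice names of a model
#' @param model A [toxpi_model()].
#' @return Character vector of slice names, in model order.
#' @export
slice_names <- function(model) {
  vapply(model$slices, `[[`, character(1), "name")
}

#' Slice weights of a model
#' @param model A [toxpi_model()].
#' @return Numeric vector of slice weights, in model order.
#' @export
slice_weights <- function(model) {
  vapply(model$slices, `[[`, numeric(1), "weight")
}

#' All component names of a model
#' @param model A [toxpi_model()].
#' @return Character vector of component names across all slices.
#' @export
component_names <- function(model) {
  unlist(lapply(model$slices, function(s)
    vapply(s$components, `[[`, character(1), "name")))
}

#' Read a ToxPi model from a JSON configuration file
#'
#' The schema is `{name, slices: [{name, domain, weight, color,
#' components: [{name, direction, weight}]}]}`.  Missing component
#' `direction` defaults to `higher_is_worse`; missing weights default to 1.
#'
#' @param path Path to the JSON file.
#' @return A [toxpi_model()].
#' @seealso [write_toxpi_model()], [pvi_like_model()]
#' @export
read_toxpi_model <- function(path) {
  if (!file.exists(path)) {
    stop("model file not found: ", path, call. = FALSE)
  }
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$slices)) {
    stop("model file '", path, "' has no 'slices' entry", call. = FALSE)
  }
  slices <- lapply(j$slices, function(s) {
    comps <- lapply(s$components, function(cc) {
      toxpi_component(cc$name,
                      direction = if (is.null(cc$direction))
                        "higher_is_worse" else cc$direction,
                      weight = if (is.null(cc$weight)) 1 else cc$weight)
    })
    toxpi_slice(s$name, comps,
                weight = if (is.null(s$weight)) 1 else s$weight,
                domain = if (is.null(s$domain)) s$name else s$domain,
                color = if (is.null(s$color)) "#808080" else s$color)
  })
  toxpi_model(if (is.null(j$name)) "model" else j$name, slices)
}

#' Write a ToxPi model to JSON
#'
#' @param model A [toxpi_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_toxpi_model <- function(model, path) {
  j <- list(
    name = model$name,
    slices = lapply(model$slices, function(s) list(
      name = s$name, domain = s$domain, weight = s$weight, color = s$color,
      components = lapply(s$components, function(cc)
        list(name = cc$name, direction = cc$direction, weight = cc$weight))))
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
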