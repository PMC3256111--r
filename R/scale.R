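#' Define a polytomous rating-scale instrument
#'
#' A scale definition names the items, groups them into subscales, and fixes
#' the common option range. Every item must belong to exactly one subscale and
#' the items of all subscales, concatenated, must equal \code{items}.
#'
#' @param items Character vector of item IDs, in instrument order.
#' @param subscales Named list mapping subscale name to an ordered character
#'   vector of item IDs.
#' @param option_min,option_max Integer option codes; every item is rated on
#'   the closed range \code{option_min:option_max}.
#' @param name Optional instrument name.
#'
#' @return An object of class \code{"scale_definition"}.
#' @examples
#' sc <- scale_definition(c("A1", "A2", "B1"),
#'                        list(A = c("A1", "A2"), B = "B1"), 1, 7)
#' score_range(sc, "A")
#' @export
scale_definition <- function(items, subscales, option_min = 1L,
                             option_max = 7L, name = "scale") {
  items <- as.character(items)
  if (anyDuplicated(items)) stop("duplicate item IDs in `items`")
  if (!is.list(subscales) || is.null(names(subscales)))
    stop("`subscales` must be a named list of item-ID vectors")
  subscales <- lapply(subscales, as.character)
  member <- unlist(subscales, use.names = FALSE)
  if (anyDuplicated(member))
    stop("an item may belong to only one subscale")
  if (!setequal(member, items) || length(member) != length(items))
    stop("subscales must partition `items` exactly")
  option_min <- as.integer(option_min)
  option_max <- as.integer(option_max)
  if (option_min >= option_max) stop("option_min must be < option_max")
  structure(list(name = name, items = items, subscales = subscales,
                 option_min = option_min, option_max = option_max),
            class = "scale_definition")
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale_definition> %s: %d items, options %d..%d\n",
              x$name, length(x$items), x$option_min, x$option_max))
  for (s in names(x$subscales))
    cat(sprintf("  %s (%d): %s\n", s, length(x$subscales[[s]]),
                paste(x$subscales[[s]], collapse = " ")))
  invisible(x)
}

#' Number of option levels of a scale
#' @param scale A \code{scale_definition}.
#' @return Integer count of option levels.
#' @export
n_options <- function(scale) scale$option_max - scale$option_min + 1L

#' Theoretical summed-score range of a subscale
#'
#' @param scale A \code{scale_definition}.
#' @param subscale Subscale name; \code{NULL} for the whole instrument.
#' @return Integer vector \code{c(min, max)}.
#' @export
score_range <- function(scale, subscale = NULL) {
  items <- subscale_items(scale, subscale)
  c(length(items) * scale$option_min, length(items) * scale$option_max)
}

#' Items of a subscale
#' @param scale A \code{scale_definition}.
#' @param subscale Subscale name; \code{NULL} returns all items.
#' @return Character vector of item IDs.
#' @export
subscale_items <- function(scale, subscale = NULL) {
  if (is.null(subscale)) return(scale$items)
  if (!subscale %in% names(scale$subscales))
    stop(sprintf("unknown subscale '%s'", subscale))
  scale$subscales[[subscale]]
}

#' The packaged 30-item PANSS definition
#'
#' Thirty clinician-rated schizophrenia symptom items scored 1 (absent) to
#' 7 (extreme): seven Positive (P1-P7), seven Negative (N1-N7) and sixteen
#' General Psychopathology (G1-G16) items.
#'
#' @return A \code{scale_definition}.
#' @export
panss_scale <- function() {
  read_scale_json(system.file("extdata", "panss_scale.json",
                              package = "ksirt", mustWork = TRUE))
}

#' Read a scale definition from JSON
#'
#' Expects keys \code{items}, \code{subscales}, \code{option_min},
#' \code{option_max} and optionally \code{name}.
#'
#' @param path Path to a JSON file.
#' @return A \code{scale_definition}.
#' @export
read_scale_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("items", "subscales", "option_min", "option_max"))
    if (is.null(x[[k]])) stop(sprintf("scale JSON missing key '%s'", k))
  scale_definition(x$items, as.list(x$subscales), x$option_min, x$option_max,
                   name = if (is.null(x$name)) "scale" else x$name)
}

#' Write a scale definition to JSON
#' @param scale A \code{scale_definition}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_scale_json <- function(scale, path) {
  jsonlite::write_json(unclass(scale), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
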