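#' Expected-score function of a fitted form
#'
#' Extracts the (isotonic) expected summed-score function of a \code{ksirt}
#' fit as a linking-ready object.
#'
#' @param fit A \code{ksirt} fit, or \code{NULL} if \code{grid}/\code{values}
#'   are given directly.
#' @param form Label, e.g. \code{"full"} or \code{"short"}.
#' @param grid,values Supply a score function directly (values must be
#'   nondecreasing over the grid).
#' @return An object of class \code{"score_function"} with fields
#'   \code{theta}, \code{T}, \code{form}, \code{subscale}.
#' @export
score_function <- function(fit = NULL, form = "full", grid = NULL,
                           values = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "ksirt"))
    grid <- fit$grid
    values <- fit$curves$T
    subscale <- fit$subscale
  } else {
    if (is.null(grid) || is.null(values) || length(grid) != length(values))
      stop("supply a fit, or matching grid and values")
    if (is.unsorted(values)) stop("score-function values must be nondecreasing")
    subscale <- NA_character_
  }
  structure(list(theta = grid, T = values, form = form, subscale = subscale),
            class = "score_function")
}

#' Invert an expected-score function at a summed score
#'
#' Linear interpolation between the bracketing grid points of the monotone
#' expected-score function. A score landing on a flat segment resolves to
#' the segment's severity midpoint; scores outside the achievable range are
#' clamped to the nearer grid end with a warning.
#'
#' @param sf A \code{score_function}.
#' @param s Summed score(s) to invert.
#' @return Severity value(s) theta.
#' @export
invert_score_function <- function(sf, s) {
  vapply(s, function(si) {
    if (si < min(sf$T)) {
      warning("summed score below achievable range; clamped")
      return(sf$theta[1])
    }
    if (si > max(sf$T)) {
      warning("summed score above achievable range; clamped")
      return(sf$theta[length(sf$theta)])
    }
    exact <- which(sf$T == si)
    if (length(exact))                       # node or flat segment: midpoint
      return((sf$theta[min(exact)] + sf$theta[max(exact)]) / 2)
    lo <- max(which(sf$T < si))
    hi <- min(which(sf$T > si))
    w <- (si - sf$T[lo]) / (sf$T[hi] - sf$T[lo])
    sf$theta[lo] + w * (sf$theta[hi] - sf$theta[lo])
  }, 0)
}

# round-half-up to integers (printed conversion tables use half-up)
round_half_up <- function(x) floor(x + 0.5)

#' Build a summed-score conversion table between two forms
#'
#' For every integer short-form summed score in the achievable expected-score
#' range, inverts the short-form expected-score function to a severity and
#' evaluates the full-form expected-score function there; mapped scores are
#' rounded half-up to integers. Composition of monotone maps, so the table
#' is monotone nondecreasing.
#'
#' @param sf_short,sf_full \code{score_function}s on the same severity grid.
#' @return A data frame (class \code{"conversion_table"}) with integer
#'   columns \code{short} and \code{full}.
#' @export
build_conversion_table <- function(sf_short, sf_full) {
  if (!isTRUE(all.equal(sf_short$theta, sf_full$theta)))
    stop("score functions must share the severity grid")
  s <- seq(ceiling(min(sf_short$T)), floor(max(sf_short$T)))
  if (!length(s)) stop("short form has no achievable integer scores")
  theta_s <- invert_score_function(sf_short, s)
  mapped <- stats::approx(sf_full$theta, sf_full$T, xout = theta_s,
                          rule = 2)$y
  structure(data.frame(short = as.integer(s),
                       full = as.integer(round_half_up(mapped))),
            class = c("conversion_table", "data.frame"))
}

#' Evaluate linking bias on a validation sample
#'
#' For each validation subject, maps the short-form summed score through the
#' conversion table and compares with the observed full-form summed score.
#' Scores outside the table are matched to the nearest row (counted).
#'
#' @param table A \code{conversion_table}.
#' @param validation A \code{ratings_matrix} containing all full-form items.
#' @param full_items,short_items Item-ID vectors of the two forms.
#' @return A list (class \code{"linking_bias"}): \code{mean_diff} (3
#'   decimals), \code{min_diff}, \code{max_diff}, \code{n},
#'   \code{n_outside}.
#' @export
evaluate_linking <- function(table, validation, full_items, short_items) {
  s_short <- summed_scores(validation, short_items)
  s_full <- summed_scores(validation, full_items)
  idx <- findInterval(s_short, table$short, all.inside = TRUE)
  # findInterval floors; snap to the nearest row instead
  idx <- ifelse(idx < nrow(table) &
                  abs(table$short[idx + 1] - s_short) <
                  abs(table$short[idx] - s_short), idx + 1L, idx)
  outside <- sum(s_short < min(table$short) | s_short > max(table$short))
  if (outside) warning(sprintf("%d score(s) outside the table; nearest row used",
                               outside))
  diff <- table$full[idx] - s_full
  structure(list(mean_diff = round(mean(diff), 3),
                 min_diff = min(diff), max_diff = max(diff),
                 n = length(diff), n_outside = outside),
            class = "linking_bias")
}

#' @export
print.linking_bias <- function(x, ...) {
  cat(sprintf(
    "<linking_bias> mean %.3f, range [%d, %d], n = %d (%d outside table)\n",
    x$mean_diff, x$min_diff, x$max_diff, x$n, x$n_outside))
  invisible(x)
}
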