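#' Operational item-selection criteria
#'
#' Five operational criteria rate each item from its fitted curves; items are
#' then classified Very Good / Good / Weak by Yes-count and the non-Weak
#' items form the short scale. Criteria 2-4 operationalize what were visual
#' judgments of the option curves; the numeric thresholds (\code{p_flat},
#' \code{tau}, percentile anchors) are declared defaults with overrides.
#'
#' \describe{
#'   \item{1 options used}{number of option levels reached by the ICC
#'     maximum, \code{round(max e) - option_min + 1}; Yes iff >= 5.}
#'   \item{2 rapid increase}{No when every non-extreme option's curve stays
#'     at or below \code{p_flat} (= 0.3), or no option's probability ever
#'     doubles along the grid; Yes when a majority of options above the
#'     floor reach their half-maximum at or below the median expected
#'     score; Somewhat when the rises occur only above the median.}
#'   \item{3 region ordering}{modal severity regions of the options must be
#'     ordered left to right with the option codes; an option with an empty
#'     modal region, or whose modal midpoint falls outside its neighbours',
#'     is a violation. Yes = 0 violations, Somewhat = 1-4, No >= 5.}
#'   \item{4 span}{an option is displaced when its support
#'     (\eqn{P \ge \tau}, default 0.05) is empty, or (for the two lowest
#'     options) lies entirely above the 25th percentile of the achievable
#'     expected-score range, or (for the two highest) entirely below the
#'     75th. No when >= 4 options are displaced, else Yes.}
#'   \item{5 slope}{Yes iff the ICC slope at the median option is >= 0.40.}
#' }
#'
#' @name criteria
NULL

#' @describeIn criteria Number of option levels the ICC reaches.
#' @param icc ICC data frame (columns \code{e}, \code{v}).
#' @param option_min Lowest option code.
#' @return \code{criterion1_options_used}: list \code{(count, rating)}.
#' @export
criterion1_options_used <- function(icc, option_min = 1L) {
  count <- as.integer(round(max(icc$e)) - option_min + 1L)
  list(count = count, rating = if (count >= 5) "Yes" else "No")
}

#' @describeIn criteria Do the option curves rise rapidly with severity?
#' @param occ OCC probability matrix (columns named by option code).
#' @param T_fun Expected subscale summed score over the grid.
#' @param grid Latent grid.
#' @param p_flat Flatness ceiling for non-extreme options (default 0.3).
#' @return \code{criterion2_rapid_increase}: rating string.
#' @export
criterion2_rapid_increase <- function(occ, T_fun, grid, p_flat = 0.3) {
  M <- ncol(occ)
  interior <- occ[, -c(1, M), drop = FALSE]
  if (ncol(interior) && max(interior) <= p_flat) return("No")
  doubles <- apply(occ, 2, function(p) {
    cm <- cummin(p)
    any(p >= 2 * cm & cm > 0)
  })
  if (!any(doubles)) return("No")
  # median expected score = T at the severity of the median subject (theta 0
  # under rank-normal scoring)
  t50 <- stats::approx(grid, T_fun, xout = 0, rule = 2)$y
  above_floor <- occ[, -1, drop = FALSE]
  early <- apply(above_floor, 2, function(p) {
    q_half <- which(p >= max(p) / 2)[1]
    T_fun[q_half] <= t50
  })
  if (sum(early) > length(early) / 2) "Yes" else "Somewhat"
}

#' @describeIn criteria Are the options' modal severity regions ordered?
#' @return \code{criterion3_region_ordering}: list \code{(violations,
#'   rating)}.
#' @export
criterion3_region_ordering <- function(occ, grid) {
  M <- ncol(occ)
  modal <- max.col(occ, ties.method = "first")
  loc <- rep(NA_real_, M)
  for (m in seq_len(M)) {
    q <- which(modal == m)
    if (length(q)) loc[m] <- (grid[min(q)] + grid[max(q)]) / 2
  }
  violations <- sum(is.na(loc))
  for (m in which(!is.na(loc))) {
    lower <- loc[seq_len(m - 1)]
    lower <- lower[!is.na(lower)]
    upper <- if (m < M) loc[(m + 1):M] else numeric(0)
    upper <- upper[!is.na(upper)]
    prev <- if (length(lower)) lower[length(lower)] else -Inf
    nxt <- if (length(upper)) upper[1] else Inf
    if (loc[m] < prev || loc[m] > nxt) violations <- violations + 1L
  }
  rating <- if (violations == 0) "Yes" else if (violations <= 4)
    "Somewhat" else "No"
  list(violations = violations, rating = rating)
}

#' @describeIn criteria Do the options span the severity continuum?
#' @param tau Support threshold on the option probability (default 0.05).
#' @return \code{criterion4_span}: list \code{(displaced, rating)}.
#' @export
criterion4_span <- function(occ, T_fun, grid, tau = 0.05) {
  M <- ncol(occ)
  t_lo <- min(T_fun) + 0.25 * diff(range(T_fun))
  t_hi <- min(T_fun) + 0.75 * diff(range(T_fun))
  displaced <- 0L
  for (m in seq_len(M)) {
    q <- which(occ[, m] >= tau)
    if (!length(q)) { displaced <- displaced + 1L; next }
    if (m <= 2 && min(T_fun[q]) > t_lo) displaced <- displaced + 1L
    if (m >= M - 1 && max(T_fun[q]) < t_hi) displaced <- displaced + 1L
  }
  list(displaced = displaced,
       rating = if (displaced >= 4) "No" else "Yes")
}

#' @describeIn criteria Is the ICC slope at the median option at least 0.40?
#' @param slope ICC slope at the median option score.
#' @return \code{criterion5_slope}: rating string.
#' @export
criterion5_slope <- function(slope) {
  if (slope >= 0.40) "Yes" else "No"
}

#' Classify an item from its five criterion ratings
#'
#' Yes-count rule: Very Good with >= 4 Yes, Good with exactly 3, Weak with
#' <= 2. Somewhat ratings carry no weight, and no criterion is a veto. This
#' is the unique simple Yes-count rule consistent with all 30 published
#' rating rows (locked in the test suite).
#'
#' @param ratings Character vector of five ratings
#'   (\code{"Yes"}/\code{"Somewhat"}/\code{"No"}).
#' @return List \code{(yes_count, rating, retained)}.
#' @export
classify_item <- function(ratings) {
  stopifnot(length(ratings) == 5)
  yes <- sum(ratings == "Yes")
  rating <- if (yes >= 4) "Very Good" else if (yes == 3) "Good" else "Weak"
  list(yes_count = yes, rating = rating, retained = rating != "Weak")
}

#' Rate and classify every item of a fitted subscale
#'
#' Applies the five operational criteria to the curves of a \code{ksirt}
#' fit and classifies each item.
#'
#' @param fit A \code{ksirt} fit.
#' @param p_flat,tau Criterion 2 and 4 thresholds (see \link{criteria}).
#' @return A data frame with one row per item: criterion-1 count, the five
#'   ratings, slope, yes_count, rating and retained flag.
#' @export
item_criteria <- function(fit, p_flat = 0.3, tau = 0.05) {
  stopifnot(inherits(fit, "ksirt"))
  grid <- fit$grid
  T_fun <- fit$curves$T
  rows <- lapply(fit$items, function(it) {
    occ <- fit$occ[[it]]
    icc <- fit$icc[[it]]
    c1 <- criterion1_options_used(icc, fit$scale$option_min)
    c2 <- criterion2_rapid_increase(occ, T_fun, grid, p_flat)
    c3 <- criterion3_region_ordering(occ, grid)
    c4 <- criterion4_span(occ, T_fun, grid, tau)
    slope <- fit$diagnostics$slope[fit$diagnostics$item == it]
    c5 <- criterion5_slope(slope)
    cls <- classify_item(c(c1$rating, c2, c3$rating, c4$rating, c5))
    data.frame(item = it, c1_count = c1$count, c1 = c1$rating, c2 = c2,
               c3 = c3$rating, c4 = c4$rating, c5 = c5, slope = slope,
               yes_count = cls$yes_count, rating = cls$rating,
               retained = cls$retained, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select the short form from item classifications
#'
#' Retains exactly the non-Weak items, preserving subscale grouping and
#' item order.
#'
#' @param classifications Data frame with columns \code{item} and
#'   \code{retained} (as from \code{\link{item_criteria}} or the packaged
#'   fixture after \code{\link{classify_item}}).
#' @param scale The full-form \code{scale_definition}.
#' @return A \code{scale_definition} for the short form.
#' @export
select_short_form <- function(classifications, scale) {
  keep <- classifications$item[classifications$retained]
  subs <- lapply(scale$subscales, intersect, keep)
  empty <- names(subs)[vapply(subs, length, 0L) == 0]
  if (length(empty))
    stop(sprintf("subscale(s) %s would lose all items",
                 paste(empty, collapse = ", ")))
  scale_definition(unlist(subs, use.names = FALSE), subs,
                   scale$option_min, scale$option_max,
                   name = paste0("mini-", scale$name))
}

#' Yes-count and percentage for one criterion within a subscale
#'
#' @param ratings Data frame with columns \code{item}, \code{subscale} and
#'   \code{c1}..\code{c5} (fixture or recomputed ratings).
#' @param subscale Subscale name.
#' @param criterion Criterion index 1-5.
#' @return List \code{(count, percent)}; percent of the subscale's items
#'   rated Yes, to 2 decimals.
#' @export
criterion_counts <- function(ratings, subscale, criterion) {
  rows <- ratings[ratings$subscale == subscale, ]
  if (!nrow(rows)) stop(sprintf("no items in subscale '%s'", subscale))
  col <- paste0("c", criterion)
  count <- sum(rows[[col]] == "Yes")
  list(count = count, percent = round(100 * count / nrow(rows), 2))
}
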