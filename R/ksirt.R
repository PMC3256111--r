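#' Equally spaced latent evaluation grid
#'
#' @param q Number of grid points (default 51).
#' @param range Closed severity range, default \code{c(-3, 3)}.
#' @return Numeric vector of strictly increasing grid points.
#' @export
latent_grid <- function(q = 51L, range = c(-3, 3)) {
  if (q < 2 || range[1] >= range[2]) stop("invalid latent grid")
  seq(range[1], range[2], length.out = q)
}

#' Rank-based latent severity scores
#'
#' Subjects are ordered by subscale summed score; mid-ranks (ties averaged)
#' are mapped through the standard-normal quantile function,
#' \eqn{\hat\theta_i = \Phi^{-1}(r_i/(N+1))}. Tied summed scores share a
#' latent score and the map is nondecreasing in the summed score.
#'
#' @param data A \code{ratings_matrix}.
#' @param items Item IDs forming the subscale.
#' @return A data frame with columns \code{subject_id}, \code{summed},
#'   \code{rank}, \code{theta}.
#' @export
latent_scores <- function(data, items) {
  s <- summed_scores(data, items)
  n <- length(s)
  if (n == 0) stop("no subjects")
  r <- rank(s, ties.method = "average")
  data.frame(subject_id = data$subject_id, summed = s, rank = r,
             theta = stats::qnorm(r / (n + 1)))
}

#' Default kernel bandwidth
#'
#' The kernel-IRT convention for standard-normal latent scores,
#' \eqn{h = 1.1 N^{-1/5}}.
#'
#' @param n Subject count (>= 2).
#' @return Bandwidth.
#' @export
default_bandwidth <- function(n) {
  if (n < 2) stop("need at least 2 subjects")
  1.1 * n^(-1 / 5)
}

#' Kernel-smoothed option characteristic curves for one item
#'
#' Nadaraya-Watson estimate with a standard Gaussian kernel:
#' \deqn{\hat P(m \mid \theta_q) = \frac{\sum_i K((\theta_q - \hat\theta_i)/h)\,
#'   1[x_i = m]}{\sum_i K((\theta_q - \hat\theta_i)/h)}.}
#'
#' @param values Integer option codes, one per subject (no missing).
#' @param theta Latent scores \eqn{\hat\theta_i} (same order as
#'   \code{values}).
#' @param grid Latent evaluation grid.
#' @param h Bandwidth (> 0).
#' @param option_range \code{c(option_min, option_max)}.
#' @return A \code{Q x M} matrix of option probabilities; rows sum to 1.
#' @export
estimate_occ <- function(values, theta, grid, h,
                         option_range = c(1L, 7L)) {
  if (h <= 0) stop("bandwidth must be positive")
  if (anyNA(values)) stop("item values must be complete")
  opts <- seq(option_range[1], option_range[2])
  W <- stats::dnorm(outer(grid, theta, "-") / h)
  denom <- rowSums(W)
  if (any(denom <= 0)) stop("zero kernel mass at a grid point")
  ind <- outer(values, opts, "==") + 0
  P <- (W %*% ind) / denom
  colnames(P) <- as.character(opts)
  P
}

#' Item characteristic curve from option curves
#'
#' Expected item score and conditional item-score variance at each grid
#' point: \eqn{e_q = \sum_m m P_{qm}}, \eqn{v_q = \sum_m m^2 P_{qm} - e_q^2}.
#'
#' @param occ OCC probability matrix (columns named by option code).
#' @return A data frame with columns \code{e} and \code{v}.
#' @export
icc_from_occ <- function(occ) {
  w <- as.numeric(colnames(occ))
  e <- drop(occ %*% w)
  v <- drop(occ %*% w^2) - e^2
  data.frame(e = e, v = pmax(v, 0))
}

#' Expected subscale summed score over the grid
#'
#' Sum of the item ICCs, followed by an isotonic (nondecreasing) projection:
#' sampling noise can produce local decreases, and downstream linking
#' requires a monotone expected-score function.
#'
#' @param iccs List of ICC data frames sharing one grid.
#' @param grid The latent grid the ICCs were evaluated on.
#' @return Numeric vector \code{T} over the grid, nondecreasing.
#' @export
expected_subscale_score <- function(iccs, grid) {
  lens <- vapply(iccs, nrow, 0L)
  if (length(unique(lens)) != 1 || lens[1] != length(grid))
    stop("all ICCs must share the latent grid")
  T_raw <- Reduce(`+`, lapply(iccs, `[[`, "e"))
  stats::isoreg(grid, T_raw)$yf
}

#' Item information function
#'
#' \eqn{I_j(\theta) = e_j'(\theta)^2 / v_j(\theta)}: squared ICC slope over
#' conditional item-score variance. Derivatives use central differences in
#' the interior and one-sided differences at the grid ends. Where the item
#' is degenerate (v = 0, which forces e' = 0) information is defined as 0.
#'
#' @param icc ICC data frame (columns \code{e}, \code{v}).
#' @param grid Latent grid.
#' @return Numeric vector of pointwise information.
#' @export
item_information <- function(icc, grid) {
  d <- grad_grid(icc$e, grid)
  ifelse(icc$v > 0, d^2 / icc$v, 0)
}

# finite-difference gradient: central interior, one-sided at ends
grad_grid <- function(y, x) {
  n <- length(y)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    g[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  g
}

#' Conditional standard error of the summed score
#'
#' \eqn{SE(\theta_q) = \sqrt{\sum_j v_j(\theta_q)}}, the conditional standard
#' deviation of the subscale summed score at each severity. An
#' information-based alternative \eqn{1/\sqrt{J\,\bar I(\theta)}} is
#' available via \code{method = "information"}.
#'
#' @param iccs List of ICC data frames.
#' @param grid Latent grid (used by the information variant).
#' @param method \code{"conditional_sd"} (default) or \code{"information"}.
#' @return Numeric vector over the grid.
#' @export
summed_score_se <- function(iccs, grid = NULL,
                            method = c("conditional_sd", "information")) {
  method <- match.arg(method)
  if (method == "conditional_sd")
    return(sqrt(Reduce(`+`, lapply(iccs, `[[`, "v"))))
  info <- Reduce(`+`, lapply(iccs, item_information, grid = grid))
  1 / sqrt(pmax(info, .Machine$double.eps))
}

#' Probability density of scores on the expected-score axis
#'
#' A Gaussian kernel density of the latent scores, transformed to the
#' expected-score metric by change of variables
#' \eqn{f_X(T(\theta)) = f_\theta(\theta) / T'(\theta)} and renormalized to
#' integrate to one (trapezoid rule) over the achievable range of T.
#'
#' @param theta Latent scores of the sample.
#' @param T_fun Expected summed score over the grid (isotonic).
#' @param grid Latent grid.
#' @param h Kernel bandwidth for the latent density (default
#'   \code{default_bandwidth(length(theta))}).
#' @return A data frame with columns \code{score} (= T over the grid) and
#'   \code{density}.
#' @export
score_density <- function(theta, T_fun, grid, h = NULL) {
  if (is.null(h)) h <- default_bandwidth(length(theta))
  dT <- grad_grid(T_fun, grid)
  if (any(dT <= 1e-8))
    stop("expected-score function is flat on part of the grid; ",
         "use a wider bandwidth")
  f_theta <- rowMeans(stats::dnorm(outer(grid, theta, "-") / h)) / h
  f <- f_theta / dT
  area <- trapz(T_fun, f)
  data.frame(score = T_fun, density = f / area)
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' ICC slope at the median option score
#'
#' Central-difference derivative of the expected item score with respect to
#' the standard-normal severity metric, evaluated at the grid point where
#' the ICC is closest to the median option score (ties broken toward lower
#' severity).
#'
#' @param icc ICC data frame.
#' @param grid Latent grid.
#' @param median_option Option code at which to evaluate (4 for a 1-7 scale).
#' @return The slope (scalar).
#' @export
icc_slope_at_median <- function(icc, grid, median_option = 4) {
  q <- which.min(abs(icc$e - median_option))   # first minimum = lower theta
  grad_grid(icc$e, grid)[q]
}

#' Item-total correlation
#'
#' Pearson product-moment correlation between the item score and the
#' subscale summed score ("item biserial correlation" in rating-scale
#' usage; the items are polytomous, so the ordinary Pearson correlation is
#' the implemented quantity).
#'
#' @param values Item option codes.
#' @param totals Subscale summed scores.
#' @return Correlation, or \code{NA} if either variable is constant.
#' @export
item_total_correlation <- function(values, totals) {
  if (stats::sd(values) == 0 || stats::sd(totals) == 0) return(NA_real_)
  stats::cor(values, totals)
}

#' Fit kernel-smoothed item response curves for one subscale
#'
#' The package's central model fit. Subjects are scored on the rank-based
#' standard-normal severity metric; each item's option characteristic curves
#' are then estimated by Gaussian-kernel (Nadaraya-Watson) smoothing of the
#' option indicators over that metric, and all derived curves follow:
#' item characteristic curves (expected item score and conditional
#' variance), the expected subscale summed score (isotonic-projected),
#' average item information, the score probability density, the summed-score
#' standard error, and per-item diagnostics (slope at the median option,
#' item-total correlation).
#'
#' @param data A \code{ratings_matrix} with complete scores on the subscale.
#' @param scale A \code{scale_definition}; defaults to the packaged PANSS.
#' @param subscale Subscale name to fit.
#' @param bandwidth Kernel bandwidth; default \eqn{1.1 N^{-1/5}}.
#' @param grid Latent evaluation grid; default 51 points on [-3, 3].
#' @param se_method Standard-error curve variant; see
#'   \code{\link{summed_score_se}}.
#' @return An object of class \code{"ksirt"} with components
#'   \code{items}, \code{scores}, \code{occ} (list of Q x M probability
#'   matrices), \code{icc} (list of e/v data frames), \code{curves}
#'   (data frame: theta, T, info, density, se) and \code{diagnostics}
#'   (data frame: item, slope, item_total_r).
#' @examples
#' cfg <- panss_cohort_config(n = 300, seed = 7)
#' fit <- ksirt(simulate_cohort(cfg), subscale = "Positive")
#' print(fit)
#' coef(fit)
#' @export
ksirt <- function(data, scale = attr(data, "scale"), subscale,
                  bandwidth = NULL, grid = latent_grid(),
                  se_method = c("conditional_sd", "information")) {
  se_method <- match.arg(se_method)
  if (is.null(scale)) stop("no scale definition supplied")
  items <- subscale_items(scale, subscale)
  df <- as.data.frame(data)
  if (anyNA(df[items])) stop("subscale item scores must be complete")
  n <- nrow(df)
  if (is.null(bandwidth)) bandwidth <- default_bandwidth(n)
  scores <- latent_scores(data, items)
  orange <- c(scale$option_min, scale$option_max)

  occ <- lapply(items, function(it)
    estimate_occ(df[[it]], scores$theta, grid, bandwidth, orange))
  names(occ) <- items
  icc <- lapply(occ, icc_from_occ)
  T_fun <- expected_subscale_score(icc, grid)
  info <- Reduce(`+`, lapply(icc, item_information, grid = grid)) /
    length(items)
  dens <- score_density(scores$theta, T_fun, grid, h = bandwidth)
  se <- summed_score_se(icc, grid, method = se_method)

  med_opt <- (scale$option_min + scale$option_max) / 2
  diagnostics <- data.frame(
    item = items,
    slope = vapply(icc, icc_slope_at_median, 0, grid = grid,
                   median_option = med_opt),
    item_total_r = vapply(items, function(it)
      item_total_correlation(df[[it]], scores$summed), 0),
    row.names = NULL)

  structure(list(
    scale = scale, subscale = subscale, items = items, n = n,
    bandwidth = bandwidth, grid = grid, scores = scores,
    occ = occ, icc = icc,
    curves = data.frame(theta = grid, T = T_fun, info = info,
                        density = dens$density, se = se),
    diagnostics = diagnostics,
    se_method = se_method), class = "ksirt")
}

#' @export
print.ksirt <- function(x, ...) {
  cat(sprintf(
    "Kernel-smoothed IRT fit: %s subscale (%d items, N = %d, h = %.4f)\n",
    x$subscale, length(x$items), x$n, x$bandwidth))
  cat(sprintf("  grid: %d points on [%.4g, %.4g]; expected score %.2f..%.2f\n",
              length(x$grid), min(x$grid), max(x$grid),
              min(x$curves$T), max(x$curves$T)))
  invisible(x)
}

#' @export
summary.ksirt <- function(object, ...) {
  out <- list(fit = object, diagnostics = object$diagnostics,
              T_range = range(object$curves$T),
              info_range = range(object$curves$info),
              se_range = range(object$curves$se))
  class(out) <- "summary.ksirt"
  out
}

#' @export
print.summary.ksirt <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  average item information %.3f..%.3f; SE %.2f..%.2f\n",
              x$info_range[1], x$info_range[2],
              x$se_range[1], x$se_range[2]))
  cat("Item diagnostics (slope at median option, item-total r):\n")
  d <- x$diagnostics
  d$slope <- round(d$slope, 3)
  d$item_total_r <- round(d$item_total_r, 3)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Item diagnostics of a kernel IRT fit
#'
#' @param object A \code{ksirt} fit.
#' @param ... Unused.
#' @return Named vector of ICC slopes at the median option (use
#'   \code{object$diagnostics} for the full table).
#' @export
coef.ksirt <- function(object, ...) {
  stats::setNames(object$diagnostics$slope, object$diagnostics$item)
}

#' Predict expected scores from a kernel IRT fit
#'
#' Linear interpolation of the fitted curves at new severities.
#'
#' @param object A \code{ksirt} fit.
#' @param theta Severities at which to evaluate (clamped to the grid).
#' @param type \code{"subscale"} for the expected summed score,
#'   \code{"items"} for a matrix of expected item scores.
#' @param ... Unused.
#' @return Numeric vector or matrix.
#' @export
predict.ksirt <- function(object, theta = object$grid,
                          type = c("subscale", "items"), ...) {
  type <- match.arg(type)
  theta <- pmin(pmax(theta, min(object$grid)), max(object$grid))
  if (type == "subscale")
    return(stats::approx(object$grid, object$curves$T, xout = theta)$y)
  sapply(object$icc, function(ic)
    stats::approx(object$grid, ic$e, xout = theta)$y)
}

#' Plot kernel IRT curves
#'
#' @param x A \code{ksirt} fit.
#' @param what One of \code{"occ"}, \code{"icc"}, \code{"curves"}.
#' @param item Item ID for \code{what = "occ"} (default: first item).
#' @param ... Passed to \code{matplot}/\code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.ksirt <- function(x, what = c("occ", "icc", "curves"),
                       item = x$items[1], ...) {
  what <- match.arg(what)
  if (what == "occ") {
    graphics::matplot(x$grid, x$occ[[item]], type = "l", lty = 1,
                      xlab = expression(theta), ylab = "P(option)",
                      main = paste("OCCs:", item), ...)
  } else if (what == "icc") {
    e <- sapply(x$icc, `[[`, "e")
    graphics::matplot(x$grid, e, type = "l", lty = 1,
                      xlab = expression(theta), ylab = "expected item score",
                      main = paste("ICCs:", x$subscale), ...)
  } else {
    old <- graphics::par(mfrow = c(2, 2))
    on.exit(graphics::par(old))
    with(x$curves, {
      graphics::plot(theta, T, type = "l", main = "Expected summed score")
      graphics::plot(theta, info, type = "l", main = "Average item information")
      graphics::plot(T, density, type = "l", main = "Score density")
      graphics::plot(theta, se, type = "l", main = "Summed-score SE")
    })
  }
  invisible(x)
}
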