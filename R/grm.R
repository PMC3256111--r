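#' Graded-response-model option probabilities
#'
#' The logistic graded response model drives the synthetic cohort generator:
#' with discrimination \eqn{a \ge 0} and strictly increasing cumulative
#' thresholds \eqn{b_2 < \dots < b_M}, the probability of option \eqn{m} at
#' severity \eqn{\theta} is
#' \deqn{P(m \mid \theta) = L(a(\theta - b_m)) - L(a(\theta - b_{m+1}))}
#' with \eqn{L} the standard logistic, \eqn{b_1 = -\infty},
#' \eqn{b_{M+1} = +\infty}. Probabilities are nonnegative and sum to one.
#'
#' @param theta Numeric vector of latent severities.
#' @param item A \code{grm_item} (see \code{\link{grm_item}}).
#' @return A \code{length(theta) x M} matrix of option probabilities.
#' @examples
#' grm_option_probs(0, grm_item(a = 1, b = c(-1, 0, 1)))
#' @export
grm_option_probs <- function(theta, item) {
  a <- item$a
  b <- item$b
  M <- length(b) + 1L
  cum <- cbind(1, stats::plogis(a * outer(theta, b, "-")), 0)
  P <- cum[, 1:M, drop = FALSE] - cum[, -1, drop = FALSE]
  colnames(P) <- NULL
  P
}

#' Construct a graded-response item
#'
#' @param a Nonnegative discrimination (logit slope).
#' @param b Strictly increasing cumulative thresholds; an item with M options
#'   has M-1 thresholds.
#' @return An object of class \code{"grm_item"}.
#' @export
grm_item <- function(a, b) {
  if (a < 0) stop("discrimination `a` must be nonnegative")
  if (is.unsorted(b, strictly = TRUE))
    stop("thresholds `b` must be strictly increasing")
  structure(list(a = a, b = as.numeric(b)), class = "grm_item")
}

#' Archetypal item parameter sets
#'
#' Four named geometries used throughout the test suite:
#' \describe{
#'   \item{ideal}{steep curves (a = 1.8) with equally spaced thresholds
#'     spanning [-2, 2]: every option owns a well-separated severity region.}
#'   \item{flat}{a = 0.3 with only the lowest option boundaries inside the
#'     observable severity range: the used options' curves are nearly level,
#'     the upper options are essentially never endorsed, and the expected
#'     item score never approaches the median option. This is the geometry
#'     of a non-discriminating item as it actually presents in rating-scale
#'     data (flat and range-restricted), and it classifies Weak.}
#'   \item{ceiling_compressed}{top threshold pushed to 3.8 so the extreme
#'     option is almost never endorsed in the observable range.}
#'   \item{disordered_regions}{low discrimination plus near-coincident
#'     interior thresholds; thresholds remain ordered but interior options
#'     lose their modal regions.}
#' }
#'
#' @param kind Archetype name.
#' @param M Number of options (>= 2).
#' @return A \code{grm_item}.
#' @export
make_archetype <- function(kind = c("ideal", "flat", "ceiling_compressed",
                                    "disordered_regions"), M = 7L) {
  kind <- match.arg(kind)
  if (M < 2) stop("need at least 2 options")
  even <- seq(-2, 2, length.out = M - 1)
  switch(kind,
    ideal = grm_item(1.8, even),
    flat = {
      b <- seq(30, length.out = M - 1, by = 1)
      b[1] <- -8; if (M > 2) b[2] <- 0.5
      grm_item(0.3, b)
    },
    ceiling_compressed = {
      b <- seq(-2, 2, length.out = M - 1)
      b[M - 1] <- max(3.8, b[M - 1] + 1.8)
      grm_item(1.8, b)
    },
    disordered_regions = {
      # interior thresholds 0.05 apart: modal regions of interior options
      # collapse even though the cumulative thresholds stay ordered
      b <- c(-2, seq(-0.05, length.out = M - 3, by = 0.05), 2)
      if (M == 2) b <- 0
      grm_item(0.4, b)
    })
}

#' Configure a synthetic rating-scale cohort
#'
#' @param scale A \code{scale_definition}.
#' @param items Named list of \code{grm_item} parameter sets, one per scale
#'   item; or a single \code{grm_item} recycled to all items.
#' @param n Number of subjects.
#' @param severity Severity (latent trait) distribution: \code{list(dist =
#'   "normal", mean, sd)} or \code{list(dist = "skew_normal", location,
#'   scale, shape)}. The default skew-normal (shape 4) makes high summed
#'   scores rarer than low ones, the usual right skew of symptom severity in
#'   trial populations.
#' @param covariates Logical: also draw age / gender / diagnosis / race
#'   columns (independent of severity).
#' @param seed Master integer seed; stage seeds are derived from it.
#' @return An object of class \code{"cohort_config"}.
#' @export
cohort_config <- function(scale, items, n,
                          severity = list(dist = "skew_normal",
                                          location = -0.8, scale = 1.4,
                                          shape = 4),
                          covariates = FALSE, seed = 1L) {
  if (inherits(items, "grm_item"))
    items <- stats::setNames(rep(list(items), length(scale$items)),
                             scale$items)
  if (!setequal(names(items), scale$items))
    stop("`items` must supply one grm_item per scale item")
  if (n < 1) stop("n must be >= 1")
  M <- n_options(scale)
  for (it in items)
    if (length(it$b) != M - 1)
      stop("each grm_item needs M-1 thresholds for an M-option scale")
  structure(list(scale = scale, items = items, n = as.integer(n),
                 severity = severity, covariates = covariates,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' A PANSS-like default cohort configuration
#'
#' Thirty 7-option items in 7/7/16 subscales. Items default to mildly varied
#' ideal-type parameters with the top threshold pushed upward so the extreme
#' option is rare; named items can be replaced by weak archetypes.
#'
#' @param n Number of subjects.
#' @param weak_items Named character vector mapping item IDs to archetype
#'   kinds (e.g. \code{c(P7 = "flat", N5 = "disordered_regions")}).
#' @param severity As in \code{\link{cohort_config}}.
#' @param seed Master seed.
#' @param covariates Draw demographic columns too.
#' @return A \code{cohort_config}.
#' @export
panss_cohort_config <- function(n, weak_items = character(0),
                                severity = list(dist = "skew_normal",
                                                location = -0.8, scale = 1.4,
                                                shape = 4),
                                seed = 1L, covariates = FALSE) {
  scale <- panss_scale()
  M <- n_options(scale)
  items <- list()
  for (j in seq_along(scale$items)) {
    id <- scale$items[j]
    # deterministic mild variation so items are not literal clones
    a <- 1.4 + 0.5 * ((j * 7) %% 11) / 10
    shift <- 0.3 + 0.06 * ((j * 5) %% 7)
    b <- seq(-2, 2, length.out = M - 1) + shift
    b[M - 1] <- b[M - 1] + 1.6        # option 7 rarely endorsed
    items[[id]] <- grm_item(a, b)
  }
  for (id in names(weak_items)) {
    if (!id %in% scale$items) stop(sprintf("unknown item '%s'", id))
    items[[id]] <- make_archetype(weak_items[[id]], M)
  }
  cohort_config(scale, items, n, severity = severity, seed = seed,
                covariates = covariates)
}

# skew-normal deviates by the delta construction
rskewnorm <- function(n, location = 0, scale = 1, shape = 0) {
  delta <- shape / sqrt(1 + shape^2)
  u0 <- stats::rnorm(n)
  u1 <- stats::rnorm(n)
  z <- delta * abs(u0) + sqrt(1 - delta^2) * u1
  location + scale * z
}

draw_severity <- function(severity, n) {
  if (severity$dist == "normal") {
    stats::rnorm(n, severity$mean, severity$sd)
  } else if (severity$dist == "skew_normal") {
    rskewnorm(n, severity$location, severity$scale, severity$shape)
  } else stop(sprintf("unknown severity distribution '%s'", severity$dist))
}

#' Simulate a rating-scale cohort from a graded response model
#'
#' Draws one latent severity per subject from the configured distribution,
#' then samples each item from its GRM option probabilities. Covariates, when
#' requested, are drawn independently of severity. Fully deterministic under
#' the config's master seed (stage seeds for severity, items and covariates
#' are derived from it).
#'
#' @param config A \code{cohort_config}.
#' @return A \code{ratings_matrix}; the simulated severities are attached as
#'   attribute \code{"theta"}.
#' @export
simulate_cohort <- function(config) {
  scale <- config$scale
  M <- n_options(scale)
  theta <- with_seed(config$seed * 11L + 1L,
                     draw_severity(config$severity, config$n))
  df <- data.frame(subject_id = seq_len(config$n))
  for (j in seq_along(scale$items)) {
    id <- scale$items[j]
    P <- grm_option_probs(theta, config$items[[id]])
    cum <- t(apply(P, 1, cumsum))
    u <- with_seed(config$seed * 11L + 1L + j, stats::runif(config$n))
    opt <- rowSums(u > cum[, -M, drop = FALSE] + 1e-15) + 1L
    df[[id]] <- as.integer(scale$option_min + opt - 1L)
  }
  if (isTRUE(config$covariates)) {
    df <- cbind(df, with_seed(config$seed * 11L + 500L, data.frame(
      age = round(pmax(18, stats::rnorm(config$n, 39.5, 12.2))),
      gender = sample(c("Male", "Female"), config$n, TRUE, c(0.665, 0.335)),
      diagnosis = sample(c("Schizophrenia", "Schizoaffective"), config$n,
                         TRUE, c(0.956, 0.044)),
      race = sample(c("Caucasian", "Asian", "Black", "Hispanic", "Other"),
                    config$n, TRUE, c(0.67, 0.07, 0.175, 0.05, 0.035)),
      stringsAsFactors = FALSE)))
  }
  out <- as_ratings(df, scale, allow_missing = FALSE)
  attr(out, "theta") <- theta
  out
}
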