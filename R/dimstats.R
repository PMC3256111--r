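#' PCA eigenvalues of an item set
#'
#' Eigenvalues of the Pearson correlation matrix of the listed items
#' (unrotated principal components), in descending order. They sum to the
#' number of items.
#'
#' @param data A \code{ratings_matrix} (or data frame).
#' @param items Item IDs.
#' @return Numeric vector of eigenvalues.
#' @export
pca_eigen <- function(data, items) {
  X <- as.matrix(as.data.frame(data)[items])
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant item(s)")
  eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
}

#' Eigenvalue-ratio unidimensionality verdict
#'
#' A subscale is taken as unidimensional when the first PCA eigenvalue is at
#' least three times the second ("about three times larger", hardened to an
#' inclusive ratio >= 3 so verdicts are deterministic). The ratio is
#' reported to 3 decimals.
#'
#' @param lambda1,lambda2 First and second eigenvalues (\code{lambda2 > 0}).
#' @return List \code{(ratio, unidimensional)}.
#' @examples
#' eigen_ratio_verdict(3.172, 0.949)  # ratio 3.342, unidimensional
#' @export
eigen_ratio_verdict <- function(lambda1, lambda2) {
  if (lambda2 <= 0) stop("second eigenvalue must be positive")
  ratio <- round(lambda1 / lambda2, 3)
  list(ratio = ratio, unidimensional = ratio >= 3)
}

#' Bartlett's test of sphericity
#'
#' Tests that a correlation matrix is the identity:
#' \eqn{\chi^2 = -(N - 1 - (2p + 5)/6)\,\ln\det R} on \eqn{p(p-1)/2}
#' degrees of freedom.
#'
#' @param R Correlation matrix.
#' @param n Sample size used to compute \code{R}.
#' @return List \code{(statistic, df, p_value)}.
#' @export
bartlett_sphericity <- function(R, n) {
  p <- ncol(R)
  detR <- det(R)
  if (detR <= 0) stop("correlation matrix must be positive definite")
  stat <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' \eqn{KMO = \sum r^2 / (\sum r^2 + \sum q^2)} over off-diagonal entries,
#' where \eqn{q} are the anti-image partial correlations obtained from the
#' inverse correlation matrix. Values above 0.6 indicate adequacy for
#' factoring.
#'
#' @param R Invertible correlation matrix.
#' @return The KMO value.
#' @export
kmo <- function(R) {
  Rinv <- solve(R)
  S <- diag(1 / sqrt(diag(Rinv)))
  Q <- -S %*% Rinv %*% S       # anti-image partial correlations
  off <- row(R) != col(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
}

#' Cronbach's alpha
#'
#' \eqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_j s_j^2}{s_T^2}\right)}.
#'
#' @param data A \code{ratings_matrix} (or data frame).
#' @param items Item IDs (at least 2).
#' @return Alpha.
#' @export
cronbach_alpha <- function(data, items) {
  X <- as.matrix(as.data.frame(data)[items])
  k <- ncol(X)
  if (k < 2) stop("need at least 2 items")
  vt <- stats::var(rowSums(X))
  if (vt == 0) stop("zero total-score variance")
  k / (k - 1) * (1 - sum(apply(X, 2, stats::var)) / vt)
}

#' Compare two subject samples on shared variables
#'
#' Pooled-variance two-sample t tests (df = Na + Nb - 2) with Cohen's d for
#' continuous variables; chi-square tests with Cramer's phi for categorical
#' variables. Subscale summed scores are compared when a scale definition is
#' attached.
#'
#' @param a,b \code{ratings_matrix} halves sharing a schema.
#' @param continuous,categorical Column names to compare; defaults pick the
#'   standard covariates present plus per-subscale and total summed scores.
#' @return A list of two data frames, \code{continuous} and
#'   \code{categorical}, classed \code{"comparison_report"}.
#' @export
compare_subsamples <- function(a, b,
                               continuous = intersect("age", names(a)),
                               categorical = intersect(
                                 c("gender", "diagnosis", "race"), names(a))) {
  scale <- attr(a, "scale")
  da <- as.data.frame(a); db <- as.data.frame(b)
  if (!is.null(scale)) {
    for (s in names(scale$subscales)) {
      da[[paste0("score_", s)]] <- summed_scores(a, scale$subscales[[s]])
      db[[paste0("score_", s)]] <- summed_scores(b, scale$subscales[[s]])
    }
    da$score_total <- summed_scores(a, scale$items)
    db$score_total <- summed_scores(b, scale$items)
    continuous <- c(continuous, paste0("score_", names(scale$subscales)),
                    "score_total")
  }
  cont <- do.call(rbind, lapply(continuous, function(v) {
    x <- da[[v]]; y <- db[[v]]
    tt <- stats::t.test(x, y, var.equal = TRUE)
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                  (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    data.frame(variable = v, mean_a = mean(x), sd_a = stats::sd(x),
               mean_b = mean(y), sd_b = stats::sd(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               cohen_d = if (sp > 0) (mean(x) - mean(y)) / sp else 0,
               stringsAsFactors = FALSE)
  }))
  cat_rows <- lapply(categorical, function(v) {
    tab <- rbind(table(factor(da[[v]])), table(factor(db[[v]],
                 levels = levels(factor(da[[v]])))))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi <- unname(ct$statistic)
    phi <- sqrt(chi / (sum(tab) * (min(dim(tab)) - 1)))
    data.frame(variable = v, chisq = chi, df = unname(ct$parameter),
               p = ct$p.value, cramer_phi = phi, stringsAsFactors = FALSE)
  })
  structure(list(continuous = cont,
                 categorical = if (length(cat_rows))
                   do.call(rbind, cat_rows) else NULL),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\nContinuous:\n")
  print(x$continuous, row.names = FALSE, digits = 4)
  if (!is.null(x$categorical)) {
    cat("Categorical:\n")
    print(x$categorical, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Dimensionality report for a subscale
#'
#' Bundles the unrotated-PCA eigenvalue ratio, Bartlett sphericity and KMO
#' for one item set.
#'
#' @param data A \code{ratings_matrix}.
#' @param items Item IDs of the subscale.
#' @return A one-row data frame: eigen1, eigen2, ratio, unidimensional,
#'   bartlett_chisq, bartlett_df, bartlett_p, kmo.
#' @export
dimensionality_report <- function(data, items) {
  ev <- pca_eigen(data, items)
  verdict <- eigen_ratio_verdict(ev[1], ev[2])
  R <- stats::cor(as.matrix(as.data.frame(data)[items]))
  bt <- bartlett_sphericity(R, nrow(data))
  data.frame(eigen1 = ev[1], eigen2 = ev[2], ratio = verdict$ratio,
             unidimensional = verdict$unidimensional,
             bartlett_chisq = bt$statistic, bartlett_df = bt$df,
             bartlett_p = bt$p_value, kmo = kmo(R))
}
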