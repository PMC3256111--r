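#' Validate a data frame of item ratings against a scale definition
#'
#' A ratings matrix is a data frame with one row per subject, one integer
#' column per item of the scale, an optional \code{subject_id} column and
#' optional covariate columns (e.g. age, gender, diagnosis, race). Item cells
#' must be integer option codes within the scale's option range, or \code{NA}.
#'
#' @param data A data frame.
#' @param scale A \code{scale_definition}.
#' @param allow_missing Permit \code{NA} item cells (default \code{TRUE};
#'   \code{clean_ratings} removes them later).
#' @return \code{data}, with item columns coerced to integer and an attribute
#'   recording the scale, classed \code{"ratings_matrix"}.
#' @export
as_ratings <- function(data, scale, allow_missing = TRUE) {
  stopifnot(is.data.frame(data))
  absent <- setdiff(scale$items, names(data))
  if (length(absent))
    stop(sprintf("ratings are missing item column(s): %s",
                 paste(absent, collapse = ", ")))
  if ("subject_id" %in% names(data)) {
    if (anyDuplicated(data$subject_id)) stop("subject IDs must be unique")
  } else {
    data$subject_id <- seq_len(nrow(data))
  }
  for (it in scale$items) {
    v <- data[[it]]
    if (is.character(v)) v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & (is.na(num) | num != round(num)))
    if (length(bad))
      stop(sprintf("non-integer value for item %s at row %d", it, bad[1]))
    out <- which(!is.na(num) &
                   (num < scale$option_min | num > scale$option_max))
    if (length(out))
      stop(sprintf("value %s for item %s at row %d outside option range %d..%d",
                   format(num[out[1]]), it, out[1],
                   scale$option_min, scale$option_max))
    if (!allow_missing && anyNA(num))
      stop(sprintf("missing value for item %s", it))
    data[[it]] <- as.integer(num)
  }
  structure(data, scale = scale, class = c("ratings_matrix", "data.frame"))
}

#' Read subject ratings from CSV
#'
#' The CSV must have a header row containing every item ID of \code{scale};
#' additional columns (subject_id, covariates) are carried along. Empty cells
#' are read as missing.
#'
#' @param path CSV path.
#' @param scale A \code{scale_definition}.
#' @return A validated \code{ratings_matrix}.
#' @export
read_ratings <- function(path, scale) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE, na.strings = "")
  as_ratings(df, scale)
}

#' Write subject ratings to CSV
#'
#' Inverse of \code{read_ratings}: missing cells are written as empty strings.
#'
#' @param data A \code{ratings_matrix} (or plain data frame).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_ratings <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Remove subjects with excluded diagnoses or missing item scores
#'
#' Listwise deletion: a subject is removed if its diagnosis is not on the
#' whitelist (checked first) or if any item score is missing. Each removed row
#' is tallied under its first matching reason.
#'
#' @param data A \code{ratings_matrix}.
#' @param diagnosis_whitelist Character vector of retained diagnoses, or
#'   \code{NULL} to skip the diagnosis rule (e.g. no diagnosis column).
#' @return A list with elements \code{data} (the cleaned
#'   \code{ratings_matrix}) and \code{report} (class
#'   \code{"cleaning_report"}: per-reason counts, percent removed of the
#'   input to 2 decimals, and the retained count).
#' @export
clean_ratings <- function(data, diagnosis_whitelist = NULL) {
  scale <- attr(data, "scale")
  n_in <- nrow(data)
  reasons <- character(0)
  reason <- rep(NA_character_, n_in)
  if (!is.null(diagnosis_whitelist) && "diagnosis" %in% names(data)) {
    dx <- as.character(data$diagnosis)
    bad_dx <- !(dx %in% diagnosis_whitelist)
    # tally excluded diagnoses separately, unknown/missing under one label
    lab <- ifelse(is.na(dx) | dx == "", "No diagnosis provided", dx)
    reason[bad_dx] <- lab[bad_dx]
  }
  miss <- rowSums(is.na(as.data.frame(data)[scale$items])) > 0
  reason[is.na(reason) & miss] <- "Item score missing"
  keep <- is.na(reason)
  if (!any(keep)) stop("no subjects remain after cleaning")
  tab <- table(factor(reason[!keep]))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  report <- structure(list(
    input = n_in,
    removed = counts,
    total_removed = sum(counts),
    percent_removed = round(100 * sum(counts) / n_in, 2),
    retained = sum(keep)
  ), class = "cleaning_report")
  cleaned <- data[keep, , drop = FALSE]
  rownames(cleaned) <- NULL
  list(data = as_ratings(as.data.frame(cleaned), scale, allow_missing = FALSE),
       report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> input %d, removed %d (%.2f%%), retained %d\n",
              x$input, x$total_removed, x$percent_removed, x$retained))
  for (r in names(x$removed))
    cat(sprintf("  %-28s %d\n", r, x$removed[[r]]))
  invisible(x)
}

#' Randomly split subjects into two disjoint halves
#'
#' Produces an evaluation half of size ceiling(N/2) and a validation half of
#' size floor(N/2); the union is the input and the assignment is
#' deterministic under \code{seed}.
#'
#' @param data A \code{ratings_matrix} with at least two rows.
#' @param seed Integer seed.
#' @return A list with \code{evaluation} and \code{validation}
#'   \code{ratings_matrix} halves.
#' @export
split_sample <- function(data, seed = 1L) {
  n <- nrow(data)
  if (n < 2) stop("need at least 2 subjects to split")
  scale <- attr(data, "scale")
  idx <- with_seed(seed, sample.int(n))
  n_eval <- ceiling(n / 2)
  take <- function(i) {
    d <- as.data.frame(data)[sort(i), , drop = FALSE]
    rownames(d) <- NULL
    as_ratings(d, scale)
  }
  list(evaluation = take(idx[seq_len(n_eval)]),
       validation = take(idx[-seq_len(n_eval)]))
}

#' Subscale summed scores
#' @param data A \code{ratings_matrix}.
#' @param items Item IDs to sum (e.g. \code{subscale_items(scale, "Positive")}).
#' @return Integer vector of summed scores, one per subject.
#' @export
summed_scores <- function(data, items) {
  m <- as.matrix(as.data.frame(data)[items])
  as.integer(rowSums(m))
}

# Evaluate `expr` under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
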