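#' Run the full scale-shortening pipeline
#'
#' Clean, split, fit each subscale on the evaluation half, rate and classify
#' the items, select the short form, refit the short form, compute
#' dimensionality and reliability statistics, and link short-form to
#' full-form summed scores with bias evaluated on the validation half.
#' Deterministic under \code{seed}.
#'
#' @param data A \code{ratings_matrix} for the full instrument.
#' @param scale Full-form \code{scale_definition} (default: attached scale).
#' @param seed Integer seed for the random split.
#' @param diagnosis_whitelist Passed to \code{\link{clean_ratings}}
#'   (\code{NULL} skips the diagnosis rule).
#' @param bandwidth,grid Kernel settings passed to \code{\link{ksirt}}.
#' @param p_flat,tau Criteria thresholds passed to
#'   \code{\link{item_criteria}}.
#' @param out_dir If non-\code{NULL}, TSV outputs and a JSON summary are
#'   written there.
#' @return A list (class \code{"ksirt_pipeline"}) with the cleaning report,
#'   the fits, classification table, short-form scale, dimensionality and
#'   reliability tables, conversion tables and linking biases, and a
#'   \code{summary} list.
#' @export
run_pipeline <- function(data, scale = attr(data, "scale"), seed = 1L,
                         diagnosis_whitelist = NULL, bandwidth = NULL,
                         grid = latent_grid(), p_flat = 0.3, tau = 0.05,
                         out_dir = NULL) {
  cleaned <- clean_ratings(data, diagnosis_whitelist)
  halves <- split_sample(cleaned$data, seed)
  eval_half <- halves$evaluation
  valid_half <- halves$validation
  subs <- names(scale$subscales)

  fits <- lapply(subs, function(s)
    ksirt(eval_half, scale, s, bandwidth = bandwidth, grid = grid))
  names(fits) <- subs
  classification <- do.call(rbind, lapply(subs, function(s) {
    cls <- item_criteria(fits[[s]], p_flat = p_flat, tau = tau)
    cbind(subscale = s, cls)
  }))
  short_scale <- select_short_form(classification, scale)

  short_fits <- lapply(subs, function(s)
    ksirt(eval_half, short_scale, s, bandwidth = bandwidth, grid = grid))
  names(short_fits) <- subs

  dimensionality <- do.call(rbind, c(
    lapply(subs, function(s)
      cbind(form = "full", subscale = s,
            dimensionality_report(eval_half, scale$subscales[[s]]))),
    lapply(subs, function(s)
      cbind(form = "short", subscale = s,
            dimensionality_report(valid_half, short_scale$subscales[[s]])))))

  reliability <- do.call(rbind, lapply(subs, function(s) {
    long <- summed_scores(valid_half, scale$subscales[[s]])
    short <- summed_scores(valid_half, short_scale$subscales[[s]])
    ct <- stats::cor.test(long, short)
    data.frame(subscale = s,
               alpha_full = cronbach_alpha(valid_half, scale$subscales[[s]]),
               alpha_short = cronbach_alpha(valid_half,
                                            short_scale$subscales[[s]]),
               long_short_r = unname(ct$estimate), p = ct$p.value)
  }))

  conversion <- list(); bias <- list()
  for (s in subs) {
    tab <- build_conversion_table(score_function(short_fits[[s]], "short"),
                                  score_function(fits[[s]], "full"))
    conversion[[s]] <- tab
    bias[[s]] <- evaluate_linking(tab, valid_half, scale$subscales[[s]],
                                  short_scale$subscales[[s]])
  }

  summary <- list(
    n_input = cleaned$report$input,
    n_removed = cleaned$report$total_removed,
    percent_removed = cleaned$report$percent_removed,
    n_evaluation = nrow(eval_half), n_validation = nrow(valid_half),
    n_items_full = length(scale$items),
    n_items_short = length(short_scale$items),
    retained_by_subscale = vapply(short_scale$subscales, length, 0L),
    percent_retained = round(100 * length(short_scale$items) /
                               length(scale$items), 2),
    mean_linking_bias = vapply(bias, `[[`, 0, "mean_diff"),
    seed = seed)

  bundle <- structure(list(
    scale = scale, short_scale = short_scale, seed = seed,
    cleaning = cleaned$report, fits = fits, short_fits = short_fits,
    classification = classification, dimensionality = dimensionality,
    reliability = reliability, conversion = conversion, bias = bias,
    summary = summary), class = "ksirt_pipeline")

  if (!is.null(out_dir)) write_pipeline(bundle, out_dir)
  bundle
}

# TSV + JSON outputs of a pipeline bundle
write_pipeline <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  tsv(bundle$classification, "classification.tsv")
  tsv(bundle$dimensionality, "dimensionality.tsv")
  tsv(bundle$reliability, "reliability.tsv")
  for (s in names(bundle$conversion))
    tsv(bundle$conversion[[s]], sprintf("conversion_%s.tsv", s))
  curves <- do.call(rbind, lapply(names(bundle$fits), function(s)
    cbind(subscale = s, bundle$fits[[s]]$curves)))
  tsv(curves, "curves.tsv")
  jsonlite::write_json(bundle$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.ksirt_pipeline <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ksirt_pipeline> %d -> %d subjects (%.2f%% removed), split %d/%d\n",
              s$n_input, s$n_evaluation + s$n_validation, s$percent_removed,
              s$n_evaluation, s$n_validation))
  cat(sprintf("  retained %d/%d items (%.2f%%): %s\n",
              s$n_items_short, s$n_items_full, s$percent_retained,
              paste(sprintf("%s %d", names(s$retained_by_subscale),
                            s$retained_by_subscale), collapse = ", ")))
  cat(sprintf("  mean linking bias: %s\n",
              paste(sprintf("%s %.3f", names(s$mean_linking_bias),
                            s$mean_linking_bias), collapse = ", ")))
  invisible(x)
}

#' Render a pipeline bundle as a markdown report
#'
#' @param bundle A \code{ksirt_pipeline}.
#' @param path Optional output file; the text is returned either way.
#' @return Character vector of markdown lines, invisibly when written.
#' @export
render_report <- function(bundle, path = NULL) {
  md_table <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) round(x, 3))
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1, function(r)
        paste0("| ", paste(trimws(as.character(r)), collapse = " | "), " |")))
  }
  s <- bundle$summary
  lines <- c(
    "# Scale-shortening report",
    "",
    sprintf("- Input subjects: %d; removed %d (%.2f%%); evaluation/validation split %d/%d (seed %d)",
            s$n_input, s$n_removed, s$percent_removed, s$n_evaluation,
            s$n_validation, s$seed),
    sprintf("- Retained %d of %d items (%.2f%%): %s",
            s$n_items_short, s$n_items_full, s$percent_retained,
            paste(sprintf("%s %d", names(s$retained_by_subscale),
                          s$retained_by_subscale), collapse = ", ")),
    "",
    "## Item classification", "",
    md_table(bundle$classification[c("subscale", "item", "c1_count", "c1",
                                     "c2", "c3", "c4", "c5", "slope",
                                     "yes_count", "rating")]),
    "",
    "## Dimensionality", "",
    md_table(bundle$dimensionality),
    "",
    "## Reliability", "",
    md_table(bundle$reliability),
    "",
    "## Linking", "")
  for (sub in names(bundle$conversion)) {
    b <- bundle$bias[[sub]]
    lines <- c(lines,
               sprintf("### %s (mean bias %.3f, range [%d, %d])", sub,
                       b$mean_diff, b$min_diff, b$max_diff), "",
               md_table(bundle$conversion[[sub]]), "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
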