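#' Packaged reference tables for the PANSS item-selection study
#'
#' The published PANSS analysis was run on proprietary clinical-trial data
#' (7,187 baseline records), so its item-level outputs are not recomputable.
#' Three packaged TSVs transcribe the printed tables cell-for-cell so that the
#' classification rule, tally arithmetic and eigenvalue-ratio rule can be
#' verified exactly:
#' \describe{
#'   \item{criteria}{30 rows: item, subscale, label, criterion-1 option count
#'     and Yes/No flag, criterion 2-5 ratings, ICC slope, item-total
#'     correlation, and the printed global rating (Very Good/Good/Weak).
#'     The G16 criterion-1 cell is printed as a bare "4" and is encoded 4/No,
#'     consistent with every other count of 4 or less.}
#'   \item{eigen}{First/second PCA eigenvalues, their ratio and the
#'     unidimensionality verdict for each subscale of the full (30-item) and
#'     abbreviated (19-item) forms.}
#'   \item{cleaning}{Per-reason removal counts from the 7,348-record input
#'     (excluded diagnoses and missing item scores) with printed percentages.}
#' }
#'
#' @param which One of \code{"criteria"}, \code{"eigen"}, \code{"cleaning"}.
#' @return A data frame mirroring the printed table.
#' @export
load_fixture <- function(which = c("criteria", "eigen", "cleaning")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("panss_", which, ".tsv"),
                      package = "ksirt", mustWork = TRUE)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (which == "criteria") {
    stopifnot(nrow(df) == 30,
              all(c("item", "c1_count", "c1", "c2", "c3", "c4", "c5",
                    "slope", "item_total_r", "rating") %in% names(df)))
    ok2 <- df$c2 %in% c("Yes", "Somewhat", "No")
    ok3 <- df$c3 %in% c("Yes", "Somewhat", "No")
    ok145 <- df$c1 %in% c("Yes", "No") & df$c4 %in% c("Yes", "No") &
      df$c5 %in% c("Yes", "No")
    if (!all(ok2 & ok3 & ok145)) stop("malformed criteria fixture")
  }
  df
}

#' @rdname load_fixture
#' @export
load_criteria_fixture <- function() load_fixture("criteria")

#' @rdname load_fixture
#' @export
load_eigen_fixture <- function() load_fixture("eigen")

#' @rdname load_fixture
#' @export
load_cleaning_fixture <- function() load_fixture("cleaning")
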