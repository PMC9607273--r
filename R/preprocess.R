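# Descriptor-matrix preprocessing: constant/correlation filtering and the
# ordered-response train/test split.

#' Drop highly correlated descriptor columns
#'
#' Standard QSAR pre-selection: zero-variance columns are removed first, then
#' columns are scanned in their original order and a column is dropped when
#' its absolute Pearson correlation with any earlier surviving column exceeds
#' `threshold` (strictly). The earlier column of each flagged pair is the
#' survivor, so the result is order-stable and no remaining pair has
#' `|r| > threshold`.
#'
#' @param x A descriptor tibble (`compound_id` + numeric columns).
#' @param threshold Correlation threshold in (0, 1]; default 0.95, the usual
#'   95% pre-filter.
#' @return The filtered tibble, with attribute `"dropped"` (a tibble of
#'   dropped column, reason, and the column that triggered the drop).
#' @export
drop_correlated <- function(x, threshold = 0.95) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("`threshold` must be in (0, 1]")
  }
  cols <- setdiff(names(x), "compound_id")
  if (length(cols) < 2) abort("Need at least 2 descriptor columns")
  m <- descriptor_values(x)
  sds <- apply(m, 2, stats::sd)
  dropped <- tibble(column = character(0), reason = character(0),
                    against = character(0))
  const <- cols[sds == 0]
  if (length(const) > 0) {
    dropped <- dplyr::bind_rows(dropped, tibble(
      column = const, reason = "constant", against = NA_character_))
    cols <- setdiff(cols, const)
  }
  keep <- character(0)
  for (cl in cols) {
    hit <- NULL
    for (k in keep) {
      if (abs(stats::cor(m[, cl], m[, k])) > threshold) { hit <- k; break }
    }
    if (is.null(hit)) {
      keep <- c(keep, cl)
    } else {
      dropped <- dplyr::bind_rows(dropped, tibble(
        column = cl, reason = "correlated", against = hit))
    }
  }
  out <- x[c("compound_id", keep)]
  attr(out, "dropped") <- dropped
  attr(out, "provenance") <- attr(x, "provenance")[keep]
  out
}

#' Ordered-response train/test split
#'
#' Compounds are sorted by descending response and every `period`-th position
#' (positions `period`, `2*period`, ... 1-based) is assigned to the test set
#' — the "each fifth by descending order of response" rule that yields an
#' 80:20 split at `period = 5`. Ties are broken by original row order
#' (stable sort). Train and test indices partition `seq_along(responses)` and
#' refer to the original row order.
#'
#' @param responses Numeric response vector (no missing values).
#' @param period Integer >= 2; default 5.
#' @return A list with integer vectors `train` and `test`.
#' @export
#' @examples
#' split <- ordered_split(log_response(pon1_dataset(), "Q"))
#' lengths(split) # 24 train, 6 test
ordered_split <- function(responses, period = 5L) {
  if (!is.numeric(period) || length(period) != 1 || period < 2 ||
      period %% 1 != 0) {
    abort("`period` must be an integer >= 2")
  }
  if (anyNA(responses)) abort("`responses` must not contain missing values")
  n <- length(responses)
  if (n < period) {
    warn(paste0("Fewer responses (", n, ") than the split period (", period,
                "); test set is empty"))
    return(list(train = seq_len(n), test = integer(0)))
  }
  ord <- order(-responses)          # stable: ties keep original row order
  pos <- seq_along(ord)
  test <- sort(ord[pos %% period == 0])
  list(train = setdiff(seq_len(n), test), test = test)
}
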