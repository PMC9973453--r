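# Normalized pairwise variability index and line aggregation ------------------

#' Normalized pairwise variability index (nPVI)
#'
#' For an ordered sequence of positive values d_1, ..., d_m (m >= 2):
#'
#' \deqn{nPVI = \frac{100}{m-1} \sum_{k=1}^{m-1}
#'   \frac{|d_k - d_{k+1}|}{(d_k + d_{k+1})/2}}
#'
#' i.e. 100 times the mean over adjacent pairs of the absolute difference
#' divided by the pair mean (the Grabe & Low normalization).  The score is 0
#' for a constant sequence, bounded above by 200, scale-invariant and
#' invariant to sequence reversal.
#'
#' @param values ordered numeric sequence of positive values (SOIs in ms,
#'   intensities in dB, ...).
#' @return the nPVI score in `[0, 200]`.
#' @examples
#' npvi(c(100, 100, 100))  # 0
#' npvi(c(100, 200))       # 66.67
#' npvi(c(120, 180, 120))  # 40
#' @export
npvi <- function(values) {
  values <- as.numeric(values)
  m <- length(values)
  if (m < 2) {
    stop_bad_arg("nPVI is undefined for sequences of length < 2")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop_bad_arg("nPVI requires strictly positive finite values")
  }
  d1 <- values[-m]
  d2 <- values[-1]
  100 * mean(abs(d1 - d2) / ((d1 + d2) / 2))
}

#' Aggregate syllable features into per-line records
#'
#' Builds one record per participant x poem x line with the nPVI over the
#' line's syllable SOIs (`npvi_soi`) and, when intensities are present, over
#' its mean intensities (`npvi_i_mean`), plus the line covariates: whether
#' the line contains a tack (`tack_line`), the number of tacks
#' (`tacks_per_line`), the number of syllable slots (`n_sylls`) and the
#' running line number.  Rows flagged excluded are omitted from the nPVI
#' sequences (but not from the tack/slot counts, which describe the
#' stimulus); lines left with fewer than two usable syllables get a missing
#' nPVI and a warning rather than being dropped silently.
#'
#' @param features a `syllable_features` table (after [compute_soi()] and
#'   [filter_max_soi()]).
#' @param use_excluded include excluded rows in the nPVI sequences.
#' @return a `line_record` data.frame.
#' @export
aggregate_lines <- function(features, use_excluded = FALSE) {
  tbl <- as.data.frame(features)
  key <- paste(tbl$participant_id, tbl$poem_id, tbl$line_no, sep = "\r")
  groups <- split(tbl, factor(key, levels = unique(key)))
  n_short <- 0L
  recs <- lapply(groups, function(g) {
    usable <- if (use_excluded) g else g[!g$excluded, , drop = FALSE]
    rec <- data.frame(
      participant_id = g$participant_id[1],
      poem_id = g$poem_id[1],
      line_no = g$line_no[1],
      npvi_soi = NA_real_,
      npvi_i_mean = NA_real_,
      tack_line = any(g$is_tack),
      tacks_per_line = sum(g$is_tack),
      n_sylls = nrow(g),
      stringsAsFactors = FALSE
    )
    for (extra in c("musical", "instruction", "meter")) {
      rec[[extra]] <- if (!is.null(g[[extra]])) g[[extra]][1] else NA_character_
    }
    if (nrow(usable) >= 2) {
      rec$npvi_soi <- npvi(usable$soi_ms)
      if (!is.null(usable$i_mean_db) && !anyNA(usable$i_mean_db)) {
        rec$npvi_i_mean <- npvi(usable$i_mean_db)
      }
    } else {
      n_short <<- n_short + 1L
    }
    rec
  })
  if (n_short > 0) {
    warning(n_short, " line(s) had fewer than 2 usable syllables; ",
            "their nPVI is missing", call. = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("line_record", "data.frame")
  out
}

#' Center (and optionally standardize) numeric covariates
#'
#' Adds a `<name>_c` column per requested variable with the mean removed;
#' with `standardize = TRUE` the column is also divided by its standard
#' deviation (the behaviour of `scale()` with defaults).  Original columns
#' are preserved.
#'
#' @param table data.frame.
#' @param variables names of numeric columns.
#' @param standardize divide by the SD as well (default `FALSE`, keeping
#'   coefficients on the original per-unit scale).
#' @return the table with the centered columns added.
#' @export
center_covariates <- function(table, variables, standardize = FALSE) {
  for (v in variables) {
    x <- table[[v]]
    if (is.null(x) || !is.numeric(x)) {
      stop_bad_arg("no numeric column '", v, "' to center")
    }
    if (standardize) {
      if (sd(x) == 0) {
        stop_bad_arg("cannot standardize zero-variance column '", v, "'")
      }
      table[[paste0(v, "_c")]] <- as.numeric(scale(x))
    } else {
      table[[paste0(v, "_c")]] <- x - mean(x)
    }
  }
  table
}
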