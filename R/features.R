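# Syllable onset intervals and exclusion rules --------------------------------

#' Compute syllable onset intervals (SOI) and durations
#'
#' Within each participant x poem x line, the SOI of a non-final syllable is
#' the time from its onset to the onset of the succeeding syllable, so any
#' within-line speaking pause is integrated into the SOI of the syllable
#' preceding it.  The line-final syllable's SOI equals its own duration: the
#' pause at the end of the line is excluded, but the syllable itself is kept
#' so line-level statistics can use all syllables of a line.
#'
#' @param tokens a syllable token table with `onset_s`/`offset_s` (from
#'   [simulate_syllables()] or [build_syllable_table()]); tokens must be
#'   sorted by onset within each line and non-overlapping.
#' @return the table with `duration_ms`, `soi_ms`, `line_final`, `excluded`
#'   (all `FALSE`) and `exclusion_reason` (`"none"`) columns added.
#' @examples
#' toks <- data.frame(participant_id = "p", poem_id = "x", line_no = 1,
#'                    onset_s = c(0, 0.25, 0.52), offset_s = c(0.25, 0.52, 0.8))
#' compute_soi(toks)$soi_ms   # 250 270 280
#' @export
compute_soi <- function(tokens) {
  tbl <- as.data.frame(tokens)
  if (!all(c("onset_s", "offset_s") %in% names(tbl))) {
    stop_bad_arg("token table needs onset_s and offset_s columns")
  }
  if (any(tbl$offset_s <= tbl$onset_s)) {
    stop_bad_arg("validation error: token with offset <= onset")
  }
  tbl$duration_ms <- (tbl$offset_s - tbl$onset_s) * 1000
  tbl$soi_ms <- NA_real_
  tbl$line_final <- FALSE
  key <- paste(tbl$participant_id, tbl$poem_id, tbl$line_no)
  groups <- split(seq_len(nrow(tbl)), factor(key, levels = unique(key)))
  for (sel in groups) {
    k <- key[sel[1]]
    on <- tbl$onset_s[sel]
    off <- tbl$offset_s[sel]
    if (is.unsorted(on, strictly = TRUE)) {
      stop_bad_arg("validation error: unsorted tokens in line ", k)
    }
    n <- length(sel)
    if (n > 1 && any(on[-1] < off[-n] - 1e-9)) {
      stop_bad_arg("validation error: overlapping tokens in line ", k)
    }
    soi <- c(diff(on) * 1000, tbl$duration_ms[sel[n]])
    tbl$soi_ms[sel] <- soi
    tbl$line_final[sel[n]] <- TRUE
  }
  tbl$excluded <- FALSE
  tbl$exclusion_reason <- "none"
  class(tbl) <- c("syllable_features", "data.frame")
  tbl
}

#' Flag syllables whose SOI exceeds a maximum
#'
#' All data where the SOI exceeds `max_ms` (strictly) are flagged for
#' exclusion with reason `"soi_over_max"`; an SOI of exactly `max_ms` is
#' retained.  The filter is idempotent and recomputes the flags from
#' `soi_ms`, so re-running it never changes the result.
#'
#' @param rows a `syllable_features` table from [compute_soi()].
#' @param max_ms threshold in milliseconds (default 2000).
#' @return the table with `excluded`/`exclusion_reason` updated.
#' @export
filter_max_soi <- function(rows, max_ms = 2000) {
  if (nrow(rows) == 0L) return(rows)
  if (is.null(rows$soi_ms)) stop_bad_arg("soi_ms not computed yet")
  over <- rows$soi_ms > max_ms
  rows$excluded <- over
  rows$exclusion_reason <- ifelse(over, "soi_over_max", "none")
  rows
}

#' Attach per-syllable mean intensity from an external table
#'
#' Joins mean-dB values (e.g. from a Praat intensity script's output) onto
#' the feature rows by interval identity.  Every feature row must have
#' exactly one intensity value; missing or duplicated keys are errors that
#' name the offending intervals.
#'
#' @param rows feature rows.
#' @param intensity data.frame with the key columns and `i_mean_db`.
#' @param key columns identifying an interval.
#' @return `rows` with `i_mean_db` populated.
#' @export
attach_intensity <- function(rows, intensity,
                             key = c("participant_id", "poem_id", "line_no",
                                     "syll_idx_in_line")) {
  if (!("i_mean_db" %in% names(intensity))) {
    stop_bad_arg("intensity table lacks an i_mean_db column")
  }
  kr <- do.call(paste, c(rows[key], sep = "\r"))
  ki <- do.call(paste, c(intensity[key], sep = "\r"))
  if (anyDuplicated(ki)) {
    dup <- ki[duplicated(ki)][1]
    stop_bad_arg("duplicate intensity key: ", gsub("\r", "/", dup))
  }
  idx <- match(kr, ki)
  if (anyNA(idx)) {
    miss <- unique(kr[is.na(idx)])
    stop_bad_arg("missing intensity for interval(s): ",
                 paste(gsub("\r", "/", head(miss, 5)), collapse = ", "),
                 if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
  }
  rows$i_mean_db <- intensity$i_mean_db[idx]
  rows
}
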