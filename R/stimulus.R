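# Metrical grids and tack substitution ---------------------------------------

METERS <- c("iambic", "trochaic")
STRESS_MARKS <- c("weak", "strong")

#' Build the alternating stress pattern of one verse line
#'
#' Iambic lines start weak (w, s, w, s, ...), trochaic lines start strong
#' (s, w, s, w, ...).  Odd line lengths truncate the pattern (catalexis).
#' @noRd
line_stress_pattern <- function(meter, n) {
  base <- if (meter == "iambic") c("weak", "strong") else c("strong", "weak")
  rep_len(base, n)
}

#' Build a metrical grid for a poem
#'
#' A poem is represented as a table of syllable slots, one row per slot, with
#' the stress mark implied by its meter: iambic lines alternate weak-strong
#' dyads, trochaic lines strong-weak.  Odd (catalectic) line lengths truncate
#' the final dyad.  Word indices group consecutive slots pairwise within a
#' line, mimicking the predominance of one- and two-syllable words in metered
#' German verse; the analysis only uses word identity as metadata.
#'
#' @param meter `"iambic"` or `"trochaic"`.
#' @param n_lines number of verse lines (>= 1).
#' @param sylls_per_line either a single count (>= 2) recycled over lines or a
#'   vector of per-line counts of length `n_lines`.
#' @param poem_id identifier stored in the `poem_id` column.
#'
#' @return A `data.frame` of class `"poem_spec"` with columns `poem_id`,
#'   `meter`, `line_no`, `word_idx`, `syll_idx_in_line`, `syll_idx_in_poem`,
#'   `label`, `stress` (`"weak"`/`"strong"`), `is_tack` (all `FALSE`) and
#'   `tack_index` (all `NA`).
#' @examples
#' grid <- build_grid("iambic", n_lines = 2, sylls_per_line = 8)
#' table(grid$stress, grid$line_no)
#' @export
build_grid <- function(meter, n_lines, sylls_per_line, poem_id = "poem") {
  meter <- match.arg(meter, METERS)
  if (length(n_lines) != 1L || is.na(n_lines) || n_lines < 1) {
    stop_bad_arg("n_lines must be a positive count")
  }
  n_lines <- as.integer(n_lines)
  if (length(sylls_per_line) == 1L) {
    sylls_per_line <- rep(as.integer(sylls_per_line), n_lines)
  }
  sylls_per_line <- as.integer(sylls_per_line)
  if (length(sylls_per_line) != n_lines || any(is.na(sylls_per_line)) ||
      any(sylls_per_line < 2)) {
    stop_bad_arg("sylls_per_line must give a count >= 2 for each of the ",
                 n_lines, " lines")
  }
  rows <- lapply(seq_len(n_lines), function(ln) {
    n <- sylls_per_line[ln]
    data.frame(
      poem_id = poem_id,
      meter = meter,
      line_no = ln,
      word_idx = ceiling(seq_len(n) / 2),
      syll_idx_in_line = seq_len(n),
      stress = line_stress_pattern(meter, n),
      stringsAsFactors = FALSE
    )
  })
  poem <- do.call(rbind, rows)
  poem$syll_idx_in_poem <- seq_len(nrow(poem))
  poem$label <- sprintf("syl%03d", poem$syll_idx_in_poem)
  poem$is_tack <- FALSE
  poem$tack_index <- NA_integer_
  poem <- poem[, c("poem_id", "meter", "line_no", "word_idx",
                   "syll_idx_in_line", "syll_idx_in_poem", "label",
                   "stress", "is_tack", "tack_index")]
  class(poem) <- c("poem_spec", "data.frame")
  poem
}

#' Assign per-line ordinal tack indices from the is_tack flags
#' @noRd
recount_tack_index <- function(poem) {
  poem$tack_index <- NA_integer_
  for (ln in unique(poem$line_no)) {
    sel <- which(poem$line_no == ln & poem$is_tack)
    if (length(sel)) poem$tack_index[sel] <- seq_along(sel)
  }
  poem
}

#' Substitute grid slots with the nonsense syllable "tack"
#'
#' Tacks are placed at random positions and occur in random number within a
#' line: each eligible slot is substituted independently with probability
#' `rate`, capped at `max_per_line` tacks per line (when more are drawn, the
#' slots with the smallest substitution draws are kept, so the result is
#' deterministic under a fixed seed).  Lines before `min_line` are never
#' touched, reflecting the stimulus-construction rule that tacked lines start
#' no earlier than the third verse.
#'
#' Substitution replaces the slot label with `"tack"` and sets `is_tack`;
#' stress marks, line and word indices are never altered.  `tack_index` is the
#' 1-based ordinal of a tack among the tacks of its line.
#'
#' @param poem a `poem_spec` from [build_grid()].
#' @param rate per-slot substitution probability in `[0, 1]`.
#' @param seed integer seed; substitution is reproducible given the seed.
#' @param min_line first line (1-based) eligible for tacks; default 3.
#' @param max_per_line cap on tacks per line; default 5.
#' @return the poem with tack slots substituted.
#' @examples
#' poem <- build_grid("trochaic", 6, 8)
#' tacked <- place_tacks(poem, rate = 0.2, seed = 42)
#' table(tacked$is_tack, tacked$line_no)
#' @export
place_tacks <- function(poem, rate, seed, min_line = 3L, max_per_line = 5L) {
  stopifnot(inherits(poem, "poem_spec"))
  if (length(rate) != 1L || is.na(rate) || rate < 0 || rate > 1) {
    stop_bad_arg("rate must be a probability in [0, 1]")
  }
  set.seed(as.integer(seed))
  u <- runif(nrow(poem))
  eligible <- poem$line_no >= min_line
  hit <- eligible & (u < rate)
  for (ln in unique(poem$line_no[hit])) {
    sel <- which(hit & poem$line_no == ln)
    if (length(sel) > max_per_line) {
      keep <- sel[order(u[sel])][seq_len(max_per_line)]
      hit[setdiff(sel, keep)] <- FALSE
    }
  }
  poem$is_tack <- hit
  poem$label[hit] <- "tack"
  recount_tack_index(poem)
}

# Study stimuli ---------------------------------------------------------------

# Line-length layouts for the six study poems.  Syllable totals are the
# published stimulus sizes (273, 270, 76, 68, 154, 150); line counts sum to
# 120 lines per participant.  C2 is partly catalectic (7-syllable lines).
study_poem_layouts <- function() {
  list(
    A1 = list(meter = "iambic",   lines = c(rep(8L, 33), 9L)),            # 273
    D2 = list(meter = "trochaic", lines = c(rep(8L, 27), rep(9L, 6))),    # 270
    C2 = list(meter = "trochaic", lines = c(rep(8L, 6), rep(7L, 4))),     # 76
    D1 = list(meter = "iambic",   lines = c(rep(8L, 4), rep(9L, 4))),     # 68
    E1 = list(meter = "iambic",   lines = c(rep(8L, 17), rep(9L, 2))),    # 154
    F2 = list(meter = "trochaic", lines = c(rep(9L, 10), rep(10L, 6)))    # 150
  )
}

#' The six study poems as tacked metrical grids
#'
#' Builds the stimulus set of the reading study: six poems (three iambic —
#' A1, D1, E1 — and three trochaic — C2, D2, F2) with the published syllable
#' totals 273, 270, 76, 68, 154 and 150, i.e. 991 syllable slots over 120
#' verse lines.  Tacks are then placed with [place_tacks()] (earliest in line
#' 3, at most 5 per line), using one sub-seed per poem derived from `seed`.
#'
#' @param tack_rate per-slot substitution probability; the default 0.18
#'   reproduces the study's overall tack share (roughly 150-160 tack syllables
#'   per reading of the full set) and the observed 0-5 tacks-per-line range.
#' @param seed integer seed for tack placement.
#' @return named list of six `poem_spec` objects.
#' @export
study_poems <- function(tack_rate = 0.18, seed = 20210901L) {
  layouts <- study_poem_layouts()
  poems <- vector("list", length(layouts))
  names(poems) <- names(layouts)
  for (i in seq_along(layouts)) {
    id <- names(layouts)[i]
    lay <- layouts[[i]]
    poem <- build_grid(lay$meter, length(lay$lines), lay$lines, poem_id = id)
    poems[[i]] <- place_tacks(poem, rate = tack_rate,
                              seed = as.integer(seed) + i)
  }
  poems
}

# Serialization ---------------------------------------------------------------

#' Write / read a poem grid as tab-separated text
#'
#' @param poem a `poem_spec`.
#' @param path file path.
#' @return `read_poem_spec()` returns the `poem_spec`; `write_poem_spec()`
#'   returns `path` invisibly.
#' @export
write_poem_spec <- function(poem, path) {
  stopifnot(inherits(poem, "poem_spec"))
  write.table(as.data.frame(poem), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_poem_spec
#' @export
read_poem_spec <- function(path) {
  poem <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  needed <- c("poem_id", "meter", "line_no", "word_idx", "syll_idx_in_line",
              "syll_idx_in_poem", "label", "stress", "is_tack", "tack_index")
  missing <- setdiff(needed, names(poem))
  if (length(missing)) {
    stop_bad_arg("poem spec file lacks columns: ",
                 paste(missing, collapse = ", "))
  }
  poem <- poem[, needed]
  poem$is_tack <- as.logical(poem$is_tack)
  poem$tack_index <- as.integer(poem$tack_index)
  class(poem) <- c("poem_spec", "data.frame")
  poem
}
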