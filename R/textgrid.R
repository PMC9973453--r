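# Praat TextGrid reading and writing -----------------------------------------
#
# Both text dialects of the format are supported: the "long" dialect with
# `key = value` lines and the "short" dialect with bare values, in UTF-8 or
# UTF-16 (BOM-detected).  Only interval tiers are returned; point tiers are
# skipped with a warning.

#' Construct an interval tier
#'
#' @param name tier name.
#' @param xmin,xmax,text vectors describing the intervals (times in seconds).
#' @return list of class `"interval_tier"` with fields `name` and
#'   `intervals` (a data.frame with columns `xmin`, `xmax`, `text`).
#' @export
interval_tier <- function(name, xmin, xmax, text) {
  tier <- list(name = as.character(name),
               intervals = data.frame(xmin = as.numeric(xmin),
                                      xmax = as.numeric(xmax),
                                      text = as.character(text),
                                      stringsAsFactors = FALSE))
  class(tier) <- "interval_tier"
  validate_tier(tier)
  tier
}

validate_tier <- function(tier) {
  iv <- tier$intervals
  bad <- which(!(iv$xmin < iv$xmax))
  if (length(bad)) {
    stop_bad_arg("tier '", tier$name, "': interval ", bad[1],
                 " has xmax <= xmin (", iv$xmax[bad[1]], " <= ",
                 iv$xmin[bad[1]], ")")
  }
  if (nrow(iv) > 1) {
    ov <- which(iv$xmin[-1] < iv$xmax[-nrow(iv)] - 1e-12)
    if (length(ov)) {
      stop_bad_arg("tier '", tier$name, "': intervals ", ov[1], " and ",
                   ov[1] + 1, " overlap or are unsorted")
    }
  }
  invisible(tier)
}

# -- encoding-aware line IO ---------------------------------------------------

read_lines_enc <- function(path) {
  head_raw <- readBin(path, "raw", n = 3L)
  enc <- "UTF-8"
  if (length(head_raw) >= 2) {
    if (head_raw[1] == as.raw(0xFF) && head_raw[2] == as.raw(0xFE)) enc <- "UTF-16"
    else if (head_raw[1] == as.raw(0xFE) && head_raw[2] == as.raw(0xFF)) enc <- "UTF-16"
  }
  con <- file(path, encoding = enc)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines)) lines[1] <- sub("^\ufeff", "", lines[1])
  lines
}

write_lines_enc <- function(lines, path, encoding = c("UTF-8", "UTF-16")) {
  encoding <- match.arg(encoding)
  txt <- paste0(paste(enc2utf8(lines), collapse = "\n"), "\n")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (encoding == "UTF-8") {
    writeBin(charToRaw(txt), con)
  } else {
    raw16 <- iconv(txt, from = "UTF-8", to = "UTF-16LE", toRaw = TRUE)[[1]]
    writeBin(c(as.raw(c(0xFF, 0xFE)), raw16), con)
  }
  invisible(path)
}

# -- parsing helpers ----------------------------------------------------------

tg_unquote <- function(s) {
  s <- sub('^\\s*"', "", s)
  s <- sub('"\\s*$', "", s)
  gsub('""', '"', s)
}

tg_quote <- function(s) paste0('"', gsub('"', '""', s), '"')

tg_num <- function(s, lineno) {
  v <- suppressWarnings(as.numeric(trimws(s)))
  if (is.na(v)) {
    stop_bad_arg("TextGrid parse error at line ", lineno,
                 ": expected a number, got '", trimws(s), "'")
  }
  v
}

fmt_time <- function(x) sprintf("%.15g", x)

#' Read a Praat TextGrid file
#'
#' Parses both the long (`key = value`) and short text dialects, in UTF-8 or
#' UTF-16 (byte-order mark detected).  Interval tiers are returned as
#' [interval_tier()] objects and validated (each interval must have
#' `xmin < xmax`; intervals must be sorted and non-overlapping).  Point tiers
#' are skipped with a warning.
#'
#' @param path path to a `.TextGrid` file.
#' @return list of `interval_tier` objects, named by tier name.
#' @export
read_textgrid <- function(path) {
  lines <- read_lines_enc(path)
  if (length(lines) < 2 || !grepl("ooTextFile", lines[1]) ||
      !grepl("TextGrid", lines[2])) {
    stop_bad_arg("TextGrid parse error at line 1: not an ooTextFile TextGrid header")
  }
  body <- lines[-(1:2)]
  body_no <- seq_along(body) + 2L
  keep <- trimws(body) != ""
  body <- body[keep]
  body_no <- body_no[keep]
  long <- any(grepl("^\\s*xmin\\s*=", body))
  tiers <- if (long) parse_tg_long(body, body_no) else parse_tg_short(body, body_no)
  tiers <- Filter(Negate(is.null), tiers)
  for (t in tiers) validate_tier(t)
  names(tiers) <- vapply(tiers, function(t) t$name, character(1))
  tiers
}

parse_tg_long <- function(body, body_no) {
  i <- 1L
  nextval <- function(key, quoted = FALSE) {
    while (i <= length(body) && !grepl(paste0("^\\s*", key, "\\s*[=:]"), body[i])) {
      i <<- i + 1L
    }
    if (i > length(body)) {
      stop_bad_arg("TextGrid parse error: expected '", key,
                   "' after line ", body_no[min(i - 1L, length(body_no))])
    }
    # quoted values: strip up to the FIRST '='; numeric: up to the LAST '='
    val <- if (quoted) sub("^[^=]*=\\s*", "", body[i])
           else sub("^.*=\\s*", "", body[i])
    i <<- i + 1L
    val
  }
  tg_xmin <- tg_num(nextval("xmin"), body_no[i - 1L])
  tg_xmax <- tg_num(nextval("xmax"), body_no[i - 1L])
  n_tiers <- as.integer(tg_num(nextval("size"), body_no[i - 1L]))
  tiers <- vector("list", n_tiers)
  for (t in seq_len(n_tiers)) {
    klass <- tg_unquote(nextval("class", quoted = TRUE))
    name <- tg_unquote(nextval("name", quoted = TRUE))
    nextval("xmin"); nextval("xmax")
    if (klass == "IntervalTier") {
      n_iv <- as.integer(tg_num(nextval("intervals"), body_no[i - 1L]))
      xmin <- xmax <- numeric(n_iv); text <- character(n_iv)
      for (k in seq_len(n_iv)) {
        xmin[k] <- tg_num(nextval("xmin"), body_no[i - 1L])
        xmax[k] <- tg_num(nextval("xmax"), body_no[i - 1L])
        text[k] <- tg_unquote(nextval("text", quoted = TRUE))
      }
      tiers[[t]] <- interval_tier(name, xmin, xmax, text)
    } else {
      n_pt <- as.integer(tg_num(nextval("points"), body_no[i - 1L]))
      for (k in seq_len(n_pt)) { nextval("number"); nextval("mark", quoted = TRUE) }
      warning("skipping point tier '", name, "'", call. = FALSE)
      tiers[[t]] <- NULL
    }
  }
  tiers
}

parse_tg_short <- function(body, body_no) {
  i <- 1L
  take <- function() {
    if (i > length(body)) stop_bad_arg("TextGrid parse error: unexpected end of file")
    v <- body[i]; i <<- i + 1L
    v
  }
  take(); take()                     # file xmin, xmax
  take()                             # <exists>
  n_tiers <- as.integer(tg_num(take(), body_no[i - 1L]))
  tiers <- vector("list", n_tiers)
  for (t in seq_len(n_tiers)) {
    klass <- tg_unquote(take())
    name <- tg_unquote(take())
    take(); take()                   # tier xmin, xmax
    n_items <- as.integer(tg_num(take(), body_no[i - 1L]))
    if (klass == "IntervalTier") {
      xmin <- xmax <- numeric(n_items); text <- character(n_items)
      for (k in seq_len(n_items)) {
        xmin[k] <- tg_num(take(), body_no[i - 1L])
        xmax[k] <- tg_num(take(), body_no[i - 1L])
        text[k] <- tg_unquote(take())
      }
      tiers[[t]] <- interval_tier(name, xmin, xmax, text)
    } else {
      for (k in seq_len(n_items)) { take(); take() }
      warning("skipping point tier '", name, "'", call. = FALSE)
      tiers[[t]] <- NULL
    }
  }
  tiers
}

#' Write tiers to a Praat TextGrid file
#'
#' @param tiers list of [interval_tier()] objects.
#' @param path output path.
#' @param dialect `"long"` (key = value) or `"short"` (bare values).
#' @param encoding `"UTF-8"` or `"UTF-16"` (little-endian with BOM).
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(tiers, path, dialect = c("long", "short"),
                           encoding = c("UTF-8", "UTF-16")) {
  dialect <- match.arg(dialect)
  encoding <- match.arg(encoding)
  if (inherits(tiers, "interval_tier")) tiers <- list(tiers)
  for (t in tiers) validate_tier(t)
  xmin <- min(vapply(tiers, function(t) min(t$intervals$xmin), numeric(1)))
  xmax <- max(vapply(tiers, function(t) max(t$intervals$xmax), numeric(1)))
  out <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "")
  if (dialect == "long") {
    out <- c(out,
             paste0("xmin = ", fmt_time(xmin)),
             paste0("xmax = ", fmt_time(xmax)),
             "tiers? <exists> ",
             paste0("size = ", length(tiers)),
             "item []: ")
    for (t in seq_along(tiers)) {
      tier <- tiers[[t]]
      iv <- tier$intervals
      out <- c(out,
               sprintf("    item [%d]:", t),
               '        class = "IntervalTier" ',
               paste0("        name = ", tg_quote(tier$name), " "),
               paste0("        xmin = ", fmt_time(min(iv$xmin))),
               paste0("        xmax = ", fmt_time(max(iv$xmax))),
               paste0("        intervals: size = ", nrow(iv)))
      for (k in seq_len(nrow(iv))) {
        out <- c(out,
                 sprintf("        intervals [%d]:", k),
                 paste0("            xmin = ", fmt_time(iv$xmin[k])),
                 paste0("            xmax = ", fmt_time(iv$xmax[k])),
                 paste0("            text = ", tg_quote(iv$text[k]), " "))
      }
    }
  } else {
    out <- c(out, fmt_time(xmin), fmt_time(xmax), "<exists>",
             as.character(length(tiers)))
    for (tier in tiers) {
      iv <- tier$intervals
      out <- c(out, '"IntervalTier"', tg_quote(tier$name),
               fmt_time(min(iv$xmin)), fmt_time(max(iv$xmax)),
               as.character(nrow(iv)))
      for (k in seq_len(nrow(iv))) {
        out <- c(out, fmt_time(iv$xmin[k]), fmt_time(iv$xmax[k]),
                 tg_quote(iv$text[k]))
      }
    }
  }
  write_lines_enc(out, path, encoding)
}

# -- syllable table construction ----------------------------------------------

#' Build the chronological syllable table from an annotated TextGrid
#'
#' Matches the non-empty intervals of the syllable tier, in chronological
#' order, to the syllable slots of the poem grid, and carries the stress,
#' tack and position metadata of each slot onto its token.  Empty-label
#' intervals are pauses and are skipped.  In strict mode (default) the
#' labeled-interval count must equal the slot count and every label must
#' agree; in lenient mode slots without a matching interval (e.g. a tack
#' omitted during oral reading) are dropped with a warning and matching
#' proceeds by label.
#'
#' @param tiers list of tiers from [read_textgrid()].
#' @param poem the `poem_spec` the recording realises.
#' @param participant one-row data.frame with at least `participant_id`
#'   (typically a [participant_profile()]).
#' @param tier_name name of the syllable tier; by default the first tier
#'   whose name contains "syll" (or the only tier).
#' @param strict strict (TRUE) or lenient (FALSE) alignment.
#' @return a `syllable_table` data.frame, one row per realised syllable
#'   token, sorted by onset, with `tack_index` recounted left-to-right
#'   within each line over the realised tacks.
#' @export
build_syllable_table <- function(tiers, poem, participant,
                                 tier_name = NULL, strict = TRUE) {
  stopifnot(inherits(poem, "poem_spec"))
  if (is.null(tier_name)) {
    hit <- grep("syll", names(tiers), ignore.case = TRUE)
    if (length(hit)) tier_name <- names(tiers)[hit[1]]
    else if (length(tiers) == 1L) tier_name <- names(tiers)[1]
    else stop_bad_arg("cannot identify the syllable tier among: ",
                      paste(names(tiers), collapse = ", "))
  }
  tier <- tiers[[tier_name]]
  if (is.null(tier)) stop_bad_arg("no tier named '", tier_name, "'")
  iv <- tier$intervals
  iv <- iv[trimws(iv$text) != "", , drop = FALSE]

  slots <- as.data.frame(poem)
  n_iv <- nrow(iv); n_slot <- nrow(slots)
  if (strict) {
    if (n_iv != n_slot) {
      div <- which(iv$text[seq_len(min(n_iv, n_slot))] !=
                     slots$label[seq_len(min(n_iv, n_slot))])
      stop_bad_arg("alignment error: ", n_iv, " labeled intervals vs ",
                   n_slot, " poem slots (first divergence at position ",
                   if (length(div)) div[1] else min(n_iv, n_slot) + 1L, ")")
    }
    div <- which(iv$text != slots$label)
    if (length(div)) {
      stop_bad_arg("alignment error: label mismatch at position ", div[1],
                   " ('", iv$text[div[1]], "' vs slot '",
                   slots$label[div[1]], "')")
    }
    match_slot <- seq_len(n_slot)
    match_iv <- seq_len(n_iv)
  } else {
    # greedy label alignment allowing omitted slots
    match_slot <- integer(0); match_iv <- integer(0)
    si <- 1L
    for (k in seq_len(n_iv)) {
      while (si <= n_slot && slots$label[si] != iv$text[k]) si <- si + 1L
      if (si > n_slot) {
        stop_bad_arg("alignment error: interval ", k, " ('", iv$text[k],
                     "') matches no remaining poem slot")
      }
      match_slot <- c(match_slot, si)
      match_iv <- c(match_iv, k)
      si <- si + 1L
    }
    n_unmatched <- n_slot - length(match_slot)
    if (n_unmatched > 0) {
      warning(n_unmatched, " poem slot(s) had no realised syllable token",
              call. = FALSE)
    }
  }

  tok <- slots[match_slot, , drop = FALSE]
  tok$onset_s <- iv$xmin[match_iv]
  tok$offset_s <- iv$xmax[match_iv]
  tok$participant_id <- participant$participant_id[1]
  for (extra in c("musical", "instruction")) {
    tok[[extra]] <- if (!is.null(participant[[extra]])) {
      participant[[extra]][1]
    } else NA_character_
  }
  tok$syllable_id <- paste0(tok$poem_id, ":", tok$label, ":",
                            ifelse(tok$is_tack, tok$syll_idx_in_poem, 0L))
  tok$syllable_id[tok$is_tack] <- NA_character_
  tok <- tok[order(tok$onset_s), , drop = FALSE]
  # recount tack ordinals over realised tokens
  tok$tack_index <- NA_integer_
  for (ln in unique(tok$line_no)) {
    sel <- which(tok$line_no == ln & tok$is_tack)
    if (length(sel)) tok$tack_index[sel] <- seq_along(sel)
  }
  rownames(tok) <- NULL
  tok <- tok[, c("participant_id", "musical", "instruction", "poem_id",
                 "meter", "line_no", "word_idx", "syll_idx_in_line",
                 "syll_idx_in_poem", "label", "syllable_id", "stress",
                 "is_tack", "tack_index", "onset_s", "offset_s")]
  class(tok) <- c("syllable_table", "data.frame")
  tok
}

#' Serialize a syllable token table as TextGrid files
#'
#' Writes one TextGrid per participant x poem recording, with a single
#' interval tier `"syllables"` in which syllable tokens carry their label and
#' gaps between tokens become empty-label pause intervals (the convention of
#' forced-alignment output).  Times are already microsecond-rounded by the
#' simulator, so re-ingesting the files reproduces the token table exactly.
#'
#' @param tokens a syllable token table with times.
#' @param dir output directory (created if needed).
#' @param dialect,encoding passed to [write_textgrid()].
#' @return manifest data.frame with `participant_id`, `poem_id`, `path`.
#' @export
emit_textgrids <- function(tokens, dir, dialect = "long", encoding = "UTF-8") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keys <- unique(tokens[, c("participant_id", "poem_id")])
  paths <- character(nrow(keys))
  for (r in seq_len(nrow(keys))) {
    sel <- tokens$participant_id == keys$participant_id[r] &
      tokens$poem_id == keys$poem_id[r]
    tk <- tokens[sel, , drop = FALSE]
    tk <- tk[order(tk$onset_s), , drop = FALSE]
    xmin <- c(tk$onset_s)
    xmax <- c(tk$offset_s)
    text <- tk$label
    # fill gaps with empty pause intervals
    gap_from <- tk$offset_s[-nrow(tk)]
    gap_to <- tk$onset_s[-1]
    has_gap <- which(gap_to > gap_from + 1e-9)
    if (length(has_gap)) {
      xmin <- c(xmin, gap_from[has_gap])
      xmax <- c(xmax, gap_to[has_gap])
      text <- c(text, rep("", length(has_gap)))
    }
    o <- order(xmin)
    tier <- interval_tier("syllables", xmin[o], xmax[o], text[o])
    paths[r] <- file.path(dir, sprintf("%s_%s.TextGrid",
                                       keys$participant_id[r],
                                       keys$poem_id[r]))
    write_textgrid(list(tier), paths[r], dialect = dialect,
                   encoding = encoding)
  }
  data.frame(participant_id = keys$participant_id,
             poem_id = keys$poem_id, path = paths,
             stringsAsFactors = FALSE)
}
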