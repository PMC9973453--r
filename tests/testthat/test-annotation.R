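test_that("TextGrids round-trip across dialects and encodings", {
  tier <- interval_tier("syllables",
                        xmin = c(0, 0.5, 1.25),
                        xmax = c(0.5, 1.25, 2.0),
                        text = c("grün", 'sagt "tack"', ""))
  words <- interval_tier("words", xmin = 0, xmax = 2.0, text = "zeile")
  for (dialect in c("long", "short")) {
    for (encoding in c("UTF-8", "UTF-16")) {
      path <- tempfile(fileext = ".TextGrid")
      write_textgrid(list(tier, words), path, dialect = dialect,
                     encoding = encoding)
      back <- read_textgrid(path)
      expect_named(back, c("syllables", "words"))
      expect_equal(back$syllables$intervals, tier$intervals,
                   info = paste(dialect, encoding))
      expect_equal(back$words$intervals, words$intervals)
      unlink(path)
    }
  }
})

test_that("long and short encodings of the same annotation parse identically", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(2:12, 1)
    bounds <- round(cumsum(runif(n + 1, 0.05, 0.6)), 6)
    tier <- interval_tier("syll", bounds[-(n + 1)], bounds[-1],
                          text = replicate(n, paste(sample(letters, 3),
                                                    collapse = "")))
    p1 <- tempfile(); p2 <- tempfile()
    write_textgrid(list(tier), p1, dialect = "long")
    write_textgrid(list(tier), p2, dialect = "short")
    expect_equal(read_textgrid(p1), read_textgrid(p2))
    unlink(c(p1, p2))
  }
})

test_that("invalid intervals are rejected with the offending index", {
  expect_error(interval_tier("t", xmin = c(0, 1), xmax = c(0.5, 0.9),
                             text = c("a", "b")),
               "interval 2")
  expect_error(interval_tier("t", xmin = c(0, 0.3), xmax = c(0.5, 0.9),
                             text = c("a", "b")),
               "overlap")
  # a malformed file: xmax before xmin in the second interval
  path <- tempfile()
  writeLines(c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
               "xmin = 0", "xmax = 1", "tiers? <exists>", "size = 1",
               "item []:", "item [1]:", 'class = "IntervalTier"',
               'name = "syll"', "xmin = 0", "xmax = 1",
               "intervals: size = 2",
               "intervals [1]:", "xmin = 0", "xmax = 0.6", 'text = "a"',
               "intervals [2]:", "xmin = 0.6", "xmax = 0.2", 'text = "b"'),
             path)
  expect_error(read_textgrid(path), "interval 2")
  unlink(path)
})

test_that("malformed numbers raise a parse error with a line reference", {
  path <- tempfile()
  writeLines(c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
               "xmin = 0", "xmax = oops", "tiers? <exists>", "size = 0"),
             path)
  expect_error(read_textgrid(path), "line")
  unlink(path)
})

test_that("point tiers are skipped with a warning", {
  path <- tempfile()
  writeLines(c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
               "xmin = 0", "xmax = 1", "tiers? <exists>", "size = 2",
               "item []:", "item [1]:", 'class = "TextTier"',
               'name = "beats"', "xmin = 0", "xmax = 1",
               "points: size = 1", "points [1]:", "number = 0.5",
               'mark = "x"',
               "item [2]:", 'class = "IntervalTier"', 'name = "syll"',
               "xmin = 0", "xmax = 1", "intervals: size = 1",
               "intervals [1]:", "xmin = 0", "xmax = 1", 'text = "a"'),
             path)
  expect_warning(tiers <- read_textgrid(path), "point tier")
  expect_named(tiers, "syll")
  unlink(path)
})

test_that("syllable tables carry slot metadata and per-line tack ordinals", {
  poem <- build_grid("iambic", 1, 8, poem_id = "p1")
  poem$is_tack[c(2, 5)] <- TRUE
  poem$label[c(2, 5)] <- "tack"
  poem <- verserhythm:::recount_tack_index(poem)
  bounds <- seq(0, 2, by = 0.25)
  tier <- interval_tier("syllables", bounds[1:8], bounds[2:9], poem$label)
  prof <- participant_profile("P01", "yes", "daily")
  tok <- build_syllable_table(list(syllables = tier), poem, prof)
  expect_equal(nrow(tok), 8L)
  expect_equal(tok$syll_idx_in_line, 1:8)
  expect_equal(tok$stress, poem$stress)
  expect_equal(tok$tack_index[tok$is_tack], c(1L, 2L))
  expect_equal(tok$onset_s, bounds[1:8])
  # pauses (empty labels) are skipped, not matched
  tier2 <- interval_tier("syllables",
                         c(bounds[1:8], 2.0), c(bounds[2:9], 2.4),
                         c(poem$label, ""))
  tok2 <- build_syllable_table(list(syllables = tier2), poem, prof)
  expect_equal(nrow(tok2), 8L)
})

test_that("strict alignment rejects count and label mismatches; lenient recovers omissions", {
  poem <- build_grid("iambic", 1, 8, poem_id = "p1")
  poem$is_tack[5] <- TRUE
  poem$label[5] <- "tack"
  poem <- verserhythm:::recount_tack_index(poem)
  prof <- participant_profile("P02", "no")
  bounds <- seq(0, 2, by = 0.25)

  # the tack was omitted during reading: only 7 realised syllables
  realised <- poem$label[-5]
  tier <- interval_tier("syllables", bounds[1:7], bounds[2:8], realised)
  expect_error(build_syllable_table(list(syllables = tier), poem, prof),
               "7 labeled intervals vs 8 poem slots")
  expect_warning(
    tok <- build_syllable_table(list(syllables = tier), poem, prof,
                                strict = FALSE),
    "1 poem slot"
  )
  expect_equal(nrow(tok), 7L)
  expect_false(any(tok$is_tack))
  expect_equal(tok$syll_idx_in_line, c(1:4, 6:8))

  # equal counts but diverging label
  tier3 <- interval_tier("syllables", bounds[1:8], bounds[2:9],
                         c(poem$label[1:4], "xyz", poem$label[6:8]))
  expect_error(build_syllable_table(list(syllables = tier3), poem, prof),
               "position 5")
})

test_that("token spans never exceed the recording span", {
  tok <- simulate_novar()
  tok <- inject_pauses(tok, seed = 8)
  for (key in unique(paste(tok$participant_id, tok$poem_id))) {
    sel <- paste(tok$participant_id, tok$poem_id) == key
    span <- max(tok$offset_s[sel]) - min(tok$onset_s[sel])
    expect_lte(sum(tok$offset_s[sel] - tok$onset_s[sel]), span + 1e-9)
  }
})

test_that("generator-emitted TextGrids re-ingest to the identical token table", {
  poems <- two_small_poems()
  pp <- four_participants()
  tok <- simulate_syllables(poems, pp, seed = 21)
  tok <- inject_pauses(tok, seed = 22)
  dir <- tempfile()
  manifest <- emit_textgrids(tok, dir)
  expect_equal(nrow(manifest), 8L)  # 4 participants x 2 poems
  back <- list()
  for (r in seq_len(nrow(manifest))) {
    tiers <- read_textgrid(manifest$path[r])
    prof <- pp[pp$participant_id == manifest$participant_id[r], ]
    back[[r]] <- build_syllable_table(tiers, poems[[manifest$poem_id[r]]],
                                      prof)
  }
  back <- do.call(rbind, back)
  ord <- function(d) {
    d <- d[order(d$participant_id, d$poem_id, d$onset_s), ]
    rownames(d) <- NULL
    d
  }
  cols <- c("participant_id", "poem_id", "line_no", "syll_idx_in_line",
            "label", "stress", "is_tack", "tack_index", "onset_s", "offset_s")
  expect_equal(as.data.frame(ord(back))[cols],
               ord(as.data.frame(tok))[cols])
  unlink(dir, recursive = TRUE)
})
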