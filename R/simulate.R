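# Synthetic oral reader -------------------------------------------------------

code_binary <- function(x, positive) ifelse(x == positive, 1, -1)

#' Sum codes used throughout the package (+1 level first)
#' @noRd
standard_codes <- function(tbl) {
  codes <- list()
  if (!is.null(tbl$stress))  codes$stress  <- code_binary(tbl$stress, "strong")
  if (!is.null(tbl$musical)) codes$musical <- code_binary(tbl$musical, "active")
  if (!is.null(tbl$meter))   codes$meter   <- code_binary(tbl$meter, "iambic")
  if (!is.null(tbl$tack_index)) {
    ti <- tbl$tack_index
    ti[is.na(ti)] <- 0
    codes$tack_index <- as.numeric(ti)
  }
  if (!is.null(tbl$tack_line)) {
    # lines WITHOUT a tack carry the +1 code
    codes$tack_line <- ifelse(tbl$tack_line, -1, 1)
  }
  if (!is.null(tbl$tacks_per_line)) {
    codes$tacks_per_line <- tbl$tacks_per_line - mean(tbl$tacks_per_line)
  }
  codes
}

#' Simulate per-syllable onset intervals and intensities
#'
#' Generates one synthetic reading of each poem by each participant from the
#' hierarchical linear structure of the study's syllable-level models: for
#' every syllable the expected response is the sum-coded fixed-effects
#' predictor plus a participant random intercept, a participant stress slope
#' (times the stress code), a syllable random intercept (regular syllables
#' only — tack rows carry no syllable intercept, mirroring the tack model
#' structure) and Gaussian residual noise.  Regular and tack syllables are
#' generated from their own parameter sets, as are the SOI and intensity
#' responses.
#'
#' Onset/offset times are laid out contiguously from the generated SOIs
#' (each syllable's duration equals its SOI, floored at 1 ms so times stay
#' strictly increasing) and rounded to microsecond precision, the grain used
#' when serializing TextGrids.  Pause structure is added separately by
#' [inject_pauses()].
#'
#' @param poems list of `poem_spec` objects (see [study_poems()]).
#' @param participants data.frame of profiles (see [study_participants()]).
#' @param seed integer seed; output is reproducible given the seed.
#' @param params_soi,params_intensity parameters for regular syllables.
#' @param params_tack_soi,params_tack_intensity parameters for tack
#'   syllables.
#' @param round_times round times to microseconds (default TRUE; disable for
#'   exact algebraic checks).
#' @return a syllable token table: one row per syllable with stimulus
#'   metadata, `onset_s`/`offset_s` times and `i_mean_db`.
#' @export
simulate_syllables <- function(poems, participants, seed,
                               params_soi = generative_params("regular_soi"),
                               params_intensity = generative_params("regular_intensity"),
                               params_tack_soi = generative_params("tack_soi"),
                               params_tack_intensity = generative_params("tack_intensity"),
                               round_times = TRUE) {
  set.seed(as.integer(seed))
  if (inherits(poems, "poem_spec")) poems <- list(poems)
  stim <- do.call(rbind, lapply(poems, as.data.frame))
  stim$syllable_id <- paste0(stim$poem_id, ":", stim$label, ":",
                             ifelse(stim$is_tack, stim$syll_idx_in_poem, 0L))
  stim$syllable_id[stim$is_tack] <- NA_character_

  n_part <- nrow(participants)
  tbl <- stim[rep(seq_len(nrow(stim)), times = n_part), , drop = FALSE]
  tbl$participant_id <- rep(participants$participant_id, each = nrow(stim))
  tbl$musical <- rep(participants$musical, each = nrow(stim))
  tbl$instruction <- rep(participants$instruction, each = nrow(stim))
  rownames(tbl) <- NULL

  param_sets <- list(soi_ms = list(regular = params_soi,
                                   tack = params_tack_soi),
                     i_mean_db = list(regular = params_intensity,
                                      tack = params_tack_intensity))
  syll_levels <- unique(stim$syllable_id[!stim$is_tack])
  codes <- standard_codes(tbl)
  is_tack <- tbl$is_tack

  for (resp in names(param_sets)) {
    y <- numeric(nrow(tbl))
    for (subset in c("regular", "tack")) {
      p <- param_sets[[resp]][[subset]]
      idx <- if (subset == "regular") !is_tack else is_tack
      # participant (intercept, slope) pairs -- drawn per parameter set
      re <- draw_re_pairs(n_part, p$participant_re$intercept_sd,
                          p$participant_re$slope_sd, p$participant_re$corr)
      rownames(re) <- participants$participant_id
      syll_re <- NULL
      if (!is.null(p$syllable_re_sd)) {
        syll_re <- setNames(rnorm(length(syll_levels), 0, p$syllable_re_sd),
                            syll_levels)
      }
      sub_codes <- lapply(codes, `[`, idx)
      lp <- linear_predictor(p$fixed_effects, sub_codes, sum(idx))
      slope_code <- eval_term(p$participant_re$slope_term, sub_codes, sum(idx))
      pid <- tbl$participant_id[idx]
      yy <- lp + re[pid, "intercept"] + re[pid, "slope"] * slope_code
      if (!is.null(syll_re)) yy <- yy + syll_re[tbl$syllable_id[idx]]
      yy <- yy + rnorm(sum(idx), 0, p$resid_sd)
      y[idx] <- yy
    }
    tbl[[resp]] <- y
  }

  # lay out contiguous times per recording; duration = SOI floored at 1 ms
  dur_s <- pmax(tbl$soi_ms, 1) / 1000
  tbl$onset_s <- NA_real_
  tbl$offset_s <- NA_real_
  for (key in unique(paste(tbl$participant_id, tbl$poem_id))) {
    sel <- which(paste(tbl$participant_id, tbl$poem_id) == key)
    on <- cumsum(c(0, dur_s[sel][-length(sel)]))
    tbl$onset_s[sel] <- on
    tbl$offset_s[sel] <- on + dur_s[sel]
  }
  if (round_times) {
    tbl$onset_s <- round_us(tbl$onset_s)
    tbl$offset_s <- round_us(tbl$offset_s)
  }
  tbl$soi_ms <- NULL   # measured SOI is recomputed from times downstream
  front <- c("participant_id", "musical", "instruction", "poem_id", "meter",
             "line_no", "word_idx", "syll_idx_in_line", "syll_idx_in_poem",
             "label", "syllable_id", "stress", "is_tack", "tack_index",
             "onset_s", "offset_s", "i_mean_db")
  tbl <- tbl[, front]
  class(tbl) <- c("syllable_table", "data.frame")
  tbl
}

#' Inject pause structure into a synthetic reading
#'
#' Adds a gap after the final syllable of every verse line (lognormal with
#' the configured mean/sd in ms) and, with probability `long_pause_prob` per
#' within-line syllable, a long hesitation that pushes the following onset so
#' that the affected SOI exceeds `long_pause_min_ms` (the excess over the
#' threshold is exponential with mean 200 ms).  Durations of syllables are
#' preserved; only onsets of subsequent material shift.  Line-final gaps
#' never enter an SOI (the line-final SOI is the syllable's own duration),
#' so only the long hesitations are visible to the SOI threshold filter.
#'
#' @param tokens a syllable token table with times (from
#'   [simulate_syllables()]).
#' @param pause_model list with `line_final_mean_ms`, `line_final_sd_ms`,
#'   `long_pause_prob`, `long_pause_min_ms`.
#' @param seed integer seed.
#' @return the table with shifted times.
#' @export
inject_pauses <- function(tokens, pause_model = generative_params("regular_soi")$pause_model,
                          seed = 1L) {
  set.seed(as.integer(seed))
  m <- pause_model$line_final_mean_ms
  s <- pause_model$line_final_sd_ms
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2

  out <- tokens
  for (key in unique(paste(tokens$participant_id, tokens$poem_id))) {
    sel <- which(paste(tokens$participant_id, tokens$poem_id) == key)
    k <- length(sel)
    line_no <- tokens$line_no[sel]
    line_final <- c(line_no[-1] != line_no[-k], TRUE)
    dur <- tokens$offset_s[sel] - tokens$onset_s[sel]
    gap_s <- numeric(k)
    n_fin <- sum(line_final)
    gap_s[line_final] <- rlnorm(n_fin, meanlog, sdlog) / 1000
    within <- which(!line_final)
    if (length(within) && pause_model$long_pause_prob > 0) {
      hit <- within[runif(length(within)) < pause_model$long_pause_prob]
      if (length(hit)) {
        need <- pmax(0, pause_model$long_pause_min_ms / 1000 - dur[hit])
        gap_s[hit] <- gap_s[hit] + need + rexp(length(hit), rate = 5) / 1000
      }
    }
    step <- diff(tokens$onset_s[sel])
    new_on <- tokens$onset_s[sel][1] + cumsum(c(0, step + gap_s[-k]))
    out$onset_s[sel] <- round_us(new_on)
    out$offset_s[sel] <- round_us(new_on + dur)
  }
  out
}

#' Simulate line-level nPVI observations directly
#'
#' Generates per-line nPVI responses from the line-level generative
#' structure: sum-coded fixed effects for the tack predictor (binary
#' tack-line contrast or centered tacks-per-line count), musical activity and
#' meter with all interactions, plus participant random intercepts and a
#' participant random slope for the tack predictor, poem random intercepts
#' and Gaussian residuals.  The line layout (120 lines per participant, with
#' tack counts per line) is taken from the supplied poems.
#'
#' @param poems list of tacked `poem_spec` objects.
#' @param participants data.frame of participant profiles.
#' @param seed integer seed.
#' @param params line-level generative parameters; the response column is
#'   named after `params$response`.
#' @return a line table with stimulus covariates and the simulated response.
#' @export
simulate_lines <- function(poems, participants, seed,
                           params = generative_params("line_tacks_per_line_soi")) {
  set.seed(as.integer(seed))
  if (inherits(poems, "poem_spec")) poems <- list(poems)
  lines <- do.call(rbind, lapply(poems, function(p) {
    agg <- split(as.data.frame(p), p$line_no)
    do.call(rbind, lapply(agg, function(g) {
      data.frame(poem_id = g$poem_id[1], meter = g$meter[1],
                 line_no = g$line_no[1],
                 tacks_per_line = sum(g$is_tack),
                 n_sylls = nrow(g), stringsAsFactors = FALSE)
    }))
  }))
  lines$tack_line <- lines$tacks_per_line >= 1
  rownames(lines) <- NULL

  n_part <- nrow(participants)
  tbl <- lines[rep(seq_len(nrow(lines)), times = n_part), , drop = FALSE]
  tbl$participant_id <- rep(participants$participant_id, each = nrow(lines))
  tbl$musical <- rep(participants$musical, each = nrow(lines))
  tbl$instruction <- rep(participants$instruction, each = nrow(lines))
  rownames(tbl) <- NULL

  codes <- standard_codes(tbl)
  lp <- linear_predictor(params$fixed_effects, codes, nrow(tbl))
  re <- draw_re_pairs(n_part, params$participant_re$intercept_sd,
                      params$participant_re$slope_sd, params$participant_re$corr)
  rownames(re) <- participants$participant_id
  poem_ids <- unique(lines$poem_id)
  poem_re <- setNames(rnorm(length(poem_ids), 0, params$poem_re_sd %||% 0),
                      poem_ids)
  slope_code <- eval_term(params$participant_re$slope_term, codes, nrow(tbl))
  y <- lp + re[tbl$participant_id, "intercept"] +
    re[tbl$participant_id, "slope"] * slope_code +
    poem_re[tbl$poem_id] + rnorm(nrow(tbl), 0, params$resid_sd)
  tbl[[params$response]] <- y
  tbl[, c("participant_id", "musical", "instruction", "poem_id", "meter",
          "line_no", "tack_line", "tacks_per_line", "n_sylls",
          params$response)]
}
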