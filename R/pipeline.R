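# End-to-end study orchestration ----------------------------------------------

KNOWN_MODELS <- c("regular_soi", "regular_intensity",
                  "tack_soi", "tack_intensity",
                  "line_tack_line_soi", "line_tack_line_intensity",
                  "line_tacks_per_line_soi", "line_tacks_per_line_intensity")

#' Configuration for a full study run
#'
#' @param mode `"simulate"` (work directly on the generated syllable table)
#'   or `"ingest"` (additionally serialize the generated reading as TextGrid
#'   files plus an intensity table, re-ingest them, and analyse the ingested
#'   data — exercising the full annotation path).
#' @param seed master seed; every stochastic stage derives its own sub-seed
#'   from it.
#' @param tack_rate per-slot tack substitution probability for the stimuli.
#' @param max_soi_ms SOI exclusion threshold in ms.
#' @param models which model fits to run (subset of
#'   `verserhythm:::KNOWN_MODELS`).
#' @param with_pauses inject line-final and long hesitation pauses.
#' @param out_dir optional directory for TSV/TextGrid outputs.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("simulate", "ingest"), seed = 1L,
                       tack_rate = 0.18, max_soi_ms = 2000,
                       models = c("regular_soi", "line_tacks_per_line_soi"),
                       with_pauses = TRUE, out_dir = NULL) {
  mode <- match.arg(mode)
  unknown <- setdiff(models, KNOWN_MODELS)
  if (length(unknown)) {
    stop_bad_arg("unknown model name(s): ", paste(unknown, collapse = ", "),
                 "; known: ", paste(KNOWN_MODELS, collapse = ", "))
  }
  structure(list(mode = mode, seed = as.integer(seed),
                 tack_rate = tack_rate, max_soi_ms = max_soi_ms,
                 models = models, with_pauses = with_pauses,
                 out_dir = out_dir),
            class = "run_config")
}

model_spec_by_name <- function(name) {
  switch(name,
    regular_soi = spec_regular("soi_ms"),
    regular_intensity = spec_regular("i_mean_db"),
    tack_soi = spec_tack("soi_ms"),
    tack_intensity = spec_tack("i_mean_db"),
    line_tack_line_soi = spec_line("npvi_soi", "tack_line"),
    line_tack_line_intensity = spec_line("npvi_i_mean", "tack_line"),
    line_tacks_per_line_soi = spec_line("npvi_soi", "tacks_per_line"),
    line_tacks_per_line_intensity = spec_line("npvi_i_mean", "tacks_per_line"),
    stop_bad_arg("unknown model name: ", name)
  )
}

#' Run the full synthetic study pipeline
#'
#' Sequences the analysis stages in a fixed order: stimulus construction,
#' synthetic reading, pause injection, (in ingest mode) TextGrid round trip,
#' SOI computation, the SOI threshold filter, the two-pass syllable-level
#' model fits, line aggregation, and the two-pass line-level fits.  All
#' randomness derives from `config$seed`, so a repeated run returns an
#' identical bundle.
#'
#' @param config a [run_config()].
#' @return list with `features` (syllable-level rows), `lines` (line
#'   records), `fits` (named list of [two_pass_outlier_fit()] results) and
#'   `metadata` (seeds, filters, counts).
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  poems <- study_poems(tack_rate = config$tack_rate, seed = seed + 1000L)
  participants <- study_participants()
  tokens <- simulate_syllables(poems, participants, seed = seed)
  if (config$with_pauses) {
    tokens <- inject_pauses(tokens,
                            generative_params("regular_soi")$pause_model,
                            seed = seed + 2000L)
  }

  if (config$mode == "ingest") {
    tg_dir <- config$out_dir %||% tempfile("verserhythm_tg_")
    manifest <- emit_textgrids(tokens, file.path(tg_dir, "textgrids"))
    intensity <- tokens[, c("participant_id", "poem_id", "line_no",
                            "syll_idx_in_line", "i_mean_db")]
    ingested <- vector("list", nrow(manifest))
    for (r in seq_len(nrow(manifest))) {
      tiers <- read_textgrid(manifest$path[r])
      prof <- participants[participants$participant_id ==
                             manifest$participant_id[r], , drop = FALSE]
      poem <- poems[[manifest$poem_id[r]]]
      ingested[[r]] <- build_syllable_table(tiers, poem, prof)
    }
    tokens <- do.call(rbind, ingested)
    features <- compute_soi(tokens)
    features <- attach_intensity(features, intensity)
  } else {
    features <- compute_soi(tokens)
  }
  features <- filter_max_soi(features, config$max_soi_ms)

  lines <- aggregate_lines(features)
  fits <- list()
  for (m in config$models) {
    spec <- model_spec_by_name(m)
    input <- if (spec$subset == "lines") lines else features
    fits[[m]] <- two_pass_outlier_fit(input, spec)
  }

  metadata <- list(
    mode = config$mode, seed = seed, tack_rate = config$tack_rate,
    max_soi_ms = config$max_soi_ms, models = config$models,
    n_tokens = nrow(features), n_excluded = sum(features$excluded),
    n_lines = nrow(lines),
    coding = c(stress = "strong=+1", musical = "active=+1",
               meter = "iambic=+1", tack_line = "no-tack=+1",
               tacks_per_line = "grand-mean centered")
  )
  bundle <- list(features = features, lines = lines, fits = fits,
                 metadata = metadata)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(features, file.path(config$out_dir, "syllable_features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(lines, file.path(config$out_dir, "line_records.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_reports(lapply(fits, `[[`, "final_fit"),
                  file.path(config$out_dir, "reports"))
  }
  bundle
}
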