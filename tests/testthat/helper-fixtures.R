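# Shared fixtures: small stimuli, participants and noise-free parameter sets.

two_small_poems <- function(tack_rate = 0.3, seed = 5) {
  list(
    ia = place_tacks(build_grid("iambic", 6, 8, poem_id = "ia"),
                     rate = tack_rate, seed = seed),
    tr = place_tacks(build_grid("trochaic", 6, 8, poem_id = "tr"),
                     rate = tack_rate, seed = seed + 1)
  )
}

four_participants <- function() study_participants()[c(1, 2, 7, 8), ]

# generative parameters with every variance zeroed (deterministic reader)
novar_params <- function(model, fixed = NULL) {
  p <- generative_params(model)
  re <- p$participant_re
  re$intercept_sd <- 0
  re$slope_sd <- 0
  args <- list(model = model, resid_sd = 0, participant_re = re)
  if (!is.null(p$syllable_re_sd)) args$syllable_re_sd <- 0
  if (!is.null(p$poem_re_sd)) args$poem_re_sd <- 0
  if (!is.null(fixed)) args$fixed_effects <- fixed
  do.call(generative_params, args)
}

simulate_novar <- function(poems = two_small_poems(),
                           participants = four_participants(),
                           seed = 3, round_times = TRUE) {
  simulate_syllables(
    poems, participants, seed = seed,
    params_soi = novar_params("regular_soi"),
    params_intensity = novar_params("regular_intensity"),
    params_tack_soi = novar_params("tack_soi"),
    params_tack_intensity = novar_params("tack_intensity"),
    round_times = round_times
  )
}

# independent straight-loop nPVI evaluation (oracle)
npvi_oracle <- function(d) {
  m <- length(d)
  acc <- 0
  for (k in 1:(m - 1)) {
    acc <- acc + abs(d[k] - d[k + 1]) / ((d[k] + d[k + 1]) / 2)
  }
  100 * acc / (m - 1)
}
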