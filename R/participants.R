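# Participant metadata and the musical-activity coding ------------------------

MUSA_FREQ <- c("Not at all", "once a month or less", "2-3 times a month",
               "1 time per week", "2-3 times per week", "4-6 times per week",
               "daily")
INSTRUCTIONS <- c("no_instruction", "rhythmic", "on_beat")

#' Construct one participant profile
#'
#' `musa_q4` records whether the participant has ever been musically active;
#' `musa_instrument` and `musa_singing` are the two parts of the follow-up
#' question on activity in the last 12 months (ordinal frequency categories).
#' The derived binary factor `musical` is computed by [code_musical()].
#'
#' @param participant_id identifier.
#' @param musa_q4 `"yes"` or `"no"`.
#' @param musa_instrument,musa_singing one of the MusA frequency categories
#'   (`"Not at all"`, `"once a month or less"`, ..., `"daily"`).
#' @param instruction reading instruction group: `"no_instruction"`,
#'   `"rhythmic"` or `"on_beat"`.
#' @return a one-row `data.frame` with the profile fields plus the derived
#'   `musical` coding.
#' @export
participant_profile <- function(participant_id, musa_q4,
                                musa_instrument = "Not at all",
                                musa_singing = "Not at all",
                                instruction = "no_instruction") {
  musa_q4 <- match.arg(musa_q4, c("yes", "no"))
  musa_instrument <- match.arg(musa_instrument, MUSA_FREQ)
  musa_singing <- match.arg(musa_singing, MUSA_FREQ)
  instruction <- match.arg(instruction, INSTRUCTIONS)
  prof <- data.frame(
    participant_id = as.character(participant_id),
    musa_q4 = musa_q4,
    musa_instrument = musa_instrument,
    musa_singing = musa_singing,
    instruction = instruction,
    stringsAsFactors = FALSE
  )
  prof$musical <- code_musical(prof)
  prof
}

#' Derive the binary musical-activity coding from the MusA answers
#'
#' Participants who have never been musically active (question 4 answered
#' "no") are coded `"not_active"`.  Otherwise a participant is `"active"`
#' when at least one of the two activity answers (instrument, singing) in the
#' last 12 months differs from "Not at all".
#'
#' @param profile a data.frame with columns `musa_q4`, `musa_instrument`,
#'   `musa_singing` (one row per participant).
#' @return character vector of `"active"` / `"not_active"`.
#' @export
code_musical <- function(profile) {
  needed <- c("musa_q4", "musa_instrument", "musa_singing")
  missing <- setdiff(needed, names(profile))
  if (length(missing)) {
    stop_bad_arg("cannot code musical activity; missing answers: ",
                 paste(missing, collapse = ", "))
  }
  if (anyNA(profile[needed])) {
    stop_bad_arg("cannot code musical activity; NA answers present")
  }
  ifelse(profile$musa_q4 == "no", "not_active",
         ifelse(profile$musa_instrument != "Not at all" |
                  profile$musa_singing != "Not at all",
                "active", "not_active"))
}

#' The 13 analysed study participants
#'
#' Six participants are musically active and seven are not.  Instruction
#' groups follow the study's (confounded) assignment: three active and one
#' inactive participant read with no instruction, three active and two
#' inactive read "rhythmically", and four inactive read "on beat".
#'
#' @return data.frame of 13 participant profiles.
#' @export
study_participants <- function() {
  active_instr <- c("no_instruction", "no_instruction", "no_instruction",
                    "rhythmic", "rhythmic", "rhythmic")
  inactive_instr <- c("no_instruction", "rhythmic", "rhythmic",
                      "on_beat", "on_beat", "on_beat", "on_beat")
  profs <- list()
  for (i in 1:6) {
    profs[[i]] <- participant_profile(
      sprintf("P%02d", i), musa_q4 = "yes",
      musa_instrument = if (i %% 2) "1 time per week" else "Not at all",
      musa_singing = if (i %% 2) "Not at all" else "2-3 times a month",
      instruction = active_instr[i]
    )
  }
  for (j in 1:7) {
    profs[[6 + j]] <- participant_profile(
      sprintf("P%02d", 6 + j),
      musa_q4 = if (j <= 4) "no" else "yes",
      musa_instrument = "Not at all", musa_singing = "Not at all",
      instruction = inactive_instr[j]
    )
  }
  do.call(rbind, profs)
}
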