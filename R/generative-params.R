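# Generative parameter sets ---------------------------------------------------
#
# The simulator treats the fitted hierarchical models of the reading study as
# generative truth: fixed effects are on the sum-coded (+1/-1) scale, variance
# components are the residual variance, participant intercept/slope variances
# with their correlation, and (where applicable) syllable or poem intercept
# variances.  One parameter set exists per response x subset combination.

#' Generative parameters for the synthetic oral reader
#'
#' Returns the default hierarchical parameter set for one model:
#'
#' * `"regular_soi"` — syllable onset intervals (ms) of regular syllables;
#'   fixed effects stress x musical x meter; random participant
#'   (intercept + stress slope) and syllable intercepts.
#' * `"regular_intensity"` — mean intensity (dB), same structure.
#' * `"tack_soi"`, `"tack_intensity"` — tack syllables; tack index enters the
#'   fixed effects; no syllable random intercept.
#' * `"line_tacks_per_line_soi"`, `"line_tack_line_soi"` and the two
#'   intensity analogues — line-level nPVI responses; random participant
#'   (intercept + predictor slope) and poem intercepts.
#'
#' Fixed-effect names use plain variable names and `:` for interactions
#' (`"stress"`, `"stress:musical:meter"`, `"tack_index"`, ...).  Binary
#' variables are coded +1 for strong / active / iambic / line-without-tack
#' and -1 otherwise; `tack_index` is the 1-based ordinal of a tack within its
#' line and `tacks_per_line` is centered before entering the predictor.
#'
#' @param model which parameter set to build.
#' @param ... named overrides for any top-level field (`fixed_effects`,
#'   `resid_sd`, `participant_re`, `syllable_re_sd`, `poem_re_sd`,
#'   `pause_model`).  Overriding `fixed_effects` replaces matching terms and
#'   keeps the rest.
#' @return a list of class `"generative_params"`.
#' @export
generative_params <- function(model = c("regular_soi", "regular_intensity",
                                        "tack_soi", "tack_intensity",
                                        "line_tacks_per_line_soi",
                                        "line_tack_line_soi",
                                        "line_tacks_per_line_intensity",
                                        "line_tack_line_intensity"),
                              ...) {
  model <- match.arg(model)
  p <- switch(model,
    regular_soi = list(
      response = "soi_ms", unit = "ms", subset = "regular",
      fixed_effects = c(
        intercept = 254.16, stress = 20.54, musical = 3.31, meter = 2.13,
        "stress:musical" = 3.63, "stress:meter" = -0.12,
        "musical:meter" = -0.70, "stress:musical:meter" = 0.06),
      resid_sd = sqrt(2623.56),
      participant_re = list(intercept_sd = sqrt(406.63),
                            slope_sd = sqrt(21.53),
                            corr = 0.81, slope_term = "stress"),
      syllable_re_sd = sqrt(5982.17)
    ),
    regular_intensity = list(
      response = "i_mean_db", unit = "dB", subset = "regular",
      fixed_effects = c(
        intercept = 65.72, stress = 0.37, musical = -0.67, meter = -0.08,
        "stress:musical" = -0.01, "stress:meter" = 0.09,
        "musical:meter" = -0.06, "stress:musical:meter" = -0.02),
      resid_sd = sqrt(8.31),
      participant_re = list(intercept_sd = sqrt(11.23),
                            slope_sd = sqrt(0.14),
                            corr = -0.02, slope_term = "stress"),
      syllable_re_sd = sqrt(6.29)
    ),
    tack_soi = list(
      response = "soi_ms", unit = "ms", subset = "tack",
      fixed_effects = c(
        intercept = 286.85, stress = -9.85, musical = -3.14, meter = -14.61,
        tack_index = 7.92,
        "stress:musical" = 10.33, "stress:meter" = -2.19,
        "musical:meter" = 13.01, "stress:tack_index" = -1.25,
        "musical:tack_index" = -4.70, "meter:tack_index" = 1.89,
        "stress:musical:meter" = -11.86, "stress:musical:tack_index" = -0.18,
        "stress:meter:tack_index" = 3.47, "musical:meter:tack_index" = -2.64,
        "stress:musical:meter:tack_index" = 3.17),
      resid_sd = sqrt(6803.36),
      participant_re = list(intercept_sd = sqrt(905.91),
                            slope_sd = sqrt(144.96),
                            corr = -0.72, slope_term = "stress"),
      syllable_re_sd = NULL
    ),
    tack_intensity = list(
      response = "i_mean_db", unit = "dB", subset = "tack",
      fixed_effects = c(
        intercept = 66.57, stress = 0.66, musical = 0.36, meter = -0.17,
        tack_index = -1.01,
        "stress:musical" = 0.28, "stress:meter" = -0.21,
        "musical:meter" = -0.34, "stress:tack_index" = -0.23,
        "musical:tack_index" = -0.56, "meter:tack_index" = -0.06,
        "stress:musical:meter" = -0.24, "stress:musical:tack_index" = 0.01,
        "stress:meter:tack_index" = 0.07, "musical:meter:tack_index" = -0.04,
        "stress:musical:meter:tack_index" = 0.11),
      resid_sd = sqrt(9.26),
      participant_re = list(intercept_sd = sqrt(9.15),
                            slope_sd = sqrt(0.05),
                            corr = 0.80, slope_term = "stress"),
      syllable_re_sd = NULL
    ),
    line_tacks_per_line_soi = list(
      response = "npvi_soi", unit = "nPVI", subset = "lines",
      fixed_effects = c(
        intercept = 51.88, tacks_per_line = -1.49, musical = -0.18,
        meter = 0.36, "tacks_per_line:musical" = -0.84,
        "tacks_per_line:meter" = 0.06, "musical:meter" = 0.79,
        "tacks_per_line:musical:meter" = -0.08),
      resid_sd = sqrt(282.25),
      participant_re = list(intercept_sd = sqrt(2.43),
                            slope_sd = sqrt(0.13),
                            corr = -0.02, slope_term = "tacks_per_line"),
      poem_re_sd = sqrt(11.81)
    ),
    line_tack_line_soi = list(
      response = "npvi_soi", unit = "nPVI", subset = "lines",
      fixed_effects = c(
        intercept = 51.93, tack_line = 2.58, musical = -0.18, meter = 0.46,
        "tack_line:musical" = 1.04, "tack_line:meter" = -0.22,
        "musical:meter" = 0.86, "tack_line:musical:meter" = 0.07),
      resid_sd = sqrt(281.64),
      participant_re = list(intercept_sd = sqrt(2.44),
                            slope_sd = sqrt(0.01),
                            corr = 1.00, slope_term = "tack_line"),
      poem_re_sd = sqrt(13.72)
    ),
    line_tacks_per_line_intensity = list(
      response = "npvi_i_mean", unit = "nPVI", subset = "lines",
      fixed_effects = c(
        intercept = 5.31, tacks_per_line = 0.04, musical = 0.17,
        meter = 0.29, "tacks_per_line:musical" = 0.14,
        "tacks_per_line:meter" = 0.04, "musical:meter" = -0.02,
        "tacks_per_line:musical:meter" = 0.00),
      resid_sd = sqrt(3.20),
      participant_re = list(intercept_sd = sqrt(0.54),
                            slope_sd = sqrt(0.07),
                            corr = -0.17, slope_term = "tacks_per_line"),
      poem_re_sd = sqrt(0.12)
    ),
    line_tack_line_intensity = list(
      response = "npvi_i_mean", unit = "nPVI", subset = "lines",
      fixed_effects = c(
        intercept = 5.31, tack_line = -0.10, musical = 0.17, meter = 0.29,
        "tack_line:musical" = -0.23, "tack_line:meter" = -0.08,
        "musical:meter" = -0.04, "tack_line:musical:meter" = 0.03),
      resid_sd = sqrt(3.22),
      participant_re = list(intercept_sd = sqrt(0.54),
                            slope_sd = sqrt(0.13),
                            corr = 0.18, slope_term = "tack_line"),
      poem_re_sd = sqrt(0.12)
    )
  )
  p$model <- model
  p$pause_model <- list(line_final_mean_ms = 300, line_final_sd_ms = 150,
                        long_pause_prob = 0.005, long_pause_min_ms = 2200)
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm == "fixed_effects") {
      fe <- dots[[nm]]
      p$fixed_effects[names(fe)] <- fe
    } else {
      p[[nm]] <- dots[[nm]]
    }
  }
  validate_generative_params(p)
  class(p) <- "generative_params"
  p
}

validate_generative_params <- function(p) {
  re <- p$participant_re
  if (p$resid_sd < 0 || re$intercept_sd < 0 || re$slope_sd < 0) {
    stop_bad_arg("standard deviations must be non-negative")
  }
  if (re$corr < -1 || re$corr > 1) {
    stop_bad_arg("random-effect correlation must lie in [-1, 1]")
  }
  if (!is.null(p$syllable_re_sd) && p$syllable_re_sd < 0) {
    stop_bad_arg("syllable_re_sd must be non-negative")
  }
  if (!is.null(p$poem_re_sd) && p$poem_re_sd < 0) {
    stop_bad_arg("poem_re_sd must be non-negative")
  }
  invisible(p)
}

#' @export
print.generative_params <- function(x, ...) {
  cat("Generative parameters:", x$model, sprintf("(%s, %s)\n",
      x$response, x$unit))
  cat("  fixed effects:\n")
  fe <- x$fixed_effects
  for (nm in names(fe)) cat(sprintf("    %-34s %8.2f\n", nm, fe[[nm]]))
  cat(sprintf("  resid sd %.2f; participant (int %.2f, slope[%s] %.2f, rho %.2f)\n",
              x$resid_sd, x$participant_re$intercept_sd,
              x$participant_re$slope_term, x$participant_re$slope_sd,
              x$participant_re$corr))
  if (!is.null(x$syllable_re_sd)) {
    cat(sprintf("  syllable intercept sd %.2f\n", x$syllable_re_sd))
  }
  if (!is.null(x$poem_re_sd)) {
    cat(sprintf("  poem intercept sd %.2f\n", x$poem_re_sd))
  }
  invisible(x)
}
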