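`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) {
  stop(..., call. = FALSE)
}

#' Split an interaction term name into its component variables
#' @noRd
term_parts <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

#' Evaluate a (possibly interaction) term over a list of code vectors
#'
#' `codes` maps plain variable names (e.g. "stress", "tack_index") to numeric
#' vectors of equal length; the value of "a:b" is the elementwise product.
#' Unknown variables raise a configuration error naming the term.
#' @noRd
eval_term <- function(term, codes, n) {
  parts <- term_parts(term)
  out <- rep(1, n)
  for (p in parts) {
    if (is.null(codes[[p]])) {
      stop_bad_arg("generative parameters reference unknown term '", term,
                   "' (no code for variable '", p, "')")
    }
    out <- out * codes[[p]]
  }
  out
}

#' Linear predictor of a sum-coded fixed-effects map
#'
#' @param fixed named numeric vector; must contain "intercept", other names
#'   are main effects or ":"-separated interactions.
#' @param codes named list of numeric code vectors.
#' @param n number of rows.
#' @noRd
linear_predictor <- function(fixed, codes, n) {
  if (!("intercept" %in% names(fixed))) {
    stop_bad_arg("fixed-effects map must contain an 'intercept' term")
  }
  lp <- rep(fixed[["intercept"]], n)
  for (term in setdiff(names(fixed), "intercept")) {
    lp <- lp + fixed[[term]] * eval_term(term, codes, n)
  }
  lp
}

#' Draw correlated (intercept, slope) random-effect pairs
#'
#' Handles boundary correlations of exactly +/-1 (these occur in fitted
#' variance components of small designs).
#' @noRd
draw_re_pairs <- function(n, intercept_sd, slope_sd, corr) {
  stopifnot(intercept_sd >= 0, slope_sd >= 0, corr >= -1, corr <= 1)
  z0 <- rnorm(n)
  z1 <- rnorm(n)
  b0 <- intercept_sd * z0
  b1 <- slope_sd * (corr * z0 + sqrt(max(0, 1 - corr^2)) * z1)
  cbind(intercept = b0, slope = b1)
}

#' Round times to microsecond precision (the serialization grain)
#' @noRd
round_us <- function(x) round(x, 6L)

#' Order a syllable table chronologically within recordings
#' @noRd
order_tokens <- function(tbl) {
  tbl[order(tbl$participant_id, tbl$poem_id, tbl$onset_s), , drop = FALSE]
}
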