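# Sum-coded mixed-effects inference -------------------------------------------

#' Sum-code a two-level factor as +1 / -1
#'
#' The designated `positive` level is coded +1, the other -1, so that in a
#' balanced design the intercept is the grand mean and the model-implied
#' difference between the two levels equals twice the coefficient.
#'
#' @param x character or factor vector with exactly two observed levels.
#' @param positive the level coded +1.  The package's model fits always name
#'   it explicitly: strong stress, active musicality, iambic meter and the
#'   line-without-tack level are +1.  Defaults to the second level in sort
#'   order, and the chosen coding is recorded in the attributes.
#' @return numeric vector of +1/-1 with attributes `positive` and `negative`
#'   recording the coding.
#' @export
sum_code <- function(x, positive = NULL) {
  lev <- sort(unique(as.character(x)))
  if (length(lev) != 2) {
    stop_bad_arg("sum_code supports exactly two levels; got ",
                 length(lev), " (", paste(lev, collapse = ", "), ")")
  }
  if (is.null(positive)) positive <- lev[2]
  if (!positive %in% lev) stop_bad_arg("level '", positive, "' not present")
  out <- ifelse(as.character(x) == positive, 1, -1)
  attr(out, "positive") <- positive
  attr(out, "negative") <- setdiff(lev, positive)
  out
}

#' Cohen's d from a mixed-model t statistic
#'
#' Uses the `d = 2t / sqrt(df)` conversion for mixed-model coefficients
#' (the EMAtools convention), with the Satterthwaite df of the term.
#'
#' @param t t statistic.
#' @param df (Satterthwaite) degrees of freedom; must be positive.
#' @return Cohen's d.
#' @examples
#' cohens_d(3.09, 16.53)  # 1.52
#' @export
cohens_d <- function(t, df) {
  if (any(df <= 0)) stop_bad_arg("degrees of freedom must be positive")
  2 * t / sqrt(df)
}

#' Intraclass correlation from variance components
#'
#' Share of total variance attributable to the random intercepts:
#' `sum(tau00) / (sum(tau00) + sigma2)`.
#'
#' @param tau00 vector of random-intercept variances.
#' @param sigma2 residual variance.
#' @return ICC in `[0, 1]`.
#' @export
icc_from_varcomp <- function(tau00, sigma2) {
  stopifnot(all(tau00 >= 0), sigma2 >= 0)
  sum(tau00) / (sum(tau00) + sigma2)
}

# Model specifications ---------------------------------------------------------

new_spec <- function(name, response, subset, fixed, random,
                     df_method = "satterthwaite", musical_only = NULL) {
  structure(list(name = name, response = response, subset = subset,
                 fixed = fixed, random = random, df_method = df_method,
                 musical_only = musical_only),
            class = "mixed_spec")
}

#' Canonical model specifications
#'
#' The four model families of the analysis:
#'
#' * `spec_regular()` — regular syllables; fixed effects
#'   stress x musical x meter; random participant (intercept + stress slope)
#'   and syllable intercept.
#' * `spec_tack()` — tack syllables; tack index joins the factorial; no
#'   syllable intercept.  `musical_only = "active"` restricts to musically
#'   active readers.
#' * `spec_line()` — line-level nPVI; the tack predictor is either the
#'   binary tack-line contrast or the centered tacks-per-line count; random
#'   participant (intercept + predictor slope) and poem intercept.
#'   `with_instruction = TRUE` additionally lets the (sum-coded, 3-level)
#'   instruction factor interact with the same predictors.
#'
#' @param response response column.
#' @param df_method `"satterthwaite"` (default) or `"residual"`.
#' @param musical_only optionally restrict to one `musical` level.
#' @param predictor line-level tack predictor.
#' @param with_instruction include instruction interactions (line models).
#' @return a `mixed_spec` object for [fit_mixed()].
#' @export
spec_regular <- function(response = c("soi_ms", "i_mean_db"),
                         df_method = "satterthwaite") {
  response <- match.arg(response)
  new_spec(paste0("regular_", response), response, "regular",
           fixed = "stress_c * musical_c * meter_c",
           random = "(1 + stress_c | participant_id) + (1 | syllable_id)",
           df_method = df_method)
}

#' @rdname spec_regular
#' @export
spec_tack <- function(response = c("soi_ms", "i_mean_db"),
                      df_method = "satterthwaite", musical_only = NULL) {
  response <- match.arg(response)
  new_spec(paste0("tack_", response), response, "tack",
           fixed = "stress_c * musical_c * meter_c * tack_index",
           random = "(1 + stress_c | participant_id)",
           df_method = df_method, musical_only = musical_only)
}

#' @rdname spec_regular
#' @export
spec_line <- function(response = c("npvi_soi", "npvi_i_mean"),
                      predictor = c("tack_line", "tacks_per_line"),
                      with_instruction = FALSE,
                      df_method = "satterthwaite") {
  response <- match.arg(response)
  predictor <- match.arg(predictor)
  pred_c <- paste0(predictor, "_c")
  fixed <- paste0(pred_c, " * musical_c * meter_c")
  if (with_instruction) {
    fixed <- paste0(fixed, " + ", pred_c, " * instruction_f * meter_c")
  }
  new_spec(paste0("line_", predictor, "_", response), response, "lines",
           fixed = fixed,
           random = paste0("(1 + ", pred_c,
                           " | participant_id) + (1 | poem_id)"),
           df_method = df_method)
}

#' Add the coded predictor columns a model spec needs
#'
#' Sum codes (+1/-1) the binary factors — stress (strong +1), musical
#' (active +1), meter (iambic +1), tack-line (line WITHOUT tacks +1) —
#' grand-mean-centers tacks-per-line, and sets sum contrasts on the 3-level
#' instruction factor.  Existing coded columns are left untouched, so
#' repeated preparation (as in the two-pass fit) never re-centers on a
#' subset.
#'
#' @param data feature or line table.
#' @param spec a `mixed_spec`.
#' @return the subset of `data` selected by the spec, with coded columns.
#' @export
prepare_model_data <- function(data, spec) {
  tbl <- as.data.frame(data)
  if (spec$subset == "regular") {
    tbl <- tbl[!tbl$is_tack & !tbl$excluded, , drop = FALSE]
  } else if (spec$subset == "tack") {
    tbl <- tbl[tbl$is_tack & !tbl$excluded, , drop = FALSE]
  } else {
    tbl <- tbl[!is.na(tbl[[spec$response]]), , drop = FALSE]
  }
  if (!is.null(spec$musical_only)) {
    tbl <- tbl[tbl$musical == spec$musical_only, , drop = FALSE]
  }
  if (is.null(tbl$stress_c) && !is.null(tbl$stress)) {
    tbl$stress_c <- as.numeric(sum_code(tbl$stress, "strong"))
  }
  if (is.null(tbl$musical_c) && !is.null(tbl$musical) &&
      is.null(spec$musical_only)) {
    tbl$musical_c <- as.numeric(sum_code(tbl$musical, "active"))
  }
  if (is.null(tbl$meter_c) && !is.null(tbl$meter)) {
    tbl$meter_c <- as.numeric(sum_code(tbl$meter, "iambic"))
  }
  if (is.null(tbl$tack_line_c) && !is.null(tbl$tack_line)) {
    tbl$tack_line_c <- ifelse(tbl$tack_line, -1, 1)  # no-tack line is +1
  }
  if (is.null(tbl$tacks_per_line_c) && !is.null(tbl$tacks_per_line)) {
    tbl <- center_covariates(tbl, "tacks_per_line")
  }
  if (grepl("instruction_f", spec$fixed) && is.null(tbl$instruction_f)) {
    f <- factor(tbl$instruction)
    stats::contrasts(f) <- stats::contr.sum(nlevels(f))
    tbl$instruction_f <- f
  }
  tbl
}

strip_code_suffix <- function(terms) {
  vapply(terms, function(tm) {
    parts <- term_parts(tm)
    paste(sub("_[cf]$", "", parts), collapse = ":")
  }, character(1))
}

# Nakagawa/Johnson variance partitioning for marginal/conditional R^2
r2_nakagawa <- function(fit, frame) {
  vf <- var(as.numeric(predict(fit, re.form = NA)))
  vc <- lme4::VarCorr(fit)
  vr <- 0
  for (g in names(vc)) {
    S <- as.matrix(vc[[g]])
    cols <- colnames(S)
    M <- sapply(cols, function(cn) {
      if (cn == "(Intercept)") rep(1, nrow(frame)) else frame[[cn]]
    })
    M <- matrix(as.numeric(M), nrow = nrow(frame))
    vr <- vr + mean(rowSums((M %*% S) * M))
  }
  s2 <- stats::sigma(fit)^2
  tot <- vf + vr + s2
  list(marginal = vf / tot, conditional = (vf + vr) / tot)
}

#' Fit a sum-coded linear mixed model
#'
#' Fits the spec's model by REML with `lmerTest`, reporting the coefficient
#' table (estimate, SE, Satterthwaite df, t, two-sided p, Cohen's d =
#' 2t/sqrt(df)), the variance components (residual sigma^2, random-intercept
#' variances tau00, random-slope variances tau11 with their correlations
#' rho01), the intraclass correlation `sum(tau00)/(sum(tau00)+sigma2)`,
#' marginal/conditional R^2 by variance partitioning, and the AIC.  Singular
#' fits (variance components on the boundary, common with 13 participants)
#' are recorded on the result, not raised as errors.
#'
#' @param data feature or line table (coded columns are added as needed via
#'   [prepare_model_data()]).
#' @param spec a `mixed_spec` from [spec_regular()], [spec_tack()] or
#'   [spec_line()].
#' @return an object of class `mixed_fit`.
#' @export
fit_mixed <- function(data, spec) {
  tbl <- prepare_model_data(data, spec)
  fit_prepared(tbl, spec)
}

fit_prepared <- function(tbl, spec) {
  if (nrow(tbl) == 0L) stop_bad_arg("no rows to fit for spec ", spec$name)
  fixed <- spec$fixed
  if (!is.null(spec$musical_only)) {
    # the musical factor is constant in the subset; drop it from the formula
    fixed <- gsub("musical_c \\* ", "", fixed)
    fixed <- gsub(" \\* musical_c", "", fixed)
  }
  fml <- as.formula(paste(spec$response, "~", fixed, "+", spec$random))
  msgs <- character(0)
  fit <- withCallingHandlers(
    lmerTest::lmer(fml, data = tbl, REML = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  beta <- lme4::fixef(fit)
  if (anyNA(beta)) {
    stop_bad_arg("rank-deficient fixed effects; aliased terms: ",
                 paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  co <- summary(fit)$coefficients
  df <- co[, "df"]
  p <- co[, "Pr(>|t|)"]
  tval <- co[, "t value"]
  if (spec$df_method == "residual") {
    df <- rep(nrow(tbl) - length(beta), length(beta))
    p <- 2 * stats::pt(-abs(tval), df)
  }
  coefs <- data.frame(
    term = strip_code_suffix(rownames(co)),
    beta = co[, "Estimate"],
    se = co[, "Std. Error"],
    df = df,
    t = tval,
    p = p,
    cohens_d = cohens_d(tval, pmax(df, 1e-8)),
    stringsAsFactors = FALSE
  )
  rownames(coefs) <- NULL

  vc <- lme4::VarCorr(fit)
  sigma2 <- stats::sigma(fit)^2
  tau00 <- c(); tau11 <- c(); rho01 <- c()
  for (g in names(vc)) {
    S <- as.matrix(vc[[g]])
    if ("(Intercept)" %in% colnames(S)) {
      tau00[g] <- S["(Intercept)", "(Intercept)"]
    }
    slopes <- setdiff(colnames(S), "(Intercept)")
    for (s in slopes) {
      tau11[paste(g, strip_code_suffix(s), sep = ".")] <- S[s, s]
      if ("(Intercept)" %in% colnames(S)) {
        corr <- attr(vc[[g]], "correlation")
        rho01[g] <- corr["(Intercept)", s]
      }
    }
  }
  r2 <- r2_nakagawa(fit, tbl)
  n_groups <- vapply(names(vc), function(g) {
    length(unique(tbl[[g]]))
  }, integer(1))

  structure(list(
    spec = spec,
    fit = fit,
    coefficients = coefs,
    varcomp = list(sigma2 = sigma2, tau00 = tau00, tau11 = tau11,
                   rho01 = rho01,
                   icc = icc_from_varcomp(tau00, sigma2)),
    n_obs = nrow(tbl),
    n_groups = n_groups,
    r2_marginal = r2$marginal,
    r2_conditional = r2$conditional,
    aic = AIC(fit),
    singular = lme4::isSingular(fit),
    messages = msgs,
    data = tbl
  ), class = "mixed_fit")
}

#' Residual outlier fences (Tukey, boxplot hinges, range 1.5)
#' @noRd
tukey_fences <- function(r, coef = 1.5) {
  fn <- unname(fivenum(as.numeric(r)))
  iqr <- fn[4] - fn[2]
  c(lower = fn[2] - coef * iqr, upper = fn[4] + coef * iqr)
}

#' Two-pass model fit with residual outlier removal
#'
#' Fits the model once on all rows, removes rows whose residual falls
#' outside the Tukey boxplot fences (hinges +/- 1.5 x the hinge IQR, the
#' behaviour of `boxplot()` with `range = 1.5`; rows exactly on a fence are
#' kept), and refits on the remainder.  The second fit is the one reported.
#'
#' @param data feature or line table.
#' @param spec a `mixed_spec`.
#' @return list with elements `first_fit`, `retained` (the rows entering the
#'   second fit), `final_fit`, `fences` and `n_dropped`.
#' @export
two_pass_outlier_fit <- function(data, spec) {
  tbl <- prepare_model_data(data, spec)
  first <- fit_prepared(tbl, spec)
  r <- residuals(first$fit)
  fences <- tukey_fences(r)
  keep <- r >= fences["lower"] & r <= fences["upper"]
  if (!any(keep)) stop_bad_arg("outlier filter removed every row")
  retained <- tbl[keep, , drop = FALSE]
  final <- fit_prepared(retained, spec)
  list(first_fit = first, retained = retained, final_fit = final,
       fences = fences, n_dropped = sum(!keep))
}

# Reporting --------------------------------------------------------------------

#' Coefficient and variance-component report for a fit
#'
#' Returns the coefficient table in the layout used throughout the package's
#' reports: estimate, standard error, df, t, p, and Cohen's d (blank when
#' |d| <= 0.1, the reporting convention).
#'
#' @param fit a `mixed_fit`.
#' @param digits rounding for display columns.
#' @return a data.frame.
#' @export
report_table <- function(fit, digits = 2) {
  co <- fit$coefficients
  data.frame(
    term = co$term,
    beta = round(co$beta, digits),
    ste = round(co$se, digits),
    df = round(co$df, digits),
    t = round(co$t, digits),
    p = signif(co$p, 3),
    d = ifelse(abs(co$cohens_d) > 0.1, round(co$cohens_d, digits), NA),
    stringsAsFactors = FALSE
  )
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("Linear mixed model fit:", x$spec$name, "\n")
  cat("  response:", x$spec$response, "  observations:", x$n_obs, "\n")
  print(report_table(x), row.names = FALSE)
  v <- x$varcomp
  cat(sprintf("Random effects: sigma2 = %.2f\n", v$sigma2))
  for (g in names(v$tau00)) cat(sprintf("  tau00[%s] = %.2f\n", g, v$tau00[g]))
  for (s in names(v$tau11)) cat(sprintf("  tau11[%s] = %.2f\n", s, v$tau11[s]))
  for (g in names(v$rho01)) cat(sprintf("  rho01[%s] = %.2f\n", g, v$rho01[g]))
  cat(sprintf("  ICC = %.2f\n", v$icc))
  cat(sprintf("Marginal/conditional R2 = %.3f/%.3f; AIC = %.3f\n",
              x$r2_marginal, x$r2_conditional, x$aic))
  if (x$singular) cat("note: singular fit (variance component on boundary)\n")
  invisible(x)
}

#' Write coefficient reports for a set of fits as TSV files
#'
#' @param fits named list of `mixed_fit` objects.
#' @param dir output directory.
#' @return invisible vector of paths.
#' @export
write_reports <- function(fits, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(fits)) {
    path <- file.path(dir, paste0(nm, "_coefficients.tsv"))
    write.table(report_table(fits[[nm]]), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
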