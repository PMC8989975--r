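#' Signed square-root transform
#'
#' Variance-stabilising transform applied to percent blood-volume
#' differences before mixed-model fitting: `sign(x) * sqrt(|x|)`. The
#' sign-preserving form is odd and strictly increasing, so it homogenises
#' variance without destroying the ordering of negative and positive
#' responses; `literal = TRUE` instead returns `sqrt(|x|)` (positive for
#' negative inputs), kept only for comparison.
#'
#' @param x Numeric vector.
#' @param literal Use the non-sign-preserving form.
#' @return Transformed vector; the inverse of the default form is
#'   `sign(y) * y^2`.
#' @examples
#' signed_sqrt(c(9, 0, -4))   # 3, 0, -2
#' @export
signed_sqrt <- function(x, literal = FALSE) {
  if (literal) sqrt(abs(x)) else sign(x) * sqrt(abs(x))
}

#' Fit the nested mixed models for evoked-response differences
#'
#' Fits, by restricted maximum likelihood, one of the two intercept-only
#' nested linear mixed models used for evoked blood-volume statistics:
#'
#' * `one_level`: `Y_ik = delta + R_i + W_ik` — random rat intercept plus
#'   residual (one stimulation per acquisition);
#' * `two_level`: `Y_ijk = delta + R_i + A_ij + W_ijk` — random rat and
#'   acquisition-within-rat intercepts plus residual.
#'
#' `Y` is the (transformed) response difference computed upstream, e.g.
#' ipsilateral minus contralateral `dbv_stim`, after [signed_sqrt()].
#'
#' Degenerate designs are flagged rather than silently altered: with a
#' single observation per rat the rat variance is confounded with the
#' residual and the model collapses to an intercept-only linear model
#' (`flags$collapsed`); a two-level fit with a single acquisition per rat
#' confounds the acquisition and rat variances and is refitted as one-level
#' (`flags$acq_confounded`).
#'
#' @param records Data frame with columns `rat`, `y`, and (for `two_level`)
#'   `acquisition`; see [simulate_dbv_records()].
#' @param form `"one_level"`, `"two_level"`, or `"none"` (intercept-only
#'   fixed model with no random effect — the reduced model when testing the
#'   rat variance with [test_random_effect()]).
#' @param response Name of the response column.
#' @return A `fus_lmm`: `delta_hat`, `se`, `sigma2` (named variance
#'   components `rat`, `acquisition`, `residual`), `logLik_reml`, `n_obs`,
#'   `n_rats`, `form`, `flags`, and the underlying `fit` object.
#' @export
fit_lmm <- function(records, form = c("one_level", "two_level", "none"),
                    response = "y") {
  form <- match.arg(form)
  df <- as.data.frame(records)
  if (!all(c("rat", response) %in% names(df))) {
    stop(sprintf("`records` must contain columns `rat` and `%s`", response),
         call. = FALSE)
  }
  df$..y <- df[[response]]
  df$rat <- factor(df$rat)
  n_rats <- nlevels(df$rat)
  if (n_rats < 2) stop("need at least 2 rats (grouping level `rat` is degenerate)",
                       call. = FALSE)
  flags <- list(collapsed = FALSE, acq_confounded = FALSE)
  if (form == "two_level") {
    if (!"acquisition" %in% names(df)) {
      stop("two_level form needs an `acquisition` column", call. = FALSE)
    }
    df$acquisition <- factor(df$acquisition)
    acq_per_rat <- tapply(df$acquisition, df$rat,
                          function(a) length(unique(a)))
    if (all(acq_per_rat == 1)) {
      flags$acq_confounded <- TRUE
      warning("a single acquisition per rat confounds the acquisition and rat variances; refitting as one_level",
              call. = FALSE)
      form <- "one_level"
    } else if (!any(acq_per_rat >= 2)) {
      stop("two_level form needs >= 2 acquisitions for some rat (grouping level `acquisition` is degenerate)",
           call. = FALSE)
    }
  }
  obs_per_rat <- table(df$rat)
  if (form == "none" || (form == "one_level" && all(obs_per_rat == 1))) {
    # no random effect (or rat confounded with residual when every rat
    # contributes a single observation): intercept-only linear model
    if (form != "none") flags$collapsed <- TRUE
    fit <- stats::lm(..y ~ 1, data = df)
    sm <- summary(fit)
    res <- list(delta_hat = unname(stats::coef(fit)[1]),
                se = unname(sm$coefficients[1, 2]),
                sigma2 = c(rat = if (flags$collapsed) NA_real_ else NULL,
                           acquisition = NA_real_,
                           residual = sm$sigma^2),
                logLik_reml = as.numeric(stats::logLik(fit, REML = TRUE)),
                n_obs = nrow(df), n_rats = n_rats, form = form,
                flags = flags, fit = fit)
    return(structure(res, class = "fus_lmm"))
  }
  fml <- if (form == "one_level") {
    ..y ~ 1 + (1 | rat)
  } else {
    ..y ~ 1 + (1 | rat) + (1 | rat:acquisition)
  }
  fit <- lmerTest::lmer(fml, data = df, REML = TRUE,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(name) {
    v <- vc$vcov[vc$grp == name]
    if (length(v)) v else NA_real_
  }
  res <- list(
    delta_hat = unname(lme4::fixef(fit)[1]),
    se = sqrt(as.numeric(stats::vcov(fit)[1, 1])),
    sigma2 = c(rat = get_vc("rat"),
               acquisition = get_vc("rat:acquisition"),
               residual = get_vc("Residual")),
    logLik_reml = as.numeric(stats::logLik(fit)),
    n_obs = nrow(df), n_rats = n_rats, form = form,
    flags = flags, fit = fit)
  structure(res, class = "fus_lmm")
}

#' @export
print.fus_lmm <- function(x, ...) {
  cat(sprintf("<fus_lmm> %s, n = %d (%d rats)\n", x$form, x$n_obs, x$n_rats))
  cat(sprintf("  delta = %.4g (SE %.3g)\n", x$delta_hat, x$se))
  s <- x$sigma2[!is.na(x$sigma2)]
  cat("  variance components:",
      paste(sprintf("%s = %.4g", names(s), s), collapse = ", "), "\n")
  invisible(x)
}

#' Broom-style tidiers for mixed-model fits
#'
#' `tidy()` returns one row for the fixed effect and one per variance
#' component; `glance()` returns one-row model-level summaries.
#'
#' @param x A `fus_lmm`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy fus_lmm
#' @export
tidy.fus_lmm <- function(x, ...) {
  s <- x$sigma2[!is.na(x$sigma2)]
  dplyr::bind_rows(
    tibble::tibble(effect = "fixed", term = "delta",
                   estimate = x$delta_hat, std.error = x$se),
    tibble::tibble(effect = "ran_pars", term = paste0("var_", names(s)),
                   estimate = unname(s), std.error = NA_real_))
}

#' @rdname tidy.fus_lmm
#' @method glance fus_lmm
#' @export
glance.fus_lmm <- function(x, ...) {
  ft <- test_fixed_effect(x)
  tibble::tibble(nobs = x$n_obs, n_rats = x$n_rats, form = x$form,
                 logLik_reml = x$logLik_reml,
                 statistic = ft$statistic, p.value = ft$p.value)
}

#' F test of the fixed effect
#'
#' Tests the nullity of the fixed side effect `delta` with
#' `F = (delta_hat / SE)^2` on 1 numerator degree of freedom. The default
#' denominator df is the residual df `n_obs - 1` (the default of the
#' mixed-model environment the models come from); `ddf = "satterthwaite"`
#' uses the Satterthwaite approximation instead.
#'
#' @param result A `fus_lmm`.
#' @param ddf Denominator-df method, `"residual"` or `"satterthwaite"`.
#' @return A list: `statistic` (F), `df1`, `df2`, `p.value`.
#' @export
test_fixed_effect <- function(result, ddf = c("residual", "satterthwaite")) {
  stopifnot(inherits(result, "fus_lmm"))
  ddf <- match.arg(ddf)
  Fstat <- (result$delta_hat / result$se)^2
  df2 <- if (ddf == "satterthwaite" && inherits(result$fit, "lmerModLmerTest")) {
    stats::coef(summary(result$fit, ddf = "Satterthwaite"))[1, "df"]
  } else {
    result$n_obs - 1
  }
  list(statistic = Fstat, df1 = 1, df2 = df2,
       p.value = stats::pf(Fstat, 1, df2, lower.tail = FALSE))
}

#' Likelihood-ratio test of a random effect
#'
#' Compares the restricted log-likelihoods of two nested fits (the reduced
#' model drops exactly one variance component; the intercept-only fixed
#' part is identical, so REML likelihoods are comparable):
#' `LR = 2 * (logLik_full - logLik_reduced)`, referred by default to a
#' chi-squared distribution with 1 df. Because the null value of a variance
#' lies on the boundary of its parameter space, the plain chi-squared
#' reference is conservative; `boundary = TRUE` uses the
#' `0.5 chi2_0 + 0.5 chi2_1` mixture instead.
#'
#' @param full,reduced `fus_lmm` fits; `reduced` must be nested in `full`
#'   (one fewer random component, same observations).
#' @param boundary Use the boundary-corrected mixture reference.
#' @return A list: `statistic` (LR), `df`, `p.value`.
#' @export
test_random_effect <- function(full, reduced, boundary = FALSE) {
  stopifnot(inherits(full, "fus_lmm"), inherits(reduced, "fus_lmm"))
  n_comp <- function(x) sum(!is.na(x$sigma2))
  d_comp <- n_comp(full) - n_comp(reduced)
  if (full$n_obs != reduced$n_obs || !d_comp %in% c(0L, 1L)) {
    stop("`reduced` must be nested in `full` (at most one variance component removed), on the same observations",
         call. = FALSE)
  }
  lr <- max(0, 2 * (full$logLik_reml - reduced$logLik_reml))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  if (boundary) p <- if (lr <= 0) 1 else 0.5 * p
  list(statistic = lr, df = 1, p.value = min(p, 1))
}

#' Shapiro-Wilk check of the conditional residuals
#'
#' @param result A `fus_lmm` with at least 3 residuals.
#' @return A list: `statistic` (W), `p.value`.
#' @export
check_residual_normality <- function(result) {
  stopifnot(inherits(result, "fus_lmm"))
  r <- stats::residuals(result$fit)
  if (length(r) < 3) stop("need at least 3 residuals", call. = FALSE)
  if (stats::sd(r) == 0) stop("residuals are constant", call. = FALSE)
  sw <- stats::shapiro.test(r)
  list(statistic = unname(sw$statistic), p.value = sw$p.value)
}
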