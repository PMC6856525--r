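# Binomial logistic model of late-stage gonad probability by Julian date,
# sex and capture region, with AICc / McFadden R-squared / likelihood-ratio
# model comparison and predicted probability curves.

#' Encode a gonad stage as early/late
#'
#' Stages I-III (immature to developing) are early (0); IV-VI (ripe to
#' spent) are late (1).
#'
#' @param stage character or factor with levels among I..VI
#' @return integer 0/1 vector
#' @export
encode_stage <- function(stage) {
  lev <- c("I", "II", "III", "IV", "V", "VI")
  s <- as.character(stage)
  if (any(!s %in% lev))
    stop("unknown gonad stage(s): ",
         paste(unique(s[!s %in% lev]), collapse = ", "), call. = FALSE)
  as.integer(s %in% c("IV", "V", "VI"))
}

#' Fit the maturity logistic model
#'
#' Binomial GLM of late-stage probability. The default right-hand side is
#' the full interaction structure `jd_c * sex * region`, where `jd_c` is the
#' Julian date centred on day 76 (the midpoint of the January-May survey
#' window), with treatment coding and reference levels sex `F`, region
#' `SP-S`. Nested sub-models are fitted by passing a different `terms`
#' string (e.g. `"jd_c + sex + region"`, or `"1"` for the null model).
#'
#' @param records maturity data frame (`sex`, `region`, `julian_date`, and
#'   `late` or `stage`)
#' @param terms right-hand-side formula string (default full interaction)
#' @param jd_center Julian date centring constant
#' @return object of class `"maturity_fit"` wrapping the `glm`
#' @export
fit_logistic <- function(records, terms = "jd_c * sex * region",
                         jd_center = 76) {
  if (is.null(records$late)) records$late <- encode_stage(records$stage)
  stopifnot(all(records$late %in% 0:1))
  d <- data.frame(late = records$late,
                  jd_c = records$julian_date - jd_center,
                  sex = factor(records$sex, levels = c("F", "M")),
                  region = factor(records$region,
                                  levels = c("SP-S", "W-CD", "ND")))
  fit <- stats::glm(stats::as.formula(paste("late ~", terms)),
                    family = stats::binomial(), data = d,
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  fitted_p <- stats::fitted(fit)
  if (any(fitted_p > 1 - 1e-8) || any(fitted_p < 1e-8))
    warning("fitted probabilities at 0/1: possible perfect separation; ",
            "coefficients are unreliable")
  structure(list(glm = fit, terms = terms, jd_center = jd_center,
                 n = nrow(d)), class = "maturity_fit")
}

#' @export
print.maturity_fit <- function(x, ...) {
  cat("Maturity logistic model: late ~", x$terms, "\n")
  print(stats::coef(x$glm))
  invisible(x)
}

#' @export
coef.maturity_fit <- function(object, ...) stats::coef(object$glm)

#' @export
logLik.maturity_fit <- function(object, ...) stats::logLik(object$glm)

#' Small-sample corrected AIC
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`; `k` counts every estimated
#' coefficient including the intercept.
#'
#' @param logLik model log-likelihood
#' @param k number of estimated coefficients
#' @param n sample size (must exceed `k + 1`)
#' @return the AICc value
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n <= k + 1", call. = FALSE)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Model comparison metrics
#'
#' Small-sample AIC `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)` (k counts all
#' estimated coefficients), McFadden pseudo-R-squared
#' `1 - lnL_model / lnL_null`, and the likelihood-ratio chi-squared test of
#' the model against the nested null with `df` equal to the difference in
#' coefficient counts.
#'
#' @param model,null_model `"maturity_fit"` objects on the same data,
#'   `null_model` nested in `model`
#' @return list with `AICc`, `AIC`, `mcfadden_r2`, `lr_chi2`, `lr_df`, `lr_p`
#' @export
model_metrics <- function(model, null_model) {
  stopifnot(inherits(model, "maturity_fit"),
            inherits(null_model, "maturity_fit"),
            model$n == null_model$n)
  ll <- as.numeric(stats::logLik(model$glm))
  ll0 <- as.numeric(stats::logLik(null_model$glm))
  k <- length(stats::coef(model$glm))
  k0 <- length(stats::coef(null_model$glm))
  n <- model$n
  list(AICc = aicc(ll, k, n),
       AIC = -2 * ll + 2 * k,
       mcfadden_r2 = 1 - ll / ll0,
       lr_chi2 = 2 * (ll - ll0), lr_df = k - k0,
       lr_p = stats::pchisq(2 * (ll - ll0), df = max(k - k0, 1),
                            lower.tail = FALSE))
}

#' Predicted maturity probability curves
#'
#' Inverse-logit of the linear predictor over a Julian-date grid for every
#' sex-by-region combination (or a user grid).
#'
#' @param model a `"maturity_fit"`
#' @param julian_dates grid of Julian dates
#' @param grid optional data frame with `julian_date`, `sex`, `region`
#' @return data frame with the grid and `p_late` in (0, 1)
#' @export
predict_curves <- function(model, julian_dates = 1:151, grid = NULL) {
  stopifnot(inherits(model, "maturity_fit"))
  if (is.null(grid))
    grid <- expand.grid(julian_date = julian_dates,
                        sex = c("F", "M"), region = c("SP-S", "W-CD", "ND"),
                        stringsAsFactors = FALSE)
  if (!all(grid$sex %in% c("F", "M")) ||
      !all(grid$region %in% c("SP-S", "W-CD", "ND")))
    stop("grid contains factor levels unseen by the model", call. = FALSE)
  nd <- data.frame(jd_c = grid$julian_date - model$jd_center,
                   sex = factor(grid$sex, levels = c("F", "M")),
                   region = factor(grid$region,
                                   levels = c("SP-S", "W-CD", "ND")))
  grid$p_late <- as.numeric(stats::predict(model$glm, newdata = nd,
                                           type = "response"))
  grid
}
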