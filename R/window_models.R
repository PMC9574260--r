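#' Aggregate bins over the prediction window
#'
#' Sums per-trial target fixations `F` and AOI samples `N` over the
#' prediction window -- 2,500 to 4,000 ms after picture onset, the span
#' after the verb in which the upcoming noun can be anticipated but has not
#' yet been heard.  The window is half-open, `[2500, 4000)`, so the
#' 4,000 ms bin is not double-counted with the growth-curve window.
#'
#' @param bins Tidy bin table from [preprocess_cohort()].
#' @param window Relative-time window `c(start, end)`, half-open.
#' @return A data.frame per trial: `subject`, `group`, `condition`, `item`,
#'   `trial`, `F`, `N`.  Trials with `N = 0` in the window are excluded
#'   (count recorded in attribute `n_excluded`).
#' @export
aggregate_window <- function(bins, window = c(2500, 4000)) {
  inw <- bins$t_start_rel >= window[1] & bins$t_start_rel < window[2]
  if (!any(inw)) stop("no bins inside the aggregation window")
  b <- bins[inw, , drop = FALSE]
  key <- interaction(b$subject, b$trial, drop = TRUE)
  first <- !duplicated(key)
  agg <- data.frame(
    subject = b$subject[first],
    group = if ("group" %in% names(b)) b$group[first] else NA_character_,
    condition = b$condition[first],
    item = b$item[first],
    trial = b$trial[first],
    F = as.numeric(rowsum(b$F, key)[as.character(key[first]), 1]),
    N = as.numeric(rowsum(b$N, key)[as.character(key[first]), 1]),
    stringsAsFactors = FALSE
  )
  empty <- agg$N == 0
  out <- agg[!empty, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(empty)
  out
}

#' Min-max normalization to \[-0.5, 0.5\]
#'
#' `x' = (x - min) / (max - min) - 0.5`, mapping the minimum to -0.5 and
#' the maximum to +0.5; used to put continuous covariates on a common scale
#' before model fitting.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return The normalized vector.
#' @examples
#' minmax_center(c(2, 4, 6))  # -0.5 0 0.5
#' @export
minmax_center <- function(values) {
  r <- range(values, na.rm = TRUE)
  if (r[1] == r[2]) stop("constant vector: min-max scaling undefined")
  (values - r[1]) / (r[2] - r[1]) - 0.5
}

#' Binomial mixed model of prediction-window fixations
#'
#' Fits `F` target fixations out of `N` AOI samples per trial with a
#' logit-link binomial mixed model.  The reference model has condition
#' fixed effects (dummy coded, UV reference), random condition slopes by
#' subject and a by-item random intercept.  Supplying a covariate adds its
#' main effect and covariate x condition interactions (the covariate is
#' min-max normalized first).  On non-convergence the random structure is
#' backed off to `(1 | subject) + (1 | item)`.
#'
#' @param aggregates Output of [aggregate_window()].
#' @param covariate Optional numeric vector, one value per row of
#'   `aggregates` (e.g. a subject covariate expanded to trials, or an
#'   item-level association strength), or the name of a column.
#' @param covariate_name Label used for the model term.
#' @param ref_condition Reference condition for dummy coding.
#' @param normalize Min-max normalize the covariate (default TRUE).
#' @param nAGQ Integration setting passed to [lme4::glmer()].
#' @return A list of class `"pl_winfit"`: `fit`, `coefficients` (term,
#'   estimate, SE, statistic = z, p), `minus2_logLik`, `provenance`.
#' @export
fit_window_model <- function(aggregates, covariate = NULL,
                             covariate_name = "covariate",
                             ref_condition = "UV", normalize = TRUE,
                             nAGQ = 1L) {
  d <- aggregates
  d$condition <- stats::relevel(factor(d$condition), ref = ref_condition)
  rhs <- "condition"
  if (!is.null(covariate)) {
    cv <- if (is.character(covariate) && length(covariate) == 1)
      d[[covariate]] else covariate
    if (length(cv) != nrow(d))
      stop("covariate must have one value per aggregate row")
    d[[covariate_name]] <- if (normalize) minmax_center(cv) else cv
    rhs <- sprintf("condition * %s", covariate_name)
  }
  structures <- c("(1 + condition | subject) + (1 | item)",
                  "(1 | subject) + (1 | item)")
  trail <- character(0); fit <- NULL; used <- NA_character_
  for (re in structures) {
    f <- stats::as.formula(sprintf("cbind(F, N - F) ~ %s + %s", rhs, re))
    cand <- tryCatch(
      lme4::glmer(f, data = d, family = stats::binomial(), nAGQ = nAGQ,
                  control = lme4::glmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore")),
      error = function(e) e, warning = function(w) w)
    if (inherits(cand, "merMod")) {
      fit <- cand; used <- re
      trail <- c(trail, paste(re, "-> converged")); break
    }
    trail <- c(trail, paste(re, "-> failed:", conditionMessage(cand)))
  }
  if (is.null(fit))
    stop("no random structure converged; attempted:\n",
         paste(trail, collapse = "\n"))
  sm <- summary(fit)$coefficients
  co <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                   SE = sm[, "Std. Error"], statistic = sm[, "z value"],
                   p = sm[, "Pr(>|z|)"], row.names = NULL,
                   stringsAsFactors = FALSE)
  structure(list(fit = fit, coefficients = co,
                 minus2_logLik = as.numeric(-2 * stats::logLik(fit)),
                 provenance = list(random_structure = used, trail = trail,
                                   covariate = if (is.null(covariate)) NA
                                               else covariate_name,
                                   n_obs = nrow(d))),
            class = "pl_winfit")
}

#' Likelihood-ratio comparison of nested window models
#'
#' The statistic is the drop in deviance, `(-2 logLik_ref) - (-2
#' logLik_ext)`, referred to a chi-squared distribution with `df_extra`
#' degrees of freedom (3 for a covariate model: one main effect plus two
#' interaction dummies).  Either fitted `"pl_winfit"` objects or bare
#' `-2 logLik` numbers may be supplied.
#'
#' @param fit_reference,fit_extended Nested fits (reference within
#'   extended), or their `-2 logLik` values.
#' @param df_extra Extra parameters in the extended model.
#' @return A data.frame row: `minus2ll_ref`, `minus2ll_ext`, `statistic`,
#'   `df`, `p`.
#' @examples
#' # a deviance drop of 6.745 on 3 df
#' compare_models(6.745, 0)$p  # 0.080
#' @export
compare_models <- function(fit_reference, fit_extended, df_extra = 3) {
  m2 <- function(f) if (inherits(f, "pl_winfit")) f$minus2_logLik else as.numeric(f)
  ref <- m2(fit_reference); ext <- m2(fit_extended)
  stat <- ref - ext
  if (stat < -1e-6)
    warning("extended model fits worse than the reference: check convergence")
  data.frame(minus2ll_ref = ref, minus2ll_ext = ext,
             statistic = stat, df = df_extra,
             p = stats::pchisq(max(stat, 0), df = df_extra,
                               lower.tail = FALSE))
}

#' BIC-approximate Bayes factor for nested window models
#'
#' `BF = exp((BIC_ref - BIC_ext) / 2)`, the Bayes factor of the extended
#' model over the reference under the BIC approximation to the marginal
#' likelihood.  The conventional reading: BF < 0.33 supports the null
#' (the covariate is not relevant), BF > 3 supports the alternative,
#' anything between is inconclusive.
#'
#' @param fit_reference,fit_extended Fitted `"pl_winfit"` objects (must be
#'   fits of the same data), or bare BIC values.
#' @return A list: `bf` and `verdict` (`"null-supported"`,
#'   `"alternative-supported"` or `"inconclusive"`).
#' @examples
#' bic_bayes_factor(100, 98)$bf  # exp(1)
#' @export
bic_bayes_factor <- function(fit_reference, fit_extended) {
  bic <- function(f) {
    if (inherits(f, "pl_winfit")) return(stats::BIC(f$fit))
    as.numeric(f)
  }
  if (inherits(fit_reference, "pl_winfit") && inherits(fit_extended, "pl_winfit") &&
      fit_reference$provenance$n_obs != fit_extended$provenance$n_obs)
    stop("models were fitted on different data")
  bf <- exp((bic(fit_reference) - bic(fit_extended)) / 2)
  verdict <- if (bf < 0.33) "null-supported"
             else if (bf > 3) "alternative-supported"
             else "inconclusive"
  list(bf = bf, verdict = verdict)
}
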