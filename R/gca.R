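#' Orthonormal polynomial time basis
#'
#' Degrees 1..`order` orthogonal polynomial contrasts over `n_bins` equally
#' spaced bins, as used to model fixation time-courses: columns are mutually
#' orthogonal, sum to zero and have unit norm, so linear/quadratic/cubic
#' terms can be interpreted independently.
#'
#' @param n_bins Number of time bins (> `order`).
#' @param order Polynomial order (default 3).
#' @return A matrix with `n_bins` rows and columns `ot1`, ..,
#'   `ot<order>`.
#' @examples
#' b <- orthogonal_time_basis(20)
#' round(crossprod(b), 10)  # identity
#' @export
orthogonal_time_basis <- function(n_bins, order = 3) {
  if (n_bins <= order) stop("need more bins than the polynomial order")
  b <- stats::poly(seq_len(n_bins), degree = order)
  b <- unclass(b)[, seq_len(order), drop = FALSE]
  colnames(b) <- paste0("ot", seq_len(order))
  attr(b, "coefs") <- NULL
  b
}

#' Empirical log-odds of a binned binary series
#'
#' `log((F + c) / (N - F + c))` for target fixations `F` out of `N` AOI
#' samples in a bin.  With `correction = 0` this is the raw log-odds
#' `log(F / (N - F))`, finite only for `0 < F < N`; the default `c = 0.5`
#' (the empirical-logit correction) keeps boundary bins finite.
#'
#' @param F Target-fixation count(s).
#' @param N AOI sample count(s); bins with `N = 0` return `NA`.
#' @param correction Additive correction `c` (default 0.5).
#' @return Numeric log-odds, vectorised.
#' @examples
#' empirical_log_odds(5, 10, 0)    # 0
#' empirical_log_odds(10, 10)      # log(21)
#' @export
empirical_log_odds <- function(F, N, correction = 0.5) {
  if (any(F < 0 | F > N, na.rm = TRUE)) stop("need 0 <= F <= N")
  out <- log((F + correction) / (N - F + correction))
  out[N == 0] <- NA_real_
  out
}

#' Deterministic random-structure back-off ladder
#'
#' Mixed-model fits use the maximal random structure that converges.  The
#' ladder starts from all polynomial slopes by subject plus a by-item
#' intercept and drops slopes one degree at a time, highest first:
#' full slopes, then no cubic, no quadratic, no linear, and finally
#' intercepts only.  The first converging member is used and reported.
#'
#' @param order Polynomial order of the time terms.
#' @return Character vector of random-effects formula fragments, maximal
#'   first.
#' @examples
#' random_structure_backoff()
#' @export
random_structure_backoff <- function(order = 3) {
  terms <- paste0("ot", seq_len(order))
  steps <- character(order + 2)
  for (k in order:0) {
    re <- if (k == 0) "(1 | subject)"
          else sprintf("(1 + %s | subject)", paste(terms[seq_len(k)], collapse = " + "))
    steps[order - k + 1] <- paste(re, "+ (1 | item)")
  }
  steps[order + 2] <- "(1 | subject) + (1 | item)"
  unique(steps)
}

#' Growth-curve analysis of binned fixation log-odds
#'
#' Fits per-bin empirical log-odds of target fixation over an analysis
#' window (default 4,000--6,000 ms relative to picture onset) with
#' third-order orthogonal polynomial time terms crossed with condition (and
#' group, when more than one is present).  Categorical terms are dummy
#' coded with UV and TD as reference levels.  The backend is a linear
#' mixed model on the empirical log-odds weighted by the per-bin sample
#' count `N`, with random polynomial slopes by subject and a by-item
#' intercept, backed off along [random_structure_backoff()] until
#' convergence.
#'
#' @param bins Tidy bin table from [preprocess_cohort()].
#' @param window Analysis window `c(start, end)` ms relative, inclusive of
#'   the start bin, exclusive of `end`.
#' @param order Polynomial order.
#' @param correction Empirical-logit correction passed to
#'   [empirical_log_odds()].
#' @param ref_condition,ref_group Reference levels for dummy coding.
#' @param bin_ms Bin width, ms.
#' @param backend `"weighted_logit"` (default): linear mixed model on
#'   empirical log-odds weighted by `N`; `"binomial"`: generalized linear
#'   mixed model of `F` of `N` with logit link (statistics are then Wald
#'   z).
#' @return A list of class `"pl_gca"`: `coefficients` (term, estimate, SE,
#'   df, statistic, p), `fit` (the underlying model), `provenance` (window,
#'   random structure used, convergence trail).
#' @export
fit_gca <- function(bins, window = c(4000, 6000), order = 3,
                    correction = 0.5, ref_condition = "UV",
                    ref_group = "TD", bin_ms = 100,
                    backend = c("weighted_logit", "binomial")) {
  backend <- match.arg(backend)
  d <- bins[bins$t_start_rel >= window[1] & bins$t_start_rel < window[2] &
              bins$N > 0, , drop = FALSE]
  if (!nrow(d)) stop("no bins with data inside the analysis window")
  ts <- sort(unique(d$t_start_rel))
  basis <- orthogonal_time_basis(length(ts), order)
  ix <- match(d$t_start_rel, ts)
  for (j in seq_len(order)) d[[paste0("ot", j)]] <- basis[ix, j]
  d$elog <- empirical_log_odds(d$F, d$N, correction)
  d$condition <- stats::relevel(factor(d$condition), ref = ref_condition)
  multi_group <- "group" %in% names(d) && length(unique(stats::na.omit(d$group))) > 1
  if (multi_group) d$group <- stats::relevel(factor(d$group), ref = ref_group)
  poly_terms <- paste(paste0("ot", seq_len(order)), collapse = " + ")
  lhs <- if (backend == "binomial") "cbind(F, N - F)" else "elog"
  fixed <- if (multi_group)
    sprintf("%s ~ (%s) * condition * group", lhs, poly_terms)
  else if (length(unique(d$condition)) > 1)
    sprintf("%s ~ (%s) * condition", lhs, poly_terms)
  else
    sprintf("%s ~ %s", lhs, poly_terms)

  trail <- character(0)
  fit <- NULL; used <- NA_character_
  for (re in random_structure_backoff(order)) {
    f <- stats::as.formula(paste(fixed, "+", re))
    cand <- tryCatch(
      if (backend == "binomial")
        lme4::glmer(f, data = d, family = stats::binomial(), nAGQ = 0L,
                    control = lme4::glmerControl(calc.derivs = FALSE,
                                                 check.conv.singular = "ignore"))
      else
        lme4::lmer(f, data = d, weights = d$N, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore")),
      error = function(e) e, warning = function(w) w)
    if (inherits(cand, "merMod")) {
      fit <- cand; used <- re
      trail <- c(trail, paste(re, "-> converged"))
      break
    }
    trail <- c(trail, paste(re, "-> failed:", conditionMessage(cand)))
  }
  if (is.null(fit))
    stop("no random structure converged; attempted:\n",
         paste(trail, collapse = "\n"))
  co <- if (backend == "binomial") coef_table_glmm(fit) else coef_table_lmm(fit)
  structure(list(coefficients = co, fit = fit,
                 provenance = list(window = window,
                                   random_structure = used,
                                   trail = trail,
                                   correction = correction,
                                   backend = backend)),
            class = "pl_gca")
}

coef_table_glmm <- function(fit) {
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
             SE = sm[, "Std. Error"], df = Inf,
             statistic = sm[, "z value"], p = sm[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

# coefficient table with residual-df t tests (normal beyond df 1000)
coef_table_lmm <- function(fit) {
  sm <- summary(fit)$coefficients
  df <- stats::nobs(fit) - nrow(sm)
  stat <- sm[, "t value"]
  p <- if (df > 1000) 2 * stats::pnorm(-abs(stat))
       else 2 * stats::pt(-abs(stat), df)
  data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
             SE = sm[, "Std. Error"], df = df, statistic = stat,
             p = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.pl_gca <- function(x, ...) {
  cat("Growth-curve analysis of target-fixation log-odds\n")
  cat(sprintf("  window: %d-%d ms (relative); random structure: %s\n",
              x$provenance$window[1], x$provenance$window[2],
              x$provenance$random_structure))
  co <- x$coefficients
  co$estimate <- round(co$estimate, 4); co$SE <- round(co$SE, 4)
  co$statistic <- round(co$statistic, 3); co$p <- signif(co$p, 3)
  print(co, row.names = FALSE)
  invisible(x)
}
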