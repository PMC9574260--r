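#' Association strength from restricted-association responses
#'
#' In a restricted association task, respondents see a cue (e.g. a noun)
#' and write the first word of a required class (e.g. a verb) that comes to
#' mind.  The association strength of a cue--word pair is the percentage of
#' respondents producing the expected word.  Matching is exact string
#' equality after case folding and accent stripping by default; pass a
#' custom `matcher(response, expected)` for stricter or looser rules.
#'
#' @param responses Character vector, one produced word per respondent.
#' @param expected The expected word.
#' @param matcher Function `(responses, expected) -> logical`; default
#'   [match_normalized()].
#' @return Percentage in `[0, 100]`.
#' @examples
#' score_association(c(rep("leer", 24), rep("ver", 6)), "leer")  # 80
#' @export
score_association <- function(responses, expected, matcher = match_normalized) {
  if (!length(responses)) stop("no responses")
  100 * sum(matcher(responses, expected)) / length(responses)
}

#' @rdname score_association
#' @export
match_normalized <- function(responses, expected) {
  norm <- function(s) {
    s <- tolower(trimws(s))
    chartr("áéíóúüñàèìòùâêîôûç",
           "aeiouunaeiouaeiouc", s)
  }
  norm(responses) == norm(expected)
}

#' Kruskal-Wallis rank test across condition groups
#'
#' Tie-corrected H with a chi-squared reference on k - 1 df.  All-identical
#' data yield H = 0, p = 1.
#'
#' @param groups A list of numeric vectors (>= 2 groups).
#' @return A list: `H`, `df`, `p`.
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))$H  # 7.2
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1)
    return(list(H = 0, df = length(groups) - 1, p = 1))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Mann-Whitney U with normal-approximation z
#'
#' `U` counts pairwise wins of `g1` over `g2` plus half-ties.  The z
#' statistic uses the normal approximation with, optionally, the
#' tie-corrected variance and a 0.5 continuity correction; `|z|` is
#' reported with its two-sided normal p.  Both corrections default to on.
#'
#' @param g1,g2 Numeric vectors.
#' @param continuity Apply the 0.5 continuity correction.
#' @param tie_correction Use the tie-corrected variance.
#' @return A list: `U`, `z` (absolute), `p`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))$U  # 0
#' @export
mann_whitney <- function(g1, g2, continuity = TRUE, tie_correction = TRUE) {
  if (!length(g1) || !length(g2)) stop("both groups must be non-empty")
  n1 <- length(g1); n2 <- length(g2); n <- n1 + n2
  r <- rank(c(g1, g2))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (tie_correction) {
    ties <- table(c(g1, g2))
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  } else {
    v <- n1 * n2 * (n + 1) / 12
  }
  if (v <= 0) return(list(U = U, z = 0, p = 1))
  num <- abs(U - mu)
  if (continuity) num <- max(num - 0.5, 0)
  z <- num / sqrt(v)
  list(U = U, z = z, p = 2 * stats::pnorm(-z))
}

#' Correlation between association strength and plausibility
#'
#' Pearson correlation with its two-sided test, linking the two
#' stimulus-norming measures.
#'
#' @param strengths,plausibilities Paired numeric vectors, n >= 3.
#' @return A list: `r`, `p`, `n`.
#' @export
strength_plausibility_correlation <- function(strengths, plausibilities) {
  if (length(strengths) != length(plausibilities) || length(strengths) < 3)
    stop("need paired vectors of length >= 3")
  if (stats::sd(strengths) == 0 || stats::sd(plausibilities) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(strengths, plausibilities)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(strengths))
}

#' Packaged association-strength norming table
#'
#' Loads the packaged item-level norming table: for each of the 28 image
#' pairs, the verb-to-target and verb-to-distractor association strength
#' (percent of respondents) of the predictive sentence (CV for pairs 1--14,
#' MV for 15--28) and of its unrelated-verb counterpart.
#'
#' @return A data.frame: `item_id`, `condition`, `target`, `distractor`,
#'   `uv_target`, `uv_distractor`.
#' @export
association_table <- function() {
  path <- system.file("extdata", "association_table.csv",
                      package = "predlook", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
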