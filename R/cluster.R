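#' Per-bin paired t series between two conditions
#'
#' One paired t statistic per 100 ms bin, computed on subject-level
#' differences between two condition curve matrices (subjects x bins, as
#' from [curve_matrix()]).  Subjects lacking a valid value in a bin for
#' either condition are dropped pairwise for that bin; bins with fewer than
#' two complete pairs, or zero variance, get `NA`.
#'
#' @param curves_a,curves_b Numeric matrices, same subjects in rows, bins
#'   in columns.
#' @return A list of class `"pl_tseries"`: `t` (per-bin statistic), `n`
#'   (complete pairs per bin), `t_start_rel` (bin times from column names).
#' @export
t_series_paired <- function(curves_a, curves_b) {
  stopifnot(all(dim(curves_a) == dim(curves_b)))
  d <- curves_a - curves_b
  t_series_from_diffs(d, colnames(curves_a))
}

#' Per-bin one-sample t series against chance
#'
#' @param curves Subjects x bins matrix of per-subject mean proportions.
#' @param mu Null value (chance level 0.5 in a two-AOI display).
#' @return As [t_series_paired()].
#' @export
t_series_one_sample <- function(curves, mu = 0.5) {
  t_series_from_diffs(curves - mu, colnames(curves))
}

t_series_from_diffs <- function(d, bin_names) {
  n <- colSums(!is.na(d))
  m <- colMeans(d, na.rm = TRUE)
  s <- apply(d, 2, stats::sd, na.rm = TRUE)
  t <- m / (s / sqrt(n))
  t[n < 2 | !is.finite(t)] <- NA_real_
  structure(list(t = unname(t), n = unname(n),
                 t_start_rel = as.numeric(bin_names)),
            class = "pl_tseries")
}

#' Critical t for cluster formation
#'
#' Two-tailed Student quantile at `alpha` with `n - 1` degrees of freedom
#' (about 2.09 for 21 subjects, 2.03 for 36).  `override` accepts a literal
#' value to reproduce a published threshold regardless of df convention; it
#' is used verbatim and recorded in an attribute.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param alpha Two-tailed alpha (default 0.05).
#' @param override Optional literal critical value.
#' @return The critical t (positive).
#' @examples
#' critical_t_for(21)  # ~2.086
#' @export
critical_t_for <- function(n_subjects, alpha = 0.05, override = NULL) {
  if (!is.null(override)) {
    out <- override
    attr(out, "source") <- "override"
    return(out)
  }
  if (n_subjects < 2) stop("need at least 2 subjects")
  stats::qt(1 - alpha / 2, df = n_subjects - 1)
}

#' Find supra-threshold clusters in a t series
#'
#' Clusters are maximal runs of contiguous bins whose `|t|` exceeds the
#' critical value and whose t values share one sign; the cluster mass is
#' the sum of its member t values.  Bins with undefined t break
#' contiguity.  Positive and negative clusters are both returned.
#'
#' @param tseries A `"pl_tseries"` (or plain numeric vector of t values).
#' @param critical_t Positive cluster-forming threshold.
#' @param bin_ms Bin width for reporting start/end times.
#' @return A data.frame per cluster: `start_ms`, `end_ms` (half-open over
#'   bins), `start_bin`, `end_bin`, `mass`, `sign`, `t_max` (largest |t|).
#' @export
find_clusters <- function(tseries, critical_t, bin_ms = 100) {
  if (critical_t <= 0) stop("critical_t must be positive")
  t <- if (inherits(tseries, "pl_tseries")) tseries$t else as.numeric(tseries)
  times <- if (inherits(tseries, "pl_tseries")) tseries$t_start_rel
           else (seq_along(t) - 1) * bin_ms
  lab <- ifelse(is.na(t) | abs(t) <= critical_t, 0, sign(t))
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  if (!any(keep))
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      start_bin = integer(0), end_bin = integer(0),
                      mass = numeric(0), sign = character(0),
                      t_max = numeric(0)))
  s <- starts[keep]; e <- ends[keep]
  mass <- mapply(function(a, b) sum(t[a:b]), s, e)
  tmax <- mapply(function(a, b) max(abs(t[a:b])), s, e)
  data.frame(start_ms = times[s], end_ms = times[e] + bin_ms,
             start_bin = s, end_bin = e, mass = mass,
             sign = ifelse(mass > 0, "+", "-"), t_max = tmax,
             stringsAsFactors = FALSE)
}

# largest |mass| among supra-threshold same-sign runs of one t vector
max_cluster_mass <- function(t, critical_t) {
  row_max_cluster_mass(matrix(t, nrow = 1), critical_t)
}

# per-row largest |cluster mass| of a permutations x bins t matrix,
# computed in one pass: rows are separated by a zero column so runs cannot
# span rows, and run sums come from one cumulative sum
row_max_cluster_mass <- function(tm, critical_t) {
  P <- nrow(tm); B <- ncol(tm)
  v <- as.vector(t(cbind(tm, 0)))
  lab <- sign(v)
  lab[is.na(v) | abs(v) <= critical_t] <- 0
  v[is.na(v)] <- 0
  r <- rle(lab)
  out <- numeric(P)
  keep <- r$values != 0
  if (!any(keep)) return(out)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cs <- c(0, cumsum(v))
  sums <- abs(cs[ends[keep] + 1] - cs[starts[keep]])
  rowid <- (starts[keep] - 1L) %/% (B + 1L) + 1L
  mx <- tapply(sums, rowid, max)
  out[as.integer(names(mx))] <- mx
  out
}

# sign-flip permutation t matrix: rows = permutations, cols = bins.
# Sign flips leave each bin's sum of squares unchanged, so the permuted t
# reduces to a single (n_perm x n_subj) %*% (n_subj x n_bins) product.
perm_t_matrix <- function(d, signs) {
  d0 <- d; d0[is.na(d0)] <- 0
  n_b <- colSums(!is.na(d))
  ss <- colSums(d0^2)
  m <- (signs %*% d0) / rep(n_b, each = nrow(signs))
  varm <- (rep(ss, each = nrow(signs)) - rep(n_b, each = nrow(signs)) * m^2) /
    rep(pmax(n_b - 1, 1), each = nrow(signs))
  varm[varm < 0] <- 0
  tm <- m / sqrt(varm / rep(n_b, each = nrow(signs)))
  tm[, n_b < 2] <- NA_real_
  tm[!is.finite(tm)] <- NA_real_
  tm
}

#' Cluster-mass permutation test on subject-level fixation curves
#'
#' Tests a paired condition contrast or a one-sample contrast against
#' chance over the picture window.  The null distribution records, per
#' iteration, the maximum |cluster mass| after randomly exchanging
#' condition labels within subject (paired) or flipping the sign of each
#' subject's deviation from `mu` (one-sample) -- both reduce to independent
#' per-subject sign flips of the subject-level difference curves.  The
#' permutation p of each observed cluster uses the add-one estimator
#' `(1 + #{perm max >= |mass|}) / (n_perm + 1)`; a cluster is significant
#' when p < 0.05.
#'
#' @param curves_a Subjects x bins matrix (condition A, or the only
#'   condition for a one-sample test).
#' @param curves_b Second condition matrix for `contrast = "paired"`.
#' @param contrast `"paired"` or `"one_sample"`.
#' @param mu Chance level for the one-sample contrast.
#' @param n_perm Number of permutations (default 100,000).
#' @param critical_t Cluster-forming threshold; defaults to
#'   [critical_t_for()] at the panel's subject count.
#' @param seed Integer seed for the permutation RNG.
#' @param block_size Permutations are generated in blocks of this many
#'   iterations to bound memory.
#' @return A data.frame of observed clusters as in [find_clusters()] with a
#'   `p` column, plus attributes `critical_t`, `n_perm` and `perm_max`
#'   (the null distribution).  Zero rows when no bin is supra-threshold.
#' @export
permutation_test <- function(curves_a, curves_b = NULL,
                             contrast = c("paired", "one_sample"),
                             mu = 0.5, n_perm = 100000,
                             critical_t = NULL, seed = 1L,
                             block_size = 20000L) {
  contrast <- match.arg(contrast)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (contrast == "paired") {
    if (is.null(curves_b)) stop("paired contrast needs two curve matrices")
    d <- curves_a - curves_b
  } else {
    d <- curves_a - mu
  }
  n_sub <- nrow(d)
  if (n_sub < 2) stop("need at least 2 subjects")
  if (is.null(critical_t)) critical_t <- critical_t_for(n_sub)
  obs <- t_series_from_diffs(d, colnames(curves_a))
  clusters <- find_clusters(obs, critical_t)
  if (!nrow(clusters)) {
    attr(clusters, "critical_t") <- as.numeric(critical_t)
    attr(clusters, "n_perm") <- n_perm
    return(clusters)
  }
  rng <- local_rng(seed)
  perm_max <- rng_eval(rng, {
    out <- numeric(n_perm)
    done <- 0L
    while (done < n_perm) {
      nb <- min(block_size, n_perm - done)
      signs <- matrix(sample(c(-1, 1), nb * n_sub, replace = TRUE), nb, n_sub)
      tm <- perm_t_matrix(d, signs)
      out[done + seq_len(nb)] <- row_max_cluster_mass(tm, critical_t)
      done <- done + nb
    }
    out
  })
  # permuted masses tied with the observed one count as exceedances; the
  # tolerance absorbs floating-point jitter in the vectorized t computation
  clusters$p <- vapply(clusters$mass, function(m) {
    thr <- abs(m) - 1e-8 * max(1, abs(m))
    (1 + sum(perm_max >= thr)) / (n_perm + 1)
  }, numeric(1))
  clusters$significant <- clusters$p < 0.05
  attr(clusters, "critical_t") <- as.numeric(critical_t)
  attr(clusters, "n_perm") <- n_perm
  attr(clusters, "perm_max") <- perm_max
  clusters
}

#' Cluster report for a whole cohort
#'
#' Runs the paired CV-vs-UV and MV-vs-UV contrasts and the three one-sample
#' chance-level tests on one group's bin table and stacks the results in
#' the reporting layout `(group, contrast, start_ms, end_ms, mass, t_max,
#' p)`.
#'
#' @param bins Tidy bin table for one group.
#' @param group Group label for the report.
#' @param n_perm,critical_t,seed Passed to [permutation_test()].
#' @return A data.frame, one row per cluster over all five contrasts.
#' @export
cluster_report <- function(bins, group = bins$group[1], n_perm = 100000,
                           critical_t = NULL, seed = 1L) {
  curves <- subject_curves(bins)
  mats <- lapply(c(CV = "CV", MV = "MV", UV = "UV"),
                 function(cc) curve_matrix(curves, cc))
  jobs <- list(
    list(label = "CV-UV", a = mats$CV, b = mats$UV, contrast = "paired"),
    list(label = "MV-UV", a = mats$MV, b = mats$UV, contrast = "paired"),
    list(label = "CV-chance", a = mats$CV, b = NULL, contrast = "one_sample"),
    list(label = "MV-chance", a = mats$MV, b = NULL, contrast = "one_sample"),
    list(label = "UV-chance", a = mats$UV, b = NULL, contrast = "one_sample"))
  out <- lapply(seq_along(jobs), function(i) {
    j <- jobs[[i]]
    cl <- permutation_test(j$a, j$b, contrast = j$contrast, n_perm = n_perm,
                           critical_t = critical_t, seed = seed + i)
    if (!nrow(cl)) return(NULL)
    data.frame(group = group, contrast = j$label,
               start_ms = cl$start_ms, end_ms = cl$end_ms,
               mass = cl$mass, t_max = cl$t_max, p = cl$p,
               significant = cl$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(group = character(0), contrast = character(0),
                      start_ms = numeric(0), end_ms = numeric(0),
                      mass = numeric(0), t_max = numeric(0), p = numeric(0),
                      significant = logical(0))
  out
}
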