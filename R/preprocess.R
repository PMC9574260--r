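#' Gap-aware Gaussian smoothing of raw gaze coordinates
#'
#' Convolves each coordinate channel with a normalized Gaussian kernel
#' (`sigma` in samples at the native rate, truncated at 4 sigma).  The
#' kernel is renormalized over the *valid* neighbours at every position, so
#' missing runs neither shrink the smoothed values nor receive leaked ones:
#' invalid samples stay invalid and contribute nothing.
#'
#' @param samples Data.frame with `t_ms`, `x_px`, `y_px`, `valid`, sorted by
#'   time.
#' @param sigma_samples Kernel standard deviation in samples (> 0).
#' @return The same data.frame with smoothed `x_px`, `y_px`.
#' @export
smooth_gaussian <- function(samples, sigma_samples = 5) {
  sm <- smooth_core(samples$x_px, samples$y_px, samples$valid, sigma_samples)
  samples$x_px <- sm$x
  samples$y_px <- sm$y
  samples
}

smooth_core <- function(x, y, v, sigma_samples = 5) {
  if (sigma_samples <= 0) stop("sigma must be positive")
  n <- length(v)
  if (!n || !any(v)) return(list(x = x, y = y))
  hw <- ceiling(4 * sigma_samples)
  k <- stats::dnorm(seq(-hw, hw), sd = sigma_samples)
  k <- k / sum(k)
  iv <- !v
  x[iv] <- 0; y[iv] <- 0
  # one convolution pass over the three channels, separated by 2*hw zeros
  # so the kernel cannot mix them
  pad <- rep(0, 2 * hw)
  z <- c(pad, x, pad, y, pad, as.numeric(v), pad)
  f <- as.numeric(stats::filter(z, k, method = "convolution", sides = 2))
  seg <- function(j) f[(2 * hw * j + n * (j - 1) + 1):(2 * hw * j + n * j)]
  den <- seg(3)
  xs <- seg(1) / den
  ys <- seg(2) / den
  xs[iv] <- NA_real_; ys[iv] <- NA_real_
  list(x = xs, y = ys)
}


#' Interpolate and resample gaze onto a regular grid
#'
#' Linearly interpolates valid samples onto a regular grid (default 20 ms =
#' 50 Hz) aligned to multiples of the period.  No extrapolation: the grid
#' spans the first to the last valid sample.  Missing runs strictly longer
#' than `max_gap_ms` -- measured as the time between the valid samples
#' flanking the run -- are not reconstructed: grid points strictly inside
#' them are `valid = FALSE`.
#'
#' @param samples Data.frame with `t_ms`, `x_px`, `y_px`, `valid`.
#' @param period_ms Output sample period, ms.
#' @param max_gap_ms Longest missing run that may be bridged, ms (strict
#'   greater-than rule).
#' @return A data.frame `t_ms`, `x_px`, `y_px`, `valid` on the regular grid,
#'   with attribute `period_ms`; `NULL` with a warning if the trial has no
#'   valid samples.
#' @export
interpolate_resample <- function(samples, period_ms = 20, max_gap_ms = 150) {
  rs <- resample_core(samples$t_ms, samples$x_px, samples$y_px,
                      samples$valid, period_ms, max_gap_ms)
  if (is.null(rs)) return(NULL)
  out <- data.frame(t_ms = rs$t, x_px = rs$x, y_px = rs$y, valid = rs$valid)
  attr(out, "period_ms") <- period_ms
  out
}

resample_core <- function(t, x, y, ok, period_ms = 20, max_gap_ms = 150) {
  if (!any(ok)) {
    warning("trial has no valid samples; flagged empty")
    return(NULL)
  }
  tv <- t[ok]; xv <- x[ok]; yv <- y[ok]
  t0 <- ceiling(tv[1] / period_ms) * period_ms
  t1 <- floor(tv[length(tv)] / period_ms) * period_ms
  if (t1 < t0) {
    warning("trial too short to cover any grid point")
    return(NULL)
  }
  grid <- seq(t0, t1, by = period_ms)
  gx <- stats::approx(tv, xv, xout = grid, method = "linear", ties = "ordered")$y
  gy <- stats::approx(tv, yv, xout = grid, method = "linear", ties = "ordered")$y
  valid <- rep(TRUE, length(grid))
  gaps <- diff(tv)
  long <- which(gaps > max_gap_ms)
  for (i in long)
    valid[grid > tv[i] & grid < tv[i + 1]] <- FALSE
  gx[!valid] <- NA_real_
  gy[!valid] <- NA_real_
  list(t = grid, x = gx, y = gy, valid = valid)
}

point_in_box <- function(x, y, box) {
  # half-open: left/top edges inside, right/bottom edges outside
  x >= box$center_x - box$width / 2 & x < box$center_x + box$width / 2 &
  y >= box$center_y - box$height / 2 & y < box$center_y + box$height / 2
}

boxes_overlap <- function(a, b) {
  ax0 <- a$center_x - a$width / 2;  ax1 <- a$center_x + a$width / 2
  bx0 <- b$center_x - b$width / 2;  bx1 <- b$center_x + b$width / 2
  ay0 <- a$center_y - a$height / 2; ay1 <- a$center_y + a$height / 2
  by0 <- b$center_y - b$height / 2; by1 <- b$center_y + b$height / 2
  (ax0 < bx1 & bx0 < ax1) & (ay0 < by1 & by0 < ay1)
}

#' Code a regular gaze series into binary AOI membership
#'
#' Each valid grid point is coded 1 for an AOI when the coordinates lie
#' inside that box, else 0.  Boxes are half-open (left/top edge inside,
#' right/bottom edge outside) so no point can belong to two adjacent boxes.
#' Invalid grid points carry `NA` flags and are excluded from all counts.
#'
#' @param series A regular series from [interpolate_resample()].
#' @param target_box,distractor_box [pl_aoi()] boxes already scaled to this
#'   trial's screen via [scale_aoi()].
#' @return The series with integer columns `target` and `distractor`.
#' @export
code_aoi <- function(series, target_box, distractor_box) {
  if (boxes_overlap(target_box, distractor_box))
    stop("target and distractor AOIs overlap")
  tgt <- ifelse(series$valid,
                as.integer(point_in_box(series$x_px, series$y_px, target_box)),
                NA_integer_)
  dis <- ifelse(series$valid,
                as.integer(point_in_box(series$x_px, series$y_px, distractor_box)),
                NA_integer_)
  series$target <- tgt
  series$distractor <- dis
  series
}

#' Bin a coded series into 100 ms fixation counts
#'
#' Bins are half-open `[t, t + bin_ms)` on the relative timebase.  Within a
#' bin, `F_target` counts target hits among the AOI samples, and `N` counts
#' AOI samples (target plus distractor); valid samples outside both AOIs
#' reduce neither count but do count toward total looking time.  `p_target
#' = F_target / N` is the per-bin target-fixation proportion (NA when
#' `N = 0`; such bins are dropped downstream).
#'
#' @param coded A coded series from [code_aoi()].
#' @param bin_ms Bin width, ms.
#' @param window Relative-time analysis window `c(start, end)`, half-open.
#' @param picture_onset_abs Absolute ms of picture onset (origin of relative
#'   time).
#' @return A data.frame per bin: `t_start_rel`, `F_target`, `F_distractor`,
#'   `N`, `p_target`, `n_valid` (valid grid points of any kind in the bin).
#' @export
bin_series <- function(coded, bin_ms = 100, window = c(0, 6000),
                       picture_onset_abs = 1000) {
  b <- bin_core(coded$t_ms - picture_onset_abs, coded$target,
                coded$distractor, coded$valid, bin_ms, window)
  data.frame(t_start_rel = b$t_start_rel, F_target = b$F_target,
             F_distractor = b$F_distractor, N = b$N,
             p_target = ifelse(b$N > 0, b$F_target / b$N, NA_real_),
             n_valid = b$n_valid)
}

bin_core <- function(t_rel, tgt, dis, vld, bin_ms = 100,
                     window = c(0, 6000)) {
  keep <- t_rel >= window[1] & t_rel < window[2]
  nb <- as.integer((window[2] - window[1]) / bin_ms)
  idx <- as.integer(floor((t_rel[keep] - window[1]) / bin_ms)) + 1L
  tgt <- tgt[keep]; dis <- dis[keep]; vld <- vld[keep]
  aoi <- !is.na(tgt) & (tgt == 1L | dis == 1L)
  Ft <- tabulate(idx[aoi & tgt == 1L], nbins = nb)
  Fd <- tabulate(idx[aoi & dis == 1L], nbins = nb)
  list(t_start_rel = window[1] + bin_ms * (seq_len(nb) - 1L),
       F_target = Ft, F_distractor = Fd, N = Ft + Fd,
       n_valid = tabulate(idx[vld], nbins = nb))
}

#' Exclude trials with too little looking at the pictures
#'
#' A trial is dropped when the participant looked at the AOIs for less than
#' `threshold` of the time the competing pictures were on screen (relative
#' 0--6,000 ms): kept iff `sum(N) / (window length / period) >= threshold`
#' (strict less-than drops).
#'
#' @param bins A bin table (multiple trials) with columns `subject`,
#'   `trial`, `N`, `t_start_rel`.
#' @param threshold Minimum looking fraction (default 0.25).
#' @param window Relative window over which looking is assessed.
#' @param period_ms Grid period underlying the bins.
#' @return A list: `kept` and `dropped` bin tables, and `summary` with one
#'   row per trial (`subject`, `trial`, `looking_fraction`, `kept`).
#' @export
exclude_trials <- function(bins, threshold = 0.25, window = c(0, 6000),
                           period_ms = 20) {
  total_pts <- (window[2] - window[1]) / period_ms
  inw <- bins$t_start_rel >= window[1] & bins$t_start_rel < window[2]
  key <- paste(bins$subject, bins$trial, sep = "\r")
  lk <- tapply(bins$N * inw, key, sum) / total_pts
  summary <- data.frame(
    subject = sub("\r.*$", "", names(lk)),
    trial = sub("^.*\r", "", names(lk)),
    looking_fraction = as.numeric(lk),
    kept = as.numeric(lk) >= threshold,
    row.names = NULL, stringsAsFactors = FALSE
  )
  keep_keys <- names(lk)[lk >= threshold]
  keep_row <- key %in% keep_keys
  list(kept = bins[keep_row, , drop = FALSE],
       dropped = bins[!keep_row, , drop = FALSE],
       summary = summary)
}

#' Run the full preprocessing chain on one trial
#'
#' Fixed order: Gaussian smoothing, interpolation/resampling, AOI coding,
#' binning.  Exclusion is applied at cohort level by [exclude_trials()].
#'
#' @inheritParams smooth_gaussian
#' @inheritParams interpolate_resample
#' @inheritParams code_aoi
#' @inheritParams bin_series
#' @return A per-bin data.frame as from [bin_series()], or `NULL` for an
#'   empty trial.
#' @export
preprocess_trial <- function(samples, target_box, distractor_box,
                             sigma_samples = 5, period_ms = 20,
                             max_gap_ms = 150, bin_ms = 100,
                             window = c(0, 6000), picture_onset_abs = 1000) {
  sm <- smooth_gaussian(samples, sigma_samples)
  rs <- suppressWarnings(interpolate_resample(sm, period_ms, max_gap_ms))
  if (is.null(rs)) return(NULL)
  cd <- code_aoi(rs, target_box, distractor_box)
  bin_series(cd, bin_ms, window, picture_onset_abs)
}

#' Preprocess a cohort's gaze table into a tidy bin table
#'
#' Splits the gaze table by trial, scales the reference AOIs to each
#' participant's screen, runs [preprocess_trial()] on every trial and
#' stacks the results into the tidy bin table used by all downstream
#' models.  Trials failing the 25% looking rule are dropped (set
#' `apply_exclusion = FALSE` to keep them).
#'
#' @param gaze Long gaze table (see [read_gaze_table()]); columns
#'   `screen_w`/`screen_h` give each participant's display, defaulting to
#'   the reference.
#' @param design Design table from [build_design()] / [generate_cohort()],
#'   with optional `group` column.
#' @param reference Reference [pl_screen()] on which the AOIs are defined.
#' @param exclusion_threshold Minimum looking fraction; `apply_exclusion`
#'   toggles the rule.
#' @inheritParams preprocess_trial
#' @return A data.frame: `subject`, `group`, `condition`, `item`,
#'   `target_side`, `trial`, `t_start_rel`, `F`, `N`, `p`.
#' @export
preprocess_cohort <- function(gaze, design, reference = pl_screen(),
                              sigma_samples = 5, period_ms = 20,
                              max_gap_ms = 150, bin_ms = 100,
                              window = c(0, 6000), picture_onset_abs = 1000,
                              exclusion_threshold = 0.25,
                              apply_exclusion = TRUE) {
  ref_aois <- pl_default_aois(reference)
  dkey <- paste(design$participant_id, design$trial_index, sep = "\r")
  gkey <- paste(gaze$participant_id, gaze$trial_index, sep = "\r")
  idx_by_trial <- split(seq_len(nrow(gaze)), factor(gkey, levels = unique(gkey)))
  gt <- gaze$t_ms; gx <- gaze$x_px; gy <- gaze$y_px
  gv <- if ("valid" %in% names(gaze)) gaze$valid else !(is.na(gx) | is.na(gy))
  has_screen <- all(c("screen_w", "screen_h") %in% names(gaze))
  nb <- as.integer((window[2] - window[1]) / bin_ms)
  starts <- window[1] + bin_ms * (seq_len(nb) - 1L)
  total_pts <- (window[2] - window[1]) / period_ms

  nt <- length(idx_by_trial)
  Fm <- matrix(0L, nb, nt)
  Nm <- matrix(0L, nb, nt)
  di <- integer(nt)      # row of design for each processed trial
  used <- logical(nt)
  for (i in seq_len(nt)) {
    ix <- idx_by_trial[[i]]
    d <- match(names(idx_by_trial)[i], dkey)
    if (is.na(d)) next
    scr <- if (has_screen) pl_screen(gaze$screen_w[ix[1]], gaze$screen_h[ix[1]])
           else reference
    side <- design$target_side[d]
    tb <- scale_aoi(ref_aois[[side]], reference, scr)
    db <- scale_aoi(ref_aois[[setdiff(c("left", "right"), side)]],
                    reference, scr)
    if (boxes_overlap(tb, db)) stop("target and distractor AOIs overlap")
    sm <- smooth_core(gx[ix], gy[ix], gv[ix], sigma_samples)
    rs <- suppressWarnings(resample_core(gt[ix], sm$x, sm$y, gv[ix],
                                         period_ms, max_gap_ms))
    if (is.null(rs)) next
    # invalid grid points carry NA coordinates, so membership is NA there
    tgt <- as.integer(point_in_box(rs$x, rs$y, tb))
    dis <- as.integer(point_in_box(rs$x, rs$y, db))
    b <- bin_core(rs$t - picture_onset_abs, tgt, dis, rs$valid, bin_ms, window)
    Fm[, i] <- b$F_target
    Nm[, i] <- b$N
    di[i] <- d
    used[i] <- TRUE
  }
  keep_trial <- used
  if (apply_exclusion)
    keep_trial <- used & (colSums(Nm) / total_pts >= exclusion_threshold)
  w <- which(keep_trial)
  d <- di[w]
  bins <- data.frame(
    subject = rep(design$participant_id[d], each = nb),
    group = if ("group" %in% names(design)) rep(design$group[d], each = nb)
            else NA_character_,
    condition = rep(design$condition[d], each = nb),
    item = rep(design$item_id[d], each = nb),
    target_side = rep(design$target_side[d], each = nb),
    trial = rep(design$trial_index[d], each = nb),
    t_start_rel = rep(starts, times = length(w)),
    F = as.integer(Fm[, w]),
    N = as.integer(Nm[, w]),
    stringsAsFactors = FALSE
  )
  bins$p <- ifelse(bins$N > 0, bins$F / bins$N, NA_real_)
  bins
}

#' Subject-level fixation curves from a bin table
#'
#' Averages per-trial bin proportions into one curve per subject x
#' condition x bin (bins with `N = 0` are dropped before averaging) -- the
#' permutation unit for the cluster tests.
#'
#' @param bins A tidy bin table from [preprocess_cohort()].
#' @return A data.frame `subject`, `condition`, `t_start_rel`, `p`.
#' @export
subject_curves <- function(bins) {
  b <- bins[!is.na(bins$p), ]
  key <- paste(b$subject, b$condition, sprintf("%06d", b$t_start_rel),
               sep = "\r")
  sums <- rowsum(cbind(b$p, 1), key)
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  out <- data.frame(
    subject = vapply(parts, `[[`, "", 1),
    condition = vapply(parts, `[[`, "", 2),
    t_start_rel = as.numeric(vapply(parts, `[[`, "", 3)),
    p = sums[, 1] / sums[, 2],
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(out$subject, out$condition, out$t_start_rel), , drop = FALSE]
}

#' Subject-by-bin curve matrix for one condition
#'
#' @param curves Output of [subject_curves()].
#' @param condition Condition label to extract.
#' @return A numeric matrix, subjects in rows, 100 ms bins in columns
#'   (dimnames give subjects and bin start times); missing cells are `NA`.
#' @export
curve_matrix <- function(curves, condition) {
  cc <- curves[curves$condition == condition, ]
  subs <- sort(unique(curves$subject))
  ts <- sort(unique(curves$t_start_rel))
  m <- matrix(NA_real_, length(subs), length(ts),
              dimnames = list(subs, ts))
  m[cbind(match(cc$subject, subs), match(cc$t_start_rel, ts))] <- cc$p
  m
}
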