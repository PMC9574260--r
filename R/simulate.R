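#' Generative parameters for one condition's fixation time-course
#'
#' The simulator drives gaze with a logistic target-preference curve
#' \deqn{p(t) = b + (a - b) / (1 + \exp(-(t - c)/s))}
#' where `b` is the pre-disambiguation baseline (chance = 0.5 in a two-AOI
#' display), `a` the asymptotic target preference, `c` the crossover time
#' (ms, relative to picture onset) and `s` the logistic scale.  The group
#' onset shift translates `c` horizontally: participants with Down syndrome
#' anticipate the target about 200 ms later than typically developing
#' children, so the default shift is `c(TD = 0, DS = 200, adult = 0)`.
#' For unrelated-verb (UV) sentences the crossover is anchored after noun
#' onset (4,000 ms relative): the default UV crossover is 4,800 ms.
#'
#' Sampling emulates a webcam tracker: ~60 Hz irregular sampling
#' (`sample_period_mean_ms = 16.7` with Gaussian jitter), ~100 px positional
#' noise, a per-sample probability `off_aoi_p` of looking away from both
#' AOIs, and missing runs that start with probability `gap_rate` per sample
#' and have geometric length with mean `gap_mean_ms`.
#'
#' @param condition `"CV"`, `"MV"` or `"UV"`; selects condition defaults.
#' @param baseline_p,asymptote_p Pre/post-disambiguation target-fixation
#'   probabilities, in `[0, 1]`.
#' @param crossover_ms Curve midpoint, ms relative to picture onset.
#' @param slope_ms Logistic scale, ms; must be positive.
#' @param onset_shift_ms Named numeric vector of per-group horizontal shifts
#'   of the crossover, ms.
#' @param noise_sd_px Isotropic Gaussian positional noise, px.
#' @param off_aoi_p Per-sample probability of an off-AOI look.
#' @param gap_rate Per-sample probability of starting a missing run.
#' @param gap_mean_ms Mean missing-run length, ms.
#' @param sample_period_mean_ms,sample_period_jitter_sd_ms Sampling period
#'   mean and jitter, ms.
#' @return An object of class `"pl_simparams"`.
#' @examples
#' sim_params("CV")
#' sim_params("UV")$crossover_ms  # anchored after the noun
#' @export
sim_params <- function(condition = c("CV", "MV", "UV"),
                       baseline_p = 0.5,
                       asymptote_p = NULL,
                       crossover_ms = NULL,
                       slope_ms = 250,
                       onset_shift_ms = c(TD = 0, DS = 200, adult = 0),
                       noise_sd_px = 100,
                       off_aoi_p = 0.15,
                       gap_rate = 0.005,
                       gap_mean_ms = 300,
                       sample_period_mean_ms = 16.7,
                       sample_period_jitter_sd_ms = 2) {
  condition <- match.arg(condition)
  if (is.null(asymptote_p))
    asymptote_p <- switch(condition, CV = 0.80, MV = 0.75, UV = 0.75)
  if (is.null(crossover_ms))
    crossover_ms <- switch(condition, CV = 2800, MV = 3100, UV = 4800)
  stopifnot(baseline_p >= 0, baseline_p <= 1,
            asymptote_p >= 0, asymptote_p <= 1,
            off_aoi_p >= 0, off_aoi_p <= 1,
            slope_ms > 0, crossover_ms >= 0, gap_mean_ms >= 0,
            sample_period_mean_ms > 0)
  structure(list(condition = condition,
                 baseline_p = baseline_p, asymptote_p = asymptote_p,
                 crossover_ms = crossover_ms, slope_ms = slope_ms,
                 onset_shift_ms = onset_shift_ms,
                 noise_sd_px = noise_sd_px, off_aoi_p = off_aoi_p,
                 gap_rate = gap_rate, gap_mean_ms = gap_mean_ms,
                 sample_period_mean_ms = sample_period_mean_ms,
                 sample_period_jitter_sd_ms = sample_period_jitter_sd_ms),
            class = "pl_simparams")
}

#' Default per-condition simulation parameters
#'
#' One [sim_params()] per condition.  `effects = "null"` sets every
#' asymptote equal to the 0.5 baseline (no condition discriminates target
#' from distractor -- the type-I calibration regime); `"cv_only"` leaves an
#' anticipatory rise in CV only, with MV matching UV (a DS-like regime);
#' `"full"` keeps the CV > MV > UV default pattern.
#'
#' @param effects `"full"`, `"cv_only"` or `"null"`.
#' @param ... Passed on to every [sim_params()] call (e.g. `off_aoi_p`).
#' @return A named list of three `"pl_simparams"` objects.
#' @export
default_sim_params <- function(effects = c("full", "cv_only", "null"), ...) {
  effects <- match.arg(effects)
  p <- list(CV = sim_params("CV", ...),
            MV = sim_params("MV", ...),
            UV = sim_params("UV", ...))
  if (effects == "null") {
    for (cc in names(p)) p[[cc]]$asymptote_p <- p[[cc]]$baseline_p
  } else if (effects == "cv_only") {
    p$MV$asymptote_p <- p$UV$asymptote_p
    p$MV$crossover_ms <- p$UV$crossover_ms
  }
  p
}

#' Logistic target-fixation probability at a relative time
#'
#' @param params A [sim_params()] object.
#' @param t_rel Time(s) in ms relative to picture onset; vectorised.
#' @param group Group label indexing `params$onset_shift_ms` (unknown labels
#'   shift by 0).
#' @return Probability of fixating the target AOI at each `t_rel`.
#' @examples
#' p <- sim_params("CV")
#' target_curve(p, p$crossover_ms)  # midpoint: (baseline + asymptote)/2
#' @export
target_curve <- function(params, t_rel, group = "TD") {
  shift <- params$onset_shift_ms[group]
  if (is.na(shift)) shift <- 0
  cc <- params$crossover_ms + unname(shift)
  params$baseline_p + (params$asymptote_p - params$baseline_p) /
    (1 + exp(-(t_rel - cc) / params$slope_ms))
}

#' Simulate one trial's raw gaze samples
#'
#' Generates irregular ~60 Hz samples over the whole trial.  At each sample
#' the gaze is off-AOI (uniform over a 200 px frame outside both AOIs) with
#' probability `off_aoi_p`; otherwise it lands near the target AOI center
#' with probability [target_curve()] at that moment, else near the
#' distractor center, with isotropic Gaussian positional noise.  Missing
#' runs (tracking loss) start with probability `gap_rate` per sample and
#' last a geometric number of samples with mean `gap_mean_ms`.
#'
#' @param params A [sim_params()].
#' @param target_side `"left"` or `"right"`.
#' @param group Group label for the onset shift.
#' @param geometry A [pl_screen()] for this participant.
#' @param timeline A [pl_timeline()].
#' @param seed Integer seed; the same seed reproduces the trial exactly.
#' @param crossover_shift_ms,asym_logit_shift Per-subject random-effect
#'   offsets applied to the crossover (ms) and to the logit of the
#'   asymptote.
#' @return A data.frame of samples: `t_ms` (absolute), `x_px`, `y_px`,
#'   `valid`.
#' @export
sample_trial <- function(params, target_side = "left", group = "TD",
                         geometry = pl_screen(), timeline = pl_timeline(),
                         seed = 1L, crossover_shift_ms = 0,
                         asym_logit_shift = 0) {
  as.data.frame(sample_trial_core(params, target_side, group, geometry,
                                  timeline, seed, crossover_shift_ms,
                                  asym_logit_shift))
}

# vector-level simulator shared by sample_trial() and generate_cohort()
sample_trial_core <- function(params, target_side, group, geometry,
                              timeline, seed, crossover_shift_ms = 0,
                              asym_logit_shift = 0) {
  rng <- local_rng(seed)
  rng_eval(rng, {
    per <- params$sample_period_mean_ms
    n <- ceiling(timeline$trial_end_abs / per) + 8L
    dt <- pmax(1, stats::rnorm(n, per, params$sample_period_jitter_sd_ms))
    t_ms <- cumsum(dt)
    t_ms <- t_ms[t_ms < timeline$trial_end_abs]
    n <- length(t_ms)
    t_rel <- t_ms - timeline$picture_onset_abs

    p2 <- params
    p2$crossover_ms <- p2$crossover_ms + crossover_shift_ms
    if (asym_logit_shift != 0)
      p2$asymptote_p <- stats::plogis(stats::qlogis(
        min(max(p2$asymptote_p, 1e-6), 1 - 1e-6)) + asym_logit_shift)
    p_t <- target_curve(p2, t_rel, group)

    W <- geometry$width_px; H <- geometry$height_px
    tx <- if (target_side == "left") W / 4 else 3 * W / 4
    dx <- W - tx
    tgt <- list(center_x = tx, center_y = H / 2, width = W / 2, height = H)
    dis <- list(center_x = dx, center_y = H / 2, width = W / 2, height = H)

    off <- stats::runif(n) < params$off_aoi_p
    on_target <- stats::runif(n) < p_t
    cx <- rep(dx, n); cx[on_target] <- tx
    x <- cx + stats::rnorm(n, 0, params$noise_sd_px)
    y <- H / 2 + stats::rnorm(n, 0, params$noise_sd_px)

    if (any(off)) {
      o <- off_aoi_points(sum(off), geometry, list(tgt, dis), margin = 200)
      x[off] <- o$x; y[off] <- o$y
    }

    valid <- rep(TRUE, n)
    starts <- which(stats::runif(n) < params$gap_rate)
    if (length(starts)) {
      mean_len <- max(1, params$gap_mean_ms / per)
      lens <- stats::rgeom(length(starts), 1 / mean_len) + 1L
      bad <- unlist(mapply(function(s, l) s:min(n, s + l - 1L), starts, lens,
                           SIMPLIFY = FALSE))
      valid[bad] <- FALSE
    }
    x[!valid] <- NA_real_
    y[!valid] <- NA_real_
    list(t_ms = t_ms, x_px = x, y_px = y, valid = valid)
  })
}

# uniform points in a frame around the screen, outside both AOI boxes
off_aoi_points <- function(k, geometry, boxes, margin = 200) {
  W <- geometry$width_px; H <- geometry$height_px
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < k) {
    m <- 2L * (k - length(xs)) + 8L
    x <- stats::runif(m, -margin, W + margin)
    y <- stats::runif(m, -margin, H + margin)
    inside <- rep(FALSE, m)
    for (b in boxes)
      inside <- inside | (x >= b$center_x - b$width / 2 &
                          x <  b$center_x + b$width / 2 &
                          y >= b$center_y - b$height / 2 &
                          y <  b$center_y + b$height / 2)
    xs <- c(xs, x[!inside]); ys <- c(ys, y[!inside])
  }
  list(x = xs[seq_len(k)], y = ys[seq_len(k)])
}

rng_eval <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(rng$seed)
  expr
}

#' Simulate a full cohort's gaze and design tables
#'
#' Builds one counterbalanced 28-trial design per subject (rotating the four
#' presentation orders) and simulates every trial.  Gaussian per-subject
#' random effects on the crossover (ms) and on the logit asymptote induce
#' the between-subject variance the mixed models assume.  Screens are drawn
#' per subject from common display sizes to emulate heterogeneous hardware.
#' A single base seed is split per subject and trial by counter, so any
#' subset of subjects is reproducible.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param group Group label (`"TD"`, `"DS"`, `"adult"`, ...).
#' @param params_by_condition Named list of [sim_params()] per condition, as
#'   from [default_sim_params()].
#' @param seed Integer base seed.
#' @param subj_crossover_sd Between-subject SD of the crossover shift, ms.
#' @param subj_asym_sd Between-subject SD of the logit-asymptote shift.
#' @param screens List of candidate [pl_screen()] objects.
#' @return A list: `gaze` (long sample table with screen geometry columns)
#'   and `design` (stacked [build_design()] rows plus a `group` column).
#' @examples
#' coh <- generate_cohort(3, "TD", seed = 42)
#' nrow(coh$design)  # 84 = 3 x 28 trials
#' @export
generate_cohort <- function(n_subjects, group = "TD",
                            params_by_condition = default_sim_params(),
                            seed = 1L,
                            subj_crossover_sd = 150,
                            subj_asym_sd = 0.3,
                            screens = list(pl_screen(1920, 1080),
                                           pl_screen(1600, 1200),
                                           pl_screen(1366, 768))) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  timeline <- pl_timeline()
  designs <- vector("list", n_subjects)
  gaze <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("%s%02d", tolower(group), i)
    des <- build_design(sid, order_id = ((i - 1L) %% 4L) + 1L,
                        seed = seed + 101L * i)
    srng <- local_rng(seed + 7919L * i)
    re <- rng_eval(srng, list(
      screen = screens[[sample.int(length(screens), 1)]],
      cshift = stats::rnorm(1, 0, subj_crossover_sd),
      ashift = stats::rnorm(1, 0, subj_asym_sd)))
    des$group <- group
    trials <- vector("list", nrow(des))
    for (j in seq_len(nrow(des))) {
      tr <- sample_trial_core(params_by_condition[[des$condition[j]]],
                              target_side = des$target_side[j], group = group,
                              geometry = re$screen, timeline = timeline,
                              seed = (seed + 2048L * i + j) %% .Machine$integer.max,
                              crossover_shift_ms = re$cshift,
                              asym_logit_shift = re$ashift)
      tr$trial_index <- rep(des$trial_index[j], length(tr$t_ms))
      trials[[j]] <- tr
    }
    nper <- vapply(trials, function(tr) length(tr$t_ms), integer(1))
    gaze[[i]] <- list(
      participant_id = rep(sid, sum(nper)),
      trial_index = unlist(lapply(trials, `[[`, "trial_index")),
      t_ms = unlist(lapply(trials, `[[`, "t_ms")),
      x_px = unlist(lapply(trials, `[[`, "x_px")),
      y_px = unlist(lapply(trials, `[[`, "y_px")),
      valid = unlist(lapply(trials, `[[`, "valid")),
      screen_w = rep(re$screen$width_px, sum(nper)),
      screen_h = rep(re$screen$height_px, sum(nper)))
    designs[[i]] <- des
  }
  gz <- data.frame(
    participant_id = unlist(lapply(gaze, `[[`, "participant_id")),
    trial_index = unlist(lapply(gaze, `[[`, "trial_index")),
    t_ms = unlist(lapply(gaze, `[[`, "t_ms")),
    x_px = unlist(lapply(gaze, `[[`, "x_px")),
    y_px = unlist(lapply(gaze, `[[`, "y_px")),
    valid = unlist(lapply(gaze, `[[`, "valid")),
    screen_w = unlist(lapply(gaze, `[[`, "screen_w")),
    screen_h = unlist(lapply(gaze, `[[`, "screen_h")),
    stringsAsFactors = FALSE)
  list(gaze = gz, design = do.call(rbind, designs))
}

#' Least-squares fit of the logistic fixation curve to a binned time-course
#'
#' Recovers asymptote and crossover (and optionally slope) from per-bin
#' target proportions by unweighted least squares against the
#' [target_curve()] form with a fixed baseline.
#'
#' @param p Observed per-bin proportions.
#' @param t_rel Bin times, ms relative to picture onset.
#' @param baseline Fixed baseline probability.
#' @param slope_ms Fixed logistic scale; if `NULL` the slope is estimated
#'   too.
#' @return Named vector with `asymptote_p`, `crossover_ms` (and `slope_ms`
#'   when estimated).
#' @export
fit_fixation_curve <- function(p, t_rel, baseline = 0.5, slope_ms = 250) {
  ok <- is.finite(p)
  p <- p[ok]; t_rel <- t_rel[ok]
  obj <- function(th) {
    a <- stats::plogis(th[1]); cc <- th[2]
    s <- if (length(th) > 2) exp(th[3]) else slope_ms
    mu <- baseline + (a - baseline) / (1 + exp(-(t_rel - cc) / s))
    sum((p - mu)^2)
  }
  init <- c(stats::qlogis(min(max(max(p), 0.55), 0.99)),
            t_rel[which.min(abs(p - (baseline + max(p)) / 2))])
  if (is.null(slope_ms)) init <- c(init, log(250))
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000))
  out <- c(asymptote_p = stats::plogis(fit$par[1]),
           crossover_ms = fit$par[2])
  if (is.null(slope_ms)) out <- c(out, slope_ms = exp(fit$par[3]))
  out
}
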