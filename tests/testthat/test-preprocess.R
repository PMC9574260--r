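test_that("gap-aware Gaussian smoothing matches a direct convolution oracle", {
  set.seed(7)
  n <- 50
  valid <- runif(n) > 0.2
  x <- rnorm(n, 400, 80); y <- rnorm(n, 500, 60)
  x[!valid] <- NA; y[!valid] <- NA
  tr <- data.frame(t_ms = seq_len(n) * 16.7, x_px = x, y_px = y, valid = valid)
  sm <- smooth_gaussian(tr, sigma_samples = 5)
  expect_equal(sm$x_px, oracle_gauss_smooth(x, valid, 5), tolerance = 1e-9)
  expect_equal(sm$y_px, oracle_gauss_smooth(y, valid, 5), tolerance = 1e-9)
  # invalid samples stay invalid and carry no values
  expect_true(all(is.na(sm$x_px[!valid])))
  expect_error(smooth_gaussian(tr, 0), "positive")
})

test_that("smoothing leaves a constant signal unchanged and an all-invalid trial untouched", {
  tr <- make_trial(n = 80, x_fun = function(t) rep(333, length(t)),
                   y_fun = function(t) rep(222, length(t)))
  sm <- smooth_gaussian(tr)
  expect_equal(sm$x_px, tr$x_px, tolerance = 1e-12)
  expect_equal(sm$y_px, tr$y_px, tolerance = 1e-12)
  dead <- make_trial(n = 30, gap_at = 1, gap_len = 30)
  expect_identical(smooth_gaussian(dead), dead)
})

test_that("resampling interpolates linearly and honours the strict >150 ms gap rule", {
  tr <- data.frame(t_ms = c(0, 40), x_px = c(100, 200), y_px = c(0, 80),
                   valid = TRUE)
  rs <- interpolate_resample(tr, period_ms = 20)
  expect_equal(rs$t_ms, c(0, 20, 40))
  expect_equal(rs$x_px, c(100, 150, 200))
  expect_equal(rs$y_px, c(0, 40, 80))

  # 160 ms between flanking valid samples: not reconstructed
  tr2 <- data.frame(t_ms = c(0, 20, 180, 200), x_px = c(1, 2, 10, 11),
                    y_px = 0, valid = TRUE)
  rs2 <- interpolate_resample(tr2)
  inside <- rs2$t_ms > 20 & rs2$t_ms < 180
  expect_true(all(!rs2$valid[inside]))
  expect_true(all(is.na(rs2$x_px[inside])))
  expect_true(all(rs2$valid[!inside]))

  # exactly 150 ms: interpolated (rule is strictly greater-than)
  tr3 <- data.frame(t_ms = c(0, 30, 180, 200), x_px = c(1, 2, 10, 11),
                    y_px = 0, valid = TRUE)
  rs3 <- interpolate_resample(tr3)
  expect_true(all(rs3$valid))

  expect_warning(out <- interpolate_resample(
    data.frame(t_ms = 1:3, x_px = NA_real_, y_px = NA_real_, valid = FALSE)),
    "no valid samples")
  expect_null(out)
})

test_that("resampling matches an independent gap-length scan on random gappy trials", {
  for (s in 1:10) {
    tr <- make_trial(n = 150, seed = s, gap_at = c(30, 90), gap_len = s,
                     x_fun = function(t) 300 + 0.05 * t,
                     y_fun = function(t) 500 - 0.02 * t)
    rs <- interpolate_resample(tr, period_ms = 20, max_gap_ms = 150)
    orc <- oracle_resample(tr$t_ms, tr$x_px, tr$valid, 20, 150)
    expect_equal(rs$t_ms, orc$t)
    expect_equal(rs$valid, orc$valid)
    expect_equal(rs$x_px[rs$valid], orc$x[orc$valid], tolerance = 1e-9)
  }
})

test_that("a gapless on-grid signal is reproduced exactly", {
  tr <- data.frame(t_ms = seq(0, 2000, by = 20),
                   x_px = sin(seq(0, 2000, by = 20) / 100) * 100 + 500,
                   y_px = 300, valid = TRUE)
  rs <- interpolate_resample(tr)
  expect_equal(rs$t_ms, tr$t_ms)
  expect_equal(rs$x_px, tr$x_px, tolerance = 1e-12)
  expect_true(all(rs$valid))
})

test_that("AOI coding uses half-open boxes with left/top edges inside", {
  tb <- pl_aoi(480, 540, 960, 1080, "left")
  db <- pl_aoi(1440, 540, 960, 1080, "right")
  corners <- data.frame(
    t_ms = seq(0, 140, by = 20),
    x_px = c(480, 0, 960, 959.999, 1000, 2000, -1, 480),
    y_px = c(540, 0, 540, 540, 540, 540, 540, 1080),
    valid = c(rep(TRUE, 7), TRUE))
  cd <- code_aoi(corners, tb, db)
  expect_equal(cd$target, c(1L, 1L, 0L, 1L, 0L, 0L, 0L, 0L))
  expect_equal(cd$distractor, c(0L, 0L, 1L, 0L, 1L, 0L, 0L, 0L))
  # invalid points yield NA flags
  corners$valid[1] <- FALSE
  corners$x_px[1] <- NA; corners$y_px[1] <- NA
  cd2 <- code_aoi(corners, tb, db)
  expect_true(is.na(cd2$target[1]) && is.na(cd2$distractor[1]))
  expect_error(code_aoi(corners, tb, pl_aoi(900, 540, 960, 1080, "right")),
               "overlap")
})

test_that("binning counts AOI samples per half-open 100 ms bin, matching a per-sample tally", {
  set.seed(21)
  for (s in 1:5) {
    n <- 300
    series <- data.frame(
      t_ms = 1000 + seq(0, by = 20, length.out = n),
      x_px = runif(n, -100, 2020), y_px = runif(n, -100, 1180),
      valid = runif(n) > 0.15)
    series$x_px[!series$valid] <- NA
    series$y_px[!series$valid] <- NA
    tb <- pl_aoi(480, 540, 960, 1080, "left")
    db <- pl_aoi(1440, 540, 960, 1080, "right")
    cd <- code_aoi(series, tb, db)
    bn <- bin_series(cd, bin_ms = 100, window = c(0, 6000))
    orc <- oracle_bin_tally(cd$t_ms - 1000, cd$target, cd$distractor,
                            100, c(0, 6000))
    expect_equal(bn$F_target, orc$F_target)
    expect_equal(bn$N, orc$N)
    expect_equal(bn$F_target + bn$F_distractor, bn$N)
    expect_true(all(is.na(bn$p_target[bn$N == 0])))
    expect_equal(bn$p_target[bn$N > 0],
                 (bn$F_target / bn$N)[bn$N > 0])
    # conservation: the bins account for every valid grid point in window
    t_rel <- cd$t_ms - 1000
    expect_equal(sum(bn$n_valid),
                 sum(cd$valid & t_rel >= 0 & t_rel < 6000))
  }
})

test_that("a bin with equal target and distractor samples has p = 0.5", {
  series <- data.frame(t_ms = 1000 + seq(0, 950, by = 50),
                       x_px = rep(c(480, 1440), 10), y_px = 540, valid = TRUE)
  cd <- code_aoi(series, pl_aoi(480, 540, 960, 1080, "left"),
                 pl_aoi(1440, 540, 960, 1080, "right"))
  bn <- bin_series(cd, window = c(0, 1000))
  expect_equal(bn$p_target, rep(0.5, 10))
})

test_that("trials looking under 25% are dropped, with a strict-less-than boundary", {
  mk <- function(subject, trial, Ns) data.frame(
    subject = subject, trial = trial, t_start_rel = seq(0, 5900, by = 100),
    N = Ns, F = 0)
  # 300 grid points in window; 25% = 75 AOI samples
  bins <- rbind(mk("s1", 1, rep(1, 60)),              # 60/300 = 20% -> drop
                mk("s1", 2, c(rep(2, 15), rep(1, 45))), # 75/300 = 25% -> keep
                mk("s2", 1, rep(5, 60)))              # 100% of 5-sample bins
  ex <- exclude_trials(bins, threshold = 0.25)
  expect_equal(sort(unique(paste(ex$kept$subject, ex$kept$trial))),
               c("s1 2", "s2 1"))
  expect_equal(unique(paste(ex$dropped$subject, ex$dropped$trial)), "s1 1")
  sm <- ex$summary[order(ex$summary$subject, ex$summary$trial), ]
  expect_equal(sm$looking_fraction, c(0.2, 0.25, 1))
  expect_equal(sm$kept, c(FALSE, TRUE, TRUE))
})

test_that("cohort preprocessing matches an independent recount and per-trial reconstruction", {
  coh <- generate_cohort(4, "TD", seed = 99)
  bins <- preprocess_cohort(coh$gaze, coh$design, apply_exclusion = FALSE)
  # recount one trial end-to-end through the exported single-trial chain
  ref <- pl_screen()
  for (pick in c(1, 37, 80)) {
    d <- coh$design[pick, ]
    tr <- coh$gaze[coh$gaze$participant_id == d$participant_id &
                   coh$gaze$trial_index == d$trial_index, ]
    scr <- pl_screen(tr$screen_w[1], tr$screen_h[1])
    aois <- pl_default_aois(ref)
    tb <- scale_aoi(aois[[d$target_side]], ref, scr)
    db <- scale_aoi(aois[[setdiff(c("left", "right"), d$target_side)]], ref, scr)
    one <- preprocess_trial(tr, tb, db)
    got <- bins[bins$subject == d$participant_id & bins$trial == d$trial_index, ]
    expect_equal(got$F, one$F_target)
    expect_equal(got$N, one$N)
  }
  # exclusion recount on a cohort with gap-heavy, low-looking trials
  lowlook <- default_sim_params("full", gap_rate = 0.03, gap_mean_ms = 500)
  coh2 <- generate_cohort(3, "TD", params_by_condition = lowlook, seed = 5)
  all_bins <- preprocess_cohort(coh2$gaze, coh2$design, apply_exclusion = FALSE)
  kept <- preprocess_cohort(coh2$gaze, coh2$design, apply_exclusion = TRUE)
  frac <- tapply(all_bins$N, paste(all_bins$subject, all_bins$trial), sum) / 300
  expect_equal(length(unique(paste(kept$subject, kept$trial))),
               sum(frac >= 0.25))
  expect_lt(sum(frac >= 0.25), nrow(coh2$design))  # the rule actually bit
})

test_that("AOI coding and binning are idempotent on their own output", {
  tb <- pl_aoi(480, 540, 960, 1080, "left")
  db <- pl_aoi(1440, 540, 960, 1080, "right")
  series <- data.frame(t_ms = 1000 + seq(0, 5980, by = 20),
                       x_px = runif(300, 0, 1920), y_px = runif(300, 0, 1080),
                       valid = TRUE)
  cd1 <- code_aoi(series, tb, db)
  cd2 <- code_aoi(cd1, tb, db)
  expect_identical(cd1$target, cd2$target)
  expect_identical(cd1$distractor, cd2$distractor)
  b1 <- bin_series(cd1)
  b2 <- bin_series(cd1)
  expect_identical(b1, b2)
})
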