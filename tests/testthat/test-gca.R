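test_that("the orthogonal time basis is orthonormal, centered, and matches Gram-Schmidt", {
  for (n in c(5, 20, 60)) {
    b <- orthogonal_time_basis(n, 3)
    G <- crossprod(b)
    expect_equal(G, diag(3), tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(colSums(b), c(ot1 = 0, ot2 = 0, ot3 = 0), tolerance = 1e-9)
    gs <- gram_schmidt_basis(n, 3)
    # columns agree up to sign
    for (j in 1:3) {
      s <- sign(sum(b[, j] * gs[, j]))
      expect_equal(b[, j], s * gs[, j], tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
  b1 <- orthogonal_time_basis(3, 1)
  expect_equal(as.numeric(b1), c(-1, 0, 1) / sqrt(2), tolerance = 1e-12)
  expect_error(orthogonal_time_basis(3, 3), "more bins")
})

test_that("empirical log-odds evaluates its closed form including boundary corrections", {
  expect_equal(empirical_log_odds(5, 10, 0), 0)
  expect_equal(empirical_log_odds(2, 10, 0), log(0.25))
  expect_equal(empirical_log_odds(10, 10, 0.5), log(21))
  expect_equal(empirical_log_odds(0, 8, 0.5), log(0.5 / 8.5))
  expect_true(is.na(empirical_log_odds(0, 0)))
  expect_error(empirical_log_odds(5, 3), "F <= N")
})

test_that("the random-structure ladder is deterministic and ordered maximal-first", {
  lad <- random_structure_backoff(3)
  expect_equal(lad[1], "(1 + ot1 + ot2 + ot3 | subject) + (1 | item)")
  expect_equal(lad[length(lad)], "(1 | subject) + (1 | item)")
  expect_true(all(diff(nchar(lad)) < 0))
  expect_identical(lad, random_structure_backoff(3))
})

make_gca_bins <- function(n_sub = 6, n_trial = 6, effect = 0, seed = 1,
                          subj_sd = 0, quadratic = FALSE) {
  set.seed(seed)
  ts <- seq(4000, 5900, by = 100)
  basis <- orthogonal_time_basis(length(ts), 3)
  out <- list()
  k <- 0
  for (s in seq_len(n_sub)) {
    u <- rnorm(1, 0, subj_sd)
    for (cond in c("UV", "CV")) for (tr in seq_len(n_trial)) {
      eta <- 0.1 + u + if (cond == "CV") {
        if (quadratic) effect * basis[, 2] * sqrt(length(ts)) else effect
      } else 0
      p <- plogis(eta + rnorm(length(ts), 0, 0.3))
      N <- rep(20L, length(ts))
      F <- rbinom(length(ts), N, p)
      k <- k + 1
      out[[k]] <- data.frame(subject = sprintf("s%02d", s), group = "TD",
                             condition = cond, item = k %% 28 + 1,
                             trial = tr + (cond == "CV") * n_trial,
                             t_start_rel = ts, F = F, N = N,
                             p = F / N)
    }
  }
  do.call(rbind, out)
}

test_that("perfectly balanced data at chance give a near-zero intercept", {
  ts <- seq(4000, 5900, by = 100)
  out <- list(); k <- 0
  # mirror-image trial pairs: every F = 8 matched by an F = 12, so the
  # log-odds are symmetric about 0 in every design cell
  for (s in 1:4) for (cond in c("UV", "CV")) for (F in c(8L, 12L)) {
    k <- k + 1
    out[[k]] <- data.frame(subject = paste0("s", s), condition = cond,
                           item = (k - 1) %% 4 + 1, trial = k,
                           t_start_rel = ts, F = F, N = 20L, p = F / 20)
  }
  bins <- do.call(rbind, out)
  fit <- fit_gca(bins, correction = 0.5)
  co <- fit$coefficients
  # exactly 0 analytically; the mixed-model optimizer reaches ~1e-5
  expect_lt(abs(co$estimate[co$term == "(Intercept)"]), 1e-4)
  expect_true(all(abs(co$estimate) < 1e-4))
})

test_that("with no grouping variance the mixed fit agrees with weighted least squares", {
  bins <- make_gca_bins(n_sub = 8, n_trial = 4, effect = 0.6, seed = 3)
  fit <- fit_gca(bins)
  d <- bins
  ts <- sort(unique(d$t_start_rel))
  basis <- orthogonal_time_basis(length(ts), 3)
  ix <- match(d$t_start_rel, ts)
  for (j in 1:3) d[[paste0("ot", j)]] <- basis[ix, j]
  d$elog <- empirical_log_odds(d$F, d$N)
  d$condition <- relevel(factor(d$condition), ref = "UV")
  ols <- lm(elog ~ (ot1 + ot2 + ot3) * condition, data = d, weights = d$N)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 0.05)
  expect_equal(fit$coefficients$statistic,
               fit$coefficients$estimate / fit$coefficients$SE,
               tolerance = 1e-6)
  expect_true(all(fit$coefficients$p >= 0 & fit$coefficients$p <= 1))
})

test_that("fitted values are invariant to an orthogonal rotation of the time basis", {
  bins <- make_gca_bins(n_sub = 5, n_trial = 3, effect = 0.4, seed = 8,
                        subj_sd = 0.4)
  f1 <- fit_gca(bins)
  d <- f1$fit@frame
  set.seed(2)
  M <- qr.Q(qr(matrix(rnorm(9), 3)))   # random orthogonal rotation
  B <- as.matrix(d[, c("ot1", "ot2", "ot3")]) %*% M
  d2 <- d
  d2$ot1 <- B[, 1]; d2$ot2 <- B[, 2]; d2$ot3 <- B[, 3]
  f2 <- lme4::lmer(formula(f1$fit), data = d2, weights = d$`(weights)`,
                   REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))
  expect_equal(unname(fitted(f2)), unname(fitted(f1$fit)), tolerance = 1e-4)
})

test_that("a pure quadratic condition contrast is recovered as the dominant interaction", {
  hits <- 0
  for (r in 1:20) {
    bins <- make_gca_bins(n_sub = 8, n_trial = 4, effect = 0.5, seed = 100 + r,
                          subj_sd = 0.2, quadratic = TRUE)
    co <- fit_gca(bins)$coefficients
    inter <- co[grepl("^ot[123]:conditionCV$", co$term), ]
    if (inter$term[which.max(abs(inter$estimate))] == "ot2:conditionCV")
      hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("the aggregated-logit and binomial backends agree on signs and rough magnitude", {
  bins <- make_gca_bins(n_sub = 8, n_trial = 4, effect = 0.6, seed = 12,
                        subj_sd = 0.2)
  f1 <- fit_gca(bins)
  f2 <- fit_gca(bins, backend = "binomial")
  c1 <- f1$coefficients; c2 <- f2$coefficients
  expect_equal(c1$term, c2$term)
  big <- abs(c1$estimate) > 0.2
  expect_equal(sign(c1$estimate[big]), sign(c2$estimate[big]))
  e1 <- c1$estimate[c1$term == "conditionCV"]
  e2 <- c2$estimate[c2$term == "conditionCV"]
  expect_lt(abs(e1 - e2) / abs(e2), 0.25)
  expect_equal(f2$provenance$backend, "binomial")
})

test_that("condition effects are flagged at close to the nominal rate under the null", {
  sig <- 0
  n_rep <- 60
  for (r in 1:n_rep) {
    bins <- make_gca_bins(n_sub = 8, n_trial = 4, effect = 0, seed = 700 + r,
                          subj_sd = 0.3)
    co <- fit_gca(bins)$coefficients
    t_cond <- co$statistic[co$term == "conditionCV"]
    if (abs(t_cond) > 1.96) sig <- sig + 1
  }
  # binomial(60, 0.05): central 99% range is 0..8
  expect_lte(sig, 8)
})
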