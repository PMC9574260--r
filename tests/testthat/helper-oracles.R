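# Independent brute-force oracles used to cross-check the vectorized
# implementations.  Deliberately naive O(n*k) loops.

oracle_gauss_smooth <- function(x, valid, sigma) {
  hw <- ceiling(4 * sigma)
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!valid[i]) next
    num <- 0; den <- 0
    for (j in max(1, i - hw):min(n, i + hw)) {
      if (!valid[j]) next
      w <- dnorm(j - i, sd = sigma)
      num <- num + w * x[j]
      den <- den + w
    }
    out[i] <- num / den
  }
  out
}

# per-grid-point linear interpolation with an explicit gap-length scan
oracle_resample <- function(t, x, valid, period, max_gap) {
  tv <- t[valid]; xv <- x[valid]
  grid <- seq(ceiling(tv[1] / period) * period,
              floor(tv[length(tv)] / period) * period, by = period)
  val <- rep(NA_real_, length(grid))
  ok <- rep(TRUE, length(grid))
  for (g in seq_along(grid)) {
    tg <- grid[g]
    lo <- max(which(tv <= tg))
    hi <- min(which(tv >= tg))
    if (tv[hi] - tv[lo] > max_gap && tg > tv[lo] && tg < tv[hi]) {
      ok[g] <- FALSE
      next
    }
    val[g] <- if (lo == hi) xv[lo]
      else xv[lo] + (xv[hi] - xv[lo]) * (tg - tv[lo]) / (tv[hi] - tv[lo])
  }
  list(t = grid, x = val, valid = ok)
}

# per-sample tally of binned AOI counts
oracle_bin_tally <- function(t_rel, tgt, dis, bin_ms, window) {
  nb <- (window[2] - window[1]) / bin_ms
  Ft <- integer(nb); Fd <- integer(nb)
  for (i in seq_along(t_rel)) {
    if (t_rel[i] < window[1] || t_rel[i] >= window[2]) next
    b <- floor((t_rel[i] - window[1]) / bin_ms) + 1
    if (!is.na(tgt[i]) && tgt[i] == 1) Ft[b] <- Ft[b] + 1L
    if (!is.na(dis[i]) && dis[i] == 1) Fd[b] <- Fd[b] + 1L
  }
  list(F_target = Ft, N = Ft + Fd)
}

oracle_paired_t <- function(a, b) {
  d <- a - b
  d <- d[!is.na(d)]
  if (length(d) < 2) return(NA_real_)
  s <- sd(d)
  if (s == 0) return(NA_real_)
  mean(d) / (s / sqrt(length(d)))
}

# exhaustive sign-flip null of the max-cluster-mass statistic
oracle_signflip_cluster_p <- function(d, critical_t, obs_mass) {
  n <- nrow(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  maxes <- apply(signs, 1, function(s) {
    ds <- d * s
    tt <- apply(ds, 2, function(col) {
      col <- col[!is.na(col)]
      if (length(col) < 2 || sd(col) == 0) return(NA_real_)
      mean(col) / (sd(col) / sqrt(length(col)))
    })
    run_max_mass(tt, critical_t)
  })
  mean(maxes >= abs(obs_mass) - 1e-8 * max(1, abs(obs_mass)))
}

run_max_mass <- function(tt, critical_t) {
  best <- 0; cur <- 0; cur_sign <- 0
  for (v in c(tt, NA)) {
    lab <- if (is.na(v) || abs(v) <= critical_t) 0 else sign(v)
    if (lab != 0 && lab == cur_sign) {
      cur <- cur + v
    } else {
      best <- max(best, abs(cur))
      cur <- if (lab != 0) v else 0
      cur_sign <- lab
    }
  }
  max(best, abs(cur))
}

gram_schmidt_basis <- function(n, order) {
  t <- seq_len(n)
  M <- cbind(1, outer(t, seq_len(order), `^`))
  Q <- matrix(0, n, order + 1)
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    if (j > 1) for (k in 1:(j - 1)) v <- v - sum(v * Q[, k]) * Q[, k]
    Q[, j] <- v / sqrt(sum(v^2))
  }
  Q[, -1, drop = FALSE]
}

# small synthetic raw trial with scriptable gap runs
make_trial <- function(n = 120, period = 16.7, seed = 1, gap_at = integer(0),
                       gap_len = 0, x_fun = function(t) 400 + 0 * t,
                       y_fun = function(t) 540 + 0 * t) {
  set.seed(seed)
  t <- cumsum(pmax(1, rnorm(n, period, 2)))
  valid <- rep(TRUE, n)
  for (s in gap_at) valid[s:min(n, s + gap_len - 1)] <- FALSE
  x <- x_fun(t); y <- y_fun(t)
  x[!valid] <- NA; y[!valid] <- NA
  data.frame(t_ms = t, x_px = x, y_px = y, valid = valid)
}
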