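# Independent brute-force oracles: explicit per-sample loops applying the
# published detector criteria, kept deliberately naive and separate from the
# package's vectorised implementations.

oracle_extrema <- function(v) {
  idx <- integer(0); pol <- integer(0)
  dir <- 0L; last_pos <- 0L
  for (i in seq_len(length(v) - 1L)) {
    d <- v[i + 1L] - v[i]
    s <- if (d > 0) 1L else if (d < 0) -1L else 0L
    if (s == 0L) next
    if (dir != 0L && s != dir) {
      idx <- c(idx, last_pos + 1L)
      pol <- c(pol, dir)
    }
    dir <- s; last_pos <- i
  }
  list(idx = idx, polarity = pol)
}

oracle_navx_marks <- function(egm, st = navx_settings()) {
  v <- egm$samples; fs <- egm$fs; n <- length(v)
  dv <- diff(v); m <- length(dv)
  ex <- oracle_extrema(v)
  maxima <- ex$idx[ex$polarity > 0]
  minima <- ex$idx[ex$polarity < 0]
  t_ms <- pp <- dur <- numeric(0)
  last <- -Inf
  for (i in seq_len(m)) {
    okl <- i == 1L || dv[i] < dv[i - 1L]
    okr <- i == m || dv[i] < dv[i + 1L]
    if (!(okl && okr && dv[i] < 0)) next
    pre <- 1L
    for (j in maxima) if (j <= i) pre <- j
    post <- n
    for (j in rev(minima)) if (j >= i + 1L) post <- j
    amp <- v[pre] - v[post]
    d_ms <- (post - pre) / fs * 1000
    t <- (i - 0.5) / fs * 1000
    if (amp >= st$pp_sensitivity_mv && d_ms < st$max_deflection_ms &&
        t - last >= st$refractory_ms) {
      t_ms <- c(t_ms, t); pp <- c(pp, amp); dur <- c(dur, d_ms)
      last <- t
    }
  }
  data.frame(t_ms = t_ms, pp_amplitude_mv = pp, duration_ms = dur)
}

oracle_carto_intervals <- function(egm, st = carto_settings()) {
  v <- egm$samples
  ex <- oracle_extrema(v)
  qual <- numeric(0)
  for (k in seq_along(ex$idx)) {
    a <- abs(v[ex$idx[k]])
    if (a >= st$v_low_mv && a <= st$v_high_mv)
      qual <- c(qual, (ex$idx[k] - 1) / egm$fs * 1000)
  }
  t0 <- t1 <- numeric(0)
  if (length(qual) >= 2) {
    for (k in seq_len(length(qual) - 1L)) {
      d <- qual[k + 1L] - qual[k]
      if (d >= st$interval_ms[1] && d <= st$interval_ms[2]) {
        t0 <- c(t0, qual[k]); t1 <- c(t1, qual[k + 1L])
      }
    }
  }
  data.frame(t_start_ms = t0, t_end_ms = t1, duration_ms = t1 - t0)
}

# a short random synthetic AEG for oracle-equivalence sweeps
random_short_aeg <- function(seed, window_s = 0.5) {
  set.seed(seed)
  pf <- aeg_profile(
    mean_interval_ms = runif(1, 45, 200),
    interval_jitter_ms = runif(1, 0, 15),
    pp_amplitude_mv = runif(1, 0.06, 0.3),
    amplitude_jitter_mv = runif(1, 0, 0.03),
    noise_rms_mv = runif(1, 0, 0.015),
    neg_fraction = runif(1, 0.6, 0.85),
    seed = seed + 1L)
  generate_aeg(pf, window_s = window_s)$egm
}

# planted-separation cohort: two archetypes with disjoint index distributions
separated_cohort_spec <- function(seed, n_total = 797) {
  cohort_spec(
    n_total = n_total,
    weights = c(fractionated = 0.5, organized = 0.5),
    seed = seed,
    profiles = list(
      fractionated = aeg_profile(
        mean_interval_ms = 60, interval_jitter_ms = 3,
        pp_amplitude_mv = 0.12, amplitude_jitter_mv = 0.01,
        noise_rms_mv = 0.005, neg_fraction = 0.7),
      organized = aeg_profile(
        mean_interval_ms = 180, interval_jitter_ms = 15,
        pp_amplitude_mv = 0.32, amplitude_jitter_mv = 0.03,
        noise_rms_mv = 0.005, neg_fraction = 0.85)))
}

sine_egm <- function(freq, amp = 1, fs = 1200, dur = 2.5) {
  t <- seq_len(round(fs * dur)) / fs
  electrogram(amp * sin(2 * pi * freq * t), fs = fs)
}

mid_rms <- function(egm) {
  n <- length(egm$samples)
  sqrt(mean(egm$samples[round(n * 0.2):round(n * 0.8)]^2))
}
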