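# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic AEG activation profile
#'
#' Parameterises one archetype of bipolar atrial activity: a renewal process
#' of activation complexes with truncated-normal inter-complex intervals,
#' optionally interleaved long gaps (bursty activity), one or more
#' sub-deflections per complex, per-deflection peak-to-peak amplitudes, and
#' additive band-limited baseline noise.
#'
#' @param mean_interval_ms Mean inter-complex interval in ms.
#' @param interval_jitter_ms SD of the interval perturbation (>= 0).
#' @param deflections_per_complex Integer >= 1; sub-deflections are rendered
#'   `subdeflection_spacing_ms` apart within a complex.
#' @param subdeflection_spacing_ms Spacing of sub-deflections in ms (10-25).
#' @param pp_amplitude_mv Mean peak-to-peak deflection amplitude in mV.
#' @param amplitude_jitter_mv SD of the per-deflection amplitude draw.
#' @param deflection_width_ms Width of the biphasic wavelet in ms (default 5).
#' @param noise_rms_mv RMS of additive Gaussian noise, band-limited to
#'   30-300 Hz before being added (0 disables noise and keeps the rendered
#'   deflections exact).
#' @param neg_fraction Fraction of the peak-to-peak amplitude carried by the
#'   negative lobe (default 0.7; bipolar AEG deflections are predominantly
#'   negative-going).
#' @param p_long Probability that an interval is drawn from the long-gap
#'   component instead (default 0: plain renewal process).
#' @param long_gap_ms,long_gap_jitter_ms Mean/SD of the long-gap component.
#' @param seed Optional per-profile RNG seed.
#' @return An `aeg_profile` list.
#' @export
aeg_profile <- function(mean_interval_ms, interval_jitter_ms = 0,
                        deflections_per_complex = 1L,
                        subdeflection_spacing_ms = 15,
                        pp_amplitude_mv = 0.2, amplitude_jitter_mv = 0,
                        deflection_width_ms = 5, noise_rms_mv = 0,
                        neg_fraction = 0.7, p_long = 0, long_gap_ms = NULL,
                        long_gap_jitter_ms = 0, seed = NULL) {
  stopifnot(mean_interval_ms > deflection_width_ms, interval_jitter_ms >= 0,
            deflections_per_complex >= 1L, amplitude_jitter_mv >= 0,
            deflection_width_ms > 0, noise_rms_mv >= 0,
            neg_fraction > 0, neg_fraction < 1, p_long >= 0, p_long < 1,
            subdeflection_spacing_ms >= 10, subdeflection_spacing_ms <= 25)
  floor_ms <- interval_floor_ms(deflection_width_ms, deflections_per_complex,
                                subdeflection_spacing_ms)
  if (floor_ms >= mean_interval_ms + 3 * interval_jitter_ms)
    stop("parameter error: infeasible profile (interval floor ",
         round(floor_ms, 2), " ms >= mean + 3 SD)", call. = FALSE)
  if (p_long > 0 && is.null(long_gap_ms))
    stop("parameter error: p_long > 0 requires long_gap_ms", call. = FALSE)
  structure(list(mean_interval_ms = mean_interval_ms,
                 interval_jitter_ms = interval_jitter_ms,
                 deflections_per_complex = as.integer(deflections_per_complex),
                 subdeflection_spacing_ms = subdeflection_spacing_ms,
                 pp_amplitude_mv = pp_amplitude_mv,
                 amplitude_jitter_mv = amplitude_jitter_mv,
                 deflection_width_ms = deflection_width_ms,
                 noise_rms_mv = noise_rms_mv, neg_fraction = neg_fraction,
                 p_long = p_long, long_gap_ms = long_gap_ms,
                 long_gap_jitter_ms = long_gap_jitter_ms, seed = seed),
            class = "aeg_profile")
}

# minimum feasible inter-complex interval: one whole complex plus the wavelet
interval_floor_ms <- function(width_ms, k, spacing_ms) {
  width_ms + (k - 1L) * spacing_ms
}

# one interval draw honouring the long-gap mixture and the truncation floor
draw_intervals <- function(n, profile, floor_ms) {
  long <- profile$p_long > 0 & stats::runif(n) < profile$p_long
  iv <- ifelse(long,
               stats::rnorm(n, profile$long_gap_ms, profile$long_gap_jitter_ms),
               stats::rnorm(n, profile$mean_interval_ms,
                            profile$interval_jitter_ms))
  bad <- which(iv < floor_ms)
  for (i in bad) {     # redraw below-floor intervals from their component
    for (tries in 1:100) {
      iv[i] <- if (long[i])
        stats::rnorm(1, profile$long_gap_ms, profile$long_gap_jitter_ms)
      else
        stats::rnorm(1, profile$mean_interval_ms, profile$interval_jitter_ms)
      if (iv[i] >= floor_ms) break
    }
    if (iv[i] < floor_ms) iv[i] <- floor_ms
  }
  iv
}

#' Ground-truth activation train for a profile
#'
#' Renewal process of complex onsets starting at time 0 with
#' truncated-normal intervals (floored so complexes cannot overlap), expanded
#' into per-deflection times and per-deflection peak-to-peak amplitude draws.
#' Deterministic under the profile seed.
#'
#' @param profile An [aeg_profile()].
#' @param window_s Window length in seconds.
#' @return Data frame: `t_ms`, `pp_mv`, `complex` (1-based complex index).
#' @export
generate_activation_train <- function(profile, window_s) {
  with_seed(profile$seed, {
    wm <- window_s * 1000
    floor_ms <- interval_floor_ms(profile$deflection_width_ms,
                                  profile$deflections_per_complex,
                                  profile$subdeflection_spacing_ms)
    n_guess <- ceiling(wm / max(floor_ms, profile$mean_interval_ms *
                                  (1 - profile$p_long) +
                                  profile$p_long * (profile$long_gap_ms %||% 0))) + 8L
    starts <- cumsum(c(0, draw_intervals(n_guess, profile, floor_ms)))
    while (starts[length(starts)] < wm)
      starts <- c(starts, starts[length(starts)] +
                    draw_intervals(8L, profile, floor_ms)[1])
    starts <- starts[starts < wm]
    k <- profile$deflections_per_complex
    t_ms <- as.vector(outer(0:(k - 1) * profile$subdeflection_spacing_ms,
                            starts, `+`))
    cx <- rep(seq_along(starts), each = k)
    keep <- t_ms < wm
    t_ms <- t_ms[keep]; cx <- cx[keep]
    pp <- stats::rnorm(length(t_ms), profile$pp_amplitude_mv,
                       profile$amplitude_jitter_mv)
    pp <- pmax(pp, 0.005)
    data.frame(t_ms = t_ms, pp_mv = pp, complex = cx)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# biphasic wavelet: difference of two Gaussians, positive lobe leading,
# normalised to unit peak-to-peak on the sample grid
biphasic_kernel <- function(fs, width_ms, neg_fraction) {
  s <- width_ms / 4          # half the lobe separation, ms
  sg <- width_ms / 6         # lobe SD, ms
  half <- ceiling((s + 4 * sg) * fs / 1000)
  t <- (-half:half) / fs * 1000
  k <- (1 - neg_fraction) * exp(-(t + s)^2 / (2 * sg^2)) -
    neg_fraction * exp(-(t - s)^2 / (2 * sg^2))
  k / (max(k) - min(k))
}

#' Render a synthetic bipolar AEG
#'
#' Draws an activation train for the profile and renders every deflection as
#' a biphasic wavelet (positive lobe then a larger negative lobe, width
#' `deflection_width_ms`, peak-to-peak amplitude per draw), then adds
#' Gaussian noise band-limited to 30-300 Hz at `noise_rms_mv`. With zero
#' noise the rendered signal is exact, so detector outputs can be compared
#' against the planted truth.
#'
#' @param profile An [aeg_profile()].
#' @param fs Sampling rate in Hz (default 1200; must be >= 1000).
#' @param window_s Window length in seconds (default 2.5).
#' @param id Label for the electrogram.
#' @return List: `egm` (an `electrogram`) and `truth` (the activation train
#'   with per-deflection times and amplitudes).
#' @export
generate_aeg <- function(profile, fs = 1200, window_s = 2.5, id = "synthetic") {
  stopifnot(fs >= 1000)
  with_seed(profile$seed, {
    truth <- generate_activation_train(structure(
      utils::modifyList(unclass(profile), list(seed = NULL)),
      class = "aeg_profile"), window_s)
    n <- round(window_s * fs)
    v <- numeric(n)
    kern <- biphasic_kernel(fs, profile$deflection_width_ms,
                            profile$neg_fraction)
    half <- (length(kern) - 1L) / 2L
    for (i in seq_len(nrow(truth))) {
      c0 <- round(truth$t_ms[i] * fs / 1000) + 1L
      idx <- (c0 - half):(c0 + half)
      ok <- idx >= 1L & idx <= n
      v[idx[ok]] <- v[idx[ok]] + truth$pp_mv[i] * kern[ok]
    }
    if (profile$noise_rms_mv > 0) {
      w <- stats::rnorm(n)
      bf <- signal::butter(2, c(30, 300) / (fs / 2), type = "pass")
      w <- as.numeric(signal::filtfilt(bf, w))
      v <- v + w * profile$noise_rms_mv / sqrt(mean(w^2))
    }
    list(egm = electrogram(v, fs = fs, id = id,
                           meta = list(synthetic = TRUE)),
         truth = truth)
  })
}

#' Archetype profiles for the four agreement quadrants
#'
#' Default activation archetypes mirroring the four zones of the CFE-Mean
#' vs ICL scatter: both systems CFAE (short-cycle doublet complexes inside
#' the CARTO voltage window), both organized (slow, large-amplitude single
#' deflections outside the window), NavX-only (sub-120 ms cycle length but
#' amplitudes straddling the top of the voltage window), and CARTO-only
#' (bursts of in-window activity separated by long gaps, so complex
#' intervals abound while the mean fractionated interval exceeds 120 ms).
#' Parameter values are engineering choices; the clinical amplitude/interval
#' distributions are not published.
#'
#' @return Named list of [aeg_profile()] objects.
#' @export
archetype_profiles <- function() {
  list(
    concordant_cfae = aeg_profile(
      mean_interval_ms = 70, interval_jitter_ms = 10,
      deflections_per_complex = 2L, subdeflection_spacing_ms = 15,
      pp_amplitude_mv = 0.12, amplitude_jitter_mv = 0.015,
      noise_rms_mv = 0.01, neg_fraction = 0.7),
    concordant_organized = aeg_profile(
      mean_interval_ms = 180, interval_jitter_ms = 20,
      pp_amplitude_mv = 0.32, amplitude_jitter_mv = 0.04,
      noise_rms_mv = 0.01, neg_fraction = 0.85),
    navx_only = aeg_profile(
      mean_interval_ms = 112, interval_jitter_ms = 12,
      pp_amplitude_mv = 0.30, amplitude_jitter_mv = 0.04,
      noise_rms_mv = 0.01, neg_fraction = 0.85),
    carto_only = aeg_profile(
      mean_interval_ms = 70, interval_jitter_ms = 8,
      pp_amplitude_mv = 0.12, amplitude_jitter_mv = 0.015,
      noise_rms_mv = 0.01, neg_fraction = 0.7,
      p_long = 0.25, long_gap_ms = 500, long_gap_jitter_ms = 50))
}

#' Cohort specification for synthetic AEG generation
#'
#' @param n_total Number of AEGs (default 797, the clinical cohort size).
#' @param weights Named mixture weights over the archetypes in `profiles`
#'   (normalised to sum 1). The default mirrors the observed quadrant
#'   occupancy 273/230/282/12 out of 797, with CARTO-only deliberately rare.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds.
#' @param seed Master seed; all per-AEG randomness derives from it.
#' @param profiles Named list of archetype [aeg_profile()]s.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_total = 797,
                        weights = c(concordant_cfae = 273,
                                    concordant_organized = 230,
                                    navx_only = 282, carto_only = 12) / 797,
                        fs = 1200, window_s = 2.5, seed = 1,
                        profiles = archetype_profiles()) {
  stopifnot(n_total > 0, length(weights) == length(profiles),
            all(weights >= 0), sum(weights) > 0)
  if (is.null(names(weights)) ||
      !setequal(names(weights), names(profiles)))
    stop("parameter error: weights must be named after the profiles",
         call. = FALSE)
  structure(list(n_total = as.integer(n_total),
                 weights = weights[names(profiles)] / sum(weights),
                 fs = fs, window_s = window_s, seed = seed,
                 profiles = profiles),
            class = "cohort_spec")
}

#' Generate a synthetic AEG cohort with planted ground truth
#'
#' Assigns an archetype to each AEG by the mixture weights, derives one seed
#' per AEG from the master seed (so cohorts are reproducible item-by-item),
#' and renders each signal. The truth table records the archetype and the
#' planted generator parameters per AEG.
#'
#' @param spec A [cohort_spec()].
#' @return List: `aegs` (named list of `electrogram`s) and `truth` (data
#'   frame: `id`, `archetype`, `seed`, `mean_interval_ms`, `pp_amplitude_mv`,
#'   `n_deflections`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  arche <- names(spec$profiles)
  draw <- with_seed(spec$seed, list(
    asg = sample(arche, spec$n_total, replace = TRUE, prob = spec$weights),
    seeds = sample.int(.Machine$integer.max - 1L, spec$n_total)))
  asg <- draw$asg
  seeds <- draw$seeds
  ids <- sprintf("aeg%04d", seq_len(spec$n_total))
  aegs <- vector("list", spec$n_total)
  ndef <- integer(spec$n_total)
  for (i in seq_len(spec$n_total)) {
    pf <- spec$profiles[[asg[i]]]
    pf$seed <- seeds[i]
    g <- generate_aeg(pf, fs = spec$fs, window_s = spec$window_s, id = ids[i])
    g$egm$meta$archetype <- asg[i]
    aegs[[i]] <- g$egm
    ndef[i] <- nrow(g$truth)
  }
  names(aegs) <- ids
  truth <- data.frame(
    id = ids, archetype = asg, seed = seeds,
    mean_interval_ms = vapply(asg, function(a)
      spec$profiles[[a]]$mean_interval_ms, 0),
    pp_amplitude_mv = vapply(asg, function(a)
      spec$profiles[[a]]$pp_amplitude_mv, 0),
    n_deflections = ndef, row.names = NULL)
  list(aegs = aegs, truth = truth)
}
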