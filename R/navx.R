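# Local extrema of a series. Returns 1-based indices and polarity (+1 local
# maximum, -1 local minimum). A plateau is represented by its first sample.
find_local_extrema <- function(v) {
  n <- length(v)
  if (n < 3L) return(list(idx = integer(0), polarity = integer(0)))
  s <- sign(diff(v))
  nzi <- which(s != 0)
  if (length(nzi) < 2L) return(list(idx = integer(0), polarity = integer(0)))
  sv <- s[nzi]
  chg <- which(sv[-length(sv)] != sv[-1L])
  list(idx = nzi[chg] + 1L, polarity = as.integer(sv[chg]))
}

#' NavX CFAE detector settings (EGM settings)
#'
#' Operator-adjustable parameters of the NavX-style negative-deflection
#' detector. A marked deflection must (1) have peak-to-peak amplitude at or
#' above `pp_sensitivity_mv` (the operator's proxy for baseline noise),
#' (2) last less than `max_deflection_ms` (rejects ventricular far-field
#' events), and (3) fall at least `refractory_ms` after the previously
#' accepted mark (avoids multiple detections of one deflection).
#'
#' @param pp_sensitivity_mv Peak-to-peak sensitivity in mV (default 0.05).
#' @param max_deflection_ms Maximum deflection duration in ms (default 10).
#' @param refractory_ms Post-mark refractory period in ms (default 30).
#' @param cfae_range_ms Inclusive CFE-Mean classification interval in ms
#'   (default `c(30, 120)`; use `c(50, 110)` to emulate CARTO EGM settings).
#' @param adaptive_k Optional multiplier: when non-`NULL` the amplitude
#'   threshold becomes `max(pp_sensitivity_mv, adaptive_k * mad(samples))`.
#' @return A `navx_settings` list.
#' @export
navx_settings <- function(pp_sensitivity_mv = 0.05, max_deflection_ms = 10,
                          refractory_ms = 30, cfae_range_ms = c(30, 120),
                          adaptive_k = NULL) {
  stopifnot(pp_sensitivity_mv > 0, max_deflection_ms > 0, refractory_ms >= 0,
            length(cfae_range_ms) == 2L, cfae_range_ms[1] < cfae_range_ms[2])
  structure(list(pp_sensitivity_mv = pp_sensitivity_mv,
                 max_deflection_ms = max_deflection_ms,
                 refractory_ms = refractory_ms,
                 cfae_range_ms = cfae_range_ms,
                 adaptive_k = adaptive_k),
            class = "navx_settings")
}

#' Detect qualifying negative deflections (NavX algorithm)
#'
#' Candidate deflections are the local minima of the first difference
#' (steepest negative slope, -dV/dt). Each candidate's deflection is
#' delimited by the nearest preceding local maximum and the nearest following
#' local minimum of the voltage (falling back to the window edges when the
#' deflection is clipped by the window); its peak-to-peak amplitude is their
#' difference and its duration their separation. Candidates failing the
#' amplitude or duration criterion are dropped; the refractory criterion is
#' applied greedily in chronological order (earliest qualifying deflection
#' wins).
#'
#' @param egm An `electrogram`.
#' @param settings A [navx_settings()].
#' @return A data frame of marks sorted by time with columns `t_ms` (time of
#'   steepest negative slope from window start), `pp_amplitude_mv`,
#'   `duration_ms`.
#' @export
detect_negative_deflections <- function(egm, settings = navx_settings()) {
  v <- egm$samples
  fs <- egm$fs
  n <- length(v)
  empty <- data.frame(t_ms = numeric(0), pp_amplitude_mv = numeric(0),
                      duration_ms = numeric(0))
  if (window_ms(egm) < settings$refractory_ms)
    warning("analysis window shorter than the refractory period")
  if (n < 3L) return(empty)
  thr <- settings$pp_sensitivity_mv
  if (!is.null(settings$adaptive_k))
    thr <- max(thr, settings$adaptive_k * stats::mad(v))

  dv <- diff(v)
  m <- length(dv)
  lo <- c(TRUE, dv[-1] < dv[-m])      # dv[i] < dv[i-1] (or boundary)
  hi <- c(dv[-m] < dv[-1], TRUE)      # dv[i] < dv[i+1] (or boundary)
  cand <- which(lo & hi & dv < 0)
  if (length(cand) == 0L) return(empty)

  ext <- find_local_extrema(v)
  vmax <- ext$idx[ext$polarity > 0]
  vmin <- ext$idx[ext$polarity < 0]
  # nearest preceding local max (<= cand), window start as fallback
  pre <- rep(1L, length(cand))
  if (length(vmax)) {
    pos <- findInterval(cand, vmax)
    pre[pos >= 1L] <- vmax[pos[pos >= 1L]]
  }
  # nearest following local min (>= cand + 1), window end as fallback
  post <- rep(n, length(cand))
  if (length(vmin)) {
    pos <- findInterval(cand, vmin) + 1L
    ok <- pos <= length(vmin)
    post[ok] <- vmin[pos[ok]]
  }
  pp <- v[pre] - v[post]
  dur_ms <- (post - pre) / fs * 1000
  t_ms <- (cand - 0.5) / fs * 1000    # midpoint of the steepest-slope pair
  keep <- pp >= thr & dur_ms < settings$max_deflection_ms
  if (!any(keep)) return(empty)
  t_ms <- t_ms[keep]; pp <- pp[keep]; dur_ms <- dur_ms[keep]
  # greedy chronological refractory
  acc <- logical(length(t_ms))
  last <- -Inf
  for (i in seq_along(t_ms)) {
    if (t_ms[i] - last >= settings$refractory_ms) {
      acc[i] <- TRUE
      last <- t_ms[i]
    }
  }
  data.frame(t_ms = t_ms[acc], pp_amplitude_mv = pp[acc],
             duration_ms = dur_ms[acc])
}

#' NavX fractionation indices from deflection marks
#'
#' The fractionated intervals (FI) are the differences between consecutive
#' mark times; CFE-Mean is their arithmetic mean and CFE-SD their sample
#' standard deviation (n-1 denominator; 0 when there is exactly one
#' interval). With fewer than two marks the indices are undefined.
#'
#' @param marks Data frame from [detect_negative_deflections()] (sorted by
#'   time).
#' @param window_len_ms Analysis window length in ms.
#' @return A `navx_indices` list: `fi_ms`, `cfe_mean_ms`, `cfe_sd_ms`,
#'   `n_marks`, `window_ms`, `defined`.
#' @export
compute_navx_indices <- function(marks, window_len_ms) {
  t_ms <- marks$t_ms
  if (is.unsorted(t_ms)) stop("contract violation: marks must be sorted by time",
                              call. = FALSE)
  n <- length(t_ms)
  if (n < 2L) {
    return(structure(list(fi_ms = numeric(0), cfe_mean_ms = NA_real_,
                          cfe_sd_ms = NA_real_, n_marks = n,
                          window_ms = window_len_ms, defined = FALSE),
                     class = "navx_indices"))
  }
  fi <- diff(t_ms)
  structure(list(fi_ms = fi,
                 cfe_mean_ms = mean(fi),
                 cfe_sd_ms = if (length(fi) == 1L) 0 else stats::sd(fi),
                 n_marks = n, window_ms = window_len_ms, defined = TRUE),
            class = "navx_indices")
}

#' Classify an AEG as CFAE by CFE-Mean (NavX rule)
#'
#' CFAE when the indices are defined and CFE-Mean lies inside the
#' classification range (both endpoints inclusive; default 30-120 ms).
#' Undefined indices (< 2 marks) classify as non-CFAE.
#'
#' @param indices A `navx_indices` object.
#' @param settings A [navx_settings()].
#' @return Logical CFAE flag.
#' @export
classify_navx <- function(indices, settings = navx_settings()) {
  r <- settings$cfae_range_ms
  isTRUE(indices$defined) &&
    indices$cfe_mean_ms >= r[1] && indices$cfe_mean_ms <= r[2]
}

#' @export
print.navx_indices <- function(x, ...) {
  if (x$defined)
    cat(sprintf("<navx_indices> %d marks, CFE-Mean = %.2f ms, CFE-SD = %.2f ms\n",
                x$n_marks, x$cfe_mean_ms, x$cfe_sd_ms))
  else
    cat(sprintf("<navx_indices> %d mark(s), CFE-Mean/CFE-SD undefined\n", x$n_marks))
  invisible(x)
}
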