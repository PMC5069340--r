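#' CARTO CFAE detector settings (EGM settings)
#'
#' Operator-adjustable parameters of the CARTO-style complex-interval
#' detector: voltage peaks and troughs qualify when their amplitude exceeds a
#' lower voltage threshold (noise floor) but not an upper one; the durations
#' between successive qualifying extrema that fall inside the programmable
#' interval window are counted as complex intervals over a 2.5-s window.
#'
#' @param v_low_mv Lower voltage threshold in mV (default 0.05).
#' @param v_high_mv Upper voltage threshold in mV (default 0.15).
#' @param interval_ms Inclusive complex-interval duration window in ms
#'   (default `c(50, 110)`).
#' @param window_s Analysis window in seconds (default 2.5; CFAE
#'   classification is only validated at 2.5 s).
#' @param icl_threshold ICL cutoff for the CFAE flag (default 7).
#' @param amplitude_mode `"absolute"` (default): an extremum qualifies when
#'   its absolute deviation from the zero baseline lies in
#'   `[v_low_mv, v_high_mv]` (band-passed signals have mean ~0).
#'   `"peak_to_peak"`: the deviation is measured against the preceding
#'   opposite-sign extremum instead.
#' @return A `carto_settings` list.
#' @export
carto_settings <- function(v_low_mv = 0.05, v_high_mv = 0.15,
                           interval_ms = c(50, 110), window_s = 2.5,
                           icl_threshold = 7,
                           amplitude_mode = c("absolute", "peak_to_peak")) {
  stopifnot(v_low_mv > 0, v_high_mv > v_low_mv,
            length(interval_ms) == 2L, interval_ms[1] < interval_ms[2],
            window_s > 0, icl_threshold >= 1)
  structure(list(v_low_mv = v_low_mv, v_high_mv = v_high_mv,
                 interval_ms = interval_ms, window_s = window_s,
                 icl_threshold = icl_threshold,
                 amplitude_mode = match.arg(amplitude_mode)),
            class = "carto_settings")
}

#' Detect voltage-window-qualifying extrema (CARTO algorithm)
#'
#' Finds all local maxima and minima of the voltage and retains those whose
#' amplitude lies inside the voltage window (inclusive at both bounds).
#'
#' @param egm An `electrogram`.
#' @param settings A [carto_settings()].
#' @return Data frame sorted by time: `t_ms`, `amplitude_mv` (signed voltage
#'   at the extremum), `polarity` (+1 peak, -1 trough).
#' @export
detect_qualifying_extrema <- function(egm, settings = carto_settings()) {
  v <- egm$samples
  ext <- find_local_extrema(v)
  empty <- data.frame(t_ms = numeric(0), amplitude_mv = numeric(0),
                      polarity = integer(0))
  if (length(ext$idx) == 0L) return(empty)
  amp <- v[ext$idx]
  if (settings$amplitude_mode == "absolute") {
    dev <- abs(amp)
  } else {
    dev <- c(NA_real_, abs(diff(amp)))   # vs preceding (opposite) extremum
    dev[1] <- abs(amp[1])
  }
  keep <- dev >= settings$v_low_mv & dev <= settings$v_high_mv
  data.frame(t_ms = sample_to_ms(ext$idx[keep], egm$fs),
             amplitude_mv = amp[keep],
             polarity = ext$polarity[keep])
}

#' Mark complex intervals between successive qualifying extrema
#'
#' For each successive pair of qualifying extrema, the pair bounds a complex
#' interval when its duration lies inside the operator-set interval window
#' (inclusive). Intervals chain: consecutive intervals share endpoints, and
#' no alternation of polarity is required.
#'
#' @param extrema Data frame from [detect_qualifying_extrema()].
#' @param settings A [carto_settings()].
#' @return Data frame: `t_start_ms`, `t_end_ms`, `duration_ms`.
#' @export
mark_complex_intervals <- function(extrema, settings = carto_settings()) {
  t <- extrema$t_ms
  if (is.unsorted(t)) stop("contract violation: extrema must be sorted by time",
                           call. = FALSE)
  if (length(t) < 2L)
    return(data.frame(t_start_ms = numeric(0), t_end_ms = numeric(0),
                      duration_ms = numeric(0)))
  dur <- diff(t)
  keep <- dur >= settings$interval_ms[1] & dur <= settings$interval_ms[2]
  data.frame(t_start_ms = t[-length(t)][keep], t_end_ms = t[-1][keep],
             duration_ms = dur[keep])
}

#' CARTO fractionation indices from complex intervals
#'
#' ICL (interval confidence level) is the number of identified complex
#' intervals; ACI is their average duration and SCI the shortest. ACI and SCI
#' are undefined when ICL is 0.
#'
#' @param intervals Data frame from [mark_complex_intervals()].
#' @return A `carto_indices` list: `icl`, `aci_ms`, `sci_ms`, `band`
#'   (`"low"` for ICL < 4, `"moderate"` for 4-6, `"high"` for >= 7),
#'   `defined`.
#' @export
compute_carto_indices <- function(intervals) {
  icl <- nrow(intervals)
  structure(list(
    icl = icl,
    aci_ms = if (icl > 0) mean(intervals$duration_ms) else NA_real_,
    sci_ms = if (icl > 0) min(intervals$duration_ms) else NA_real_,
    band = icl_band(icl),
    defined = icl > 0), class = "carto_indices")
}

#' Fractionation band for an ICL value
#'
#' The conventional cutpoints: ICL < 4 low, 4 <= ICL < 7 moderate,
#' ICL >= 7 high fractionation.
#'
#' @param icl Integer interval confidence level(s).
#' @return Character vector of band labels.
#' @export
icl_band <- function(icl) {
  ifelse(icl >= 7, "high", ifelse(icl >= 4, "moderate", "low"))
}

#' Classify an AEG as CFAE by ICL (CARTO rule)
#'
#' CFAE when `icl >= icl_threshold` (default 7). The fractionation band is
#' always assigned by the conventional cutpoints regardless of the threshold.
#' ICL classification is only validated for 2.5-s windows; other windows
#' require `allow_nonstandard_window = TRUE` and are otherwise an error.
#'
#' @param indices A `carto_indices` object.
#' @param settings A [carto_settings()].
#' @param window_s Window length the indices were computed on (default the
#'   settings' window).
#' @param allow_nonstandard_window Permit classification at windows != 2.5 s.
#' @return List with `cfae` (logical) and `band`.
#' @export
classify_carto <- function(indices, settings = carto_settings(),
                           window_s = settings$window_s,
                           allow_nonstandard_window = FALSE) {
  if (abs(window_s - 2.5) > 1e-9 && !allow_nonstandard_window)
    stop("no validated ICL threshold for windows other than 2.5 s; ",
         "set allow_nonstandard_window = TRUE to override", call. = FALSE)
  list(cfae = indices$icl >= settings$icl_threshold, band = indices$band)
}

#' @export
print.carto_indices <- function(x, ...) {
  if (x$defined)
    cat(sprintf("<carto_indices> ICL = %d (%s), ACI = %.2f ms, SCI = %.2f ms\n",
                x$icl, x$band, x$aci_ms, x$sci_ms))
  else
    cat("<carto_indices> ICL = 0 (low), ACI/SCI undefined\n")
  invisible(x)
}
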