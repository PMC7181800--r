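#' Ripple detection parameters
#'
#' Defaults follow the standard offline SPW-R detection recipe: the LFP is
#' band-passed at 100-280 Hz (2nd-order Butterworth, forward and reverse),
#' rectified and smoothed with a Savitzky-Golay filter; events require the
#' smoothed envelope to exceed its mean by 2 SD and the filtered trace to
#' exceed its mean by 4 SD, for at least 20 ms; of two events with peaks
#' closer than 40 ms, the smaller-amplitude one is discarded.
#'
#' @param band ripple band (Hz).
#' @param order Butterworth order of the single pass.
#' @param sg_window_ms Savitzky-Golay smoothing window (ms).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param thresh_smoothed envelope threshold (SD above mean).
#' @param thresh_filtered filtered-trace threshold (SD above mean).
#' @param min_duration_ms minimum event duration (ms).
#' @param merge_peak_gap_ms peak-to-peak gap below which the smaller event
#'   is discarded (ms).
#' @param min_events_for_session sessions with fewer detected events should
#'   be excluded from summary statistics.
#' @return list of class `RippleParams`.
#' @export
ripple_params <- function(band = c(100, 280), order = 2,
                          sg_window_ms = 11, sg_order = 2,
                          thresh_smoothed = 2, thresh_filtered = 4,
                          min_duration_ms = 20, merge_peak_gap_ms = 40,
                          min_events_for_session = 100) {
  stopifnot(thresh_smoothed > 0, thresh_filtered > 0, min_duration_ms > 0,
            merge_peak_gap_ms > 0, band[1] > 0, band[1] < band[2])
  structure(as.list(environment()), class = "RippleParams")
}

# rectified band-passed trace smoothed with Savitzky-Golay
ripple_envelope <- function(trace, fs, params) {
  filtered <- bandpass_zero_phase(trace, fs, params$band[1], params$band[2],
                                  params$order)
  w <- round(params$sg_window_ms / 1000 * fs)
  if (w %% 2 == 0) w <- w + 1
  w <- max(w, params$sg_order + 2 + (params$sg_order %% 2))
  if (w %% 2 == 0) w <- w + 1
  env <- signal::sgolayfilt(abs(filtered), p = params$sg_order, n = w)
  list(filtered = filtered, envelope = env)
}

# discard the smaller of any two events with peaks closer than gap_s
merge_close_events <- function(ev, gap_s) {
  repeat {
    if (nrow(ev) < 2) return(ev)
    gaps <- diff(ev$peak)
    bad <- which(gaps < gap_s)
    if (!length(bad)) return(ev)
    i <- bad[1]
    drop <- if (ev$amplitude[i] < ev$amplitude[i + 1]) i else i + 1L
    ev <- ev[-drop, , drop = FALSE]
  }
}

#' Detect sharp-wave ripples in an LFP trace
#'
#' @param trace numeric LFP vector (single channel).
#' @param fs sampling rate (Hz); must exceed twice the upper band edge.
#' @param params a [ripple_params()] object.
#' @param channel channel id recorded in the output.
#' @param t0 time of the first sample (s).
#' @return an `EventTable` of kind `"ripple"`: onset/offset are the
#'   envelope threshold crossings, peak is the envelope maximum and
#'   amplitude its envelope value. Thresholds are in SD units, so detection
#'   is invariant to positive rescaling of the trace.
#' @export
detect_ripples <- function(trace, fs, params = ripple_params(),
                           channel = NA, t0 = 0) {
  if (fs <= 2 * params$band[2])
    stop("sampling rate incompatible with the ripple band")
  if (length(trace) < fs) stop("trace shorter than 1 s")
  e <- ripple_envelope(trace, fs, params)
  env <- e$envelope; filt <- e$filtered
  th_env <- mean(env) + params$thresh_smoothed * stats::sd(env)
  th_filt <- mean(filt) + params$thresh_filtered * stats::sd(filt)
  above <- env > th_env
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1); ends <- which(d == -1) - 1L
  keep <- onset <- peak <- offset <- amp <- numeric(0)
  min_len <- params$min_duration_ms / 1000 * fs
  for (i in seq_along(starts)) {
    s <- starts[i]; en <- ends[i]
    if (en - s + 1 < min_len) next
    if (max(filt[s:en]) <= th_filt) next
    ip <- s - 1L + which.max(env[s:en])
    onset <- c(onset, t0 + (s - 1) / fs)
    peak <- c(peak, t0 + (ip - 1) / fs)
    offset <- c(offset, t0 + (en - 1) / fs)
    amp <- c(amp, env[ip])
  }
  ev <- event_table(onset, peak, offset, amp, channel, kind = "ripple",
                    params = unclass(params))
  ev <- merge_close_events(ev, params$merge_peak_gap_ms / 1000)
  attr(ev, "kind") <- "ripple"
  attr(ev, "params") <- unclass(params)
  class(ev) <- c("EventTable", "data.frame")
  ev
}

#' Per-event ripple shape statistics
#'
#' @param events an `EventTable` from [detect_ripples()].
#' @param filtered ripple-band filtered trace the events were detected on.
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample (s).
#' @return data.frame with per-event `duration_ms` (offset - onset),
#'   `n_cycles` (filtered-trace peaks above half the event's peak
#'   amplitude between onset and offset) and `peak_power` (squared peak
#'   filtered amplitude).
#' @export
ripple_shape_stats <- function(events, filtered, fs, t0 = 0) {
  n <- length(filtered)
  out <- data.frame(duration_ms = numeric(nrow(events)),
                    n_cycles = integer(nrow(events)),
                    peak_power = numeric(nrow(events)))
  for (i in seq_len(nrow(events))) {
    i0 <- floor((events$onset[i] - t0) * fs) + 1L
    i1 <- ceiling((events$offset[i] - t0) * fs) + 1L
    if (i0 < 1 || i1 > n) stop("event outside trace")
    seg <- filtered[i0:i1]
    pk <- max(abs(seg))
    is_peak <- diff(sign(diff(seg))) == -2
    idx <- which(is_peak) + 1L
    out$n_cycles[i] <- sum(seg[idx] > pk / 2)
    out$duration_ms[i] <- (events$offset[i] - events$onset[i]) * 1000
    out$peak_power[i] <- pk^2
  }
  out
}

#' Build a session-adaptive negative-wave template
#'
#' Averages the low-passed (< 30 Hz) trace around the 50 largest-amplitude
#' negative deflections, replacing a manually curated template.
#'
#' @param trace LFP trace (superficial channel).
#' @param fs sampling rate (Hz).
#' @param n_events number of deflections to average.
#' @param halfwidth_s template half width (s).
#' @return numeric template vector (negative-going).
#' @export
negative_wave_template <- function(trace, fs, n_events = 50,
                                   halfwidth_s = 0.05) {
  lp <- lowpass_zero_phase(trace, fs, 30)
  h <- round(halfwidth_s * fs)
  is_min <- which(diff(sign(diff(lp))) == 2) + 1L
  is_min <- is_min[is_min > h & is_min <= length(lp) - h]
  is_min <- is_min[order(lp[is_min])]       # most negative first
  is_min <- utils::head(is_min, n_events)
  if (!length(is_min)) stop("no negative deflections found")
  tmpl <- rowMeans(vapply(is_min, function(i) lp[(i - h):(i + h)],
                          numeric(2 * h + 1)))
  tmpl - mean(tmpl)
}

#' Detect negative waves by template matching
#'
#' Correlates the trace with a (negative-going) template and reports local
#' maxima of the matched-filter output exceeding `threshold_rms` times its
#' RMS. Polarity matters: positive-going copies of the template produce
#' negative matched-filter output and are not detected.
#'
#' @param trace LFP trace.
#' @param fs sampling rate (Hz).
#' @param template template vector (e.g. [negative_wave_template()]);
#'   must not be flat.
#' @param threshold_rms detection threshold in RMS units of the
#'   matched-filter output (default 1).
#' @param channel,t0 bookkeeping metadata.
#' @return `EventTable` of kind `"negative_wave"`; peak is the most
#'   negative trace sample within a template width of the match,
#'   amplitude is that sample value.
#' @export
detect_negative_waves <- function(trace, fs, template, threshold_rms = 1,
                                  channel = NA, t0 = 0) {
  if (stats::sd(template) < .Machine$double.eps)
    stop("degenerate template: flat")
  tmpl <- (template - mean(template)) / stats::sd(template)
  mf <- conv_same(trace - mean(trace), rev(tmpl))
  th <- threshold_rms * sqrt(mean(mf^2))
  loc_max <- which(diff(sign(diff(mf))) == -2) + 1L
  cand <- loc_max[mf[loc_max] > th]
  # keep one detection per template span (largest matched-filter value)
  span <- length(template)
  cand <- cand[order(-mf[cand])]
  keep <- logical(0); kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= span / 2)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  h <- floor(span / 2)
  onset <- peak <- offset <- amp <- numeric(0)
  for (i in kept) {
    i0 <- max(1L, i - h); i1 <- min(length(trace), i + h)
    ip <- i0 - 1L + which.min(trace[i0:i1])
    if (trace[ip] >= 0) next       # a negative wave must deflect below 0
    onset <- c(onset, t0 + (i0 - 1) / fs)
    peak <- c(peak, t0 + (ip - 1) / fs)
    offset <- c(offset, t0 + (i1 - 1) / fs)
    amp <- c(amp, trace[ip])
  }
  event_table(onset, peak, offset, amp, channel, kind = "negative_wave",
              params = list(threshold_rms = threshold_rms))
}

#' Event cross-correlogram with jitter confidence bands
#'
#' Counts of target event peaks in lag bins relative to reference peaks.
#' 95% bands come from surrogate CCGs in which target times are jittered
#' uniformly within +/- `halfwindow`.
#'
#' @param reference,target `EventTable`s (peak times are used).
#' @param binsize lag bin width (s).
#' @param halfwindow half-width of the lag window (s).
#' @param n_jitter number of jitter surrogates for the confidence bands.
#' @return list with `lags` (bin centres, s), `counts`, `lower`, `upper`
#'   (per-bin 2.5% and 97.5% surrogate quantiles).
#' @export
event_ccg <- function(reference, target, binsize = 0.005,
                      halfwindow = 0.25, n_jitter = 200) {
  if (binsize <= 0) stop("binsize must be positive")
  if (!nrow(reference) || !nrow(target)) stop("both event tables must be non-empty")
  ref <- reference$peak; tgt <- target$peak
  breaks <- seq(-halfwindow, halfwindow, by = binsize)
  if (breaks[length(breaks)] < halfwindow)
    breaks <- c(breaks, halfwindow)
  count_ccg <- function(tg) {
    lags <- unlist(lapply(ref, function(r) {
      d <- tg - r
      d[d >= -halfwindow & d < halfwindow]
    }))
    if (!length(lags)) return(rep(0, length(breaks) - 1))
    as.numeric(table(cut(lags, breaks, right = FALSE)))
  }
  obs <- count_ccg(tgt)
  sur <- matrix(0, n_jitter, length(obs))
  for (j in seq_len(n_jitter))
    sur[j, ] <- count_ccg(tgt + stats::runif(length(tgt), -halfwindow,
                                             halfwindow))
  list(lags = (breaks[-1] + breaks[-length(breaks)]) / 2,
       counts = obs,
       lower = apply(sur, 2, stats::quantile, 0.025),
       upper = apply(sur, 2, stats::quantile, 0.975))
}

#' Cross-regional ripple power coupling
#'
#' Per event, the peak ripple-band power in each region within a window
#' around the event peak; summarized by the least-squares slope and the
#' Spearman rank correlation of target-on-reference power.
#'
#' @param events reference `EventTable`.
#' @param powerA,powerB ripple-band power series for the two regions,
#'   co-sampled at `fs`.
#' @param fs sampling rate of the power series (Hz).
#' @param halfwindow search half-window around each event peak (s).
#' @param t0 time of the first power sample (s).
#' @return list with `slope` (least squares, B on A), `rho` (Spearman),
#'   and the per-event `powerA`, `powerB` vectors.
#' @export
ripple_power_coupling <- function(events, powerA, powerB, fs,
                                  halfwindow = 0.05, t0 = 0) {
  if (nrow(events) < 3) stop("insufficient data: need >= 3 events")
  h <- round(halfwindow * fs)
  pk <- round((events$peak - t0) * fs) + 1L
  grab <- function(p, i) {
    i0 <- max(1L, i - h); i1 <- min(length(p), i + h)
    max(p[i0:i1])
  }
  pa <- vapply(pk, function(i) grab(powerA, i), numeric(1))
  pb <- vapply(pk, function(i) grab(powerB, i), numeric(1))
  slope <- if (stats::var(pa) == 0) NA_real_ else
    stats::cov(pa, pb) / stats::var(pa)
  rho <- suppressWarnings(stats::cor(pa, pb, method = "spearman"))
  list(slope = slope, rho = rho, powerA = pa, powerB = pb)
}

#' Lags of target envelope peaks relative to reference events
#'
#' For each reference event, the lag (ms) of the target ripple-band
#' envelope maximum within `window` of the reference peak — the
#' propagation-delay estimate between regions.
#'
#' @param events reference `EventTable`.
#' @param envelope target-region ripple-band envelope, sampled at `fs`
#'   (>= 1 kHz recommended).
#' @param fs envelope sampling rate (Hz).
#' @param window two-element search window relative to the reference peak
#'   (s), e.g. `c(-0.01, 0.02)`.
#' @param t0 time of the first envelope sample (s).
#' @return list with `lags_ms` per event, `median_ms`, `sem_ms`.
#' @export
peak_power_lags <- function(events, envelope, fs, window = c(-0.02, 0.02),
                            t0 = 0) {
  pk <- round((events$peak - t0) * fs) + 1L
  i_lo <- round(window[1] * fs); i_hi <- round(window[2] * fs)
  lags <- rep(NA_real_, length(pk))
  clipped <- FALSE
  for (k in seq_along(pk)) {
    i0 <- pk[k] + i_lo; i1 <- pk[k] + i_hi
    if (i0 < 1 || i1 > length(envelope)) {
      clipped <- TRUE
      i0 <- max(1L, i0); i1 <- min(length(envelope), i1)
      if (i1 <= i0) next
    }
    lags[k] <- (i0 - 1L + which.max(envelope[i0:i1]) - pk[k]) / fs * 1000
  }
  if (clipped) warning("search window clipped at trace edges")
  lags <- lags[!is.na(lags)]
  list(lags_ms = lags, median_ms = stats::median(lags), sem_ms = sem(lags))
}

#' Ripple-band power envelope
#'
#' Squared magnitude of the analytic signal of the band-passed trace —
#' the instantaneous ripple-band power used by the coupling and lag
#' estimators.
#'
#' @inheritParams bandpass_zero_phase
#' @param band ripple band (Hz).
#' @return numeric power series, same length as `trace`.
#' @export
ripple_band_power <- function(trace, fs, band = c(100, 280)) {
  Mod(analytic_signal(bandpass_zero_phase(trace, fs, band[1], band[2])))^2
}
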