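#' Smoothed multi-unit activity (MUA) population rate
#'
#' Sums all units' spikes into 1 ms bins and convolves with a Gaussian
#' kernel (SD 30 ms). Refuses sessions with fewer than `min_units` units
#' (packet structure is not interpretable from small populations).
#'
#' @param sd a `SpikeData`.
#' @param duration session duration (s).
#' @param gaussian_sd_ms kernel SD (ms).
#' @param min_units minimum number of units (default 16, i.e. > 15).
#' @param binsize_s bin width (s, default 1 ms).
#' @return list of class `MuaSeries`: `rate` (Hz, per bin), `counts`
#'   (spikes per bin), `binsize`, `times` (bin centres, s).
#' @export
smoothed_mua <- function(sd, duration, gaussian_sd_ms = 30, min_units = 16,
                         binsize_s = 0.001) {
  if (nrow(sd$units) < min_units)
    stop("insufficient units: packet analysis needs >= ", min_units)
  nb <- floor(duration / binsize_s)
  idx <- floor(sd$spikes$time / binsize_s) + 1L
  idx <- idx[idx >= 1 & idx <= nb]
  counts <- tabulate(idx, nb)
  k <- gaussian_kernel(gaussian_sd_ms / 1000 / binsize_s)
  rate <- conv_same(counts, k) / binsize_s
  structure(list(rate = rate, counts = counts, binsize = binsize_s,
                 times = (seq_len(nb) - 0.5) * binsize_s),
            class = "MuaSeries")
}

#' Detect population activity packets
#'
#' Packets are local maxima of the smoothed MUA rate that (i) exceed the
#' local average (centred 10 s window) by at least 60% for at least 25 ms,
#' and (ii) are flanked on both sides, within 1 s, by minima below 20% of
#' the local average sustained for at least 25 ms. Packets closer than
#' 15 ms are merged (larger peak kept). All criteria are relative to the
#' local average, so detection is invariant to rate rescaling.
#'
#' @param mua a [smoothed_mua()] result.
#' @param local_window_s local-average window (s).
#' @param exceed_frac required fractional excess over the local average.
#' @param exceed_min_s minimum duration of the excess (s). The standard
#'   value is 0.025; 0.040 is an alternative convention.
#' @param trough_frac flanking-minimum level as a fraction of the local
#'   average.
#' @param trough_min_s minimum flanking-trough duration (s).
#' @param search_s how far each side to look for flanking troughs (s).
#' @param merge_gap_s merge packets closer than this (s).
#' @return `EventTable` of kind `"packet"`; peak = rate maximum,
#'   onset/offset = span of the above-threshold excursion.
#' @export
detect_packets <- function(mua, local_window_s = 10, exceed_frac = 0.6,
                           exceed_min_s = 0.025, trough_frac = 0.2,
                           trough_min_s = 0.025, search_s = 1,
                           merge_gap_s = 0.015) {
  r <- mua$rate
  nb <- length(r)
  if (nb * mua$binsize < local_window_s)
    stop("series shorter than the local-average window")
  w <- round(local_window_s / mua$binsize)
  if (w %% 2 == 0) w <- w + 1
  # centred moving average via cumulative sums, edge-renormalized
  cs <- cumsum(c(0, r))
  h <- (w - 1) / 2
  lo <- pmax(seq_len(nb) - h, 1); hi <- pmin(seq_len(nb) + h, nb)
  local_avg <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  above <- r > (1 + exceed_frac) * local_avg
  low <- r < trough_frac * local_avg
  min_len <- round(exceed_min_s / mua$binsize)
  tr_len <- round(trough_min_s / mua$binsize)
  srch <- round(search_s / mua$binsize)
  # run-length segments of the above-threshold mask
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1); ends <- which(d == -1) - 1L
  # sustained-low mask: a bin is "trough-certified" if it starts a run of
  # >= tr_len low bins
  low_run <- stats::filter(as.numeric(low), rep(1, tr_len), sides = 1)
  trough_at <- which(!is.na(low_run) & low_run == tr_len)  # run END index
  onset <- peak <- offset <- amp <- numeric(0)
  for (i in seq_along(starts)) {
    s <- starts[i]; en <- ends[i]
    if (en - s + 1 < min_len) next
    left_ok <- length(trough_at) &&
      any(trough_at >= s - srch & trough_at < s + tr_len)
    right_ok <- length(trough_at) &&
      any(trough_at > en & trough_at <= en + srch + tr_len)
    if (!left_ok || !right_ok) next
    ip <- s - 1L + which.max(r[s:en])
    onset <- c(onset, mua$times[s]); offset <- c(offset, mua$times[en])
    peak <- c(peak, mua$times[ip]); amp <- c(amp, r[ip])
  }
  ev <- event_table(onset, peak, offset, amp, NA, kind = "packet")
  ev <- merge_close_events(ev, merge_gap_s)
  attr(ev, "kind") <- "packet"
  class(ev) <- c("EventTable", "data.frame")
  ev
}

#' State index: fraction of non-silent MUA bins in a sliding window
#'
#' For each step, the proportion of nonzero 1 ms population spike-count
#' bins inside a 0.5 s moving window. Values near 1 indicate the
#' desynchronized regime; low values the synchronized (packet) regime.
#'
#' @param mua a [smoothed_mua()] result (the raw 1 ms `counts` are used).
#' @param window_s window length (s).
#' @param step_s step size (s).
#' @return list with `si` in \[0,1\] and `times` (window centres, s).
#' @export
state_index <- function(mua, window_s = 0.5, step_s = 0.001) {
  nz <- as.numeric(mua$counts > 0)
  nb <- length(nz)
  w <- round(window_s / mua$binsize)
  if (w > nb) stop("window longer than the series")
  step <- max(1L, round(step_s / mua$binsize))
  cs <- cumsum(c(0, nz))
  starts <- seq(1L, nb - w + 1L, by = step)
  si <- (cs[starts + w] - cs[starts]) / w
  list(si = si, times = (starts - 1 + w / 2) * mua$binsize)
}

#' EMG estimate from high-frequency LFP channel correlations
#'
#' Band-passes every channel at 300-600 Hz and computes, per sliding
#' window, the mean pairwise zero-lag correlation coefficient. Muscular
#' activity appears as a broadband signal common to all channels, so high
#' values indicate high EMG tone.
#'
#' @param rec a multichannel `Recording` (>= 2 channels).
#' @param band filter band (Hz); the upper edge is clipped below Nyquist.
#' @param window_s correlation window length (s).
#' @param step_s window step (s).
#' @return list with `emg` (mean pairwise correlation per window) and
#'   `times` (window centres, s).
#' @export
emg_from_lfp <- function(rec, band = c(300, 600), window_s = 0.5,
                         step_s = 0.1) {
  nch <- nrow(rec$samples)
  if (nch < 2) stop("insufficient channels: EMG estimate needs >= 2")
  fs <- rec$fs
  hi <- min(band[2], 0.48 * fs)
  filt <- t(apply(rec$samples, 1, bandpass_zero_phase, fs = fs,
                  low = band[1], high = hi, order = 4))
  n <- ncol(filt)
  w <- round(window_s * fs); step <- max(1L, round(step_s * fs))
  starts <- seq(1L, n - w + 1L, by = step)
  emg <- vapply(starts, function(s) {
    C <- stats::cor(t(filt[, s:(s + w - 1), drop = FALSE]))
    mean(C[upper.tri(C)])
  }, numeric(1))
  list(emg = emg, times = rec$t0 + (starts - 1 + w / 2) / fs)
}

# deepest interior minimum of a kernel-smoothed histogram between the two
# largest modes; NA when the density is effectively unimodal
density_valley <- function(x) {
  d <- stats::density(x, n = 512)
  y <- d$y
  pk <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(pk) < 2) return(NA_real_)
  pk <- pk[order(-y[pk])][1:2]
  lo <- min(pk); hi <- max(pk)
  if (hi - lo < 2) return(NA_real_)
  seg <- y[(lo + 1):(hi - 1)]
  if (min(seg) > 0.8 * min(y[pk])) return(NA_real_)  # no real valley
  d$x[lo + which.min(seg)]
}

#' Segment brain states from the state index and EMG series
#'
#' Thresholds are set at the valley of the (bimodal) distribution of each
#' series; when a distribution is unimodal a configured fixed cutoff is
#' used with a warning. Labels: `synchronized` where the state index is
#' below its threshold, otherwise `desync_highEMG` / `desync_lowEMG` by
#' the EMG threshold. Intervals shorter than `min_interval_s` are merged
#' into their predecessor.
#'
#' @param si a [state_index()] result.
#' @param emg an [emg_from_lfp()] result.
#' @param si_cutoff,emg_cutoff fallback fixed cutoffs.
#' @param min_interval_s minimum reported interval length (s).
#' @return an `IntervalSet` with labels `synchronized`, `desync_lowEMG`,
#'   `desync_highEMG`.
#' @export
segment_states <- function(si, emg, si_cutoff = 0.8, emg_cutoff = 0.5,
                           min_interval_s = 2) {
  th_si <- density_valley(si$si)
  if (is.na(th_si)) {
    warning("state-index distribution unimodal; using fixed cutoff")
    th_si <- si_cutoff
  }
  th_emg <- density_valley(emg$emg)
  if (is.na(th_emg)) {
    warning("EMG distribution unimodal; using fixed cutoff")
    th_emg <- emg_cutoff
  }
  # classify on the coarser (EMG) time base
  emg_at <- stats::approx(emg$times, emg$emg, xout = si$times,
                          rule = 2)$y
  lab <- ifelse(si$si < th_si, "synchronized",
                ifelse(emg_at > th_emg, "desync_highEMG", "desync_lowEMG"))
  # run-length encode into intervals
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  startsi <- c(1, utils::head(ends, -1) + 1)
  dt <- si$times[2] - si$times[1]
  iv <- data.frame(start = si$times[startsi] - dt / 2,
                   stop = si$times[ends] + dt / 2, label = r$values)
  # absorb short intervals into the previous one
  repeat {
    short <- which(iv$stop - iv$start < min_interval_s)
    if (!length(short) || nrow(iv) == 1) break
    i <- short[1]
    if (i == 1) {
      iv$start[2] <- iv$start[1]
      iv <- iv[-1, , drop = FALSE]
    } else {
      iv$stop[i - 1] <- iv$stop[i]
      iv <- iv[-i, , drop = FALSE]
    }
    # merge adjacent identical labels
    j <- 1
    while (j < nrow(iv)) {
      if (iv$label[j] == iv$label[j + 1]) {
        iv$stop[j] <- iv$stop[j + 1]
        iv <- iv[-(j + 1), , drop = FALSE]
      } else j <- j + 1
    }
  }
  interval_set(iv$start, iv$stop, iv$label)
}
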