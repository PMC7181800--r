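#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x real numeric vector.
#' @return complex vector; `Mod` is the instantaneous amplitude envelope,
#'   `Arg` the instantaneous phase (peak = 0, trough = +/- pi for a cosine).
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase by the filter-Hilbert method
#'
#' Band-passes the trace (zero phase) and extracts the analytic phase.
#' Phase convention: band peak = 0, trough = +/- pi (cosine convention),
#' recorded in the result.
#'
#' @param trace numeric signal.
#' @param fs sampling rate (Hz).
#' @param band two-element band (Hz).
#' @param min_amplitude samples whose envelope falls below this fraction of
#'   the median envelope are flagged invalid (phase undefined).
#' @return list with `phase` (radians), `amplitude`, `valid` (logical mask)
#'   and `convention`.
#' @export
filter_hilbert_phase <- function(trace, fs, band, min_amplitude = 1e-3) {
  filt <- bandpass_zero_phase(trace, fs, band[1], band[2])
  z <- analytic_signal(filt)
  amp <- Mod(z)
  ref <- stats::median(amp)
  valid <- if (stats::sd(trace) <= .Machine$double.eps ||
               ref <= .Machine$double.eps) rep(FALSE, length(amp))
           else amp > min_amplitude * ref
  list(phase = Arg(z), amplitude = amp, valid = valid,
       convention = "peak=0, trough=+/-pi")
}

#' Inter-trial phase clustering (resultant length)
#'
#' Modulus of the mean unit phasor, `|n^-1 sum exp(i phase)|`; 1 for
#' identical phases, 0 for balanced symmetric phase sets.
#'
#' @param phases numeric vector of phase angles (radians), non-empty.
#' @return scalar in \[0, 1\].
#' @export
itpc <- function(phases) {
  if (!length(phases)) stop("empty phase vector")
  Mod(mean(exp(1i * phases)))
}

#' Rayleigh test of circular non-uniformity
#'
#' Z = n R^2 with the standard finite-n corrected p-value approximation.
#'
#' @param phases phase angles (radians), n >= 5.
#' @return p-value.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n < 5) stop("insufficient data: Rayleigh test needs n >= 5")
  R <- n * itpc(phases)
  Z <- R^2 / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  min(max(p, .Machine$double.xmin), 1)
}

# cycles per frequency, log-interpolated between the cycle_range ends
morlet_cycles <- function(freqs, cycle_range, full_range = range(freqs)) {
  if (length(freqs) == 1 || diff(log(full_range)) == 0)
    return(rep(cycle_range[1], length(freqs)))
  frac <- (log(freqs) - log(full_range[1])) / diff(log(full_range))
  exp(log(cycle_range[1]) + frac * diff(log(cycle_range)))
}

#' Complex Morlet wavelet spectrogram
#'
#' Convolution with complex Morlet wavelets whose number of cycles is
#' logarithmically interpolated across frequency between the ends of
#' `cycle_range`. Kernels are scaled so a unit-amplitude sinusoid at a bin
#' frequency yields unit magnitude.
#'
#' @param trace numeric signal.
#' @param fs sampling rate (Hz).
#' @param freqs strictly increasing frequency vector, below Nyquist.
#' @param cycle_range two-element cycle counts at the lowest and highest
#'   analysed frequency (default 3 to 12).
#' @param t0 time of the first sample (s).
#' @return object of class `Spectrogram`: list with complex `values`
#'   (frequency x time), `freqs`, `times`, `normalization = "raw"`.
#' @export
morlet_spectrogram <- function(trace, fs, freqs, cycle_range = c(3, 12),
                               t0 = 0) {
  if (any(freqs >= fs / 2) || any(freqs <= 0))
    stop("frequencies must lie in (0, fs/2)")
  if (is.unsorted(freqs, strictly = TRUE)) stop("freqs must be increasing")
  cycles <- morlet_cycles(freqs, cycle_range)
  vals <- matrix(0i, length(freqs), length(trace))
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sd_t <- cycles[i] / (2 * pi * f)
    h <- ceiling(4 * sd_t * fs)
    tt <- seq(-h, h) / fs
    env <- exp(-tt^2 / (2 * sd_t^2))
    k <- env * exp(2i * pi * f * tt)
    k <- k / (sum(env) / 2)       # unit response to a unit sine at f
    vals[i, ] <- conv_same(as.complex(trace), k)
  }
  structure(list(values = vals, freqs = freqs,
                 times = t0 + (seq_along(trace) - 1) / fs,
                 normalization = "raw"),
            class = "Spectrogram")
}

#' @export
print.Spectrogram <- function(x, ...) {
  cat(sprintf("Spectrogram: %d freqs (%g-%g Hz) x %d times, %s\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), x$normalization))
  invisible(x)
}

#' Event-triggered average spectrogram, z-scored against baseline
#'
#' For each event and frequency, power samples in the peri-event window are
#' z-scored against the mean and SD of that event's baseline period (which
#' must end at least 100 ms before the event reference time); the z-maps
#' are then averaged across events.
#'
#' @param spec a raw `Spectrogram` (complex or power values).
#' @param events `EventTable`; `reference` selects the alignment column.
#' @param window two-element peri-event window (s).
#' @param baseline two-element baseline window (s, relative to reference);
#'   must satisfy `baseline[2] <= -0.1`.
#' @param reference `"onset"` or `"peak"`.
#' @return `Spectrogram` with `values` = average z-scored power, `times` =
#'   lags relative to the event reference, `normalization =
#'   "zscore_baseline"`.
#' @export
event_triggered_spectrogram <- function(spec, events, window = c(-0.2, 0.3),
                                        baseline = c(-0.4, -0.1),
                                        reference = "onset") {
  if (baseline[2] > -0.1 + 1e-9)
    stop("baseline must end at least 100 ms before the event")
  pow <- if (is.complex(spec$values)) Mod(spec$values)^2 else spec$values
  dt <- spec$times[2] - spec$times[1]
  refs <- events[[reference]]
  i_ref <- round((refs - spec$times[1]) / dt) + 1L
  w_idx <- round(window[1] / dt):round(window[2] / dt)
  b_idx <- round(baseline[1] / dt):round(baseline[2] / dt)
  ok <- i_ref + min(c(w_idx, b_idx)) >= 1 &
        i_ref + max(c(w_idx, b_idx)) <= ncol(pow)
  i_ref <- i_ref[ok]
  if (!length(i_ref)) stop("insufficient data: no events within range")
  acc <- matrix(0, nrow(pow), length(w_idx))
  for (i in i_ref) {
    b <- pow[, i + b_idx, drop = FALSE]
    mu <- rowMeans(b)
    sdv <- apply(b, 1, stats::sd)
    sdv[sdv == 0] <- Inf
    acc <- acc + (pow[, i + w_idx, drop = FALSE] - mu) / sdv
  }
  structure(list(values = acc / length(i_ref), freqs = spec$freqs,
                 times = w_idx * dt, normalization = "zscore_baseline",
                 baseline = baseline, n_events = length(i_ref)),
            class = "Spectrogram")
}

#' Cross-regional wavelet phase coherogram
#'
#' At each (frequency, peri-event lag), the resultant length (ITPC) of the
#' across-event distribution of wavelet phase differences between the two
#' traces. Swapping the traces conjugates the phase differences and leaves
#' the magnitudes unchanged.
#'
#' @param traceA,traceB co-sampled LFP traces.
#' @param fs sampling rate (Hz).
#' @param events `EventTable`; alignment on `reference`.
#' @param freqs analysis frequencies (Hz).
#' @param window peri-event window (s).
#' @param cycle_range Morlet cycle range.
#' @param reference `"onset"` or `"peak"`.
#' @return `Spectrogram`-like object with `values` = coherence in \[0,1\].
#' @export
phase_coherogram <- function(traceA, traceB, fs, events, freqs,
                             window = c(-0.1, 0.1), cycle_range = c(3, 12),
                             reference = "onset") {
  stopifnot(length(traceA) == length(traceB))
  if (nrow(events) < 10)
    warning("fewer than 10 events: coherence estimates will be noisy")
  wa <- morlet_spectrogram(traceA, fs, freqs, cycle_range)
  wb <- morlet_spectrogram(traceB, fs, freqs, cycle_range)
  dphi <- wa$values * Conj(wb$values)
  dphi <- dphi / pmax(Mod(dphi), .Machine$double.xmin)  # unit phasors
  i_ref <- round(events[[reference]] * fs) + 1L
  w_idx <- round(window[1] * fs):round(window[2] * fs)
  ok <- i_ref + w_idx[1] >= 1 & i_ref + w_idx[length(w_idx)] <= ncol(dphi)
  i_ref <- i_ref[ok]
  if (!length(i_ref)) stop("insufficient data: no events within range")
  acc <- matrix(0i, length(freqs), length(w_idx))
  for (i in i_ref) acc <- acc + dphi[, i + w_idx, drop = FALSE]
  structure(list(values = Mod(acc) / length(i_ref), freqs = freqs,
                 times = w_idx / fs, normalization = "coherence",
                 n_events = length(i_ref)),
            class = "Spectrogram")
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Tridiagonal eigenvector formulation; tapers are unit-energy and sign
#' fixed so each integrates non-negatively.
#'
#' @param n taper length (samples).
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @return n x k matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  w <- nw / n
  t <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off <- t[-1] * (n - t[-1]) / 2
  A[cbind(2:n, 1:(n - 1))] <- off
  A[cbind(1:(n - 1), 2:n)] <- off
  e <- eigen(A, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
  }
  tap
}

#' Multitaper spike-field coherence around events
#'
#' Coherence between the spike point process (binned at the LFP rate) and
#' the LFP over windows centred on event peaks, using Slepian tapers
#' (default 5 tapers, time-bandwidth product 3). Cross- and auto-spectra
#' are averaged over tapers and windows before forming the coherence.
#'
#' @param spike_times numeric spike times (s).
#' @param trace LFP trace.
#' @param fs sampling rate (Hz).
#' @param events `EventTable`; windows are `peak +/- halfwindow`.
#' @param halfwindow half window length (s; default 0.1, i.e. +/- 100 ms).
#' @param n_tapers,tw number of tapers and time-bandwidth product.
#' @param t0 time of the first LFP sample (s).
#' @return list with `freq` (Hz) and `coherence` in \[0,1\].
#' @export
spike_field_coherence <- function(spike_times, trace, fs, events,
                                  halfwindow = 0.1, n_tapers = 5, tw = 3,
                                  t0 = 0) {
  nwin <- 2L * round(halfwindow * fs)
  i_pk <- round((events$peak - t0) * fs) + 1L
  i_pk <- i_pk[i_pk - nwin / 2 >= 1 & i_pk + nwin / 2 - 1 <= length(trace)]
  if (!length(i_pk)) stop("insufficient data: no usable event windows")
  # binned spike train on the LFP clock
  counts <- numeric(length(trace))
  bi <- round((spike_times - t0) * fs) + 1L
  bi <- bi[bi >= 1 & bi <= length(trace)]
  for (b in bi) counts[b] <- counts[b] + 1
  total_spk <- 0
  tap <- dpss_tapers(nwin, tw, n_tapers)
  sxx <- syy <- numeric(nwin); sxy <- complex(nwin)
  sxy <- rep(0i, nwin)
  for (i in i_pk) {
    idx <- (i - nwin / 2):(i + nwin / 2 - 1)
    x <- trace[idx] - mean(trace[idx])
    y <- counts[idx] - mean(counts[idx])
    total_spk <- total_spk + sum(counts[idx])
    for (j in seq_len(n_tapers)) {
      X <- stats::fft(x * tap[, j]); Y <- stats::fft(y * tap[, j])
      sxx <- sxx + Mod(X)^2
      syy <- syy + Mod(Y)^2
      sxy <- sxy + X * Conj(Y)
    }
  }
  if (total_spk == 0) stop("insufficient data: no spikes in event windows")
  nf <- nwin %/% 2 + 1
  coh <- Mod(sxy)^2 / (sxx * syy)
  list(freq = (seq_len(nf) - 1) * fs / nwin, coherence = coh[seq_len(nf)],
       n_windows = length(i_pk), n_spikes = total_spk)
}

# Shannon entropy with the 0 log 0 = 0 convention
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Modulation index of a phase-binned amplitude profile
#'
#' Kullback-Leibler divergence of the normalized mean-amplitude-per-bin
#' profile from the uniform distribution, divided by `log(n_bins)`: 0 for
#' a flat profile, exactly 1 when all amplitude falls in a single bin.
#'
#' @param bin_means mean amplitude per phase bin (>= 0).
#' @return scalar in \[0, 1\].
#' @export
modulation_index <- function(bin_means) {
  s <- sum(bin_means)
  if (s <= 0) return(0)
  p <- bin_means / s
  (log(length(bin_means)) - shannon_entropy(p)) / log(length(bin_means))
}

#' Phase-amplitude coupling modulation index with shift surrogates
#'
#' Wavelet phase at low frequencies and wavelet amplitude at high
#' frequencies (the outermost second on each side is excluded from the
#' estimate, since both series carry shared wavelet edge attenuation
#' there); amplitudes are averaged within 50 phase bins and the
#' modulation index is the KL divergence of the normalized bin profile
#' from uniform, divided by log(number of bins). Significance per
#' (phase, amplitude) frequency pair is assessed with circularly
#' time-shifted amplitude surrogates (shifts uniform in
#' \[1 s, T - 1 s\]): a z-score (Pz) is reported against the surrogate
#' distribution, the p-value is taken from the empirical surrogate tail
#' (the MI null is right-skewed, so the normal tail of Pz would run
#' liberal), and MI values with p >= alpha are zeroed in the masked
#' matrix.
#'
#' @param trace numeric signal.
#' @param fs sampling rate (Hz).
#' @param phase_freqs phase frequencies (Hz; default 39 log-spaced 2-40).
#' @param amp_freqs amplitude frequencies (Hz; default 91 log-spaced
#'   50-500, truncated below Nyquist).
#' @param n_bins number of phase bins (default 50).
#' @param n_surrogates number of shift surrogates (default 200).
#' @param alpha significance level for masking.
#' @param cycle_range Morlet cycle range.
#' @return list with matrices `mi`, `pz`, `p`, `mi_masked`
#'   (phase freq x amplitude freq) plus the frequency axes.
#' @export
pac_modulation_index <- function(trace, fs,
                                 phase_freqs = exp(seq(log(2), log(40),
                                                       length.out = 39)),
                                 amp_freqs = exp(seq(log(50), log(500),
                                                     length.out = 91)),
                                 n_bins = 50, n_surrogates = 200,
                                 alpha = 0.05, cycle_range = c(3, 12)) {
  amp_freqs <- amp_freqs[amp_freqs < fs / 2]
  n <- length(trace)
  if (n < 4 * fs / min(phase_freqs))
    stop("trace too short for the slowest phase frequency")
  wp <- morlet_spectrogram(trace, fs, phase_freqs, cycle_range)
  wa <- morlet_spectrogram(trace, fs, amp_freqs, cycle_range)
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  shift_lo <- round(fs); shift_hi <- n - round(fs)
  if (shift_hi <= shift_lo) stop("trace too short for shift surrogates")
  shifts <- shift_lo + floor(stats::runif(n_surrogates) *
                             (shift_hi - shift_lo))
  np <- length(phase_freqs); na <- length(amp_freqs)
  mi <- pz <- pmat <- matrix(0, np, na)
  binned_mi <- function(bins, amp) {
    m <- rowsum(amp, bins, reorder = TRUE)
    cnt <- tabulate(bins, n_bins)
    m <- as.numeric(m) / pmax(cnt[sort(unique(bins))], 1)
    prof <- numeric(n_bins)
    prof[sort(unique(bins))] <- m
    modulation_index(prof)
  }
  # the outermost second on each side carries shared wavelet edge
  # attenuation in both the phase and amplitude series; evaluating MI on
  # the interior keeps the observed pairing exchangeable with the shifts
  keep <- (round(fs) + 1):(n - round(fs))
  for (i in seq_len(np)) {
    ph <- Arg(wp$values[i, ])
    bins <- findInterval(ph, edges, rightmost.closed = TRUE)
    bins[bins < 1] <- 1; bins[bins > n_bins] <- n_bins
    bins_in <- bins[keep]
    for (j in seq_len(na)) {
      amp <- Mod(wa$values[j, ])
      mi[i, j] <- binned_mi(bins_in, amp[keep])
      sur <- vapply(shifts, function(s) {
        binned_mi(bins_in, amp[((seq_len(n) - 1 + s) %% n) + 1][keep])
      }, numeric(1))
      sdv <- stats::sd(sur)
      pz[i, j] <- if (sdv > 0) (mi[i, j] - mean(sur)) / sdv else 0
      # exact empirical tail: the MI null is right-skewed, so the
      # normal approximation through the z-score runs liberal
      pmat[i, j] <- (1 + sum(sur >= mi[i, j])) / (1 + n_surrogates)
    }
  }
  mi_masked <- mi
  mi_masked[pmat >= alpha] <- 0
  list(mi = mi, pz = pz, p = pmat, mi_masked = mi_masked,
       phase_freqs = phase_freqs, amp_freqs = amp_freqs)
}
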