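#' Construct a multichannel Recording
#'
#' A `Recording` holds a channels-by-time matrix of extracellular signal
#' together with its sampling rate and a per-channel metadata table. The time
#' axis is implied: sample `i` (0-based) occurs at `t0 + i / fs` seconds.
#'
#' @param samples numeric matrix, channels x time. A vector is treated as a
#'   single channel.
#' @param fs sampling rate in Hz (> 0).
#' @param channels data.frame with columns `id`, `shank`, `depth_um`,
#'   `region`; one row per channel, in row order of `samples`. Regions use
#'   the labels `"CA1"`, `"SUB"`, `"gRSC_sup"`, `"gRSC_deep"` or `"other"`.
#'   If `NULL` a minimal table is generated.
#' @param t0 start time in seconds.
#' @return an object of class `Recording`.
#' @export
recording <- function(samples, fs, channels = NULL, t0 = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), is.numeric(fs), fs > 0)
  if (is.null(channels)) {
    channels <- data.frame(id = seq_len(nrow(samples)), shank = 1L,
                           depth_um = 0, region = "other")
  }
  if (nrow(channels) != nrow(samples))
    stop("channel table length must equal the number of sample rows")
  if (anyDuplicated(channels$id))
    stop("channel ids must be unique")
  structure(list(samples = samples, fs = fs, channels = channels, t0 = t0),
            class = "Recording")
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("Recording: %d channel(s) x %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' Time axis of a Recording
#' @param rec a `Recording`.
#' @return numeric vector of sample times in seconds.
#' @export
rec_times <- function(rec) {
  rec$t0 + (seq_len(ncol(rec$samples)) - 1) / rec$fs
}

#' Construct a SpikeData object
#'
#' Sorted spike times with per-unit metadata (region, layer, waveform
#' features and putative cell type).
#'
#' @param spikes data.frame with columns `time` (s) and `unit`.
#' @param units data.frame with column `unit` plus any of `region`, `layer`
#'   (`"superficial"`, `"deep"`, `"unknown"`), `rate` (Hz), `width_ms`
#'   (trough-to-peak), `asymmetry`, `type` (`"pyramidal"`, `"interneuron"`,
#'   `"unclassified"`). Missing columns are filled with defaults.
#' @param duration session duration in seconds; used to (re)compute mean
#'   rates when absent.
#' @return an object of class `SpikeData`.
#' @export
spike_data <- function(spikes, units = NULL, duration = NULL) {
  stopifnot(all(c("time", "unit") %in% names(spikes)))
  spikes <- spikes[order(spikes$unit, spikes$time), , drop = FALSE]
  rownames(spikes) <- NULL
  if (is.null(units)) units <- data.frame(unit = sort(unique(spikes$unit)))
  if (!all(spikes$unit %in% units$unit))
    stop("every spike's unit id must exist in the unit table")
  defaults <- list(region = "other", layer = "unknown", rate = NA_real_,
                   width_ms = NA_real_, asymmetry = NA_real_,
                   type = "unclassified")
  for (nm in names(defaults))
    if (is.null(units[[nm]])) units[[nm]] <- defaults[[nm]]
  if (!is.null(duration) && anyNA(units$rate)) {
    n <- table(factor(spikes$unit, levels = units$unit))
    units$rate <- as.numeric(n) / duration
  }
  structure(list(spikes = spikes, units = units), class = "SpikeData")
}

#' @export
print.SpikeData <- function(x, ...) {
  cat(sprintf("SpikeData: %d spikes from %d units\n",
              nrow(x$spikes), nrow(x$units)))
  invisible(x)
}

#' Spike times of one unit
#' @param sd a `SpikeData`.
#' @param unit unit id.
#' @return numeric vector of spike times (s).
#' @export
unit_spikes <- function(sd, unit) {
  sd$spikes$time[sd$spikes$unit == unit]
}

#' Construct an EventTable
#'
#' Typed detected events (ripples, negative waves, packets, stimulation
#' pulses) with onset/peak/offset times in seconds and a peak amplitude.
#'
#' @param onset,peak,offset event times (s), `onset <= peak <= offset`.
#' @param amplitude peak amplitude (detector units).
#' @param channel channel id the event was detected on.
#' @param kind event type tag, e.g. `"ripple"`.
#' @param params list of detection parameters, kept as metadata.
#' @return a data.frame of class `EventTable`, sorted by onset.
#' @export
event_table <- function(onset = numeric(), peak = onset, offset = onset,
                        amplitude = NA_real_, channel = NA,
                        kind = "event", params = list()) {
  n <- length(onset)
  ev <- data.frame(onset = onset, peak = peak, offset = offset,
                   amplitude = rep_len(amplitude, n),
                   channel = rep_len(channel, n))
  if (nrow(ev) && any(ev$onset > ev$peak | ev$peak > ev$offset))
    stop("events must satisfy onset <= peak <= offset")
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, kind = kind, params = params,
            class = c("EventTable", "data.frame"))
}

#' Construct an IntervalSet
#'
#' Labelled half-open intervals `[start, stop)`, e.g. brain-state epochs.
#'
#' @param start,stop interval bounds in seconds, `start < stop`.
#' @param label character label per interval.
#' @return data.frame of class `IntervalSet`.
#' @export
interval_set <- function(start = numeric(), stop = numeric(),
                         label = character()) {
  if (length(start) && any(start >= stop)) stop("intervals need start < stop")
  iv <- data.frame(start = start, stop = stop,
                   label = rep_len(as.character(label), length(start)))
  iv <- iv[order(iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  structure(iv, class = c("IntervalSet", "data.frame"))
}

#' Total duration covered by an IntervalSet
#' @param iv an `IntervalSet`.
#' @param label optional label filter.
#' @return total covered time in seconds.
#' @export
interval_duration <- function(iv, label = NULL) {
  if (!is.null(label)) iv <- iv[iv$label %in% label, , drop = FALSE]
  if (!nrow(iv)) return(0)
  sum(iv$stop - iv$start)
}

#' Membership of time points in an IntervalSet
#' @param t numeric vector of times (s).
#' @param iv an `IntervalSet`.
#' @param label optional label filter.
#' @return logical vector, `TRUE` where `t` falls in `[start, stop)`.
#' @export
in_intervals <- function(t, iv, label = NULL) {
  if (!is.null(label)) iv <- iv[iv$label %in% label, , drop = FALSE]
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(iv)))
    out <- out | (t >= iv$start[i] & t < iv$stop[i])
  out
}

# ---------------------------------------------------------------------------
# Binary + tabular I/O.  Raw files follow the flat interleaved .dat
# convention: little-endian signed 16-bit, channel-interleaved frames.

#' Read a flat interleaved binary recording
#'
#' Reads the de-facto raw `.dat` format: frames of `n_channels` consecutive
#' little-endian signed 16-bit samples. No scaling is applied unless the
#' channel map carries a `gain` column (signal units per count).
#'
#' @param path file path.
#' @param n_channels number of interleaved channels.
#' @param fs sampling rate in Hz.
#' @param channel_map optional data.frame (id, shank, depth_um, region and
#'   optionally gain), one row per channel.
#' @param t0 start time (s).
#' @return a `Recording`.
#' @export
read_binary_recording <- function(path, n_channels, fs, channel_map = NULL,
                                  t0 = 0) {
  sz <- file.info(path)$size
  if (is.na(sz)) stop("file not found: ", path)
  bytes_per_frame <- n_channels * 2L
  if (sz %% bytes_per_frame != 0)
    stop("malformed file: size ", sz, " not divisible by frame size ",
         bytes_per_frame)
  n_frames <- sz %/% bytes_per_frame
  con <- file(path, "rb"); on.exit(close(con))
  raw <- readBin(con, "integer", n = n_frames * n_channels, size = 2L,
                 signed = TRUE, endian = "little")
  samples <- matrix(as.numeric(raw), nrow = n_channels)  # column = frame
  if (!is.null(channel_map) && !is.null(channel_map$gain))
    samples <- samples * channel_map$gain
  recording(samples, fs, channels = channel_map, t0 = t0)
}

#' Write a Recording as flat interleaved binary
#'
#' Values are rounded to the nearest integer and must fit in signed 16 bits.
#'
#' @param rec a `Recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_binary_recording <- function(rec, path) {
  v <- round(as.vector(rec$samples))  # column-major == interleaved frames
  if (any(v < -32768 | v > 32767))
    stop("samples exceed the signed 16-bit range; rescale before writing")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.integer(v), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read / write an EventTable as TSV
#'
#' Columns: kind, onset_s, peak_s, offset_s, amplitude, channel.
#'
#' @param path file path.
#' @param ev an `EventTable`.
#' @return `read_events`: an `EventTable`; `write_events`: `path` invisibly.
#' @export
read_events <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  event_table(onset = d$onset_s, peak = d$peak_s, offset = d$offset_s,
              amplitude = d$amplitude, channel = d$channel,
              kind = if (nrow(d)) d$kind[1] else "event")
}

#' @rdname read_events
#' @export
write_events <- function(ev, path) {
  d <- data.frame(kind = attr(ev, "kind"), onset_s = ev$onset,
                  peak_s = ev$peak, offset_s = ev$offset,
                  amplitude = ev$amplitude, channel = ev$channel)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write spike tables as TSV
#'
#' Spikes: columns time_s, unit_id. Units: column unit_id plus metadata.
#'
#' @param spike_path,unit_path file paths (unit table optional on read).
#' @param sd a `SpikeData`.
#' @return `read_spikes`: a `SpikeData`; `write_spikes`: invisibly `NULL`.
#' @export
read_spikes <- function(spike_path, unit_path = NULL) {
  s <- utils::read.delim(spike_path, stringsAsFactors = FALSE)
  spikes <- data.frame(time = s$time_s, unit = s$unit_id)
  units <- NULL
  if (!is.null(unit_path)) {
    u <- utils::read.delim(unit_path, stringsAsFactors = FALSE)
    names(u)[names(u) == "unit_id"] <- "unit"
    units <- u
  }
  spike_data(spikes, units)
}

#' @rdname read_spikes
#' @export
write_spikes <- function(sd, spike_path, unit_path = NULL) {
  utils::write.table(
    data.frame(time_s = sd$spikes$time, unit_id = sd$spikes$unit),
    spike_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(unit_path)) {
    u <- sd$units
    names(u)[names(u) == "unit"] <- "unit_id"
    utils::write.table(u, unit_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Filtering primitives

# Zero-phase filtering with odd-reflect edge padding (3x the filter length),
# forward and reverse application; signal::filtfilt pads nothing.
zerophase_filter <- function(b, a, x) {
  b <- as.numeric(b); a <- as.numeric(a)
  n <- length(x)
  pad <- min(3L * max(length(b), length(a)) * 3L, n - 1L)
  if (pad < 1) stop("trace too short to filter")
  pre  <- 2 * x[1] - x[seq(pad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(pre, x, post)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass forward and backward
#' (`filtfilt` scheme with reflect padding), giving zero net phase shift and
#' a squared single-pass magnitude response.
#'
#' @param trace numeric signal vector.
#' @param fs sampling rate (Hz).
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth order of the single pass (default 2, the
#'   convention for ripple-band filtering).
#' @return filtered trace, same length as input.
#' @export
bandpass_zero_phase <- function(trace, fs, low, high, order = 2) {
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band must satisfy 0 < low < high < fs/2")
  bt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  zerophase_filter(bt$b, bt$a, trace)
}

#' Zero-phase Butterworth low-pass filter
#' @inheritParams bandpass_zero_phase
#' @param cutoff cutoff frequency in Hz.
#' @return filtered trace.
#' @export
lowpass_zero_phase <- function(trace, fs, cutoff, order = 4) {
  if (!(cutoff > 0 && cutoff < fs / 2))
    stop("cutoff must lie in (0, fs/2)")
  bt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  zerophase_filter(bt$b, bt$a, trace)
}

#' Resample an LFP recording
#'
#' Anti-alias low-pass filtering with a windowed-sinc FIR (default cutoff
#' 450 Hz, the LFP extraction convention) applied with zero phase, followed
#' by decimation onto the target rate. Integer decimation factors pick every
#' k-th sample; otherwise the band-limited signal is linearly interpolated
#' onto the new time grid.
#'
#' @param rec a `Recording`.
#' @param target_fs target sampling rate in Hz, `< rec$fs` (typically 1250
#'   or 1000).
#' @param cutoff anti-alias cutoff in Hz (default 450).
#' @return a `Recording` at `target_fs`.
#' @export
resample_lfp <- function(rec, target_fs, cutoff = 450) {
  if (target_fs >= rec$fs) stop("target_fs must be below the original rate")
  cutoff <- min(cutoff, 0.45 * target_fs)
  fs <- rec$fs
  ntaps <- 2L * ceiling(2 * fs / cutoff) + 1L
  h <- signal::fir1(ntaps - 1L, cutoff / (fs / 2), type = "low")
  n_in <- ncol(rec$samples)
  ratio <- fs / target_fs
  n_out <- floor(n_in / ratio)
  idx_exact <- 1 + (seq_len(n_out) - 1) * ratio
  out <- matrix(0, nrow(rec$samples), n_out)
  for (ch in seq_len(nrow(rec$samples))) {
    y <- zerophase_filter(h, 1, rec$samples[ch, ])
    if (abs(ratio - round(ratio)) < 1e-9) {
      out[ch, ] <- y[round(idx_exact)]
    } else {
      out[ch, ] <- stats::approx(seq_len(n_in), y, xout = idx_exact)$y
    }
  }
  recording(out, target_fs, channels = rec$channels, t0 = rec$t0)
}
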