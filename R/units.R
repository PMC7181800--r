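#' Quality-control filter for sorted units
#'
#' Discards units with mean firing rate below 0.5 Hz or an inter-spike
#' interval violation fraction above 0.01 (fraction of ISIs shorter than
#' the refractory period, default 2 ms).
#'
#' @param sd a `SpikeData`.
#' @param duration session duration (s); needed to compute rates if the
#'   unit table lacks them.
#' @param min_rate minimum mean rate (Hz).
#' @param max_isi_violation maximum allowed ISI-violation fraction.
#' @param refractory_ms refractory period defining a violation (ms).
#' @return filtered `SpikeData`.
#' @export
qc_filter_units <- function(sd, duration, min_rate = 0.5,
                            max_isi_violation = 0.01, refractory_ms = 2) {
  keep <- logical(nrow(sd$units))
  for (i in seq_len(nrow(sd$units))) {
    u <- sd$units$unit[i]
    st <- unit_spikes(sd, u)
    rate <- length(st) / duration
    viol <- if (length(st) > 1)
      mean(diff(st) < refractory_ms / 1000) else 0
    keep[i] <- rate >= min_rate && viol <= max_isi_violation
  }
  units <- sd$units[keep, , drop = FALSE]
  spikes <- sd$spikes[sd$spikes$unit %in% units$unit, , drop = FALSE]
  spike_data(spikes, units, duration = duration)
}

#' Classify units into putative pyramidal cells and interneurons
#'
#' Two-cluster k-means on standardized trough-to-peak width, waveform
#' asymmetry and log firing rate. The cluster with the narrower mean
#' width and higher mean rate is labelled `"interneuron"`. Standardization
#' makes the labels invariant to per-feature rescaling.
#'
#' @param units data.frame with columns `width_ms`, `asymmetry`, `rate`.
#' @param seed RNG seed for the k-means restarts.
#' @return character vector of labels (`"pyramidal"`, `"interneuron"`, or
#'   `"unclassified"` if clustering is degenerate).
#' @export
classify_cell_types <- function(units, seed = 1) {
  n <- nrow(units)
  if (n < 2) return(rep("unclassified", n))
  X <- cbind(units$width_ms, units$asymmetry, log(pmax(units$rate, 1e-3)))
  if (any(apply(X, 2, stats::sd) == 0) || anyNA(X))
    return(rep("unclassified", n))
  Xs <- scale(X)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  km <- stats::kmeans(Xs, centers = 2, nstart = 20)
  cw <- tapply(units$width_ms, km$cluster, mean)
  cr <- tapply(units$rate, km$cluster, mean)
  # narrow + fast cluster = interneurons; rank by width minus rate order
  score <- rank(cw) - rank(cr)
  int_cluster <- as.integer(names(which.min(score)))
  ifelse(km$cluster == int_cluster, "interneuron", "pyramidal")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Peri-event time histogram of a spike train
#'
#' Spike counts in lag bins relative to event reference times. Events
#' closer than `min_sep` to the preceding event are excluded before
#' counting (avoiding contamination from event bursts). Baseline z-scores
#' use bins ending at least 100 ms before the reference.
#'
#' @param spike_times numeric spike times (s).
#' @param events `EventTable`.
#' @param binsize bin width (s).
#' @param halfwindow lag half-window (s).
#' @param min_sep minimum event separation (s, default 0.5).
#' @param reference `"onset"` or `"peak"`.
#' @param baseline_end latest lag (s) still counted as baseline
#'   (default -0.1).
#' @return object of class `Peth`: list with `lags` (bin centres),
#'   `counts`, `n_events`, `binsize`, `z` (per-bin z-score against the
#'   baseline-bin mean/SD), `baseline_bins` logical mask.
#' @export
peth <- function(spike_times, events, binsize = 0.01, halfwindow = 0.5,
                 min_sep = 0.5, reference = "onset", baseline_end = -0.1) {
  refs <- events[[reference]]
  if (length(refs) > 1 && min_sep > 0) {
    gap_prev <- c(Inf, diff(refs))
    gap_next <- c(diff(refs), Inf)
    refs <- refs[gap_prev >= min_sep & gap_next >= min_sep]
  }
  if (!length(refs)) stop("insufficient data: no qualifying events")
  breaks <- seq(-halfwindow, halfwindow, by = binsize)
  nb <- length(breaks) - 1
  counts <- numeric(nb)
  for (r in refs) {
    d <- spike_times - r
    d <- d[d >= -halfwindow & d < breaks[nb + 1]]
    if (length(d))
      counts <- counts + tabulate(findInterval(d, breaks), nb)
  }
  lags <- (breaks[-1] + breaks[-(nb + 1)]) / 2
  bl <- lags < baseline_end
  mu <- mean(counts[bl]); sdv <- stats::sd(counts[bl])
  z <- if (isTRUE(sdv > 0)) (counts - mu) / sdv else rep(0, nb)
  structure(list(lags = lags, counts = counts, n_events = length(refs),
                 binsize = binsize, z = z, baseline_bins = bl),
            class = "Peth")
}

#' @export
print.Peth <- function(x, ...) {
  cat(sprintf("Peth: %d bins of %g ms, %d events, %d spikes\n",
              length(x$lags), x$binsize * 1000, x$n_events, sum(x$counts)))
  invisible(x)
}

#' Convolution-based PETH significance
#'
#' The expected count per bin is predicted by Gaussian-convolving the PETH
#' with the test window excluded (test-window counts are replaced by the
#' baseline mean before smoothing, so a planted response cannot inflate
#' its own prediction). Per-bin Poisson acceptance bands are placed at a
#' global level `alpha`, Bonferroni-divided across test-window bins. The
#' unit is flagged `"excited"` if any test bin exceeds the upper band,
#' `"suppressed"` if any falls below the lower band (excitation wins if
#' both).
#'
#' @param p a [peth()] object.
#' @param kernel_sd_ms Gaussian kernel SD (ms, default 10).
#' @param alpha global significance level (default 0.01).
#' @param test_window lag window tested (s, default 0 to 0.1).
#' @return list with `flag` (`"excited"`, `"suppressed"`, `"none"`),
#'   `significant_bins` (lag indices), `predictor`, `upper`, `lower`,
#'   `latency_to_peak_s` (lag of the smoothed-PETH maximum inside the
#'   test window, `NA` when not excited).
#' @export
peth_significance <- function(p, kernel_sd_ms = 10, alpha = 0.01,
                              test_window = c(0, 0.1)) {
  counts <- p$counts
  if (sum(counts) == 0)
    return(list(flag = "none", significant_bins = integer(),
                predictor = counts, upper = counts, lower = counts,
                latency_to_peak_s = NA_real_))
  test <- p$lags >= test_window[1] & p$lags <= test_window[2]
  n_test <- sum(test)
  masked <- counts
  masked[test] <- mean(counts[p$baseline_bins])
  k <- gaussian_kernel(kernel_sd_ms / 1000 / p$binsize)
  pred <- pmax(conv_same(masked, k), 1e-12)
  a_bin <- alpha / 2 / max(n_test, 1)
  upper <- stats::qpois(1 - a_bin, pred)
  lower <- stats::qpois(a_bin, pred)
  exc <- which(test & counts > upper)
  sup <- which(test & counts < lower)
  flag <- if (length(exc)) "excited" else if (length(sup)) "suppressed"
          else "none"
  smoothed <- conv_same(counts, k)
  lat <- if (flag == "excited") {
    idx <- which(test)
    p$lags[idx[which.max(smoothed[idx])]]
  } else NA_real_
  list(flag = flag, significant_bins = c(exc, sup), predictor = pred,
       upper = upper, lower = lower, latency_to_peak_s = lat)
}

#' Standardized cross-covariance of two spike trains
#'
#' The cross-correlation histogram (CCH) of spike pairs, both spikes
#' restricted to `restriction`, converted to a covariance estimate
#' `CCE = CCH / (b T) - R1 R2` and standardized by `sqrt(b T / (R1 R2))`,
#' where `b` is the bin size, `T` the total restricted observation time
#' and `R1`, `R2` the restricted firing rates. Independent trains give
#' standardized values with mean 0 and SD 1.
#'
#' @param spikesA,spikesB spike time vectors (s); A is the reference.
#' @param binsize bin width `b` (s).
#' @param halfwindow lag half-window (s).
#' @param restriction optional `IntervalSet`; only spikes inside it are
#'   used and `T` is its total duration. `NULL` uses `c(0, T_total)`.
#' @param total_duration session duration (s), required when
#'   `restriction` is `NULL`.
#' @return object of class `CrossCov`: list with `lags`, `cch`, `cce`,
#'   `standardized`, `peak_value`, `peak_lag_s`, `rates`, `T`, `binsize`.
#' @export
standardized_cross_covariance <- function(spikesA, spikesB, binsize = 0.001,
                                          halfwindow = 0.05,
                                          restriction = NULL,
                                          total_duration = NULL) {
  if (is.null(restriction)) {
    if (is.null(total_duration))
      stop("total_duration required without a restriction")
    restriction <- interval_set(0, total_duration, "all")
  }
  Tobs <- interval_duration(restriction)
  if (Tobs <= 0) stop("insufficient data: empty restriction")
  a <- spikesA[in_intervals(spikesA, restriction)]
  b2 <- spikesB[in_intervals(spikesB, restriction)]
  r1 <- length(a) / Tobs; r2 <- length(b2) / Tobs
  if (r1 == 0 || r2 == 0) stop("insufficient data: empty restricted train")
  breaks <- seq(-halfwindow, halfwindow, by = binsize)
  nb <- length(breaks) - 1
  cch <- numeric(nb)
  for (s in a) {
    d <- b2 - s
    d <- d[d >= -halfwindow & d < breaks[nb + 1]]
    if (length(d)) cch <- cch + tabulate(findInterval(d, breaks), nb)
  }
  cce <- cch / (binsize * Tobs) - r1 * r2
  std <- cce * sqrt(binsize * Tobs / (r1 * r2))
  lags <- (breaks[-1] + breaks[-(nb + 1)]) / 2
  ipk <- which.max(std)
  structure(list(lags = lags, cch = cch, cce = cce, standardized = std,
                 peak_value = std[ipk], peak_lag_s = lags[ipk],
                 rates = c(r1, r2), T = Tobs, binsize = binsize),
            class = "CrossCov")
}

#' Opto-tag units by light-pulse responses
#'
#' A unit is `"responsive"` if its PETH around pulse onsets is flagged
#' excited by [peth_significance()] restricted to the within-pulse window.
#'
#' @param sd a `SpikeData`.
#' @param pulses `EventTable` of light pulses (>= 50 required).
#' @param pulse_duration_s pulse length (s, default 0.01).
#' @param alpha significance level.
#' @return data.frame with `unit` and `responsive` (logical).
#' @export
opto_tag_units <- function(sd, pulses, pulse_duration_s = 0.01,
                           alpha = 0.01) {
  if (nrow(pulses) < 50) stop("insufficient data: need >= 50 pulses")
  res <- logical(nrow(sd$units))
  for (i in seq_len(nrow(sd$units))) {
    st <- unit_spikes(sd, sd$units$unit[i])
    if (!length(st)) { res[i] <- FALSE; next }
    ph <- peth(st, pulses, binsize = 0.002, halfwindow = 0.25,
               min_sep = 0, reference = "onset")
    sig <- peth_significance(ph, alpha = alpha,
                             test_window = c(0, pulse_duration_s))
    res[i] <- sig$flag == "excited"
  }
  data.frame(unit = sd$units$unit, responsive = res)
}
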