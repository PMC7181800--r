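#' Configuration for the synthetic two-region session generator
#'
#' Default values follow the in-vivo phenomenology the generator emulates:
#' CA1 sharp-wave ripples at 0.68 events/s with a ~170 Hz carrier and
#' ~26 ms duration, a fraction of events propagating to the granular
#' retrosplenial cortex (gRSC) with a ~5 ms delay as a superficial
#' negative wave plus ripple that reverses polarity in depth, spike trains
#' phase-locked to ripple cycles, and alternation between a synchronized
#' (3-10 Hz activity-packet) state and desynchronized states with low or
#' high EMG contamination.
#'
#' @param duration session length (s).
#' @param fs LFP sampling rate (Hz).
#' @param ca1_ripple_rate CA1 ripple incidence (events/s).
#' @param ripple_freq ripple carrier frequency (Hz), within 140-200.
#' @param ripple_duration_ms ripple envelope duration (ms).
#' @param ripple_snr CA1 ripple peak amplitude in units of broadband noise SD.
#' @param sharp_wave_amp amplitude of the CA1 sharp-wave deflection (noise SD).
#' @param propagation_prob probability a CA1 ripple propagates to gRSC.
#' @param propagation_delay_ms CA1 -> gRSC peak delay (ms).
#' @param grsc_ripple_snr gRSC ripple amplitude on the most superficial
#'   channel (noise SD).
#' @param neg_wave_amp gRSC negative-wave amplitude on the most superficial
#'   channel (noise SD); deep channels carry the polarity-reversed wave.
#' @param n_grsc_channels number of gRSC depth channels (top half labelled
#'   superficial).
#' @param grsc_spacing_um vertical spacing of gRSC channels (micrometers).
#' @param n_units named list of unit counts: `ca1_pyr`, `ca1_int`,
#'   `grsc_sup_pyr`, `grsc_deep_pyr`, `grsc_int`.
#' @param base_rate named list of mean baseline firing rates (Hz) for
#'   `pyr` and `int` units (log-normal spread of 0.4 around these).
#' @param ripple_gain named list: multiplicative rate gain during the
#'   response window for `ca1` and `grsc` units.
#' @param phase_lock_kappa named list of von Mises concentrations for
#'   `ca1_pyr`, `ca1_int`, `grsc` units.
#' @param state_dwell_s mean dwell time (s) of each brain state; states
#'   cycle synchronized -> desync_lowEMG -> desync_highEMG.
#' @param packet_rate activity-packet rate in the synchronized state (Hz,
#'   3-10 band).
#' @param ripple_packet_coupling if `TRUE`, ripples falling in synchronized
#'   epochs are drawn near packet times.
#' @param emg_amplitude amplitude of the common 300-600 Hz contaminant
#'   during high-EMG epochs (noise SD units).
#' @param n_ripple_types number of planted ensemble ripple types (1 = no
#'   type structure).
#' @param type_separation strength of the type-specific CA1 gain contrast
#'   (0 = identical templates).
#' @param grsc_type_coupling strength of type-specific gRSC gain offsets
#'   (0 = gRSC blind to type).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a validated list of class `SynthConfig`.
#' @export
synth_config <- function(duration = 600, fs = 1250,
                         ca1_ripple_rate = 0.68, ripple_freq = 170,
                         ripple_duration_ms = 26, ripple_snr = 8,
                         sharp_wave_amp = 4,
                         propagation_prob = 0.35, propagation_delay_ms = 5,
                         grsc_ripple_snr = 5, neg_wave_amp = 4,
                         n_grsc_channels = 8, grsc_spacing_um = 100,
                         n_units = list(ca1_pyr = 35, ca1_int = 8,
                                        grsc_sup_pyr = 10,
                                        grsc_deep_pyr = 14, grsc_int = 8),
                         base_rate = list(pyr = 2.5, int = 14),
                         ripple_gain = list(ca1 = 5, grsc = 5),
                         phase_lock_kappa = list(ca1_pyr = 2, ca1_int = 1,
                                                 grsc = 1),
                         state_dwell_s = c(synchronized = 40,
                                           desync_lowEMG = 40,
                                           desync_highEMG = 40),
                         packet_rate = 4,
                         ripple_packet_coupling = TRUE,
                         emg_amplitude = 1,
                         n_ripple_types = 1, type_separation = 0,
                         grsc_type_coupling = 0,
                         seed = 1) {
  cfg <- as.list(environment())
  stopifnot(duration > 0, fs > 0, ca1_ripple_rate > 0, ripple_freq > 0,
            ripple_duration_ms > 0, ripple_snr > 0,
            propagation_prob >= 0, propagation_prob <= 1,
            propagation_delay_ms >= 0, packet_rate >= 3, packet_rate <= 10,
            n_ripple_types >= 1, type_separation >= 0,
            all(unlist(n_units) >= 0), all(state_dwell_s > 0))
  class(cfg) <- "SynthConfig"
  cfg
}

#' Plant ensemble ripple-type templates
#'
#' Builds per-type multiplicative gain templates over the CA1 pyramidal
#' population (and, optionally, the gRSC population). Units are assigned
#' round-robin to types; a unit belonging to a type fires with gain
#' `1 + separation` times its usual ripple gain during ripples of that
#' type, so `separation = 0` makes all templates identical.
#'
#' @param n_types number of ripple types (>= 2 for non-trivial structure).
#' @param n_units number of units the template covers.
#' @param separation template contrast (>= 0).
#' @return matrix `n_types x n_units` of gain multipliers.
#' @export
plant_ripple_types <- function(n_types, n_units, separation) {
  stopifnot(n_types >= 1, separation >= 0, n_units >= 1)
  membership <- matrix(0, n_types, n_units)
  assign <- rep_len(seq_len(n_types), n_units)
  for (u in seq_len(n_units)) membership[assign[u], u] <- 1
  1 + separation * membership
}

# piecewise state sequence cycling through the three labels
synth_states <- function(duration, dwell) {
  labels <- names(dwell)
  start <- 0; k <- 0L
  st <- sp <- numeric(); lab <- character()
  while (start < duration) {
    k <- k + 1L
    l <- labels[((k - 1L) %% length(labels)) + 1L]
    d <- stats::rexp(1, 1 / dwell[[l]])
    d <- max(d, 5)                       # epochs long enough to segment
    stop_t <- min(start + d, duration)
    st <- c(st, start); sp <- c(sp, stop_t); lab <- c(lab, l)
    start <- stop_t
  }
  interval_set(st, sp, lab)
}

# packet centre times within synchronized intervals
synth_packets <- function(states, rate) {
  centers <- numeric()
  sync <- states[states$label == "synchronized", , drop = FALSE]
  for (i in seq_len(nrow(sync))) {
    t <- sync$start[i] + 0.1
    while (t < sync$stop[i] - 0.1) {
      centers <- c(centers, t)
      # quasi-periodic: silent troughs must outlast the MUA smoothing
      t <- t + stats::runif(1, 0.9, 1.4) / rate
    }
  }
  centers
}

# multiplicative population gate: near-silent between packets in the
# synchronized state, flat elsewhere
synth_state_gate <- function(tt, states, packets, packet_sd = 0.012) {
  gate <- rep(1, length(tt))
  sync_mask <- in_intervals(tt, states, "synchronized")
  gate[sync_mask] <- 0.02
  amp <- 8
  h <- ceiling(4 * packet_sd * attr(tt, "fs"))
  fs <- attr(tt, "fs")
  for (pc in packets) {
    i0 <- max(1L, floor((pc - 4 * packet_sd) * fs) + 1L)
    i1 <- min(length(tt), ceiling((pc + 4 * packet_sd) * fs) + 1L)
    if (i1 < i0) next
    idx <- i0:i1
    gate[idx] <- gate[idx] + amp * exp(-(tt[idx] - pc)^2 / (2 * packet_sd^2))
  }
  gate
}

# CA1 ripple times: Poisson overall, optionally snapped to packets in
# synchronized epochs; refractory 0.25 s so planted events never merge
synth_ripple_times <- function(cfg, states, packets) {
  n_exp <- stats::rpois(1, cfg$ca1_ripple_rate * (cfg$duration - 2))
  t <- sort(stats::runif(n_exp, 1, cfg$duration - 1))
  if (cfg$ripple_packet_coupling && length(packets)) {
    in_sync <- in_intervals(t, states, "synchronized")
    for (i in which(in_sync)) {
      pc <- packets[which.min(abs(packets - t[i]))]
      t[i] <- pc + stats::rnorm(1, 0, 0.01)
    }
    t <- sort(t)
  }
  t <- t[t > 1 & t < cfg$duration - 1]
  if (length(t) > 1) t <- t[c(TRUE, diff(t) > 0.25)]
  t
}

# dur is the full-width at half maximum of the Hann envelope; the planted
# oscillation spans twice that. Segment builders return (idx, values) so
# callers can accumulate in place without copying whole traces.
burst_seg <- function(n, fs, center, dur, freq, amp) {
  half <- dur
  i0 <- max(1L, floor((center - half) * fs) + 1L)
  i1 <- min(n, ceiling((center + half) * fs) + 1L)
  if (i1 <= i0) return(NULL)
  idx <- i0:i1
  tt <- (idx - 1) / fs
  env <- 0.5 * (1 + cos(pi * pmin(abs(tt - center) / half, 1)))  # Hann
  list(idx = idx, v = amp * env * cos(2 * pi * freq * (tt - center)))
}

gauss_seg <- function(n, fs, center, sd, amp) {
  i0 <- max(1L, floor((center - 4 * sd) * fs) + 1L)
  i1 <- min(n, ceiling((center + 4 * sd) * fs) + 1L)
  if (i1 <= i0) return(NULL)
  idx <- i0:i1
  tt <- (idx - 1) / fs
  list(idx = idx, v = amp * exp(-(tt - center)^2 / (2 * sd^2)))
}

# band-limited common contaminant for the EMG channel-correlation estimate
synth_emg_source <- function(n, fs) {
  e <- bandpass_zero_phase(stats::rnorm(n), fs, 300, min(600, 0.48 * fs),
                           order = 4)
  e / stats::sd(e)
}

# Spike train of one unit: inhomogeneous Poisson baseline (1 ms bins,
# state-gated) plus explicit per-ripple response spikes with von Mises
# phases relative to the planted oscillation (peak = phase 0 convention).
synth_unit_spikes <- function(cfg, base, gate_vec, ripples, gains, mu, kappa,
                              resp_window, osc_delay, osc_amp_ok) {
  dt <- 0.001
  nb <- length(gate_vec)
  tt <- (seq_len(nb) - 0.5) * dt
  lam <- base * gate_vec * dt
  counts <- stats::rpois(nb, lam)
  times <- rep(tt[counts > 0], counts[counts > 0]) +
    stats::runif(sum(counts), -dt / 2, dt / 2)
  dur <- cfg$ripple_duration_ms / 1000
  fr <- cfg$ripple_freq
  n_cyc <- max(1L, floor(dur * fr))
  for (k in seq_along(ripples)) {
    g <- gains[k]
    if (g <= 0) next
    t_peak <- ripples[k] + osc_delay
    # oscillation-locked spikes across the burst
    n_osc <- stats::rpois(1, base * g * dur)
    if (n_osc > 0 && osc_amp_ok) {
      ph <- rvonmises(n_osc, mu, kappa)
      cyc <- sample.int(n_cyc, n_osc, replace = TRUE) -
        floor(n_cyc / 2) - 1L    # integer cycle offsets, centred
      times <- c(times, t_peak + (cyc + ph / (2 * pi)) / fr)
    }
    # elevated tail over the remainder of the response window
    tail_len <- resp_window - dur
    if (tail_len > 0) {
      n_tail <- stats::rpois(1, base * g * tail_len)
      if (n_tail > 0)
        times <- c(times, ripples[k] + osc_delay + dur / 2 +
                     stats::runif(n_tail, 0, tail_len))
    }
  }
  times <- sort(times[times > 0 & times < cfg$duration])
  # impose a refractory period, as spike sorting upstream would
  if (length(times) > 1) times <- times[c(TRUE, diff(times) > 0.0025)]
  times
}

#' Generate a synthetic two-region session with ground truth
#'
#' Produces a CA1 recording (one channel: pink-noise background, planted
#' Hann-enveloped ripple bursts riding on negative sharp waves), a
#' multichannel gRSC recording (delayed negative waves with depth polarity
#' reversal; ripple bursts confined to superficial channels), spike trains
#' for both regions (inhomogeneous Poisson with ripple-gain and von Mises
#' phase modulation, gated by packet structure in the synchronized state),
#' and a `GroundTruth` list of everything planted.
#'
#' @param cfg a [synth_config()] object.
#' @param lfp generate the LFP traces (default `TRUE`); `FALSE` returns
#'   `NULL` recordings, for spike-only analyses. Spike and ground-truth
#'   streams are seeded independently of the LFP stream, so they are
#'   identical either way.
#' @return list with elements `ca1` (`Recording`), `grsc` (`Recording`),
#'   `spikes` (`SpikeData`), `truth` (list: `ripples`, `grsc_ripples`,
#'   `packets` as `EventTable`s; `states` as `IntervalSet`; `type_labels`,
#'   `propagated`, `templates`, `grsc_templates`; `units` data.frame with
#'   per-unit true preferred phase `mu`, concentration `kappa` and
#'   baseline rate).
#' @export
generate_session <- function(cfg, lfp = TRUE) {
  stopifnot(inherits(cfg, "SynthConfig"))
  fs <- cfg$fs; n <- floor(cfg$duration * fs)

  set.seed(sub_seed(cfg$seed, 1))
  states <- synth_states(cfg$duration, cfg$state_dwell_s)
  packets <- synth_packets(states, cfg$packet_rate)

  set.seed(sub_seed(cfg$seed, 2))
  ripples <- synth_ripple_times(cfg, states, packets)
  n_rip <- length(ripples)
  propagated <- stats::runif(n_rip) < cfg$propagation_prob
  delay <- cfg$propagation_delay_ms / 1000
  dur <- cfg$ripple_duration_ms / 1000

  type_labels <- sample.int(cfg$n_ripple_types, n_rip, replace = TRUE)
  templates <- plant_ripple_types(cfg$n_ripple_types, cfg$n_units$ca1_pyr,
                                  cfg$type_separation)
  n_grsc_units <- cfg$n_units$grsc_sup_pyr + cfg$n_units$grsc_deep_pyr +
    cfg$n_units$grsc_int
  grsc_templates <- plant_ripple_types(cfg$n_ripple_types,
                                       max(n_grsc_units, 1),
                                       cfg$grsc_type_coupling)

  # ---- LFP ---------------------------------------------------------------
  ca1_rec <- grsc_rec <- NULL
  ng <- cfg$n_grsc_channels
  n_sup <- ceiling(ng / 2)
  if (lfp) {
  set.seed(sub_seed(cfg$seed, 3))
  ca1 <- pink_noise(n, fs)
  for (k in seq_len(n_rip)) {
    b <- burst_seg(n, fs, ripples[k], dur, cfg$ripple_freq, cfg$ripple_snr)
    if (!is.null(b)) ca1[b$idx] <- ca1[b$idx] + b$v
    g <- gauss_seg(n, fs, ripples[k], 0.015, -cfg$sharp_wave_amp)
    if (!is.null(g)) ca1[g$idx] <- ca1[g$idx] + g$v
  }

  set.seed(sub_seed(cfg$seed, 4))
  depth <- seq_len(ng) * cfg$grsc_spacing_um
  # superficial negative wave, polarity-reversed and weaker in depth
  wave_prof <- c(seq(1, 0.4, length.out = n_sup),
                 seq(-0.2, -0.6, length.out = ng - n_sup))
  rip_prof <- c(seq(1, 0.3, length.out = n_sup), rep(0, ng - n_sup))
  grsc <- matrix(0, ng, n)
  for (ch in seq_len(ng)) grsc[ch, ] <- pink_noise(n, fs)
  for (k in which(propagated)) {
    tk <- ripples[k] + delay
    g <- gauss_seg(n, fs, tk, 0.015, -cfg$neg_wave_amp)
    b <- burst_seg(n, fs, tk, dur, cfg$ripple_freq, cfg$grsc_ripple_snr)
    for (ch in seq_len(ng)) {
      if (!is.null(g))
        grsc[ch, g$idx] <- grsc[ch, g$idx] + wave_prof[ch] * g$v
      if (!is.null(b) && rip_prof[ch] > 0)
        grsc[ch, b$idx] <- grsc[ch, b$idx] + rip_prof[ch] * b$v
    }
  }

  # common high-frequency contaminant, strong only in high-EMG epochs
  set.seed(sub_seed(cfg$seed, 5))
  emg <- synth_emg_source(n, fs)
  tt_lfp <- (seq_len(n) - 1) / fs
  emg_gate <- ifelse(in_intervals(tt_lfp, states, "desync_highEMG"), 1, 0.05)
  emg <- emg * emg_gate * cfg$emg_amplitude
  ca1 <- ca1 + emg
  for (ch in seq_len(ng)) grsc[ch, ] <- grsc[ch, ] + emg

  ca1_rec <- recording(matrix(ca1, 1), fs,
                       data.frame(id = 1L, shank = 1L, depth_um = 0,
                                  region = "CA1"))
  grsc_rec <- recording(grsc, fs,
                        data.frame(id = seq_len(ng) + 1L, shank = 1L,
                                   depth_um = depth,
                                   region = ifelse(seq_len(ng) <= n_sup,
                                                   "gRSC_sup", "gRSC_deep")))
  }

  # ---- units -------------------------------------------------------------
  set.seed(sub_seed(cfg$seed, 6))
  nu <- cfg$n_units
  groups <- c(rep("ca1_pyr", nu$ca1_pyr), rep("ca1_int", nu$ca1_int),
              rep("grsc_sup_pyr", nu$grsc_sup_pyr),
              rep("grsc_deep_pyr", nu$grsc_deep_pyr),
              rep("grsc_int", nu$grsc_int))
  n_units_total <- length(groups)
  is_int <- grepl("int", groups)
  is_ca1 <- grepl("ca1", groups)
  base <- exp(stats::rnorm(n_units_total,
                           log(ifelse(is_int, cfg$base_rate$int,
                                      cfg$base_rate$pyr)), 0.4))
  mu_ph <- stats::runif(n_units_total, -pi, pi)
  kappa <- ifelse(groups == "ca1_pyr", cfg$phase_lock_kappa$ca1_pyr,
           ifelse(groups == "ca1_int", cfg$phase_lock_kappa$ca1_int,
                  cfg$phase_lock_kappa$grsc))
  width <- ifelse(is_int, stats::rnorm(n_units_total, 0.30, 0.04),
                  stats::rnorm(n_units_total, 0.85, 0.10))
  asym <- ifelse(is_int, stats::rnorm(n_units_total, 0.05, 0.1),
                 stats::rnorm(n_units_total, 0.45, 0.1))
  units <- data.frame(
    unit = seq_len(n_units_total), group = groups,
    region = ifelse(is_ca1, "CA1",
                    ifelse(groups == "grsc_deep_pyr", "gRSC_deep",
                           "gRSC_sup")),
    layer = ifelse(groups == "grsc_sup_pyr", "superficial",
            ifelse(groups == "grsc_deep_pyr", "deep", "unknown")),
    rate = NA_real_, width_ms = pmax(width, 0.1), asymmetry = asym,
    type = ifelse(is_int, "interneuron", "pyramidal"),
    mu = mu_ph, kappa = kappa, base_rate = base)

  tt_spk <- (seq_len(floor(cfg$duration / 0.001)) - 0.5) * 0.001
  attr(tt_spk, "fs") <- 1000
  gate_vec <- synth_state_gate(tt_spk, states, packets)

  ca1_pyr_idx <- which(groups == "ca1_pyr")
  grsc_idx <- which(!is_ca1)
  sp_list <- vector("list", n_units_total)
  for (u in seq_len(n_units_total)) {
    set.seed(sub_seed(cfg$seed, 100 + u))
    if (is_ca1[u]) {
      tmpl_col <- match(u, ca1_pyr_idx)
      mult <- if (!is.na(tmpl_col)) templates[type_labels, tmpl_col]
              else rep(1, n_rip)
      gains <- cfg$ripple_gain$ca1 * mult
      sp_list[[u]] <- synth_unit_spikes(cfg, base[u], gate_vec, ripples,
                                        gains, mu_ph[u], kappa[u],
                                        resp_window = 0.1, osc_delay = 0,
                                        osc_amp_ok = TRUE)
    } else {
      gcol <- match(u, grsc_idx)
      mult <- grsc_templates[type_labels, gcol]
      gains <- cfg$ripple_gain$grsc * mult * as.numeric(propagated)
      sup <- units$layer[u] == "superficial"
      sp_list[[u]] <- synth_unit_spikes(cfg, base[u], gate_vec, ripples,
                                        gains, mu_ph[u], kappa[u],
                                        resp_window = 0.2,
                                        osc_delay = delay,
                                        osc_amp_ok = sup)
    }
  }
  spikes <- data.frame(
    time = unlist(sp_list),
    unit = rep(seq_len(n_units_total), lengths(sp_list)))
  sd_obj <- spike_data(spikes, units, duration = cfg$duration)
  units$rate <- sd_obj$units$rate[match(units$unit, sd_obj$units$unit)]

  truth <- list(
    ripples = event_table(onset = ripples - dur / 2, peak = ripples,
                          offset = ripples + dur / 2,
                          amplitude = cfg$ripple_snr, channel = 1L,
                          kind = "ripple"),
    grsc_ripples = event_table(onset = ripples[propagated] + delay - dur / 2,
                               peak = ripples[propagated] + delay,
                               offset = ripples[propagated] + delay + dur / 2,
                               amplitude = cfg$grsc_ripple_snr, channel = 2L,
                               kind = "ripple"),
    packets = event_table(onset = packets - 0.04, peak = packets,
                          offset = packets + 0.04, kind = "packet"),
    states = states,
    type_labels = type_labels, propagated = propagated,
    templates = templates, grsc_templates = grsc_templates,
    units = units)
  list(ca1 = ca1_rec, grsc = grsc_rec, spikes = sd_obj, truth = truth)
}
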