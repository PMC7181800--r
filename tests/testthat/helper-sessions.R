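# Shared synthetic sessions, generated once per test run.

.session_cache <- new.env(parent = emptyenv())

cached_session <- function(key, cfg, lfp = TRUE) {
  if (is.null(.session_cache[[key]]))
    assign(key, generate_session(cfg, lfp = lfp), envir = .session_cache)
  get(key, envir = .session_cache)
}

# standard mid-length session used by several files
std_session <- function() {
  cached_session("std300", synth_config(duration = 300, seed = 42))
}

# label of the interval covering each time point (NA outside)
label_at_times <- function(iv, tt) {
  lab <- rep(NA_character_, length(tt))
  for (i in seq_len(nrow(iv)))
    lab[tt >= iv$start[i] & tt < iv$stop[i]] <- iv$label[i]
  lab
}

# SpikeData restricted to one region set
region_spikes <- function(sd, regions, duration) {
  u <- sd$units[sd$units$region %in% regions, , drop = FALSE]
  spike_data(sd$spikes[sd$spikes$unit %in% u$unit, , drop = FALSE], u,
             duration = duration)
}

f1_score <- function(truth, detected, tol) {
  m <- match_events(truth, detected, tol)
  prec <- m$n_matched / max(length(detected), 1)
  rec <- m$sensitivity
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}
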