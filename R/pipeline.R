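#' Pipeline configuration
#'
#' Bundles the synthetic-session configuration (or input file paths), the
#' per-stage parameters (all defaulting to the standard values used
#' throughout the package) and the set of enabled stages. Round-trips
#' losslessly through YAML.
#'
#' @param synth a [synth_config()] list, or `NULL` when reading data from
#'   files.
#' @param input optional list of file paths (`ca1_dat`, `grsc_dat`,
#'   `channel_map`, `spikes`, `units`, `n_channels`, `fs`).
#' @param stages character vector of enabled stages, a subset of
#'   `c("detect", "spectral", "laminar", "units", "state", "typing")`.
#' @param ripple a [ripple_params()] list.
#' @param typing list of typing parameters (`k`, `window`, `n_perm`).
#' @param seed master seed.
#' @param out_dir output directory.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            input = NULL,
                            stages = c("detect", "spectral", "laminar",
                                       "units", "state", "typing"),
                            ripple = ripple_params(),
                            typing = list(k = 10, window = 0.1,
                                          n_perm = 200),
                            seed = 1, out_dir = tempfile("swrpipe_run_")) {
  cfg <- list(synth = synth, input = input, stages = stages,
              ripple = ripple, typing = typing, seed = seed,
              out_dir = out_dir)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param cfg a `PipelineConfig`.
#' @param path YAML file path.
#' @return `read_pipeline_config`: a `PipelineConfig`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(rapply(unclass(cfg), unclass, how = "replace"), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(seed = raw$seed)
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  if (!is.null(cfg$synth)) {
    cfg$synth <- do.call(synth_config, cfg$synth[names(cfg$synth) %in%
                                                   names(formals(synth_config))])
  }
  class(cfg$ripple) <- "RippleParams"
  class(cfg) <- "PipelineConfig"
  cfg
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic session
#' (or files named in the config): ripple/negative-wave detection, then
#' spectral and laminar analyses, unit and state statistics, and ripple
#' typing. Writes TSV outputs, a log and a manifest (parameters, seed,
#' package version) to `cfg$out_dir`. The run is a pure function of
#' (inputs, config, seed).
#'
#' @param cfg a [pipeline_config()].
#' @return invisible list of in-memory stage results (also written to
#'   disk).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "pipeline.log")
  log_line <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                                "\n", file = logf, append = TRUE, sep = "")
  res <- list()

  # ---- inputs ------------------------------------------------------------
  if (!is.null(cfg$input)) {
    ca1 <- read_binary_recording(cfg$input$ca1_dat, 1, cfg$input$fs)
    cm <- utils::read.delim(cfg$input$channel_map)
    grsc <- read_binary_recording(cfg$input$grsc_dat, nrow(cm),
                                  cfg$input$fs, channel_map = cm)
    spikes <- read_spikes(cfg$input$spikes, cfg$input$units)
    truth <- NULL
    duration <- ncol(ca1$samples) / ca1$fs
    log_line("loaded recordings from files")
  } else {
    sess <- generate_session(cfg$synth)
    ca1 <- sess$ca1; grsc <- sess$grsc; spikes <- sess$spikes
    truth <- sess$truth
    duration <- cfg$synth$duration
    log_line("generated synthetic session, seed ", cfg$synth$seed)
  }
  res$duration <- duration
  fs <- ca1$fs
  enabled <- function(s) s %in% cfg$stages
  skip <- function(s) log_line("stage ", s, " disabled; skipping it and dependents")

  # ---- detection ---------------------------------------------------------
  ripples <- NULL
  if (enabled("detect")) {
    ripples <- detect_ripples(ca1$samples[1, ], fs, cfg$ripple, channel = 1)
    write_events(ripples, file.path(cfg$out_dir, "ripples_ca1.tsv"))
    sup_ch <- which(grsc$channels$region == "gRSC_sup")[1]
    tmpl <- negative_wave_template(grsc$samples[sup_ch, ], fs)
    nw <- detect_negative_waves(grsc$samples[sup_ch, ], fs, tmpl,
                                channel = grsc$channels$id[sup_ch])
    write_events(nw, file.path(cfg$out_dir, "negative_waves_grsc.tsv"))
    res$ripples <- ripples; res$negative_waves <- nw
    res$session_usable <- nrow(ripples) >= cfg$ripple$min_events_for_session
    log_line("detected ", nrow(ripples), " CA1 ripples, ", nrow(nw),
             " gRSC negative waves")
  } else skip("detect")

  dependent <- function(s) {
    if (!enabled(s)) { skip(s); return(FALSE) }
    if (is.null(ripples)) {
      log_line("stage ", s, " skipped: requires the detect stage")
      return(FALSE)
    }
    TRUE
  }

  # ---- spectral ----------------------------------------------------------
  if (dependent("spectral") && nrow(ripples) >= 3) {
    sup_ch <- which(grsc$channels$region == "gRSC_sup")[1]
    pa <- ripple_band_power(ca1$samples[1, ], fs)
    pb <- ripple_band_power(grsc$samples[sup_ch, ], fs)
    coup <- ripple_power_coupling(ripples, pa, pb, fs)
    lag <- peak_power_lags(ripples, sqrt(pb), fs)
    res$power_coupling <- coup[c("slope", "rho")]
    res$propagation_lag <- lag[c("median_ms", "sem_ms")]
    write_tsv(data.frame(slope = coup$slope, rho = coup$rho,
                         median_lag_ms = lag$median_ms,
                         sem_lag_ms = lag$sem_ms),
              file.path(cfg$out_dir, "coupling_summary.tsv"))
    log_line(sprintf("power coupling slope %.3f rho %.3f; lag %.2f ms",
                     coup$slope, coup$rho, lag$median_ms))
  }

  # ---- laminar -----------------------------------------------------------
  if (dependent("laminar") && nrow(ripples) >= 3) {
    w_idx <- round(-0.1 * fs):round(0.1 * fs)
    i_pk <- round(ripples$peak * fs) + 1L
    i_pk <- i_pk[i_pk + w_idx[1] >= 1 &
                 i_pk + w_idx[length(w_idx)] <= ncol(grsc$samples)]
    avg <- matrix(0, nrow(grsc$samples), length(w_idx))
    for (i in i_pk) avg <- avg + grsc$samples[, i + w_idx]
    avg <- avg / length(i_pk)
    csd <- inverse_csd(avg, spacing = diff(grsc$channels$depth_um[1:2]))
    m <- cbind(depth_um = csd$depths_um, csd$values)
    write_tsv(as.data.frame(m), file.path(cfg$out_dir, "csd_ripple_avg.tsv"))
    ica <- ica_event_loadings(grsc$samples, fs, ripples)
    write_tsv(data.frame(channel = grsc$channels$id,
                         loading = ica$loadings),
              file.path(cfg$out_dir, "ica_loadings.tsv"))
    res$csd <- csd; res$ica <- ica
    log_line(sprintf("laminar stage done; ICA depth p = %.3g", ica$p_depth))
  }

  # ---- units -------------------------------------------------------------
  if (dependent("units")) {
    qc <- qc_filter_units(spikes, duration)
    qc$units$type_kmeans <- classify_cell_types(qc$units, seed = cfg$seed)
    peths <- lapply(qc$units$unit, function(u) {
      p <- peth(unit_spikes(qc, u), ripples)
      s <- peth_significance(p)
      data.frame(unit = u, flag = s$flag,
                 latency_s = s$latency_to_peak_s)
    })
    peth_tab <- do.call(rbind, peths)
    write_tsv(peth_tab, file.path(cfg$out_dir, "unit_modulation.tsv"))
    res$units_qc <- qc; res$unit_modulation <- peth_tab
    log_line(sum(peth_tab$flag == "excited"), " / ", nrow(peth_tab),
             " units excited around ripples")
  } else qc <- NULL

  # ---- state -------------------------------------------------------------
  if (enabled("state") && nrow(spikes$units) >= 16) {
    mua <- smoothed_mua(spikes, duration)
    packets <- detect_packets(mua)
    si <- state_index(mua, step_s = 0.05)
    emg <- emg_from_lfp(grsc)
    states <- segment_states(si, emg)
    write_events(packets, file.path(cfg$out_dir, "packets.tsv"))
    write_tsv(as.data.frame(states), file.path(cfg$out_dir, "states.tsv"))
    res$packets <- packets; res$states <- states
    log_line(nrow(packets), " packets; states: ",
             paste(unique(states$label), collapse = ", "))
  } else if (!enabled("state")) skip("state")

  # ---- typing ------------------------------------------------------------
  if (dependent("typing") && nrow(ripples) >= cfg$typing$k) {
    ca1_units <- spikes$units[spikes$units$region == "CA1", , drop = FALSE]
    ca1_sd <- spike_data(
      spikes$spikes[spikes$spikes$unit %in% ca1_units$unit, , drop = FALSE],
      ca1_units, duration = duration)
    M <- ripple_rate_vectors(ca1_sd, ripples$onset,
                             window = cfg$typing$window)
    cl <- cluster_ripples(M, k = cfg$typing$k, seed = cfg$seed)
    write_tsv(data.frame(onset_s = ripples$onset, label = cl$labels),
              file.path(cfg$out_dir, "ripple_types.tsv"))
    write_tsv(as.data.frame(cl$similarity),
              file.path(cfg$out_dir, "ripple_similarity.tsv"))
    res$typing <- cl
    log_line("typed ripples into ", cfg$typing$k, " clusters")
  }

  # ---- manifest ----------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("swrpipe")),
    seed = cfg$seed,
    stages = cfg$stages,
    parameters = list(ripple = unclass(cfg$ripple),
                      typing = cfg$typing,
                      synth = if (!is.null(cfg$synth)) unclass(cfg$synth)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  log_line("pipeline complete")
  invisible(res)
}
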