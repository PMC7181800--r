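# Ensemble-content typing of ripples and downstream discrimination tests.

# per-event spike counts of one unit in [ref + w1, ref + w2)
window_counts <- function(spikes, refs, w1, w2) {
  vapply(refs, function(r) sum(spikes >= r + w1 & spikes < r + w2),
         numeric(1))
}

#' Ripple ensemble rate-vector matrix
#'
#' Per-ripple, per-unit firing rates in a single window after ripple
#' onset (default 100 ms), normalized per unit across ripples.
#' Fast-spiking interneurons are excluded.
#'
#' @param sd `SpikeData` for the source region (CA1).
#' @param onsets ripple onset times (s).
#' @param window window length after onset (s, default 0.1).
#' @param exclude_fs exclude units typed `"interneuron"` (default `TRUE`).
#' @param normalize `"zscore"` (per-unit z-score across ripples; constant
#'   columns become 0) or `"minmax"`.
#' @return ripples x units numeric matrix with unit ids as column names.
#' @export
ripple_rate_vectors <- function(sd, onsets, window = 0.1,
                                exclude_fs = TRUE, normalize = "zscore") {
  units <- sd$units
  if (exclude_fs) units <- units[units$type != "interneuron", , drop = FALSE]
  if (!nrow(units)) stop("no eligible units")
  M <- vapply(units$unit, function(u)
    window_counts(unit_spikes(sd, u), onsets, 0, window),
    numeric(length(onsets)))
  M <- matrix(M, nrow = length(onsets))
  colnames(M) <- units$unit
  if (normalize == "zscore") {
    mu <- colMeans(M)
    sdv <- apply(M, 2, stats::sd)
    sdv[sdv == 0] <- Inf                  # constant columns -> 0
    M <- sweep(sweep(M, 2, mu), 2, sdv, "/")
  } else if (normalize == "minmax") {
    rng <- apply(M, 2, function(x) diff(range(x)))
    rng[rng == 0] <- Inf
    M <- sweep(sweep(M, 2, apply(M, 2, min)), 2, rng, "/")
  } else stop("unknown normalization: ", normalize)
  M
}

#' Cluster ripples by ensemble content
#'
#' k-means (squared Euclidean distance, k-means++-style seeding via
#' multiple restarts with a fixed seed) on the rate-vector matrix, plus
#' the label-sorted Pearson similarity matrix of ripple pairs.
#'
#' @param M ripples x units rate-vector matrix.
#' @param k number of clusters (default 10).
#' @param seed RNG seed for the restarts.
#' @param nstart number of k-means restarts.
#' @return list with `labels` (1..k per ripple), `similarity`
#'   (label-sorted correlation matrix), `order` (ripple order used),
#'   `kmeans` (the stats::kmeans fit).
#' @export
cluster_ripples <- function(M, k = 10, seed = 1, nstart = 25) {
  if (nrow(M) < k) stop("fewer ripples than clusters")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_distinct <- nrow(unique(M))
  if (n_distinct < k) {
    warning("only ", n_distinct, " distinct rate vectors; k reduced")
    k <- n_distinct
  }
  km <- stats::kmeans(M, centers = k, nstart = nstart, iter.max = 100)
  ord <- order(km$cluster)
  Mt <- t(M[ord, , drop = FALSE])
  sdv <- apply(Mt, 2, stats::sd)
  sim <- suppressWarnings(stats::cor(Mt))
  sim[sdv == 0, ] <- 0; sim[, sdv == 0] <- 0
  diag(sim) <- 1
  list(labels = km$cluster, similarity = sim, order = ord, kmeans = km)
}

# ---------------------------------------------------------------------------
# ANCOVA: OLS with group dummies + continuous covariate, F-test on the
# group block. Vectorized over response columns (shared design).

ancova_group_f <- function(Y, group, covariate = NULL) {
  Y <- as.matrix(Y)
  g <- factor(group)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  X_red <- cbind(1, covariate)
  X_full <- cbind(stats::model.matrix(~g), covariate)
  qr_f <- qr(X_full); qr_r <- qr(X_red)
  rss_f <- colSums(qr.resid(qr_f, Y)^2)
  rss_r <- colSums(qr.resid(qr_r, Y)^2)
  df1 <- qr_f$rank - qr_r$rank
  df2 <- nrow(Y) - qr_f$rank
  Fstat <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  list(F = Fstat, p = p, df1 = df1, df2 = df2)
}

#' Per-unit ANCOVA discrimination of ripple type
#'
#' For each downstream (gRSC) unit and peri-ripple lag bin, an ANCOVA of
#' spike counts on the CA1 ripple-cluster label, with the CA1 population
#' firing rate in the same bin as a continuous covariate (controlling for
#' overall population-burst size). A unit discriminates ripple type when
#' any post-onset bin has a group main effect `p < alpha`. A label-shuffle
#' F-ratio null is available via `n_shuffle`.
#'
#' @param sd_target `SpikeData` of the downstream region.
#' @param onsets ripple onset times (s).
#' @param labels ripple cluster labels (length of `onsets`).
#' @param ca1_spikes pooled CA1 spike times (s) for the covariate.
#' @param binsize bin width (s, default 0.01).
#' @param halfwindow lag half-window (s, default 0.1).
#' @param alpha per-bin significance threshold (default 0.01).
#' @param n_shuffle number of label shuffles for the F null (0 = skip).
#' @param min_per_label drop labels with fewer ripples than this.
#' @return list with `table` (per unit: min post-onset p, its lag and F,
#'   `discriminates`), `fraction` of discriminating units, `p` and `F`
#'   (unit x bin matrices), `lags`, and `shuffle_f` (shuffles x units
#'   matrix of max post-onset F) when requested.
#' @export
unit_discrimination_ancova <- function(sd_target, onsets, labels,
                                       ca1_spikes, binsize = 0.01,
                                       halfwindow = 0.1, alpha = 0.01,
                                       n_shuffle = 0, min_per_label = 5) {
  keep_lab <- names(which(table(labels) >= min_per_label))
  sel <- labels %in% keep_lab
  onsets <- onsets[sel]; labels <- labels[sel]
  if (length(unique(labels)) < 2)
    stop("need >= 2 labels with enough ripples")
  edges <- seq(-halfwindow, halfwindow, by = binsize)
  nb <- length(edges) - 1
  lags <- (edges[-1] + edges[-(nb + 1)]) / 2
  units <- sd_target$units$unit
  # counts: ripple x bin per unit, and CA1 covariate per ripple x bin
  count_mat <- function(spk) {
    t(vapply(onsets, function(r) {
      d <- spk - r
      d <- d[d >= -halfwindow & d < edges[nb + 1]]
      tabulate(findInterval(d, edges), nb)
    }, numeric(nb)))
  }
  cov_mat <- count_mat(ca1_spikes)
  unit_counts <- lapply(units, function(u) count_mat(unit_spikes(sd_target, u)))
  g <- factor(labels)
  pmat <- fmat <- matrix(NA_real_, length(units), nb)
  for (b in seq_len(nb)) {
    Y <- vapply(unit_counts, function(cm) cm[, b], numeric(length(onsets)))
    Y <- matrix(Y, nrow = length(onsets))
    xc <- cov_mat[, b]
    if (stats::var(xc) == 0) {
      warning("constant covariate in bin ", b, "; dropped")
      xc <- NULL
    }
    res <- ancova_group_f(Y, g, xc)
    pmat[, b] <- res$p
    fmat[, b] <- res$F
  }
  post <- lags > 0
  disc <- apply(pmat[, post, drop = FALSE] < alpha, 1, any)
  best <- apply(pmat[, post, drop = FALSE], 1, which.min)
  tab <- data.frame(unit = units,
                    min_p = apply(pmat[, post, drop = FALSE], 1, min),
                    best_lag_s = lags[post][best],
                    F_at_best = fmat[, post, drop = FALSE][
                      cbind(seq_along(units), best)],
                    discriminates = disc)
  out <- list(table = tab, fraction = mean(disc), p = pmat, F = fmat,
              lags = lags)
  if (n_shuffle > 0) {
    sh <- matrix(NA_real_, n_shuffle, length(units))
    for (s in seq_len(n_shuffle)) {
      gs <- sample(g)
      fs_max <- rep(-Inf, length(units))
      for (b in which(post)) {
        Y <- vapply(unit_counts, function(cm) cm[, b],
                    numeric(length(onsets)))
        Y <- matrix(Y, nrow = length(onsets))
        xc <- cov_mat[, b]
        if (stats::var(xc) == 0) xc <- NULL
        fs_max <- pmax(fs_max, ancova_group_f(Y, gs, xc)$F)
      }
      sh[s, ] <- fs_max
    }
    out$shuffle_f <- sh
  }
  out
}

#' Fisher's method for combining p-values
#'
#' `-2 sum(log p) ~ chi-squared with 2n degrees of freedom` under the
#' null; the identity for a single p-value.
#'
#' @param p vector of independent p-values.
#' @return combined p-value.
#' @export
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  if (length(p) == 1) return(p)
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' LFP discrimination of ripple type in one session
#'
#' Wavelet amplitude of the downstream LFP at log-spaced frequency bands,
#' z-scored per ripple over the whole observation window, averaged into
#' lag bins; per (band, lag) an ANCOVA of amplitude on ripple label with
#' the CA1 population rate (spike count in the window) as covariate.
#'
#' @param trace downstream LFP.
#' @param fs sampling rate (Hz).
#' @param onsets ripple onset times (s).
#' @param labels ripple cluster labels.
#' @param ca1_spikes pooled CA1 spike times (covariate).
#' @param freqs analysis bands (Hz; default 80 log-spaced 5-300).
#' @param window observation window (s, default +/- 0.5).
#' @param lag_binsize lag bin width (s).
#' @param t0 time of the first sample (s).
#' @return list with `p` (band x lag), `F`, `freqs`, `lags`.
#' @export
lfp_discrimination_session <- function(trace, fs, onsets, labels,
                                       ca1_spikes,
                                       freqs = exp(seq(log(5), log(300),
                                                       length.out = 80)),
                                       window = c(-0.5, 0.5),
                                       lag_binsize = 0.025, t0 = 0) {
  freqs <- freqs[freqs < fs / 2]
  spec <- morlet_spectrogram(trace, fs, freqs, t0 = t0)
  amp <- Mod(spec$values)
  w_idx <- round(window[1] * fs):round(window[2] * fs)
  i_ref <- round((onsets - t0) * fs) + 1L
  ok <- i_ref + w_idx[1] >= 1 & i_ref + w_idx[length(w_idx)] <= ncol(amp)
  i_ref <- i_ref[ok]; labels <- labels[ok]; onsets <- onsets[ok]
  if (length(i_ref) < 10) stop("insufficient data: too few usable ripples")
  bin_per_lag <- round(lag_binsize * fs)
  nlag <- floor(length(w_idx) / bin_per_lag)
  w_idx <- w_idx[seq_len(nlag * bin_per_lag)]
  lag_id <- rep(seq_len(nlag), each = bin_per_lag)
  lags <- (tapply(w_idx / fs, lag_id, mean))
  nf <- length(freqs)
  # per-ripple z-scored, lag-binned amplitude: array ripple x band x lag
  A <- array(0, c(length(i_ref), nf, nlag))
  for (k in seq_along(i_ref)) {
    seg <- amp[, i_ref[k] + w_idx, drop = FALSE]
    mu <- rowMeans(seg); sdv <- apply(seg, 1, stats::sd)
    sdv[sdv == 0] <- Inf
    segz <- (seg - mu) / sdv
    A[k, , ] <- t(rowsum(t(segz), lag_id) / tabulate(lag_id, nlag))
  }
  covariate <- window_counts(ca1_spikes, onsets, window[1], window[2])
  g <- factor(labels)
  if (stats::var(covariate) == 0) covariate <- NULL
  pm <- fm <- matrix(NA_real_, nf, nlag)
  for (l in seq_len(nlag)) {
    res <- ancova_group_f(A[, , l], g, covariate)
    pm[, l] <- res$p; fm[, l] <- res$F
  }
  list(p = pm, F = fm, freqs = freqs, lags = as.numeric(lags))
}

#' Combine per-session LFP discrimination maps across subjects
#'
#' Per (band, lag) cell, session p-values are combined with Fisher's
#' method; cells with combined `p >= alpha` are masked out.
#'
#' @param session_maps list of [lfp_discrimination_session()] results
#'   with identical axes.
#' @param alpha Bonferroni-style significance threshold (default 0.0004).
#' @return list with `p_combined`, `significant` (logical matrix),
#'   `freqs`, `lags`.
#' @export
lfp_discrimination <- function(session_maps, alpha = 0.0004) {
  stopifnot(length(session_maps) >= 1)
  dims <- dim(session_maps[[1]]$p)
  pc <- matrix(NA_real_, dims[1], dims[2])
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    pc[i, j] <- fisher_combine(vapply(session_maps,
                                      function(m) m$p[i, j], numeric(1)))
  list(p_combined = pc, significant = pc < alpha,
       freqs = session_maps[[1]]$freqs, lags = session_maps[[1]]$lags)
}
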