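test_that("Morlet spectrogram localizes a sinusoid and is linear", {
  fs <- 1250
  t <- seq(1 / fs, 8, by = 1 / fs)
  x <- sin(2 * pi * 150 * t)
  freqs <- seq(60, 300, by = 10)
  sp <- morlet_spectrogram(x, fs, freqs)
  pw <- rowMeans(Mod(sp$values[, 2000:8000])^2)
  expect_equal(freqs[which.max(pw)], 150)
  far <- abs(freqs - 150) > 30
  expect_gt(max(pw), 10 * max(pw[far]))
  # unit-amplitude sine -> unit magnitude at its own bin
  expect_equal(max(pw), 1, tolerance = 0.02)
  # zero signal, zero power; amplitude doubling quadruples power
  expect_equal(sum(Mod(morlet_spectrogram(rep(0, 1000), fs,
                                          freqs)$values)^2), 0)
  sp2 <- morlet_spectrogram(2 * x, fs, freqs)
  expect_equal(Mod(sp2$values)^2, 4 * Mod(sp$values)^2, tolerance = 1e-8)
  expect_error(morlet_spectrogram(x, fs, c(100, 700)), "fs/2")
})

test_that("event-triggered spectrograms z-score against baseline", {
  fs <- 1250
  set.seed(21)
  x <- pink_noise(120 * fs, fs)
  freqs <- seq(100, 250, by = 25)
  sp <- morlet_spectrogram(x, fs, freqs)
  ev <- event_table(onset = seq(5, 115, by = 1), kind = "r")
  # stationary noise: |z| stays small nearly everywhere
  z <- event_triggered_spectrogram(sp, ev, window = c(-0.1, 0.2),
                                   baseline = c(-0.5, -0.15))
  expect_gt(mean(abs(z$values) < 3), 0.99)
  # single event equals that event's own z-map
  z1 <- event_triggered_spectrogram(sp, ev[1, ], window = c(-0.1, 0.2),
                                    baseline = c(-0.5, -0.15))
  expect_equal(z1$n_events, 1)
  expect_error(event_triggered_spectrogram(sp, ev, baseline = c(-0.2, 0)),
               "baseline")
  # planted ripples: strongest z at the ripple band after onset
  s <- std_session()
  spr <- morlet_spectrogram(s$ca1$samples[1, ], s$ca1$fs, freqs)
  zr <- event_triggered_spectrogram(spr, s$truth$ripples,
                                    reference = "peak",
                                    window = c(-0.05, 0.05),
                                    baseline = c(-0.5, -0.15))
  ridge <- apply(zr$values, 1, max)
  expect_equal(zr$freqs[which.max(ridge)], 175)
})

test_that("phase coherograms are high for shared signals, near-null floor otherwise", {
  fs <- 1250
  set.seed(22)
  n <- 40 * fs
  x <- bandpass_zero_phase(rnorm(n), fs, 80, 300) +
    0.01 * rnorm(n)
  ev <- event_table(onset = seq(2, 38, by = 0.4), kind = "r")
  # identical traces: coherence 1 everywhere
  co <- phase_coherogram(x, x, fs, ev, freqs = c(100, 150, 200),
                         window = c(-0.02, 0.02))
  expect_true(all(co$values > 0.999))
  # independent traces: near the resultant-length null ~ sqrt(pi / 4n)
  y <- bandpass_zero_phase(rnorm(n), fs, 80, 300)
  co0 <- phase_coherogram(x, y, fs, ev, freqs = c(100, 150, 200),
                          window = c(-0.02, 0.02))
  expect_lt(mean(co0$values), 0.2)
  # delayed copy: coherence stays high with phase offset 2 pi f delay
  d <- round(0.004 * fs)
  xb <- c(rep(0, d), x[1:(n - d)])
  cod <- phase_coherogram(x, xb, fs, ev, freqs = c(100, 150, 200),
                          window = c(-0.02, 0.02))
  expect_gt(mean(cod$values), 0.8)
  # swapping traces leaves magnitudes unchanged
  co_sw <- phase_coherogram(xb, x, fs, ev, freqs = c(100, 150, 200),
                            window = c(-0.02, 0.02))
  expect_equal(co_sw$values, cod$values, tolerance = 1e-10)
})

test_that("multitaper spike-field coherence peaks at the locking frequency", {
  fs <- 1250
  set.seed(23)
  n <- 120 * fs
  t <- (seq_len(n) - 1) / fs
  lfp <- sin(2 * pi * 160 * t) + 0.5 * rnorm(n)
  ev <- event_table(onset = seq(2, 118, by = 0.8),
                    peak = seq(2, 118, by = 0.8), kind = "r")
  spk <- unlist(lapply(ev$peak, function(p) {
    troughs <- round(160 * p) / 160 + 1 / 320 + (0:8) / 160
  }))
  sfc <- spike_field_coherence(spk, lfp, fs, ev)
  pk <- sfc$freq[which.max(sfc$coherence)]
  # within the multitaper bandwidth (TW=3 over 0.2 s -> 15 Hz)
  expect_lt(abs(pk - 160), 16)
  # independent Poisson spikes: coherence stays at the bias floor
  spk0 <- sort(runif(1500, 0, 120))
  sfc0 <- spike_field_coherence(spk0, lfp, fs, ev)
  expect_lt(max(sfc0$coherence), 0.05)
  expect_error(spike_field_coherence(numeric(), lfp, fs, ev),
               "insufficient|no spikes")
  # tapers: orthonormal
  tp <- dpss_tapers(200, 3, 5)
  expect_equal(crossprod(tp), diag(5), tolerance = 1e-8)
})

test_that("filter-Hilbert phase advances at the signal frequency", {
  fs <- 1250
  t <- seq(1 / fs, 10, by = 1 / fs)
  x <- sin(2 * pi * 150 * t)
  ph <- filter_hilbert_phase(x, fs, c(100, 280))
  mid <- 2000:10000
  slope <- mean(diff(ph$phase[mid]) %% (2 * pi)) * fs / (2 * pi)
  expect_equal(slope, 150, tolerance = 0.001)
  expect_true(all(ph$valid[mid]))
  # constant signal: all phases flagged invalid
  ph0 <- filter_hilbert_phase(rep(1, 5000), fs, c(100, 280))
  expect_false(any(ph0$valid))
  # sign flip shifts phase by pi
  ph2 <- filter_hilbert_phase(-x, fs, c(100, 280))
  d <- ph2$phase[mid] - ph$phase[mid]
  expect_lt(max(abs(abs(atan2(sin(d), cos(d))) - pi)), 0.01)
})

test_that("ITPC and the Rayleigh test match closed forms", {
  expect_equal(itpc(rep(1.3, 17)), 1)
  expect_equal(itpc(c(0, pi / 2, pi, 3 * pi / 2)), 0, tolerance = 1e-12)
  expect_error(itpc(numeric()), "empty")
  set.seed(24)
  r <- itpc(rvonmises(1000, 0.7, 2))
  expect_lt(abs(r - besselI(2, 1) / besselI(2, 0)), 0.05)
  # all-equal phases: essentially zero p
  expect_lt(rayleigh_test(rep(0.2, 50)), 1e-10)
  expect_error(rayleigh_test(rep(0.2, 4)), "n >= 5")
  # uniform phases: p is uniform on (0, 1)
  p <- replicate(400, rayleigh_test(runif(40, -pi, pi)))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("the PAC modulation index matches a brute-force KL computation", {
  fs <- 500
  set.seed(25)
  n <- 20 * fs
  t <- (seq_len(n) - 1) / fs
  x <- sin(2 * pi * 8 * t) +
    (1 + cos(2 * pi * 8 * t)) * 0.3 * sin(2 * pi * 160 * t) +
    0.1 * rnorm(n)
  pac <- pac_modulation_index(x, fs, phase_freqs = c(4, 8),
                              amp_freqs = c(80, 160), n_surrogates = 60)
  # independent direct computation at the (8, 160) pair
  wp <- morlet_spectrogram(x, fs, c(4, 8))
  wa <- morlet_spectrogram(x, fs, c(80, 160))
  inner <- (fs + 1):(n - fs)            # the estimator evaluates interior
  ph <- Arg(wp$values[2, ])[inner]; am <- Mod(wa$values[2, ])[inner]
  edges <- seq(-pi, pi, length.out = 51)
  mb <- vapply(seq_len(50), function(b) {
    sel <- if (b < 50) ph >= edges[b] & ph < edges[b + 1]
           else ph >= edges[b] & ph <= edges[b + 1]
    if (any(sel)) mean(am[sel]) else 0
  }, numeric(1))
  pr <- mb / sum(mb); pr <- pr[pr > 0]
  mi_bf <- (log(50) + sum(pr * log(pr))) / log(50)
  expect_lt(abs(pac$mi[2, 2] - mi_bf), 1e-6)
  # the genuinely coupled pair carries the largest raw MI
  expect_equal(which.max(pac$mi), 4L)    # column-major: (2,2)
  expect_true(all(pac$mi >= 0 & pac$mi <= 1))
})

test_that("degenerate and null PAC cases behave exactly", {
  # all amplitude in one phase bin: raw MI exactly 1
  p <- numeric(50); p[17] <- 1
  expect_identical((log(50) - swrpipe:::shannon_entropy(p)) / log(50), 1)
  # zero-coupling noise: masked MI zeroed nearly everywhere
  fs <- 250
  set.seed(26)
  zeroed <- vapply(1:12, function(i) {
    x <- rnorm(8 * fs)
    pac <- pac_modulation_index(x, fs, phase_freqs = c(6, 10),
                                amp_freqs = c(60, 90), n_surrogates = 60)
    mean(pac$mi_masked == 0)
  }, numeric(1))
  expect_gte(mean(zeroed), 0.9)
})
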