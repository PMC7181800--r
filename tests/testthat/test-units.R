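test_that("unit QC applies the rate and ISI-violation rules", {
  dur <- 100
  slow <- seq(0, dur, by = 2.5)                  # 0.4 Hz -> removed
  regular <- seq(0, dur, by = 0.2)               # 5 Hz, no violations
  base <- seq(0, dur, by = 0.21)
  doublets <- base[seq(1, length(base), by = 20)] + 0.001  # ~5% ISIs at 1 ms
  bursty <- sort(c(base, doublets))
  sd <- spike_data(data.frame(
    time = c(slow, regular, bursty),
    unit = rep(1:3, c(length(slow), length(regular), length(bursty)))))
  out <- qc_filter_units(sd, dur)
  expect_equal(out$units$unit, 2)
})

test_that("cell-type k-means separates feature blobs, scale-invariantly", {
  set.seed(41)
  units <- data.frame(
    width_ms = c(rnorm(20, 0.9, 0.05), rnorm(10, 0.3, 0.03)),
    asymmetry = c(rnorm(20, 0.4, 0.05), rnorm(10, 0.05, 0.05)),
    rate = c(exp(rnorm(20, log(2), 0.2)), exp(rnorm(10, log(15), 0.2))))
  lab <- classify_cell_types(units)
  expect_equal(lab, rep(c("pyramidal", "interneuron"), c(20, 10)))
  # rescaling features leaves labels unchanged (standardization)
  units2 <- units
  units2$width_ms <- units2$width_ms * 1000
  units2$asymmetry <- units2$asymmetry / 7
  expect_equal(classify_cell_types(units2), lab)
  expect_equal(classify_cell_types(units[1, , drop = FALSE]),
               "unclassified")
})

test_that("PETHs count spikes per lag bin with the separation filter", {
  set.seed(42)
  dur <- 600
  ev <- event_table(onset = seq(5, dur - 5, by = 1.1), kind = "r")
  st <- sort(runif(rpois(1, 10 * dur), 0, dur))
  p <- peth(st, ev, binsize = 0.01, halfwindow = 0.5)
  # homogeneous Poisson at 10 Hz: mean count/bin = 10 * 0.01 * n_events
  expect_equal(mean(p$counts), 10 * 0.01 * p$n_events, tolerance = 0.1)
  # spikes only at the reference: single maximal bin at lag 0
  p2 <- peth(ev$onset + 1e-4, ev, binsize = 0.01, halfwindow = 0.2)
  expect_equal(p2$lags[which.max(p2$counts)], 0.005)
  expect_equal(sum(p2$counts), p2$n_events)
  # events 200 ms apart are excluded by the 500 ms separation rule
  ev3 <- event_table(onset = c(1, 1.2), kind = "r")
  expect_error(peth(st, ev3), "insufficient")
})

test_that("convolution significance is calibrated and detects planted gain", {
  set.seed(43)
  n_ev <- 200
  ev <- event_table(onset = seq(2, 2 + 1.1 * (n_ev - 1), by = 1.1),
                    kind = "r")
  dur <- max(ev$onset) + 2
  flags <- replicate(150, {
    st <- sort(runif(rpois(1, 5 * dur), 0, dur))
    peth_significance(peth(st, ev))$flag
  })
  expect_lte(mean(flags != "none"), 0.04)      # global alpha 0.01
  hits <- replicate(60, {
    st <- sort(runif(rpois(1, 5 * dur), 0, dur))
    extra <- unlist(lapply(ev$onset, function(o)
      o + runif(rpois(1, 10 * 0.03), 0, 0.03)))  # 3x gain for 30 ms
    peth_significance(peth(sort(c(st, extra)), ev))$flag == "excited"
  })
  expect_gte(mean(hits), 0.95)
  # suppression is detected too
  sup <- replicate(30, {
    st <- sort(runif(rpois(1, 20 * dur), 0, dur))
    drop <- unlist(lapply(ev$onset, function(o)
      which(st > o & st < o + 0.08)))
    peth_significance(peth(st[-drop], ev))$flag == "suppressed"
  })
  expect_gte(mean(sup), 0.9)
  # zero-spike unit: no modulation
  expect_equal(peth_significance(peth(numeric(), ev))$flag, "none")
})

test_that("standardized cross-covariance obeys its formula and null", {
  # formula identity: CCH == b*T*R1*R2 in every bin -> CCE = 0
  cc <- list(cch = rep(6, 11), binsize = 0.001, T = 600,
             rates = c(0.1, 100))
  cce <- cc$cch / (cc$binsize * cc$T) - prod(cc$rates)
  expect_equal(cce, rep(0, 11))
  set.seed(44)
  # independence: standardized values ~ mean 0, SD 1 (pooled over pairs)
  pool <- unlist(lapply(1:20, function(i) {
    a <- sort(runif(3000, 0, 600)); b <- sort(runif(3000, 0, 600))
    standardized_cross_covariance(a, b, total_duration = 600)$standardized
  }))
  expect_lt(abs(mean(pool)), 0.05)
  expect_gt(sd(pool), 0.9); expect_lt(sd(pool), 1.1)
  # planted shift recovered at the correct lag bin
  a <- sort(runif(4000, 0, 600))
  cc8 <- standardized_cross_covariance(a, a + 0.008, total_duration = 600)
  expect_lte(abs(cc8$peak_lag_s - 0.008), cc8$binsize)
  expect_gt(cc8$peak_value, 10)
  # antisymmetry under swapping with lag negation
  b <- sort(runif(3000, 0, 600))
  f <- standardized_cross_covariance(a, b, total_duration = 600)
  r <- standardized_cross_covariance(b, a, total_duration = 600)
  expect_equal(f$standardized, rev(r$standardized), tolerance = 1e-10)
})

test_that("within-ripple restriction concentrates planted coupling", {
  # contrast taken in desynchronized epochs, where no common packet
  # modulation can induce covariance on its own
  s <- std_session()
  desync <- in_intervals(s$truth$ripples$onset, s$truth$states,
                         c("desync_lowEMG", "desync_highEMG"))
  rip <- s$truth$ripples[desync & s$truth$propagated, ]
  within <- interval_set(rip$onset - 0.25, rip$onset + 0.25, "in")
  gaps <- interval_set(rip$onset + 0.55, rip$onset + 1.05, "out")
  ca1_u <- s$truth$units$unit[s$truth$units$group == "ca1_pyr"][1:5]
  grsc_u <- s$truth$units$unit[s$truth$units$group == "grsc_sup_pyr"][1:5]
  vals <- sapply(1:5, function(i) {
    a <- unit_spikes(s$spikes, ca1_u[i])
    b <- unit_spikes(s$spikes, grsc_u[i])
    c(standardized_cross_covariance(a, b, binsize = 0.01,
                                    halfwindow = 0.1,
                                    restriction = within)$peak_value,
      standardized_cross_covariance(a, b, binsize = 0.01,
                                    halfwindow = 0.1,
                                    restriction = gaps)$peak_value)
  })
  expect_gt(mean(vals[1, ]), mean(vals[2, ]))
})

test_that("opto-tagging flags only pulse-driven units", {
  set.seed(45)
  pulses <- event_table(onset = seq(1, 121, by = 0.4), kind = "pulse")
  dur <- 123
  driven <- sort(c(runif(300, 0, dur),
                   rep(pulses$onset, 3) + runif(3 * nrow(pulses), 0, 0.01)))
  silent_bg <- sort(runif(600, 0, dur))
  sd <- spike_data(data.frame(
    time = c(driven, silent_bg),
    unit = rep(1:2, c(length(driven), length(silent_bg)))),
    units = data.frame(unit = 1:3), duration = dur)
  res <- opto_tag_units(sd, pulses)
  expect_true(res$responsive[res$unit == 1])
  expect_false(res$responsive[res$unit == 2])
  expect_false(res$responsive[res$unit == 3])   # no spikes at all
  expect_error(opto_tag_units(sd, pulses[1:10, ]), "insufficient")
})
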