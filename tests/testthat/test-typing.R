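test_that("rate vectors normalize per unit and exclude interneurons", {
  dur <- 60
  onsets <- seq(1, 59, by = 1)
  sd <- spike_data(data.frame(
    time = c(onsets + 0.05,                       # unit 1: once per window
             rep(onsets[1:10] + 0.02, 3),         # unit 2: varies
             onsets + 0.01),                      # unit 3: interneuron
    unit = rep(1:3, c(59, 30, 59))),
    units = data.frame(unit = 1:3,
                       type = c("pyramidal", "pyramidal", "interneuron")),
    duration = dur)
  M <- ripple_rate_vectors(sd, onsets)
  expect_equal(colnames(M), c("1", "2"))          # interneuron excluded
  expect_true(all(M[, 1] == 0))                   # constant column -> 0
  expect_equal(mean(M[, 2]), 0, tolerance = 1e-10)
  Mm <- ripple_rate_vectors(sd, onsets, normalize = "minmax")
  expect_true(all(Mm >= 0 & Mm <= 1))
})

test_that("k-means typing recovers planted template structure", {
  set.seed(61)
  # two orthogonal templates
  M <- rbind(matrix(rep(c(3, 0), each = 40), 40),
             matrix(rep(c(0, 3), each = 40), 40)) +
    matrix(rnorm(160, sd = 0.3), 80)
  truth <- rep(1:2, each = 40)
  cl <- cluster_ripples(M, k = 2, seed = 1)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
  expect_equal(dim(cl$similarity), c(80, 80))
  expect_equal(diag(cl$similarity), rep(1, 80))
  expect_equal(cl$similarity, t(cl$similarity))
  # identical rows collapse to one label with unit similarity
  M1 <- matrix(rep(c(1, 2, 3), each = 12), 12)
  expect_warning(cl1 <- cluster_ripples(M1, k = 2, seed = 1), "distinct")
  expect_true(all(cl1$similarity == 1))
  expect_error(cluster_ripples(M1[1:4, ], k = 10), "fewer")
  # similarity is invariant to per-unit affine rescaling before z-scoring
  V <- matrix(rnorm(300), 50)
  Vs <- scale(V)
  Va <- scale(sweep(sweep(V, 2, c(2, 3, 4, 5, 6, 7), "*"), 2, 1:6, "+"))
  expect_equal(cor(t(Vs)), cor(t(Va)), tolerance = 1e-10)
})

test_that("the ANCOVA group F matches the textbook lm route", {
  set.seed(62)
  n <- 120
  g <- factor(rep(1:3, each = 40))
  x <- rnorm(n)
  y <- as.numeric(g) * 0.5 + 0.8 * x + rnorm(n)
  ours <- swrpipe:::ancova_group_f(matrix(y), g, x)
  fit <- lm(y ~ x + g)
  a <- anova(fit)
  expect_equal(ours$F, a["g", "F value"], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(ours$p, a["g", "Pr(>F)"], tolerance = 1e-10,
               ignore_attr = TRUE)
  # covariate-explained rates: group effect stays at chance
  y2 <- 2 * x + rnorm(n, sd = 0.1)
  p2 <- replicate(200, {
    swrpipe:::ancova_group_f(matrix(2 * x + rnorm(n, sd = 0.1)),
                             sample(g), x)$p
  })
  expect_gt(mean(p2 < 0.05), 0.01); expect_lt(mean(p2 < 0.05), 0.12)
})

test_that("unit discrimination detects planted label-specific gains", {
  set.seed(63)
  dur <- 500
  onsets <- seq(2, dur - 2, by = 1.2)
  labels <- rep_len(1:4, length(onsets))
  ca1 <- sort(runif(20000, 0, dur))
  # two units follow label 1 with +80% rate in the post window, two ignore
  mk_unit <- function(gain_lab) {
    base <- sort(runif(3000, 0, dur))
    extra <- unlist(lapply(onsets[labels == gain_lab], function(o)
      o + runif(rpois(1, 6 * 0.1), 0, 0.1)))
    sort(c(base, extra))
  }
  u1 <- mk_unit(1); u2 <- mk_unit(1)
  sd <- spike_data(data.frame(
    time = c(u1, u2, sort(runif(3000, 0, dur)),
             sort(runif(3000, 0, dur))),
    unit = rep(1:4, c(length(u1), length(u2), 3000, 3000))),
    units = data.frame(unit = 1:4), duration = dur)
  res <- unit_discrimination_ancova(sd, onsets, labels, ca1,
                                    n_shuffle = 10)
  expect_true(all(res$table$discriminates[1:2]))
  expect_equal(dim(res$shuffle_f), c(10, 4))
  # observed max-F of a null unit sits inside its shuffle distribution
  expect_gt(mean(res$shuffle_f[, 3] >
                 max(res$F[3, res$lags > 0])), 0.05)
})

test_that("Fisher combination reproduces the chi-squared closed form", {
  expect_equal(fisher_combine(c(0.5, 0.5, 0.5)),
               pchisq(-2 * 3 * log(0.5), df = 6, lower.tail = FALSE))
  expect_equal(fisher_combine(0.123), 0.123)      # single session: identity
  set.seed(64)
  # uniform inputs stay uniform after combination
  pc <- replicate(300, fisher_combine(runif(3)))
  expect_gt(ks.test(pc, "punif")$p.value, 0.01)
})

test_that("LFP discrimination flags planted band-limited label contrast", {
  set.seed(65)
  fs <- 500; dur <- 260
  onsets <- seq(2, dur - 2, by = 1.3)
  labels <- rep_len(1:2, length(onsets))
  x <- rnorm(dur * fs)
  # label 2 ripples are preceded by an 8 Hz burst
  for (o in onsets[labels == 2]) {
    idx <- round((o - 0.4) * fs):round(o * fs)
    x[idx] <- x[idx] + 1.5 * sin(2 * pi * 8 * (idx / fs))
  }
  ca1 <- sort(runif(5000, 0, dur))
  m <- lfp_discrimination_session(x, fs, onsets, labels, ca1,
                                  freqs = c(4, 8, 16, 60, 120))
  comb <- lfp_discrimination(list(m), alpha = 0.0004)
  pre <- comb$lags < 0 & comb$lags > -0.4
  expect_true(any(comb$significant[2, pre]))      # 8 Hz band, pre-onset
  expect_false(any(comb$significant[5, ]))        # 120 Hz band untouched
})

test_that("t-SNE density permutation test calibrates and separates", {
  set.seed(66)
  n <- 60
  V <- rbind(matrix(rnorm(n * 6), n) + 6, matrix(rnorm(n * 6), n))
  lab <- rep(1:2, each = n)
  res <- tsne_density_test(V, V, lab, n_perm = 150, seed = 2)
  # each label's significant region avoids the other's
  sig1 <- res$grsc$significant[1, , ]
  sig2 <- res$grsc$significant[2, , ]
  expect_gt(sum(sig1), 0); expect_gt(sum(sig2), 0)
  # the two labels occupy (near-)disjoint map regions
  expect_lt(sum(sig1 & sig2) / sum(sig1 | sig2), 0.02)
  # permuting point order leaves the binned density map unchanged
  Y <- res$grsc$coords
  d1 <- swrpipe:::binned_density(Y, res$grsc$grid_x, res$grsc$grid_y, 4)
  perm <- sample(nrow(Y))
  d2 <- swrpipe:::binned_density(Y[perm, ], res$grsc$grid_x,
                                 res$grsc$grid_y, 4)
  expect_equal(d1, d2, tolerance = 1e-12)
  # labels with < 5 ripples are excluded with a warning
  lab2 <- lab; lab2[1:3] <- 3
  expect_warning(tsne_density_test(V, V, lab2, n_perm = 2, seed = 2),
                 "excluding")
})
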