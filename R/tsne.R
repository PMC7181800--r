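# Exact (O(n^2)) t-SNE embedding and the density permutation test used to
# ask whether downstream population activity clusters by ripple type.

# row-wise conditional affinities at a target perplexity (binary search
# on the Gaussian bandwidth)
tsne_affinities <- function(D2, perplexity) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:60) {
      w <- exp(-d * beta)
      sw <- sum(w)
      if (sw < .Machine$double.xmin) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(d * w) / sw
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Exact t-SNE embedding
#'
#' Standard t-SNE with exact pairwise affinities (suitable for the
#' hundreds-of-ripples regime): Gaussian input affinities calibrated to a
#' target perplexity, Student-t output kernel, gradient descent with
#' momentum, adaptive gains and early exaggeration. The map is
#' initialized by sampling points from an isotropic Gaussian around the
#' origin.
#'
#' @param X observations x features matrix.
#' @param perplexity target perplexity (default 30; reduced automatically
#'   if `nrow(X)` is too small).
#' @param n_iter gradient-descent iterations.
#' @param seed RNG seed for the initialization.
#' @param eta learning rate.
#' @return observations x 2 matrix of map coordinates (arbitrary units).
#' @export
tsne_embed <- function(X, perplexity = 30, n_iter = 500, seed = 1,
                       eta = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10) stop("too few observations for t-SNE")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  ss <- rowSums(X^2)
  D2 <- pmax(outer(ss, ss, "+") - 2 * X %*% t(X), 0)
  P <- tsne_affinities(D2, perplexity)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  exag <- 4; stop_exag <- 100
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= stop_exag) P * exag else P
    sy <- rowSums(Y^2)
    num <- 1 / (1 + outer(sy, sy, "+") - 2 * Y %*% t(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it < 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- mom * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

# 2D binned density of points, Gaussian-smoothed (sigma in bins)
binned_density <- function(xy, grid_x, grid_y, sigma) {
  ix <- findInterval(xy[, 1], grid_x, all.inside = TRUE)
  iy <- findInterval(xy[, 2], grid_y, all.inside = TRUE)
  H <- matrix(0, length(grid_x), length(grid_y))
  for (k in seq_len(nrow(xy))) H[ix[k], iy[k]] <- H[ix[k], iy[k]] + 1
  kern <- gaussian_kernel(sigma, radius = 3)
  H <- apply(H, 2, conv_same, k = kern)
  t(apply(t(H), 2, conv_same, k = kern))
}

#' t-SNE density permutation test of ripple-type clustering
#'
#' Embeds the source (CA1) and downstream (gRSC) population rate vectors
#' separately with t-SNE; for each region, per-label densities on a
#' binned, Gaussian-smoothed map (normalized by the number of ripples in
#' the label) are compared against a label-permutation null. Map bins
#' whose observed label density exceeds the permutation quantile
#' `1 - alpha` are flagged significant for that label.
#'
#' @param ca1_vectors,grsc_vectors ripples x units rate-vector matrices
#'   (the gRSC vectors conventionally use a 200 ms post-onset window).
#' @param labels ripple cluster labels.
#' @param perplexity t-SNE perplexity (default 30).
#' @param bin map bin size (arbitrary units, default 1).
#' @param sigma smoothing SD (AU, default 4).
#' @param n_perm number of label permutations (default 1000).
#' @param alpha per-bin significance level (default 0.01).
#' @param seed RNG seed (embedding init and permutations).
#' @param min_per_label labels with fewer ripples are excluded (warning).
#' @return list with one element per region (`ca1`, `grsc`), each a list:
#'   `coords`, `labels_used`, `density` (label x X x Y array),
#'   `significant` (logical array, same shape), `grid_x`, `grid_y`,
#'   `flag_fraction` (overall fraction of flagged bins).
#' @export
tsne_density_test <- function(ca1_vectors, grsc_vectors, labels,
                              perplexity = 30, bin = 1, sigma = 4,
                              n_perm = 1000, alpha = 0.01, seed = 1,
                              min_per_label = 5) {
  stopifnot(nrow(ca1_vectors) == length(labels),
            nrow(grsc_vectors) == length(labels))
  if (length(labels) < 50) stop("insufficient data: need >= 50 ripples")
  tab <- table(labels)
  small <- names(tab)[tab < min_per_label]
  if (length(small)) {
    warning("excluding labels with < ", min_per_label, " ripples: ",
            paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    ca1_vectors <- ca1_vectors[keep, , drop = FALSE]
    grsc_vectors <- grsc_vectors[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  labs <- sort(unique(labels))
  region_test <- function(V, region_seed) {
    Y <- tsne_embed(V, perplexity = perplexity, seed = region_seed)
    pad <- 3 * sigma * bin
    grid_x <- seq(min(Y[, 1]) - pad, max(Y[, 1]) + pad, by = bin)
    grid_y <- seq(min(Y[, 2]) - pad, max(Y[, 2]) + pad, by = bin)
    dens <- function(lab_vec) {
      out <- array(0, c(length(labs), length(grid_x), length(grid_y)))
      for (li in seq_along(labs)) {
        sel <- lab_vec == labs[li]
        out[li, , ] <- binned_density(Y[sel, , drop = FALSE],
                                      grid_x, grid_y, sigma) / sum(sel)
      }
      out
    }
    obs <- dens(labels)
    exceed <- array(0L, dim(obs))
    for (p in seq_len(n_perm)) {
      perm <- dens(sample(labels))
      exceed <- exceed + (perm >= obs)
    }
    pval <- (exceed + 1) / (n_perm + 1)
    sig <- pval < alpha
    list(coords = Y, labels_used = labels, density = obs,
         p = pval, significant = sig, grid_x = grid_x, grid_y = grid_y,
         flag_fraction = mean(sig))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  list(ca1 = region_test(ca1_vectors, seed),
       grsc = region_test(grsc_vectors, seed + 1))
}
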