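#' Inverse current-source-density estimate
#'
#' Delta-source inverse CSD: each electrode depth is assumed to host a
#' planar disk of current with radius `diameter/2` in a homogeneous medium
#' of conductivity `conductivity`; the forward matrix mapping disk sources
#' to electrode potentials is inverted to recover the CSD from an
#' event-triggered average potential profile. The shank-average reference
#' is subtracted from the potentials before inversion. Sinks are negative
#' by convention.
#'
#' @param mean_lfp depth x time matrix of event-averaged potentials
#'   (>= 3 depths; averages of >150 events are recommended).
#' @param spacing electrode spacing (micrometers).
#' @param diameter source disk diameter (micrometers, default 500).
#' @param conductivity extracellular conductivity (relative units).
#' @param subtract_shank_mean subtract the across-depth average per time
#'   point before inversion (default `TRUE`).
#' @return object of class `DepthProfile`: list with `values` (depth x
#'   time CSD, sinks negative), `depths_um`, `method = "iCSD"`.
#' @export
inverse_csd <- function(mean_lfp, spacing, diameter = 500,
                        conductivity = 1, subtract_shank_mean = TRUE) {
  if (!is.matrix(mean_lfp) || nrow(mean_lfp) < 3)
    stop("insufficient channels: inverse CSD needs >= 3 depths")
  stopifnot(spacing > 0, diameter > 0, conductivity > 0)
  nd <- nrow(mean_lfp)
  z <- (seq_len(nd) - 1) * spacing
  phi <- mean_lfp
  if (subtract_shank_mean)
    phi <- sweep(phi, 2, colMeans(phi))
  R <- diameter / 2
  dz <- abs(outer(z, z, "-"))
  F_fwd <- (spacing / (2 * conductivity)) * (sqrt(dz^2 + R^2) - dz)
  csd <- solve(F_fwd, phi)
  structure(list(values = csd, depths_um = z, spacing_um = spacing,
                 method = "iCSD", convention = "sink = negative",
                 forward_matrix = F_fwd),
            class = "DepthProfile")
}

#' Forward potential from a CSD depth profile
#'
#' The delta-source forward model matching [inverse_csd()]; useful for
#' validating recovery of planted sources.
#'
#' @param csd depth x time matrix of current sources (sinks negative).
#' @inheritParams inverse_csd
#' @return depth x time matrix of potentials.
#' @export
forward_csd_potential <- function(csd, spacing, diameter = 500,
                                  conductivity = 1) {
  nd <- nrow(csd)
  z <- (seq_len(nd) - 1) * spacing
  R <- diameter / 2
  dz <- abs(outer(z, z, "-"))
  F_fwd <- (spacing / (2 * conductivity)) * (sqrt(dz^2 + R^2) - dz)
  F_fwd %*% csd
}

#' @export
print.DepthProfile <- function(x, ...) {
  cat(sprintf("DepthProfile (%s): %d depths x %d samples\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# JADE (joint approximate diagonalization of eigenmatrices) ICA for the
# laminar voltage-loading analysis.

# Jacobi joint diagonalization of a list of symmetric matrices
joint_diagonalize <- function(Ms, tol = 1e-9, max_sweeps = 100) {
  m <- nrow(Ms[[1]])
  V <- diag(m)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (p in seq_len(m - 1)) for (q in (p + 1):m) {
      g <- vapply(Ms, function(M) c(M[p, p] - M[q, q], M[p, q] + M[q, p]),
                  numeric(2))
      G <- g %*% t(g)
      ton <- G[1, 1] - G[2, 2]
      toff <- G[1, 2] + G[2, 1]
      theta <- 0.5 * atan2(toff, ton + sqrt(ton^2 + toff^2))
      if (abs(theta) > tol) {
        changed <- TRUE
        cs <- cos(theta); sn <- sin(theta)
        Rot <- diag(m); Rot[p, p] <- cs; Rot[q, q] <- cs
        Rot[p, q] <- -sn; Rot[q, p] <- sn
        V <- V %*% Rot
        Ms <- lapply(Ms, function(M) t(Rot) %*% M %*% Rot)
      }
    }
    if (!changed) break
  }
  V
}

#' JADE independent component analysis
#'
#' Blind source separation by joint approximate diagonalization of
#' fourth-order cumulant matrices, after PCA whitening.
#'
#' @param X channels x samples data matrix.
#' @param n_components number of components to extract (<= channels).
#' @return list with `mixing` (channels x components; column j holds the
#'   per-channel loadings of source j), `unmixing`, `sources`
#'   (components x samples).
#' @export
jade_ica <- function(X, n_components = nrow(X)) {
  stopifnot(is.matrix(X), n_components <= nrow(X))
  nT <- ncol(X)
  X <- X - rowMeans(X)
  C <- X %*% t(X) / nT
  e <- eigen(C, symmetric = TRUE)
  if (e$values[n_components] < 1e-12 * e$values[1])
    stop("degenerate input: data rank below requested components")
  m <- n_components
  W <- diag(1 / sqrt(e$values[seq_len(m)])) %*% t(e$vectors[, seq_len(m)])
  iW <- e$vectors[, seq_len(m)] %*% diag(sqrt(e$values[seq_len(m)]))
  Z <- W %*% X                       # whitened, m x nT
  # cumulant matrix set
  Ms <- list()
  for (i in seq_len(m)) for (j in seq_len(i)) {
    Zij <- Z * rep(Z[i, ] * Z[j, ], each = m)
    M <- Zij %*% t(Z) / nT
    M[i, j] <- M[i, j] - 1
    M[j, i] <- M[j, i] - 1
    if (i == j) M <- M - diag(m)
    Ms[[length(Ms) + 1]] <- if (i == j) M else sqrt(2) * M
  }
  V <- joint_diagonalize(Ms)
  sources <- t(V) %*% Z
  mixing <- iW %*% V                 # channels x components
  list(mixing = mixing, unmixing = t(V) %*% W, sources = sources)
}

#' ICA voltage loadings around events with a depth comparison
#'
#' Runs JADE ICA on event-window-concatenated multichannel data, selects
#' the component with the largest event-locked variance (variance of its
#' event-triggered average), and compares the leading component's
#' per-channel loadings between the top and bottom halves of the probe
#' with a two-sided rank-sum test.
#'
#' @param traces channels x time matrix (channel order = depth order,
#'   superficial first).
#' @param fs sampling rate (Hz).
#' @param events `EventTable`; windows are `peak + window`.
#' @param window two-element peri-event window (s).
#' @param n_components number of ICA components (default all channels).
#' @param t0 time of the first sample (s).
#' @return list with `loadings` (per-channel, sign-normalized so the
#'   largest-magnitude loading is positive), `component` index,
#'   `p_depth` (rank-sum p, top vs bottom half), `mixing`, `sources_avg`
#'   (event-triggered average of each source).
#' @export
ica_event_loadings <- function(traces, fs, events, window = c(-0.1, 0.1),
                               n_components = nrow(traces), t0 = 0) {
  stopifnot(nrow(traces) >= n_components)
  w_idx <- round(window[1] * fs):round(window[2] * fs)
  i_pk <- round((events$peak - t0) * fs) + 1L
  i_pk <- i_pk[i_pk + w_idx[1] >= 1 &
               i_pk + w_idx[length(w_idx)] <= ncol(traces)]
  if (!length(i_pk)) stop("insufficient data: no usable event windows")
  segs <- lapply(i_pk, function(i) traces[, i + w_idx, drop = FALSE])
  X <- do.call(cbind, segs)
  ica <- jade_ica(X, n_components)
  # event-locked variance of each source
  nw <- length(w_idx)
  src_avg <- matrix(0, n_components, nw)
  for (k in seq_along(i_pk))
    src_avg <- src_avg + ica$sources[, (k - 1) * nw + seq_len(nw),
                                     drop = FALSE]
  src_avg <- src_avg / length(i_pk)
  lock_var <- apply(src_avg, 1, stats::var) *
    colSums(ica$mixing^2)            # scale-aware: loading energy
  comp <- which.max(lock_var)
  load <- ica$mixing[, comp]
  if (load[which.max(abs(load))] < 0) load <- -load
  nch <- length(load)
  top <- load[seq_len(floor(nch / 2))]
  bottom <- load[(nch - floor(nch / 2) + 1):nch]
  p <- stats::wilcox.test(top, bottom, exact = FALSE)$p.value
  list(loadings = load, component = comp, p_depth = p,
       mixing = ica$mixing, sources_avg = src_avg)
}
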