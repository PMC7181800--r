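# Shared numeric helpers (internal unless exported).

# FFT-based linear convolution (real or complex), "same" central part.
conv_same <- function(x, k) {
  n <- length(x); m <- length(k)
  L <- stats::nextn(n + m - 1, 2)
  X <- stats::fft(c(x, rep(0, L - n)))
  K <- stats::fft(c(k, rep(0, L - m)))
  y <- stats::fft(X * K, inverse = TRUE) / L
  if (!is.complex(x) && !is.complex(k)) y <- Re(y)
  start <- floor(m / 2) + 1
  y[start:(start + n - 1)]
}

gaussian_kernel <- function(sd_samples, radius = 4) {
  h <- max(1L, ceiling(radius * sd_samples))
  t <- seq(-h, h)
  k <- exp(-t^2 / (2 * sd_samples^2))
  k / sum(k)
}

#' Pink (1/f) noise
#'
#' Spectrally shaped Gaussian noise with amplitude proportional to
#' 1/sqrt(f) above a 1 Hz corner, standardized to unit variance. Used as
#' the LFP background of the synthetic generator.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @return numeric vector of length `n`, sd 1.
#' @export
pink_noise <- function(n, fs) {
  L <- stats::nextn(n, 2)
  f <- c(0, seq_len(L - 1)) * fs / L
  f <- pmin(f, fs - f)              # two-sided frequency axis
  amp <- 1 / sqrt(pmax(f, 1))      # 1 Hz corner keeps DC finite
  amp[1] <- 0
  spec <- amp * (stats::rnorm(L) + 1i * stats::rnorm(L))
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  as.numeric(scale(x))
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` reduces to the circular
#' uniform distribution.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (n == 0) return(numeric())
  if (kappa < 1e-8) {
    th <- stats::runif(n, -pi, pi)
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    th <- numeric(n); i <- 1L
    while (i <= n) {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        th[i] <- sign(u[3] - 0.5) * acos(f)
        i <- i + 1L
      }
    }
  }
  ang <- th + mu
  atan2(sin(ang), cos(ang))
}

#' Greedy matching of detected events to ground-truth events
#'
#' Matches each true time to the nearest unmatched detected time within
#' `tol` seconds, in order of increasing distance. Used to score detector
#' sensitivity and false-detection rate against planted events.
#'
#' @param truth,detected numeric vectors of event times (s).
#' @param tol matching tolerance (s).
#' @return list with `n_matched`, `sensitivity` (matched / truth),
#'   `false_rate_per_event` (unmatched detections / detections),
#'   `matched_pairs` (two-column matrix of indices), `errors` (s).
#' @export
match_events <- function(truth, detected, tol = 0.02) {
  if (!length(truth) || !length(detected)) {
    return(list(n_matched = 0L,
                sensitivity = ifelse(length(truth), 0, NA_real_),
                false_rate_per_event = ifelse(length(detected), 1, NA_real_),
                matched_pairs = matrix(0L, 0, 2), errors = numeric()))
  }
  d <- abs(outer(truth, detected, "-"))
  d[d > tol] <- Inf
  pairs <- matrix(0L, 0, 2)
  while (any(is.finite(d))) {
    ij <- arrayInd(which.min(d), dim(d))
    pairs <- rbind(pairs, ij)
    d[ij[1], ] <- Inf
    d[, ij[2]] <- Inf
  }
  errs <- truth[pairs[, 1]] - detected[pairs[, 2]]
  list(n_matched = nrow(pairs),
       sensitivity = nrow(pairs) / length(truth),
       false_rate_per_event = 1 - nrow(pairs) / length(detected),
       matched_pairs = pairs, errors = errs)
}

# standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))

# draw a sub-seed deterministically; keeps component streams independent
sub_seed <- function(seed, k) (seed * 48271 + k * 16807) %% 2147483647L
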