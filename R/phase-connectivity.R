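#' Zero-phase band-pass filter
#'
#' Filters every row in the frequency domain with a real, non-negative
#' response: unit gain inside `(low, high)`, zero outside, with
#' raised-cosine transition edges of width `transition` Hz. A real response
#' applied to the DFT introduces no phase distortion, which matters because
#' every downstream quantity is a phase. The DC component is always removed.
#'
#' @param ts a [node_ts].
#' @param low,high band edges in Hz, `0 < low < high < Nyquist`.
#' @param transition transition-band width in Hz on each edge.
#' @return a filtered [node_ts].
#' @export
bandpass_filter <- function(ts, low, high, transition = 0.008) {
  nyq <- 1 / (2 * ts$dt)
  if (!(low > 0 && high > low && high < nyq))
    stop("band must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  T_len <- n_time(ts)
  freqs <- (seq_len(T_len) - 1L) / (T_len * ts$dt)
  freqs <- pmin(freqs, 1 / ts$dt - freqs)  # fold to [0, Nyquist]
  H <- raised_cosine_response(freqs, low, high, transition)
  H[1L] <- 0  # remove DC
  X <- t(stats::mvfft(t(ts$values)))
  Y <- Re(t(stats::mvfft(t(X * rep(H, each = nrow(X))), inverse = TRUE))) /
    T_len
  out <- node_ts(Y, dt = ts$dt, node_ids = ts$node_ids)
  out
}

raised_cosine_response <- function(f, low, high, w) {
  H <- numeric(length(f))
  passband <- f >= low & f <= high
  H[passband] <- 1
  lo_edge <- f > low - w & f < low
  H[lo_edge] <- 0.5 * (1 + cos(pi * (low - f[lo_edge]) / w))
  hi_edge <- f > high & f < high + w
  H[hi_edge] <- 0.5 * (1 + cos(pi * (f[hi_edge] - high) / w))
  H
}

#' Censor high-motion frames and fill them by cubic-spline interpolation
#'
#' Frames whose framewise displacement meets or exceeds `threshold` are
#' discarded and re-estimated per node with a cubic spline through the
#' retained frames. Censored frames before the first (or after the last)
#' retained frame take the nearest retained value, since cubic extrapolation
#' is unstable.
#'
#' @param ts a [node_ts].
#' @param fd numeric vector of framewise displacement (mm), length T.
#' @param threshold censoring threshold in mm (default 0.5).
#' @return a [node_ts] with attribute `fraction_replaced`.
#' @export
censor_interpolate <- function(ts, fd, threshold = 0.5) {
  T_len <- n_time(ts)
  if (length(fd) != T_len)
    stop("fd must have one value per time point (", T_len, ")")
  bad <- which(fd >= threshold)
  if (length(bad) == T_len) stop("all frames censored")
  if (length(bad) >= T_len / 2)
    stop("refusing to interpolate: ", length(bad), " of ", T_len,
         " frames censored (>= 50%)")
  if (length(bad) == 0L) {
    attr(ts, "fraction_replaced") <- 0
    return(ts)
  }
  good <- setdiff(seq_len(T_len), bad)
  vals <- ts$values
  interior <- bad[bad > min(good) & bad < max(good)]
  edges <- setdiff(bad, interior)
  for (i in seq_len(nrow(vals))) {
    if (length(interior))
      vals[i, interior] <- stats::spline(good, vals[i, good],
                                         xout = interior,
                                         method = "fmm")$y
    if (length(edges)) {
      lo <- edges[edges < min(good)]; hi <- edges[edges > max(good)]
      if (length(lo)) vals[i, lo] <- vals[i, min(good)]
      if (length(hi)) vals[i, hi] <- vals[i, max(good)]
    }
  }
  out <- node_ts(vals, dt = ts$dt, node_ids = ts$node_ids)
  attr(out, "fraction_replaced") <- length(bad) / T_len
  out
}

#' Analytic signal: instantaneous amplitude and phase per node
#'
#' Builds the discrete analytic associate of every row in the frequency
#' domain (negative frequencies zeroed, positive doubled, DC and Nyquist
#' kept), so the imaginary part is the discrete Hilbert transform. The
#' modulus gives instantaneous amplitude, the argument instantaneous phase.
#' Meaningful phase requires mean-centered, narrow-band rows (the Bedrosian
#' condition); a violation warns but does not fail.
#'
#' @param ts a [node_ts].
#' @param band optional (low, high) Hz band for an occupancy warning check.
#' @param pad `"none"` (default) or `"mirror"`: mirror padding reflects
#'   each row about its ends before the transform and keeps the central
#'   segment, attenuating edge ringing at the cost of distorting true
#'   boundary dynamics.
#' @return an `analytic_signal_set`: list with `amplitude` and `phase`
#'   matrices (node x time), `dt`, `node_ids`.
#' @export
analytic_signal <- function(ts, band = NULL, pad = c("none", "mirror")) {
  pad <- match.arg(pad)
  if (pad == "mirror") {
    x0 <- ts$values
    T0 <- ncol(x0)
    xp <- cbind(x0[, T0:1, drop = FALSE], x0, x0[, T0:1, drop = FALSE])
    tsp <- node_ts(xp, dt = ts$dt, node_ids = ts$node_ids)
    full <- analytic_signal(tsp, band = band, pad = "none")
    keep <- (T0 + 1L):(2L * T0)
    full$amplitude <- full$amplitude[, keep, drop = FALSE]
    full$phase <- full$phase[, keep, drop = FALSE]
    full$analytic <- full$analytic[, keep, drop = FALSE]
    return(full)
  }
  x <- ts$values
  T_len <- ncol(x)
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0))
    warning("constant row(s) ", paste(which(sds == 0), collapse = ", "),
            ": phase defined as 0")
  dc <- abs(rowMeans(x))
  if (any(dc > 0.05 * pmax(sds, .Machine$double.eps)))
    warning("some rows are not mean-centered; phases may be distorted")
  if (!is.null(band)) {
    occ <- band_power_fraction(ts, band)
    if (any(occ < 0.9, na.rm = TRUE))
      warning("narrow-band (Bedrosian) check: ",
              sum(occ < 0.9, na.rm = TRUE),
              " row(s) carry < 90% spectral mass inside the band")
  }
  h <- numeric(T_len)
  if (T_len %% 2L == 0L) {
    h[c(1L, T_len / 2L + 1L)] <- 1
    h[2:(T_len / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((T_len + 1L) / 2L)] <- 2
  }
  X <- t(stats::mvfft(t(x)))
  Z <- t(stats::mvfft(t(X * rep(h, each = nrow(x))), inverse = TRUE)) / T_len
  phase <- atan2(Im(Z), Re(Z))
  phase[sds == 0, ] <- 0
  structure(list(amplitude = Mod(Z), phase = phase, analytic = Z,
                 dt = ts$dt, node_ids = ts$node_ids),
            class = "analytic_signal_set")
}

#' @export
print.analytic_signal_set <- function(x, ...) {
  cat(sprintf("analytic_signal_set: %d nodes x %d time points\n",
              nrow(x$phase), ncol(x$phase)))
  invisible(x)
}

#' Instantaneous phase-difference matrix at one time point
#'
#' The streaming primitive behind [phase_difference_tensor()]:
#' `d[i, j] = |sin(phi_i - phi_j)|`, a symmetric hollow matrix with entries
#' in \[0, 1\] (0 = phase-locked). Downstream per-frame operations use this
#' so the full node x node x time tensor never has to be materialized.
#'
#' @param ph an `analytic_signal_set`.
#' @param t time index (1-based).
#' @return an N x N matrix.
#' @export
phase_difference_at <- function(ph, t) {
  phi <- ph$phase[, t]
  d <- abs(sin(outer(phi, phi, "-")))
  diag(d) <- 0
  d
}

#' Instantaneous phase-difference tensor
#'
#' Stacks [phase_difference_at()] over all time points into an
#' N x N x T array. The |sin| wrapping maps phase differences to \[0, 1\]
#' and removes phase-unwrapping ambiguity; note it conflates in-phase and
#' antiphase alignment (both give d = 0).
#'
#' @param ph an `analytic_signal_set`.
#' @return a `phase_difference_tensor`: list with array `d`, `node_ids`,
#'   `dt`.
#' @export
phase_difference_tensor <- function(ph) {
  N <- nrow(ph$phase); T_len <- ncol(ph$phase)
  d <- array(0, dim = c(N, N, T_len))
  for (t in seq_len(T_len)) d[, , t] <- phase_difference_at(ph, t)
  structure(list(d = d, node_ids = ph$node_ids, dt = ph$dt),
            class = "phase_difference_tensor")
}

#' Threshold a phase-difference tensor into a binary graph sequence
#'
#' Draws an edge at time t between nodes whose stored phase difference
#' `d = |sin(dphi)|` falls below the threshold. With
#' `compare = "sin"` (default) the rule is `d < sin(theta)`, equivalent to
#' `|dphi| < theta` near zero but also admitting antiphase pairs
#' (`|dphi|` near pi); `compare = "angle"` uses `d < theta` directly.
#'
#' @param D a `phase_difference_tensor`.
#' @param theta angular threshold in radians, in (0, pi/2).
#' @param compare `"sin"` or `"angle"`.
#' @return a `graph_sequence`: list of per-t binary adjacency matrices,
#'   `threshold`, `density_per_t`.
#' @export
threshold_binarize <- function(D, theta = pi / 16,
                               compare = c("sin", "angle")) {
  compare <- match.arg(compare)
  if (!(theta > 0 && theta < pi / 2))
    stop("theta must lie in (0, pi/2)")
  cut <- if (compare == "sin") sin(theta) else theta
  T_len <- dim(D$d)[3L]
  adj <- vector("list", T_len)
  N <- dim(D$d)[1L]
  dens <- numeric(T_len)
  for (t in seq_len(T_len)) {
    a <- (D$d[, , t] < cut) * 1
    diag(a) <- 0
    adj[[t]] <- a
    dens[t] <- sum(a) / (N * (N - 1))
  }
  structure(list(adjacency = adj, threshold = theta, compare = compare,
                 density_per_t = dens, node_ids = D$node_ids),
            class = "graph_sequence")
}

#' @export
print.graph_sequence <- function(x, ...) {
  cat(sprintf(
    "graph_sequence: %d nodes, %d frames, theta = %.4g rad, density %.3f +/- %.3f\n",
    nrow(x$adjacency[[1L]]), length(x$adjacency), x$threshold,
    mean(x$density_per_t), stats::sd(x$density_per_t)))
  invisible(x)
}

#' Largest-connected-component fraction per frame
#'
#' @param g a `graph_sequence`.
#' @return numeric vector in (0, 1\]: per frame, the size of the largest
#'   connected component divided by N.
#' @export
largest_component_fraction <- function(g) {
  vapply(g$adjacency, function(a) {
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
      a, mode = "undirected"))
    max(comp$csize) / nrow(a)
  }, numeric(1L))
}

#' Multivariate phase-randomized surrogate
#'
#' Adds one random conjugate-symmetric phase sequence (DC and Nyquist
#' untouched) to the DFT of every row and inverse-transforms. Sharing the
#' phase sequence across rows preserves every cross-spectrum, hence the
#' full stationary auto- and cross-correlation structure, while destroying
#' any nonstationarity. Per-row periodogram magnitudes are preserved to
#' machine precision.
#'
#' @param ts a [node_ts].
#' @param seed integer RNG seed.
#' @return a surrogate [node_ts].
#' @export
phase_randomize <- function(ts, seed = 1L) {
  T_len <- n_time(ts)
  if (T_len < 4L) stop("need at least 4 time points")
  with_seed(seed, {
    half <- floor((T_len - 1L) / 2L)           # strictly positive freqs
    xi <- stats::runif(half, 0, 2 * pi)
    shift <- numeric(T_len)
    shift[1L + seq_len(half)] <- xi            # positive frequencies
    shift[T_len + 1L - seq_len(half)] <- -xi   # conjugate mirror
    rot <- exp(1i * shift)
    X <- t(stats::mvfft(t(ts$values)))
    Y <- Re(t(stats::mvfft(t(X * rep(rot, each = nrow(X))),
                           inverse = TRUE))) / T_len
    node_ts(Y, dt = ts$dt, node_ids = ts$node_ids)
  })
}

#' Sliding-window Pearson correlation per node pair
#'
#' The conventional alternative to instantaneous phase synchrony: Pearson
#' correlation inside a rectangular window slid along the series.
#'
#' @param ts a [node_ts].
#' @param window window length in frames (3 <= window <= T).
#' @param step step between window starts in frames.
#' @return a `sliding_window_set`: matrix `r` (pair x window) of
#'   correlations, `pairs` (2-column index matrix), `centers` (frame index
#'   of each window center).
#' @export
sliding_window_correlation <- function(ts, window, step = 1L) {
  T_len <- n_time(ts)
  if (window > T_len) stop("window (", window, ") exceeds T (", T_len, ")")
  if (window < 3L) stop("window must be >= 3")
  starts <- seq(1L, T_len - window + 1L, by = step)
  pairs <- t(utils::combn(n_nodes(ts), 2L))
  r <- matrix(NA_real_, nrow(pairs), length(starts))
  for (w in seq_along(starts)) {
    seg <- ts$values[, starts[w]:(starts[w] + window - 1L), drop = FALSE]
    cm <- suppressWarnings(stats::cor(t(seg)))
    r[, w] <- cm[pairs]
  }
  structure(list(r = r, pairs = pairs,
                 centers = starts + (window - 1) / 2,
                 window = window, step = step, node_ids = ts$node_ids),
            class = "sliding_window_set")
}

#' Agreement between instantaneous phase synchrony and sliding windows
#'
#' For each node pair, correlates the instantaneous synchrony series
#' `1 - d` sampled at the window centers with the sliding-window
#' correlation series. Pairs where either series has (near-)zero variance
#' are reported as missing.
#'
#' @param D a `phase_difference_tensor`.
#' @param sw a `sliding_window_set` over the same nodes.
#' @return list with `per_pair` correlations (NA where degenerate),
#'   `mean_r` (mean over defined pairs), `n_defined`.
#' @export
compare_ips_sliding <- function(D, sw) {
  if (dim(D$d)[1L] != length(sw$node_ids))
    stop("node sets differ between tensor and sliding windows")
  centers <- round(sw$centers)
  per_pair <- vapply(seq_len(nrow(sw$pairs)), function(p) {
    i <- sw$pairs[p, 1L]; j <- sw$pairs[p, 2L]
    ips <- 1 - D$d[i, j, centers]
    swr <- sw$r[p, ]
    if (stats::sd(ips) < 1e-12 || stats::sd(swr) < 1e-12) return(NA_real_)
    stats::cor(ips, swr)
  }, numeric(1L))
  list(per_pair = per_pair,
       mean_r = mean(per_pair, na.rm = TRUE),
       n_defined = sum(!is.na(per_pair)))
}
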