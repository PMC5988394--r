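make_tone <- function(f, T_len = 200, dt = 3, n = 1) {
  tgrid <- (seq_len(T_len) - 1) * dt
  node_ts(t(replicate(n, cos(2 * pi * f * tgrid))), dt = dt)
}

test_that("bandpass keeps in-band tones and kills out-of-band tones", {
  tone_in <- make_tone(0.05)
  out <- bandpass_filter(tone_in, 0.03, 0.07)
  mid <- 50:150  # away from edges
  ratio <- sd(out$values[1, mid]) / sd(tone_in$values[1, mid])
  expect_equal(ratio, 1, tolerance = 0.05)

  tone_out <- make_tone(0.15)
  atten <- bandpass_filter(tone_out, 0.03, 0.07)
  expect_lt(sd(atten$values[1, ]) / sd(tone_out$values[1, ]), 0.1)

  zero <- node_ts(matrix(0, 2, 100) + 0, dt = 3)
  expect_true(all(bandpass_filter(zero, 0.03, 0.07)$values == 0))
  expect_error(bandpass_filter(tone_in, 0.05, 0.2), "Nyquist")
  # DC removal
  shifted <- node_ts(make_tone(0.05)$values + 5, dt = 3)
  expect_lt(abs(mean(bandpass_filter(shifted, 0.03, 0.07)$values)), 1e-10)
})

test_that("censor_interpolate reproduces polynomials and matches spline oracle", {
  T_len <- 50
  ramp <- node_ts(rbind(seq_len(T_len), 2 * seq_len(T_len) + 3), dt = 1)
  fd <- rep(0, T_len); fd[25] <- 1
  out <- censor_interpolate(ramp, fd)
  expect_equal(out$values[, 25], ramp$values[, 25])
  expect_equal(attr(out, "fraction_replaced"), 1 / T_len)

  # untouched when nothing censored
  clean <- censor_interpolate(ramp, rep(0, T_len))
  expect_identical(clean$values, ramp$values)
  expect_equal(attr(clean, "fraction_replaced"), 0)

  # random signal, 3 interior censored frames, independent spline oracle
  set.seed(42)
  ts <- node_ts(matrix(rnorm(2 * T_len), 2, T_len), dt = 1)
  fd <- rep(0, T_len); fd[c(10, 23, 37)] <- 0.7
  out <- censor_interpolate(ts, fd)
  good <- setdiff(seq_len(T_len), c(10, 23, 37))
  for (i in 1:2) {
    oracle <- stats::spline(good, ts$values[i, good],
                            xout = c(10, 23, 37), method = "fmm")$y
    expect_equal(out$values[i, c(10, 23, 37)], oracle)
    expect_equal(out$values[i, good], ts$values[i, good])
  }

  # edge censored frames take nearest retained value
  fd_edge <- rep(0, T_len); fd_edge[c(1, 2, T_len)] <- 1
  oute <- censor_interpolate(ts, fd_edge)
  expect_equal(oute$values[, 1], ts$values[, 3])
  expect_equal(oute$values[, 2], ts$values[, 3])
  expect_equal(oute$values[, T_len], ts$values[, T_len - 1])

  expect_error(censor_interpolate(ts, rep(1, T_len)), "all frames censored")
  fd_half <- c(rep(1, 25), rep(0, 25))
  expect_error(censor_interpolate(ts, fd_half), "50%")
  expect_error(censor_interpolate(ts, fd[1:10]), "one value per time point")
})

test_that("analytic signal recovers tone phase and satisfies identities", {
  T_len <- 256; dt <- 1; f <- 10 / T_len  # exactly periodic on the grid
  tgrid <- (seq_len(T_len) - 1) * dt
  ts <- node_ts(rbind(cos(2 * pi * f * tgrid)), dt = dt)
  ph <- analytic_signal(ts)
  expect_equal(max(abs(Re(ph$analytic[1, ]) - ts$values[1, ])), 0,
               tolerance = 1e-10)
  mid <- 30:220
  expect_equal(ph$amplitude[1, mid], rep(1, length(mid)), tolerance = 1e-8)
  unwrapped <- cumsum(c(ph$phase[1, 1],
                        atan2(sin(diff(ph$phase[1, ])),
                              cos(diff(ph$phase[1, ])))))
  slopes <- unname(diff(unwrapped[mid]))
  expect_equal(slopes, rep(2 * pi * f * dt, length(slopes)),
               tolerance = 1e-6)

  # brute-force discrete Hilbert transform oracle on a random even-length row
  set.seed(3)
  x <- rnorm(16); x <- x - mean(x)
  n <- 16
  X <- fft(x)
  h <- c(1, rep(2, n / 2 - 1), 1, rep(0, n / 2 - 1))
  z_oracle <- fft(X * h, inverse = TRUE) / n
  ph2 <- analytic_signal(node_ts(rbind(x, x), dt = 1))
  expect_equal(Im(ph2$analytic[1, ]), Im(z_oracle), tolerance = 1e-10)

  # a constant row triggers both the constant-row and centering warnings
  expect_warning(
    expect_warning(analytic_signal(node_ts(matrix(1, 1, 20) + 0, dt = 1)),
                   "constant"),
    "mean-centered")
})

test_that("mirror padding preserves the interior and calms the edges", {
  T_len <- 200; dt <- 3
  tgrid <- (seq_len(T_len) - 1) * dt
  ts <- node_ts(rbind(cos(2 * pi * 0.05 * tgrid + 0.7)), dt = dt)
  plain <- analytic_signal(ts)
  mirrored <- analytic_signal(ts, pad = "mirror")
  mid <- 50:150
  # interior phases agree between the two edge policies
  expect_lt(max(abs(sin(mirrored$phase[1, mid] - plain$phase[1, mid]))),
            0.02)
  # mirrored edge amplitudes remain bounded near the true envelope
  expect_true(all(mirrored$amplitude[1, c(1:5, 196:200)] > 0.5 &
                  mirrored$amplitude[1, c(1:5, 196:200)] < 1.5))
})

test_that("phase-difference tensor: wrapping identities and invariants", {
  T_len <- 5
  phases <- rbind(rep(0.3, T_len),
                  rep(0.3, T_len),          # identical
                  rep(0.3 + pi / 2, T_len), # quarter cycle -> d = 1
                  rep(0.3 + pi, T_len))     # antiphase -> d = 0
  ph <- list(phase = phases, dt = 1, node_ids = paste0("n", 1:4))
  class(ph) <- "analytic_signal_set"
  D <- phase_difference_tensor(ph)
  expect_equal(D$d[1, 2, ], rep(0, T_len))
  expect_equal(D$d[1, 3, ], rep(1, T_len))
  expect_equal(D$d[1, 4, ], rep(0, T_len))
  # property: symmetric, hollow, in [0, 1] on random phases
  set.seed(1)
  phr <- list(phase = matrix(runif(8 * 6, -pi, pi), 8, 6), dt = 1,
              node_ids = paste0("n", 1:8))
  class(phr) <- "analytic_signal_set"
  Dr <- phase_difference_tensor(phr)
  for (t in 1:6) {
    expect_equal(Dr$d[, , t], t(Dr$d[, , t]))
    expect_true(all(diag(Dr$d[, , t]) == 0))
  }
  expect_true(all(Dr$d >= 0 & Dr$d <= 1))
})

test_that("threshold_binarize: limits, monotonicity, compare modes", {
  set.seed(2)
  phr <- list(phase = matrix(runif(10 * 8, -pi, pi), 10, 8), dt = 1,
              node_ids = paste0("n", 1:10))
  class(phr) <- "analytic_signal_set"
  D <- phase_difference_tensor(phr)

  Dzero <- D; Dzero$d[] <- 0
  g <- threshold_binarize(Dzero, pi / 16)
  expect_true(all(g$density_per_t == 1))

  thetas <- pi / c(4, 8, 12, 16, 20, 24)
  dens <- sapply(thetas, function(th)
    mean(threshold_binarize(D, th)$density_per_t))
  expect_true(all(diff(dens) <= 0))  # descending theta -> non-increasing

  expect_error(threshold_binarize(D, 2), "theta")
  ga <- threshold_binarize(D, pi / 16, compare = "angle")
  gs <- threshold_binarize(D, pi / 16, compare = "sin")
  # both rules agree except in the sliver between sin(theta) and theta
  expect_true(mean(ga$density_per_t) <= mean(gs$density_per_t) + 1e-12)
})

test_that("largest component fraction matches BFS oracle", {
  two_cliques <- matrix(0, 10, 10)
  two_cliques[1:5, 1:5] <- 1; two_cliques[6:10, 6:10] <- 1
  diag(two_cliques) <- 0
  g <- list(adjacency = list(two_cliques), threshold = 0.1,
            density_per_t = 0, node_ids = paste0("n", 1:10))
  class(g) <- "graph_sequence"
  expect_equal(largest_component_fraction(g), 0.5)

  set.seed(4)
  adjs <- lapply(1:20, function(i) random_adjacency(12, runif(1, 0.05, 0.4)))
  gseq <- list(adjacency = adjs, threshold = 0.1, density_per_t = 0,
               node_ids = paste0("n", 1:12))
  class(gseq) <- "graph_sequence"
  oracle <- sapply(adjs, function(a) max(table(brute_components(a))) / 12)
  expect_equal(largest_component_fraction(gseq), oracle)
})

test_that("phase randomization preserves spectra and correlation structure", {
  set.seed(9)
  n <- 20; T_len <- 512
  base <- matrix(rnorm(n * T_len), n, T_len)
  # smooth to create cross-correlation
  mix <- matrix(rnorm(n * n, 0, 0.3), n, n); diag(mix) <- 1
  x <- mix %*% base
  x <- t(apply(x, 1, function(r) stats::filter(r, rep(1 / 5, 5),
                                               circular = TRUE)))
  ts <- node_ts(x, dt = 1)
  surr <- phase_randomize(ts, seed = 1)
  p_orig <- abs(t(apply(ts$values, 1, fft)))^2
  p_surr <- abs(t(apply(surr$values, 1, fft)))^2
  expect_equal(p_surr, p_orig, tolerance = 1e-10)
  expect_identical(phase_randomize(ts, seed = 1)$values, surr$values)

  cors <- lapply(1:50, function(s) cor(t(phase_randomize(ts, s)$values)))
  mean_cor <- Reduce(`+`, cors) / 50
  expect_equal(mean_cor[upper.tri(mean_cor)],
               cor(t(ts$values))[upper.tri(mean_cor)], tolerance = 0.12)
})

test_that("sliding windows match the Pearson oracle", {
  set.seed(10)
  ts <- node_ts(matrix(rnorm(4 * 60), 4, 60), dt = 1)
  sw <- sliding_window_correlation(ts, window = 20, step = 5)
  # direct oracle for pair (1,3), window starting at 11
  w2 <- 11:30
  expect_equal(sw$r[which(sw$pairs[, 1] == 1 & sw$pairs[, 2] == 3), 3],
               cor(ts$values[1, w2], ts$values[3, w2]))
  # identical rows correlate 1 in every window
  dup <- node_ts(rbind(ts$values[1, ], ts$values[1, ]), dt = 1)
  expect_equal(max(abs(sliding_window_correlation(dup, 10)$r - 1)), 0,
               tolerance = 1e-12)
  # window = T equals full-series Pearson
  full <- sliding_window_correlation(ts, window = 60)
  expect_equal(full$r[, 1], cor(t(ts$values))[t(combn(4, 2))])
  expect_error(sliding_window_correlation(ts, window = 61), "exceeds")
})

test_that("IPS vs sliding-window agreement behaves as specified", {
  set.seed(11)
  cfg <- synthetic_config(n_nodes = 8, n_modules = 2, T_len = 150,
                          connector_frac = 0, seed = 12)
  ts <- gen_coupled_phase_network(cfg)
  ph <- suppressWarnings(analytic_signal(ts))
  D <- phase_difference_tensor(ph)
  sw <- sliding_window_correlation(ts, window = 10, step = 2)
  res <- compare_ips_sliding(D, sw)
  expect_length(res$per_pair, choose(8, 2))
  expect_true(res$n_defined > 0)
  # degenerate: constant synchrony flagged missing
  Dc <- D; Dc$d[1, 2, ] <- 0.5; Dc$d[2, 1, ] <- 0.5
  swc <- sw; swc$r[1, ] <- 0.9
  resc <- compare_ips_sliding(Dc, swc)
  expect_true(is.na(resc$per_pair[1]))
})
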