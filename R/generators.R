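#' Configuration for the coupled phase-oscillator generator
#'
#' Describes a synthetic resting-state-like multichannel signal: band-limited
#' phase oscillators organized into hierarchically coupled modules (pairs of
#' micromodules), a roaming connector population, and ring coupling between
#' frequency-adjacent modules that switches between "segregated" (weak) and
#' "integrated" (strong) regimes on a schedule; observed as `sin(phase)`
#' plus Gaussian noise.
#'
#' Defaults emulate a typical slow-oscillation fMRI regime: 0.03-0.07 Hz at
#' a 3-second sampling interval, 200 time points, six modules, alternating
#' 25-frame segregated/integrated blocks.
#'
#' @param n_nodes number of nodes.
#' @param n_modules number of modules (<= n_nodes).
#' @param T_len number of time points.
#' @param dt sampling interval in seconds.
#' @param band frequency band (low, high) in Hz; must lie inside
#'   (0, Nyquist).
#' @param freq_spread standard deviation (Hz) of node frequencies around
#'   their module's center frequency, truncated to the band. Slow
#'   oscillations cluster tightly in frequency; the spread sets how fast
#'   uncoupled pairs drift through phase alignment (drift period
#'   ~ 1/spread).
#' @param module_freq_spread half-range (Hz) of the evenly spaced module
#'   center frequencies around the band center. Against the global
#'   coupling this sets the inter-module slipping rate: offsets comparable
#'   to the coupling give slow, intermittent alignment episodes
#'   (metastable synchrony) rather than frozen phase relations.
#' @param coupling_within phase pull (rad/s) toward the micromodule mean
#'   phase (always active).
#' @param coupling_between phase pull (rad/s) toward the global mean phase
#'   when segregated.
#' @param coupling_sibling phase pull (rad/s) toward the parent module's
#'   mean phase, binding the two micromodules of a module loosely
#'   together. Near-critical against the sibling frequency offset this
#'   keeps the sibling alignment sweeping through the community
#'   detector's merge/split indifference point, so partitions (and with
#'   them participation coefficients) fluctuate irregularly over time
#'   while the underlying edges stay smooth.
#' @param coupling_jitter standard deviation of per-node log-normal jitter
#'   on coupling strength; > 0 plants node heterogeneity in synchrony.
#' @param connector_frac fraction of each module's nodes that are
#'   "connectors": weakly anchored to their module (quarter-strength
#'   within-coupling) and pulled toward the global mean phase with
#'   `connector_coupling`, they wander between the phase clusters of
#'   different modules. This plants the core-periphery gradient seen in
#'   real functional networks: connector nodes carry persistent,
#'   irregular between-module participation, core nodes stable
#'   intramodular clustering.
#' @param connector_coupling global phase pull (rad/s) on connector
#'   nodes; near-critical against the module frequency spread so
#'   connectors drift among modules rather than locking anywhere.
#' @param connector_phase_noise intensity (rad/sqrt(s)) of the phase
#'   diffusion on connector nodes. Connector dynamics are stochastic,
#'   not quasi-periodic: their between-module alignments appear and
#'   dissolve unpredictably, which is what makes participation
#'   irregular where it is largest.
#' @param integration_strength fraction of `coupling_within` applied as the
#'   global pull during integrated regimes. Integration in functional
#'   networks is partial, diffuse coherence, not whole-brain phase locking;
#'   a fraction below 1 keeps the integrated state away from a fully
#'   synchronized (hence re-clustered) graph.
#' @param state_schedule data.frame with columns `start`, `end` (0-based,
#'   end-exclusive frame indices) and `regime` in
#'   `c("segregated", "integrated")`; must tile `[0, T)` without overlap.
#' @param noise_sd standard deviation of additive Gaussian observation noise
#'   (signal amplitude is 1).
#' @param seed integer RNG seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_nodes = 128L, n_modules = 6L, T_len = 200L,
                             dt = 3, band = c(0.03, 0.07),
                             freq_spread = 0.0015,
                             module_freq_spread = 0.004,
                             coupling_within = 0.3, coupling_between = 0.015,
                             coupling_sibling = 0.1,
                             coupling_jitter = 0.3,
                             connector_frac = 0.25, connector_coupling = 0.025,
                             connector_phase_noise = 0.05,
                             integration_strength = 0.2,
                             state_schedule = NULL, noise_sd = 0.01,
                             seed = 1L) {
  if (is.null(state_schedule)) {
    # eight equal alternating blocks (75 s dwell at the default TR),
    # starting segregated
    brk <- round(seq(0, T_len, length.out = 9L))
    state_schedule <- data.frame(
      start = brk[-9L], end = brk[-1L],
      regime = rep(c("segregated", "integrated"), 4L),
      stringsAsFactors = FALSE)
  }
  cfg <- list(n_nodes = as.integer(n_nodes), n_modules = as.integer(n_modules),
              T_len = as.integer(T_len), dt = dt, band = band,
              freq_spread = freq_spread,
              module_freq_spread = module_freq_spread,
              coupling_within = coupling_within,
              coupling_between = coupling_between,
              coupling_sibling = coupling_sibling,
              coupling_jitter = coupling_jitter,
              connector_frac = connector_frac,
              connector_coupling = connector_coupling,
              connector_phase_noise = connector_phase_noise,
              integration_strength = integration_strength,
              state_schedule = state_schedule, noise_sd = noise_sd,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (n_modules > n_nodes) stop("n_modules must not exceed n_nodes")
    nyq <- 1 / (2 * dt)
    if (!(band[1] > 0 && band[2] > band[1] && band[2] < nyq))
      stop("band must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
    if (coupling_within < 0 || coupling_between < 0 || noise_sd < 0)
      stop("coupling and noise_sd must be non-negative")
    s <- state_schedule[order(state_schedule$start), , drop = FALSE]
    if (!all(s$regime %in% c("segregated", "integrated")))
      stop("invalid regime in state_schedule")
    if (s$start[1L] != 0L || s$end[nrow(s)] != T_len ||
        (nrow(s) > 1L && any(s$start[-1L] != s$end[-nrow(s)])))
      stop("state_schedule must tile [0, T) without gaps or overlap")
  })
  invisible(cfg)
}

#' Generate a modular coupled phase-oscillator network signal
#'
#' Integrates first-order stochastic phase dynamics with a hierarchical
#' coupling structure: strong locking inside micromodules, loose binding
#' of sibling micromodules into modules, ring coupling between
#' frequency-adjacent modules (regime-dependent: weak when segregated,
#' stronger when integrated), and a roaming connector population pulled
#' toward the global mean phase. The observable is `sin(phase)` plus
#' Gaussian noise.
#'
#' Node traits (module membership, connector status, coupling jitter,
#' module frequency ladder) are drawn from `config$seed`, playing the role
#' of anatomy: they are shared by all subjects generated from the same
#' config. Per-subject dynamics (node frequencies, initial phases, phase
#' diffusion, observation noise) are drawn from `subject_seed`, which
#' defaults to `config$seed`. Everything is deterministic given the two
#' seeds.
#'
#' @param config a [synthetic_config].
#' @param subject_seed integer seed for the subject-level randomness;
#'   `NULL` uses `config$seed`.
#' @return a [node_ts] with attributes `modules` (planted module labels),
#'   `connector` (logical), and `phases` (the latent phase matrix).
#' @export
gen_coupled_phase_network <- function(config, subject_seed = NULL) {
  validate_synthetic_config(config)
  N <- config$n_nodes; T_len <- config$T_len; dt <- config$dt
  if (is.null(subject_seed)) subject_seed <- config$seed
  # --- population-level structure (shared across subjects) ---
  structure_draw <- with_seed(config$seed, {
    modules <- sort(rep_len(seq_len(config$n_modules), N))
    # each module is split into two loosely bound micromodules; phase
    # coupling is hierarchical: micromodule (strong), module (weak),
    # ring (regime-dependent)
    micro <- 2L * (modules - 1L) + rep_len(1:2, N)
    # distinct module center frequencies spread across the middle of the
    # band: locked modules then drift through mutual alignment a few times
    # per scan instead of holding a frozen phase relation; sibling
    # micromodules sit half a node-spread apart so their alignment also
    # drifts slowly
    centers <- mean(config$band) +
      seq(-1, 1, length.out = config$n_modules) * config$module_freq_spread
    centers <- sample(centers)
    micro_centers <- rep(centers, each = 2L) +
      rep(c(-0.5, 0.5), config$n_modules) * config$freq_spread
    connector <- stats::runif(N) < config$connector_frac
    jit <- exp(stats::rnorm(N, 0, config$coupling_jitter))
    # per-node micromodule center, then contiguous micro codes so that
    # positional indexing of per-micromodule summaries is safe
    node_center <- micro_centers[micro]
    micro <- as.integer(factor(micro))
    list(modules = modules, micro = micro, centers = centers,
         node_center = node_center, connector = connector, jit = jit)
  })
  modules <- structure_draw$modules; micro <- structure_draw$micro
  centers <- structure_draw$centers
  node_center <- structure_draw$node_center
  connector <- structure_draw$connector; jit <- structure_draw$jit
  # --- subject-level dynamics ---
  with_seed(subject_seed, {
    freq <- pmin(pmax(stats::rnorm(N, node_center, config$freq_spread),
                      config$band[1]), config$band[2])
    # connectors roam: frequencies drawn across the module ladder
    freq[connector] <- pmin(pmax(
      stats::rnorm(sum(connector), mean(config$band),
                   config$module_freq_spread),
      config$band[1]), config$band[2])
    omega <- 2 * pi * freq
    theta <- matrix(0, N, T_len)
    theta[, 1L] <- stats::runif(N, -pi, pi)
    regime_of <- character(T_len)
    for (k in seq_len(nrow(config$state_schedule))) {
      sch <- config$state_schedule[k, ]
      regime_of[(sch$start + 1L):sch$end] <- sch$regime
    }
    circ_mean <- function(x) atan2(mean(sin(x)), mean(cos(x)))
    # frequency-adjacent module neighbors on an open chain (ends reflect)
    ord <- order(centers)
    rk <- match(seq_len(config$n_modules), ord)        # rank in frequency
    ring_prev <- ord[pmax(rk - 1L, 1L)]
    ring_next <- ord[pmin(rk + 1L, config$n_modules)]
    # integrate on substeps small enough that the coupling relaxation is
    # stable (explicit Euler needs step * coupling well below 1)
    k_max <- max(config$coupling_within, config$coupling_between, 1e-6)
    n_sub <- max(1L, ceiling(dt * k_max / 0.1))
    h <- dt / n_sub
    for (t in seq_len(T_len - 1L)) {
      k_ring <- if (regime_of[t] == "segregated") config$coupling_between
                else config$integration_strength * config$coupling_within
      th <- theta[, t]
      for (s in seq_len(n_sub)) {
        psi_micro <- vapply(split(th, micro), circ_mean, 0)
        psi_mod <- vapply(split(th, modules), circ_mean, 0)
        # ring coupling: each node is pulled toward the mean phases of the
        # two frequency-adjacent modules. Integration then spreads through
        # chains of partially overlapping phase arcs without ever
        # collapsing the network into one synchronized cluster (which
        # would be a single community, i.e. zero participation).
        ring_target <- atan2(sin(psi_mod[ring_prev]) + sin(psi_mod[ring_next]),
                             cos(psi_mod[ring_prev]) + cos(psi_mod[ring_next]))
        psi_glob <- circ_mean(th)
        k_within <- config$coupling_within * ifelse(connector, 0.25, 1)
        k_conn <- ifelse(connector, config$connector_coupling, 0)
        drift <- omega +
          jit * (k_within * sin(psi_micro[micro] - th) +
                 config$coupling_sibling * sin(psi_mod[modules] - th) +
                 k_ring * sin(ring_target[modules] - th) +
                 k_conn * sin(psi_glob - th))
        th <- th + h * drift
        if (config$connector_phase_noise > 0 && any(connector))
          th[connector] <- th[connector] +
            sqrt(h) * config$connector_phase_noise *
            stats::rnorm(sum(connector))
      }
      theta[, t + 1L] <- th
    }
    y <- sin(theta)
    if (config$noise_sd > 0)
      y <- y + matrix(stats::rnorm(N * T_len, 0, config$noise_sd), N, T_len)
    out <- node_ts(y, dt = dt)
    attr(out, "modules") <- modules
    attr(out, "connector") <- connector
    attr(out, "phases") <- theta
    attr(out, "config") <- config
    out
  })
}

#' Write or read a generator configuration as flat key = value text
#'
#' The scalar fields are stored one per line as `key = value`; the state
#' schedule is flattened to `schedule = start:end:regime,...`. Every value
#' is printed with full precision so a round trip reproduces the config.
#'
#' @param config a [synthetic_config].
#' @param path file to write to / read from.
#' @return `write_synthetic_config()` returns `path` invisibly;
#'   `read_synthetic_config()` returns a [synthetic_config].
#' @export
write_synthetic_config <- function(config, path) {
  scalars <- config[setdiff(names(config), "state_schedule")]
  lines <- vapply(names(scalars), function(k) {
    sprintf("%s = %s", k,
            paste(sprintf("%.17g", as.numeric(scalars[[k]])),
                  collapse = ","))
  }, "")
  sch <- config$state_schedule
  lines <- c(lines, sprintf("schedule = %s",
                            paste(sprintf("%d:%d:%s", sch$start, sch$end,
                                          sch$regime), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  args <- list()
  for (i in seq_along(keys)) {
    if (keys[i] == "schedule") {
      parts <- strsplit(strsplit(vals[i], ",")[[1L]], ":")
      args$state_schedule <- data.frame(
        start = as.integer(vapply(parts, `[[`, "", 1L)),
        end = as.integer(vapply(parts, `[[`, "", 2L)),
        regime = vapply(parts, `[[`, "", 3L),
        stringsAsFactors = FALSE)
    } else {
      args[[keys[i]]] <- as.numeric(strsplit(vals[i], ",")[[1L]])
    }
  }
  do.call(synthetic_config, args)
}

#' Generate a group of subjects from one population structure
#'
#' Calls [gen_coupled_phase_network()] once per subject with the same
#' config (so node traits, like anatomy, are shared) and a distinct
#' subject seed (so oscillator frequencies, initial phases and noise
#' differ between subjects).
#'
#' @param config a [synthetic_config].
#' @param n_subjects number of subjects.
#' @return list of [node_ts], one per subject.
#' @export
gen_group <- function(config, n_subjects) {
  lapply(seq_len(n_subjects), function(s) {
    gen_coupled_phase_network(config,
                              subject_seed = config$seed + 7919L * s)
  })
}

#' Generate a bank of pure sinusoids
#'
#' Each row is a single sinusoid whose frequency is drawn from `freqs` and
#' whose phase offset is uniform. Serves as the "regular signal" reference
#' for entropy benchmarking.
#'
#' @param n number of rows.
#' @param freqs candidate frequencies in Hz (all below Nyquist).
#' @param T_len number of time points.
#' @param dt sampling interval in seconds.
#' @param seed integer RNG seed.
#' @param random_phase if `FALSE` all phase offsets are zero.
#' @return a [node_ts].
#' @export
gen_sine_bank <- function(n, freqs, T_len, dt, seed = 1L,
                          random_phase = TRUE) {
  nyq <- 1 / (2 * dt)
  if (any(freqs >= nyq))
    stop("all frequencies must be below the Nyquist frequency ", nyq, " Hz")
  with_seed(seed, {
    f <- sample(rep_len(freqs, max(n, length(freqs))), n)
    ph <- if (random_phase) stats::runif(n, 0, 2 * pi) else rep(0, n)
    tgrid <- (seq_len(T_len) - 1L) * dt
    y <- t(vapply(seq_len(n),
                  function(i) sin(2 * pi * f[i] * tgrid + ph[i]),
                  numeric(T_len)))
    node_ts(y, dt = dt)
  })
}

#' Generate i.i.d. uniform white noise
#'
#' Entries are i.i.d. uniform on \[0, 1\]; the "random signal" reference for
#' entropy benchmarking.
#'
#' @param n number of rows.
#' @param T_len number of time points.
#' @param seed integer RNG seed.
#' @param dt sampling interval attached to the result.
#' @return a [node_ts].
#' @export
gen_white_noise <- function(n, T_len, seed = 1L, dt = 1) {
  with_seed(seed,
            node_ts(matrix(stats::runif(n * T_len), n, T_len), dt = dt))
}

#' Generate fractional Brownian motion paths
#'
#' Exact-covariance construction: the fractional Gaussian noise covariance
#' gamma(k) = (|k+1|^2H - 2|k|^2H + |k-1|^2H) / 2 is Cholesky-factorized and
#' correlated increments are cumulatively summed. Exact for any T, at
#' O(T^3) cost, so T is capped at 10^4.
#'
#' @param n number of rows (independent paths).
#' @param T_len number of time points (<= 10^4).
#' @param hurst Hurst exponent in (0, 1); 0.5 gives standard Brownian
#'   motion.
#' @param seed integer RNG seed.
#' @param dt sampling interval attached to the result.
#' @return a [node_ts].
#' @export
gen_fbm <- function(n, T_len, hurst = 0.8, seed = 1L, dt = 1) {
  if (hurst <= 0 || hurst >= 1) stop("hurst must lie in (0, 1)")
  if (T_len > 1e4) stop("T_len > 1e4 not supported by the exact method")
  k <- 0:(T_len - 1L)
  acf_fgn <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                    abs(k - 1)^(2 * hurst))
  L <- chol(stats::toeplitz(acf_fgn))
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * T_len), n, T_len)
    incr <- z %*% L  # rows of correlated fGn
    node_ts(t(apply(incr, 1L, cumsum)), dt = dt)
  })
}

#' Fraction of periodogram mass inside a frequency band
#'
#' Utility for band-compliance checks on generated or filtered signals.
#'
#' @param ts a [node_ts].
#' @param band (low, high) in Hz.
#' @return numeric vector, one fraction per node.
#' @export
band_power_fraction <- function(ts, band) {
  x <- ts$values
  T_len <- ncol(x)
  x <- x - rowMeans(x)
  spec <- abs(t(stats::mvfft(t(x))))^2
  freqs <- (seq_len(T_len) - 1L) / (T_len * ts$dt)
  half <- freqs <= 1 / (2 * ts$dt) + 1e-12
  inband <- half & freqs >= band[1] & freqs <= band[2]
  rowSums(spec[, inband, drop = FALSE]) / rowSums(spec[, half, drop = FALSE])
}
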