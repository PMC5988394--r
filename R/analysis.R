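#' Pipeline configuration
#'
#' Bundles every tunable of the per-subject pipeline: the temporal band,
#' the phase-difference threshold, the Louvain resolution, entropy
#' parameters, and handling flags.
#'
#' @param band band-pass edges in Hz (default 0.03-0.07, the slow
#'   oscillation band that satisfies the narrow-band phase condition).
#' @param theta phase threshold in radians (default pi/16).
#' @param compare `"sin"` (edge iff `|sin dphi| < sin(theta)`) or
#'   `"angle"`.
#' @param gamma Louvain resolution (default 2: finer modules, fewer
#'   all-intramodular nodes).
#' @param params an [entropy_params].
#' @param nonzero_pc use nonzero-only SampEn for the participation
#'   coefficient.
#' @param bandpass apply the band-pass filter (disable for pre-filtered
#'   input).
#' @param fd_threshold framewise-displacement censoring threshold in mm.
#' @param edge_exclude fraction of frames at each end of the record
#'   excluded from the entropy stage (Hilbert edge effects); metrics are
#'   still computed for every frame. Default 0.
#' @param pad edge handling for the analytic signal, see
#'   [analytic_signal()].
#' @param seed base RNG seed for Louvain tie-breaking.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(band = c(0.03, 0.07), theta = pi / 16,
                            compare = c("sin", "angle"), gamma = 2,
                            params = entropy_params(), nonzero_pc = FALSE,
                            bandpass = TRUE, fd_threshold = 0.5,
                            edge_exclude = 0, pad = c("none", "mirror"),
                            seed = 1L) {
  if (edge_exclude < 0 || edge_exclude >= 0.5)
    stop("edge_exclude must lie in [0, 0.5)")
  structure(list(band = band, theta = theta,
                 compare = match.arg(compare), gamma = gamma,
                 params = params, nonzero_pc = nonzero_pc,
                 bandpass = bandpass, fd_threshold = fd_threshold,
                 edge_exclude = edge_exclude, pad = match.arg(pad),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full per-subject pipeline
#'
#' Chains temporal preprocessing (optional censoring and band-pass),
#' analytic-signal phase extraction, per-frame phase-synchrony graph
#' construction at the configured threshold, per-frame clustering
#' coefficient, Louvain partition and participation coefficient, and
#' node-wise sample entropy of both metric series. Graphs are built one
#' frame at a time from the phase matrix; the full N x N x T tensor is
#' never materialized.
#'
#' @param ts a [node_ts].
#' @param config a [pipeline_config].
#' @param fd optional framewise-displacement vector for censoring.
#' @return list with `metrics` (a `metric_time_series`: matrices `cc`,
#'   `pc` (node x time), `partitions`, `density_per_t`, `q_per_t`),
#'   `entropy` (an `entropy_map`), and `provenance`.
#' @export
run_subject <- function(ts, config = pipeline_config(), fd = NULL) {
  if (!is.null(fd)) ts <- censor_interpolate(ts, fd, config$fd_threshold)
  if (config$bandpass)
    ts <- bandpass_filter(ts, config$band[1], config$band[2])
  ph <- suppressWarnings(analytic_signal(ts, pad = config$pad))
  N <- n_nodes(ts); T_len <- n_time(ts)
  cut <- if (config$compare == "sin") sin(config$theta) else config$theta
  cc <- matrix(0, N, T_len)
  pc <- matrix(0, N, T_len)
  dens <- numeric(T_len)
  qv <- numeric(T_len)
  partitions <- vector("list", T_len)
  empty_frames <- 0L
  for (t in seq_len(T_len)) {
    a <- (phase_difference_at(ph, t) < cut) * 1
    diag(a) <- 0
    dens[t] <- sum(a) / (N * (N - 1))
    if (dens[t] == 0) {
      empty_frames <- empty_frames + 1L
      partitions[[t]] <- louvain_partition(a, config$gamma,
                                           seed = config$seed + t)
      next
    }
    cc[, t] <- clustering_coefficient(a)
    part <- louvain_partition(a, config$gamma, seed = config$seed + t)
    partitions[[t]] <- part
    qv[t] <- part$Q
    pc[, t] <- participation_coefficient(a, part)
  }
  if (empty_frames == T_len)
    stop("every frame produced an empty graph; threshold too strict ",
         "or input degenerate")
  metrics <- structure(list(cc = cc, pc = pc, partitions = partitions,
                            density_per_t = dens, q_per_t = qv,
                            node_ids = ts$node_ids),
                       class = "metric_time_series")
  ent_in <- metrics
  if (config$edge_exclude > 0) {
    drop_n <- floor(config$edge_exclude * T_len)
    keep <- (drop_n + 1L):(T_len - drop_n)
    ent_in$cc <- ent_in$cc[, keep, drop = FALSE]
    ent_in$pc <- ent_in$pc[, keep, drop = FALSE]
  }
  emap <- entropy_map(ent_in, config$params,
                      nonzero_pc = config$nonzero_pc)
  list(metrics = metrics, entropy = emap,
       provenance = list(config = config, n_nodes = N, T_len = T_len,
                         empty_frames = empty_frames,
                         density_mean = mean(dens),
                         density_sd = stats::sd(dens),
                         q_mean = mean(qv), q_sd = stats::sd(qv),
                         package_version =
                           as.character(utils::packageVersion("phasentropy"))))
}

#' Pooled clustering-participation correlation
#'
#' Pearson correlation between clustering-coefficient and
#' participation-coefficient values pooled over every subject, node and
#' time point. A negative value reflects the segregation/integration
#' antagonism: frames and nodes that are highly clustered participate
#' little across modules.
#'
#' @param metrics_list list of `metric_time_series`, one per subject.
#' @return the pooled correlation (NA with attribute `reason` when either
#'   pooled vector has zero variance), with attribute `n` (pooled sample
#'   size).
#' @export
pooled_cc_pc_correlation <- function(metrics_list) {
  stopifnot(length(metrics_list) >= 1L)
  cc <- unlist(lapply(metrics_list, function(m) as.numeric(m$cc)))
  pc <- unlist(lapply(metrics_list, function(m) as.numeric(m$pc)))
  if (stats::sd(cc) == 0 || stats::sd(pc) == 0)
    return(structure(NA_real_, reason = "zero_variance", n = length(cc)))
  structure(stats::cor(cc, pc), n = length(cc))
}

#' Compare SampEn distributions of the two metrics
#'
#' Reduces each subject to node-averaged SampEn of the clustering and of
#' the participation coefficient, then runs a two-sample t-test (PC minus
#' CC; Student's pooled-variance by default, or paired).
#'
#' @param emaps list of `entropy_map`, one per subject.
#' @param paired use a paired t-test instead of the (default) two-sample
#'   test.
#' @return list with `t`, `p`, `df`, `mean_cc`, `mean_pc`, `n`.
#' @export
compare_entropy_distributions <- function(emaps, paired = FALSE) {
  if (length(emaps) < 2L) stop("need at least 2 subjects")
  cc <- vapply(emaps, function(e) mean(e$sampen_cc, na.rm = TRUE),
               numeric(1L))
  pc <- vapply(emaps, function(e) mean(e$sampen_pc, na.rm = TRUE),
               numeric(1L))
  tt <- stats::t.test(pc, cc, paired = paired, var.equal = !paired)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       mean_cc = mean(cc), mean_pc = mean(pc), n = length(emaps))
}

#' Correlation between a metric's time-average and its SampEn
#'
#' Across nodes, correlates the group-averaged time-mean of each metric
#' with the group-averaged SampEn of the same metric.
#'
#' @param metrics_list list of `metric_time_series`.
#' @param emaps matching list of `entropy_map`.
#' @return named numeric `c(cc = r, pc = r)`; a metric with zero variance
#'   in either vector yields NA.
#' @export
metric_vs_entropy_correlation <- function(metrics_list, emaps) {
  stopifnot(length(metrics_list) == length(emaps))
  avg_nodes <- function(get_metric, get_ent) {
    mmean <- rowMeans(vapply(metrics_list,
                             function(m) rowMeans(get_metric(m)),
                             numeric(nrow(metrics_list[[1L]]$cc))))
    emean <- rowMeans(vapply(emaps, get_ent,
                             numeric(nrow(metrics_list[[1L]]$cc))),
                      na.rm = TRUE)
    if (stats::sd(mmean) == 0 || stats::sd(emean, na.rm = TRUE) == 0)
      return(NA_real_)
    stats::cor(mmean, emean, use = "complete.obs")
  }
  c(cc = avg_nodes(function(m) m$cc, function(e) e$sampen_cc),
    pc = avg_nodes(function(m) m$pc, function(e) e$sampen_pc))
}

#' Surrogate contrast: original vs phase-randomized pipeline
#'
#' Re-runs the full pipeline on multivariate phase-randomized surrogates
#' of each subject and reports the metric-vs-SampEn correlations side by
#' side. Because the surrogates preserve the full stationary correlation
#' structure, small differences indicate the original relationships are
#' carried by zero-lag correlation structure rather than nonstationarity.
#'
#' @param ts_list list of [node_ts], one per subject.
#' @param config a [pipeline_config].
#' @param seed integer seed for the surrogate phases.
#' @return list with `original`, `surrogate` (each the output of
#'   [metric_vs_entropy_correlation()]) and `abs_diff`.
#' @export
surrogate_contrast <- function(ts_list, config = pipeline_config(),
                               seed = 1L) {
  run_group <- function(tss) {
    runs <- lapply(tss, run_subject, config = config)
    list(metrics = lapply(runs, `[[`, "metrics"),
         emaps = lapply(runs, `[[`, "entropy"))
  }
  orig <- run_group(ts_list)
  surr_ts <- lapply(seq_along(ts_list), function(i) {
    phase_randomize(ts_list[[i]], seed = seed + i)
  })
  surr <- run_group(surr_ts)
  r_orig <- metric_vs_entropy_correlation(orig$metrics, orig$emaps)
  r_surr <- metric_vs_entropy_correlation(surr$metrics, surr$emaps)
  list(original = r_orig, surrogate = r_surr,
       abs_diff = abs(r_orig - r_surr),
       pooled_original = as.numeric(pooled_cc_pc_correlation(orig$metrics)),
       pooled_surrogate = as.numeric(pooled_cc_pc_correlation(surr$metrics)))
}

#' PCA-based network definition from an average synchrony matrix
#'
#' Takes the first K eigenvectors (uncentered principal components) of a
#' symmetric average synchrony matrix (stored as `1 - mean(d)`) and
#' assigns each node to the component with the largest absolute loading.
#' The assignment is invariant to sign flips of the loadings. Nodes whose
#' top two absolute loadings differ by less than `margin` (relative) are
#' flagged ambiguous.
#'
#' @param mean_sync symmetric node x node matrix.
#' @param K number of components (default 5).
#' @param margin relative loading margin below which a node is flagged.
#' @return a `network_assignment`: list with `labels` (1..K), `loadings`
#'   (node x K), `ambiguous` (logical), `K`.
#' @export
pca_network_definition <- function(mean_sync, K = 5L, margin = 0.1) {
  mean_sync <- as.matrix(mean_sync)
  if (!isSymmetric(unname(mean_sync), tol = 1e-8))
    stop("mean_sync must be symmetric")
  N <- nrow(mean_sync)
  if (K >= N) stop("K must be smaller than the number of nodes")
  eig <- eigen(mean_sync, symmetric = TRUE)
  ord <- order(abs(eig$values), decreasing = TRUE)
  vals <- eig$values[ord][seq_len(K + 1L)]
  if (abs(vals[K]) - abs(vals[K + 1L]) < 1e-10 * max(abs(vals), 1))
    stop("degenerate spectrum: components ", K, " and ", K + 1L,
         " are not separated; network definition is not unique")
  loadings <- eig$vectors[, ord[seq_len(K)], drop = FALSE]
  absl <- abs(loadings)
  labels <- max.col(absl, ties.method = "first")
  top2 <- t(apply(absl, 1L, function(v) sort(v, decreasing = TRUE)[1:2]))
  ambiguous <- (top2[, 1L] - top2[, 2L]) < margin * top2[, 1L]
  structure(list(labels = labels, loadings = loadings,
                 ambiguous = ambiguous, K = as.integer(K)),
            class = "network_assignment")
}

#' One-way network ANOVA on node-wise SampEn with Bonferroni post-hoc
#'
#' Group-averages node-wise SampEn across subjects, groups nodes by
#' network assignment, and runs a one-way fixed-effects ANOVA plus all
#' pairwise Student t-tests with Bonferroni correction
#' (factor = K(K-1)/2).
#'
#' @param emaps list of `entropy_map`.
#' @param assignment a `network_assignment` (or bare label vector).
#' @param metric `"pc"` or `"cc"`.
#' @return list with `F`, `p`, `df`, `pairwise` (data.frame: groups, mean
#'   difference, t, raw and Bonferroni-adjusted p, significance at 0.05),
#'   `bonferroni_factor`.
#' @export
network_anova <- function(emaps, assignment, metric = c("pc", "cc")) {
  metric <- match.arg(metric)
  labels <- if (inherits(assignment, "network_assignment"))
    assignment$labels else as.integer(assignment)
  field <- paste0("sampen_", metric)
  y <- rowMeans(vapply(emaps, `[[`, numeric(length(labels)), field),
                na.rm = TRUE)
  keep <- !is.na(y)
  y <- y[keep]; g <- labels[keep]
  sizes <- table(g)
  if (any(sizes < 2L))
    stop("group(s) with < 2 nodes: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  groups <- sort(unique(g))
  fit <- stats::oneway.test(y ~ factor(g), var.equal = TRUE)
  pairs <- t(utils::combn(groups, 2L))
  k_comp <- nrow(pairs)
  pw <- do.call(rbind, lapply(seq_len(k_comp), function(i) {
    a <- y[g == pairs[i, 1L]]; b <- y[g == pairs[i, 2L]]
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(group1 = pairs[i, 1L], group2 = pairs[i, 2L],
               mean_diff = mean(a) - mean(b),
               t = unname(tt$statistic), p = tt$p.value,
               p_bonferroni = min(1, tt$p.value * k_comp))
  }))
  pw$significant <- pw$p_bonferroni < 0.05
  list(F = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter), pairwise = pw,
       bonferroni_factor = k_comp)
}

#' Density threshold sweep
#'
#' Re-runs the graph-metric and entropy stages of the pipeline at a
#' descending sequence of phase thresholds, re-using each subject's
#' analytic phases. At each threshold it reports the mean edge density,
#' node-mean SampEn of both metrics (nonzero-only SampEn for the
#' participation coefficient, which grows sparse at strict thresholds),
#' and the metric-vs-SampEn correlations.
#'
#' @param ts_list list of [node_ts].
#' @param thetas thresholds in radians, sorted descending (default
#'   pi/4 ... pi/24).
#' @param config a [pipeline_config]; its `theta` is ignored.
#' @return data.frame with one row per theta: `theta`, `mean_density`,
#'   `sampen_cc`, `sampen_pc`, `r_cc`, `r_pc`.
#' @export
density_sweep <- function(ts_list,
                          thetas = pi / c(4, 8, 12, 16, 20, 24),
                          config = pipeline_config()) {
  if (any(thetas <= 0 | thetas >= pi / 2))
    stop("all thetas must lie in (0, pi/2)")
  if (is.unsorted(rev(thetas)))
    stop("thetas must be sorted in descending order")
  rows <- lapply(thetas, function(th) {
    cfg <- config
    cfg$theta <- th
    cfg$nonzero_pc <- TRUE
    runs <- lapply(ts_list, run_subject, config = cfg)
    metrics <- lapply(runs, `[[`, "metrics")
    emaps <- lapply(runs, `[[`, "entropy")
    r <- metric_vs_entropy_correlation(metrics, emaps)
    data.frame(
      theta = th,
      mean_density = mean(vapply(metrics,
                                 function(m) mean(m$density_per_t),
                                 numeric(1L))),
      sampen_cc = mean(vapply(emaps,
                              function(e) mean(e$sampen_cc, na.rm = TRUE),
                              numeric(1L))),
      sampen_pc = mean(vapply(emaps,
                              function(e) mean(e$sampen_pc, na.rm = TRUE),
                              numeric(1L))),
      r_cc = r[["cc"]], r_pc = r[["pc"]])
  })
  do.call(rbind, rows)
}

#' Group-averaged synchrony matrix
#'
#' Time- and subject-averaged instantaneous synchrony `1 - d`, the input
#' to [pca_network_definition()]. Computed streaming from the analytic
#' phases.
#'
#' @param ts_list list of [node_ts].
#' @param config a [pipeline_config] (band-pass settings are honored).
#' @return symmetric N x N matrix of mean synchrony.
#' @export
mean_synchrony_matrix <- function(ts_list, config = pipeline_config()) {
  acc <- NULL
  for (ts in ts_list) {
    if (config$bandpass)
      ts <- bandpass_filter(ts, config$band[1], config$band[2])
    ph <- suppressWarnings(analytic_signal(ts))
    T_len <- n_time(ts)
    s <- matrix(0, n_nodes(ts), n_nodes(ts))
    for (t in seq_len(T_len)) s <- s + (1 - phase_difference_at(ph, t))
    s <- s / T_len
    diag(s) <- 1
    acc <- if (is.null(acc)) s else acc + s
  }
  acc / length(ts_list)
}
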