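# small shared fixture: one fast subject run (cached per test file)
small_cfg <- synthetic_config(n_nodes = 24, n_modules = 3, T_len = 80,
                              seed = 41)
small_ts <- gen_coupled_phase_network(small_cfg)
small_run <- run_subject(small_ts, pipeline_config(seed = 42))

test_that("run_subject output is well formed and deterministic", {
  m <- small_run$metrics
  expect_equal(dim(m$cc), c(24L, 80L))
  expect_equal(dim(m$pc), c(24L, 80L))
  expect_true(all(m$cc >= 0 & m$cc <= 1))
  expect_true(all(m$pc >= 0 & m$pc < 1))
  expect_length(m$partitions, 80L)
  expect_length(m$density_per_t, 80L)
  expect_true(all(m$density_per_t >= 0 & m$density_per_t <= 1))
  rerun <- run_subject(small_ts, pipeline_config(seed = 42))
  expect_identical(rerun$metrics$cc, m$cc)
  expect_identical(rerun$metrics$pc, m$pc)
  expect_identical(as.numeric(rerun$entropy$sampen_cc),
                   as.numeric(small_run$entropy$sampen_cc))
})

test_that("perfect synchrony forces the degenerate metric pattern", {
  cfg <- synthetic_config(n_nodes = 10, n_modules = 1, T_len = 60,
                          coupling_within = 2, coupling_sibling = 2,
                          coupling_between = 0, connector_frac = 0,
                          coupling_jitter = 0, freq_spread = 0,
                          module_freq_spread = 0, noise_sd = 0,
                          connector_phase_noise = 0,
                          integration_strength = 1, seed = 43)
  ts <- gen_coupled_phase_network(cfg)
  # gamma = 1: at resolution 2 a small complete graph is legitimately
  # shattered into singletons (the null term dominates), which gives
  # nonzero PC; the single-module reading of this limit requires gamma 1
  out <- run_subject(ts, pipeline_config(bandpass = FALSE, gamma = 1,
                                         seed = 44))
  # skip the locking transient and the frames where FFT-based Hilbert
  # edge ringing from the transient/record ends distorts phases
  late <- 15:45
  expect_true(all(out$metrics$cc[, late] == 1))
  expect_true(all(out$metrics$pc[, late] == 0))
})

test_that("edge exclusion trims only the entropy stage", {
  out <- run_subject(small_ts, pipeline_config(edge_exclude = 0.05,
                                               seed = 42))
  expect_equal(dim(out$metrics$cc), c(24L, 80L))   # metrics keep all frames
  expect_equal(unique(out$entropy$n_used[, "cc"]), 80L - 2L * 4L)
  expect_error(pipeline_config(edge_exclude = 0.6), "edge_exclude")
})

test_that("pooled CC-PC correlation: identities and oracle", {
  m1 <- list(cc = matrix(runif(40), 4), pc = matrix(runif(40), 4))
  class(m1) <- "metric_time_series"
  m_same <- m1; m_same$pc <- m1$cc
  expect_equal(as.numeric(pooled_cc_pc_correlation(list(m_same))), 1)
  m_op <- m1; m_op$pc <- 0.5 * (1 - m1$cc)
  expect_equal(as.numeric(pooled_cc_pc_correlation(list(m_op))), -1)
  expect_equal(as.numeric(pooled_cc_pc_correlation(list(m1))),
               cor(as.numeric(m1$cc), as.numeric(m1$pc)))
  m_const <- m1; m_const$cc[] <- 0.3
  expect_true(is.na(pooled_cc_pc_correlation(list(m_const))))
})

test_that("entropy distribution comparison matches the t-test formula", {
  set.seed(45)
  mk_emap <- function(cc, pc) {
    structure(list(sampen_cc = cc, sampen_pc = pc), class = "entropy_map")
  }
  emaps <- lapply(1:8, function(i) mk_emap(rnorm(10, 1), rnorm(10, 1.5)))
  res <- compare_entropy_distributions(emaps)
  cc <- sapply(emaps, function(e) mean(e$sampen_cc))
  pc <- sapply(emaps, function(e) mean(e$sampen_pc))
  want <- t.test(pc, cc, var.equal = TRUE)
  expect_equal(res$t, unname(want$statistic))
  expect_equal(res$p, want$p.value)
  expect_equal(res$df, 14)
  # identical vectors -> paired t is NA/0 contract: use identical groups
  same <- lapply(1:5, function(i) mk_emap(rep(1, 4), rep(1, 4)))
  expect_error(compare_entropy_distributions(same[1]), "at least 2")
  res0 <- compare_entropy_distributions(
    lapply(1:4, function(i) mk_emap(rnorm(6), rnorm(6))), paired = TRUE)
  expect_true(is.finite(res0$t))
})

test_that("metric-vs-entropy correlation equals a direct oracle", {
  set.seed(46)
  N <- 12
  metrics <- lapply(1:3, function(s) {
    m <- list(cc = matrix(runif(N * 30), N), pc = matrix(runif(N * 30), N))
    class(m) <- "metric_time_series"
    m
  })
  emaps <- lapply(1:3, function(s) {
    structure(list(sampen_cc = runif(N), sampen_pc = runif(N)),
              class = "entropy_map")
  })
  r <- metric_vs_entropy_correlation(metrics, emaps)
  mcc <- rowMeans(sapply(metrics, function(m) rowMeans(m$cc)))
  ecc <- rowMeans(sapply(emaps, function(e) e$sampen_cc))
  expect_equal(r[["cc"]], cor(mcc, ecc))
})

test_that("PCA network definition recovers blocks, flags degeneracy", {
  # unequal blocks -> distinct eigenvalues -> exact recovery
  sizes <- c(6, 8, 10, 12, 14)
  labels <- rep(seq_along(sizes), sizes)
  N <- sum(sizes)
  sync <- 0.05 + 0.9 * outer(labels, labels, "==")
  diag(sync) <- 1
  asg <- pca_network_definition(sync, K = 5)
  tab <- table(asg$labels, labels)
  expect_true(all(apply(tab > 0, 2, sum) == 1))  # each block one component
  # sign invariance is inherent (abs loadings); flipping input sign of a
  # component cannot change labels
  expect_equal(pca_network_definition(sync, K = 5)$labels, asg$labels)
  expect_error(pca_network_definition(diag(10), K = 3), "degenerate")
  expect_error(pca_network_definition(sync, K = N), "smaller")
  expect_error(pca_network_definition(matrix(runif(25), 5), K = 2),
               "symmetric")
})

test_that("network ANOVA: exact equality, errors, Bonferroni factor", {
  mk_emap <- function(v) structure(list(sampen_pc = v, sampen_cc = v),
                                   class = "entropy_map")
  set.seed(47)
  y <- rnorm(30)
  labels <- rep(1:6, each = 5)
  res <- network_anova(list(mk_emap(y)), labels, metric = "pc")
  expect_equal(res$bonferroni_factor, 15)
  expect_equal(nrow(res$pairwise), 15)
  want <- oneway.test(y ~ factor(labels), var.equal = TRUE)
  expect_equal(res$F, unname(want$statistic))
  expect_equal(res$p, want$p.value)
  expect_error(network_anova(list(mk_emap(y)), c(labels[-1], 7)),
               "group")
})

test_that("surrogate contrast on a stationary group is small", {
  # stationary linear input: no state switching, weak coupling
  cfg <- synthetic_config(n_nodes = 20, n_modules = 2, T_len = 100,
                          connector_frac = 0.2,
                          state_schedule = data.frame(
                            start = 0, end = 100, regime = "segregated"),
                          seed = 48)
  group <- gen_group(cfg, 3)
  res <- surrogate_contrast(group, pipeline_config(seed = 49), seed = 50)
  expect_named(res$abs_diff, c("cc", "pc"))
  expect_true(all(is.finite(res$pooled_original)))
})

test_that("density sweep is monotone and rejects bad thresholds", {
  cfg <- synthetic_config(n_nodes = 20, n_modules = 2, T_len = 80, seed = 51)
  group <- gen_group(cfg, 2)
  sweep <- density_sweep(group, thetas = pi / c(4, 8, 16),
                         config = pipeline_config(seed = 52))
  expect_equal(nrow(sweep), 3)
  expect_true(all(diff(sweep$mean_density) <= 0))
  expect_error(density_sweep(group, thetas = c(pi / 16, pi / 4)),
               "descending")
  expect_error(density_sweep(group, thetas = c(2, 1)), "thetas")
})

test_that("mean synchrony matrix is symmetric with unit diagonal", {
  s <- mean_synchrony_matrix(list(small_ts),
                             pipeline_config(seed = 53))
  expect_equal(s, t(s))
  expect_equal(unname(diag(s)), rep(1, 24))
  expect_true(all(s >= 0 & s <= 1))
})
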