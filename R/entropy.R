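#' Sample entropy parameters
#'
#' @param m template (embedding) length, >= 1; default 2.
#' @param tau delay between template points, >= 1; default 1.
#' @param r_factor similarity tolerance as a multiple of the signal's
#'   standard deviation; default 0.2. Scaling r with the SD makes SampEn
#'   invariant to affine amplitude changes, so metric series with
#'   different amplitudes are comparable.
#' @return an `entropy_params` list.
#' @export
entropy_params <- function(m = 2L, tau = 1L, r_factor = 0.2) {
  if (m < 1L || tau < 1L) stop("m and tau must be >= 1")
  if (r_factor <= 0) stop("r_factor must be positive")
  structure(list(m = as.integer(m), tau = as.integer(tau),
                 r_factor = r_factor), class = "entropy_params")
}

#' Sample entropy of a time series
#'
#' `SampEn(m, r, N) = -ln(U^{m+1}/U^m)` where `U^m` counts template pairs
#' (self-matches excluded) of length `m` whose Chebyshev distance is at
#' most `r = r_factor * SD(x)`; SD uses the population (1/N) convention.
#' Low values indicate temporal regularity, high values randomness.
#'
#' Degenerate and undefined cases are flagged rather than returned as
#' infinities: a constant series returns 0 with attribute
#' `reason = "degenerate"` (every template matches every other); zero
#' matches at length m or m+1 return `NA` with a reason attribute so group
#' statistics can drop them explicitly.
#'
#' @param x numeric vector, length `N >= m*tau + 2`.
#' @param params an [entropy_params].
#' @return a single numeric (NA if undefined) with attributes `reason`
#'   (NULL when defined), `n_used`, and `counts` (m+1- and m-length match
#'   counts).
#' @export
sample_entropy <- function(x, params = entropy_params()) {
  x <- as.numeric(x)
  n <- length(x)
  m <- params$m; tau <- params$tau
  if (n < m * tau + 2L)
    stop("series too short: need N >= m*tau + 2 = ", m * tau + 2L,
         ", got ", n)
  sd_pop <- sqrt(mean((x - mean(x))^2))
  if (sd_pop == 0) {
    return(structure(0, reason = "degenerate", n_used = n,
                     counts = c(A = NA_real_, B = NA_real_)))
  }
  r <- params$r_factor * sd_pop
  cnt <- sampen_pair_counts(x, m, tau, r)
  A <- cnt[[1L]]; B <- cnt[[2L]]
  if (B == 0)
    return(structure(NA_real_, reason = "no_m_matches", n_used = n,
                     counts = c(A = A, B = B)))
  if (A == 0)
    return(structure(NA_real_, reason = "no_m1_matches", n_used = n,
                     counts = c(A = A, B = B)))
  structure(-log(A / B), reason = NULL, n_used = n, counts = c(A = A, B = B))
}

#' Sample entropy of the nonzero samples only
#'
#' Removes exactly-zero samples, concatenates the remainder preserving
#' order, and applies [sample_entropy()]. Intended for sparse metric
#' series (e.g. participation coefficients at coarse parcellations), where
#' runs of structural zeros deflate plain SampEn.
#'
#' @inheritParams sample_entropy
#' @return as [sample_entropy()]; `n_used` records the number of nonzero
#'   samples; `NA` with `reason = "too_few_nonzero"` when fewer than
#'   `m*tau + 2` remain.
#' @export
sample_entropy_nonzero <- function(x, params = entropy_params()) {
  x <- as.numeric(x)
  nz <- x[x != 0]
  if (length(nz) < params$m * params$tau + 2L)
    return(structure(NA_real_, reason = "too_few_nonzero",
                     n_used = length(nz),
                     counts = c(A = NA_real_, B = NA_real_)))
  sample_entropy(nz, params)
}

#' SampEn stability as a function of series length
#'
#' Monte-Carlo mean and SD of sample entropy at each requested length for
#' a user-supplied stationary generator, e.g. to check that a given record
#' length suffices for stable estimates.
#'
#' @param generator `function(n)` returning one series of length `n`,
#'   drawing from the current RNG stream.
#' @param lengths integer vector of series lengths.
#' @param reps replicates per length.
#' @param seed integer RNG seed.
#' @param params an [entropy_params].
#' @return data.frame with columns `length`, `mean`, `sd`, `n_defined`.
#' @export
sampen_length_stability <- function(generator, lengths, reps = 100L,
                                    seed = 1L, params = entropy_params()) {
  with_seed(seed, {
    rows <- lapply(lengths, function(n) {
      vals <- vapply(seq_len(reps), function(r) {
        as.numeric(sample_entropy(generator(n), params))
      }, numeric(1L))
      data.frame(length = n, mean = mean(vals, na.rm = TRUE),
                 sd = stats::sd(vals, na.rm = TRUE),
                 n_defined = sum(!is.na(vals)))
    })
    do.call(rbind, rows)
  })
}

#' Node-wise sample entropy of metric time series
#'
#' Applies [sample_entropy()] (or the nonzero-only variant) to every row
#' of the clustering- and participation-coefficient matrices of a
#' `metric_time_series`.
#'
#' @param metrics a `metric_time_series` (see [run_subject()]).
#' @param params an [entropy_params].
#' @param nonzero_pc if `TRUE`, the participation coefficient uses
#'   [sample_entropy_nonzero()].
#' @return an `entropy_map`: list with numeric vectors `sampen_cc`,
#'   `sampen_pc` (NA where undefined), character vectors `reason_cc`,
#'   `reason_pc`, matrix `n_used`, and `params`.
#' @export
entropy_map <- function(metrics, params = entropy_params(),
                        nonzero_pc = FALSE) {
  one <- function(x, fn) {
    v <- fn(x, params)
    list(value = as.numeric(v),
         reason = if (is.null(attr(v, "reason"))) NA_character_
                  else attr(v, "reason"),
         n_used = attr(v, "n_used"))
  }
  cc <- apply(metrics$cc, 1L, one, fn = sample_entropy)
  pc_fn <- if (nonzero_pc) sample_entropy_nonzero else sample_entropy
  pc <- apply(metrics$pc, 1L, one, fn = pc_fn)
  structure(list(
    sampen_cc = vapply(cc, `[[`, 0, "value"),
    sampen_pc = vapply(pc, `[[`, 0, "value"),
    reason_cc = vapply(cc, `[[`, "", "reason"),
    reason_pc = vapply(pc, `[[`, "", "reason"),
    n_used = cbind(cc = vapply(cc, `[[`, 0L, "n_used"),
                   pc = vapply(pc, `[[`, 0L, "n_used")),
    params = params, nonzero_pc = nonzero_pc),
    class = "entropy_map")
}

#' @export
print.entropy_map <- function(x, ...) {
  cat(sprintf(
    "entropy_map: %d nodes; SampEn CC %.3f +/- %.3f, PC %.3f +/- %.3f (%d/%d undefined)\n",
    length(x$sampen_cc),
    mean(x$sampen_cc, na.rm = TRUE), stats::sd(x$sampen_cc, na.rm = TRUE),
    mean(x$sampen_pc, na.rm = TRUE), stats::sd(x$sampen_pc, na.rm = TRUE),
    sum(is.na(x$sampen_cc)), sum(is.na(x$sampen_pc))))
  invisible(x)
}
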