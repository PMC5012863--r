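#' Functional connectivity matrix
#'
#' Pairwise Pearson correlation between regional time series, the standard
#' resting-state functional-connectivity estimate.
#'
#' @param x an `observable_series` or a numeric regions x time matrix.
#' @return symmetric correlation matrix with unit diagonal and region ids
#'   as dimnames.
#' @export
fc_matrix <- function(x) {
  vals <- if (inherits(x, "observable_series")) x$values else x
  if (!is.matrix(vals)) stop_("input must be a matrix or observable_series")
  if (ncol(vals) < 3) stop_("need at least 3 time points")
  sds <- apply(vals, 1, sd)
  if (any(sds == 0)) {
    bad <- rownames(vals)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop_("constant time series (undefined correlation) for region(s): %s",
          paste(bad, collapse = ", "))
  }
  r <- cor(t(vals))
  diag(r) <- 1
  r
}

#' Seed-based functional connectivity
#'
#' The correlations between one target region and every other region: the
#' target's row of the FC matrix with the diagonal entry removed.
#'
#' @param fc an FC matrix (see [fc_matrix()]).
#' @param target region id (or index) of the seed.
#' @return named numeric vector of length N - 1.
#' @export
seed_fc <- function(fc, target) {
  ids <- rownames(fc)
  idx <- if (is.character(target)) match(target, ids) else as.integer(target)
  if (is.na(idx) || idx < 1 || idx > nrow(fc)) {
    stop_("unknown target region: %s", format(target))
  }
  fc[idx, -idx]
}

#' Fisher z-transform of correlation coefficients
#'
#' `z = atanh(r)`, variance-stabilizing for averaging and inference.
#'
#' @param r correlations with |r| < 1.
#' @return transformed values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop_("fisher_z requires |r| < 1")
  atanh(r)
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Per region, the mean of the one-sided amplitude spectrum (square root of
#' power) over the DFT bins whose frequency lies in `band`. Series are
#' mean-centred first; since the band excludes 0 Hz, ALFF is invariant to
#' constant offsets.
#'
#' @param x an `observable_series`, a regions x time matrix, or a single
#'   series.
#' @param sampling_interval sample spacing, s (taken from the series object
#'   when available).
#' @param band numeric `c(low, high)` in Hz; default 0.01-0.1 Hz, the
#'   conventional slow BOLD fluctuation band.
#' @return named non-negative vector, one amplitude per region, with the
#'   band attached as an attribute.
#' @export
alff <- function(x, sampling_interval = NULL, band = c(0.01, 0.1)) {
  if (inherits(x, "observable_series")) {
    if (is.null(sampling_interval)) {
      sampling_interval <- diff(x$times[1:2])
    }
    vals <- x$values
  } else {
    vals <- x
  }
  if (is.null(sampling_interval)) stop_("sampling_interval is required")
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = 1)
  if (band[1] <= 0 || band[2] <= band[1]) {
    stop_("band must satisfy 0 < low < high")
  }
  nt <- ncol(vals)
  nyq <- 1 / (2 * sampling_interval)
  if (band[1] > nyq) {
    stop_("band lies above the Nyquist frequency %g Hz", nyq)
  }
  freqs <- (seq_len(nt) - 1) / (nt * sampling_interval)
  sel <- which(freqs >= band[1] & freqs <= min(band[2], nyq))
  if (length(sel) < 2) {
    stop_("band [%g, %g] Hz contains fewer than 2 DFT bins at this length",
          band[1], band[2])
  }
  out <- apply(vals, 1, function(v) {
    amp <- 2 * Mod(fft(v - mean(v))) / nt
    mean(amp[sel])
  })
  structure(out, band = band)
}

# Exact null distribution of the positive-rank sum W+ for given doubled
# ranks (integers), by convolution over the 2^n equiprobable sign
# assignments. Returns the probability mass over achievable doubled sums.
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  mass <- numeric(total + 1)  # index k+1 holds P(2*W+ = k) * 2^n
  mass[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), mass[seq_len(total + 1 - r)])
    mass <- mass + shifted
  }
  mass / 2^length(ranks2)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped; ties receive midranks. The null distribution is computed
#' exactly (by enumeration over all sign assignments, via convolution) when
#' the number of non-zero pairs is at most `exact_limit`, and by a normal
#' approximation with continuity and tie correction above it.
#'
#' @param pre,post equal-length paired samples (>= 5 pairs).
#' @param exact `TRUE`/`FALSE` to force the exact or approximate null;
#'   default `NULL` chooses exact when `n_effective <= exact_limit`.
#' @param exact_limit threshold for the automatic choice (default 25).
#' @return list with `statistic` (positive-rank sum V), `p_value`
#'   (two-sided), `n_effective`, `method`.
#' @examples
#' paired_rank_test(rep(0, 6), 1:6)  # all-positive differences: p = 0.03125
#' @export
paired_rank_test <- function(pre, post, exact = NULL, exact_limit = 25) {
  if (length(pre) != length(post)) stop_("pre and post must be paired")
  if (length(pre) < 5) stop_("need at least 5 pairs")
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_("all differences are zero")
  ranks <- rank(abs(d))
  v <- sum(ranks[d > 0])
  if (is.null(exact)) exact <- n <= exact_limit
  if (exact) {
    ranks2 <- as.integer(round(2 * ranks))
    mass <- signed_rank_null(ranks2)
    v2 <- as.integer(round(2 * v))
    p_le <- sum(mass[seq_len(v2 + 1)])
    p_ge <- sum(mass[(v2 + 1):length(mass)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    # V = sum r_i B_i with B_i ~ Bernoulli(1/2): mu and the second/fourth
    # cumulants follow from the per-term cumulants r_i^2/4 and -r_i^4/8
    # (valid with midranks). An Edgeworth term sharpens the usual
    # continuity-corrected normal tail.
    mu <- sum(ranks) / 2
    sigma2 <- sum(ranks^2) / 4
    gamma2 <- (-sum(ranks^4) / 8) / sigma2^2
    edge_cdf <- function(z) {
      pnorm(z) - stats::dnorm(z) * gamma2 / 24 * (z^3 - 3 * z)
    }
    z_le <- (v + 0.5 - mu) / sqrt(sigma2)
    z_ge <- (v - 0.5 - mu) / sqrt(sigma2)
    p_le <- edge_cdf(z_le)
    p_ge <- 1 - edge_cdf(z_ge)
    p <- min(1, max(0, 2 * min(p_le, p_ge)))
    method <- "normal-approximation"
  }
  list(statistic = v, p_value = p, n_effective = n, method = method)
}

#' Bonferroni correction
#'
#' Flags test i as significant iff `p_i < alpha / m`, where m is the number
#' of tests. `NA` p-values (e.g. regions with no change under a paired
#' design) are never significant.
#'
#' @param p_values vector of p-values in [0, 1] (NA allowed).
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of comparisons; defaults to `length(p_values)`.
#' @return list with `significant` (logical mask), `threshold`
#'   (`alpha / m`), `m`.
#' @export
bonferroni <- function(p_values, alpha = 0.05, m = length(p_values)) {
  if (m < 1) stop_("need at least one test")
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) stop_("p-value outside [0, 1]: %g", p_values[!ok][1])
  thr <- alpha / m
  sig <- !is.na(p_values) & p_values < thr
  list(significant = sig, threshold = thr, m = m)
}

#' Correlate paired change scores
#'
#' Pearson correlation between two sets of per-unit changes (for example,
#' per-trial ALFF change at a target against its FC change with a cluster),
#' with the usual t-distribution p-value.
#'
#' @param delta_a,delta_b equal-length numeric vectors (>= 3).
#' @return list with `r`, `p_value`, `n`.
#' @export
correlate_changes <- function(delta_a, delta_b) {
  if (length(delta_a) != length(delta_b) || length(delta_a) < 3) {
    stop_("need equal-length vectors with at least 3 pairs")
  }
  if (sd(delta_a) == 0 || sd(delta_b) == 0) {
    stop_("zero variance in a change vector: correlation undefined")
  }
  ct <- cor.test(delta_a, delta_b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(delta_a))
}
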