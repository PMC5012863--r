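# Shared fixtures, all built in code.

# 3-region example: edges AB = 1, AC = 2.
toy_connectome <- function() {
  W <- matrix(c(0, 1, 2,
                1, 0, 0,
                2, 0, 0), 3, byrow = TRUE)
  connectome(W, region_ids = c("A", "B", "C"))
}

# Random dense symmetric connectome with distinct weights.
rand_connectome <- function(n, seed, with_coords = FALSE) {
  set.seed(seed)
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(n * (n - 1) / 2, 0.1, 10)
  W <- W + t(W)
  coords <- if (with_coords) matrix(runif(3 * n, -50, 50), n, 3) else NULL
  connectome(W, coordinates = coords)
}

# Short-run configuration for unit tests of the simulator.
fast_config <- function(lambda, ...) {
  sim_config(lambda, dt = 0.05, duration = 90, transient = 18,
             sampling_interval = 1.5, ...)
}

# Small two-module synthetic study for cheap experiment tests.
toy_study <- function(seed = 5) {
  spec <- connectome_spec(n_regions = 16, n_modules = 2, seed = seed)
  x <- normalize_connectome(generate_connectome(spec))
  list(x = x, profile = assign_frequencies(node_strength(x)))
}

# The default study conditions (128-region synthetic connectome), built once
# per session and shared across test files.
.study_cache <- new.env(parent = emptyenv())
study <- function() {
  if (is.null(.study_cache$x)) {
    x <- normalize_connectome(generate_connectome(connectome_spec()))
    .study_cache$x <- x
    .study_cache$profile <- assign_frequencies(node_strength(x))
  }
  list(x = .study_cache$x, profile = .study_cache$profile)
}

# Exhaustive breadth-first search, the independent connectivity oracle.
bfs_connected <- function(W) {
  n <- nrow(W)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- which(W[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# Brute-force Pearson correlation by explicit summation.
pearson_oracle <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# Direct DFT amplitude at bin k (0-based) by explicit summation.
dft_amplitude <- function(v, k) {
  n <- length(v)
  t <- 0:(n - 1)
  re <- sum(v * cos(-2 * pi * k * t / n))
  im <- sum(v * sin(-2 * pi * k * t / n))
  2 * sqrt(re^2 + im^2) / n
}

# Exhaustive signed-rank null: two-sided p by enumerating all 2^n sign
# assignments of the (midranked) absolute differences.
wilcoxon_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  v_obs <- sum(ranks[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% ranks)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

percentile_ci <- function(x, n_boot = 2000, seed = 1) {
  set.seed(seed)
  means <- replicate(n_boot, mean(sample(x, replace = TRUE)))
  quantile(means, c(0.025, 0.975))
}
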