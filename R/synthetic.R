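#' Specification of a synthetic connectome
#'
#' Describes a modular random network (stochastic block model) with
#' designated hub and sensory nodes and heavy-tailed (log-normal) edge
#' weights, used as a stand-in for a tractography-derived whole-brain
#' connectome. Hubs attach with boosted probability to the whole network;
#' sensory nodes attach with damped probability and damped weights, making
#' them low-strength peripheral nodes. Defaults give an edge density around
#' 0.38, so that sparsification to 30% density is a real intervention.
#'
#' @param n_regions number of regions (>= 8).
#' @param n_modules number of modules; regions are split into contiguous
#'   blocks of near-equal size.
#' @param hub_ids labels for designated hub regions (placed in module 1).
#' @param sensory_ids labels for designated sensory regions (module 2).
#' @param p_intra,p_inter within- / between-module connection probabilities.
#' @param weight_meanlog,weight_sdlog log-normal edge-weight parameters.
#' @param hub_boost multiplicative factor (>= 1) on hub edge probabilities.
#' @param sensory_damp factor in (0, 1] damping sensory edge probabilities
#'   and weights.
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return an object of class `connectome_spec`.
#' @export
connectome_spec <- function(n_regions = 128, n_modules = 4,
                            hub_ids = "hub1", sensory_ids = "sens1",
                            p_intra = 0.6, p_inter = 0.3,
                            weight_meanlog = 0, weight_sdlog = 1,
                            hub_boost = 6, sensory_damp = 0.4, seed = 1) {
  if (n_regions < 8) stop_("n_regions must be at least 8")
  if (n_modules < 2 || n_modules > n_regions) {
    stop_("n_modules must be between 2 and n_regions")
  }
  if (length(intersect(hub_ids, sensory_ids)) > 0) {
    stop_("hub_ids and sensory_ids must be disjoint")
  }
  for (p in c(p_intra, p_inter)) {
    if (!is_scalar_number(p) || p < 0 || p > 1) {
      stop_("connection probabilities must lie in [0, 1]")
    }
  }
  if (p_intra == 0 && p_inter == 0) {
    stop_("spec infeasible: p_intra and p_inter are both zero")
  }
  if (hub_boost < 1) stop_("hub_boost must be >= 1")
  if (sensory_damp <= 0 || sensory_damp > 1) {
    stop_("sensory_damp must lie in (0, 1]")
  }
  structure(list(n_regions = as.integer(n_regions),
                 n_modules = as.integer(n_modules),
                 hub_ids = hub_ids, sensory_ids = sensory_ids,
                 p_intra = p_intra, p_inter = p_inter,
                 weight_meanlog = weight_meanlog,
                 weight_sdlog = weight_sdlog,
                 hub_boost = hub_boost, sensory_damp = sensory_damp,
                 seed = seed),
            class = "connectome_spec")
}

# Near-uniform points on a sphere (spherical Fibonacci lattice), used to
# place module centres so that modules occupy disjoint spatial clusters.
sphere_points <- function(k, radius) {
  i <- seq_len(k) - 0.5
  phi <- acos(1 - 2 * i / k)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate a synthetic connectome with hub and sensory structure
#'
#' Samples the network described by a [connectome_spec()] and returns it as
#' a [connectome()] with module-clustered coordinates. The construction
#' guarantees the designed strength contracts: every hub's strength exceeds
#' the 90th percentile (the top hub attains the maximum), every sensory
#' node's strength lies below the 25th percentile, and the graph is
#' connected (secondary components, if sampled, are attached to the first
#' hub by a median-weight edge). Output is identical for identical specs.
#'
#' @param spec a `connectome_spec`.
#' @return a `connectome` with coordinates; weights are in arbitrary
#'   tract-count-like units (normalize before simulating).
#' @export
generate_connectome <- function(spec) {
  stopifnot(inherits(spec, "connectome_spec"))
  n <- spec$n_regions
  k <- spec$n_modules
  module <- sort(rep_len(seq_len(k), n))
  ids <- sprintf("R%03d", seq_len(n))
  # designated nodes sit at the start of modules 1 (hubs) and 2 (sensory)
  hub_pos <- which(module == 1)[seq_along(spec$hub_ids)]
  sens_pos <- which(module == 2)[seq_along(spec$sensory_ids)]
  if (anyNA(hub_pos) || anyNA(sens_pos)) {
    stop_("modules too small to place the designated hub/sensory nodes")
  }
  ids[hub_pos] <- spec$hub_ids
  ids[sens_pos] <- spec$sensory_ids

  with_seed(spec$seed, {
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- ut[, 1]; j <- ut[, 2]
    p <- ifelse(module[i] == module[j], spec$p_intra, spec$p_inter)
    is_hub <- i %in% hub_pos | j %in% hub_pos
    is_sens <- i %in% sens_pos | j %in% sens_pos
    p[is_hub] <- pmin(1, p[is_hub] * spec$hub_boost)
    p[is_sens] <- spec$p_inter * spec$sensory_damp
    present <- runif(length(p)) < p
    w <- numeric(length(p))
    w[present] <- rlnorm(sum(present), spec$weight_meanlog, spec$weight_sdlog)
    w[is_sens] <- w[is_sens] * spec$sensory_damp

    W <- matrix(0, n, n)
    W[ut] <- w
    W <- W + t(W)

    # connectivity repair: attach stray components to the first hub
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected"))
    if (comp$no > 1) {
      wmed <- stats::median(w[present])
      main <- comp$membership[hub_pos[1]]
      for (cc in setdiff(seq_len(comp$no), main)) {
        v <- which(comp$membership == cc)[1]
        W[v, hub_pos[1]] <- W[hub_pos[1], v] <- wmed
      }
    }

    # enforce the strength contracts deterministically
    scale_rows <- function(W, pos, f) {
      W[pos, ] <- W[pos, ] * f
      W[, pos] <- t(W[pos, , drop = FALSE])
      W
    }
    for (iter in 1:5) {
      s <- colSums(W)
      ok_hub <- all(s[hub_pos] > quantile(s, 0.9)) &&
        max(s[hub_pos]) >= max(s)
      if (ok_hub) break
      W <- scale_rows(W, hub_pos, 1.1 * max(s) / min(s[hub_pos]))
    }
    for (iter in 1:5) {
      s <- colSums(W)
      if (all(s[sens_pos] < quantile(s, 0.25))) break
      W <- scale_rows(W, sens_pos,
                      0.8 * quantile(s, 0.25) / max(s[sens_pos]))
    }

    centers <- sphere_points(k, radius = 70)
    coords <- centers[module, , drop = FALSE] +
      matrix(runif(3 * n, -15, 15), n, 3)
    connectome(W, region_ids = ids, coordinates = coords)
  })
}

#' Specification of synthetic BOLD-like signals
#'
#' Band-limited sinusoidal components plus Gaussian noise, used as a fixture
#' for testing amplitude and connectivity metrics.
#'
#' @param n_signals number of signals.
#' @param duration total length, s.
#' @param sampling_interval sample spacing, s.
#' @param component_freqs,component_amps equal-length vectors of component
#'   frequencies (Hz) and amplitudes.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed RNG seed.
#' @return an object of class `bold_spec`.
#' @export
bold_spec <- function(n_signals = 4, duration = 300, sampling_interval = 2.25,
                      component_freqs = 0.05, component_amps = 1,
                      noise_sd = 0, seed = 1) {
  if (duration <= 0 || sampling_interval <= 0) {
    stop_("duration and sampling_interval must be positive")
  }
  if (length(component_freqs) != length(component_amps)) {
    stop_("component_freqs and component_amps must have equal length")
  }
  structure(list(n_signals = as.integer(n_signals), duration = duration,
                 sampling_interval = sampling_interval,
                 component_freqs = component_freqs,
                 component_amps = component_amps,
                 noise_sd = noise_sd, seed = seed),
            class = "bold_spec")
}

#' Generate synthetic BOLD-like signals
#'
#' Each signal is `sum_k amp_k * sin(2 pi f_k t + phi_k)` plus Gaussian
#' noise, with one random phase per component per signal drawn from the
#' seeded RNG.
#'
#' @param spec a [bold_spec()].
#' @return list with `times` (s) and `values` (n_signals x T matrix).
#' @export
generate_bold <- function(spec) {
  stopifnot(inherits(spec, "bold_spec"))
  nyq <- 1 / (2 * spec$sampling_interval)
  if (any(spec$component_freqs > nyq)) {
    stop_("component frequency %g Hz exceeds the Nyquist frequency %g Hz",
          max(spec$component_freqs), nyq)
  }
  nt <- floor(spec$duration / spec$sampling_interval)
  t <- (seq_len(nt) - 1) * spec$sampling_interval
  with_seed(spec$seed, {
    vals <- matrix(0, spec$n_signals, nt)
    for (s in seq_len(spec$n_signals)) {
      for (k in seq_along(spec$component_freqs)) {
        phi <- runif(1, 0, 2 * pi)
        vals[s, ] <- vals[s, ] + spec$component_amps[k] *
          sin(2 * pi * spec$component_freqs[k] * t + phi)
      }
      if (spec$noise_sd > 0) {
        vals[s, ] <- vals[s, ] + rnorm(nt, 0, spec$noise_sd)
      }
    }
    list(times = t, values = vals)
  })
}

#' Model-generated reference functional connectivity
#'
#' Simulates baseline (unperturbed) dynamics at a known coupling and returns
#' the across-trial mean Fisher-z seed-FC vector for each designated target.
#' Used as the ground truth for calibration-recovery: [calibrate_lambda()]
#' against this reference should select the generating coupling.
#'
#' @param x a normalized `connectome`.
#' @param profile a `frequency_profile` aligned with `x`.
#' @param lambda_true generating coupling (> 0 for a non-trivial reference).
#' @param config a [sim_config()]; its `lambda` is overridden.
#' @param targets region ids whose seed-FC vectors form the reference.
#' @param n_trials number of baseline trials averaged.
#' @param seed base seed; trial t uses `seed + t`.
#' @return list with `targets` (named list of mean z seed-FC vectors),
#'   `lambda_true`, `n_trials`.
#' @export
generate_reference_fc <- function(x, profile, lambda_true, config, targets,
                                  n_trials = 12, seed = 100) {
  if (lambda_true < 0) stop_("lambda_true must be non-negative")
  config$lambda <- lambda_true
  acc <- NULL
  for (t in seq_len(n_trials)) {
    traj <- simulate_kuramoto(x, profile, config, seed = seed + t)
    fc <- fc_matrix(observable(traj))
    zs <- lapply(targets, function(tg) fisher_z_clamped(seed_fc(fc, tg)))
    acc <- if (is.null(acc)) zs else Map(`+`, acc, zs)
  }
  names(acc) <- targets
  list(targets = lapply(acc, function(v) v / n_trials),
       lambda_true = lambda_true, n_trials = n_trials)
}
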