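#' Default frequency-reduction grid
#'
#' Twelve logarithmically spaced reductions spanning 1e-5 to 1e-2 Hz, the
#' range over which local inhibition is swept.
#'
#' @param from,to grid end points, Hz.
#' @param n number of points.
#' @return increasing numeric vector of `delta_omega` values, Hz.
#' @export
delta_grid <- function(from = 1e-5, to = 1e-2, n = 12) {
  10^seq(log10(from), log10(to), length.out = n)
}

perturbed_profile <- function(profile, target, delta_omega) {
  if (!target %in% names(profile)) {
    stop_("unknown target region: %s", target)
  }
  if (delta_omega < 0) stop_("delta_omega must be >= 0")
  if (unclass(profile)[target] - delta_omega < -1e-12) {
    stop_("delta_omega %g would drive omega of '%s' below zero",
          delta_omega, target)
  }
  profile[target] <- unclass(profile)[target] - delta_omega
  profile
}

trial_seed_fc <- function(x, profile, config, target, initial_phases) {
  traj <- simulate_kuramoto(x, profile, config,
                            initial_phases = initial_phases)
  seed_fc(fc_matrix(observable(traj)), target)
}

#' Run one paired virtual-inhibition trial
#'
#' Simulates a baseline run and a perturbed run in which the target
#' region's natural frequency is reduced by `delta_omega` (the virtual
#' analog of local inhibitory stimulation), both from identical initial
#' phases drawn from `trial_seed`. The paired design makes the
#' `delta_omega = 0` null exact: pre and post are then bitwise identical.
#'
#' @param x a normalized `connectome`.
#' @param profile a `frequency_profile` aligned with `x`.
#' @param config a [sim_config()].
#' @param target region id to perturb.
#' @param delta_omega frequency reduction, Hz (>= 0, at most the target's
#'   frequency).
#' @param trial_seed seed for the shared initial phases.
#' @return an object of class `trial_pair`: list with `pre_fc` and
#'   `post_fc` (target-to-rest seed-FC vectors), `target`, `delta_omega`,
#'   `seed`.
#' @export
run_trial_pair <- function(x, profile, config, target, delta_omega,
                           trial_seed) {
  post_profile <- perturbed_profile(profile, target, delta_omega)
  theta0 <- with_seed(trial_seed, runif(length(profile), 0, 2 * pi))
  pre <- trial_seed_fc(x, profile, config, target, theta0)
  post <- if (delta_omega == 0) {
    pre
  } else {
    trial_seed_fc(x, post_profile, config, target, theta0)
  }
  structure(list(pre_fc = pre, post_fc = post, target = target,
                 delta_omega = delta_omega, seed = trial_seed),
            class = "trial_pair")
}

#' Sweep the virtual-inhibition strength
#'
#' For each frequency reduction on the grid, runs `n_trials` paired trials
#' (trial t uses seed `base_seed + t`) and aggregates the change in
#' target-to-rest functional connectivity. Within a trial the baseline
#' simulation is shared across the grid (identical seed implies an
#' identical baseline), which is equivalent to independent trial pairs per
#' grid point. Changes are averaged over regions per trial, then summarized
#' as mean and standard error over trials per grid point.
#'
#' @inheritParams run_trial_pair
#' @param deltas increasing grid of frequency reductions, Hz.
#' @param n_trials paired trials per grid point (>= 2).
#' @param base_seed base RNG seed.
#' @param transform `"fisher"` (default) compares Fisher-z connectivity,
#'   `"raw"` compares correlation units.
#' @return an object of class `sweep_result`: list with `target`, `deltas`,
#'   `mean_change`, `sem`, `per_region` (grid x regions mean-change
#'   matrix), `trial_means` (trials x grid matrix), `transform`.
#' @export
sweep_delta_omega <- function(x, profile, config, target,
                              deltas = delta_grid(), n_trials = 100,
                              base_seed = 1,
                              transform = c("fisher", "raw")) {
  transform <- match.arg(transform)
  if (n_trials < 2) stop_("n_trials must be at least 2")
  if (is.unsorted(deltas, strictly = TRUE)) {
    stop_("deltas must be strictly increasing")
  }
  for (dw in deltas) perturbed_profile(profile, target, dw)  # validate grid
  tf <- if (transform == "fisher") fisher_z_clamped else identity
  n_reg <- length(profile) - 1L
  trial_means <- matrix(NA_real_, n_trials, length(deltas))
  per_region_acc <- matrix(0, length(deltas), n_reg)
  for (t in seq_len(n_trials)) {
    theta0 <- with_seed(base_seed + t, runif(length(profile), 0, 2 * pi))
    pre <- tf(trial_seed_fc(x, profile, config, target, theta0))
    for (d in seq_along(deltas)) {
      post <- if (deltas[d] == 0) {
        pre
      } else {
        tf(trial_seed_fc(x, perturbed_profile(profile, target, deltas[d]),
                         config, target, theta0))
      }
      change <- post - pre
      trial_means[t, d] <- mean(change)
      per_region_acc[d, ] <- per_region_acc[d, ] + change
    }
  }
  colnames(per_region_acc) <- setdiff(names(profile), target)
  structure(list(target = target, deltas = deltas,
                 mean_change = colMeans(trial_means),
                 sem = apply(trial_means, 2, sd) / sqrt(n_trials),
                 per_region = per_region_acc / n_trials,
                 trial_means = trial_means, transform = transform,
                 n_trials = n_trials, base_seed = base_seed),
            class = "sweep_result")
}

#' Frequency reduction with the largest connectivity increase
#'
#' Returns the grid value maximizing the mean FC change of a sweep; ties
#' resolve to the smallest reduction. For a fast sensory target this peak
#' is expected where the slowed frequency meets the network mean.
#'
#' @param sweep a `sweep_result`.
#' @return the peak `delta_omega`, Hz.
#' @export
peak_delta <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  sweep$deltas[which.max(sweep$mean_change)]
}

#' Per-region paired statistics across trials
#'
#' For every non-target region, applies the paired signed-rank test to its
#' pre vs. post connectivity with the target across trials, with Bonferroni
#' correction over the N - 1 regions. Regions whose differences are all
#' zero (e.g. under a null perturbation) are reported as no-change
#' (`NA` p-value, not significant).
#'
#' @param trials list of `trial_pair` objects (>= 5) for one condition.
#' @param alpha family-wise error rate.
#' @return data frame with columns `region`, `statistic`, `p_value`,
#'   `significant`; the Bonferroni threshold and m are attached as
#'   attributes.
#' @export
per_region_stats <- function(trials, alpha = 0.05) {
  if (length(trials) < 5) stop_("need at least 5 trials")
  stopifnot(all(vapply(trials, inherits, logical(1), "trial_pair")))
  pre <- do.call(rbind, lapply(trials, `[[`, "pre_fc"))
  post <- do.call(rbind, lapply(trials, `[[`, "post_fc"))
  regions <- colnames(pre)
  stat <- p <- rep(NA_real_, length(regions))
  for (r in seq_along(regions)) {
    if (all(post[, r] == pre[, r])) next  # no change anywhere: skip
    res <- paired_rank_test(pre[, r], post[, r])
    stat[r] <- res$statistic
    p[r] <- res$p_value
  }
  bf <- bonferroni(p, alpha = alpha, m = length(regions))
  out <- data.frame(region = regions, statistic = stat, p_value = p,
                    significant = bf$significant)
  attr(out, "threshold") <- bf$threshold
  attr(out, "m") <- bf$m
  out
}

#' Control-site experiment
#'
#' Applies the virtual inhibition to control regions that are neither the
#' designated hub nor sensory node, and additionally tracks the
#' sensory-hub connectivity across trials; inhibiting an irrelevant site
#' should leave that edge unmodulated.
#'
#' @inheritParams run_trial_pair
#' @param controls region ids of the control sites (distinct from
#'   `hub_id`/`sensory_id`).
#' @param hub_id,sensory_id the designated nodes whose mutual FC is
#'   monitored.
#' @param delta_omega frequency reduction, Hz (default 0.001).
#' @param n_trials trials per control site.
#' @param base_seed base RNG seed.
#' @param transform `"fisher"` or `"raw"` (as in [sweep_delta_omega()]).
#' @return named list, one entry per control site, each with `mean_change`
#'   and `sem` of the control-to-rest FC change, `pair_change` (per-trial
#'   sensory-hub FC change) and `pair_test` (paired signed-rank test on the
#'   sensory-hub edge, or `NULL` when unchanged).
#' @export
control_site_experiment <- function(x, profile, config, controls, hub_id,
                                    sensory_id, delta_omega = 0.001,
                                    n_trials = 50, base_seed = 1,
                                    transform = c("fisher", "raw")) {
  transform <- match.arg(transform)
  if (any(controls %in% c(hub_id, sensory_id))) {
    stop_("control sites must be distinct from the designated hub/sensory nodes")
  }
  tf <- if (transform == "fisher") fisher_z_clamped else identity
  out <- list()
  for (ctrl in controls) {
    changes <- numeric(n_trials)
    pair_pre <- pair_post <- numeric(n_trials)
    for (t in seq_len(n_trials)) {
      theta0 <- with_seed(base_seed + t, runif(length(profile), 0, 2 * pi))
      fc_pre <- fc_matrix(observable(simulate_kuramoto(
        x, profile, config, initial_phases = theta0)))
      fc_post <- if (delta_omega == 0) {
        fc_pre
      } else {
        fc_matrix(observable(simulate_kuramoto(
          x, perturbed_profile(profile, ctrl, delta_omega), config,
          initial_phases = theta0)))
      }
      changes[t] <- mean(tf(seed_fc(fc_post, ctrl)) -
                           tf(seed_fc(fc_pre, ctrl)))
      pair_pre[t] <- tf(fc_pre[sensory_id, hub_id])
      pair_post[t] <- tf(fc_post[sensory_id, hub_id])
    }
    pair_test <- if (all(pair_post == pair_pre)) {
      NULL
    } else {
      paired_rank_test(pair_pre, pair_post)
    }
    out[[ctrl]] <- list(mean_change = mean(changes),
                        sem = sd(changes) / sqrt(n_trials),
                        pair_change = pair_post - pair_pre,
                        pair_test = pair_test)
  }
  out
}

#' Calibrate the global coupling against reference connectivity
#'
#' For each coupling on the grid, simulates `n_trials` baseline runs,
#' forms the across-trial mean Fisher-z seed-FC vector of each reference
#' target, and scores the coupling by the Pearson correlation between the
#' concatenated simulated vectors and the reference. The selected coupling
#' maximizes the fit (ties resolve to the smallest coupling).
#'
#' @inheritParams run_trial_pair
#' @param reference output of [generate_reference_fc()] (or a compatible
#'   list with a `targets` element of named seed-FC vectors).
#' @param lambda_grid positive couplings to evaluate.
#' @param n_trials baseline trials per coupling.
#' @param base_seed base RNG seed (use seeds distinct from those that
#'   produced the reference for a meaningful recovery test).
#' @return an object of class `calibration_result`: list with
#'   `lambda_grid`, `fit_r`, `selected_lambda`.
#' @export
calibrate_lambda <- function(x, profile, config, reference, lambda_grid,
                             n_trials = 8, base_seed = 1) {
  if (length(lambda_grid) < 1 || any(lambda_grid <= 0)) {
    stop_("lambda_grid must be non-empty and positive")
  }
  ref_vec <- unlist(reference$targets, use.names = FALSE)
  if (sd(ref_vec) == 0) stop_("reference connectivity has zero variance")
  targets <- names(reference$targets)
  fit_r <- numeric(length(lambda_grid))
  for (l in seq_along(lambda_grid)) {
    config$lambda <- lambda_grid[l]
    acc <- vector("list", length(targets))
    for (t in seq_len(n_trials)) {
      traj <- simulate_kuramoto(x, profile, config, seed = base_seed + t)
      fc <- fc_matrix(observable(traj))
      for (g in seq_along(targets)) {
        z <- fisher_z_clamped(seed_fc(fc, targets[g]))
        acc[[g]] <- if (is.null(acc[[g]])) z else acc[[g]] + z
      }
    }
    sim_vec <- unlist(lapply(acc, function(v) v / n_trials),
                      use.names = FALSE)
    fit_r[l] <- cor(sim_vec, ref_vec)
  }
  best <- which(fit_r == max(fit_r))[1L]
  structure(list(lambda_grid = lambda_grid, fit_r = fit_r,
                 selected_lambda = lambda_grid[best]),
            class = "calibration_result")
}
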