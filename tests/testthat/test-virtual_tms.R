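fake_trial <- function(pre, post, target = "t") {
  structure(list(pre_fc = pre, post_fc = post, target = target,
                 delta_omega = 0.001, seed = 0), class = "trial_pair")
}

test_that("a null perturbation leaves every statistic exactly at zero", {
  st <- toy_study()
  cfg <- fast_config(lambda = 0.3)
  tp <- run_trial_pair(st$x, st$profile, cfg, "sens1", 0, trial_seed = 11)
  expect_identical(tp$pre_fc, tp$post_fc)

  sw <- sweep_delta_omega(st$x, st$profile, cfg, "sens1", deltas = 0,
                          n_trials = 3, base_seed = 20)
  expect_identical(sw$mean_change, 0)
  expect_identical(unname(sw$per_region[1, ]), rep(0, 15))

  trials <- lapply(1:5, function(t)
    run_trial_pair(st$x, st$profile, cfg, "sens1", 0, trial_seed = t))
  st_out <- per_region_stats(trials)
  expect_equal(sum(st_out$significant), 0)
  expect_true(all(is.na(st_out$p_value)))
})

test_that("trial pairs are deterministic and respect the frequency bound", {
  st <- toy_study()
  cfg <- fast_config(lambda = 0.3)
  a <- run_trial_pair(st$x, st$profile, cfg, "sens1", 0.003, trial_seed = 7)
  b <- run_trial_pair(st$x, st$profile, cfg, "sens1", 0.003, trial_seed = 7)
  expect_identical(a$pre_fc, b$pre_fc)
  expect_identical(a$post_fc, b$post_fc)
  expect_error(run_trial_pair(st$x, st$profile, cfg, "sens1", 0.5,
                              trial_seed = 1), "below zero")
  expect_error(run_trial_pair(st$x, st$profile, cfg, "nope", 0.001,
                              trial_seed = 1), "unknown target")
})

test_that("per-region statistics match direct calls of the rank test", {
  set.seed(14)
  n_tr <- 8
  regions <- paste0("r", 1:6)
  trials <- lapply(1:n_tr, function(t) {
    pre <- structure(runif(6, -0.2, 0.6), names = regions)
    post <- pre + c(rnorm(5, 0.1, 0.05), 0)  # region r6 never changes
    fake_trial(pre, post)
  })
  out <- per_region_stats(trials, alpha = 0.05)
  pre_mat <- do.call(rbind, lapply(trials, `[[`, "pre_fc"))
  post_mat <- do.call(rbind, lapply(trials, `[[`, "post_fc"))
  for (r in 1:5) {
    direct <- paired_rank_test(pre_mat[, r], post_mat[, r])
    expect_equal(out$p_value[r], direct$p_value)
    expect_equal(out$statistic[r], direct$statistic)
  }
  expect_true(is.na(out$p_value[6]))
  expect_false(out$significant[6])
  expect_equal(attr(out, "threshold"), 0.05 / 6)

  # duplicating the trial list preserves each region's sign pattern direction
  out2 <- per_region_stats(c(trials, trials), alpha = 0.05)
  expect_equal(sign(out2$statistic - 0), sign(out$statistic - 0))
})

test_that("sensory inhibition significantly recruits distant regions, including the hub", {
  sd <- study()
  cfg <- sim_config(lambda = 0.16)
  trials <- lapply(1:50, function(t)
    run_trial_pair(sd$x, sd$profile, cfg, "sens1", 0.009, trial_seed = 700 + t))
  out <- per_region_stats(trials)
  expect_gt(sum(out$significant), nrow(out) / 2)
  hub_row <- out[out$region == "hub1", ]
  expect_true(hub_row$significant)
  hub_change <- mean(sapply(trials, function(tr)
    tr$post_fc[["hub1"]] - tr$pre_fc[["hub1"]]))
  expect_gt(hub_change, 0)
  .study_cache$sens_hub_direct <- hub_change
})

test_that("inhibiting an irrelevant control site leaves the sensory-hub edge unmodulated", {
  sd <- study()
  cfg <- sim_config(lambda = 0.16)
  ctrl <- control_site_experiment(sd$x, sd$profile, cfg, controls = "R070",
                                  hub_id = "hub1", sensory_id = "sens1",
                                  delta_omega = 0.001, n_trials = 30,
                                  base_seed = 900, transform = "raw")
  spill <- abs(mean(ctrl$R070$pair_change))
  direct <- abs(.study_cache$sens_hub_direct)
  expect_lt(spill, 0.05 * direct)

  expect_error(control_site_experiment(sd$x, sd$profile, cfg,
                                       controls = "hub1", hub_id = "hub1",
                                       sensory_id = "sens1"),
               "distinct")
})

test_that("control runs are deterministic and exactly null at zero reduction", {
  st <- toy_study()
  cfg <- fast_config(lambda = 0.3)
  c1 <- control_site_experiment(st$x, st$profile, cfg, controls = "R006",
                                hub_id = "hub1", sensory_id = "sens1",
                                delta_omega = 0.001, n_trials = 6,
                                base_seed = 31)
  c2 <- control_site_experiment(st$x, st$profile, cfg, controls = "R006",
                                hub_id = "hub1", sensory_id = "sens1",
                                delta_omega = 0.001, n_trials = 6,
                                base_seed = 31)
  expect_identical(c1, c2)

  c0 <- control_site_experiment(st$x, st$profile, cfg, controls = "R006",
                                hub_id = "hub1", sensory_id = "sens1",
                                delta_omega = 0, n_trials = 6, base_seed = 31)
  expect_identical(c0$R006$mean_change, 0)
  expect_null(c0$R006$pair_test)
})

test_that("sweep summaries aggregate trial means with their standard errors", {
  st <- toy_study()
  cfg <- fast_config(lambda = 0.3)
  sw <- sweep_delta_omega(st$x, st$profile, cfg, "sens1",
                          deltas = c(0.001, 0.005), n_trials = 4,
                          base_seed = 60)
  expect_equal(dim(sw$trial_means), c(4, 2))
  expect_equal(sw$mean_change, colMeans(sw$trial_means))
  expect_equal(sw$sem, apply(sw$trial_means, 2, sd) / 2)
  expect_true(all(sw$sem >= 0))
  expect_equal(colnames(sw$per_region),
               setdiff(names(st$profile), "sens1"))
  # deterministic under the same base seed
  sw2 <- sweep_delta_omega(st$x, st$profile, cfg, "sens1",
                           deltas = c(0.001, 0.005), n_trials = 4,
                           base_seed = 60)
  expect_identical(sw$trial_means, sw2$trial_means)
  expect_error(sweep_delta_omega(st$x, st$profile, cfg, "sens1",
                                 deltas = c(0.005, 0.001), n_trials = 4),
               "increasing")
})

test_that("the peak reduction resolves ties toward the smallest grid value", {
  sw <- structure(list(deltas = c(0.001, 0.002, 0.003),
                       mean_change = c(0.5, 0.2, 0.1)),
                  class = "sweep_result")
  expect_equal(peak_delta(sw), 0.001)
  sw$mean_change <- c(0.2, 0.5, 0.5)
  expect_equal(peak_delta(sw), 0.002)
  sw$deltas <- 0.004
  sw$mean_change <- 0.3
  expect_equal(peak_delta(sw), 0.004)
})

test_that("calibration selects sensibly on degenerate grids and validates input", {
  st <- toy_study()
  cfg <- fast_config(lambda = 1)
  ref <- generate_reference_fc(st$x, st$profile, lambda_true = 0.5,
                               config = cfg, targets = c("sens1", "hub1"),
                               n_trials = 3, seed = 70)
  cal <- calibrate_lambda(st$x, st$profile, cfg, ref, lambda_grid = 0.5,
                          n_trials = 3, base_seed = 80)
  expect_equal(cal$selected_lambda, 0.5)
  expect_true(all(cal$fit_r >= -1 & cal$fit_r <= 1))

  bad_ref <- list(targets = list(sens1 = rep(0.3, 15)))
  expect_error(calibrate_lambda(st$x, st$profile, cfg, bad_ref,
                                lambda_grid = c(0.1, 0.2)),
               "variance")
  expect_error(calibrate_lambda(st$x, st$profile, cfg, ref,
                                lambda_grid = numeric(0)), "grid")
})

test_that("the default reduction grid spans 1e-5 to 1e-2 in 12 log steps", {
  g <- delta_grid()
  expect_length(g, 12)
  expect_equal(g[1], 1e-5)
  expect_equal(g[12], 1e-2)
  expect_true(all(diff(log10(g)) > 0))
  expect_equal(diff(log10(g)), rep(3 / 11, 11), tolerance = 1e-12)
})
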