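# kuranet

Whole-brain Kuramoto simulation with a strength-dependent hierarchy of
intrinsic timescales, and a "virtual inhibition" experiment framework for
asking how slowing one region's rhythm reshapes its functional
connectivity with the rest of the brain.

## Who this is for

Computational neuroscientists studying how local perturbations (for
example inhibitory TMS) propagate through large-scale brain networks, and
anyone who needs a reproducible, connectome-constrained phase-oscillator
testbed with calibrated coupling, paired perturbation trials and the
standard resting-state metrics (seed-based FC, Fisher z, ALFF,
signed-rank statistics with Bonferroni correction).

## The model

Each of N regions carries a phase θ_i(t) obeying

    dθ_i/dt = Ω_i + λ Σ_j W_ji sin(θ_j − θ_i)

with W the normalized structural connectivity matrix and λ a global
coupling calibrated against baseline functional connectivity. Natural
frequencies encode the timescale hierarchy: with node strength
s_i = Σ_j W_ji,

    ω_i = b − (b − a) · ((s_i − s_min)/(s_max − s_min))^2,

a = 0.01 Hz, b = 0.1 Hz, so high-strength hubs fluctuate slowly and
weakly connected sensory regions fast. Local inhibition is modelled by
reducing the target's ω by Δω and comparing paired simulations that share
initial phases. Slowing a fast sensory node moves it toward the bulk
rhythm and *increases* its connectivity with the network (up to the point
where its frequency meets the network mean); slowing an already-slow hub
moves it away and *decreases* its connectivity.

The simulation core is compiled (RcppArmadillo, Heun integrator); an
8-minute, 128-region run takes a fraction of a second, so hundred-trial
sweeps are routine.

## Worked example

```r
library(kuranet)

# synthetic 128-region connectome with a designated hub and sensory node
x <- normalize_connectome(generate_connectome(connectome_spec()))
profile <- assign_frequencies(node_strength(x))
summarize_frequencies(profile, hub_ids = "hub1", sensory_ids = "sens1")
#> $mean_omega    : 0.0928
#> $omega_hub     : hub1 0.01
#> $omega_sensory : sens1 0.1
#> $hub_below_mean      : TRUE
#> $sensory_above_mean  : TRUE

cfg <- sim_config(lambda = 0.16)   # calibrated coupling for this ensemble
sweep_delta_omega(x, profile, cfg, "sens1",
                  deltas = c(0.001, 0.005, 0.009), n_trials = 20,
                  base_seed = 1)
#>   delta_omega_hz mean_change_z    sem
#> 1          0.001        0.1932 0.0009
#> 2          0.005        1.3948 0.0011
#> 3          0.009        1.6020 0.0010

sweep_delta_omega(x, profile, cfg, "hub1",
                  deltas = c(0.001, 0.005, 0.009), n_trials = 20,
                  base_seed = 1)
#>   delta_omega_hz mean_change_z   sem
#> 1          0.001       -0.0137 0e+00
#> 2          0.005       -0.0675 1e-04
#> 3          0.009       -0.1198 2e-04
```

The frequency summary shows the hierarchy: the hub sits at the slow
bound (0.01 Hz), the sensory node at the fast bound (0.1 Hz), the network
mean in between (0.0928 Hz). The sweeps show the opposite effect
directions: slowing the sensory node raises its mean Fisher-z
connectivity with the other 127 regions (by 1.6 z at Δω = 0.009 Hz,
where its slowed frequency approaches the network mean), while the same
reductions applied to the hub lower its connectivity. Standard errors
are across 20 paired trials.

A command-line interface wrapping these functions is installed at
`exec/kuranet` (subcommands `generate`, `frequencies`, `simulate`,
`sweep`, `calibrate`); every run writes a provenance JSON next to its
outputs.

See `vignettes/virtual-stimulation.Rmd` for the model assumptions,
calibration procedure, the synthetic-connectome design and its
limitations.

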