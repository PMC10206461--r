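#!/usr/bin/env Rscript
# Step 1 — simulate the study system.
#
# Two artefacts:
#   (a) a desk-scale flock (150 hens x 84 days) from the behaviour-level
#       generator, with known variance components — the input for the
#       statistical stages (steps 3-5);
#   (b) a one-week trajectory demo (12 hens) from the trajectory-level
#       generator — a raw zone-transition stream in the tracking format,
#       the input for the extraction stage (step 2).

suppressMessages(library(aviarytraits))
dir.create("results", showWarnings = FALSE)

cfg <- flock_config(n_hens = 150, n_days = 84, seed = 2024)
sim <- simulate_behaviour_table(cfg)
write_behaviours(sim$behaviours, "results/behaviours.csv")
yaml::write_yaml(list(
  sigma_A = apply(sim$truth$sigma_A, 1, as.list),
  true_R = as.list(round(sim$truth$R, 4)),
  vaccination_dates = as.character(sim$calendar$vaccination_dates)),
  "results/ground_truth.yaml")
utils::write.csv(sim$calendar$temperature, "results/temperature.csv",
                 row.names = FALSE)

cat(sprintf("Flock: %d hens x %d days -> %d tracked hen-days (%.1f%% missing)\n",
            cfg$n_hens, cfg$n_days, nrow(sim$behaviours),
            100 * (1 - nrow(sim$behaviours) / (cfg$n_hens * cfg$n_days))))
cat("True latent-scale repeatabilities:\n")
print(round(sim$truth$R, 3))

demo_cfg <- flock_config(n_hens = 12, n_days = 7, seed = 2025,
                         prob_missing = 0)
targets <- behaviour_targets(demo_cfg)
stream <- simulate_transitions(targets, day_schedule(), seed = 2025)
write_transitions(stream, "results/transitions_demo.csv")
utils::write.csv(targets, "results/transition_targets.csv", row.names = FALSE)
cat(sprintf("Trajectory demo: %d transition records for %d hen-days (%d adjusted)\n",
            nrow(stream), nrow(targets), length(attr(stream, "adjustments"))))
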