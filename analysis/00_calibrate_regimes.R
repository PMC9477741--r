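#!/usr/bin/env Rscript
# Calibration of the regime presets.
#
# Each named experimental condition is represented by a two-state
# persistent-random-walk parameter set. This script is the frozen record of
# how those parameters were chosen: a grid search per condition, scoring each
# candidate by the summed relative error of the cohort mean speed, arrest
# coefficient and straightness produced by the *full* analysis pipeline on a
# 500-track simulated cohort (fixed seed). The winning parameters are frozen
# into regime_table(); re-running this script reproduces them.
#
# Conditions for which the study reports only a direction of change
# (flagellin, rag2_steady, ilf_steady) are not calibrated to numbers; their
# presets are fixed by hand to be clearly separated from the arrested
# regimes, and no numeric target is attached to them.
#
# Output: results/calibration_achieved.csv (winner per regime + statistics),
#         results/calibration_grid_<regime>.csv (full scored grids).

suppressPackageStartupMessages(library(villustrack))

dir.create("results", showWarnings = FALSE)
cfg <- sim_config(n_tracks = 500, seed = 20220823)

specs <- list(
  wt_villus_steady = list(
    # villus ILC3s, steady state: speed < 2 um/min, arrest ~90%, straightness ~0.18
    target = c(mean_speed = 1.3, arrest_coefficient = 90, straightness = 0.18),
    grid = expand.grid(p_AP = c(0.015, 0.02, 0.025, 0.03),
                       p_PA = c(0.06, 0.08, 0.10),
                       v_run = c(6, 7, 8),
                       sigma_arrest = 0.06,
                       sigma_turn = c(1.0, 1.2, 1.5))),
  ncr1_steady = list(
    # NKp46+ IL-22+ ILC3s: average speed ~3.4 um/min, most cells (>60%) arrested.
    # Only the speed is printed; the arrest/straightness targets are the
    # package's own choice, set high enough that the winning preset keeps a
    # clear majority of cells above the per-cell arrest cutoff.
    target = c(mean_speed = 3.4, arrest_coefficient = 84, straightness = 0.40),
    grid = expand.grid(p_AP = c(0.008, 0.009, 0.010),
                       p_PA = c(0.07, 0.075, 0.08),
                       v_run = c(28, 31, 34),
                       sigma_arrest = c(0.08, 0.20),
                       sigma_turn = c(0.3, 0.45))),
  t_reconstituted = list(
    # after T cell reconstitution: straightness ~0.25, arrest ~85%, speed < 2.2
    target = c(mean_speed = 1.6, arrest_coefficient = 85, straightness = 0.25),
    grid = expand.grid(p_AP = c(0.015, 0.02, 0.025, 0.03),
                       p_PA = c(0.08, 0.10, 0.12),
                       v_run = c(7, 8, 9),
                       sigma_arrest = 0.08,
                       sigma_turn = c(0.7, 0.85, 1.0))),
  pan_blockade_post = list(
    # after CXCL12/CXCL16/CCL21/CCL25 blockade: arrest > 70%, motility reduced
    target = c(mean_speed = 1.8, arrest_coefficient = 80, straightness = 0.32),
    grid = expand.grid(p_AP = c(0.02, 0.025, 0.03),
                       p_PA = c(0.10, 0.12, 0.15),
                       v_run = c(9, 11, 13),
                       sigma_arrest = 0.08,
                       sigma_turn = c(0.45, 0.6, 0.8))),
  ccl25_blockade_post = list(
    # after CCL25 blockade: speed ~2 um/min, arrest ~85%, straightness ~0.3
    target = c(mean_speed = 2.0, arrest_coefficient = 85, straightness = 0.30),
    grid = expand.grid(p_AP = c(0.015, 0.02, 0.025),
                       p_PA = c(0.10, 0.12, 0.15),
                       v_run = c(10, 12, 14),
                       sigma_arrest = 0.08,
                       sigma_turn = c(0.5, 0.65, 0.8)))
)

rows <- list()
for (nm in names(specs)) {
  sp <- specs[[nm]]
  cat(sprintf("calibrating %s over %d grid points ...\n", nm, nrow(sp$grid)))
  t0 <- Sys.time()
  win <- calibrate_regime(sp$target, sp$grid, cfg = cfg, name = nm)
  ach <- attr(win, "achieved")
  cat(sprintf("  -> p_AP=%g p_PA=%g v_run=%g sigma_arrest=%g sigma_turn=%g\n",
              win$p_AP, win$p_PA, win$v_run, win$sigma_arrest, win$sigma_turn))
  cat(sprintf("  achieved: speed=%.3f arrest=%.2f straightness=%.3f (%.1f s)\n",
              ach$mean_speed, ach$arrest_coefficient, ach$straightness,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  utils::write.csv(attr(win, "grid_results"),
                   sprintf("results/calibration_grid_%s.csv", nm),
                   row.names = FALSE)
  rows[[nm]] <- data.frame(regime = nm, p_AP = win$p_AP, p_PA = win$p_PA,
                           v_run = win$v_run, sigma_arrest = win$sigma_arrest,
                           sigma_turn = win$sigma_turn,
                           target_speed = sp$target["mean_speed"],
                           target_arrest = sp$target["arrest_coefficient"],
                           target_straightness = sp$target["straightness"],
                           achieved_speed = ach$mean_speed,
                           achieved_arrest = ach$arrest_coefficient,
                           achieved_straightness = ach$straightness)
}
out <- do.call(rbind, rows)
utils::write.csv(out, "results/calibration_achieved.csv", row.names = FALSE)
cat("\nfrozen winners written to results/calibration_achieved.csv\n")
print(out, row.names = FALSE)
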