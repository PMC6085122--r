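# shared fixture builders: everything is generated in code at test time

# segment a simulated cohort and join fitted cycles to ground truth
fit_vs_truth <- function(sim, ...) {
  segs <- qc_filter(segment_cohort(sim$traces, ...),
                    frame_interval_min = sim$config$frame_interval_min)
  merge(segs, sim$truth, by = c("cell_id", "cycle_index"))
}

# a clean on-grid noiseless single-cycle configuration: every true phase
# boundary falls exactly on the 3-min frame grid (G1 15, S 36, G2M 6, Ana 12)
ongrid_config <- function(seed = 1) {
  sim_config(n_cells = 1, n_generations = 1, n_mother_cycles = 0,
             a_G1 = 0, V_target_G1 = 29.25, mu_unb = 0.35,
             a_G2M = 0, Vb_target_G2M = 16.8, mu_bud = 0.4,
             T_S_mean = 36, T_S_sd = 0, T_Ana_mean = 12,
             eta_sd = 0, sigma_F = 0, sigma_V = 0, tau_mat_min = 0,
             founder_v_mean = 24, founder_v_sd = 0, seed = seed)
}

# synthetic plateau-ramp-plateau window on the frame grid
make_window <- function(t1 = 15, t2 = 51, F1 = 100, F2 = 200, t_end = 72,
                        by = 3, noise_sd = 0) {
  t <- seq(0, t_end, by = by)
  f <- ifelse(t <= t1, F1, ifelse(t <= t2, F1 + (t - t1) / (t2 - t1) * (F2 - F1), F2))
  if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
  data.frame(t_min = t, fluo_au = f)
}
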