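# Shared fixtures: a fine grid long enough for the 30 s hypoxic bolus to
# return to baseline, and peak relaxation-rate change of a voxel under a
# given inlet (fine-grid sampling so the peak is not aliased).
sim_grid <- function(duration = 150) time_grid(duration)

peak_dr2s <- function(inlet, voxel, ...) {
  s <- simulate_signal_timecourse(inlet, voxel, tr = NULL, ...)
  max(signal_to_relaxation(s)$dr2s)
}

fig2_inlets <- function(grid = sim_grid()) {
  list(
    dohb = hypoxic_bolus(grid, base_sat = 0.98, target_sat = 0.75,
                         plateau_duration = 30, onset = 10),
    gd = gamma_variate_bolus(grid, a = 2, b = 2.5, c = 3, onset = 10)
  )
}
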