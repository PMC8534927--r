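# Shared parameter sets and lazily cached runs.  Everything is generated in
# code with fixed seeds; heavy runs are built once per test session.

high_load <- function(...) kinetics_params(Satt = 0.8, ...)
low_load <- function(...) kinetics_params(Satt = 0.2, ...)
# unit-step (TASEP) limit: secondaries pinned full, one lane, pure forward
tasep_kin <- function() kinetics_params(Satt = 1, Sdet = 0, Px = 1, Py = 0)
# effective unit hop rate in the TASEP limit at the study kinetics
tasep_r <- 0.8

.run_cache <- new.env(parent = emptyenv())
cached <- function(name, maker) {
  if (!exists(name, envir = .run_cache)) assign(name, maker(), envir = .run_cache)
  get(name, envir = .run_cache)
}

# quasi-2D runs reused by several observable tests
run_hd_highload <- function() cached("hd_high", function()
  simulate_run(run_config(lattice_config(300, 4), high_load(),
                          boundary_rates(0.9, 0.3),
                          warmup = 10000, sample = 30000, seed = 23)))
run_ld_lowload <- function() cached("ld_low", function()
  simulate_run(run_config(lattice_config(300, 4), low_load(),
                          boundary_rates(0.2, 0.9),
                          warmup = 10000, sample = 30000, seed = 24)))
run_hd_lowload <- function() cached("hd_low", function()
  simulate_run(run_config(lattice_config(300, 4), low_load(),
                          boundary_rates(0.9, 0.2),
                          warmup = 10000, sample = 30000, seed = 25)))

# single-motor trajectory ensemble on an empty cylinder (high-load defaults)
msd_ensemble_fixture <- function() cached("msd_fix", function()
  single_motor_ensemble(n = 200, Lx = 300, Ly = 4,
                        kinetics = kinetics_params(), seed = 900))
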