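# 01 — Simulate the study colony.
#
# Generates ARGOS-like fixes for a small colony of central-place foragers
# (two haulout sites, repeated foraging trips to offshore patches), plus a
# shelf bathymetry grid and its Horn slope. Writes:
#   fixes.csv        raw simulated ARGOS fixes (with class errors, wet/dry)
#   truth.csv        noise-free positions and behavioural states
#   bathymetry.asc   synthetic shelf bathymetry (ESRI ASCII)
#   slope.asc        seafloor slope, degrees

source(file.path("analysis", "_common.R"))

sims <- lapply(seq_len(CFG$n_animals), function(i) {
  cfg <- sim_config(seed = SEED + i,
                    colony = c(135.0 + 0.4 * (i - 1), -34.5),
                    n_trips = CFG$n_trips,
                    trip_hours = CFG$trip_hours,
                    haulout_hours = CFG$haulout_hours,
                    patch_centers = list(c(135.0 + 0.4 * (i - 1) + 0.15,
                                           -34.75)),
                    animal_id = sprintf("sim%02d", i))
  simulate_tracks(cfg)
})

fixes <- do.call(rbind, lapply(sims, `[[`, "fixes"))
write_fixes_csv(fixes, rpath("fixes.csv"))

truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
truth$t <- format(truth$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
write.csv(truth, rpath("truth.csv"), row.names = FALSE, quote = FALSE)

bathy <- simulate_bathymetry(sim_config(seed = SEED), half_extent_deg = 1.5)
write_esri_ascii(bathy, rpath("bathymetry.asc"))
write_esri_ascii(grid_slope(bathy), rpath("slope.asc"))

message(sprintf("simulated %d animals, %d fixes -> %s",
                length(sims), nrow(fixes), RESULTS))
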