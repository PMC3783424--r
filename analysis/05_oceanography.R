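# 05 — Water-column structure along the tracks.
#
# Simulates animal-borne CTD casts at every 4th at-sea position, then for
# each cast computes sigma-theta (EOS-80), mixed layer depth (0.125 kg m-3
# vs the 4-m reference), thermocline intensity, benthic temperature /
# salinity / transition-layer thickness, and the strict upwelled-water
# flag (T < 17 degC, sigma-theta > 26, S < 35.6). Monthly benthic fields
# are gridded by inverse-distance weighting. Writes:
#   ctd_profiles.csv       simulated cast levels
#   water_column.csv       per-cast descriptors + upwelling flag
#   benthic_temp_mXX.asc   monthly benthic temperature fields

source(file.path("analysis", "_common.R"))

tracks <- rebuild_tracks()
bathy <- read_esri_ascii(rpath("bathymetry.asc"))
ocfg <- ocean_config()

profs <- list()
for (ai in seq_along(tracks)) {
  tr <- tracks[[ai]]
  at_sea <- tr$interp[which(tr$interp$wet), ]
  locs <- at_sea[seq(1, nrow(at_sea), by = CFG$profile_every), ]
  locs$bottom_m <- pmax(6, sample_grid(bathy, locs$lon, locs$lat))
  sim <- simulate_ctd_profiles(locs, ocfg, seed = SEED + 100 + ai,
                               animal_id = tr$animal_id)
  sim$profiles$profile_id <- paste0(tr$animal_id, "_",
                                    sim$profiles$profile_id)
  profs[[ai]] <- sim$profiles
}
profiles <- do.call(rbind, profs)
write_ctd_csv(profiles, rpath("ctd_profiles.csv"))

wc <- summarize_profiles(profiles, delta = CFG$delta_sigma,
                         surface_ref_depth = CFG$surface_ref_m)
out <- wc; out$t <- format(out$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
write.csv(out, rpath("water_column.csv"), row.names = FALSE, quote = FALSE)

gspec <- raster_grid(matrix(0, ceiling(2.4 / CFG$field_cell_deg),
                            ceiling(3 / CFG$field_cell_deg)),
                     xll = 133.8, yll = -35.7,
                     cellsize = CFG$field_cell_deg)
for (m in sort(unique(wc$month))) {
  sub <- wc[wc$month == m, ]
  fld <- monthly_field(sub$lon, sub$lat, sub$benthic_temp, gspec,
                       power = CFG$idw_power, max_dist = CFG$idw_max_dist_km)
  write_esri_ascii(fld, rpath(sprintf("benthic_temp_m%02d.asc", m)))
}

message(sprintf("%d casts; upwelled benthic water at %.0f%% of casts",
                nrow(wc), 100 * mean(wc$upwelled, na.rm = TRUE)))
message(sprintf("MLD range %.1f-%.1f m", min(wc$mld_m), max(wc$mld_m)))
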