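# Shared setup for the numbered analysis scripts. Each script does
#   source(file.path("analysis", "_common.R"))
# and reads/writes under RESULTS. Run the scripts in order from the
# repository root:
#   Rscript analysis/01_simulate_colony.R
#   Rscript analysis/02_process_tracks.R
#   ...

suppressPackageStartupMessages(library(aslforage))

SEED <- as.integer(Sys.getenv("ASL_SEED", "42"))
RESULTS <- Sys.getenv("ASL_RESULTS", "results/analysis")
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)
rpath <- function(...) file.path(RESULTS, ...)

# analysis constants (see pipeline_config() for the same defaults)
CFG <- pipeline_config()

# Rebuild the cleaned + interpolated per-animal tracks from the raw fixes
# written by 01_simulate_colony.R. Cleaning is deterministic, so every
# downstream script sees identical tracks.
rebuild_tracks <- function() {
  fixes <- read_fixes_csv(rpath("fixes.csv"))
  lapply(split(fixes, fixes$animal_id), function(f) {
    f <- drop_unclassified(f)
    f <- dedup_fixes(f)
    f <- speed_filter(f, vmax = CFG$vmax)
    ip <- interpolate_track(f, dt = CFG$dt_h, mode = CFG$interp_mode)
    ip$wet <- f$wet[findInterval(as.numeric(ip$t), as.numeric(f$t),
                                 rightmost.closed = FALSE)]
    list(animal_id = f$animal_id[1], fixes = f, interp = ip)
  })
}

# interpolated positions of one foraging trip
trip_positions <- function(tr, window) {
  tr$interp[tr$interp$t >= window$start_t & tr$interp$t <= window$end_t, ]
}
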