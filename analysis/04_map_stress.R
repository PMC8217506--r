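#!/usr/bin/env Rscript
# Stage 4 -- vessel-stress mapping and exceedance areas.
# Assigns each tissue element the peak tensile axial stress of the beams
# in its neighbourhood and quantifies the slice area above 150/200/250/300
# kPa, the thresholds compared against extravasation imaging.

suppressPackageStartupMessages(library(vascufem))
geo <- readRDS("results/run/geometry.rds")
h <- readRDS("results/run/macro_history.rds")
map <- map_vessel_stress(h, geo$mesh, geo$beams)
areas <- threshold_area(map, geo$mesh,
                        slice = list(axis = 2, coordinate = 4000))
print(areas)
saveRDS(map, "results/run/stress_map.rds")
utils::write.csv(areas, "results/run/threshold_areas.csv",
                 row.names = FALSE)
message("stage 4 done: results/run/{stress_map.rds,threshold_areas.csv}")
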