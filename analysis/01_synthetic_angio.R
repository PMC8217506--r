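#!/usr/bin/env Rscript
# Stage 1 -- synthetic angioarchitecture and tissue volume.
# Generates the calibrated vascular network (diameters 10-100 um, mean
# 17.85 um, volume fraction 5.4%) for the cortical slab of the demo block,
# plus a segmented tissue image, and writes both with their statistics.

suppressPackageStartupMessages(library(vascufem))
dir.create("results/run", showWarnings = FALSE, recursive = TRUE)
cfg <- default_config()
write_run_config(cfg, "results/run/config.yaml")

set.seed(cfg$seeds$network)
# vascular slab under the impact site (um)
net <- generate_network(c(6000, 6000, 2600),
                        vessel_calibration(max_active_tips = 256),
                        seed = cfg$seeds$network)
stats <- network_stats(net)
message(sprintf("generated %d segments | mean diameter %.2f um | vf %.2f%%",
                stats$n_segments, stats$mean_diameter,
                100 * stats$volume_fraction))

# the demo simulation carries a 500-segment subsample of this network
keep <- sort(sample(nrow(net$segments), 500))
sub <- net
sub$segments <- net$segments[keep, ]
used <- sort(unique(c(sub$segments$node_a, sub$segments$node_b)))
remap <- integer(nrow(net$nodes))
remap[used] <- seq_along(used)
sub$nodes <- net$nodes[used, ]
sub$segments$node_a <- remap[sub$segments$node_a]
sub$segments$node_b <- remap[sub$segments$node_b]
# position the slab 1 mm in from the block faces, flush under the surface
sub$nodes$x <- sub$nodes$x + 1000
sub$nodes$y <- sub$nodes$y + 1000
sub$nodes$z <- sub$nodes$z + 5200

write_network(sub, "results/run/network")
write_network_json(sub, "results/run/network.json")
utils::write.csv(data.frame(statistic = names(unlist(stats)),
                            value = as.numeric(unlist(stats))),
                 "results/run/network_stats.csv", row.names = FALSE)

# coarse tissue volume for meshing (30 um voxels keep the demo light;
# the 5.92 um default is exercised in the unit tests)
img <- generate_tissue_image(c(8000, 8000, 8000), spacing = 400 / 3,
                             seed = cfg$seeds$image)
write_voxel_image(img, "results/run/tissue_volume.txt")
message("stage 1 done: results/run/{network*,tissue_volume.txt}")
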