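#!/usr/bin/env Rscript
# Stage 2 -- voxel meshing and beam discretization.
# Thresholds the tissue volume, builds the hexahedral block mesh (400 um
# elements after 3x coarsening) and splits the vascular centrelines into
# beam elements with per-node radii.

suppressPackageStartupMessages(library(vascufem))
img <- read_voxel_image("results/run/tissue_volume.txt")
mask <- segment_image(img, 100)
mesh <- voxelize(mask, img$spacing, coarsen = 3)
message(sprintf("tissue mesh: %d nodes, %d hexahedra (%.0f um)",
                nrow(mesh$nodes), nrow(mesh$elements),
                mesh$element_size[1]))

net <- read_network_json("results/run/network.json")
beams <- discretize_network(net, max_len = 150)
message(sprintf("vasculature: %d beam elements from %d segments",
                nrow(beams$elements), nrow(net$segments)))

saveRDS(list(mesh = mesh, beams = beams), "results/run/geometry.rds")
message("stage 2 done: results/run/geometry.rds")
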