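#!/usr/bin/env Rscript
# Stage 5 -- microscale submodel of the high-deformation region.
# Refines the region under the impactor rim (highest strain and shear),
# clips the beams to it and re-solves with displacement boundary
# conditions interpolated from the macro solution.

suppressPackageStartupMessages(library(vascufem))
geo <- readRDS("results/run/geometry.rds")
h <- readRDS("results/run/macro_history.rds")
spec <- submodel_spec(c(3200, 3200, 5200), c(4800, 4800, 7600),
                      refinement = 2)
sub <- extract_submodel(geo$mesh, geo$beams, spec)
message(sprintf("submodel: %d hexahedra (%.0f um), %d beams",
                nrow(sub$mesh$elements), sub$mesh$element_size[1],
                if (is.null(sub$beams)) 0L else nrow(sub$beams$elements)))
hs <- run_submodel(sub, h, controls = solver_controls(t_end = 1))
saveRDS(list(sub = sub, history = hs), "results/run/micro.rds")
message("stage 5 done: results/run/micro.rds")
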