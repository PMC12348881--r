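#!/usr/bin/env Rscript
# Generate the synthetic study data: a 3D co-culture stack (B and T cells
# on a stromal scaffold), its ground truth, a scaffold-only volume, and a
# toy DE/PPI omics bundle. All downstream analyses read from results/data.

suppressPackageStartupMessages(library(nichequant))

seed <- 42L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

p <- sim_params(seed = seed)  # 64x128x128, 50 B : 5 T, diameter 6.2 px
sim <- generate_coculture_stack(p)
write_stack(sim$stack, file.path(out, "coculture_stack.tif"))
write_labels(sim$labels, file.path(out, "labels_truth.tif"))
write_ground_truth(sim$truth, file.path(out, "truth.json"))

sv <- generate_scaffold_volume(
  sim_params(shape = c(48L, 96L, 96L), scaffold_density = 0.03, seed = seed))
write_stack(list(CD90 = sv$channel), file.path(out, "scaffold_channel.tif"))
write_labels(array(as.integer(sv$mask), dim = dim(sv$mask)),
             file.path(out, "scaffold_truth.tif"))

bundle <- generate_omics_bundle(n_genes = 100, n_planted = 6, seed = seed)
write_omics_bundle(bundle, file.path(out, "omics"))

tc <- sim$truth$cells
cat(sprintf(
  "Simulated %d cells (%d B, %d T), %d planted adjacent B-T pairs, %d apoptotic B cells.\n",
  nrow(tc), sum(tc$type == "B"), sum(tc$type == "T"),
  sum(!is.na(tc$coloc_partner_id)) / 2, sum(tc$apoptotic)))
cat(sprintf("Scaffold mask: %d voxels, %d planted crosstalk edges.\n",
            sum(sv$mask), nrow(bundle$planted)))
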