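#!/usr/bin/env Rscript
# Phenotype the segmented cells: per-mask CD19/CD3 intensities, per-stack
# sum scaling and log transform, pooled percentile thresholds (40th CD19 /
# 95th CD3), classification, co-localization counting, and the caspase-3
# apoptotic fraction across simulated treatment conditions.

suppressPackageStartupMessages(library(nichequant))

data_dir <- "results/data"
out <- "results"

stack <- read_stack(file.path(data_dir, "coculture_stack.tif"))
labs <- read_labels(file.path(out, "labels_segmented.tif"))
labs <- array(as.integer(labs), dim = dim(labs))
truth <- read_ground_truth(file.path(data_dir, "truth.json"))

tab <- normalize_intensities(extract_mask_intensities(
  labs, stack, c("CD19", "CD3", "CASP3"), stack_id = "stack42"))
thr <- pool_and_threshold(tab, c(CD19 = 40, CD3 = 95))
tab <- classify_cells(tab, thr)
cc <- count_colocalized(labs, tab, mode = "double_pos_or_adjacent",
                        markers = c("CD19", "CD3"))
write.csv(cc$table, file.path(out, "cell_table.csv"), row.names = FALSE)
write.csv(cc$counts, file.path(out, "stack_counts.csv"), row.names = FALSE)

tc <- truth$cells
cat(sprintf("Classified %d masks: %d CD19+, %d CD3+ (planted %d B, %d T).\n",
            cc$counts$n_total_masks, cc$counts$n_cd19, cc$counts$n_cd3,
            sum(tc$type == "B"), sum(tc$type == "T")))
cat(sprintf("Co-localized (double-positive or adjacent): %d masks.\n",
            cc$counts$n_coloc))

# apoptosis: an untreated control and a treated condition with a higher
# planted apoptotic fraction, 4 z-stacks each
mk <- function(frac, seed) {
  sim <- generate_coculture_stack(sim_params(frac_apoptotic_b = frac,
                                             seed = seed))
  normalize_intensities(extract_mask_intensities(
    sim$labels, sim$stack, c("CD19", "CD3", "CASP3"),
    stack_id = paste0("f", frac, "s", seed)))
}
conds <- list(control = lapply(101:104, mk, frac = 0.1),
              ap1_inhibitor = lapply(201:204, mk, frac = 0.3))
thr2 <- pool_and_threshold(unlist(conds, recursive = FALSE))
conds <- lapply(conds, function(l) lapply(l, classify_cells,
                                          thresholds = thr2))
apo <- quantify_apoptosis(conds, control = "control")
write.csv(apo$summary, file.path(out, "apoptosis_summary.csv"),
          row.names = FALSE)
print(apo$summary, row.names = FALSE)
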