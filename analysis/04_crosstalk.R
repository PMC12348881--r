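#!/usr/bin/env Rscript
# Cross-reference the PPI edge table against the B-cell core-vs-periphery
# DE genes and the stromal-cluster DE genes (adjusted p < 0.05 and >= 10%
# expressing cells), classify the surviving edges, and flag
# condition-exclusive stromal clusters.

suppressPackageStartupMessages(library(nichequant))

data_dir <- "results/data/omics"
out <- "results"

ppi <- read_ppi_table(file.path(data_dir, "ppi.tsv"), "generic_tsv")
b_de <- read_b_de_table(file.path(data_dir, "b_de.tsv"))
cl_de <- read_cluster_de_table(file.path(data_dir, "cluster_de.tsv"))
planted <- read.delim(file.path(data_dir, "planted.tsv"))

bmsc_map <- filter_bmsc_genes(cl_de, min_pct = 0.10, alpha = 0.05)
res <- cross_reference(ppi, b_de, bmsc_map)
write.csv(res, file.path(out, "interactions.csv"), row.names = FALSE)

key <- function(df) paste(pmin(df$gene_a, df$gene_b),
                          pmax(df$gene_a, df$gene_b), df$class)
cat(sprintf("PPI edges in: %d; records surviving cross-reference: %d\n",
            nrow(ppi), nrow(res)))
cat(sprintf("Planted edges recovered: %d of %d; decoys surviving: %d\n",
            sum(key(planted) %in% key(res)), nrow(planted),
            sum(!(key(res) %in% key(planted)))))
print(table(res$class))

# condition-exclusivity on a toy stromal clustering: cluster 5 only
# contains cells from the tumor-contact condition
set.seed(42)
assignments <- c(rep(0, 150), rep(1, 80), rep(5, 60))
conditions <- c(sample(rep(c("contact", "control"), 75)),
                sample(rep(c("contact", "control"), 40)),
                rep("contact", 60))
excl <- condition_exclusivity(assignments, conditions, exclusive_min = 0.95)
write.csv(excl, file.path(out, "cluster_exclusivity.csv"), row.names = FALSE)
cat("Condition-exclusive clusters:",
    paste(excl$cluster[excl$exclusive], collapse = ", "), "\n")
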