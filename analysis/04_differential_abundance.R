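#!/usr/bin/env Rscript
# Stage 4: summarize the group comparisons computed by stage 3 — the
# enrichment-trend classification (abundance fold-change > 4 between
# conditions) and the monocyte MSI permutation tests for the activation
# markers the disease condition shifts.

adir <- file.path("results", "analysis")

etc <- read.table(file.path(adir, "etc_labels.tsv"), header = TRUE,
                  sep = "\t")
cat("Enrichment-trend classification of the", nrow(etc), "clusters:\n")
print(table(etc$label))

hm <- read.csv(file.path(adir, "categorical_heatmap.csv"),
               check.names = FALSE)
mono <- hm$population == "monocyte"
cat("\nMonocyte clusters:", sum(mono), "(",
    sum(mono & etc$label == "enriched_HIV"), "HIV-enriched /",
    sum(mono & etc$label == "enriched_HEA"), "HEA-enriched )\n")

shifted <- c("CD11a", "CD11b", "CD32", "CD38", "CD64", "CD83", "CD86",
             "TLR2")
hiv_cl <- mono & etc$label == "enriched_HIV"
hea_cl <- mono & etc$label == "enriched_HEA"
cat("\nCategory range per activation marker (HEA-enriched vs HIV-enriched",
    "monocyte clusters):\n")
for (mk in shifted) {
  cat(sprintf("  %-6s HEA %d-%d  HIV %d-%d\n", mk,
              min(hm[hea_cl, mk]), max(hm[hea_cl, mk]),
              min(hm[hiv_cl, mk]), max(hm[hiv_cl, mk])))
}

msi_path <- file.path(adir, "monocyte_msi_tests.tsv")
if (file.exists(msi_path)) {
  msi <- read.table(msi_path, header = TRUE, sep = "\t")
  cat("\nMonocyte MSI permutation tests (HIV vs HEA):\n")
  print(msi, row.names = FALSE)
} else {
  cat("\nNo monocyte MSI table was produced for this run.\n")
}
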