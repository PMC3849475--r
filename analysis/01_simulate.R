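#!/usr/bin/env Rscript
# Step 1 — simulate a drug-target world with known ground truth.
#
# Generates the default four-cluster synthetic dataset (depressants,
# stimulants, analgesics, steroids; 20 drugs x 15 genes per cluster; one
# boosted hub drug per cluster; two bridge genes joining the cluster pairs)
# and writes the DrugBank-dialect XML, the accession-to-gene mapping, the
# ground truth and a config echo under results/synthetic/. Also writes an
# external 62-gene candidate list with 17 genes planted inside the illicit
# target-gene set.

library(illicitnet)

seed <- 20130101L
cfg <- synthetic_config(seed = seed)
gen <- generate_synthetic(cfg)
paths <- write_synthetic_bundle(gen, "results/synthetic")

overlap <- min(17L, length(gen$ground_truth$illicit_target_genes))
cand <- generate_candidate_list(gen$ground_truth, overlap_count = overlap,
                                decoy_count = 62L - overlap, seed = seed)
writeLines(cand, "results/synthetic/candidate_genes.txt")

cat("simulated", length(gen$records), "drugs over",
    nrow(gen$mapping), "genes;",
    length(gen$ground_truth$illicit_drugs), "illicit drugs,",
    length(gen$ground_truth$illicit_target_genes), "illicit target genes\n")
cat("planted hubs:", paste(gen$ground_truth$hub_drugs, collapse = ", "), "\n")
cat("planted bridges:", paste(gen$ground_truth$bridge_genes, collapse = ", "),
    "\n")
cat("candidate list: ", length(cand), " genes, ", overlap,
    " inside the illicit target set\n", sep = "")
cat("wrote:", paste(basename(c(paths, "candidate_genes.txt")),
                    collapse = ", "), "-> results/synthetic/\n")
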