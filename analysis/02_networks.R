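#!/usr/bin/env Rscript
# Step 2 — build the three drug-target networks from the simulated files.
#
# Reads the XML and mapping written by 01_simulate.R the same way a real
# DrugBank-dialect export would be read, then builds: (1) the illicit
# drug-target network, (2) the illicit-extended network (illicit-related
# drugs restricted to illicit target genes), (3) the full network; and the
# illicit / illicit-related / other drug partition. Edge lists, the
# partition table and SIF/GraphML exports go to results/networks/.

library(illicitnet)

records <- parse_drugbank("results/synthetic/drugbank.xml")
mapping <- load_gene_mapping("results/synthetic/gene_mapping.tsv")

illicit <- select_illicit(records)
full_net <- build_network(records, mapping)
illicit_net <- build_network(records, mapping, drug_filter = illicit)
extended_net <- build_extended(records, mapping, illicit)
partition <- partition_drugs(records, mapping)

dir.create("results/networks", showWarnings = FALSE, recursive = TRUE)
names_of <- stats::setNames(vapply(records, `[[`, "", "name"),
                            vapply(records, `[[`, "", "drug_id"))
write_edge_list(illicit_net, "results/networks/illicit_edges.tsv", names_of)
write_edge_list(extended_net, "results/networks/extended_edges.tsv", names_of)
write_edge_list(full_net, "results/networks/full_edges.tsv", names_of)
write_partition(partition, "results/networks/partition.tsv")
export_sif(extended_net, "results/networks/extended.sif")

report <- function(label, net) {
  cat(sprintf("%-9s %4d drugs  %3d genes  %4d edges  drug deg %.2f  gene deg %.2f\n",
              label, length(net$drugs), length(net$genes), nrow(net$edges),
              nrow(net$edges) / length(net$drugs),
              nrow(net$edges) / length(net$genes)))
}
report("illicit", illicit_net)
report("extended", extended_net)
report("full", full_net)
print(partition)

# structural identities that must hold by construction
stopifnot(
  length(extended_net$drugs) + length(extended_net$genes) ==
    sum(extended_net$drug_labels == "illicit") +
    sum(extended_net$drug_labels == "illicit-related") +
    length(extended_net$genes),
  all(paste(illicit_net$edges$drug_id, illicit_net$edges$gene_symbol) %in%
        paste(extended_net$edges$drug_id, extended_net$edges$gene_symbol)))
cat("extended-network node identity and subgraph inclusion verified\n")
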