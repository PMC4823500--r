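#!/usr/bin/env Rscript
# Ingest the study tables (score filter > 0.4, self-loop and duplicate
# removal, PPI source merging) and build the three networks: the
# compound-target bipartite network, the herb-target-disease network, and
# the first-neighbor PPI expansion network. Exports GraphML/SIF/TSV under
# results/paper_study/networks/.

library(pharmnet)

fix <- fixture_paths("results/paper_study/fixture")
out <- "results/paper_study/networks"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

compounds <- read_compound_table(fix$compounds)
cti <- read_interaction_table(fix$compound_interactions, min_score = 0.4)
disease <- read_disease_targets(fix$disease_targets)
ppi <- merge_ppi_sources(lapply(fix$ppi, read_interaction_table,
                                min_score = 0.4))

net1 <- build_compound_target_network(compounds, cti)
net2 <- build_herb_target_disease_network(compounds, cti, disease, ppi)
net3 <- build_ppi_expansion_network(compound_target_ids(compounds, cti),
                                    disease, ppi)

for (net in list(net1, net2, net3)) {
  write_network_graphml(net, file.path(out, paste0(net$name, ".graphml")))
  write_network_sif(net, file.path(out, paste0(net$name, ".sif")))
  write_edge_tsv(net, file.path(out, paste0(net$name, "_edges.tsv")))
  tal <- role_tally(net)
  cat(sprintf("%-22s %4d nodes %5d edges  (%s)\n", net$name,
              igraph::vcount(net), igraph::ecount(net),
              paste(names(tal), tal, sep = "=", collapse = ", ")))
}
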