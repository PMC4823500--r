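#!/usr/bin/env Rscript
# Functional-term enrichment of the nominated potential targets against the
# study's annotation table: fold enrichment and EASE-variant hypergeometric
# p-values, sorted by p. Writes results/paper_study/enrichment.tsv.

library(pharmnet)

ann <- read_annotation_table("results/paper_study/fixture/annotations.gmt")
hubs <- jsonlite::read_json("results/paper_study/hubs/hub_selection.json",
                            simplifyVector = TRUE)
study <- hubs$potential_targets

res <- enrich(study, ann, ease = TRUE, correction = "BH")
write_enrichment_tsv(res, "results/paper_study/enrichment.tsv")

cat("study set:", length(study), "potential targets;",
    nrow(res), "terms with at least one hit\n\n")
print(head(res[, c("term_id", "term_name", "k", "K", "fold", "p", "q")], 5),
      row.names = FALSE)
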