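#!/usr/bin/env Rscript
# rADG growth classes, farm and enterotype effects on family abundances,
# weaning percent changes, and the two-step growth-class procedure.

library(weanotype)

tab <- read_count_table("results/filtered_counts.tsv")
taxonomy <- read_taxonomy("results/data/taxonomy.tsv")
metadata <- read_metadata("results/data/metadata.tsv")
md <- metadata[match(rownames(tab), metadata$sample_id), ]

records <- classify_within_farm(compute_radg(metadata))
print(class_summary(records), row.names = FALSE)
utils::write.table(records, "results/growth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

rel_family <- to_relative(aggregate_taxa(tab, taxonomy, "family"))
rel_genus <- to_relative(aggregate_taxa(tab, taxonomy, "genus"))

pc <- percent_change(rel_family, md)
sig <- pc[!pc$undefined & pc$p_adj < 0.05, ]
sig <- sig[order(-abs(sig$percent_change)), ]
cat("\nfamilies with significant d26 -> d35 change (BH p < 0.05):\n")
print(head(data.frame(family = sig$taxon,
                      change = sprintf("%+.0f%%", sig$percent_change),
                      p_adj = signif(sig$p_adj, 2)), 12), row.names = FALSE)
utils::write.table(pc, "results/percent_change.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

i26 <- md$age_point == "d26"
kw26 <- kruskal_dunn(rel_family[i26, ], md$farm_id[i26])$tests
kw35 <- kruskal_dunn(rel_family[!i26, ], md$farm_id[!i26])$tests
cat("\nfamilies with a farm effect (KW, BH p < 0.05): d26:",
    sum(kw26$p_adj < 0.05), "of", nrow(kw26), "| d35:",
    sum(kw35$p_adj < 0.05), "of", nrow(kw35), "\n")

ts <- two_step_radg(rel_genus, records, md, alpha_pre = 0.1,
                    n_perm = 5000, seed = derive_seed(1, "two_step"))
cat("\ntwo-step rADG procedure:", length(ts$retained),
    "genera retained at step 1 (BH p < 0.1);",
    ts$n_pigs_step2, "complete pigs in step 2\n")
if (!is.null(ts$step2)) {
  s2 <- ts$step2[order(ts$step2$p_interaction), ]
  cat("strongest class-by-age interactions:\n")
  print(head(data.frame(genus = s2$taxon,
                        p_class = signif(s2$p_class, 2),
                        p_interaction = signif(s2$p_interaction, 2)), 8),
        row.names = FALSE)
  utils::write.table(ts$step2, "results/two_step.tsv", sep = "\t",
                     quote = FALSE, row.names = FALSE)
}
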