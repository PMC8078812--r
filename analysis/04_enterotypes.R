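#!/usr/bin/env Rscript
# Enterotype discovery on genus-level relative abundances: JSD + PAM with
# CH-based selection of K, silhouette validation against random subsets,
# and d26 -> d35 transition dynamics.

library(weanotype)

tab <- read_count_table("results/filtered_counts.tsv")
taxonomy <- read_taxonomy("results/data/taxonomy.tsv")
metadata <- read_metadata("results/data/metadata.tsv")

rel_genus <- to_relative(aggregate_taxa(tab, taxonomy, "genus"))
sol <- choose_k(rel_genus, k_range = 2:8, pseudocount = 1e-6)
print(sol)

val <- silhouette_validation(rel_genus, sol, n_subsets = 100, frac = 0.8,
                             seed = derive_seed(1, "silhouette"))
cat(sprintf("mean silhouette %.3f sits at the %.0fth percentile of %d random subsets\n",
            val$observed, val$percentile, length(val$null)))

tr <- enterotype_transitions(sol$labels, metadata)
cat("\nd26 -> d35 transition counts over", tr$n_pigs, "complete pigs:\n")
print(tr$counts)
cat(sprintf("shift fraction: %.3f\n", tr$shift_fraction))

cat("\nper-enterotype mean abundance (%) of the discriminating genera:\n")
key <- intersect(c("Prevotella", "Faecalibacterium", "Roseburia",
                   "Lachnospira", "Bacteroides"), colnames(sol$profiles))
print(round(100 * sol$profiles[, key], 2))

utils::write.table(
  data.frame(sample_id = names(sol$labels),
             enterotype = paste0("E", sol$labels)),
  "results/enterotypes.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(k = as.integer(names(sol$ch_curve)), ch = sol$ch_curve),
  "results/ch_curve.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(as.data.frame(tr$counts), "results/transitions.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nwrote results/{enterotypes,ch_curve,transitions}.tsv\n")
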