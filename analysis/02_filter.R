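#!/usr/bin/env Rscript
# Quality control and OTU filtering: drop samples under 5000 reads, keep
# known-phylum OTUs present in >=5 samples with >0.01% of total reads, and
# rarefy to 4831 reads for alpha diversity.

library(weanotype)

counts <- read_count_table("results/data/counts.tsv")
taxonomy <- read_taxonomy("results/data/taxonomy.tsv")
metadata <- read_metadata("results/data/metadata.tsv")

cat("input:", nrow(counts), "samples x", ncol(counts), "OTUs\n")
tab <- qc_filter_samples(counts, min_reads = 5000)
cat("QC: excluded", length(attr(tab, "excluded")),
    "samples under 5000 reads\n")
tab <- filter_otus(tab, taxonomy, min_prevalence = 5, min_frac_total = 1e-4)
md <- metadata[metadata$sample_id %in% rownames(tab), ]
cat("filtered table:", nrow(tab), "samples x", ncol(tab), "OTUs;",
    sum(md$age_point == "d26"), "at d26,",
    sum(md$age_point == "d35"), "at d35\n")

write_count_table(tab, "results/filtered_counts.tsv")
rar <- rarefy(tab, depth = 4831, seed = derive_seed(1, "rarefy"))
write_count_table(rar, "results/rarefied_counts.tsv")
cat("wrote results/filtered_counts.tsv and results/rarefied_counts.tsv\n")
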