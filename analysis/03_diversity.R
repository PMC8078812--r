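#!/usr/bin/env Rscript
# Alpha diversity by age, beta diversity with PERMANOVA on age, and the
# farm dispersion-homogeneity caveat.

library(weanotype)

rar <- read_count_table("results/rarefied_counts.tsv")
tab <- read_count_table("results/filtered_counts.tsv")
metadata <- read_metadata("results/data/metadata.tsv")
md <- metadata[match(rownames(tab), metadata$sample_id), ]

alpha <- alpha_diversity(rar)
alpha$age_point <- md$age_point[match(alpha$sample_id, md$sample_id)]
by_age <- aggregate(cbind(richness, shannon) ~ age_point, alpha, mean)
cat("alpha diversity by age (rarefied to 4831 reads):\n")
print(by_age, row.names = FALSE)
utils::write.table(alpha, "results/alpha.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

d <- beta_distance(to_relative(tab), "bray_curtis")
ad <- permanova(d, md$age_point, n_perm = 999,
                seed = derive_seed(1, "permanova"))
cat(sprintf("\nage PERMANOVA (Bray-Curtis, 999 perms): F = %.2f, p = %.3g\n",
            ad$F, ad$p))
disp <- dispersion_test(d, md$farm_id, n_perm = 999,
                        seed = derive_seed(1, "dispersion"))
cat(sprintf("farm dispersion test: F = %.2f, p = %.3g\n", disp$F, disp$p))
if (disp$p < 0.05)
  cat("farm dispersions are heterogeneous: a farm PERMANOVA would conflate",
      "location and dispersion, so it is reported with this caveat\n")
adf <- permanova(d, md$farm_id, n_perm = 999,
                 seed = derive_seed(1, "permanova_farm"))
cat(sprintf("farm PERMANOVA (interpret with caveat): F = %.2f, p = %.3g\n",
            adf$F, adf$p))
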