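# Shared fixtures, all built in code.

toy_counts <- function() {
  count_table(matrix(c(5L, 0L, 2L,
                       1L, 3L, 0L), nrow = 2, byrow = TRUE,
                     dimnames = list(c("s1", "s2"), c("o1", "o2", "o3"))))
}

toy_taxonomy <- function(otus = c("o1", "o2", "o3"),
                         phylum = c("Firmicutes", "Firmicutes", "unknown"),
                         family = c("Lachnospiraceae", "Lachnospiraceae",
                                    "unknown"),
                         genus = c("Blautia", "Roseburia", "unknown")) {
  data.frame(otu_id = otus, phylum = phylum, class = "unknown",
             order = "unknown", family = family, genus = genus,
             species = "unknown", stringsAsFactors = FALSE)
}

toy_metadata <- function(n_pigs = 4, farm = 1) {
  pig <- sprintf("F%02dP%02d", farm, seq_len(n_pigs))
  data.frame(
    sample_id = c(paste0(pig, "_d26"), paste0(pig, "_d35")),
    pig_id = rep(pig, 2),
    farm_id = farm,
    age_point = rep(c("d26", "d35"), each = n_pigs),
    weight_d26 = 8, weight_d35 = 9.5, weight_d48 = 14,
    interval_days = 22,
    stringsAsFactors = FALSE)
}

# small cohort for cheap pipeline-level tests
small_config <- function() {
  cfg <- calibrate_default_config()
  cfg$n_farms <- 6L
  cfg$pigs_per_farm <- 8L
  cfg$missing_d26_farm <- 1L
  cfg$missing_d35_farm <- 2L
  cfg
}

# memoised full-size cohorts and their clusterings for acceptance checks
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(seed) {
  key <- paste0("cohort_", seed)
  if (is.null(.cohort_cache[[key]])) {
    cfg <- cached_default_config()
    coh <- generate_cohort(cfg, seed = seed)
    tab <- filter_otus(qc_filter_samples(coh$counts), coh$taxonomy)
    .cohort_cache[[key]] <- list(
      cohort = coh, tab = tab,
      rel_genus = to_relative(aggregate_taxa(tab, coh$taxonomy, "genus")),
      rel_family = to_relative(aggregate_taxa(tab, coh$taxonomy, "family")),
      rel_phylum = to_relative(aggregate_taxa(tab, coh$taxonomy, "phylum")))
  }
  .cohort_cache[[key]]
}

cached_default_config <- function() {
  if (is.null(.cohort_cache$config))
    .cohort_cache$config <- calibrate_default_config()
  .cohort_cache$config
}

cached_pam4 <- function(seed) {
  key <- paste0("pam4_", seed)
  if (is.null(.cohort_cache[[key]])) {
    cc <- cached_cohort(seed)
    d <- jsd_distance(cc$rel_genus)
    fit <- pam_cluster(d, 4)
    labels <- canonical_enterotypes(fit$labels, cc$rel_genus)$labels
    .cohort_cache[[key]] <- list(labels = labels, dist = d)
  }
  .cohort_cache[[key]]
}
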