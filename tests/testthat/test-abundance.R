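test_that("count tables round-trip through TSV in both dialects", {
  tab <- toy_counts()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, path)
  expect_identical(unclass(read_count_table(path)), unclass(tab))

  # transposed dialect (OTUs as rows) is auto-detected
  df <- data.frame(otu_id = colnames(tab), t(unclass(tab)), check.names = FALSE)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(unclass(read_count_table(path2)), unclass(tab))
})

test_that("malformed inputs are rejected with the offender named", {
  m <- matrix(1L, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
  expect_error(count_table(m), "duplicate sample id: a")
  m2 <- matrix(c(1, 2.5, 3, 4), 2, 2,
               dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(count_table(m2), "non-integer count")
  md <- toy_metadata()
  md$weight_d26[2] <- 0
  expect_error(validate_metadata(md), md$sample_id[2])
  md2 <- toy_metadata()
  md2$pig_id[5] <- md2$pig_id[6]   # same pig twice at d35
  expect_error(validate_metadata(md2), "twice")
})

test_that("Greengenes taxonomy strings parse with the unknown sentinel", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\ttaxonomy",
               "o1\tk__Bacteria; p__Firmicutes; f__Lachnospiraceae",
               "o2\t"), path)
  tax <- read_taxonomy(path)
  expect_equal(tax$phylum, c("Firmicutes", "unknown"))
  expect_equal(tax$family, c("Lachnospiraceae", "unknown"))
  expect_equal(tax$genus, c("unknown", "unknown"))
})

test_that("QC retains exactly the samples at or above the read cutoff", {
  m <- matrix(0L, 3, 2, dimnames = list(c("low", "edge", "high"), c("a", "b")))
  m[1, 1] <- 4999L; m[2, 1] <- 5000L; m[3, ] <- c(6000L, 6000L)
  tab <- count_table(m)
  kept <- qc_filter_samples(tab, 5000)
  expect_equal(rownames(kept), c("edge", "high"))
  expect_equal(attr(kept, "excluded"), "low")
  all_kept <- qc_filter_samples(tab, 0)
  attr(all_kept, "excluded") <- NULL
  expect_identical(unclass(all_kept), unclass(tab))
  expect_error(qc_filter_samples(tab, 1e9), "below")

  # brute-force cross-check on random depths
  set.seed(42)
  m <- matrix(rpois(20 * 5, 1200), 20, 5,
              dimnames = list(paste0("s", 1:20), paste0("o", 1:5)))
  tab <- count_table(m)
  kept <- qc_filter_samples(tab, 6000)
  expect_equal(rownames(kept),
               rownames(m)[vapply(seq_len(20),
                                  function(i) sum(m[i, ]) >= 6000, logical(1))])
})

test_that("OTU filtering applies known-phylum, prevalence and strict 0.01%", {
  # prevalence boundary: nonzero in 4 samples -> removed; in 5 -> kept
  m <- matrix(0L, 6, 2, dimnames = list(paste0("s", 1:6), c("four", "five")))
  m[1:4, 1] <- 1000L
  m[1:5, 2] <- 1000L
  tax <- toy_taxonomy(c("four", "five"), rep("Firmicutes", 2),
                      rep("F", 2), rep("G", 2))
  out <- filter_otus(count_table(m), tax, min_prevalence = 5,
                     min_frac_total = 0)
  expect_equal(colnames(out), "five")

  # abundance boundary: exactly 0.01% of the grand total is removed
  m <- matrix(0L, 5, 2, dimnames = list(paste0("s", 1:5), c("big", "edge")))
  m[, 1] <- c(199980L, 199980L, 199980L, 199980L, 199980L)  # 999900
  m[, 2] <- 20L                                             # 100 of 1e6
  tax <- toy_taxonomy(c("big", "edge"), rep("Firmicutes", 2),
                      rep("F", 2), rep("G", 2))
  out <- filter_otus(count_table(m), tax, min_prevalence = 1,
                     min_frac_total = 1e-4)
  expect_equal(colnames(out), "big")

  # unknown phylum removed, missing taxonomy rejected
  tab <- toy_counts()
  out <- filter_otus(tab, toy_taxonomy(), min_prevalence = 1,
                     min_frac_total = 0)
  expect_equal(colnames(out), c("o1", "o2"))
  expect_error(filter_otus(tab, toy_taxonomy()[-1, ], 1, 0), "o1")
})

test_that("OTU filtering equals the brute-force predicate and is idempotent", {
  set.seed(7)
  m <- matrix(rbinom(50 * 200, 20, 0.08), 50, 200,
              dimnames = list(paste0("s", 1:50), paste0("o", 1:200)))
  tab <- count_table(m)
  phy <- sample(c("Firmicutes", "Bacteroidetes", "unknown"), 200, TRUE,
                prob = c(.45, .45, .1))
  tax <- toy_taxonomy(colnames(m), phy, rep("F", 200), rep("G", 200))
  out <- filter_otus(tab, tax, min_prevalence = 5, min_frac_total = 1e-4)
  grand <- sum(m)
  keep <- vapply(seq_len(200), function(j) {
    phy[j] != "unknown" && sum(m[, j] > 0) >= 5 && sum(m[, j]) / grand > 1e-4
  }, logical(1))
  expect_equal(colnames(out), colnames(m)[keep])
  # applying the filter twice changes nothing further
  expect_identical(unclass(filter_otus(out, tax, 5, 1e-4)), unclass(out))
})

test_that("rarefaction subsamples without replacement, reproducibly", {
  set.seed(3)
  m <- matrix(rpois(8 * 30, 300), 8, 30,
              dimnames = list(paste0("s", 1:8), paste0("o", 1:30)))
  tab <- count_table(m)
  r1 <- rarefy(tab, 5000, seed = 11)
  expect_true(all(rowSums(r1) == 5000))
  expect_true(all(unclass(r1) <= unclass(tab)))
  expect_identical(unclass(rarefy(tab, 5000, seed = 11)), unclass(r1))
  expect_error(rarefy(tab, 5000), "seed")
  expect_error(rarefy(tab, sum(m[1, ]) + 1e6, seed = 1), "s1")

  # a row already at the target depth is returned unchanged
  one <- count_table(matrix(c(3L, 4L), 1, 2,
                            dimnames = list("s", c("a", "b"))))
  expect_identical(unclass(rarefy(one, 7, seed = 1)), unclass(one))
})

test_that("rarefied counts match the hypergeometric expectation", {
  counts <- c(a = 600L, b = 300L, c = 100L)
  tab <- count_table(matrix(counts, 1, 3, dimnames = list("s", names(counts))))
  depth <- 250
  reps <- 400
  draws <- t(vapply(seq_len(reps), function(i)
    as.numeric(rarefy(tab, depth, seed = i)), numeric(3)))
  N <- sum(counts)
  expected <- depth * counts / N
  vr <- depth * (counts / N) * (1 - counts / N) * (N - depth) / (N - 1)
  se <- sqrt(vr / reps)
  expect_true(all(abs(colMeans(draws) - expected) < 3 * se + 1e-9))
})

test_that("rank aggregation is additive, conservative and composable", {
  m <- matrix(c(3L, 4L, 2L,
                1L, 0L, 5L), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("p1", "p2", "x")))
  tax <- toy_taxonomy(c("p1", "p2", "x"),
                      phylum = c("Bacteroidetes", "Bacteroidetes", "Firmicutes"),
                      family = c("Prevotellaceae", "Prevotellaceae", "unknown"),
                      genus = c("Prevotella", "Prevotella", "unknown"))
  tab <- count_table(m)
  gen <- aggregate_taxa(tab, tax, "genus")
  expect_equal(gen["s1", "Prevotella"], 7L)
  expect_equal(sum(gen), sum(tab))

  # genus -> family via the genus-to-family map equals direct family
  fam_direct <- aggregate_taxa(tab, tax, "family")
  g2f <- unique(tax[, c("genus", "family")])
  g2f$genus[g2f$genus == "unknown"] <- "unknown-genus"
  gtax <- data.frame(otu_id = colnames(gen),
                     phylum = "x", class = "x", order = "x",
                     family = g2f$family[match(colnames(gen), g2f$genus)],
                     genus = colnames(gen), species = "x",
                     stringsAsFactors = FALSE)
  fam_via <- aggregate_taxa(gen, gtax, "family")
  expect_equal(unclass(fam_via[, colnames(fam_direct)]), unclass(fam_direct))
})

test_that("the synthetic roster aggregates to its six phyla plus unknown", {
  coh <- generate_cohort(small_config(), seed = 1)
  ph <- aggregate_taxa(coh$counts, coh$taxonomy, "phylum")
  expect_setequal(colnames(ph),
                  c("Firmicutes", "Bacteroidetes", "Proteobacteria",
                    "Spirochaetes", "Fusobacteria", "Actinobacteria",
                    "unknown-phylum"))
})

test_that("relative abundances row-normalise and keep zero rows zero", {
  m <- matrix(c(2L, 2L, 0L, 0L), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "z"), c("a", "b")))
  rel <- to_relative(count_table(m))
  expect_equal(rel["s1", ], c(a = 0.5, b = 0.5))
  expect_equal(rel["z", ], c(a = 0, b = 0))
  set.seed(1)
  r <- to_relative(count_table(matrix(rpois(50, 10), 5, 10,
    dimnames = list(paste0("s", 1:5), paste0("o", 1:10)))))
  expect_equal(unname(rowSums(r)), rep(1, 5), tolerance = 1e-9)
})
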