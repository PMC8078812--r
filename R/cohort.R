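# Synthetic multi-farm weaning cohort: configuration, calibration, generation.

#' Validate a cohort configuration
#' @param config a cohort_config list.
#' @return the config, invisibly, or an error.
#' @export
validate_config <- function(config) {
  stopifnot(
    config$n_farms >= 1, config$pigs_per_farm >= 1,
    is.matrix(config$M), all(config$M >= 0),
    max(abs(colSums(config$M) - 1)) < 1e-8,
    length(config$pi26) == ncol(config$M),
    abs(sum(config$pi26) - 1) < 1e-8, all(config$pi26 >= 0),
    is.matrix(config$transition),
    max(abs(rowSums(config$transition) - 1)) < 1e-8,
    all(config$transition >= 0),
    config$theta > 0,
    all(unlist(config$sigma_farm) >= 0),
    config$depth$sdlog >= 0, config$depth$floor >= 1,
    all(config$age_mult > 0)
  )
  invisible(config)
}

# expected genus-level profile (fractions) for one (enterotype, age) cell,
# before farm effects and sampling noise
cell_profile <- function(config, ent, age) {
  p <- config$M[, ent]
  if (age == "d35") {
    fam <- config$taxa$family
    a <- config$age_mult[fam]
    a[is.na(a)] <- 1
    p <- p * a
  }
  p / sum(p)
}

# expected pooled taxon means per age: mixture over enterotype cells
expected_taxon_means <- function(config) {
  pi26 <- config$pi26
  pi35 <- as.numeric(pi26 %*% config$transition)
  ents <- colnames(config$M)
  m26 <- rowSums(sapply(seq_along(ents), function(e)
    pi26[e] * cell_profile(config, ents[e], "d26")))
  m35 <- rowSums(sapply(seq_along(ents), function(e)
    pi35[e] * cell_profile(config, ents[e], "d35")))
  list(d26 = m26, d35 = m35, pi26 = pi26, pi35 = pi35)
}

# pooled family means per age (fractions)
expected_family_means <- function(config) {
  em <- expected_taxon_means(config)
  fam <- config$taxa$family
  list(d26 = tapply(em$d26, fam, sum), d35 = tapply(em$d35, fam, sum),
       pi26 = em$pi26, pi35 = em$pi35)
}

# rescale the transition-matrix diagonal (off-diagonals proportionally) so
# the expected shift fraction 1 - sum_e pi26[e] T[e,e] equals `shift`
rescale_shift <- function(T0, pi26, shift) {
  d <- diag(T0)
  c0 <- (1 - shift) / sum(pi26 * d)
  if (any(c0 * d >= 1)) stop("cannot reach target shift with this transition shape")
  Tn <- T0
  for (e in seq_len(nrow(T0))) {
    Tn[e, ] <- T0[e, ] * (1 - c0 * d[e]) / (1 - d[e])
    Tn[e, e] <- c0 * d[e]
  }
  Tn
}

# expected measured cluster mean (fraction) of each taxon in each state:
# samples labelled with state e are a mixture of d26 and d35 samples with
# occupancy weights proportional to pi26[e] and pi35[e]
expected_cluster_means <- function(config) {
  pi26 <- config$pi26
  pi35 <- as.numeric(pi26 %*% config$transition)
  ents <- colnames(config$M)
  sapply(seq_along(ents), function(e) {
    w35 <- pi35[e] / (pi26[e] + pi35[e])
    (1 - w35) * cell_profile(config, ents[e], "d26") +
      w35 * cell_profile(config, ents[e], "d35")
  })
}

#' Calibrated default cohort configuration
#'
#' Returns the configuration that defines the study conditions the workflow
#' is exercised under: 16 farms x 18 male piglets x 2 ages and four
#' enterotype states. Because age effects enter both through the state
#' transition matrix and through family-level age multipliers, the two are
#' fitted jointly: the transition-matrix diagonal is rescaled in closed form
#' so the expected enterotype shift fraction equals `target_shift`; then an
#' alternating fixed point (a) solves the family age multipliers so the
#' expected pooled d26-to-d35 percent changes of six key families match
#' `target_changes`, and (b) adjusts the latent state profiles of the 13
#' discriminating genera so their expected measured cluster means (pooled
#' over both ages with the state occupancy weights) match the reference
#' profile table. Calibration residuals are attached as attribute
#' `"residuals"`; calibration aborts if any relative residual exceeds `tol`.
#'
#' @param target_changes named vector of pooled family percent changes.
#' @param target_shift expected fraction of pigs changing enterotype.
#' @param tol maximum tolerated relative calibration residual.
#' @return a `cohort_config` list.
#' @export
calibrate_default_config <- function(
    target_changes = c(Prevotellaceae = 143, Bacteroidaceae = -61,
                       Enterobacteriaceae = -42, Christensenellaceae = -35,
                       Clostridiaceae = -32, Lachnospiraceae = 21),
    target_shift = 0.75, tol = 0.02) {
  disc <- discriminating_profiles()
  ents <- c("E1", "E2", "E3", "E4")
  target_disc <- as.matrix(disc[, ents])
  rownames(target_disc) <- disc$genus
  roster <- default_taxa_roster()
  pi26 <- c(E1 = 0.35, E2 = 0.30, E3 = 0.20, E4 = 0.15)
  T0 <- rbind(
    E1 = c(0.18, 0.40, 0.30, 0.12),
    E2 = c(0.02, 0.22, 0.50, 0.26),
    E3 = c(0.01, 0.05, 0.34, 0.60),
    E4 = c(0.01, 0.03, 0.16, 0.80))
  colnames(T0) <- rownames(T0)
  Tn <- rescale_shift(T0, pi26, target_shift)

  config <- list(
    n_farms = 16L, pigs_per_farm = 18L,
    taxa = roster$taxa, M = roster$M,
    pi26 = pi26, transition = Tn,
    age_mult = stats::setNames(rep(1, length(unique(roster$taxa$family))),
                               unique(roster$taxa$family)),
    sigma_farm = list(d26 = 0.15, d35 = 0.30,
                      d26_extra = c(Christensenellaceae = 0.50,
                                    Lactobacillaceae = 0.50)),
    theta = 200,
    depth = list(meanlog = log(12000), sdlog = 0.68, floor = 1000),
    contaminant_frac = 0.005, n_contaminants = 5L,
    otus_per_genus = 3L, n_rich_genera = 10L, rich_otus = 5L,
    split_ratio = c(d26 = 0.35, d35 = 0.90),
    growth = list(intercept = 37, ent_effect = 3,
                  bacteroidetes_effect = 30, proteobacteria_effect = -60,
                  farm_sd = 4.5, resid_sd = 6.5,
                  w26_mean = 8.1, w26_sd = 1.1),
    missing_d26_farm = 1L, missing_d35_farm = 2L,
    seed = 1L)
  class(config) <- "cohort_config"

  fams <- names(target_changes)
  stopifnot(all(fams %in% config$taxa$family))
  disc_idx <- match(disc$genus, config$taxa$taxon)
  disc_values <- target_disc
  for (outer in seq_len(60)) {
    # (a) family age multipliers vs pooled percent changes
    for (it in seq_len(200)) {
      em <- expected_family_means(config)
      achieved <- 100 * (em$d35[fams] / em$d26[fams] - 1)
      ratio <- (1 + target_changes / 100) / (1 + achieved / 100)
      if (max(abs(ratio - 1)) < 1e-13) break
      config$age_mult[fams] <- config$age_mult[fams] * ratio
    }
    # (b) latent discriminating-genus profiles vs expected cluster means
    cm <- 100 * expected_cluster_means(config)[disc_idx, ]
    adj <- target_disc / cm
    if (max(abs(adj - 1)) < 1e-13) break
    disc_values <- disc_values * adj
    roster <- default_taxa_roster(disc_values)
    config$M <- roster$M
  }
  em <- expected_family_means(config)
  achieved <- 100 * (em$d35[fams] / em$d26[fams] - 1)
  resid_change <- achieved - target_changes
  resid_disc <- 100 * expected_cluster_means(config)[disc_idx, ] - target_disc
  resid <- c(resid_change, max_cluster_mean = max(abs(resid_disc)))
  if (max(abs(resid_change / target_changes)) > tol ||
      max(abs(resid_disc / target_disc)) > tol)
    stop("calibration residuals exceed tolerance: ",
         paste(sprintf("%s=%+.2f", names(resid), resid), collapse = ", "))
  attr(config, "residuals") <- resid
  attr(config, "expected_shift") <- 1 - sum(pi26 * diag(Tn))
  validate_config(config)
  config
}

# OTU-level expansion: each genus-level taxon is split into a fixed number
# of OTUs with geometric within-genus weights. The split is steeper before
# weaning (suckling communities are dominated by few strains per genus) and
# more even after (solid feed recruits additional strains), so observed OTU
# richness rises post-weaning while genus-level composition is untouched.
otu_layout <- function(config) {
  taxa <- config$taxa
  pooled <- rowMeans(config$M)
  n_otus <- rep(config$otus_per_genus, nrow(taxa))
  n_otus[order(pooled, decreasing = TRUE)[seq_len(config$n_rich_genera)]] <-
    config$rich_otus
  split_w <- function(ratio) lapply(n_otus, function(k) {
    w <- ratio ^ (seq_len(k) - 1); w / sum(w)
  })
  otu_id <- unlist(lapply(seq_len(nrow(taxa)), function(i)
    sprintf("OTU_%s_%02d", taxa$taxon[i], seq_len(n_otus[i]))))
  data.frame(
    otu_id = otu_id,
    taxon_idx = rep(seq_len(nrow(taxa)), n_otus),
    w26 = unlist(split_w(config$split_ratio[["d26"]])),
    w35 = unlist(split_w(config$split_ratio[["d35"]])),
    stringsAsFactors = FALSE)
}

cohort_taxonomy <- function(config, layout) {
  taxa <- config$taxa[layout$taxon_idx, ]
  tax <- data.frame(
    otu_id = layout$otu_id,
    phylum = taxa$phylum, class = "unknown", order = "unknown",
    family = taxa$family, genus = taxa$genus,
    species = "unknown", stringsAsFactors = FALSE, row.names = NULL)
  if (config$n_contaminants > 0) {
    cont <- data.frame(
      otu_id = sprintf("OTU_contam_%02d", seq_len(config$n_contaminants)),
      phylum = "unknown", class = "unknown", order = "unknown",
      family = "unknown", genus = "unknown", species = "unknown",
      stringsAsFactors = FALSE)
    tax <- rbind(tax, cont)
  }
  tax
}

#' Generate a synthetic multi-farm weaning cohort
#'
#' Draws, per pig, a pre-weaning enterotype from `pi26` and a post-weaning
#' enterotype from the transition matrix row; per sample, an expected genus
#' profile (enterotype means, family age multipliers at d35, log-normal
#' farm-by-family multipliers), a composition from a Dirichlet with
#' concentration `theta`, and counts from a multinomial at a log-normal read
#' depth. A small unknown-phylum contaminant mass exercises the
#' known-phylum filter. Growth: rADG (g/kg/day) is linear in the d35
#' enterotype ordinal and in the pig's latent Bacteroidetes/Proteobacteria
#' deviations, plus farm and residual noise; the d48 weight is back-solved
#' from rADG, the d26 weight and the weighing interval.
#'
#' @param config a `cohort_config`, e.g. [calibrate_default_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return list with `counts` ([count_table()]), `taxonomy`, `metadata`,
#'   and `truth` (per-pig latent enterotypes, rADG and deviations).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_config(config)
  set.seed(seed)
  ents <- colnames(config$M)
  K <- length(ents)
  fams <- unique(config$taxa$family)
  layout <- otu_layout(config)
  taxonomy <- cohort_taxonomy(config, layout)

  # persistent farm-by-family environmental direction, stronger after weaning
  Z <- matrix(stats::rnorm(config$n_farms * length(fams)),
              config$n_farms, length(fams), dimnames = list(NULL, fams))
  farm_growth <- stats::rnorm(config$n_farms, 0, config$growth$farm_sd)

  pigs <- expand.grid(pig = seq_len(config$pigs_per_farm),
                      farm = seq_len(config$n_farms))
  n_pigs <- nrow(pigs)
  pig_id <- sprintf("F%02dP%02d", pigs$farm, pigs$pig)
  ent26 <- sample(K, n_pigs, replace = TRUE, prob = config$pi26)
  ent35 <- vapply(ent26, function(e)
    sample.int(K, 1, prob = config$transition[e, ]), integer(1))

  # latent phylum deviations of the pig's expected (noise-free) composition
  phyl <- config$taxa$phylum
  pig_profile <- function(e26, e35)
    (cell_profile(config, ents[e26], "d26") +
       cell_profile(config, ents[e35], "d35")) / 2
  prof <- mapply(pig_profile, ent26, ent35)
  b_share <- colSums(prof[phyl == "Bacteroidetes", , drop = FALSE])
  p_share <- colSums(prof[phyl == "Proteobacteria", , drop = FALSE])
  b_dev <- b_share - mean(b_share)
  p_dev <- p_share - mean(p_share)

  gr <- config$growth
  radg <- gr$intercept + gr$ent_effect * (ent35 - mean(seq_len(K))) +
    gr$bacteroidetes_effect * b_dev + gr$proteobacteria_effect * p_dev +
    farm_growth[pigs$farm] + stats::rnorm(n_pigs, 0, gr$resid_sd)
  w26 <- pmax(4.5, stats::rnorm(n_pigs, gr$w26_mean, gr$w26_sd))
  n_days <- sample(21:23, n_pigs, replace = TRUE)
  w48 <- w26 * (1 + radg * n_days / 1000)
  w35 <- w26 * (1 + 0.6 * radg * 9 / 1000) *
    exp(stats::rnorm(n_pigs, 0, 0.01))

  samples <- rbind(
    data.frame(pig = seq_len(n_pigs), age = "d26", ent = ent26),
    data.frame(pig = seq_len(n_pigs), age = "d35", ent = ent35))
  drop <- (samples$age == "d26" & pigs$farm[samples$pig] == config$missing_d26_farm) |
          (samples$age == "d35" & pigs$farm[samples$pig] == config$missing_d35_farm)
  samples <- samples[!drop, , drop = FALSE]
  n_samp <- nrow(samples)
  sample_id <- paste0(pig_id[samples$pig], "_", samples$age)

  depths <- pmax(config$depth$floor,
                 round(stats::rlnorm(n_samp, config$depth$meanlog,
                                     config$depth$sdlog)))
  n_otu <- nrow(taxonomy)
  counts <- matrix(0L, n_samp, n_otu,
                   dimnames = list(sample_id, taxonomy$otu_id))
  n_main <- nrow(layout)
  for (s in seq_len(n_samp)) {
    farm <- pigs$farm[samples$pig[s]]
    age <- samples$age[s]
    p <- cell_profile(config, ents[samples$ent[s]], age)
    sig <- rep(config$sigma_farm[[age]], length(fams))
    names(sig) <- fams
    extra <- config$sigma_farm[[paste0(age, "_extra")]]
    if (!is.null(extra)) sig[names(extra)] <- extra
    sig <- sig[config$taxa$family]
    # mean-one log-normal multipliers keep expected family means on target
    mult <- exp(sig * Z[farm, config$taxa$family] - sig^2 / 2)
    p <- p * mult
    p <- p / sum(p)
    p_otu <- p[layout$taxon_idx] *
      (if (age == "d26") layout$w26 else layout$w35)
    p_otu <- (1 - config$contaminant_frac) * p_otu / sum(p_otu)
    if (config$n_contaminants > 0)
      p_otu <- c(p_otu, rep(config$contaminant_frac / config$n_contaminants,
                            config$n_contaminants))
    gam <- stats::rgamma(length(p_otu), shape = config$theta * p_otu)
    comp <- if (sum(gam) > 0) gam / sum(gam) else p_otu
    counts[s, ] <- stats::rmultinom(1, depths[s], comp)[, 1]
  }

  metadata <- data.frame(
    sample_id = sample_id,
    pig_id = pig_id[samples$pig],
    farm_id = pigs$farm[samples$pig],
    age_point = samples$age,
    weight_d26 = round(w26[samples$pig], 2),
    weight_d35 = round(w35[samples$pig], 2),
    weight_d48 = round(w48[samples$pig], 2),
    interval_days = n_days[samples$pig],
    stringsAsFactors = FALSE)

  truth <- data.frame(
    pig_id = pig_id, farm_id = pigs$farm,
    ent_d26 = ents[ent26], ent_d35 = ents[ent35],
    radg = radg, bacteroidetes_dev = b_dev, proteobacteria_dev = p_dev,
    stringsAsFactors = FALSE)

  out <- list(counts = count_table(counts), taxonomy = taxonomy,
              metadata = validate_metadata(metadata), truth = truth,
              config = config, seed = seed)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$counts), "samples,", ncol(x$counts),
      "OTUs,", nrow(x$truth), "pigs,", x$config$n_farms, "farms\n")
  invisible(x)
}

#' Summarise the latent truth of a synthetic cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @return list with the latent d26 enterotype frequencies, the latent
#'   d26->d35 transition counts, the latent shift fraction, and per-farm
#'   mean rADG.
#' @export
truth_report <- function(cohort) {
  tr <- cohort$truth
  ents <- colnames(cohort$config$M)
  f26 <- table(factor(tr$ent_d26, levels = ents))
  trans <- table(factor(tr$ent_d26, levels = ents),
                 factor(tr$ent_d35, levels = ents))
  list(
    ent_d26_freq = as.numeric(f26) / nrow(tr),
    transition_counts = unclass(trans),
    shift_fraction = 1 - sum(diag(trans)) / sum(trans),
    farm_radg = tapply(tr$radg, tr$farm_id, mean))
}

#' Write a cohort to TSV files
#' @param cohort a synthetic cohort.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(cohort$counts, file.path(dir, "counts.tsv"))
  write_taxonomy(cohort$taxonomy, file.path(dir, "taxonomy.tsv"))
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
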