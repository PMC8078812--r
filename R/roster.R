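# Taxa roster and enterotype mean profiles for the synthetic cohort.
#
# Thirteen discriminating genera carry fixed per-enterotype means (percent of
# composition); the remaining "filler" genera absorb the residual mass of
# their phylum so that each enterotype profile sums to 100% and the pooled
# phylum shares land near the field-typical values for weaning piglets
# (Firmicutes ~63%, Bacteroidetes ~29%, Proteobacteria ~5.2%,
# Spirochaetes ~1.7%, Fusobacteria ~1.3%). Filler mass within a phylum
# follows fixed base weights raised to an enterotype-specific power: flatter
# tails for the "mature" community states, so that observed richness rises
# across the E1..E4 gradient and hence from pre- to post-weaning.

discriminating_profiles <- function() {
  df <- data.frame(
    genus   = c("Prevotella", "Faecalibacterium", "Roseburia", "Lachnospira",
                "Bacteroides", "Coprococcus", "Treponema", "Paludibacter",
                "Ruminococcus", "Mitsuokella", "Oscillospira", "Lactobacillus",
                "Campylobacter"),
    family  = c("Prevotellaceae", "Ruminococcaceae", "Lachnospiraceae",
                "Lachnospiraceae", "Bacteroidaceae", "Lachnospiraceae",
                "Spirochaetaceae", "Porphyromonadaceae", "Ruminococcaceae",
                "Veillonellaceae", "Ruminococcaceae", "Lactobacillaceae",
                "Campylobacteraceae"),
    phylum  = c("Bacteroidetes", "Firmicutes", "Firmicutes", "Firmicutes",
                "Bacteroidetes", "Firmicutes", "Spirochaetes", "Bacteroidetes",
                "Firmicutes", "Firmicutes", "Firmicutes", "Firmicutes",
                "Proteobacteria"),
    E1 = c(3.87, 0.35, 0.24, 0.02, 16.10, 0.12, 0.54, 0.02, 1.27, 0.02, 2.43, 1.82, 1.52),
    E2 = c(1.32, 0.24, 0.17, 0.05,  5.71, 0.35, 1.21, 0.26, 2.25, 0.01, 3.59, 0.88, 0.57),
    E3 = c(11.29, 2.41, 1.20, 0.48, 0.59, 0.86, 3.77, 0.27, 2.16, 0.03, 2.79, 0.78, 1.14),
    E4 = c(31.40, 11.08, 4.36, 1.08, 0.63, 0.93, 1.09, 0.06, 1.34, 0.21, 2.05, 0.68, 1.11),
    stringsAsFactors = FALSE
  )
  df
}

filler_roster <- function() {
  g <- function(genus, family, phylum, w)
    data.frame(genus = genus, family = family, phylum = phylum, w = w,
               stringsAsFactors = FALSE)
  rbind(
    # Firmicutes fillers
    g("Blautia", "Lachnospiraceae", "Firmicutes", 8),
    g("Dorea", "Lachnospiraceae", "Firmicutes", 3),
    g("Anaerostipes", "Lachnospiraceae", "Firmicutes", 1),
    g("unknown", "Lachnospiraceae", "Firmicutes", 6),
    g("Butyricicoccus", "Ruminococcaceae", "Firmicutes", 2),
    g("Anaerofilum", "Ruminococcaceae", "Firmicutes", 1),
    g("unknown", "Ruminococcaceae", "Firmicutes", 9),
    g("Christensenella", "Christensenellaceae", "Firmicutes", 5),
    g("unknown", "Christensenellaceae", "Firmicutes", 1),
    g("Clostridium", "Clostridiaceae", "Firmicutes", 4),
    g("Sarcina", "Clostridiaceae", "Firmicutes", 1),
    g("SMB53", "Clostridiaceae", "Firmicutes", 1),
    g("Pediococcus", "Lactobacillaceae", "Firmicutes", 0.5),
    g("unknown", "Lactobacillaceae", "Firmicutes", 1.5),
    g("Megasphaera", "Veillonellaceae", "Firmicutes", 2),
    g("Dialister", "Veillonellaceae", "Firmicutes", 1),
    g("Phascolarctobacterium", "Veillonellaceae", "Firmicutes", 2),
    g("Anaerovibrio", "Veillonellaceae", "Firmicutes", 0.5),
    g("Catenibacterium", "Erysipelotrichaceae", "Firmicutes", 1),
    g("Bulleidia", "Erysipelotrichaceae", "Firmicutes", 0.5),
    g("unknown", "Erysipelotrichaceae", "Firmicutes", 1),
    g("Streptococcus", "Streptococcaceae", "Firmicutes", 1.5),
    g("Lactococcus", "Streptococcaceae", "Firmicutes", 0.5),
    g("Enterococcus", "Enterococcaceae", "Firmicutes", 0.5),
    g("unknown", "Peptostreptococcaceae", "Firmicutes", 1),
    g("Turicibacter", "Turicibacteraceae", "Firmicutes", 0.5),
    g("Mogibacterium", "Mogibacteriaceae", "Firmicutes", 0.3),
    g("Staphylococcus", "Staphylococcaceae", "Firmicutes", 0.2),
    # Bacteroidetes fillers
    g("unknown", "Prevotellaceae", "Bacteroidetes", 2),
    g("unknown", "S24-7", "Bacteroidetes", 4),
    g("Parabacteroides", "Porphyromonadaceae", "Bacteroidetes", 1.5),
    g("unknown", "Porphyromonadaceae", "Bacteroidetes", 0.5),
    g("unknown", "Rikenellaceae", "Bacteroidetes", 1),
    g("CF231", "Paraprevotellaceae", "Bacteroidetes", 1),
    g("YRC22", "Paraprevotellaceae", "Bacteroidetes", 0.5),
    g("unknown", "RF16", "Bacteroidetes", 1),
    # Proteobacteria fillers
    g("Escherichia", "Enterobacteriaceae", "Proteobacteria", 3),
    g("unknown", "Enterobacteriaceae", "Proteobacteria", 0.5),
    g("Succinivibrio", "Succinivibrionaceae", "Proteobacteria", 1),
    g("Desulfovibrio", "Desulfovibrionaceae", "Proteobacteria", 0.5),
    g("Sutterella", "Alcaligenaceae", "Proteobacteria", 0.5),
    g("Actinobacillus", "Pasteurellaceae", "Proteobacteria", 0.3),
    # Spirochaetes fillers
    g("unknown", "Spirochaetaceae", "Spirochaetes", 1),
    g("Sphaerochaeta", "Spirochaetaceae", "Spirochaetes", 0.5),
    # Fusobacteria
    g("Fusobacterium", "Fusobacteriaceae", "Fusobacteria", 1),
    # Actinobacteria
    g("Bifidobacterium", "Bifidobacteriaceae", "Actinobacteria", 0.5),
    g("Collinsella", "Coriobacteriaceae", "Actinobacteria", 0.5)
  )
}

# per-enterotype phylum mass targets (percent), chosen so the mixture pools
# to the field-typical shares for a balanced maturational state distribution;
# Spirochaetes at E3 must at least cover the fixed Treponema mean.
phylum_targets <- function() {
  t <- rbind(
    Bacteroidetes  = c(30, 21.5, 24, 35.5),
    Proteobacteria = c(5.2, 5.2, 5.2, 5.2),
    Spirochaetes   = c(1.7, 1.7, 4.6, 1.7),
    Fusobacteria   = c(1.3, 1.3, 1.3, 1.3),
    Actinobacteria = c(0.2, 0.2, 0.2, 0.2)
  )
  rbind(t, Firmicutes = 100 - colSums(t))
}

# tail-flattening exponents per enterotype (smaller = flatter = richer)
filler_gamma <- c(E1 = 1.45, E2 = 1.05, E3 = 0.85, E4 = 0.95)

# Deterministic per-enterotype log-scale tilts of the filler weights. Real
# enterotypes differ across many background taxa, not only the discriminating
# genera; a low-discrepancy (golden-ratio) sequence gives each state a fixed,
# reproducible signature without any RNG. The tilt scale delta shrinks along
# the maturational gradient: immature states are lumpier (a few background
# taxa dominate), mature states more even, which raises observed richness
# from pre- to post-weaning.
filler_delta <- c(E1 = 2.3, E2 = 2.1, E3 = 1.5, E4 = 1.7)

filler_tilt <- function(n_filler, ent_index, delta = filler_delta[[ent_index]]) {
  alpha <- (sqrt(5) - 1) / 2 * ent_index
  u <- (seq_len(n_filler) * alpha + ent_index / 7) %% 1
  u <- pmin(pmax(u, 1e-4), 1 - 1e-4)
  exp(delta * stats::qnorm(u))
}

#' Default taxa roster and enterotype mean profiles
#'
#' Builds the genus-level roster of the synthetic cohort (genus, family,
#' phylum) together with the four enterotype mean profiles `M` (fractions
#' summing to 1 per enterotype). Thirteen discriminating genera have fixed
#' means; filler genera absorb the per-phylum residual mass with
#' enterotype-specific tail flatness.
#'
#' @param disc_values optional 13 x 4 matrix of discriminating-genus means
#'   (percent) overriding the built-in state profiles; used by the
#'   calibration loop, which adjusts the latent state profiles so that the
#'   expected measured cluster means land on the built-in values.
#' @return list with `taxa` (data.frame genus/family/phylum; genus labels of
#'   unclassified fillers are the sentinel `"unknown"` and are disambiguated
#'   by family in the internal `taxon` key) and `M` (taxa x 4 matrix of
#'   fractions).
#' @export
default_taxa_roster <- function(disc_values = NULL) {
  disc <- discriminating_profiles()
  if (!is.null(disc_values)) disc[, c("E1", "E2", "E3", "E4")] <- disc_values
  fill <- filler_roster()
  targets <- phylum_targets()
  ents <- c("E1", "E2", "E3", "E4")

  taxa <- rbind(disc[, c("genus", "family", "phylum")],
                fill[, c("genus", "family", "phylum")])
  taxa$taxon <- ifelse(taxa$genus == "unknown",
                       paste0("unc_", taxa$family), taxa$genus)
  if (anyDuplicated(taxa$taxon)) stop("roster taxon keys must be unique")

  M <- matrix(0, nrow(taxa), 4, dimnames = list(taxa$taxon, ents))
  M[seq_len(nrow(disc)), ] <- as.matrix(disc[, ents])
  for (e in ents) {
    ei <- match(e, ents)
    tilt <- filler_tilt(nrow(fill), ei)
    for (ph in rownames(targets)) {
      idx_f <- which(fill$phylum == ph)
      if (!length(idx_f)) next
      fixed <- sum(disc[disc$phylum == ph, e])
      budget <- targets[ph, ei] - fixed
      if (budget < 0) stop("phylum target below fixed mass for ", ph, " in ", e)
      w <- fill$w[idx_f] ^ filler_gamma[[e]] * tilt[idx_f]
      M[nrow(disc) + idx_f, e] <- budget * w / sum(w)
    }
  }
  M <- M / 100
  stopifnot(max(abs(colSums(M) - 1)) < 1e-12)
  list(taxa = taxa[, c("taxon", "genus", "family", "phylum")], M = M)
}
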