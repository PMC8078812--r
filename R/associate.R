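# Factor-effect tests on aggregated taxa: Kruskal-Wallis with Dunn post hoc,
# BH control, weaning percent-change summaries, and the two-step permutation
# procedure for the growth-class-by-age interaction.

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate;
#' monotone-enforced and capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted vector of the same length.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Dunn pairwise z-tests on joint ranks with ties correction
dunn_pairs <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  tie_term <- {
    t <- table(r)
    sum(t^3 - t) / (12 * (N - 1))
  }
  rbar <- tapply(r, g, mean)
  ng <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / ng[[pr[1]]] + 1 / ng[[pr[2]]]))
    (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
}

#' Kruskal-Wallis tests with Dunn post hoc across taxa
#'
#' For each taxon column, a Kruskal-Wallis chi-square test (ties-corrected)
#' of the factor effect; p-values are BH-adjusted across taxa. For taxa with
#' raw KW p < 0.05, pairwise Dunn z-tests are run with BH correction across
#' the pairs of that taxon. Factor levels with fewer than 2 samples are
#' dropped with a warning.
#'
#' @param rel relative-abundance matrix (samples x taxa).
#' @param groups factor with one level per sample.
#' @return list with `tests` (taxon, statistic, p, p_adj) and `dunn`
#'   (pairwise rows for taxa passing the KW screen).
#' @export
kruskal_dunn <- function(rel, groups) {
  groups <- factor(groups)
  small <- names(which(table(groups) < 2))
  if (length(small)) {
    warning("dropping factor level(s) with <2 samples: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    rel <- rel[keep, , drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("factor needs at least two usable levels")
  tests <- do.call(rbind, lapply(colnames(rel), function(tx) {
    kw <- stats::kruskal.test(rel[, tx], groups)
    data.frame(taxon = tx, statistic = unname(kw$statistic),
               p = kw$p.value, stringsAsFactors = FALSE)
  }))
  tests$p_adj <- bh_adjust(tests$p)
  dunn <- do.call(rbind, lapply(tests$taxon[tests$p < 0.05], function(tx) {
    dp <- dunn_pairs(rel[, tx], groups)
    dp$p_adj <- bh_adjust(dp$p)
    cbind(taxon = tx, dp)
  }))
  list(tests = tests, dunn = dunn)
}

#' Pooled d26-to-d35 percent change per taxon
#'
#' `100 * (mean_d35 - mean_d26) / mean_d26` over cross-sample arithmetic
#' means of relative abundance, with a paired Wilcoxon signed-rank p-value
#' over pigs having both samples, BH-adjusted across taxa. Taxa whose d26
#' mean is zero get `NA` change and are flagged.
#'
#' @param rel relative-abundance matrix (samples x taxa).
#' @param metadata sample metadata for the rows of `rel`.
#' @return data.frame per taxon: `mean_d26`, `mean_d35`, `percent_change`,
#'   `p`, `p_adj`, `undefined`.
#' @export
percent_change <- function(rel, metadata) {
  md <- metadata[match(rownames(rel), metadata$sample_id), ]
  if (any(is.na(md$sample_id))) stop("metadata missing for some samples")
  i26 <- md$age_point == "d26"
  i35 <- md$age_point == "d35"
  if (!any(i26) || !any(i35)) stop("both age points are required")
  m26 <- colMeans(rel[i26, , drop = FALSE])
  m35 <- colMeans(rel[i35, , drop = FALSE])
  common <- intersect(md$pig_id[i26], md$pig_id[i35])
  r26 <- rel[i26, , drop = FALSE][match(common, md$pig_id[i26]), , drop = FALSE]
  r35 <- rel[i35, , drop = FALSE][match(common, md$pig_id[i35]), , drop = FALSE]
  p <- vapply(seq_len(ncol(rel)), function(j) {
    diffs <- r35[, j] - r26[, j]
    if (all(diffs == 0)) return(1)
    suppressWarnings(stats::wilcox.test(diffs)$p.value)
  }, numeric(1))
  undefined <- m26 == 0
  out <- data.frame(
    taxon = colnames(rel), mean_d26 = m26, mean_d35 = m35,
    percent_change = ifelse(undefined, NA_real_, 100 * (m35 - m26) / m26),
    p = p, p_adj = bh_adjust(p), undefined = undefined,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# residual sum of squares of Y against the column space of X, per column of Y
rss_proj <- function(Y, X) {
  Q <- qr.Q(qr(X))
  colSums(Y^2) - colSums((crossprod(Q, Y))^2)
}

#' Two-step test of the growth-class effect on taxa
#'
#' Step 1 (prescreen): per taxon and age point, a Wilcoxon rank-sum test of
#' rADG+ vs rADG- on all samples available at that age, BH-adjusted across
#' taxa; a taxon is retained when its (adjusted, by default) p-value falls
#' below `alpha_pre` at either age. Step 2 (confirmation): on pigs of both
#' classes having samples at both ages, each retained taxon is fit by least
#' squares as `abundance ~ class + age + class:age`; F statistics for the
#' class effect (additive model), the age effect (additive model) and the
#' interaction (full vs additive) are referred to a permutation distribution
#' in which pig-level class labels are permuted within farm, keeping both of
#' a pig's samples together (the exchangeable unit is the pig).
#'
#' @param rel relative-abundance matrix (samples x taxa).
#' @param records classified growth records ([classify_within_farm()]).
#' @param metadata sample metadata for the rows of `rel`.
#' @param alpha_pre retention threshold for step 1 (default 0.1).
#' @param n_perm permutations for step 2 (default 5000).
#' @param seed integer seed.
#' @param adjust_step1 apply BH before thresholding in step 1 (default TRUE;
#'   FALSE thresholds raw p-values).
#' @return list with `step1` (per taxon/age p-values and retention),
#'   `step2` (per retained taxon: F and permutation p for class, age,
#'   interaction), and `n_pigs_step2`.
#' @export
two_step_radg <- function(rel, records, metadata, alpha_pre = 0.1,
                          n_perm = 5000, seed = 1, adjust_step1 = TRUE) {
  md <- metadata[match(rownames(rel), metadata$sample_id), ]
  cls <- records$class[match(md$pig_id, records$pig_id)]
  keep <- cls %in% c("rADG+", "rADG-")
  rel <- rel[keep, , drop = FALSE]
  md <- md[keep, ]
  cls <- cls[keep]

  step1 <- do.call(rbind, lapply(c("d26", "d35"), function(age) {
    idx <- md$age_point == age
    p <- vapply(colnames(rel), function(tx) {
      x <- rel[idx, tx]
      g <- cls[idx]
      if (length(unique(g)) < 2) return(NA_real_)
      suppressWarnings(stats::wilcox.test(x ~ factor(g))$p.value)
    }, numeric(1))
    data.frame(taxon = colnames(rel), age = age, p = p,
               p_adj = bh_adjust(p), stringsAsFactors = FALSE)
  }))
  crit <- if (adjust_step1) step1$p_adj else step1$p
  retained <- unique(step1$taxon[crit < alpha_pre & !is.na(crit)])

  # step 2: complete pigs only
  p26 <- md$pig_id[md$age_point == "d26"]
  p35 <- md$pig_id[md$age_point == "d35"]
  common <- intersect(p26, p35)
  pig_class <- cls[match(common, md$pig_id)]
  if (min(table(pig_class)) < 2) stop("fewer than 2 complete pigs in a class")
  step2 <- NULL
  if (length(retained)) {
    sel <- md$pig_id %in% common
    mds <- md[sel, ]
    Y <- rel[sel, retained, drop = FALSE]
    pig <- mds$pig_id
    farm <- records$farm_id[match(pig, records$pig_id)]
    age_f <- as.numeric(mds$age_point == "d35")
    class_of_pig <- stats::setNames(pig_class, common)

    f_stats <- function(cl_sample) {
      X_add <- cbind(1, cl_sample, age_f)
      X_full <- cbind(X_add, cl_sample * age_f)
      X_age <- cbind(1, age_f)
      X_cls <- cbind(1, cl_sample)
      n <- nrow(X_full)
      rss_full <- rss_proj(Y, X_full)
      rss_add <- rss_proj(Y, X_add)
      rbind(
        class = (rss_proj(Y, X_age) - rss_add) / (rss_add / (n - 3)),
        age = (rss_proj(Y, X_cls) - rss_add) / (rss_add / (n - 3)),
        interaction = (rss_add - rss_full) / (rss_full / (n - 4)))
    }
    obs <- f_stats(as.numeric(class_of_pig[pig] == "rADG+"))
    set.seed(seed)
    exceed <- matrix(0, nrow(obs), ncol(obs), dimnames = dimnames(obs))
    for (b in seq_len(n_perm)) {
      perm_class <- class_of_pig
      for (f in unique(farm)) {
        pigs_f <- unique(pig[farm == f])
        perm_class[pigs_f] <- sample(class_of_pig[pigs_f])
      }
      Fp <- f_stats(as.numeric(perm_class[pig] == "rADG+"))
      exceed <- exceed + (Fp >= obs)
    }
    pmat <- (1 + exceed) / (1 + n_perm)
    step2 <- data.frame(
      taxon = retained,
      F_class = obs["class", ], p_class = pmat["class", ],
      F_age = obs["age", ], p_age = pmat["age", ],
      F_interaction = obs["interaction", ],
      p_interaction = pmat["interaction", ],
      stringsAsFactors = FALSE)
    rownames(step2) <- NULL
  }
  list(step1 = step1, retained = retained, step2 = step2,
       n_pigs_step2 = length(common))
}
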