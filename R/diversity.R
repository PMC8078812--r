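# Alpha diversity, beta-diversity distances, PCoA, PERMANOVA and the
# dispersion-homogeneity test.

#' Per-sample alpha diversity
#'
#' Observed richness (number of nonzero OTUs) and Shannon index in natural
#' logarithm units. Intended for rarefied tables; a warning is emitted when
#' row sums are unequal, since unequal effort biases richness.
#'
#' @param table a [count_table()] (ideally rarefied).
#' @return data.frame with `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(table) {
  rs <- rowSums(table)
  if (length(unique(rs)) > 1)
    warning("row sums are unequal; alpha diversity is depth-sensitive")
  data.frame(
    sample_id = rownames(table),
    richness = as.integer(rowSums(table > 0)),
    shannon = as.numeric(vegan::diversity(unclass(table), index = "shannon")),
    stringsAsFactors = FALSE)
}

#' Jensen-Shannon divergence distance matrix
#'
#' `d(p, q) = sqrt(H(m) - (H(p) + H(q))/2)` with `m = (p + q)/2` and Shannon
#' entropy `H` in nats. Zero proportions are replaced by `pseudocount` and
#' rows renormalised first (set `pseudocount = 0` to keep exact zeros, under
#' the convention `0 log 0 = 0`).
#'
#' @param rel relative-abundance matrix, samples x taxa (rows sum to 1).
#' @param pseudocount replacement for zero entries before renormalisation.
#' @return a `dist` object.
#' @export
jsd_distance <- function(rel, pseudocount = 1e-6) {
  P <- unclass(rel)
  if (any(P < 0)) stop("negative entries in relative abundances")
  if (pseudocount > 0) {
    P[P == 0] <- pseudocount
    P <- P / rowSums(P)
  }
  xlogx <- function(m) { r <- m * log(m); r[m == 0] <- 0; r }
  H <- -rowSums(xlogx(P))
  n <- nrow(P)
  d <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    M <- (P[j, , drop = FALSE] + rep(P[i, ], each = length(j))) / 2
    Hm <- -rowSums(xlogx(M))
    d[j, i] <- d[i, j] <- sqrt(pmax(0, Hm - (H[i] + H[j]) / 2))
  }
  stats::as.dist(d)
}

#' Beta-diversity distance matrix
#'
#' Tree-free community distances: Bray-Curtis (via [vegan::vegdist()]) or
#' the square-root Jensen-Shannon divergence.
#'
#' @param rel relative-abundance matrix, samples x taxa.
#' @param metric `"bray_curtis"` or `"jsd"`.
#' @param pseudocount passed to [jsd_distance()].
#' @return a `dist` object with a `"metric"` attribute.
#' @export
beta_distance <- function(rel, metric = c("bray_curtis", "jsd"),
                          pseudocount = 1e-6) {
  metric <- match.arg(metric)
  if (any(rel < 0)) stop("negative entries in relative abundances")
  d <- switch(metric,
    bray_curtis = vegan::vegdist(unclass(rel), method = "bray"),
    jsd = jsd_distance(rel, pseudocount))
  attr(d, "metric") <- metric
  d
}

#' Write a distance matrix as square TSV
#' @param d a `dist` object.
#' @param path output path.
#' @export
write_distance <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Principal coordinates analysis
#'
#' Classical scaling of the double-centred squared-distance matrix. Axes are
#' ordered by eigenvalue; axes with negative eigenvalues (non-Euclidean
#' distances) are reported in `eig` but not embedded.
#'
#' @param d a `dist` object or symmetric matrix.
#' @return list with `points` (samples x axes), `eig` (all eigenvalues) and
#'   `negative` (TRUE if any eigenvalue is meaningfully negative).
#' @export
pcoa <- function(d) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  cs <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- cs$eig
  keep <- which(eig > max(eig) * 1e-9)
  pts <- cs$points[, keep, drop = FALSE]
  colnames(pts) <- paste0("PCo", seq_along(keep))
  list(points = pts, eig = eig, negative = any(eig < -max(eig) * 1e-8))
}

# distance-based sums of squares: total and within-group
ss_decompose <- function(D2, labels) {
  n <- nrow(D2)
  total <- sum(D2) / (2 * n)
  within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    within <- within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  c(total = total, within = within)
}

#' Distance-based permutation ANOVA (PERMANOVA)
#'
#' One-factor pseudo-F from the distance-based sums-of-squares
#' decomposition, with a permutation p-value under the "+1" convention
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#'
#' @param d `dist` object or symmetric matrix.
#' @param labels group labels, one per sample.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return list with `F`, `p`, `df`, and the permuted F values.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1) {
  D2 <- as.matrix(d)^2
  labels <- as.character(labels)
  n <- nrow(D2)
  stopifnot(length(labels) == n)
  tab <- table(labels)
  if (length(tab) < 2) stop("permanova needs at least two groups")
  if (any(tab < 2)) stop("each group needs at least two samples")
  a <- length(tab)
  f_stat <- function(lab) {
    ss <- ss_decompose(D2, lab)
    ((ss["total"] - ss["within"]) / (a - 1)) / (ss["within"] / (n - a))
  }
  F_obs <- as.numeric(f_stat(labels))
  set.seed(seed)
  F_perm <- vapply(seq_len(n_perm),
                   function(i) as.numeric(f_stat(sample(labels))), numeric(1))
  list(F = F_obs, p = (1 + sum(F_perm >= F_obs)) / (1 + n_perm),
       df = c(a - 1, n - a), F_perm = F_perm)
}

#' Homogeneity-of-dispersion test
#'
#' Embeds the samples by PCoA (non-negative-eigenvalue axes only), computes
#' each sample's Euclidean distance to its own group centroid in that
#' embedding, and tests equality of mean dispersion across groups with a
#' one-way ANOVA F whose p-value is obtained by permuting group labels.
#'
#' @inheritParams permanova
#' @return list with `F`, `p`, and per-sample `distances` to own centroid.
#' @export
dispersion_test <- function(d, labels, n_perm = 999, seed = 1) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("dispersion test needs at least two groups")
  if (any(tab < 2)) stop("each group needs at least two samples")
  pts <- pcoa(d)$points
  dist_to_centroid <- function(lab) {
    z <- numeric(nrow(pts))
    for (g in unique(lab)) {
      idx <- which(lab == g)
      cen <- colMeans(pts[idx, , drop = FALSE])
      z[idx] <- sqrt(rowSums(sweep(pts[idx, , drop = FALSE], 2, cen)^2))
    }
    z
  }
  anova_f <- function(z, lab) {
    gm <- tapply(z, lab, mean)
    ng <- tapply(z, lab, length)
    ssb <- sum(ng * (gm - mean(z))^2)
    ssw <- sum((z - gm[lab])^2)
    (ssb / (length(gm) - 1)) / (ssw / (length(z) - length(gm)))
  }
  z_obs <- dist_to_centroid(labels)
  F_obs <- anova_f(z_obs, labels)
  set.seed(seed)
  F_perm <- vapply(seq_len(n_perm), function(i) {
    lab <- sample(labels)
    anova_f(dist_to_centroid(lab), lab)
  }, numeric(1))
  list(F = F_obs, p = (1 + sum(F_perm >= F_obs)) / (1 + n_perm),
       distances = stats::setNames(z_obs, rownames(pts)))
}
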