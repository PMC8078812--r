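# Enterotype discovery: deterministic PAM on JSD distances, CH-based K
# selection, silhouette validation, and longitudinal transition dynamics.

#' Deterministic k-medoids (PAM) clustering
#'
#' BUILD phase: greedy seeding, first medoid minimising total distance, each
#' further medoid maximising the cost reduction. SWAP phase: steepest-descent
#' medoid/non-medoid swaps until no swap improves the total cost. All ties
#' are broken by the lowest sample index, so the result is fully determined
#' by the distance matrix.
#'
#' @param d `dist` object or symmetric distance matrix.
#' @param k number of clusters, `2 <= k < n`.
#' @return list with integer `labels` (named by sample), `medoids` (sample
#'   ids), total `cost`, and the non-increasing `cost_trace` across SWAP
#'   iterations.
#' @export
pam_cluster <- function(d, k) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (k < 2) stop("k must be at least 2")
  if (k >= n) stop("k must be smaller than the number of samples")

  # BUILD
  medoids <- which.min(colSums(dm))
  nd <- dm[, medoids]
  while (length(medoids) < k) {
    gain <- colSums(pmax(nd - dm, 0))
    gain[medoids] <- -Inf
    m <- which.max(gain)            # which.max takes the first (lowest index)
    medoids <- c(medoids, m)
    nd <- pmin(nd, dm[, m])
  }

  cost_of <- function(meds) sum(row_mins(dm[, meds, drop = FALSE]))
  cost <- cost_of(medoids)
  trace <- cost

  # SWAP (steepest descent, vectorised over points per candidate pair)
  repeat {
    dmed <- dm[, medoids, drop = FALSE]
    nearest_idx <- max.col(-dmed, ties.method = "first")
    nd <- dmed[cbind(seq_len(n), nearest_idx)]
    nd2 <- apply(dmed, 1, function(r) sort(r, partial = 2)[2])
    best_delta <- -1e-12
    best <- NULL
    nonmed <- setdiff(seq_len(n), medoids)
    for (mi in seq_along(medoids)) {
      mask <- nearest_idx == mi
      alt <- ifelse(mask, nd2, nd)    # nearest distance with medoid mi removed
      for (h in nonmed) {
        newv <- pmin(alt, dm[, h])
        delta <- sum(newv) - cost
        if (delta < best_delta) { best_delta <- delta; best <- c(mi, h) }
      }
    }
    if (is.null(best)) break
    medoids[best[1]] <- best[2]
    cost <- cost_of(medoids)
    trace <- c(trace, cost)
    if (any(diff(trace) > 1e-9)) stop("PAM cost increased; internal error")
  }

  medoids <- sort(medoids)
  labels <- max.col(-dm[, medoids, drop = FALSE], ties.method = "first")
  labels[medoids] <- seq_len(k)     # a medoid belongs to its own cluster
  names(labels) <- rownames(dm)
  list(labels = labels, medoids = rownames(dm)[medoids],
       cost = cost_of(medoids), cost_trace = trace)
}

#' Distance-based Calinski-Harabasz index
#'
#' `CH = (B / (K - 1)) / (W / (n - K))` with the within-cluster sum of
#' squares `W = sum_k (1/n_k) sum_{i<j in k} d_ij^2` and `B = total - W`.
#' Computable from the distance matrix alone, without coordinates. Returns
#' `Inf` (with attribute `degenerate = TRUE`) when `W = 0`.
#'
#' @param d `dist` or symmetric matrix.
#' @param labels cluster labels.
#' @return the CH value.
#' @export
ch_index <- function(d, labels) {
  D2 <- as.matrix(d)^2
  labels <- as.character(labels)
  k <- length(unique(labels))
  n <- nrow(D2)
  if (k < 2) stop("CH index needs at least two clusters")
  ss <- ss_decompose(D2, labels)
  W <- ss["within"]; B <- ss["total"] - W
  if (W <= 0) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  as.numeric((B / (k - 1)) / (W / (n - k)))
}

#' Per-sample silhouette widths from a distance matrix
#'
#' `s(i) = (b - a) / max(a, b)` with `a` the mean distance to the sample's
#' own cluster and `b` the smallest mean distance to another cluster;
#' singletons score 0.
#'
#' @param d `dist` or symmetric matrix.
#' @param labels cluster labels.
#' @return numeric vector of widths in `[-1, 1]`.
#' @export
silhouette_width <- function(d, labels) {
  dm <- as.matrix(d)
  labels <- as.character(labels)
  groups <- unique(labels)
  # mean distance of every sample to every cluster
  means <- sapply(groups, function(g)
    rowMeans(dm[, labels == g, drop = FALSE]))
  sizes <- table(labels)[groups]
  s <- numeric(nrow(dm))
  for (i in seq_len(nrow(dm))) {
    gi <- match(labels[i], groups)
    ni <- sizes[[gi]]
    if (ni == 1) { s[i] <- 0; next }
    a <- means[i, gi] * ni / (ni - 1)   # exclude self
    b <- min(means[i, -gi])
    s[i] <- (b - a) / max(a, b)
  }
  stats::setNames(s, rownames(dm))
}

#' Canonically rename clusters along the maturational gradient
#'
#' Cluster labels from PAM are arbitrary; for transition-direction
#' statements they are renamed E1..EK by ascending mean of
#' Prevotella + Faecalibacterium relative abundance, so the highest label is
#' the most mature (Prevotella-rich) community state.
#'
#' @param labels integer cluster labels named by sample id.
#' @param rel_genus genus-level relative abundances for the same samples.
#' @return list with renamed integer `labels` and the `order` mapping
#'   (old label of each new position).
#' @export
canonical_enterotypes <- function(labels, rel_genus) {
  key_genera <- intersect(c("Prevotella", "Faecalibacterium"),
                          colnames(rel_genus))
  if (!length(key_genera)) {
    warning("Prevotella/Faecalibacterium absent; keeping arbitrary labels")
    return(list(labels = labels, order = sort(unique(labels))))
  }
  score <- rowSums(rel_genus[names(labels), key_genera, drop = FALSE])
  ord <- order(tapply(score, labels, mean))
  new <- match(labels, ord)
  names(new) <- names(labels)
  list(labels = new, order = ord)
}

#' Enterotype discovery with CH-based selection of K
#'
#' Computes JSD distances on genus-level relative abundances, runs PAM for
#' each candidate K, and selects the K maximising the distance-based CH
#' index. Clusters of the winning solution are canonically renamed along the
#' Prevotella + Faecalibacterium gradient. A solution is flagged as weak
#' structure when the winning CH fails to exceed 1.2x the median of the CH
#' curve.
#'
#' @param rel_genus genus-level relative abundances (samples x genera).
#' @param k_range candidate cluster counts (default 2:8; shrunk with a
#'   warning if the sample count is too small).
#' @param pseudocount zero replacement before JSD (default 1e-6).
#' @return an `enterotype_solution`: `k`, `labels`, `medoids`, `ch_curve`,
#'   `mean_silhouette`, `silhouette`, `weak_structure`, `profiles`
#'   (per-cluster mean genus profile), and the `dist` used.
#' @export
choose_k <- function(rel_genus, k_range = 2:8, pseudocount = 1e-6) {
  n <- nrow(rel_genus)
  if (max(k_range) >= n) {
    warning("shrinking k_range: fewer samples than max K")
    k_range <- k_range[k_range < n]
  }
  d <- jsd_distance(rel_genus, pseudocount)
  fits <- lapply(k_range, function(k) pam_cluster(d, k))
  ch <- vapply(seq_along(k_range), function(i)
    ch_index(d, fits[[i]]$labels), numeric(1))
  names(ch) <- k_range
  best <- which.max(ch)
  fit <- fits[[best]]
  ren <- canonical_enterotypes(fit$labels, rel_genus)
  labels <- ren$labels
  sil <- silhouette_width(d, labels)
  profiles <- t(sapply(sort(unique(labels)), function(g)
    colMeans(rel_genus[names(labels)[labels == g], , drop = FALSE])))
  rownames(profiles) <- paste0("E", sort(unique(labels)))
  out <- list(
    k = k_range[best], labels = labels,
    medoids = fit$medoids[ren$order], ch_curve = ch,
    mean_silhouette = mean(sil), silhouette = sil,
    weak_structure = ch[best] < 1.2 * stats::median(ch),
    profiles = profiles, dist = d)
  class(out) <- "enterotype_solution"
  out
}

#' @export
print.enterotype_solution <- function(x, ...) {
  cat("enterotype_solution: K =", x$k, "over", length(x$labels), "samples;",
      "mean silhouette", round(x$mean_silhouette, 3),
      if (x$weak_structure) "(weak structure)" else "", "\n")
  cat("CH curve:", paste(names(x$ch_curve), round(x$ch_curve, 1),
                         sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Silhouette validation against random subsets
#'
#' Re-clusters `n_subsets` random subsets (fraction `frac`, sampled without
#' replacement) at the same K and compares the full solution's mean
#' silhouette to the subset distribution.
#'
#' @param rel_genus genus-level relative abundances.
#' @param solution an `enterotype_solution`.
#' @param n_subsets number of random subsets (default 100).
#' @param frac subset fraction (default 0.8).
#' @param seed integer seed.
#' @param pseudocount passed to [jsd_distance()].
#' @return list with `observed` mean silhouette, subset `null` values, and
#'   the `percentile` of the observed value within the null.
#' @export
silhouette_validation <- function(rel_genus, solution, n_subsets = 100,
                                  frac = 0.8, seed = 1, pseudocount = 1e-6) {
  n <- nrow(rel_genus)
  m <- max(ceiling(frac * n), solution$k + 2)
  set.seed(seed)
  null <- vapply(seq_len(n_subsets), function(i) {
    idx <- sort(sample.int(n, m))
    ds <- jsd_distance(rel_genus[idx, , drop = FALSE], pseudocount)
    fit <- pam_cluster(ds, solution$k)
    mean(silhouette_width(ds, fit$labels))
  }, numeric(1))
  obs <- solution$mean_silhouette
  list(observed = obs, null = null, percentile = 100 * mean(null <= obs))
}

#' Enterotype transition dynamics between d26 and d35
#'
#' Counts d26 -> d35 label pairs over pigs with samples at both ages and
#' reports the fraction of pigs whose enterotype changed.
#'
#' @param labels integer enterotype labels named by sample id.
#' @param metadata sample metadata linking samples to pigs and age points.
#' @return list with `counts` (KxK), row-normalised `probabilities`,
#'   `shift_fraction`, and `n_pigs`.
#' @export
enterotype_transitions <- function(labels, metadata) {
  md <- metadata[match(names(labels), metadata$sample_id), ]
  if (any(is.na(md$sample_id))) stop("labels contain samples absent from metadata")
  l26 <- labels[md$age_point == "d26"]
  l35 <- labels[md$age_point == "d35"]
  p26 <- md$pig_id[md$age_point == "d26"]
  p35 <- md$pig_id[md$age_point == "d35"]
  common <- intersect(p26, p35)
  if (!length(common)) stop("no pig has samples at both age points")
  k <- max(labels)
  counts <- table(factor(l26[match(common, p26)], levels = seq_len(k)),
                  factor(l35[match(common, p35)], levels = seq_len(k)))
  counts <- unclass(counts)
  dimnames(counts) <- list(d26 = paste0("E", seq_len(k)),
                           d35 = paste0("E", seq_len(k)))
  probs <- counts / pmax(rowSums(counts), 1)
  list(counts = counts, probabilities = probs,
       shift_fraction = 1 - sum(diag(counts)) / sum(counts),
       n_pigs = length(common))
}
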