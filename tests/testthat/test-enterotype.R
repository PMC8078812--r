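test_that("PAM matches exhaustive search on a colinear toy problem", {
  x <- c(0, 1, 10, 11)
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  fit <- pam_cluster(d, 2)
  expect_equal(unname(fit$labels), c(1, 1, 2, 2))
  expect_equal(fit$cost, 2)

  # oracle: enumerate every medoid pair
  best <- Inf
  for (i in 1:3) for (j in (i + 1):4) {
    cost <- sum(pmin(d[, i], d[, j]))
    best <- min(best, cost)
  }
  expect_equal(fit$cost, best)
})

test_that("PAM degenerate and invariance properties hold", {
  set.seed(5)
  P <- matrix(rgamma(12 * 8, 1), 12, 8)
  P <- P / rowSums(P)
  rownames(P) <- paste0("s", 1:12)
  d <- jsd_distance(P)
  # K = n - 1 leaves exactly one 2-point cluster
  fit <- pam_cluster(d, 11)
  expect_equal(sort(unname(table(fit$labels)), decreasing = TRUE),
               c(2, rep(1, 10)), ignore_attr = TRUE)
  # duplicating every point preserves the partition structure
  P2 <- rbind(P, P)
  rownames(P2) <- paste0("s", 1:24)
  fit1 <- pam_cluster(jsd_distance(P), 3)
  fit2 <- pam_cluster(jsd_distance(P2), 3)
  expect_equal(unname(fit2$labels[1:12]), unname(fit2$labels[13:24]))
  expect_equal(length(unique(paste(fit1$labels, fit2$labels[1:12]))), 3)
  # SWAP never increases the cost
  expect_true(all(diff(fit$cost_trace) <= 1e-12))
  expect_error(pam_cluster(d, 12), "smaller")
})

test_that("PAM cost is no worse than the reference implementation", {
  skip_if_not_installed("cluster")
  set.seed(6)
  for (i in 1:3) {
    P <- matrix(rgamma(40 * 10, 0.8), 40, 10)
    P <- P / rowSums(P)
    rownames(P) <- paste0("s", 1:40)
    d <- jsd_distance(P)
    mine <- pam_cluster(d, 4)
    ref <- cluster::pam(d, 4)
    ref_cost <- sum(as.matrix(d)[cbind(seq_len(40),
                                       match(ref$medoids, rownames(P))[ref$clustering])])
    expect_lte(mine$cost, ref_cost * (1 + 1e-8))
  }
})

test_that("the CH index agrees with a direct-summation oracle", {
  set.seed(8)
  P <- matrix(rgamma(15 * 6, 1), 15, 6)
  P <- P / rowSums(P)
  rownames(P) <- paste0("s", 1:15)
  d <- jsd_distance(P)
  labels <- rep(1:3, each = 5)
  ch <- ch_index(d, labels)
  # independent re-evaluation with explicit loops
  dm <- as.matrix(d)^2
  n <- 15; k <- 3
  total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) total <- total + dm[i, j] / n
  W <- 0
  for (g in 1:3) {
    idx <- which(labels == g)
    for (i in idx) for (j in idx) if (i < j) W <- W + dm[i, j] / length(idx)
  }
  oracle <- ((total - W) / (k - 1)) / (W / (n - k))
  expect_equal(ch, oracle, tolerance = 1e-9)
  expect_error(ch_index(d, rep(1, 15)), "two clusters")

  # identical points within clusters give W = 0, flagged as infinite
  dup <- rbind(P[1, ], P[1, ], P[2, ], P[2, ])
  rownames(dup) <- paste0("x", 1:4)
  res <- ch_index(jsd_distance(dup, pseudocount = 0), c(1, 1, 2, 2))
  expect_true(is.infinite(res))
})

test_that("CH prefers the true labels on well-separated clouds", {
  set.seed(12)
  wins <- 0
  for (i in 1:50) {
    pts <- rbind(matrix(rnorm(20, 0, 0.3), 10), matrix(rnorm(20, 4, 0.3), 10))
    rownames(pts) <- paste0("s", 1:20)
    d <- stats::dist(pts)
    truth <- rep(1:2, each = 10)
    rand <- sample(truth)
    if (ch_index(d, truth) > ch_index(d, rand) || all(rand == truth))
      wins <- wins + 1
  }
  expect_equal(wins, 50)
})

test_that("choose_k finds the generator's K and is order-invariant", {
  set.seed(13)
  # two-component mixture of compositions
  prof1 <- c(10, 1, 1, 1, 4, 1); prof2 <- c(1, 8, 1, 6, 1, 1)
  draw <- function(prof, n) {
    t(sapply(seq_len(n), function(i) {
      g <- rgamma(6, prof * 8); g / sum(g)
    }))
  }
  P <- rbind(draw(prof1, 30), draw(prof2, 30))
  colnames(P) <- c("Prevotella", "Bacteroides", "g3", "Faecalibacterium",
                   "g5", "g6")
  rownames(P) <- paste0("s", 1:60)
  sol <- choose_k(P, 2:6)
  expect_equal(sol$k, 2)

  # permuting sample order permutes labels identically
  perm <- sample(60)
  sol2 <- choose_k(P[perm, ], 2:6)
  expect_equal(unname(sol2$labels[rownames(P)]), unname(sol$labels))

  # a single structureless blob is flagged weak
  blob <- draw(rep(2, 6), 40)
  colnames(blob) <- colnames(P); rownames(blob) <- paste0("b", 1:40)
  expect_true(choose_k(blob, 2:6)$weak_structure)
})

test_that("silhouettes are bounded, near 1 when separated, near 0 when not", {
  set.seed(14)
  tight <- rbind(matrix(rnorm(30, 0, 0.001), 15), matrix(rnorm(30, 9, 0.001), 15))
  rownames(tight) <- paste0("s", 1:30)
  s <- silhouette_width(stats::dist(tight), rep(1:2, each = 15))
  expect_gt(mean(s), 0.99)

  noise <- matrix(rnorm(400), 200, 2)
  rownames(noise) <- paste0("n", 1:200)
  s2 <- silhouette_width(stats::dist(noise), sample(1:2, 200, TRUE))
  expect_lt(abs(mean(s2)), 0.1)
  expect_true(all(s2 >= -1 & s2 <= 1))
})

test_that("silhouette validation reports a percentile against subsets", {
  set.seed(15)
  P <- rbind(matrix(rgamma(20 * 6, c(9, 1, 1, 1, 1, 1) * 10), 20, 6, byrow = TRUE),
             matrix(rgamma(20 * 6, c(1, 9, 1, 1, 1, 1) * 10), 20, 6, byrow = TRUE))
  P <- P / rowSums(P)
  colnames(P) <- c("Prevotella", "Faecalibacterium", letters[1:4])
  rownames(P) <- paste0("s", 1:40)
  sol <- choose_k(P, 2:4)
  val <- silhouette_validation(P, sol, n_subsets = 20, seed = 3)
  expect_length(val$null, 20)
  expect_true(val$percentile >= 0 && val$percentile <= 100)
})

test_that("transition dynamics count switchers exactly", {
  md <- toy_metadata(4)
  labels <- stats::setNames(c(1, 1, 2, 3,  2, 1, 3, 4), md$sample_id)
  tr <- enterotype_transitions(labels, md)
  expect_equal(tr$shift_fraction, 0.75)
  expect_equal(tr$n_pigs, 4)
  expect_equal(sum(tr$counts), 4)

  same <- stats::setNames(rep(c(1, 2, 3, 2), 2), md$sample_id)
  expect_equal(enterotype_transitions(same, md)$shift_fraction, 0)
  md26 <- md[md$age_point == "d26", ]
  expect_error(
    enterotype_transitions(stats::setNames(c(1, 2, 1, 2),
                                           md26$sample_id), md26),
    "both age points|no pig")
})

test_that("canonical renaming orders clusters along the Prevotella gradient", {
  P <- rbind(a = c(0.05, 0.01, 0.94), b = c(0.06, 0.02, 0.92),
             c = c(0.40, 0.20, 0.40), d = c(0.45, 0.15, 0.40))
  colnames(P) <- c("Prevotella", "Faecalibacterium", "other")
  labels <- stats::setNames(c(1L, 1L, 2L, 2L), rownames(P))
  ren <- canonical_enterotypes(labels, P)
  expect_equal(unname(ren$labels), c(1L, 1L, 2L, 2L))
  flipped <- stats::setNames(c(2L, 2L, 1L, 1L), rownames(P))
  ren2 <- canonical_enterotypes(flipped, P)
  expect_equal(unname(ren2$labels), c(1L, 1L, 2L, 2L))
})
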