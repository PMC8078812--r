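make_regression <- function(n = 120, p = 8, beta = c(x1 = 2, x2 = -1.5),
                            sd = 1, seed = 1, farms = 6) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("i", 1:n), paste0("x", 1:p)))
  y <- as.numeric(X[, names(beta), drop = FALSE] %*% beta + rnorm(n, 0, sd))
  list(X = X, y = y, farm = rep(seq_len(farms), length.out = n))
}

test_that("OTU preselection finds a planted class separation", {
  md <- toy_metadata(20)
  rec <- compute_radg(md)
  set.seed(41)
  rec$radg <- rnorm(20)
  rec <- classify_within_farm(rec)
  rel <- matrix(abs(rnorm(40 * 12)), 40, 12,
                dimnames = list(md$sample_id, paste0("otu", 1:12)))
  plus_pigs <- rec$pig_id[rec$class == "rADG+"]
  rel[md$pig_id %in% plus_pigs, "otu7"] <-
    rel[md$pig_id %in% plus_pigs, "otu7"] + 6
  rel <- rel / rowSums(rel)
  sel <- preselect_otus(rel, rec, md, m = 3)
  expect_equal(sel$otu_id[sel$age == "d26"][1], "otu7")
  expect_equal(sel$otu_id[sel$age == "d35"][1], "otu7")

  expect_equal(nrow(preselect_otus(rel, rec, md, m = 0)), 0)
  perm <- sample(ncol(rel))
  sel2 <- preselect_otus(rel[, perm], rec, md, m = 3)
  expect_setequal(sel2$otu_id, sel$otu_id)
})

test_that("best subset recovers an exact linear relation", {
  reg <- make_regression(n = 60, p = 5, beta = c(x1 = 2), sd = 0)
  fit <- best_subset(reg$X, reg$y, p_max = 3)
  expect_equal(fit$features, "x1")
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["x1"]), 2, tolerance = 1e-9)
})

test_that("exhaustive search matches an independent enumeration oracle", {
  reg <- make_regression(n = 50, p = 10,
                         beta = c(x1 = 1, x4 = -0.8), sd = 1.5, seed = 2)
  fit <- best_subset(reg$X, reg$y, p_max = 3)
  expect_equal(fit$method, "exhaustive")
  # oracle: lm() over every subset of size <= 3
  best_a <- -Inf; best_feats <- NULL
  for (size in 1:3) for (feats in utils::combn(colnames(reg$X), size,
                                               simplify = FALSE)) {
    df <- data.frame(y = reg$y, reg$X[, feats, drop = FALSE])
    a <- summary(stats::lm(y ~ ., df))$adj.r.squared
    if (a > best_a) { best_a <- a; best_feats <- feats }
  }
  expect_setequal(fit$features, best_feats)
  expect_equal(fit$adj_r2, best_a, tolerance = 1e-9)
})

test_that("the criterion is non-decreasing in the subset-size cap", {
  reg <- make_regression(n = 80, p = 12, seed = 3)   # forces forward search
  fits <- lapply(c(2, 4, 6), function(pm)
    best_subset(reg$X, reg$y, p_max = pm, exhaustive_limit = 5))
  crit <- vapply(fits, `[[`, numeric(1), "adj_r2")
  expect_true(all(diff(crit) >= -1e-12))
})

test_that("pure-noise candidates do not survive farm cross-validation", {
  cvs <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(90 * 6), 90, 6,
                dimnames = list(NULL, paste0("x", 1:6)))
    y <- rnorm(90)
    farm <- rep(1:6, each = 15)
    fit <- best_subset(X, y, p_max = 3)
    leave_one_farm_out(X, y, farm, fit$features)$mean_r2
  }, numeric(1))
  expect_lte(mean(cvs), 0)
})

test_that("leave-one-farm-out is exact for a shared linear law and degrades
           with farm-specific shifts", {
  reg <- make_regression(n = 120, p = 4, beta = c(x1 = 1.2, x2 = 0.5), sd = 0)
  cv <- leave_one_farm_out(reg$X, reg$y, reg$farm, c("x1", "x2"))
  expect_equal(unname(cv$r2), rep(1, 6), tolerance = 1e-9)

  mean_cv <- vapply(c(0, 2, 5), function(shift) {
    y2 <- reg$y + shift * (reg$farm - mean(reg$farm)) + rnorm(120, 0, 0.5)
    leave_one_farm_out(reg$X, y2, reg$farm, c("x1", "x2"))$mean_r2
  }, numeric(1))
  expect_true(all(diff(mean_cv) < 0))

  expect_error(leave_one_farm_out(reg$X, reg$y, rep(1:2, 60), "x1"),
               "3 farms")
})

test_that("weaning weight alone does not predict an independent rADG", {
  set.seed(44)
  n <- 280
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "weight_d26"))
  y <- rnorm(n)                      # radg independent of weight
  farm <- rep(1:14, each = 20)
  cv <- leave_one_farm_out(X, y, farm, "weight_d26")
  expect_lt(abs(cv$mean_r2), 0.2)
})

test_that("true features are recovered at moderate signal-to-noise", {
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 250
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("x", 1:10)))
    # two real features, noise scaled for in-sample adjusted R2 near 0.3
    y <- 0.45 * X[, "x1"] + 0.45 * X[, "x2"] + rnorm(n)
    fit <- best_subset(X, y, p_max = 4)
    if (all(c("x1", "x2") %in% fit$features)) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
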