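# Best-subset linear prediction of continuous rADG from microbiota features
# with leave-one-farm-out validation.

#' Univariate preselection of OTU predictors of the growth class
#'
#' Ranks OTUs, separately per age point, by the absolute standardised
#' Wilcoxon rank-sum statistic between rADG+ and rADG- samples, and keeps
#' the top `m` per age. A transparent, seed-free stand-in for multivariate
#' discriminant preselection.
#'
#' @param rel_otu OTU-level relative abundances (samples x OTUs).
#' @param records classified growth records.
#' @param metadata sample metadata for the rows of `rel_otu`.
#' @param m OTUs kept per age point (default 10).
#' @return data.frame with `otu_id`, `age`, `score` for the selected OTUs.
#' @export
preselect_otus <- function(rel_otu, records, metadata, m = 10) {
  if (m == 0) return(data.frame(otu_id = character(), age = character(),
                                score = numeric(), stringsAsFactors = FALSE))
  md <- metadata[match(rownames(rel_otu), metadata$sample_id), ]
  cls <- records$class[match(md$pig_id, records$pig_id)]
  keep <- cls %in% c("rADG+", "rADG-")
  out <- do.call(rbind, lapply(c("d26", "d35"), function(age) {
    idx <- keep & md$age_point == age
    g <- cls[idx] == "rADG+"
    n1 <- sum(g); n2 <- sum(!g)
    score <- vapply(colnames(rel_otu), function(ot) {
      r <- rank(rel_otu[idx, ot])
      W <- sum(r[g]) - n1 * (n1 + 1) / 2
      abs(W - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    }, numeric(1))
    top <- order(score, decreasing = TRUE)[seq_len(min(m, length(score)))]
    data.frame(otu_id = colnames(rel_otu)[top], age = age,
               score = score[top], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Assemble the pig-level feature matrix
#'
#' One row per pig having samples at both ages; columns are the supplied
#' taxa tables at d26 and d35 (suffixed `_d26` / `_d35`) plus optionally the
#' weaning weight.
#'
#' @param tables named list of relative-abundance matrices (samples x
#'   features), e.g. family, genus and preselected-OTU tables.
#' @param metadata sample metadata.
#' @param records growth records (supplies rADG and farm).
#' @param include_weight add `weight_d26` as a feature (default FALSE).
#' @return list with `X` (pigs x features), `y` (rADG), `farm` vector.
#' @export
build_feature_matrix <- function(tables, metadata, records,
                                 include_weight = FALSE) {
  md26 <- metadata[metadata$age_point == "d26", ]
  md35 <- metadata[metadata$age_point == "d35", ]
  common <- intersect(md26$pig_id, md35$pig_id)
  common <- intersect(common, records$pig_id)
  if (!length(common)) stop("no pig has data at both age points")
  blocks <- lapply(names(tables), function(nm) {
    tab <- tables[[nm]]
    s26 <- md26$sample_id[match(common, md26$pig_id)]
    s35 <- md35$sample_id[match(common, md35$pig_id)]
    if (!all(c(s26, s35) %in% rownames(tab)))
      stop("table '", nm, "' lacks some samples of complete pigs")
    b <- cbind(tab[s26, , drop = FALSE], tab[s35, , drop = FALSE])
    colnames(b) <- c(paste0(colnames(tab), "_d26"),
                     paste0(colnames(tab), "_d35"))
    b
  })
  X <- if (length(blocks)) do.call(cbind, blocks) else
    matrix(numeric(0), nrow = length(common), ncol = 0)
  rownames(X) <- common
  if (include_weight)
    X <- cbind(X, weight_d26 = records$weight_d26[match(common, records$pig_id)])
  list(X = X, y = records$radg[match(common, records$pig_id)],
       farm = records$farm_id[match(common, records$pig_id)])
}

adj_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

fit_r2 <- function(X, y) {
  fit <- stats::lm.fit(cbind(1, X), y)
  if (fit$rank < ncol(X) + 1) return(NA_real_)   # rank-deficient: reject
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Best-subset linear model by adjusted R-squared
#'
#' Exhaustive search over all subsets of size `<= p_max` when there are at
#' most `exhaustive_limit` candidate features, otherwise forward stepwise
#' selection up to `p_max` (the best model over all visited sizes is kept).
#' The criterion is the adjusted R-squared of the OLS fit; rank-deficient
#' subsets are rejected; ties break lexicographically on the sorted feature
#' names.
#'
#' @param X feature matrix (observations x candidates).
#' @param y response (rADG).
#' @param p_max maximum subset size (default 10).
#' @param exhaustive_limit candidate count up to which the search is
#'   exhaustive (default 20).
#' @return list with `features`, `coefficients` (incl. intercept),
#'   `adj_r2`, and the search `method`.
#' @export
best_subset <- function(X, y, p_max = 10, exhaustive_limit = 20) {
  stopifnot(nrow(X) > p_max + 2)
  cand <- colnames(X)
  best <- list(adj_r2 = -Inf, features = character())
  consider <- function(feats) {
    r2 <- fit_r2(X[, feats, drop = FALSE], y)
    if (is.na(r2)) return()
    a <- adj_r2(r2, nrow(X), length(feats))
    key <- paste(sort(feats), collapse = "|")
    if (a > best$adj_r2 + 1e-12 ||
        (abs(a - best$adj_r2) <= 1e-12 &&
         key < paste(sort(best$features), collapse = "|")))
      best <<- list(adj_r2 = a, features = feats)
  }
  if (length(cand) <= exhaustive_limit) {
    method <- "exhaustive"
    for (size in seq_len(min(p_max, length(cand)))) {
      cmb <- utils::combn(cand, size, simplify = FALSE)
      for (feats in cmb) consider(feats)
    }
  } else {
    method <- "forward"
    current <- character()
    while (length(current) < p_max) {
      remaining <- setdiff(cand, current)
      scores <- vapply(remaining, function(f) {
        r2 <- fit_r2(X[, c(current, f), drop = FALSE], y)
        if (is.na(r2)) -Inf else adj_r2(r2, nrow(X), length(current) + 1)
      }, numeric(1))
      if (!any(is.finite(scores))) break
      nxt <- remaining[order(-scores, remaining)][1]
      current <- c(current, nxt)
      consider(current)
    }
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1,
                             X[, best$features, drop = FALSE]), y)
  list(features = best$features,
       coefficients = stats::setNames(fit$coefficients,
                                      c("(Intercept)", best$features)),
       adj_r2 = best$adj_r2, method = method)
}

#' Leave-one-farm-out validation of a fixed feature set
#'
#' For each farm, refits the coefficients of the selected features on all
#' other farms, predicts the held-out farm, and computes the held-out
#' `R_i^2 = 1 - SSE / SST` (SST around the held-out farm's own mean),
#' adjusted as `1 - (1 - R^2)(n_i - 1)/(n_i - p - 1)`. Farms with
#' `n_i <= p + 1` are skipped with a warning. The mean over farms keeps
#' negative fold values (no flooring).
#'
#' @param X feature matrix (pigs x features).
#' @param y response.
#' @param farm farm id per pig (at least 3 farms).
#' @param features character vector of selected feature names.
#' @return list with per-farm `r2` (adjusted), `mean_r2`, and `skipped`.
#' @export
leave_one_farm_out <- function(X, y, farm, features) {
  farms <- unique(farm)
  if (length(farms) < 3) stop("need at least 3 farms for cross-validation")
  p <- length(features)
  r2 <- c(); skipped <- c()
  for (f in farms) {
    test <- farm == f
    n_i <- sum(test)
    if (n_i <= p + 1) {
      warning("farm ", f, " has too few pigs for the model size; skipped")
      skipped <- c(skipped, f)
      next
    }
    fit <- stats::lm.fit(cbind(1, X[!test, features, drop = FALSE]), y[!test])
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    pred <- cbind(1, X[test, features, drop = FALSE]) %*% coefs
    sse <- sum((y[test] - pred)^2)
    sst <- sum((y[test] - mean(y[test]))^2)
    r2 <- c(r2, stats::setNames(adj_r2(1 - sse / sst, n_i, p), f))
  }
  list(r2 = r2, mean_r2 = mean(r2), skipped = skipped)
}
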