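# End-to-end orchestration: simulate/ingest -> QC -> diversity -> enterotypes
# -> growth -> associations -> prediction, with per-stage seeds and a
# machine-readable report.

#' Default pipeline run configuration
#'
#' @param cohort a `cohort_config` for synthetic mode (default
#'   [calibrate_default_config()]); ignored when `paths` is given.
#' @param paths optional named list with `counts`, `taxonomy`, `metadata`
#'   TSV paths for real-data mode.
#' @param seed global seed; per-stage seeds derive from it via
#'   [derive_seed()].
#' @param out_dir optional directory for per-stage TSV outputs.
#' @return a `run_config` list of all stage parameters.
#' @export
run_config <- function(cohort = NULL, paths = NULL, seed = 1, out_dir = NULL) {
  structure(list(
    cohort = cohort, paths = paths, seed = seed, out_dir = out_dir,
    min_reads = 5000, min_prevalence = 5, min_frac_total = 1e-4,
    rarefaction_depth = 4831,
    beta_metric = "bray_curtis", n_perm = 999,
    k_range = 2:8, pseudocount = 1e-6, n_subsets = 100,
    lower_frac = 0.40, upper_frac = 0.40,
    alpha_pre = 0.1, n_perm_two_step = 1000,
    p_max = 10, preselect_m = 10
  ), class = "run_config")
}

stage_log <- function(report, stage, ...) {
  msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  message(msg)
  report$log <- c(report$log, msg)
  report
}

#' Run the full analysis pipeline
#'
#' Executes all stages in dependency order on either a synthetic cohort or
#' files read from `config$paths`. Any stage failure aborts with a message
#' naming the stage. Returns a structured report; when `config$out_dir` is
#' set, per-stage tables are also written as TSV.
#'
#' @param config a [run_config()].
#' @return a `run_report` list: sample/OTU bookkeeping per filter, alpha
#'   and beta diversity results, the enterotype solution and transitions,
#'   growth class summaries, percent changes, two-step results, and the
#'   prediction table with its leave-one-farm-out validation.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- list(seed = config$seed, log = character())
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # ingest
  dat <- run_stage("ingest", {
    if (!is.null(config$paths)) {
      list(counts = read_count_table(config$paths$counts),
           taxonomy = read_taxonomy(config$paths$taxonomy),
           metadata = read_metadata(config$paths$metadata))
    } else {
      cohort <- config$cohort %||% calibrate_default_config()
      generate_cohort(cohort, seed = derive_seed(config$seed, "simulate"))
    }
  })
  report <- stage_log(report, "ingest", nrow(dat$counts), " samples, ",
                      ncol(dat$counts), " OTUs")

  # qc + filtering
  filt <- run_stage("filter", {
    tab <- qc_filter_samples(dat$counts, config$min_reads)
    excluded <- attr(tab, "excluded")
    tab <- filter_otus(tab, dat$taxonomy, config$min_prevalence,
                       config$min_frac_total)
    list(tab = tab, excluded = excluded)
  })
  md <- dat$metadata[dat$metadata$sample_id %in% rownames(filt$tab), ]
  report$counts_in <- c(samples = nrow(dat$counts), otus = ncol(dat$counts))
  report$counts_kept <- c(samples = nrow(filt$tab), otus = ncol(filt$tab))
  report$samples_per_age <- table(md$age_point)
  report <- stage_log(report, "filter", "kept ", nrow(filt$tab), "/",
                      nrow(dat$counts), " samples and ", ncol(filt$tab), "/",
                      ncol(dat$counts), " OTUs")

  # diversity (alpha on rarefied counts; beta + tests on relative abundances)
  div <- run_stage("diversity", {
    rar <- rarefy(filt$tab, config$rarefaction_depth,
                  seed = derive_seed(config$seed, "rarefy"))
    alpha <- alpha_diversity(rar)
    alpha$age_point <- md$age_point[match(alpha$sample_id, md$sample_id)]
    rel_otu <- to_relative(filt$tab)
    d <- beta_distance(rel_otu, config$beta_metric)
    ad <- permanova(d, alpha$age_point, config$n_perm,
                    seed = derive_seed(config$seed, "permanova"))
    disp <- dispersion_test(d, md$farm_id, config$n_perm,
                            seed = derive_seed(config$seed, "dispersion"))
    list(alpha = alpha, permanova_age = ad, dispersion_farm = disp)
  })
  report$alpha_by_age <- stats::aggregate(
    cbind(richness, shannon) ~ age_point, div$alpha, mean)
  report$permanova_age <- div$permanova_age[c("F", "p")]
  report$dispersion_farm <- div$dispersion_farm[c("F", "p")]
  report <- stage_log(report, "diversity",
                      "age PERMANOVA F=", round(div$permanova_age$F, 2),
                      " p=", div$permanova_age$p,
                      " (farm dispersion p=", div$dispersion_farm$p,
                      "; a significant farm dispersion cautions against a",
                      " farm PERMANOVA)")

  # enterotypes on genus-level relative abundances of the unrarefied table
  ent <- run_stage("enterotype", {
    rel_genus <- to_relative(aggregate_taxa(filt$tab, dat$taxonomy, "genus"))
    sol <- choose_k(rel_genus, config$k_range, config$pseudocount)
    tr <- enterotype_transitions(sol$labels, md)
    list(rel_genus = rel_genus, solution = sol, transitions = tr)
  })
  report$enterotype_k <- ent$solution$k
  report$ch_curve <- ent$solution$ch_curve
  report$transition_counts <- ent$transitions$counts
  report$shift_fraction <- ent$transitions$shift_fraction
  report <- stage_log(report, "enterotype", "K=", ent$solution$k,
                      ", shift fraction ",
                      round(ent$transitions$shift_fraction, 3))

  # growth classes
  gro <- run_stage("growth", {
    rec <- classify_within_farm(compute_radg(dat$metadata),
                                config$lower_frac, config$upper_frac)
    list(records = rec, summary = class_summary(rec))
  })
  report$class_summary <- gro$summary
  report <- stage_log(report, "growth",
                      paste(gro$summary$class, gro$summary$n, collapse = ", "))

  # associations
  asc <- run_stage("associate", {
    rel_family <- to_relative(aggregate_taxa(filt$tab, dat$taxonomy, "family"))
    pc <- percent_change(rel_family, md)
    kw_farm <- kruskal_dunn(
      rel_family[md$age_point == "d26", , drop = FALSE],
      md$farm_id[md$age_point == "d26"])
    ts <- two_step_radg(ent$rel_genus, gro$records, md,
                        alpha_pre = config$alpha_pre,
                        n_perm = config$n_perm_two_step,
                        seed = derive_seed(config$seed, "two_step"))
    list(rel_family = rel_family, percent_change = pc,
         kw_farm_d26 = kw_farm, two_step = ts)
  })
  report$percent_change <- asc$percent_change
  report$two_step <- asc$two_step$step2
  report <- stage_log(report, "associate", length(asc$two_step$retained),
                      " taxa retained for step 2")

  # prediction
  prd <- run_stage("predict", {
    rel_otu <- to_relative(filt$tab)
    pre <- preselect_otus(rel_otu, gro$records, md, config$preselect_m)
    fm <- build_feature_matrix(
      list(family = asc$rel_family, genus = ent$rel_genus,
           otu = rel_otu[, unique(pre$otu_id), drop = FALSE]),
      md, gro$records)
    model <- best_subset(fm$X, fm$y, config$p_max)
    cv <- leave_one_farm_out(fm$X, fm$y, fm$farm, model$features)
    base <- build_feature_matrix(list(), md, gro$records, include_weight = TRUE)
    cv_w <- leave_one_farm_out(base$X, base$y, base$farm, "weight_d26")
    list(model = model, cv = cv, cv_weight_only = cv_w)
  })
  report$model <- prd$model
  report$cv_mean_r2 <- prd$cv$mean_r2
  report$cv_weight_only_r2 <- prd$cv_weight_only$mean_r2
  report <- stage_log(report, "predict",
                      "in-sample adj R2=", round(prd$model$adj_r2, 3),
                      ", farm-CV mean R2=", round(prd$cv$mean_r2, 3),
                      ", weight-only ", round(prd$cv_weight_only$mean_r2, 3))

  if (!is.null(out)) {
    utils::write.table(div$alpha, file.path(out, "alpha.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = names(ent$solution$labels),
                 enterotype = paste0("E", ent$solution$labels)),
      file.path(out, "enterotypes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gro$records, file.path(out, "growth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(asc$percent_change, file.path(out, "percent_change.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed ", x$seed, ")\n", sep = "")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}
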