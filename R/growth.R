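# Relative average daily gain (rADG) and the within-farm growth classes.

#' Compute per-pig growth records
#'
#' `adg = (W_d48 - W_d26) / N` (kg/day) and
#' `radg = 1000 * adg / W_d26` (g/kg/day): post-weaning gain relative to the
#' weaning weight, the study's robustness proxy. Metadata rows are collapsed
#' to one record per pig; pigs with a nonpositive interval or missing weight
#' are skipped with a warning.
#'
#' @param metadata sample metadata (see [read_metadata()]).
#' @return data.frame with one row per pig: `pig_id`, `farm_id`,
#'   `weight_d26`, `weight_d48`, `interval_days`, `adg`, `radg`, and a
#'   `class` column initialised to `"excluded"`.
#' @export
compute_radg <- function(metadata) {
  md <- metadata[!duplicated(metadata$pig_id), ]
  ok <- is.finite(md$weight_d26) & is.finite(md$weight_d48) &
    md$weight_d26 > 0 & is.finite(md$interval_days) & md$interval_days > 0
  if (any(!ok)) {
    warning("skipping ", sum(!ok), " pig(s) with missing weights or interval")
    md <- md[ok, ]
  }
  adg <- (md$weight_d48 - md$weight_d26) / md$interval_days
  data.frame(
    pig_id = md$pig_id, farm_id = md$farm_id,
    weight_d26 = md$weight_d26, weight_d48 = md$weight_d48,
    interval_days = md$interval_days,
    adg = adg, radg = 1000 * adg / md$weight_d26,
    class = "excluded", stringsAsFactors = FALSE)
}

#' Assign within-farm rADG growth classes
#'
#' Within each farm, pigs are sorted by rADG (ties broken by pig id): the
#' bottom `floor(lower_frac * n)` become `rADG-`, the top
#' `floor(upper_frac * n)` become `rADG+`, and the middle pigs stay
#' `excluded`. With the default 40/40 split an 18-pig farm yields 7 + 7
#' classed pigs and 4 excluded. Farms with fewer than 5 pigs are skipped
#' with a warning.
#'
#' @param records output of [compute_radg()].
#' @param lower_frac,upper_frac class fractions (defaults 0.40).
#' @return `records` with the `class` column filled in.
#' @export
classify_within_farm <- function(records, lower_frac = 0.40, upper_frac = 0.40) {
  stopifnot(lower_frac >= 0, upper_frac >= 0, lower_frac + upper_frac <= 1)
  records$class <- "excluded"
  for (f in unique(records$farm_id)) {
    idx <- which(records$farm_id == f)
    n <- length(idx)
    if (n < 5) {
      warning("farm ", f, " has fewer than 5 pigs; skipped")
      next
    }
    ord <- idx[order(records$radg[idx], records$pig_id[idx])]
    n_lo <- floor(lower_frac * n)
    n_hi <- floor(upper_frac * n)
    if (n_lo > 0) records$class[ord[seq_len(n_lo)]] <- "rADG-"
    if (n_hi > 0) records$class[ord[n - n_hi + seq_len(n_hi)]] <- "rADG+"
  }
  records
}

#' Summarise growth classes
#'
#' @param records classified growth records.
#' @return data.frame per class with `n`, mean and sem of rADG, and mean
#'   weaning weight (`weight_d26`).
#' @export
class_summary <- function(records) {
  cls <- sort(unique(records$class))
  out <- do.call(rbind, lapply(cls, function(cl) {
    r <- records[records$class == cl, ]
    data.frame(class = cl, n = nrow(r),
               radg_mean = mean(r$radg),
               radg_sem = stats::sd(r$radg) / sqrt(nrow(r)),
               weight_d26_mean = mean(r$weight_d26),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
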