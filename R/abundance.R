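#' Construct and validate a count table
#'
#' A count table is an integer matrix of samples (rows) by OTUs (columns)
#' with unique, non-empty dimnames. It is the raw observational unit of the
#' workflow: every downstream step (QC, filtering, rarefaction, aggregation)
#' consumes and returns this shape.
#'
#' @param counts numeric matrix, samples x OTUs, with rownames (sample ids)
#'   and colnames (OTU ids).
#' @return The validated integer matrix with class `"count_table"`.
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry sample ids (rownames) and OTU ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ", rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU id: ", colnames(counts)[duplicated(colnames(counts))][1])
  if (any(is.na(counts))) stop("counts contain NA")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (max(abs(counts - round(counts))) > 1e-8) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop("non-integer count at sample '", rownames(counts)[bad[1]],
         "', OTU '", colnames(counts)[bad[2]], "'")
  }
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_table", class(counts))
  counts
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x), "samples x", ncol(x), "OTUs;",
      "total reads", sum(x), "\n")
  invisible(x)
}

ranks6 <- c("phylum", "class", "order", "family", "genus", "species")

#' Read a tab-delimited count table
#'
#' The canonical dialect has samples as rows with a leading `sample_id`
#' column. A transposed dialect (OTUs as rows, leading `otu_id` column) is
#' auto-detected from the header and transposed on read.
#'
#' @param path file path to a TSV with a header row.
#' @return A [count_table()].
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs an id column plus counts: ", path)
  idcol <- names(df)[1]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (identical(tolower(idcol), "otu_id") || identical(idcol, "#OTU ID")) m <- t(m)
  count_table(m)
}

#' Write a count table as TSV (samples as rows)
#' @param table a [count_table()].
#' @param path output path.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

parse_greengenes <- function(s) {
  out <- stats::setNames(rep("unknown", 6L), ranks6)
  if (is.na(s) || !nzchar(s)) return(out)
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  prefix <- c(p = "phylum", c = "class", o = "order", f = "family",
              g = "genus", s = "species")
  for (p in parts) {
    m <- regmatches(p, regexec("^([kpcofgs])__(.*)$", p))[[1]]
    if (length(m) == 3 && m[2] %in% names(prefix) && nzchar(trimws(m[3])))
      out[prefix[m[2]]] <- trimws(m[3])
  }
  out
}

#' Read an OTU taxonomy map
#'
#' Accepts either an `otu_id` column plus the six rank columns
#' (phylum..species), or an `otu_id` column plus a single `taxonomy` column
#' holding Greengenes-style strings (`k__Bacteria; p__Firmicutes; ...`).
#' Blank or missing ranks are normalised to the sentinel `"unknown"`, which
#' is never merged with a named rank downstream.
#'
#' @param path TSV path.
#' @return data.frame with columns `otu_id`, `phylum`, ..., `species`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!"otu_id" %in% names(df)) stop("taxonomy file lacks an otu_id column: ", path)
  if ("taxonomy" %in% names(df)) {
    mat <- t(vapply(df$taxonomy, parse_greengenes, character(6)))
    out <- data.frame(otu_id = as.character(df$otu_id), mat,
                      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    missing <- setdiff(ranks6, names(df))
    if (length(missing))
      stop("taxonomy file lacks rank column(s): ", paste(missing, collapse = ", "))
    out <- df[, c("otu_id", ranks6)]
    out$otu_id <- as.character(out$otu_id)
    for (r in ranks6) {
      v <- trimws(as.character(out[[r]]))
      v[is.na(v) | !nzchar(v)] <- "unknown"
      out[[r]] <- v
    }
  }
  if (anyDuplicated(out$otu_id))
    stop("duplicate otu_id in taxonomy: ", out$otu_id[duplicated(out$otu_id)][1])
  out
}

#' Write a taxonomy map as TSV
#' @param taxonomy data.frame as returned by [read_taxonomy()].
#' @param path output path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

metadata_cols <- c("sample_id", "pig_id", "farm_id", "age_point",
                   "weight_d26", "weight_d35", "weight_d48", "interval_days")

#' Validate a sample metadata table
#' @param df data.frame with the required columns.
#' @return the validated data.frame.
#' @export
validate_metadata <- function(df) {
  missing <- setdiff(metadata_cols, names(df))
  if (length(missing))
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         df$sample_id[duplicated(df$sample_id)][1])
  key <- paste(df$pig_id, df$age_point)
  if (anyDuplicated(key))
    stop("pig appears twice at one age point: ", key[duplicated(key)][1])
  if (!all(df$age_point %in% c("d26", "d35")))
    stop("age_point must be 'd26' or 'd35'; offending sample: ",
         df$sample_id[!df$age_point %in% c("d26", "d35")][1])
  for (w in c("weight_d26", "weight_d35", "weight_d48")) {
    bad <- which(!is.finite(df[[w]]) | df[[w]] <= 0)
    if (length(bad))
      stop("nonpositive ", w, " for sample '", df$sample_id[bad[1]], "'")
  }
  bad <- which(!is.finite(df$interval_days) | df$interval_days <= 0)
  if (length(bad))
    stop("nonpositive interval_days for sample '", df$sample_id[bad[1]], "'")
  df
}

#' Read a sample metadata table
#' @param path TSV path with the exact columns `sample_id, pig_id, farm_id,
#'   age_point, weight_d26, weight_d35, weight_d48, interval_days`.
#' @return validated data.frame.
#' @export
read_metadata <- function(path) {
  validate_metadata(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Drop low-depth samples
#'
#' Removes samples whose total read count falls below `min_reads`
#' (default 5000, the study's quality cutoff). Excluded sample ids are
#' attached as attribute `"excluded"`.
#'
#' @param table a [count_table()].
#' @param min_reads minimum row sum retained (samples with fewer reads than
#'   this are excluded; a sample with exactly `min_reads` reads is kept).
#' @return the filtered count_table.
#' @export
qc_filter_samples <- function(table, min_reads = 5000) {
  stopifnot(min_reads >= 0)
  keep <- rowSums(table) >= min_reads
  if (!any(keep)) stop("all samples fall below ", min_reads, " reads")
  out <- count_table(unclass(table)[keep, , drop = FALSE])
  attr(out, "excluded") <- rownames(table)[!keep]
  out
}

#' Filter OTUs on known phylum, prevalence and total abundance
#'
#' Retains OTUs that (i) have a known phylum, (ii) are present (nonzero) in
#' at least `min_prevalence` samples, and (iii) carry strictly more than
#' `min_frac_total` of the grand total of reads of the input table. Column
#' order is preserved. The grand total is taken over the whole input table,
#' before any OTU is removed.
#'
#' @param table a [count_table()].
#' @param taxonomy taxonomy data.frame covering every OTU in `table`.
#' @param min_prevalence minimum number of samples with a nonzero count
#'   (default 5).
#' @param min_frac_total strict lower bound on column sum / grand total
#'   (default 1e-4, i.e. 0.01%).
#' @return the filtered count_table.
#' @export
filter_otus <- function(table, taxonomy, min_prevalence = 5,
                        min_frac_total = 1e-4) {
  miss <- setdiff(colnames(table), taxonomy$otu_id)
  if (length(miss)) stop("taxonomy missing for OTU '", miss[1], "'")
  phyl <- taxonomy$phylum[match(colnames(table), taxonomy$otu_id)]
  grand <- sum(as.numeric(table))
  prevalence <- colSums(table > 0)
  frac <- colSums(table) / grand
  keep <- phyl != "unknown" & prevalence >= min_prevalence & frac > min_frac_total
  count_table(unclass(table)[, keep, drop = FALSE])
}

rarefy_row <- function(x, depth) {
  tot <- sum(x)
  if (tot == depth) return(x)
  picked <- sample.int(tot, depth)        # reads without replacement
  breaks <- c(0, cumsum(x))
  tabulate(findInterval(picked, breaks, left.open = TRUE), nbins = length(x))
}

#' Rarefy a count table to fixed depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric), so each rarefied row sums exactly to `depth` and no
#' count exceeds its original value.
#'
#' @param table a [count_table()].
#' @param depth target reads per sample (default 4831).
#' @param seed mandatory integer seed.
#' @return rarefied count_table.
#' @export
rarefy <- function(table, depth = 4831, seed) {
  if (missing(seed)) stop("rarefy requires an explicit seed")
  short <- rowSums(table) < depth
  if (any(short))
    stop("sample '", rownames(table)[short][1], "' has fewer than ",
         depth, " reads")
  set.seed(seed)
  out <- t(apply(unclass(table), 1, rarefy_row, depth = depth))
  dimnames(out) <- dimnames(table)
  count_table(out)
}

#' Aggregate OTU counts to a taxonomic rank
#'
#' Sums OTU columns sharing the same named value at `rank`; OTUs with the
#' sentinel value form a single explicit `unknown-<rank>` column rather than
#' being dropped, so grand totals are conserved.
#'
#' @param table a [count_table()].
#' @param taxonomy taxonomy data.frame covering every OTU.
#' @param rank one of `"phylum","class","order","family","genus"`.
#' @return count_table with one column per distinct rank value.
#' @export
aggregate_taxa <- function(table, taxonomy,
                           rank = c("genus", "family", "order", "class", "phylum")) {
  rank <- match.arg(rank)
  miss <- setdiff(colnames(table), taxonomy$otu_id)
  if (length(miss)) stop("taxonomy missing for OTU '", miss[1], "'")
  grp <- taxonomy[[rank]][match(colnames(table), taxonomy$otu_id)]
  grp[grp == "unknown"] <- paste0("unknown-", rank)
  out <- t(rowsum(t(unclass(table)), group = grp, reorder = FALSE))
  count_table(out)
}

#' Row-normalise a table to relative abundances
#'
#' @param table count or abundance matrix, samples x taxa.
#' @return numeric matrix whose rows sum to 1; all-zero rows stay zero.
#' @export
to_relative <- function(table) {
  m <- unclass(table)
  storage.mode(m) <- "double"
  rs <- rowSums(m)
  rs[rs == 0] <- 1          # all-zero rows stay all-zero
  out <- m / rs
  class(out) <- c("rel_abundance", "matrix", "array")
  out
}
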