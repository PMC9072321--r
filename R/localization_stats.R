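#' Normalize a count matrix to counts per million
#'
#' Each sample (column) is scaled so its total over all tiles is 1e6,
#' preserving relative tile proportions within the sample.
#'
#' @param counts Tile x sample numeric matrix.
#' @return Matrix of the same shape; every column sums to 1e6.
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  bad <- which(!(tot > 0))
  if (length(bad) > 0) {
    stop("sample(s) with non-positive total counts: ",
         paste(colnames(counts)[bad], collapse = ", "))
  }
  sweep(counts, 2, tot / 1e6, `/`)
}

#' Per-replicate normalized log2 ratios between paired samples
#'
#' Adds a pseudocount of 0.5 to every raw count, normalizes each sample to
#' counts per million, and computes `log2(norm_num / norm_den)` per tile for
#' each (numerator, denominator) sample pair. Used for Nuc/Cyto ratios
#' (numerator = nuclear) and identically for WCE/input expression ratios.
#' A tile enters a pair's ratios only if its raw count is at least
#' `min_reads` in both members of the pair.
#'
#' @param counts Tile x sample raw count matrix.
#' @param pairs Data frame with columns `numerator`, `denominator` (sample
#'   names) and optionally `replicate`; one row per replicate pair.
#' @param pseudocount Added to raw counts before normalization (default 0.5).
#' @param min_reads Per-sample minimum raw reads for a tile to be ratioed.
#' @return A `ratio_table`: data.table with `tile_id`, `replicate`,
#'   `num_level`, `den_level` (CPM), `log2_ratio`.
#' @export
compute_ratios <- function(counts, pairs, pseudocount = 0.5, min_reads = 20L) {
  counts <- as.matrix(counts)
  pairs <- as.data.table(pairs)
  stopifnot(all(c("numerator", "denominator") %in% names(pairs)))
  missing <- setdiff(unique(c(pairs$numerator, pairs$denominator)),
                     colnames(counts))
  if (length(missing) > 0) {
    stop("pair sample(s) absent from the count matrix: ",
         paste(missing, collapse = ", "))
  }
  if (!"replicate" %in% names(pairs)) pairs$replicate <- seq_len(nrow(pairs))
  norm <- normalize_counts(counts + pseudocount)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    num <- pairs$numerator[i]; den <- pairs$denominator[i]
    keep <- counts[, num] >= min_reads & counts[, den] >= min_reads
    data.table(
      tile_id = rownames(counts)[keep],
      replicate = pairs$replicate[i],
      num_level = norm[keep, num],
      den_level = norm[keep, den],
      log2_ratio = log2(norm[keep, num] / norm[keep, den])
    )
  })
  tab <- data.table::rbindlist(out)
  class(tab) <- c("ratio_table", class(tab))
  tab
}

#' Summarize replicate ratios and call localized tiles
#'
#' Per tile: the median log2 ratio across replicates and a two-sided
#' one-sample test of the replicate ratios against 0 (t-test by default).
#' A tile is called `cytoplasmic` when median < -threshold and P < alpha,
#' `nuclear` when median > +threshold and P < alpha, else `unclassified`.
#' With a single replicate the class is assigned from the threshold alone
#' and the P-value is reported absent. A BH-adjusted P column is emitted for
#' reference but does not enter the classification.
#'
#' @param ratios A `ratio_table` from [compute_ratios].
#' @param threshold Absolute median log2 ratio required (default 0.3,
#'   roughly a 25% difference).
#' @param alpha Per-tile significance level (default 0.05, unadjusted).
#' @param test `"t"` (one-sample t-test) or `"wilcoxon"` (signed-rank).
#' @return data.table with `tile_id`, `n_rep`, `median_log2_ratio`,
#'   `p_value`, `padj`, `class`.
#' @export
call_localized_tiles <- function(ratios, threshold = 0.3, alpha = 0.05,
                                 test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  ratios <- as.data.table(ratios)
  one_p <- function(x) {
    if (length(x) < 2L) return(NA_real_)
    if (test == "t") {
      if (sd(x) == 0) return(if (all(x == 0)) 1 else NA_real_)
      t.test(x, mu = 0)$p.value
    } else {
      wilcox.test(x, mu = 0, exact = FALSE)$p.value
    }
  }
  summ <- ratios[, list(n_rep = .N,
                        median_log2_ratio = median(log2_ratio),
                        p_value = one_p(log2_ratio)),
                 by = tile_id]
  summ[, "padj" := p.adjust(p_value, method = "BH")]
  sig <- ifelse(summ$n_rep == 1L, TRUE,
                !is.na(summ$p_value) & summ$p_value < alpha)
  summ[, "class" := ifelse(median_log2_ratio < -threshold & sig, "cytoplasmic",
                    ifelse(median_log2_ratio > threshold & sig, "nuclear",
                           "unclassified"))]
  summ[]
}

#' Two-group rank-sum comparison
#'
#' Two-sided Wilcoxon/Mann-Whitney rank-sum test: exact when both groups
#' have at most 10 observations and there are no ties, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param values Numeric vector.
#' @param labels Vector with exactly two distinct values, same length.
#' @return List with `statistic` (W for the first group) and `p_value`.
#' @export
group_comparison <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  groups <- split(values, labels)
  if (length(groups) != 2L || any(lengths(groups) == 0L)) {
    stop("group_comparison needs exactly two non-empty groups")
  }
  x <- groups[[1]]; y <- groups[[2]]
  exact <- length(x) <= 10L && length(y) <= 10L &&
    !anyDuplicated(c(x, y))
  res <- wilcox.test(x, y, alternative = "two.sided", exact = exact,
                     correct = TRUE)
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' G/C fraction of a sequence
#'
#' @param seq Non-empty DNA/RNA string.
#' @return (#G + #C) / length, in \[0, 1\].
#' @export
gc_content <- function(seq) {
  vapply(seq, function(s) {
    if (is.na(s) || nchar(s) == 0L) stop("gc_content: empty sequence")
    b <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    sum(b %in% c("G", "C")) / length(b)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Spearman correlation of tile localization across contexts
#'
#' Correlates per-tile median log2(Nuc/Cyto) between every pair of contexts
#' over the intersection of quantified tiles.
#'
#' @param tables Named list of per-context summaries (data frames with
#'   `tile_id` and `median_log2_ratio`, as from [call_localized_tiles]).
#' @param min_overlap Minimum shared tiles required for an entry (default 3);
#'   pairs below it get `NA` with a message.
#' @return Symmetric context x context Spearman correlation matrix with unit
#'   diagonal.
#' @export
context_correlation <- function(tables, min_overlap = 3L) {
  stopifnot(length(tables) >= 1, !is.null(names(tables)))
  ctx <- names(tables)
  mat <- matrix(NA_real_, length(ctx), length(ctx), dimnames = list(ctx, ctx))
  diag(mat) <- 1
  for (i in seq_along(ctx)) for (j in seq_along(ctx)) {
    if (j <= i) next
    a <- as.data.table(tables[[i]]); b <- as.data.table(tables[[j]])
    shared <- intersect(a$tile_id, b$tile_id)
    if (length(shared) < min_overlap) {
      message("context_correlation: only ", length(shared),
              " shared tiles between ", ctx[i], " and ", ctx[j],
              "; entry left NA")
      next
    }
    va <- a$median_log2_ratio[match(shared, a$tile_id)]
    vb <- b$median_log2_ratio[match(shared, b$tile_id)]
    mat[i, j] <- mat[j, i] <- cor(va, vb, method = "spearman")
  }
  mat
}
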