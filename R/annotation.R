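IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = "[AG]", Y = "[CT]", S = "[GC]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

normalize_nt <- function(x) gsub("U", "T", toupper(x), fixed = TRUE)

iupac_to_regex <- function(pattern) {
  pattern <- normalize_nt(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_MAP))
  if (length(bad) > 0) {
    stop("invalid IUPAC character(s) in motif: ", paste(unique(bad), collapse = ", "))
  }
  paste(IUPAC_MAP[chars], collapse = "")
}

#' Count motif occurrences in a sequence
#'
#' Scans left to right for matches to an IUPAC consensus or a position
#' weight matrix. In the default non-overlapping mode the scan restarts
#' after the end of each accepted match; overlapping mode counts every
#' matching window. Sequences and consensus patterns are uppercased with U
#' mapped to T before scanning.
#'
#' @param seq DNA/RNA sequence.
#' @param motif IUPAC consensus string, or a 4 x L numeric PWM with rownames
#'   A, C, G, T and columns summing to 1.
#' @param overlapping Count overlapping matches (default FALSE).
#' @param pwm_threshold Minimum log2 odds score (vs uniform background) for
#'   a window to count in PWM mode.
#' @param pwm_prior Pseudo-probability added to PWM cells before log-odds.
#' @return Integer occurrence count.
#' @export
scan_motif <- function(seq, motif, overlapping = FALSE, pwm_threshold = 0,
                       pwm_prior = 1e-3) {
  seq <- normalize_nt(seq)
  if (is.matrix(motif)) {
    stopifnot(nrow(motif) == 4, !is.null(rownames(motif)),
              setequal(rownames(motif), c("A", "C", "G", "T")),
              all(abs(colSums(motif) - 1) < 1e-6))
    L <- ncol(motif)
    n <- nchar(seq)
    if (n < L) return(0L)
    lo <- log2((motif[c("A", "C", "G", "T"), , drop = FALSE] + pwm_prior) /
                 (0.25 + pwm_prior))
    b <- strsplit(seq, "", fixed = TRUE)[[1]]
    row <- match(b, c("A", "C", "G", "T"))
    starts <- seq_len(n - L + 1L)
    scores <- vapply(starts, function(s) {
      r <- row[s:(s + L - 1L)]
      if (anyNA(r)) -Inf else sum(lo[cbind(r, seq_len(L))])
    }, numeric(1))
    hits <- starts[scores >= pwm_threshold]
    if (overlapping) return(length(hits))
    count <- 0L; next_free <- 1L
    for (h in hits) {
      if (h >= next_free) { count <- count + 1L; next_free <- h + L }
    }
    return(count)
  }
  rx <- iupac_to_regex(motif)
  L <- nchar(normalize_nt(motif))
  if (overlapping) {
    n <- nchar(seq)
    if (n < L) return(0L)
    wins <- substring(seq, seq_len(n - L + 1L), L:n)
    return(sum(grepl(paste0("^", rx, "$"), wins)))
  }
  m <- gregexpr(rx, seq)[[1]]
  if (m[1] < 0) 0L else length(m)
}

#' Read eCLIP clusters from a narrowPeak/BED6+ file
#'
#' narrowPeak columns: chrom, start, end (0-based half-open), name, score,
#' strand, signalValue (fold enrichment over input), pValue (-log10), qValue,
#' peak. The returned `p_value` is back-transformed from the -log10 column.
#'
#' @param path Path to a headerless narrowPeak file.
#' @return data.table with `chrom`, `start`, `end`, `name`, `strand`,
#'   `fold`, `p_value`.
#' @export
read_clusters <- function(path) {
  x <- fread(path, header = FALSE)
  if (ncol(x) < 8L) stop("narrowPeak file needs >= 8 columns: ", path)
  data.table(chrom = as.character(x[[1]]), start = x[[2]], end = x[[3]],
             name = as.character(x[[4]]), strand = as.character(x[[6]]),
             fold = x[[7]], p_value = 10^(-x[[8]]))
}

#' Filter eCLIP clusters on significance and enrichment
#'
#' Keeps clusters with P below `p_max` and fold enrichment over the input
#' control of at least `min_fold`.
#'
#' @param clusters data.table with `p_value` and `fold` columns.
#' @param p_max Significance cutoff (default 0.01, strict inequality).
#' @param min_fold Minimum fold enrichment (default 2, inclusive).
#' @return The filtered table.
#' @export
filter_clusters <- function(clusters, p_max = 0.01, min_fold = 2) {
  clusters <- as.data.table(clusters)
  clusters[p_value < p_max & fold >= min_fold]
}

#' Count cluster overlaps per feature
#'
#' Strand-aware interval intersection: for each feature, the number of
#' clusters overlapping it by at least one base. Intervals are 0-based
#' half-open; strand "." matches either strand.
#'
#' @param features data.frame with `chrom`, `start`, `end`, optional
#'   `strand` (default "."), and an id column (`tile_id`, `circ_id`, or
#'   `name`).
#' @param clusters Filtered cluster table ([filter_clusters]).
#' @return data.table with the feature id column and `n_clusters`.
#' @export
intersect_clusters <- function(features, clusters) {
  features <- as.data.table(features)
  clusters <- as.data.table(clusters)
  id_col <- intersect(c("tile_id", "circ_id", "name"), names(features))[1]
  if (is.na(id_col)) stop("features need an id column (tile_id/circ_id/name)")
  strand_of <- function(x) {
    s <- if ("strand" %in% names(x)) as.character(x$strand) else
      rep(".", nrow(x))
    s[!s %in% c("+", "-")] <- "*"
    s
  }
  gr_f <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(features$start + 1L, features$end),
    strand = strand_of(features))
  gr_c <- GenomicRanges::GRanges(
    clusters$chrom,
    IRanges::IRanges(clusters$start + 1L, clusters$end),
    strand = strand_of(clusters))
  n <- GenomicRanges::countOverlaps(gr_f, gr_c, minoverlap = 1L,
                                    ignore.strand = FALSE)
  out <- data.table(id = features[[id_col]], n_clusters = as.integer(n))
  data.table::setnames(out, "id", id_col)
  out
}

#' Stratify localization values by an annotation count and compare strata
#'
#' Assigns each feature to a bin of its annotation count (e.g. number of
#' motifs: 0, 1, >1), summarizes each bin, and runs pairwise two-sided
#' rank-sum comparisons between bins.
#'
#' @param values Named numeric vector (e.g. per-tile median log2 ratios) or
#'   a data.frame with an id column and a `median_log2_ratio`/`log2_ratio`
#'   column.
#' @param annotation Named integer vector of per-feature counts (same ids).
#' @param bins Named list of inclusive count ranges, e.g.
#'   `list("0" = c(0, 0), "1" = c(1, 1), ">1" = c(2, Inf))`; must not overlap.
#' @return List with `assignments` (feature, bin, value), `summary` (per-bin
#'   n, median, quartiles), `comparisons` (pairwise bin tests; empty bins
#'   skipped with a message).
#' @export
stratify <- function(values, annotation,
                     bins = list("0" = c(0, 0), "1" = c(1, 1),
                                 ">1" = c(2, Inf))) {
  if (is.data.frame(values)) {
    id_col <- intersect(c("tile_id", "circ_id", "name"), names(values))[1]
    val_col <- intersect(c("median_log2_ratio", "log2_ratio", "value"),
                         names(values))[1]
    values <- setNames(values[[val_col]], values[[id_col]])
  }
  ids <- intersect(names(values), names(annotation))
  ann <- annotation[ids]
  bin_of <- rep(NA_character_, length(ids))
  for (b in names(bins)) {
    bin_of[ann >= bins[[b]][1] & ann <= bins[[b]][2]] <- b
  }
  assignments <- data.table(id = ids, bin = bin_of, value = values[ids])
  summary <- assignments[!is.na(bin_of),
                         list(n = .N, median = median(value),
                              q1 = quantile(value, 0.25),
                              q3 = quantile(value, 0.75)),
                         by = "bin"]
  combos <- utils::combn(names(bins), 2, simplify = FALSE)
  comparisons <- list()
  for (cc in combos) {
    sel <- assignments[bin_of %in% cc]
    if (length(unique(sel$bin)) < 2L) {
      message("stratify: empty bin in comparison ", cc[1], " vs ", cc[2],
              "; skipped")
      next
    }
    gc_res <- group_comparison(sel$value, factor(sel$bin, levels = cc))
    comparisons[[length(comparisons) + 1L]] <-
      data.table(bin_a = cc[1], bin_b = cc[2],
                 statistic = gc_res$statistic, p_value = gc_res$p_value)
  }
  list(assignments = assignments, summary = summary,
       comparisons = if (length(comparisons)) data.table::rbindlist(comparisons)
                     else data.table(bin_a = character(), bin_b = character(),
                                     statistic = numeric(), p_value = numeric()))
}

#' Minimum free energy of a sequence via RNAfold
#'
#' Thin wrapper over the ViennaRNA `RNAfold` binary (default parameters).
#' Returns `NA` with a message when the program is not on the PATH, so the
#' annotation pipeline can continue without the energy column.
#'
#' @param seq DNA/RNA sequence (T is fine; RNAfold treats it as U).
#' @return Minimum free energy in kcal/mol, or `NA_real_` if unavailable.
#' @export
fold_energy <- function(seq) {
  bin <- Sys.which("RNAfold")
  if (!nzchar(bin)) {
    message("RNAfold not found on PATH; folding energy unavailable")
    return(NA_real_)
  }
  out <- suppressWarnings(system2(bin, args = "--noPS", input = seq,
                                  stdout = TRUE, stderr = FALSE))
  line <- grep("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", out, value = TRUE)
  if (length(line) == 0L) return(NA_real_)
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1",
                 line[length(line)]))
}
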