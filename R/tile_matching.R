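#' Matcher configuration
#'
#' Bundles the read-to-tile matching parameters. Defaults are the analysis
#' constants of the assay: the fixed amplicon adapter, mismatches tolerated
#' only at bases with Phred quality >= 35, at most 2 mismatches in the first
#' 15 compared nt ("seed") and 4 overall, and a minimum of 20 reads per tile
#' per sample for downstream ratios. The UMI length is a library-prep choice
#' (not an analysis constant) and defaults to 10 nt.
#'
#' @param adapter Adapter sequence searched for exactly in R1.
#' @param umi_length UMI length preceding the adapter.
#' @param quality_min Minimum Phred quality at which a mismatch is tolerated.
#' @param seed_length Length of the seed region (first compared bases).
#' @param max_seed_mm,max_total_mm Mismatch budgets in seed / overall.
#' @param min_reads Minimum raw reads per tile per sample to enter ratios.
#' @param count_mode `"umi"` collapses reads to distinct UMIs per tile per
#'   sample (amplification-duplicate removal, the default); `"read"` counts
#'   raw reads.
#' @return A `matcher_config` list.
#' @export
matcher_config <- function(adapter = "TAGGAGGCCTCATCTGACTG", umi_length = 10L,
                           quality_min = 35L, seed_length = 15L,
                           max_seed_mm = 2L, max_total_mm = 4L,
                           min_reads = 20L, count_mode = c("umi", "read")) {
  count_mode <- match.arg(count_mode)
  stopifnot(nchar(adapter) > 0, seed_length > 0, max_seed_mm <= max_total_mm,
            umi_length >= 0)
  structure(list(adapter = adapter, umi_length = as.integer(umi_length),
                 quality_min = as.integer(quality_min),
                 seed_length = as.integer(seed_length),
                 max_seed_mm = as.integer(max_seed_mm),
                 max_total_mm = as.integer(max_total_mm),
                 min_reads = as.integer(min_reads), count_mode = count_mode),
            class = "matcher_config")
}

read_sequence <- function(read) {
  if (is.character(read)) read[[1]] else read$sequence
}

#' Find the adapter in a read
#'
#' @param read A read (character sequence, or a list/row with `$sequence`).
#' @param adapter Adapter sequence (exact match, no mismatches).
#' @return 0-based start of the first exact occurrence, or `NA_integer_`.
#' @export
find_adapter <- function(read, adapter) {
  stopifnot(nchar(adapter) > 0)
  pos <- regexpr(adapter, read_sequence(read), fixed = TRUE)
  if (pos < 0) NA_integer_ else as.integer(pos) - 1L
}

#' Extract the UMI preceding the adapter
#'
#' @param read A read (character sequence or list with `$sequence`).
#' @param adapter_pos 0-based adapter start from [find_adapter].
#' @param umi_length UMI length.
#' @return The UMI string, or `NA_character_` if the read is truncated
#'   (`adapter_pos < umi_length`). `umi_length = 0` returns `""`.
#' @export
extract_umi <- function(read, adapter_pos, umi_length) {
  if (is.na(adapter_pos) || adapter_pos < umi_length) return(NA_character_)
  substr(read_sequence(read), adapter_pos - umi_length + 1L, adapter_pos)
}

phred_values <- function(quality) {
  if (is.numeric(quality)) as.integer(quality)
  else as.integer(charToRaw(quality)) - 33L
}

#' Score an insert against one tile sequence
#'
#' Gapless comparison over the overlap (`min` of the two lengths) starting at
#' tile position 0. A candidate is valid iff no mismatch falls on a base with
#' quality below `quality_min`, at most `max_seed_mm` mismatches lie in the
#' first `seed_length` compared bases, and at most `max_total_mm` overall.
#'
#' @param insert Insert sequence (bases after the adapter).
#' @param insert_quals Phred qualities of the insert: integer vector or
#'   Phred+33 string.
#' @param tile_seq Tile sequence.
#' @param cfg A [matcher_config].
#' @return List with `valid`, `seed_mm`, `total_mm`.
#' @export
score_candidate <- function(insert, insert_quals, tile_seq, cfg = matcher_config()) {
  L <- min(nchar(insert), nchar(tile_seq))
  if (L == 0L) return(list(valid = FALSE, seed_mm = 0L, total_mm = 0L))
  a <- strsplit(substr(insert, 1L, L), "", fixed = TRUE)[[1]]
  b <- strsplit(substr(tile_seq, 1L, L), "", fixed = TRUE)[[1]]
  q <- phred_values(insert_quals)[seq_len(L)]
  mm <- which(a != b)
  seed_mm <- sum(mm <= cfg$seed_length)
  total_mm <- length(mm)
  valid <- !any(q[mm] < cfg$quality_min) &&
    seed_mm <= cfg$max_seed_mm && total_mm <= cfg$max_total_mm
  list(valid = valid, seed_mm = as.integer(seed_mm),
       total_mm = as.integer(total_mm))
}

#' Match one read against a tile library
#'
#' Locates the adapter, extracts the UMI and insert, scores the insert
#' against every tile and returns the unique minimum-mismatch tile. Ties at
#' the minimum are discarded as `ambiguous`; reads with no valid candidate
#' are `unmatched`; reads without the adapter (or with a truncated UMI) are
#' `no_adapter`.
#'
#' @param read A read: character sequence, or list with `sequence` and
#'   `quality` (Phred+33 string or integer vector).
#' @param library A `tile_library`.
#' @param cfg A [matcher_config].
#' @return List with `status` (one of matched/no_adapter/unmatched/ambiguous),
#'   `tile_id`, `umi`, `seed_mm`, `total_mm`.
#' @export
match_read <- function(read, library, cfg = matcher_config()) {
  stopifnot(nrow(library) > 0)
  seq <- read_sequence(read)
  qual <- if (is.list(read) && !is.null(read$quality)) read$quality
          else strrep(rawToChar(as.raw(74L)), nchar(seq))
  if (is.numeric(qual)) qual <- rawToChar(as.raw(as.integer(qual) + 33L))
  pos <- find_adapter(seq, cfg$adapter)
  umi <- extract_umi(seq, pos, cfg$umi_length)
  if (is.na(pos) || is.na(umi)) {
    return(list(status = "no_adapter", tile_id = NA_character_,
                umi = NA_character_, seed_mm = NA_integer_,
                total_mm = NA_integer_))
  }
  from <- pos + nchar(cfg$adapter) + 1L
  insert <- substr(seq, from, nchar(seq))
  iq <- substr(qual, from, nchar(qual))
  res <- cpp_match_inserts(insert, iq, library$sequence, cfg$seed_length,
                           cfg$max_seed_mm, cfg$max_total_mm, cfg$quality_min)
  status <- c("matched", "unmatched", "ambiguous")[res$status[1]]
  list(status = status,
       tile_id = if (status == "matched") library$tile_id[res$tile[1]]
                 else NA_character_,
       umi = umi, seed_mm = res$seed_mm[1], total_mm = res$total_mm[1])
}

#' Count reads (or UMIs) per tile for one sample
#'
#' Runs the full matching procedure over a FASTQ file or in-memory read
#' table and tallies matched reads per tile, collapsing to distinct UMIs
#' when `cfg$count_mode == "umi"`.
#'
#' @param reads FASTQ path or a data.table with `sequence` and `quality`.
#' @param library A `tile_library`.
#' @param cfg A [matcher_config].
#' @param sample_id Sample label recorded in the stats.
#' @return List with `counts` (named integer vector over all library tiles)
#'   and `stats` (one-row data.table: total, matched, no_adapter, unmatched,
#'   ambiguous). The four status counts always sum to `total`.
#' @export
count_tiles <- function(reads, library, cfg = matcher_config(),
                        sample_id = "sample") {
  if (is.character(reads)) reads <- read_fastq(reads)
  reads <- as.data.table(reads)
  n_total <- nrow(reads)

  pos0 <- regexpr(cfg$adapter, reads$sequence, fixed = TRUE)
  has_adapter <- pos0 > 0 & (pos0 - 1L) >= cfg$umi_length
  status <- rep("no_adapter", n_total)

  idx <- which(has_adapter)
  tile <- rep(NA_character_, n_total)
  umi <- rep(NA_character_, n_total)
  if (length(idx) > 0) {
    p <- as.integer(pos0[idx])
    umi[idx] <- substr(reads$sequence[idx], p - cfg$umi_length, p - 1L)
    from <- p + nchar(cfg$adapter)
    insert <- substr(reads$sequence[idx], from, nchar(reads$sequence[idx]))
    iq <- substr(reads$quality[idx], from, nchar(reads$quality[idx]))
    res <- cpp_match_inserts(insert, iq, library$sequence, cfg$seed_length,
                             cfg$max_seed_mm, cfg$max_total_mm,
                             cfg$quality_min)
    status[idx] <- c("matched", "unmatched", "ambiguous")[res$status]
    ok <- which(status[idx] == "matched")
    tile[idx[ok]] <- library$tile_id[res$tile[ok]]
  }

  hits <- data.table(tile_id = tile[status == "matched"],
                     umi = umi[status == "matched"])
  per_tile <- if (cfg$count_mode == "umi") {
    hits[, list(n = data.table::uniqueN(umi)), by = tile_id]
  } else {
    hits[, list(n = .N), by = tile_id]
  }
  counts <- setNames(integer(nrow(library)), library$tile_id)
  counts[per_tile$tile_id] <- per_tile$n

  stats <- data.table(
    sample_id = sample_id, total = n_total,
    matched = sum(status == "matched"),
    no_adapter = sum(status == "no_adapter"),
    unmatched = sum(status == "unmatched"),
    ambiguous = sum(status == "ambiguous")
  )
  list(counts = counts, stats = stats)
}

#' Build a tile x sample count matrix from several read sets
#'
#' @param read_sets Named list of FASTQ paths or read tables (names become
#'   sample ids).
#' @param library A `tile_library`.
#' @param cfg A [matcher_config].
#' @return List with `counts` (tile x sample integer matrix) and `stats`
#'   (per-sample status totals).
#' @export
build_count_matrix <- function(read_sets, library, cfg = matcher_config()) {
  stopifnot(length(read_sets) > 0, !is.null(names(read_sets)))
  res <- lapply(names(read_sets), function(s) {
    count_tiles(read_sets[[s]], library, cfg, sample_id = s)
  })
  counts <- do.call(cbind, lapply(res, `[[`, "counts"))
  colnames(counts) <- names(read_sets)
  list(counts = counts, stats = data.table::rbindlist(lapply(res, `[[`, "stats")))
}
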