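# Independent brute-force oracles and tiny fixture builders, written without
# reusing the package's matching/scoring code paths.

ADAPTER <- "TAGGAGGCCTCATCTGACTG"

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

phred_string <- function(q) rawToChar(as.raw(as.integer(q) + 33L))

# assemble a synthetic R1 read by hand
make_read <- function(insert, umi = "ACGTACGTAT", adapter = ADAPTER,
                      qual = NULL) {
  seq <- paste0(umi, adapter, insert)
  if (is.null(qual)) qual <- phred_string(rep(40L, nchar(seq)))
  list(sequence = seq, quality = qual)
}

# reference scorer: character-by-character, no shortcuts
oracle_score <- function(insert, quals, tile, seed_len = 15, max_seed = 2,
                         max_total = 4, qual_min = 35) {
  L <- min(nchar(insert), nchar(tile))
  if (L == 0) return(list(valid = FALSE, seed = 0, total = 0))
  seed_mm <- 0; total_mm <- 0; low_q_mm <- FALSE
  q <- as.integer(charToRaw(quals)) - 33L
  for (i in seq_len(L)) {
    if (substr(insert, i, i) != substr(tile, i, i)) {
      total_mm <- total_mm + 1
      if (i <= seed_len) seed_mm <- seed_mm + 1
      if (q[i] < qual_min) low_q_mm <- TRUE
    }
  }
  list(valid = !low_q_mm && seed_mm <= max_seed && total_mm <= max_total,
       seed = seed_mm, total = total_mm)
}

# exhaustive matcher: score every tile, pick the unique argmin
oracle_match <- function(read, library, cfg = matcher_config()) {
  pos <- regexpr(cfg$adapter, read$sequence, fixed = TRUE)
  if (pos < 0 || pos - 1L < cfg$umi_length) return("no_adapter")
  from <- pos + nchar(cfg$adapter)
  insert <- substr(read$sequence, from, nchar(read$sequence))
  iq <- substr(read$quality, from, nchar(read$quality))
  res <- lapply(library$sequence, function(tile)
    oracle_score(insert, iq, tile, cfg$seed_length, cfg$max_seed_mm,
                 cfg$max_total_mm, cfg$quality_min))
  valid <- vapply(res, `[[`, logical(1), "valid")
  if (!any(valid)) return("unmatched")
  totals <- vapply(res, `[[`, numeric(1), "total")[valid]
  ids <- library$tile_id[valid]
  best <- which(totals == min(totals))
  if (length(best) > 1) "ambiguous" else paste0("matched:", ids[best])
}

# exhaustive two-sided rank-sum P, enumerating every group-label assignment
oracle_wilcoxon_p <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  ranks <- rank(all_v)
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(all_v), n1)
  w_all <- apply(combos, 2, function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

make_junction_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  write_chimeric(rows, path)
  path
}

junction_row <- function(chrom = "chr1", donor = 3000L, acceptor = 1001L,
                         strand = "+", chrom2 = chrom, strand2 = strand,
                         type = 1L, name = "pair1", sample = "s1") {
  data.table::data.table(sample_id = sample, chrom_donor = chrom,
                         pos_donor = donor, strand_donor = strand,
                         chrom_acceptor = chrom2, pos_acceptor = acceptor,
                         strand_acceptor = strand2, junction_type = type,
                         repeat_left = 0L, repeat_right = 0L, read_name = name)
}

make_circ_annotation <- function(n = 3, chrom = "chr1", strand = "+") {
  tilefate:::as_circ_annotation(data.frame(
    circ_id = paste0("circ_", seq_len(n)),
    chrom = chrom,
    start = seq(1000L, by = 10000L, length.out = n),
    end = seq(3000L, by = 10000L, length.out = n),
    strand = strand,
    exon_count = 2L,
    mature_length = 2000L
  ))
}
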