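#' Read circRNA annotations (BED6+ with exon count and mature length)
#'
#' Columns: chrom, start, end (0-based half-open genomic span of the mature
#' circle), circ_id, score (ignored), strand, exon_count, mature_length.
#'
#' @param path Path to a tab-separated BED6+2 file (no header).
#' @return A `circ_annotation` data.table.
#' @export
read_circ_annotation <- function(path) {
  ann <- fread(path, header = FALSE,
               col.names = c("chrom", "start", "end", "circ_id", "score",
                             "strand", "exon_count", "mature_length"))
  as_circ_annotation(ann[, c("circ_id", "chrom", "start", "end", "strand",
                             "exon_count", "mature_length"), with = FALSE])
}

as_circ_annotation <- function(x) {
  x <- as.data.table(x)
  stopifnot(all(c("circ_id", "chrom", "start", "end", "strand",
                  "exon_count", "mature_length") %in% names(x)),
            all(x$start < x$end), all(x$exon_count >= 1),
            all(x$mature_length >= 1))
  if (anyDuplicated(x$circ_id)) stop("duplicated circRNA ids in annotation")
  class(x) <- c("circ_annotation", class(x))
  x
}

#' Parse chimeric junction records
#'
#' Reads the tab-separated chimeric-junction dialect (headerless; columns
#' chrom/pos/strand of donor, chrom/pos/strand of acceptor, junction type,
#' repeat lengths, read name, ...). Retains same-chromosome, strand-concordant
#' records with junction type >= 0; inter-chromosomal (translocation),
#' strand-discordant, and negative-type (non-chimeric/encompassing) records
#' are dropped and their counts reported in the `dropped` attribute.
#'
#' @param path Path to the junction TSV.
#' @return data.table of retained `junction_record` rows (`chrom`,
#'   `pos_donor`, `pos_acceptor`, `strand`, `read_name`) with attribute
#'   `dropped` (named counts by reason).
#' @export
parse_chimeric <- function(path) {
  raw <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(raw) < 10L) {
    stop("malformed junction file ", path, ": expected >= 10 columns, got ",
         ncol(raw))
  }
  data.table::setnames(raw, 1:10,
    c("chrom_donor", "pos_donor", "strand_donor", "chrom_acceptor",
      "pos_acceptor", "strand_acceptor", "junction_type", "repeat_left",
      "repeat_right", "read_name"))
  bad <- which(is.na(raw$pos_donor) | is.na(raw$pos_acceptor) |
                 raw$pos_donor < 1 | raw$pos_acceptor < 1)
  if (length(bad) > 0) stop("malformed junction record at line ", bad[1],
                            " of ", path)
  inter <- raw$chrom_donor != raw$chrom_acceptor
  discord <- !inter & raw$strand_donor != raw$strand_acceptor
  nonchim <- !inter & !discord & raw$junction_type < 0
  keep <- !(inter | discord | nonchim)
  out <- raw[keep, list(chrom = chrom_donor, pos_donor, pos_acceptor,
                        strand = strand_donor, read_name)]
  attr(out, "dropped") <- c(interchromosomal = sum(inter),
                            strand_discordant = sum(discord),
                            nonchimeric_type = sum(nonchim))
  out
}

#' Assign junction records to annotated circRNAs with boundary tolerance
#'
#' A record supports a circRNA when, on a matching chromosome and strand
#' (record strand "." matches either), its donor and acceptor are each
#' within `tolerance` nt of the circle's two back-splice boundaries (either
#' boundary orientation is accepted). A record within tolerance of several
#' annotations is assigned to the one with the smallest summed boundary
#' distance; exact ties are counted for every tied annotation and flagged.
#'
#' @param records Parsed junction records (see [parse_chimeric]); an
#'   optional `sample_id` column splits counts by sample.
#' @param annotations A `circ_annotation`.
#' @param tolerance Maximum per-boundary distance in nt (default 5).
#' @return A `circ_counts` list: `counts` (circRNA x sample matrix),
#'   `assignment` (per-record class: assigned / unmatched), `ties` (number
#'   of tie-flagged records).
#' @export
assign_junctions <- function(records, annotations, tolerance = 5L) {
  records <- as.data.table(records)
  if (!"chrom" %in% names(records) && "chrom_donor" %in% names(records)) {
    # raw junction-dialect columns: keep same-chromosome, concordant records
    records <- records[chrom_donor == chrom_acceptor &
                         strand_donor == strand_acceptor]
    records <- records[, c(list(chrom = chrom_donor, strand = strand_donor),
                           .SD),
                       .SDcols = intersect(c("pos_donor", "pos_acceptor",
                                             "read_name", "sample_id"),
                                           names(records))]
  }
  annotations <- as.data.table(annotations)
  if (!"sample_id" %in% names(records)) records$sample_id <- "sample_1"
  samples <- unique(records$sample_id)
  counts <- matrix(0L, nrow(annotations), length(samples),
                   dimnames = list(annotations$circ_id, samples))
  assignment <- rep("unmatched", nrow(records))
  n_ties <- 0L

  # annotated back-splice boundaries in 1-based coordinates
  b_start <- annotations$start + 1L
  b_end <- annotations$end
  for (r in seq_len(nrow(records))) {
    cand <- which(annotations$chrom == records$chrom[r] &
                    (records$strand[r] == "." |
                       annotations$strand == records$strand[r]))
    if (length(cand) == 0L) next
    d_fwd <- abs(records$pos_donor[r] - b_end[cand]) +
      abs(records$pos_acceptor[r] - b_start[cand])
    ok_fwd <- abs(records$pos_donor[r] - b_end[cand]) <= tolerance &
      abs(records$pos_acceptor[r] - b_start[cand]) <= tolerance
    d_rev <- abs(records$pos_donor[r] - b_start[cand]) +
      abs(records$pos_acceptor[r] - b_end[cand])
    ok_rev <- abs(records$pos_donor[r] - b_start[cand]) <= tolerance &
      abs(records$pos_acceptor[r] - b_end[cand]) <= tolerance
    d <- ifelse(ok_fwd & ok_rev, pmin(d_fwd, d_rev),
                ifelse(ok_fwd, d_fwd, ifelse(ok_rev, d_rev, NA_real_)))
    if (all(is.na(d))) next
    best <- which(d == min(d, na.rm = TRUE))
    if (length(best) > 1L) n_ties <- n_ties + 1L
    counts[cand[best], records$sample_id[r]] <-
      counts[cand[best], records$sample_id[r]] + 1L
    assignment[r] <- "assigned"
  }
  structure(list(counts = counts, assignment = assignment, ties = n_ties),
            class = "circ_counts")
}

#' Filter circRNAs on read-pair support and annotation size
#'
#' Keeps circRNAs supported by at least `min_pairs` read pairs in at least
#' one sample, with at most `max_exons` exons and a mature length of at most
#' `max_length` nt.
#'
#' @param counts A `circ_counts` (or bare circRNA x sample matrix).
#' @param annotations A `circ_annotation` covering every counted circRNA.
#' @param min_pairs,max_exons,max_length Filter thresholds (defaults 10, 5,
#'   5000).
#' @return The filtered circRNA x sample count matrix.
#' @export
filter_circs <- function(counts, annotations, min_pairs = 10L, max_exons = 5L,
                         max_length = 5000L) {
  mat <- if (inherits(counts, "circ_counts")) counts$counts else as.matrix(counts)
  annotations <- as.data.table(annotations)
  missing <- setdiff(rownames(mat), annotations$circ_id)
  if (length(missing) > 0) {
    stop("no annotation for counted circRNA(s): ", paste(missing, collapse = ", "))
  }
  ann <- annotations[match(rownames(mat), circ_id)]
  keep <- apply(mat, 1, max) >= min_pairs &
    ann$exon_count <= max_exons & ann$mature_length <= max_length
  mat[keep, , drop = FALSE]
}

#' Per-circRNA log2(Nuc/Cyto) ratios from read-pair counts
#'
#' Applies the same convention as tile ratios: pseudocount 0.5 on raw
#' read-pair counts, per-sample normalization to counts per million, then
#' `log2(nuclear / cytoplasmic)`.
#'
#' @param counts Filtered circRNA x sample count matrix.
#' @param nuclear,cytoplasmic Column names of the two fractions.
#' @param pseudocount Added to raw counts (default 0.5).
#' @return data.table with `circ_id` and `log2_ratio`.
#' @export
circ_ratios <- function(counts, nuclear, cytoplasmic, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  missing <- setdiff(c(nuclear, cytoplasmic), colnames(counts))
  if (length(missing) > 0) stop("fraction sample(s) absent: ",
                                paste(missing, collapse = ", "))
  ratios <- compute_ratios(counts,
                           data.frame(numerator = nuclear,
                                      denominator = cytoplasmic),
                           pseudocount = pseudocount, min_reads = 0L)
  data.table(circ_id = ratios$tile_id, log2_ratio = ratios$log2_ratio)
}
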