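#' Generate a synthetic tile library
#'
#' Draws `n_tiles` distinct random DNA sequences of fixed length whose G/C
#' fraction falls inside `gc_range`. Each tile first receives a target G/C
#' fraction drawn uniformly from the feasible part of `gc_range`, then G/C and
#' A/T bases are placed at random positions.
#'
#' @param n_tiles Number of tiles (>= 1).
#' @param tile_length Tile length in nt (>= 30); the study's libraries used
#'   140 nt and 110 nt tiles.
#' @param gc_range Numeric length-2 vector, allowed G/C fraction per tile.
#' @param seed Integer seed; identical seeds give identical libraries.
#' @return A `tile_library` data.table (`tile_id`, `gene`, `sequence`).
#' @export
generate_tile_library <- function(n_tiles, tile_length, gc_range = c(0.25, 0.75),
                                  seed = 1L) {
  stopifnot(n_tiles >= 1, tile_length >= 30, length(gc_range) == 2,
            gc_range[1] <= gc_range[2], gc_range[1] >= 0, gc_range[2] <= 1)
  g_lo <- ceiling(gc_range[1] * tile_length - 1e-9)
  g_hi <- floor(gc_range[2] * tile_length + 1e-9)
  if (g_lo > g_hi) {
    stop("gc_range [", gc_range[1], ", ", gc_range[2],
         "] admits no integer G/C count at tile_length ", tile_length)
  }
  set.seed(seed)
  seqs <- character(0)
  for (attempt in 1:50) {
    need <- n_tiles - length(seqs)
    if (need == 0L) break
    new <- vapply(seq_len(need), function(i) {
      g <- if (g_lo == g_hi) g_lo else sample(g_lo:g_hi, 1L)
      bases <- c(sample(c("G", "C"), g, replace = TRUE),
                 sample(c("A", "T"), tile_length - g, replace = TRUE))
      paste(sample(bases), collapse = "")
    }, character(1))
    seqs <- unique(c(seqs, new))
  }
  if (length(seqs) < n_tiles) {
    stop("could not generate ", n_tiles, " unique tiles; sequence space too small")
  }
  as_tile_library(data.table(
    tile_id = sprintf("tile_%04d", seq_len(n_tiles)),
    gene = sprintf("gene_%02d", (seq_len(n_tiles) - 1L) %% 10L + 1L),
    sequence = seqs[seq_len(n_tiles)]
  ))
}

#' Simulate amplicon R1 reads with UMIs and known localization shifts
#'
#' Each read is `[UMI][adapter][tile insert]` with per-base substitution
#' errors at `error_rate` and Phred qualities drawn from a truncated normal.
#' Per tile and sample, the number of reads is Poisson with expectation
#' `depth` in cytoplasmic (and any non-nuclear) samples and
#' `depth * 2^shift` in nuclear samples, so the expected Nuc/Cyto count
#' ratio equals `2^shift`.
#'
#' @param library A `tile_library`.
#' @param design Data frame with columns `sample_id` and `fraction`
#'   (`"nuclear"`, `"cytoplasmic"`, or anything else for unshifted samples
#'   such as WCE/input); extra columns are carried through.
#' @param shifts Named numeric vector of true log2(Nuc/Cyto) shifts, one per
#'   tile id in `library` (missing tiles default to 0; unknown ids error).
#' @param depth Expected reads per tile per sample at shift 0.
#' @param adapter Adapter sequence placed between UMI and insert.
#' @param umi_length UMI length in nt.
#' @param error_rate Per-base substitution probability in the insert.
#' @param indel_rate Optional per-base indel probability (default 0); indels
#'   make reads unmatchable by the gapless matcher and exercise the
#'   unmatched-read accounting.
#' @param quality_mean,quality_sd,quality_range Truncated-normal Phred model
#'   (default 37 +/- 4 truncated to \[2, 41\], straddling the Q35 rule).
#' @param seed Integer seed.
#' @param dir If non-NULL, write one FASTQ per sample into `dir` and return
#'   file paths instead of in-memory reads.
#' @return List with `reads` (named list of read tables, or FASTQ paths if
#'   `dir` is given), `design`, and `truth` (the shift vector used).
#' @export
simulate_fragment_reads <- function(library, design, shifts = NULL,
                                    depth = 200,
                                    adapter = "TAGGAGGCCTCATCTGACTG",
                                    umi_length = 10L, error_rate = 0.005,
                                    indel_rate = 0,
                                    quality_mean = 37, quality_sd = 4,
                                    quality_range = c(2L, 41L),
                                    seed = 1L, dir = NULL) {
  stopifnot(nchar(adapter) > 0, error_rate >= 0, error_rate < 0.5,
            umi_length >= 0, depth > 0)
  stopifnot(all(c("sample_id", "fraction") %in% names(design)))
  if (is.null(shifts)) shifts <- setNames(numeric(0), character(0))
  unknown <- setdiff(names(shifts), library$tile_id)
  if (length(unknown) > 0) {
    stop("shifts given for tile ids absent from the library: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  shift_all <- setNames(rep(0, nrow(library)), library$tile_id)
  shift_all[names(shifts)] <- shifts

  set.seed(seed)
  reads <- vector("list", nrow(design))
  names(reads) <- design$sample_id
  for (s in seq_len(nrow(design))) {
    mult <- if (identical(design$fraction[s], "nuclear")) 2^shift_all else
      rep(1, nrow(library))
    n_per_tile <- rpois(nrow(library), depth * mult)
    inserts <- rep(library$sequence, n_per_tile)
    sim <- cpp_simulate_reads(inserts, adapter, as.integer(umi_length),
                              error_rate, indel_rate,
                              quality_mean, quality_sd,
                              as.integer(quality_range[1]),
                              as.integer(quality_range[2]))
    tab <- data.table(
      id = sprintf("%s:%07d", design$sample_id[s], seq_along(sim$sequence)),
      sequence = sim$sequence, quality = sim$quality
    )
    if (!is.null(dir)) {
      path <- file.path(dir, paste0(design$sample_id[s], ".fastq"))
      write_fastq(tab, path)
      reads[[s]] <- path
    } else {
      reads[[s]] <- tab
    }
  }
  list(reads = reads, design = as.data.table(design), truth = shift_all)
}

#' Simulate a transcription-shutoff decay series with spike-ins
#'
#' Expected tile signal at time `t` is `baseline * 2^(-t / half_life)`,
#' multiplied by a per-sample scale factor that the spike-in rows also carry
#' (so spike normalization is identifiable), with multiplicative lognormal
#' noise of the given coefficient of variation.
#'
#' @param library A `tile_library`.
#' @param half_lives Named numeric vector of true half-lives (hours, > 0),
#'   one per tile.
#' @param timepoints Hours after transcription shutoff; must include 0.
#' @param replicates Replicate samples per timepoint.
#' @param spike_levels Named numeric vector of spike-in species and their
#'   input levels; defaults emulate two spikes added at a 10:1 ratio.
#' @param scale_factors Optional named per-sample scale factors; defaults to
#'   lognormal draws (sdlog 0.3) to mimic varying recovery per sample.
#' @param noise_cv Lognormal noise CV (>= 0); 0 gives exact expectations.
#' @param baseline Expected tile signal at t = 0 before scaling.
#' @param seed Integer seed.
#' @return List with `counts` (tiles + spikes x samples matrix), `samples`
#'   (sample_id, timepoint, replicate), `spike_ids`, `half_lives`.
#' @export
simulate_decay_series <- function(library, half_lives,
                                  timepoints = c(0, 2, 4, 8), replicates = 1L,
                                  spike_levels = c(spike_rluc_hi = 1000,
                                                   spike_rluc_lo = 100),
                                  scale_factors = NULL, noise_cv = 0.1,
                                  baseline = 1000, seed = 1L) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  stopifnot(0 %in% timepoints, all(half_lives > 0),
            setequal(names(half_lives), library$tile_id))
  set.seed(seed)
  samples <- data.table(
    timepoint = rep(timepoints, each = replicates),
    replicate = rep(seq_len(replicates), length(timepoints))
  )
  samples[, sample_id := sprintf("t%g_rep%d", timepoint, replicate)]
  if (is.null(scale_factors)) {
    scale_factors <- setNames(rlnorm(nrow(samples), 0, 0.3), samples$sample_id)
  }
  stopifnot(all(samples$sample_id %in% names(scale_factors)))

  hl <- half_lives[library$tile_id]
  expected <- outer(seq_len(nrow(library)), seq_len(nrow(samples)),
                    function(i, j) baseline * 2^(-samples$timepoint[j] / hl[i]))
  expected <- rbind(expected,
                    matrix(rep(spike_levels, nrow(samples)),
                           nrow = length(spike_levels)))
  expected <- sweep(expected, 2, scale_factors[samples$sample_id], `*`)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    expected <- expected * matrix(
      rlnorm(length(expected), -sdlog^2 / 2, sdlog), nrow = nrow(expected))
  }
  rownames(expected) <- c(library$tile_id, names(spike_levels))
  colnames(expected) <- samples$sample_id
  list(counts = expected, samples = samples,
       spike_ids = names(spike_levels), half_lives = half_lives)
}

#' Simulate chimeric back-splice junction records
#'
#' Emits read-pair records in the tab-separated chimeric-junction dialect
#' whose donor/acceptor coordinates are the annotated back-splice boundaries
#' plus integer jitter; per-circRNA record counts are Poisson around the
#' requested abundance.
#'
#' @param annotations `circ_annotation` table (see [read_circ_annotation]).
#' @param abundance Named numeric vector (one sample) or circRNA x sample
#'   matrix of expected read pairs; names/rownames must be annotated ids.
#' @param jitter_sd SD (nt) of the rounded-normal coordinate jitter (>= 0).
#' @param offset If non-NULL, a fixed integer offset applied to both
#'   boundaries instead of random jitter (for boundary-tolerance checks).
#' @param seed Integer seed.
#' @return A data.table of junction records with a `sample_id` column; use
#'   [write_chimeric] to serialize per sample.
#' @export
simulate_chimeric_junctions <- function(annotations, abundance, jitter_sd = 1,
                                        offset = NULL, seed = 1L) {
  stopifnot(jitter_sd >= 0)
  if (is.null(dim(abundance))) {
    abundance <- matrix(abundance, ncol = 1,
                        dimnames = list(names(abundance), "sample_1"))
  }
  unknown <- setdiff(rownames(abundance), annotations$circ_id)
  if (length(unknown) > 0) stop("abundance for unannotated circRNAs: ",
                                paste(unknown, collapse = ", "))
  set.seed(seed)
  ann <- as.data.table(annotations)[match(rownames(abundance), circ_id)]
  out <- list()
  for (s in colnames(abundance)) {
    n <- rpois(nrow(ann), abundance[, s])
    idx <- rep(seq_len(nrow(ann)), n)
    if (length(idx) == 0L) next
    jit <- function(k) {
      if (!is.null(offset)) rep(as.integer(offset), k)
      else as.integer(round(rnorm(k, 0, jitter_sd)))
    }
    # back-splice: on '+' the donor is the circle's 3' genomic end,
    # the acceptor its 5' start; reversed on '-'
    end1 <- ann$end[idx]                 # 1-based last base of [start,end)
    start1 <- ann$start[idx] + 1L
    plus <- ann$strand[idx] != "-"
    donor <- ifelse(plus, end1, start1) + jit(length(idx))
    acceptor <- ifelse(plus, start1, end1) + jit(length(idx))
    out[[s]] <- data.table(
      sample_id = s,
      chrom_donor = ann$chrom[idx],
      pos_donor = donor,
      strand_donor = ann$strand[idx],
      chrom_acceptor = ann$chrom[idx],
      pos_acceptor = acceptor,
      strand_acceptor = ann$strand[idx],
      junction_type = 1L, repeat_left = 0L, repeat_right = 0L,
      read_name = sprintf("%s:pair%06d", s, seq_along(idx))
    )
  }
  if (length(out) == 0L) {
    return(data.table(sample_id = character(), chrom_donor = character(),
                      pos_donor = integer(), strand_donor = character(),
                      chrom_acceptor = character(), pos_acceptor = integer(),
                      strand_acceptor = character(), junction_type = integer(),
                      repeat_left = integer(), repeat_right = integer(),
                      read_name = character()))
  }
  data.table::rbindlist(out)
}

#' Write junction records in the chimeric-junction TSV dialect
#'
#' @param junctions Output of [simulate_chimeric_junctions] (one sample).
#' @param path Output path (headerless TSV, one row per read pair).
#' @return `path`, invisibly.
#' @export
write_chimeric <- function(junctions, path) {
  cols <- c("chrom_donor", "pos_donor", "strand_donor", "chrom_acceptor",
            "pos_acceptor", "strand_acceptor", "junction_type",
            "repeat_left", "repeat_right", "read_name")
  fwrite(as.data.table(junctions)[, cols, with = FALSE], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}
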